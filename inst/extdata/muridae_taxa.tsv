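subfamily	tribe	genus	species	sequence_source
Murinae	Apodemyini	Apodemus	Apodemus agrarius	OZ030007
Murinae	Apodemyini	Apodemus	Apodemus sylvaticus	XM_052180919 (NC_067475)
Murinae	Apodemyini	Tokudaia	Tokudaia muenninki	BTHS01000002
Murinae	Apodemyini	Tokudaia	Tokudaia osimensis	BPMZ01000917
Murinae	Apodemyini	Tokudaia	Tokudaia tokunoshimensis	BTHU01000003
Murinae	Arvicanthini	Arvicanthis	Arvicanthis niloticus	XM_034500638 (NC_047661)
Murinae	Arvicanthini	Dasymys	Dasymys incomtus	Sequence obtained in this study
Murinae	Arvicanthini	Dasymys	Dasymys rufulus	Sequence obtained in this study
Murinae	Arvicanthini	Grammomys	Grammomys dolichurus	JADRCF010501649
Murinae	Arvicanthini	Grammomys	Grammomys surdaster	XM_028755672 (NW_021620880)
Murinae	Arvicanthini	Lemniscomys	Lemniscomys zebra	Sequence obtained in this study
Murinae	Arvicanthini	Rhabdomys	Rhabdomys dilectus	JADRCG010009874
Murinae	Arvicanthini	Rhabdomys	Rhabdomys pumilio	JANHMN010000001
Murinae	Hydromyini	Conilurus	Conilurus penicilatus	Sequence obtained in this study
Murinae	Hydromyini	Pseudomys	Pseudomys australis	Sequence obtained in this study
Murinae	Hydromyini	Rhynchomys	Rhynchomys soricoides	JADRCH010007518
Murinae	Hydromyini	Uromys	Uromys caudimaculatus	CM052704
Murinae	Millardini	Millardia	Millardia meltada	Sequence obtained in this study
Murinae	Murini	Mus	Mus caroli	XM_021159142 (NC_034572)
Murinae	Murini	Mus	Mus minutoides	LR750027
Murinae	Murini	Mus	Mus musculus	NM_007696 (ENSMUSG00000074340)
Murinae	Murini	Mus	Mus pahari	XM_021197069 (NC_034593)
Murinae	Murini	Mus	Mus spicilegus	ENSMSIT00000008008 (MUSP714)
Murinae	Murini	Mus	Mus spretus	T0062152 (SPRETEiJ)
Murinae	Otomyini	Myotomys	Myotomys unisulcatus	Sequence obtained in this study
Murinae	Otomyini	Parotomys	Parotomys brantsii	Sequence obtained in this study
Murinae	Praomyini	Mastomys	Mastomys coucha	XM_031376141 (NW_022196898)
Murinae	Praomyini	Myomyscus	Myomyscus brockmani	Sequence obtained in this study
Murinae	Praomyini	Praomys	Praomys rostratus	Sequence obtained in this study
Murinae	Rattini	Bandicota	Bandicota bengalensis	Sequence obtained in this study
Murinae	Rattini	Berylmys	Berylmys bowersi	Sequence obtained in this study
Murinae	Rattini	Bunomys	Bunomys chrysocomus	Sequence obtained in this study
Murinae	Rattini	Chryromyscus	Chriromyscus chiropus	Sequence obtained in this study
Murinae	Rattini	Diplothrix	Diplothrix legata	Sequence obtained in this study
Murinae	Rattini	Leopoldamys	Leopoldamys edwardsi	Sequence obtained in this study
Murinae	Rattini	Maxomys	Maxomys surifer	Sequence obtained in this study
Murinae	Rattini	Micromys	Micromys minutus	OZ004784
Murinae	Rattini	Niviventer	Niviventer confucianus	Sequence obtained in this study
Murinae	Rattini	Rattus	Rattus exulans	Sequence obtained in this study
Murinae	Rattini	Rattus	Rattus norvegicus	Rnor_6.0 (chromosome 2)
Murinae	Rattini	Rattus	Rattus rattus	NC_046156
Murinae	Rattini	Rattus	Rattus tanezumi	Sequence obtained in this study
Deomyinae		Acomys	Acomys cahirinus	CM057038
Deomyinae		Acomys	Acomys russatus	LR87723
Gerbillinae		Meriones	Meriones unguiculatus	XM_021658779
Gerbillinae		Pachyuromys	Pachyuromys duprasi	CM053744
Gerbillinae		Psammomys	Psammomys obesus	XM_055628096
Gerbillinae		Rhombomys	Rhombomys opimus	REGO01000051
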