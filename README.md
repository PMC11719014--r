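# pseudoscan

Pseudogene screening of multi-species coding alignments, Dollo-parsimony
gene-loss mapping, and the two companion computations of oviduct
gene-expression studies: 2^−ΔΔCt relative quantification and
peptide-to-protein span mapping.

## The problem

When a gene dies in one lineage, its corpse keeps evolving in the genome.
Comparative surveys detect this by aligning the locus across many species
against one functional reference and asking, species by species, whether
the reading frame still encodes a protein. Three classes of disabling
mutation settle the question: loss of the ATG initiation codon, frameshift
indels (length ≢ 0 mod 3), and premature stop codons (in-frame TAA/TAG/TGA
before the reference terminal stop). Because partial sequences, `N` bases
and IUPAC ambiguity codes are everywhere in such data, the screen must
separate *forced* lesions (every resolution of the codon disrupts) from
*possible* ones, and unsequenced gaps from genuine deletions. The
per-species calls are then placed on the species tree under Dollo parsimony
— the gene is gained once and only ever lost — giving statements of the
form "the loss occurred after the divergence of X".

`pseudoscan` implements this pipeline for murine-style data: a gapped
nucleotide FASTA alignment with a designated functional reference row, a
BED-like exon annotation of the reference, and a Newick species tree. The
package is tidyverse-native: every stage takes and returns tibbles, fitted
objects have broom-style `tidy()`/`glance()` methods, and each result type
has a ggplot2 `autoplot()`.

## The model in brief

* **Coding map.** Exon intervals on the ungapped reference are projected
  into alignment columns; reference-gap columns inside exons (insertions in
  other taxa) are kept but carry no reference coordinate. The frame is
  anchored at the reference start codon; positions are 1-based nucleotide
  coordinates in the concatenated exonic reference.
* **Frame walk.** Each taxon is read in its *own* frame: the cumulative
  indel offset (insertions − deletions, mod 3) shifts the codon grouping of
  its ungapped exonic bases. Maximal leading/trailing gap runs are treated
  as unsequenced (excluded from codons, indels and coverage); internal runs
  ≥ `unsequenced_run_min` count as unsequenced only when they abut a
  supplied amplicon boundary.
* **Calls.** `pseudogenized` ⇔ at least one forced lesion; `intact`
  requires zero forced-or-possible lesions *and* determinate-base coverage
  ≥ `coverage_threshold` (default 0.5); everything else is
  `indeterminate`.
* **Dollo losses.** The minimal set of branches covering every
  pseudogenized tip exactly once while excluding all intact tips;
  indeterminate tips are free. Ties go to the deepest consistent branch
  (configurable to shallowest).
* **ΔΔCt.** Replicate Cts are averaged per sample/gene; ΔCt = Ct(target) −
  Ct(reference) per sample; ΔΔCt = mean ΔCt(test) − mean ΔCt(control);
  fold change = 2^−ΔΔCt, with a two-sided Welch test on per-sample ΔCt.
* **Peptides.** Exact, overlap-aware peptide location in protein FASTA
  records (1-based inclusive spans) and per-gene distinct-peptide counts
  across isoforms.

A seeded synthetic-data module generates the whole study shape — a 6-exon
locus whose exons sum to 626 bp, ~40 taxa, a 10-taxon lesioned clade
carrying the classic lesion catalogue, qPCR tables and peptide sets — with
machine-readable ground truth, so every stage is testable end to end
without downloads.

## Worked example

```r
library(pseudoscan)

fix <- simulate_murinae_fixture(seed = 1)
statuses <- screen_alignment(fix$alignment, "reference", fix$exons)
stop_report(statuses)
#> # A tibble: 10 × 6
#>    taxon            call          coverage start_loss frameshifts       stops
#>  1 rnor_like        pseudogenized    0.992 "1"        "6:1,100:4,251:4" 56, 250, 263, …
#>  2 rexulans_like    pseudogenized    0.994 ""         "100:4,251:4"     111, 120, 189, 243
#>  5 berylmys_like    pseudogenized    0.998 ""         "22:1"            29, 56, 140, …
#>  9 niviventer_like  pseudogenized    1     ""         ""                478
#> 10 chiromyscus_like pseudogenized    1     ""         ""                178
```

The rat-like taxon shows its start-codon loss (`start_loss` at position 1),
the 1-bp deletion at position 6, the shared exon-1 insertion (`100:4`) and
the shared 4-bp deletion at 251, with the stop cascade the shifted frame
produces; the two taxa carrying substitution-only nonsense each show a
single stop and no indel. Mapping the calls onto the species tree:

```r
events <- dollo_losses(fix$tree, statuses)
narrate_losses(events)
#> # A tibble: 1 × 4
#>    node clade                             sister       narrative
#> 1    71 rnor_like, rexulans_like, ...     maxomys_like loss after the divergence of maxomys_like
```

One loss, on the stem of the whole lesioned clade, phrased against the
intact sister lineage. The expression stage:

```r
qp <- make_qpcr_table(seed = 1, effect_log2 = 0, sd_ct = 0.2)
run_panel(qp$records, targets = c("Chia", "Chit1", "Chi3l1", "Chid1"),
          references = c("Actb1", "Hprt1"),
          test_group = "day3", control_group = "postovulatory")
#> # A tibble: 8 × 10
#>   target reference    ddct fold_change statistic    df p_value n_test n_control significant
#> 1 Chia   Actb1     -0.155        1.11     -1.45   3.42  0.232       3         3 FALSE
#> 2 Chia   Hprt1      0.146        0.904     1.51   3.54  0.214       3         3 FALSE
#> ...
```

With no implanted effect, fold changes hover around 1 and the panel is
(up to type-I error) flagged not significant. Peptide mapping:

```r
locate_peptides(c(CHID1 = "MKLALVCGSVHAAQRLD"), "LALVCGSVH")
#> # A tibble: 1 × 5
#>   peptide   protein start   end n_occurrences
#> 1 LALVCGSVH CHID1       3    11             1
```

A command-line wrapper over the same functions lives at
`inst/scripts/pseudoscan.R` (subcommands `simulate`, `screen`, `map-loss`,
`qpcr`, `peptides`, `all`).

## Not in scope

Alignment construction (MUSCLE/SeaView) and tree inference (PhyML/MrBayes)
— alignments and trees are inputs; dN/dS or selection tests; molecular
dating; primer design; MS/MS spectral search and scoring; qPCR primer
efficiency correction.
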