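---
title: "Screening coding alignments for pseudogenization: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening coding alignments for pseudogenization: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pseudoscan)
```

## The screening model

`pseudoscan` decides, per taxon of a gapped nucleotide alignment, whether a
gene still encodes a protein. One row is designated the functional
reference; an exon annotation on the *ungapped* reference defines the
coding region; the frame is anchored at the reference start codon. The
screen looks for three lesion classes:

* **start loss** — the taxon's first codon is not ATG;
* **frameshift indel** — an insertion or deletion relative to the
  reference whose length is not a multiple of 3;
* **premature stop** — a codon, read in the taxon's *own* shifted frame,
  that is a stop (TAA/TAG/TGA) strictly before the reference terminal
  stop.

The central mechanism is the frame walk (`taxon_frame_walk()`): exonic
columns are traversed left to right; every taxon indel changes the
cumulative offset (insertions − deletions, mod 3); the taxon's ungapped
exonic bases are regrouped into codons under that offset. This is what
makes a 1-bp deletion early in exon 1 cascade into stop codons hundreds of
bases downstream, while two indels whose lengths cancel mod 3 silence each
other beyond the second.

### Ambiguity policy

Real survey data carry IUPAC ambiguity codes and `N` runs. The screen is
deliberately conservative: a lesion is `forced` only when *every* IUPAC
resolution of the codon disrupts (e.g. `TRA` resolves to TAA and TGA, both
stops), and `possible` when only some do (e.g. `TRR`). Possible lesions
never flip a taxon to `pseudogenized`; they only block an `intact` call.
Consequently masking bases of an intact taxon with `N` can move it to
`indeterminate` but never to `pseudogenized` — a property the test suite
checks directly. `N` is data-missing, not a gap: it occupies a column and
contributes no indel.

### Unsequenced versus deleted gaps

Alignment gaps conflate two realities: a region that was never sequenced
and a genuine deletion. Survey figures typically annotate both with `-`
and give no per-column disambiguation, so the package uses an explicit,
deterministic rule: a taxon's maximal leading and trailing gap runs over
the exonic projection are *unsequenced* (excluded from codons, indel
accounting and coverage); an internal gap run of at least
`unsequenced_run_min` columns (default 30) is unsequenced only when an
amplicon annotation is supplied and the run abuts an amplicon boundary.
Everything else is a deletion. The premise behind ghost-advancing the
coordinate through unsequenced reference positions is that an unamplified
segment is assumed reference-like in length; a taxon violating that
assumption would need its amplicons declared.

### Position conventions

Reported positions are 1-based *nucleotide* positions of the affected
codon's first base (or of the indel) in the concatenated exonic reference.
Stop-position tables in the survey literature use values that exceed the
codon count of the region and are spaced by multiples of 3 within a fixed
frame, which identifies them as nucleotide, not codon, coordinates.
Columns that are gaps in the reference (insertions carried by other taxa)
do not advance the numbering by default; an insertion is reported at the
reference position immediately preceding it. Whether reference-gap columns
should be counted cannot be settled without the original full alignment
figure, so it is exposed as `count_reference_gap_columns` (default
`FALSE`). On-disk interval formats are 0-based half-open (BED convention);
all human-facing reports are 1-based inclusive.

### Classification

`pseudogenized` ⇔ at least one forced lesion. `intact` requires zero
lesions of either certainty *and* determinate-base coverage (non-N,
non-gap fraction of exonic reference positions) at or above
`coverage_threshold`. The default threshold of 0.5 reflects that partial
amplicons covering roughly half of the analyzed region are still routinely
called in surveys; taxa below it, or carrying only possible lesions, are
`indeterminate` — an honest category for partial sequences in which no
stop was observed. The reference terminal stop codon, when inside the
analyzed region, is excluded from premature-stop calling for every taxon,
by definition. A region whose exonic length is not divisible by 3 keeps
its trailing remainder bases in the annotation but outside any codon, with
a warning.

## Dollo loss mapping

Gene presence is modelled as a Dollo character: one gain at the root,
irreversible losses. `dollo_losses()` finds the minimal set of branches
such that every pseudogenized tip descends from exactly one loss and no
intact tip from any; indeterminate tips are free variables, mirroring how
partial sequences are treated verbally in surveys ("no evidence of a stop
codon"). The minimal solution is computed exactly: maximal clades
containing a pseudogenized tip and no intact tip each receive one loss on
their stem. Among equally minimal placements the default puts each loss on
the *deepest* consistent branch — one early event rather than many tip
losses, matching how such results are narrated — with
`tie_break = "shallow"` (the MRCA of the pseudogenized tips) available for
sensitivity analysis. Minimality is certified in the tests against
exhaustive enumeration over all branch subsets on trees of up to 8 tips.
`narrate_losses()` phrases each event against the sister lineage that
diverged immediately before the loss branch.

## Relative expression (2^−ΔΔCt)

Replicate Cts are arithmetically averaged per sample and gene before any
differencing; ΔCt is target minus reference per sample; ΔΔCt is the test
group's mean ΔCt minus the calibrator group's; the fold change is
2^−ΔΔCt. The calibrator is an explicit argument (`control_group`) because
which oviduct stage calibrates the other is a reporting choice, not a
property of the data. Two endogenous reference genes are analyzed
separately by default — how a study combined its references is rarely
stated — with `combine_refs = "mean"` averaging their per-sample Cts as an
alternative. The group comparison is a two-sided Welch t-test on
per-sample ΔCt values, a standard choice for n = 3 designs; it is
conservative at that sample size (observed type-I ≈ 0.04 at α = 0.05 in
the null simulations), and no replicate-outlier handling is applied.
Primer-efficiency correction and standard curves are out of scope.

## Peptide mapping

`locate_peptides()` reports every exact, overlap-aware occurrence of each
peptide in each protein record as a 1-based inclusive span; matching is
residue-exact (no isoleucine/leucine equivalence) because published span
tables are residue-exact, with `collapse_il = TRUE` available since
mass spectrometry cannot distinguish the two. Multi-isoform proteins get
one row per record, and `summarize_counts()` counts distinct peptides once
per gene regardless of isoform multiplicity.

## What the synthetic generator emulates — and what it does not

`simulate_murinae_fixture()` builds the desk-scale shape of a murine
pseudogene survey: a 6-exon locus whose exons sum to 626 bp (208 complete
codons plus a 2-base remainder), about 40 taxa, and a 10-taxon focal clade
carrying the classic lesion catalogue — an initiation-codon substitution
(ATG→ATA) with a 1-bp deletion at exonic position 6; a shared 4-bp exon-1
insertion and a shared 4-bp deletion at position 251 in exon 3 across a
subgroup; a 1-bp deletion at position 22; substitution-only nonsense;
ambiguity codes; and a masked trailing segment in one partial taxon. The
intact lineages that diverge before the clade make the implanted loss
identifiable, and the generator's truth table is computed by an
*independent* strip-gaps-and-translate oracle over each taxon's mutated
sequence, never by the alignment-column machinery it is used to test.

Non-lesioned taxa receive only stop-avoiding neutral point substitutions
(default rate 0.01 per exonic site, one hit per codon), so they remain
intact by construction. The generator does **not** emulate realistic
substitution models (HKY/GTR), empirically fitted indel length
distributions, alignment error, or heterogeneous coverage along amplicons
— lesions are specified, not evolved. Passing tests therefore demonstrate
that the detector is exact for the lesion classes and data artifacts it
models (including every IUPAC code and masked segments), not that any
particular real alignment is error-free: on real data, alignment quality
around indels remains the analyst's responsibility.

qPCR tables are drawn with per-sample loading offsets (SD 0.5 cycles),
per-gene baselines uniform on 18–28 cycles, triplicate wells with Gaussian
noise (default SD 0.2 cycles — typical SYBR-green replicate scatter), and
three samples per group, matching the common minimal oviduct design.

## Numerical and degenerate-input choices

* Forced/possible stop testing enumerates all ≤ 64 IUPAC resolutions of a
  codon; no probabilistic shortcut.
* Codons are emitted only when all three positions are actually sequenced
  bases; codons truncated by sequence ends, masked segments or the
  trailing remainder are never scanned.
* Reports are deterministic: identical inputs give byte-identical TSVs;
  all generator randomness sits behind explicit seeds.
* Welch tests on essentially constant data (e.g. noiseless simulations)
  return `NA` p-values and are flagged not significant rather than
  erroring.
* Degenerate inputs fail fast with named errors: ragged alignments,
  alphabet violations (with row and column), overlapping exon intervals,
  duplicate tree tips, missing statuses, conflicting lesions.

## Problem sizes used in the checks

The package's own acceptance checks run at sizes chosen to make the
certifications exact yet quick: 500 random lesioned taxa for the
stop-detector oracle equivalence, exhaustive Dollo enumeration on 15
random trees of 4–8 tips, 200 null qPCR panels (1600 tests) for the
type-I rate, 100 simulated panels for 2-fold recovery, and the full
40-taxon fixture for lesion-catalogue recovery. Larger sizes change none
of the qualitative conclusions, as the properties checked are exact
equalities or calibrations.

## Known limitations

* The screen assumes the reference itself is functional and correctly
  annotated; a broken reference poisons every call.
* Frameshift positions are reported relative to the reference frame; in
  `count_reference_gap_columns = TRUE` mode, positions follow alignment
  columns instead and are not comparable across alignments.
* Dollo parsimony cannot distinguish one early loss from several recent
  ones when intervening tips are all indeterminate; the tie-break flag
  only chooses which extreme to report.
* The ΔΔCt model assumes equal amplification efficiency of target and
  reference; efficiency-corrected models are intentionally out of scope.
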