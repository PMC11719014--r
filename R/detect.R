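#' Detect disabling mutations in one taxon
#'
#' Scans a taxon's frame walk for the three classes of lesion that disrupt a
#' protein-coding gene:
#'
#' * `start_loss` — the taxon's first codon cannot be (or may not be) ATG;
#' * `frameshift_indel` — an insertion or deletion relative to the reference
#'   whose length is not a multiple of 3;
#' * `premature_stop` — a codon, read in the taxon's own shifted frame,
#'   whose IUPAC resolutions are stops (TAA/TAG/TGA), strictly before the
#'   reference terminal stop.
#'
#' Ambiguity is handled conservatively: a call is `forced` only when every
#' IUPAC resolution of the codon disrupts; when only some resolutions do,
#' the mutation is emitted with certainty `possible` and can never by itself
#' flip a taxon to pseudogenized. Positions are 1-based first-base positions
#' in the concatenated exonic alignment, anchored to reference coordinates
#' by default (insertions report the reference position immediately
#' preceding them).
#'
#' @inheritParams taxon_frame_walk
#' @return A tibble with columns `kind`, `aln_nt_pos`, `length` (indel
#'   length in bases, `NA` otherwise), `certainty` (`forced` or `possible`)
#'   and `frame_offset_at_site` (cumulative indel offset mod 3), sorted by
#'   position.
#' @export
detect_disabling_mutations <- function(aln, cmap, taxon,
                                       unsequenced_run_min = 30,
                                       amplicons = NULL,
                                       count_reference_gap_columns = FALSE) {
  w <- walk_taxon(aln, cmap, taxon, unsequenced_run_min, amplicons,
                  count_reference_gap_columns)
  empty <- tibble(kind = character(0), aln_nt_pos = integer(0),
                  length = integer(0), certainty = character(0),
                  frame_offset_at_site = integer(0))
  out <- list(empty)

  # start-codon check on the taxon's first emitted codon
  first <- w$codons[w$codons$codon_index == 1L, ]
  if (nrow(first) == 1L) {
    res <- codon_resolutions(first$codon)
    if (!all(res == "ATG")) {
      out <- c(out, list(tibble(
        kind = "start_loss",
        aln_nt_pos = first$aln_nt_pos,
        length = NA_integer_,
        certainty = if (any(res == "ATG")) "possible" else "forced",
        frame_offset_at_site = first$frame_offset
      )))
    }
  }

  # frameshift indels
  fs <- w$indels[w$indels$length %% 3L != 0L, ]
  if (nrow(fs)) {
    out <- c(out, list(tibble(
      kind = "frameshift_indel",
      aln_nt_pos = fs$aln_nt_pos,
      length = fs$length,
      certainty = "forced",
      frame_offset_at_site = fs$frame_offset
    )))
  }

  # premature stops, strictly before the reference terminal stop
  term <- attr(cmap, "terminal_stop_codon")
  term_pos <- if (is.na(term)) Inf else {
    ref_start <- 3L * (term - 1L) + 1L
    if (count_reference_gap_columns) {
      cmap$col_pos[match(ref_start, cmap$ref_pos)]
    } else {
      ref_start
    }
  }
  cod <- w$codons[w$codons$aln_nt_pos < term_pos, ]
  if (nrow(cod)) {
    stops <- cod |>
      mutate(
        forced = map_lgl(.data$codon, is_forced_stop),
        possible = map_lgl(.data$codon, is_possible_stop)
      ) |>
      filter(.data$possible)
    if (nrow(stops)) {
      out <- c(out, list(tibble(
        kind = "premature_stop",
        aln_nt_pos = stops$aln_nt_pos,
        length = NA_integer_,
        certainty = ifelse(stops$forced, "forced", "possible"),
        frame_offset_at_site = stops$frame_offset
      )))
    }
  }

  bind_rows(out) |> arrange(.data$aln_nt_pos, .data$kind)
}

#' Classify one taxon from its mutation list and coverage
#'
#' A taxon is `pseudogenized` when it carries at least one forced disabling
#' mutation; `intact` when it carries no disabling mutation (forced or
#' possible) and its determinate-base coverage of the exonic reference
#' reaches `coverage_threshold`; otherwise `indeterminate`. Possible-only
#' mutation lists therefore yield `indeterminate`, never `pseudogenized`.
#'
#' @param mutations Tibble from [detect_disabling_mutations()].
#' @param coverage Fraction in \[0, 1\] of exonic reference positions at
#'   which the taxon has a determinate (non-N, non-gap) base.
#' @param coverage_threshold Minimum coverage for an `intact` call
#'   (default 0.5).
#' @return A one-row tibble: `call`, `coverage`, `n_forced`, `n_possible`.
#' @export
classify_taxon <- function(mutations, coverage, coverage_threshold = 0.5) {
  stopifnot(coverage >= 0, coverage <= 1)
  n_forced <- sum(mutations$certainty == "forced")
  n_possible <- sum(mutations$certainty == "possible")
  call <- if (n_forced >= 1L) {
    "pseudogenized"
  } else if (n_possible == 0L && coverage >= coverage_threshold) {
    "intact"
  } else {
    "indeterminate"
  }
  tibble(call = call, coverage = coverage,
         n_forced = n_forced, n_possible = n_possible)
}
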