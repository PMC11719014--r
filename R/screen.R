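#' Screen every taxon of an alignment for pseudogenization
#'
#' Runs the full per-taxon analysis — coding-map projection, frame walk,
#' disabling-mutation detection and classification — over all taxa of a
#' gapped alignment, against one designated functional reference.
#'
#' @inheritParams build_coding_map
#' @inheritParams taxon_frame_walk
#' @param coverage_threshold Minimum determinate-base coverage for an
#'   `intact` call (default 0.5).
#' @param taxa Taxa to screen; defaults to every taxon in the alignment
#'   (including the reference, which should come out intact).
#' @return A tibble of class `pseudoscan_screen`, one row per taxon:
#'   `taxon`, `call` (`intact` / `pseudogenized` / `indeterminate`),
#'   `coverage`, `n_forced`, `n_possible` and a list column `mutations`
#'   holding each taxon's [detect_disabling_mutations()] table.
#' @export
#' @examples
#' locus <- make_reference_locus(seed = 1, exon_lengths = c(60, 60))
#' sim <- apply_scenarios(locus, scenarios = list(
#'   clean = list(),
#'   broken = list(lesion_deletion(6, 1))
#' ))
#' screen_alignment(sim$alignment, "reference", locus$exons)
screen_alignment <- function(aln, reference_id, exons,
                             coverage_threshold = 0.5,
                             unsequenced_run_min = 30,
                             amplicons = NULL,
                             count_reference_gap_columns = FALSE,
                             taxa = NULL) {
  cmap <- build_coding_map(aln, reference_id, exons)
  taxa <- taxa %||% aln$taxon
  rows <- purrr::map(taxa, function(tx) {
    w <- walk_taxon(aln, cmap, tx, unsequenced_run_min, amplicons,
                    count_reference_gap_columns)
    muts <- detect_disabling_mutations(aln, cmap, tx, unsequenced_run_min,
                                       amplicons,
                                       count_reference_gap_columns)
    status <- classify_taxon(muts, w$coverage, coverage_threshold)
    mutate(status, taxon = tx, mutations = list(muts))
  })
  out <- bind_rows(rows) |>
    select("taxon", "call", "coverage", "n_forced", "n_possible", "mutations")
  class(out) <- c("pseudoscan_screen", class(out))
  attr(out, "reference_id") <- reference_id
  out
}

#' Tabulate stop positions and lesions per pseudogenized taxon
#'
#' Flattens a screening result into the reporting convention used for
#' pseudogene surveys: one row per pseudogenized taxon, with the forced
#' premature-stop positions comma-joined in ascending order, and separate
#' columns for start-codon loss and frameshift indels (`pos:len` pairs).
#'
#' @param statuses Result of [screen_alignment()].
#' @param all_taxa If `TRUE`, include intact and indeterminate taxa as well
#'   (their lesion columns are empty strings). Default `FALSE`.
#' @return A tibble with columns `taxon`, `call`, `coverage`, `start_loss`,
#'   `frameshifts` and `stops`.
#' @export
stop_report <- function(statuses, all_taxa = FALSE) {
  stopifnot(nrow(statuses) >= 1)
  rows <- purrr::map2(statuses$taxon, statuses$mutations, function(tx, m) {
    forced <- m[m$certainty == "forced", ]
    stops <- sort(forced$aln_nt_pos[forced$kind == "premature_stop"])
    fs <- forced[forced$kind == "frameshift_indel", ]
    fs <- fs[order(fs$aln_nt_pos), ]
    sl <- forced$aln_nt_pos[forced$kind == "start_loss"]
    tibble(
      taxon = tx,
      start_loss = if (length(sl)) as.character(sl[1]) else "",
      frameshifts = paste(sprintf("%d:%d", fs$aln_nt_pos, fs$length),
                          collapse = ","),
      stops = paste(stops, collapse = ", ")
    )
  })
  out <- bind_rows(rows) |>
    left_join(select(tibble::as_tibble(statuses), "taxon", "call",
                     "coverage"),
              by = "taxon") |>
    select("taxon", "call", "coverage", "start_loss", "frameshifts", "stops")
  if (!all_taxa) out <- filter(out, .data$call == "pseudogenized")
  out
}

#' @importFrom rlang %||%
NULL
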