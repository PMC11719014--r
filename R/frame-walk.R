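#' Walk a taxon's reading frame through the exonic alignment
#'
#' Traverses the exonic columns of the coding map left to right for one
#' taxon, maintaining the cumulative indel offset (insertions relative to
#' the reference minus deletions, mod 3) and emitting the taxon's codons
#' read in its OWN shifted frame over its ungapped exonic bases. Maximal
#' leading and trailing gap runs (and, when an amplicon annotation is
#' supplied, long internal gap runs abutting an amplicon boundary) are
#' treated as unsequenced: they are excluded from codon emission and from
#' indel accounting, on the premise that an unamplified region is assumed to
#' match the reference in length.
#'
#' @param aln Alignment tibble.
#' @param cmap Coding map from [build_coding_map()].
#' @param taxon Taxon identifier.
#' @param unsequenced_run_min Minimum length (columns) for an internal gap
#'   run to be considered unsequenced rather than deleted; only applied when
#'   `amplicons` is given. Default 30.
#' @param amplicons Optional tibble (`label`, `start`, `end`, 0-based
#'   half-open on the concatenated exonic reference) of amplified segments.
#'   Internal gap runs of at least `unsequenced_run_min` columns whose ends
#'   fall next to an amplicon boundary are treated as unsequenced.
#' @param count_reference_gap_columns If `TRUE`, reported positions count
#'   every exonic alignment column; by default (`FALSE`) they are anchored
#'   to the reference coordinate system and insertion columns report the
#'   reference position immediately preceding them.
#' @return A tibble with one row per complete, fully sequenced codon of the
#'   taxon: `codon_index` (codon number in the taxon's own frame-shifted
#'   coding sequence), `aln_nt_pos` (1-based reported position of the
#'   codon's first base), `codon` (3-character string, IUPAC codes possible)
#'   and `frame_offset` (cumulative indel offset mod 3 at the codon's first
#'   base).
#' @export
taxon_frame_walk <- function(aln, cmap, taxon, unsequenced_run_min = 30,
                             amplicons = NULL,
                             count_reference_gap_columns = FALSE) {
  walk_taxon(aln, cmap, taxon, unsequenced_run_min, amplicons,
             count_reference_gap_columns)$codons
}

# Full per-column walk shared by taxon_frame_walk() and
# detect_disabling_mutations(). Returns per-column state, emitted codons,
# indel runs and coverage.
walk_taxon <- function(aln, cmap, taxon, unsequenced_run_min = 30,
                       amplicons = NULL,
                       count_reference_gap_columns = FALSE) {
  if (!taxon %in% aln$taxon) {
    abort(paste0("unknown taxon: '", taxon, "'"))
  }
  chars_full <- toupper(strsplit(aln$sequence[aln$taxon == taxon], "",
                                 fixed = TRUE)[[1]])
  ch <- chars_full[cmap$column]
  gap <- ch == "-"
  n <- length(ch)

  unseq <- unsequenced_mask(gap, cmap, unsequenced_run_min, amplicons)

  # classify every exonic column for this taxon
  cls <- rep("base", n)
  cls[gap & !cmap$ref_gap] <- "del"
  cls[!gap & cmap$ref_gap] <- "ins"
  cls[gap & cmap$ref_gap] <- "skip"
  cls[unseq] <- "unseq"

  # taxon CDS coordinate: advances on every taxon base; unsequenced
  # reference positions advance as ghosts (assumed reference-like)
  adv <- (cls %in% c("base", "ins")) | (cls == "unseq" & !cmap$ref_gap)
  cds_pos <- cumsum(adv)

  # cumulative indel offset over the sequenced region
  delta <- integer(n)
  delta[cls == "ins"] <- 1L
  delta[cls == "del"] <- -1L
  offset <- cumsum(delta)

  report_pos <- if (count_reference_gap_columns) cmap$col_pos else
    cmap$report_pos

  # emitted codons: triples of consecutive CDS positions, all three being
  # actual sequenced bases
  is_base <- cls %in% c("base", "ins")
  codons <- tibble(
    codon_index = integer(0), aln_nt_pos = integer(0),
    codon = character(0), frame_offset = integer(0)
  )
  if (any(is_base)) {
    bt <- tibble(
      cds = cds_pos[is_base],
      base = ch[is_base],
      pos = report_pos[is_base],
      off = offset[is_base] %% 3L
    )
    bt$ci <- (bt$cds - 1L) %/% 3L + 1L
    bt$slot <- (bt$cds - 1L) %% 3L + 1L
    codons <- bt |>
      group_by(.data$ci) |>
      summarise(
        complete = n() == 3L && all(sort(.data$slot) == 1:3),
        codon = paste(.data$base, collapse = ""),
        aln_nt_pos = .data$pos[1],
        frame_offset = .data$off[1],
        .groups = "drop"
      ) |>
      filter(.data$complete) |>
      mutate(codon_index = .data$ci) |>
      select("codon_index", "aln_nt_pos", "codon", "frame_offset")
  }

  # indel runs (over columns that carry indel information: drop skip/unseq)
  informative <- which(cls %in% c("base", "del", "ins"))
  indels <- tibble(kind = character(0), aln_nt_pos = integer(0),
                   length = integer(0), frame_offset = integer(0))
  if (length(informative)) {
    icls <- cls[informative]
    r <- rle(icls)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    run_rows <- which(r$values %in% c("del", "ins"))
    if (length(run_rows)) {
      first_row <- informative[starts[run_rows]]
      last_row <- informative[ends[run_rows]]
      indels <- tibble(
        kind = r$values[run_rows],
        aln_nt_pos = as.integer(report_pos[first_row]),
        length = r$lengths[run_rows],
        frame_offset = offset[last_row] %% 3L
      )
    }
  }

  # coverage: determinate (non-N, non-gap) bases over reference exonic
  # positions
  ref_cols <- !cmap$ref_gap
  determinate <- ref_cols & !gap & ch != "N" & cls != "unseq"
  coverage <- sum(determinate) / sum(ref_cols)

  list(
    taxon = taxon,
    columns = tibble(column = cmap$column, char = ch, class = cls,
                     cds_pos = cds_pos, offset = offset %% 3L,
                     report_pos = report_pos),
    codons = codons,
    indels = indels,
    coverage = coverage
  )
}

# leading/trailing (and optionally long internal) gap runs are unsequenced
unsequenced_mask <- function(gap, cmap, unsequenced_run_min, amplicons) {
  n <- length(gap)
  unseq <- rep(FALSE, n)
  if (!any(gap)) return(unseq)
  r <- rle(gap)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  if (r$values[1]) unseq[seq_len(ends[1])] <- TRUE
  if (r$values[length(r$values)]) {
    unseq[starts[length(starts)]:n] <- TRUE
  }
  if (!is.null(amplicons)) {
    bounds <- sort(unique(c(amplicons$start, amplicons$end)))
    internal <- which(r$values & r$lengths >= unsequenced_run_min)
    for (k in internal) {
      span <- range(cmap$report_pos[starts[k]:ends[k]], na.rm = TRUE)
      # 0-based half-open boundaries against 1-based run span
      if (any(abs(bounds - (span[1] - 1L)) <= 1L) ||
          any(abs(bounds - span[2]) <= 1L)) {
        unseq[starts[k]:ends[k]] <- TRUE
      }
    }
  }
  unseq
}
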