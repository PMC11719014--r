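#' Project exon annotations into alignment-column codon coordinates
#'
#' Builds the coordinate system the screening stage runs in: every alignment
#' column that belongs to a reference exon is listed, reference-gap columns
#' inside exon spans (insertions carried by other taxa) are kept but flagged
#' and carry no reference coordinate, and each reference base receives its
#' 1-based position in the concatenated exonic reference plus the codon it
#' falls in. The reading frame is anchored at the first exonic base (the
#' reference start codon). If the concatenated exonic length is not divisible
#' by 3 the trailing partial codon is dropped with a warning.
#'
#' @param aln Alignment tibble (see [read_alignment()]).
#' @param reference_id Taxon identifier of the functional reference row.
#' @param exons Exon annotation tibble (see [read_exons()]); 0-based
#'   half-open intervals on the ungapped reference sequence.
#' @return A tibble of class `coding_map` with one row per exonic alignment
#'   column: `column` (alignment column index), `exon` (label), `ref_gap`
#'   (logical), `ref_pos` (1-based position in the concatenated exonic
#'   reference, `NA` for reference-gap columns), `codon` (1-based codon
#'   index, `NA` for reference gaps and the dropped remainder), `report_pos`
#'   (position used in reports: `ref_pos`, or for an insertion column the
#'   reference position immediately preceding it) and `col_pos` (running
#'   index counting every exonic column, used when
#'   `count_reference_gap_columns = TRUE` downstream). Attributes:
#'   `reference_id`, `exonic_length`, `n_codons`, `terminal_stop_codon`
#'   (index of the reference terminal stop, or `NA` if the analyzed region
#'   does not end in one) and `ref_codons` (the reference codon strings).
#' @export
build_coding_map <- function(aln, reference_id, exons) {
  validate_alignment(aln)
  validate_exons(exons)
  if (!reference_id %in% aln$taxon) {
    abort(paste0("unknown taxon: '", reference_id, "' not in alignment"))
  }
  ref <- toupper(strsplit(aln$sequence[aln$taxon == reference_id], "",
                          fixed = TRUE)[[1]])
  is_base <- ref != "-"
  ungapped_len <- sum(is_base)
  if (any(exons$end > ungapped_len)) {
    abort(paste0("annotation out of range: reference has ", ungapped_len,
                 " bases"))
  }
  # 0-based ungapped reference position of each non-gap column
  refpos0 <- ifelse(is_base, cumsum(is_base) - 1L, NA_integer_)

  exon_of <- rep(NA_character_, length(ref))
  exon_off <- stats::setNames(
    c(0L, cumsum(exons$end - exons$start))[seq_len(nrow(exons))],
    exons$label
  )
  for (i in seq_len(nrow(exons))) {
    hit <- !is.na(refpos0) & refpos0 >= exons$start[i] & refpos0 < exons$end[i]
    exon_of[hit] <- exons$label[i]
  }

  # a reference-gap column is exonic iff its flanking reference bases both
  # fall in an exon (insertions inside exon spans, not intron insertions)
  prev_exon <- fill_run(exon_of, forward = TRUE)
  next_exon <- fill_run(exon_of, forward = FALSE)
  gap_exonic <- !is_base & !is.na(prev_exon) & !is.na(next_exon)
  exon_of[gap_exonic] <- prev_exon[gap_exonic]

  keep <- !is.na(exon_of)
  cm <- tibble(
    column = which(keep),
    exon = exon_of[keep],
    ref_gap = !is_base[keep],
    ref_pos = NA_integer_
  )
  base_rows <- !cm$ref_gap
  cm$ref_pos[base_rows] <- exon_off[cm$exon[base_rows]] +
    (refpos0[cm$column[base_rows]] -
       exons$start[match(cm$exon[base_rows], exons$label)]) + 1L

  L <- sum(exons$end - exons$start)
  n_codons <- L %/% 3L
  if (L %% 3L != 0L) {
    warning("trailing partial codon dropped: exonic length ", L,
            " is not divisible by 3 (", n_codons, " complete codons)",
            call. = FALSE)
  }
  cm$codon <- ifelse(!is.na(cm$ref_pos) & cm$ref_pos <= 3L * n_codons,
                     (cm$ref_pos - 1L) %/% 3L + 1L, NA_integer_)
  prev_pos <- fill_run(cm$ref_pos, forward = TRUE)
  cm$report_pos <- ifelse(cm$ref_gap,
                          ifelse(is.na(prev_pos), 0L, prev_pos), cm$ref_pos)
  cm$col_pos <- seq_len(nrow(cm))

  ref_exonic <- ref[cm$column][!cm$ref_gap]
  ref_codons <- codon_strings(ref_exonic, n_codons)
  terminal <- if (n_codons >= 1 && is_forced_stop(ref_codons[n_codons])) {
    n_codons
  } else {
    NA_integer_
  }

  structure(cm,
            class = c("coding_map", class(cm)),
            reference_id = reference_id,
            exonic_length = L,
            n_codons = n_codons,
            terminal_stop_codon = terminal,
            ref_codons = ref_codons)
}

# carry the last (or next) non-NA value across a vector
fill_run <- function(x, forward = TRUE) {
  if (!forward) return(rev(fill_run(rev(x), forward = TRUE)))
  idx <- cumsum(!is.na(x))
  vals <- x[!is.na(x)]
  out <- rep(x[NA_integer_][1], length(x))
  out[idx > 0] <- vals[idx[idx > 0]]
  out
}

codon_strings <- function(bases, n_codons) {
  if (n_codons == 0) return(character(0))
  b <- bases[seq_len(3L * n_codons)]
  paste0(b[c(TRUE, FALSE, FALSE)], b[c(FALSE, TRUE, FALSE)],
         b[c(FALSE, FALSE, TRUE)])
}

# enumerate all IUPAC resolutions of a codon string (<= 64)
codon_resolutions <- function(codon) {
  chars <- strsplit(toupper(codon), "", fixed = TRUE)[[1]]
  sets <- IUPAC_SETS[chars]
  if (any(vapply(sets, is.null, logical(1)))) {
    abort(paste0("alphabet violation: cannot resolve codon '", codon, "'"))
  }
  grid <- expand.grid(sets, stringsAsFactors = FALSE)
  paste0(grid[[1]], grid[[2]], grid[[3]])
}

# TRUE when every IUPAC resolution of the codon is a stop
is_forced_stop <- function(codon) {
  all(codon_resolutions(codon) %in% STOP_CODONS)
}

# TRUE when at least one resolution is a stop
is_possible_stop <- function(codon) {
  any(codon_resolutions(codon) %in% STOP_CODONS)
}
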