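#' @importFrom rlang abort .data
#' @importFrom dplyr mutate filter arrange select group_by summarise ungroup
#'   bind_rows left_join distinct n lag lead across all_of rename count pull
#' @importFrom tibble tibble as_tibble
#' @importFrom purrr map map_chr map_int map_lgl map2 pmap imap keep
NULL

# IUPAC nucleotide codes accepted in alignments; '-' is the only gap symbol
# ('.' is rejected on purpose), 'N' is data-missing, not a gap.
IUPAC_CODES <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N", "-")

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

STOP_CODONS <- c("TAA", "TAG", "TGA")

validate_alignment <- function(aln) {
  stopifnot(is.data.frame(aln))
  if (!all(c("taxon", "sequence") %in% names(aln))) {
    abort("alignment must have columns 'taxon' and 'sequence'")
  }
  if (nrow(aln) < 2) abort("alignment needs at least 2 records")
  if (anyDuplicated(aln$taxon)) {
    abort(paste0("duplicate taxon: ", aln$taxon[duplicated(aln$taxon)][1]))
  }
  widths <- nchar(aln$sequence)
  if (length(unique(widths)) != 1L) {
    bad <- aln$taxon[widths != widths[1]][1]
    abort(paste0("unaligned input: row '", bad, "' has width ",
                 widths[aln$taxon == bad][1], ", expected ", widths[1]))
  }
  for (i in seq_len(nrow(aln))) {
    chars <- toupper(strsplit(aln$sequence[i], "", fixed = TRUE)[[1]])
    bad <- which(!(chars %in% IUPAC_CODES))
    if (length(bad)) {
      abort(paste0("alphabet violation: row '", aln$taxon[i], "' column ",
                   bad[1], " has symbol '", chars[bad[1]], "'"))
    }
  }
  invisible(aln)
}

#' Read a gapped multiple sequence alignment from FASTA
#'
#' Reads an aligned nucleotide FASTA into a tibble with one row per taxon.
#' All rows must have identical width, taxon identifiers must be unique, and
#' the alphabet is restricted to IUPAC nucleotide codes plus `-` (gap) and
#' `N` (undetermined base). `.` is not accepted as a gap. Case is preserved
#' in the `sequence` column; all downstream comparisons are case-insensitive.
#'
#' @param path Path to a FASTA file with at least two records.
#' @return A tibble with columns `taxon` (character) and `sequence`
#'   (character, all the same width). The alignment width is `nchar()` of any
#'   row.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">a", "ATG---", ">b", "ATGCCC"), fa)
#' read_alignment(fa)
read_alignment <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) < 2) abort("alignment needs at least 2 records")
  aln <- tibble(
    taxon = sub("\\s.*$", "", names(seqs)),
    sequence = unname(as.character(seqs))
  )
  validate_alignment(aln)
  aln
}

#' Write an alignment tibble back to FASTA
#'
#' @param aln Alignment tibble as returned by [read_alignment()].
#' @param path Output path.
#' @param width Line-wrap width for sequence lines.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path, width = 70) {
  validate_alignment(aln)
  lines <- unlist(purrr::map2(aln$taxon, aln$sequence, function(t, s) {
    starts <- seq(1, nchar(s), by = width)
    c(paste0(">", t), substring(s, starts, pmin(starts + width - 1, nchar(s))))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Read an exon annotation table
#'
#' Reads a BED-like, tab-separated, three-column table (`label`, `start`,
#' `end`) of exon intervals on the UNGAPPED reference sequence. Intervals are
#' 0-based half-open on disk (BED convention); human-facing reports elsewhere
#' in the package are 1-based inclusive.
#'
#' @param path Path to the TSV file (no header).
#' @return A tibble with columns `label`, `start`, `end` (0-based half-open),
#'   sorted by `start`, with non-overlapping intervals.
#' @export
read_exons <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  raw <- tryCatch(
    utils::read.table(path, sep = "\t", header = FALSE,
                      col.names = c("label", "start", "end"),
                      colClasses = c("character", "integer", "integer")),
    error = function(e) abort(paste0("no exons: cannot parse '", path, "'"))
  )
  if (nrow(raw) == 0) abort("no exons")
  exons <- as_tibble(raw) |> arrange(.data$start)
  validate_exons(exons)
  exons
}

validate_exons <- function(exons) {
  if (nrow(exons) == 0) abort("no exons")
  if (any(exons$end <= exons$start)) {
    bad <- which(exons$end <= exons$start)[1]
    abort(paste0("invalid interval: '", exons$label[bad], "' has end <= start"))
  }
  if (nrow(exons) > 1) {
    if (any(exons$start[-1] < exons$end[-nrow(exons)])) {
      abort("invalid interval: overlapping exons")
    }
  }
  invisible(exons)
}

#' Read a rooted species tree from a Newick file
#'
#' @param path Path to a file holding a single Newick string.
#' @return An [ape::read.tree()] `phylo` object with unique tip labels;
#'   unlabeled internal nodes are tolerated.
#' @export
read_tree <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  tree <- tryCatch(
    suppressWarnings(ape::read.tree(path)),
    error = function(e) NULL
  )
  if (is.null(tree) || !inherits(tree, "phylo")) abort("bad newick")
  if (anyDuplicated(tree$tip.label)) {
    abort(paste0("duplicate tip: ",
                 tree$tip.label[duplicated(tree$tip.label)][1]))
  }
  tree
}

#' Write a screening or loss report as TSV
#'
#' Thin wrapper around [readr::write_tsv()] that flattens list columns into
#' comma-joined strings first, so every pipeline table can be written with a
#' fixed header.
#'
#' @param x A tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path) {
  for (nm in names(x)[vapply(x, is.list, logical(1))]) {
    x[[nm]] <- map_chr(x[[nm]], function(el) paste(unlist(el), collapse = ","))
  }
  readr::write_tsv(x, path)
  invisible(path)
}
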