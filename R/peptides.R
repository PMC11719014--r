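AA_ALPHABET <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Locate peptides in protein sequences by exact matching
#'
#' Reports every exact occurrence of each peptide in each protein as a
#' 1-based inclusive span, the convention of MS/MS span tables. Matching is
#' residue-exact by default; `collapse_il = TRUE` folds isoleucine and
#' leucine together before matching (spans still index the original
#' sequence). Overlapping occurrences are all reported.
#'
#' @param proteins Path to a protein FASTA file, or a named character
#'   vector of protein sequences.
#' @param peptides Character vector of peptide sequences (uppercase
#'   amino-acid alphabet).
#' @param collapse_il Treat I and L as equivalent (default `FALSE`).
#' @return A tibble with one row per occurrence: `peptide`, `protein`,
#'   `start`, `end`, `n_occurrences` (occurrences of that peptide in that
#'   protein). Peptides with zero hits anywhere are attached as the
#'   `unmatched` attribute and retrievable with [unmatched_peptides()].
#' @export
#' @examples
#' locate_peptides(c(p1 = "MKLALVCGSVHAA"), "LALVCGSVH")
locate_peptides <- function(proteins, peptides, collapse_il = FALSE) {
  if (length(peptides) == 0) abort("peptides must be non-empty")
  if (is.character(proteins) && length(proteins) == 1 &&
      file.exists(proteins)) {
    seqs <- Biostrings::readBStringSet(proteins)
    proteins <- stats::setNames(as.character(seqs),
                                sub("\\s.*$", "", names(seqs)))
  }
  stopifnot(is.character(proteins), !is.null(names(proteins)))
  check_aa <- function(x, what) {
    chars <- unique(strsplit(paste(x, collapse = ""), "")[[1]])
    bad <- setdiff(chars, AA_ALPHABET)
    if (length(bad)) {
      abort(paste0("alphabet violation: illegal residue '", bad[1],
                   "' in ", what))
    }
  }
  check_aa(peptides, "peptides")
  check_aa(proteins, "proteins")

  fold <- function(x) if (collapse_il) gsub("I", "L", x, fixed = TRUE) else x
  subj <- fold(proteins)

  hits <- purrr::map(unique(peptides), function(pep) {
    q <- fold(pep)
    per_prot <- purrr::imap(subj, function(s, id) {
      m <- Biostrings::matchPattern(q, Biostrings::BString(s))
      if (length(m) == 0) return(NULL)
      tibble(peptide = pep, protein = id,
             start = Biostrings::start(m), end = Biostrings::end(m))
    })
    bind_rows(per_prot)
  }) |> bind_rows()

  if (nrow(hits)) {
    hits <- hits |>
      group_by(.data$peptide, .data$protein) |>
      mutate(n_occurrences = n()) |>
      ungroup() |>
      arrange(.data$peptide, .data$protein, .data$start)
  } else {
    hits <- tibble(peptide = character(0), protein = character(0),
                   start = integer(0), end = integer(0),
                   n_occurrences = integer(0))
  }
  attr(hits, "unmatched") <- setdiff(unique(peptides), hits$peptide)
  hits
}

#' Peptides that matched no protein
#'
#' @param hits Result of [locate_peptides()].
#' @return Character vector of unmatched peptide sequences.
#' @export
unmatched_peptides <- function(hits) {
  attr(hits, "unmatched") %||% character(0)
}

#' Count distinct peptides per gene
#'
#' Collapses peptide-to-protein hits over a protein-to-gene grouping: a
#' peptide found in several isoforms of one gene is counted once, the usual
#' "n different peptides of gene X" summary of proteomic surveys. Genes in
#' the grouping with no hits are reported with count 0.
#'
#' @param hits Result of [locate_peptides()].
#' @param groupings Tibble with columns `protein` and `gene` covering every
#'   hit protein.
#' @return Tibble with columns `gene` and `n_peptides`, sorted by gene.
#' @export
summarize_counts <- function(hits, groupings) {
  stopifnot(all(c("protein", "gene") %in% names(groupings)))
  unknown <- setdiff(hits$protein, groupings$protein)
  if (length(unknown)) {
    abort(paste0("no grouping for protein '", unknown[1], "'"))
  }
  counted <- hits |>
    left_join(distinct(groupings, .data$protein, .data$gene),
              by = "protein") |>
    distinct(.data$gene, .data$peptide) |>
    count(.data$gene, name = "n_peptides")
  tibble(gene = sort(unique(groupings$gene))) |>
    left_join(counted, by = "gene") |>
    mutate(n_peptides = dplyr::coalesce(.data$n_peptides, 0L))
}
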