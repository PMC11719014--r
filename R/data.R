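#' Muridae taxon sampling table
#'
#' The survey's taxon sampling: 48 murid rodents (42 Murinae across eight
#' tribes plus Deomyinae and Gerbillinae outgroups) with genus, species and
#' the provenance of each sequence — a public accession or
#' "Sequence obtained in this study" for the 20 newly sequenced species.
#' Shipped as plain TSV under `extdata`.
#'
#' @return A tibble with columns `subfamily`, `tribe`, `genus`, `species`,
#'   `sequence_source`.
#' @export
#' @examples
#' tx <- muridae_taxa()
#' sum(tx$subfamily == "Murinae")
muridae_taxa <- function() {
  path <- system.file("extdata", "muridae_taxa.tsv", package = "pseudoscan",
                      mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(.default = readr::col_character()))
}

#' Tallies of the taxon sampling table
#'
#' Convenience counts used in reporting: the number of Murinae taxa, the
#' number of newly sequenced species, and the number of genera sampled in
#' the Rattini tribe.
#'
#' @param taxa Tibble from [muridae_taxa()].
#' @return One-row tibble: `n_murinae`, `n_new_species`,
#'   `n_rattini_genera`.
#' @export
taxon_tallies <- function(taxa = muridae_taxa()) {
  tibble(
    n_murinae = sum(taxa$subfamily == "Murinae"),
    n_new_species = dplyr::n_distinct(
      taxa$species[taxa$sequence_source == "Sequence obtained in this study"]
    ),
    n_rattini_genera = dplyr::n_distinct(
      taxa$genus[!is.na(taxa$tribe) & taxa$tribe == "Rattini"]
    )
  )
}
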