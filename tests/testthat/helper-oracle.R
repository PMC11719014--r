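# Independent brute-force oracles, deliberately written as naive loops with
# their own IUPAC handling (Biostrings::IUPAC_CODE_MAP), so they share no
# code path with the package internals they certify.

oracle_resolutions <- function(codon) {
  sets <- lapply(strsplit(codon, "")[[1]], function(ch) {
    strsplit(Biostrings::IUPAC_CODE_MAP[[ch]], "")[[1]]
  })
  out <- character(0)
  for (a in sets[[1]]) for (b in sets[[2]]) for (c in sets[[3]]) {
    out <- c(out, paste0(a, b, c))
  }
  out
}

# Forced premature-stop positions for one taxon: strip gaps, walk the
# exonic columns keeping the cumulative frame offset, scan codons.
# Returns 1-based reference-frame first-base positions.
oracle_forced_stops <- function(ref_seq, taxon_seq, exon_cols, exonic_length) {
  rc <- toupper(strsplit(ref_seq, "")[[1]])[exon_cols]
  tc <- toupper(strsplit(taxon_seq, "")[[1]])[exon_cols]
  n <- length(tc)
  gap <- tc == "-"
  lead <- 0L
  while (lead < n && gap[lead + 1L]) lead <- lead + 1L
  trail <- 0L
  while (trail < n && lead + trail < n && gap[n - trail]) trail <- trail + 1L
  sequenced <- rep(TRUE, n)
  if (lead > 0) sequenced[1:lead] <- FALSE
  if (trail > 0) sequenced[(n - trail + 1L):n] <- FALSE

  bases <- character(0)   # NA = unsequenced ghost (assumed reference-like)
  refpos <- integer(0)
  rp <- 0L
  for (i in seq_len(n)) {
    if (rc[i] != "-") {
      rp <- rp + 1L
      if (!sequenced[i]) {
        bases <- c(bases, NA_character_)
        refpos <- c(refpos, rp)
      } else if (tc[i] != "-") {
        bases <- c(bases, tc[i])
        refpos <- c(refpos, rp)
      } # else: deletion, no CDS advance
    } else if (sequenced[i] && tc[i] != "-") {
      bases <- c(bases, tc[i])           # insertion
      refpos <- c(refpos, NA_integer_)
    }
  }

  n_codons <- exonic_length %/% 3L
  term_start <- 3L * (n_codons - 1L) + 1L
  stops <- integer(0)
  k <- 1L
  while (3L * k <= length(bases)) {
    idx <- (3L * k - 2L):(3L * k)
    cod <- bases[idx]
    if (!anyNA(cod)) {
      pos <- refpos[idx[1]]
      if (is.na(pos)) {
        before <- refpos[seq_len(idx[1] - 1L)]
        pos <- if (any(!is.na(before))) max(before, na.rm = TRUE) else 0L
      }
      res <- oracle_resolutions(paste(cod, collapse = ""))
      if (pos < term_start && all(res %in% c("TAA", "TAG", "TGA"))) {
        stops <- c(stops, pos)
      }
    }
    k <- k + 1L
  }
  stops
}

# exonic alignment columns for an alignment built by apply_scenarios()
exonic_columns <- function(aln, reference_id, exons) {
  cmap <- suppressWarnings(build_coding_map(aln, reference_id, exons))
  cmap$column
}

# Minimal Dollo loss count by exhaustive enumeration over branch subsets.
# A branch is identified by the node below it; the root branch is allowed.
oracle_dollo_min <- function(tree, calls) {
  tips <- tree$tip.label
  n_tip <- length(tips)
  n_node <- n_tip + tree$Nnode
  # ancestors (self included) of every tip
  parent <- integer(n_node)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  anc <- lapply(seq_len(n_tip), function(t) {
    path <- t
    while (parent[path[length(path)]] > 0L) {
      path <- c(path, parent[path[length(path)]])
    }
    path
  })
  pseudo <- which(calls[tips] == "pseudogenized")
  intact <- which(calls[tips] == "intact")
  if (length(pseudo) == 0) return(0L)
  best <- Inf
  for (mask in 0:(2^n_node - 1)) {
    chosen <- which(bitwAnd(mask, 2^(seq_len(n_node) - 1L)) > 0)
    if (length(chosen) >= best) next
    ok <- TRUE
    for (t in pseudo) {
      if (sum(anc[[t]] %in% chosen) != 1L) { ok <- FALSE; break }
    }
    if (ok) for (t in intact) {
      if (any(anc[[t]] %in% chosen)) { ok <- FALSE; break }
    }
    if (ok) best <- length(chosen)
  }
  as.integer(best)
}

# naive sliding-window peptide scan (overlap-aware)
oracle_peptide_hits <- function(protein, peptide) {
  L <- nchar(protein)
  k <- nchar(peptide)
  hits <- integer(0)
  for (s in seq_len(max(0L, L - k + 1L))) {
    if (substr(protein, s, s + k - 1L) == peptide) hits <- c(hits, s)
  }
  hits
}
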