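#' Simulate a functional reference locus with exon structure
#'
#' Generates an intronated nucleotide locus whose concatenated exonic
#' sequence is a clean open reading frame: it begins with ATG, its last
#' complete codon is a stop, and no internal complete codon is a stop. When
#' the total exonic length is not divisible by 3, the remainder bases after
#' the stop are kept (they belong to the exon annotation but to no complete
#' codon), mirroring partial-gene regions whose final codon is cut by the
#' amplicon boundary.
#'
#' @param seed Integer seed; the locus is deterministic given
#'   `(seed, exon_lengths, gc, intron_length)`.
#' @param exon_lengths Integer vector of exon lengths (bases); the default
#'   six exons sum to 626.
#' @param gc GC content used for base sampling (default 0.45).
#' @param intron_length Length of the introns separating exons (default 60).
#' @return A list of class `reference_locus`: `sequence` (the ungapped
#'   genomic string), `exons` (tibble `label`/`start`/`end`, 0-based
#'   half-open), `exonic_seq` (concatenated exonic string) and
#'   `exonic_length`.
#' @export
make_reference_locus <- function(seed,
                                 exon_lengths = c(112, 54, 148, 90, 122, 100),
                                 gc = 0.45, intron_length = 60) {
  L <- sum(exon_lengths)
  if (L < 9) abort("bad spec: total exonic length must be >= 9")
  withr::with_seed(seed, {
    probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    draw <- function(n) sample(names(probs), n, replace = TRUE, prob = probs)
    n_codons <- L %/% 3L
    remainder <- L %% 3L
    body <- character(n_codons - 2L)
    for (i in seq_along(body)) {
      repeat {
        cd <- paste(draw(3), collapse = "")
        if (!cd %in% STOP_CODONS) break
      }
      body[i] <- cd
    }
    exonic <- paste0("ATG", paste(body, collapse = ""),
                     sample(STOP_CODONS, 1),
                     paste(draw(remainder), collapse = ""))
    introns <- replicate(length(exon_lengths) - 1L,
                         paste(draw(intron_length), collapse = ""))
    pieces <- character(0)
    starts <- integer(length(exon_lengths))
    ends <- integer(length(exon_lengths))
    at <- 0L
    off <- 0L
    for (i in seq_along(exon_lengths)) {
      starts[i] <- at
      ends[i] <- at + exon_lengths[i]
      pieces <- c(pieces, substr(exonic, off + 1L, off + exon_lengths[i]))
      off <- off + exon_lengths[i]
      at <- ends[i]
      if (i < length(exon_lengths)) {
        pieces <- c(pieces, introns[i])
        at <- at + intron_length
      }
    }
    structure(list(
      sequence = paste(pieces, collapse = ""),
      exons = tibble(label = paste0("exon", seq_along(exon_lengths)),
                     start = starts, end = ends),
      exonic_seq = exonic,
      exonic_length = L
    ), class = "reference_locus")
  })
}

# ---- lesion constructors ---------------------------------------------------
# Positions are 1-based coordinates in the concatenated exonic reference.

#' Lesion constructors for synthetic scenarios
#'
#' Build the typed lesions that [apply_scenarios()] implants into a taxon:
#' a start-codon substitution (ATG to ATA), a point substitution, a
#' deletion, an insertion (placed after the given position), an IUPAC
#' ambiguity code, or an unsequenced mask over a range of exons. Positions
#' are 1-based coordinates in the concatenated exonic reference.
#'
#' @param pos 1-based exonic reference position.
#' @param base Replacement base (A/C/G/T).
#' @param len Deletion length in bases.
#' @param seq Inserted sequence (A/C/G/T string), placed after `pos`.
#' @param code IUPAC ambiguity code (e.g. "Y", "R", "N").
#' @param exon_from,exon_to Exon numbers (1-based, inclusive) of the masked
#'   range; the mask extends through flanking introns so that it reads as a
#'   contiguous unsequenced run.
#' @return A lesion object (a tagged list).
#' @name lesions
NULL

#' @rdname lesions
#' @export
lesion_start_loss <- function() {
  structure(list(type = "start_codon_substitution", pos = 3L, base = "A"),
            class = "pseudoscan_lesion")
}

#' @rdname lesions
#' @export
lesion_point <- function(pos, base) {
  structure(list(type = "point_substitution", pos = as.integer(pos),
                 base = toupper(base)), class = "pseudoscan_lesion")
}

#' @rdname lesions
#' @export
lesion_deletion <- function(pos, len) {
  structure(list(type = "deletion", pos = as.integer(pos),
                 len = as.integer(len)), class = "pseudoscan_lesion")
}

#' @rdname lesions
#' @export
lesion_insertion <- function(pos, seq) {
  structure(list(type = "insertion", pos = as.integer(pos),
                 seq = toupper(seq)), class = "pseudoscan_lesion")
}

#' @rdname lesions
#' @export
lesion_ambiguity <- function(pos, code) {
  structure(list(type = "ambiguity", pos = as.integer(pos),
                 base = toupper(code)), class = "pseudoscan_lesion")
}

#' @rdname lesions
#' @export
lesion_mask <- function(exon_from, exon_to = exon_from) {
  structure(list(type = "mask_unsequenced", exon_from = as.integer(exon_from),
                 exon_to = as.integer(exon_to)), class = "pseudoscan_lesion")
}

# exonic positions claimed by a lesion (for conflict checks)
lesion_span <- function(lesion, locus) {
  switch(lesion$type,
    start_codon_substitution = 3L,
    point_substitution = lesion$pos,
    ambiguity = lesion$pos,
    deletion = seq(lesion$pos, lesion$pos + lesion$len - 1L),
    insertion = lesion$pos,
    mask_unsequenced = {
      off <- c(0L, cumsum(locus$exons$end - locus$exons$start))
      seq(off[lesion$exon_from] + 1L, off[lesion$exon_to + 1L])
    }
  )
}

#' Implant lesion scenarios into an alignment with ground truth
#'
#' Builds a column-consistent gapped alignment from a reference locus and a
#' set of per-taxon lesion scenarios. Deletions become gap columns in the
#' carrier; insertions open reference-gap columns that are shared between
#' taxa carrying the identical insertion; masks become leading/trailing gap
#' runs. Alongside the alignment, a truth table lists every expected
#' disabling mutation per taxon with its reported position, computed by an
#' independent strip-gaps-and-translate oracle over each taxon's mutated
#' exonic sequence (not by the alignment-column machinery the screen stage
#' uses).
#'
#' @param locus A [make_reference_locus()] result.
#' @param scenarios Named list: taxon id to list of lesions (see
#'   [lesions]); an empty lesion list yields a clean reference copy.
#' @param reference_id Name of the reference row added to the alignment
#'   (default `"reference"`).
#' @param coverage_threshold Threshold used for the truth table's expected
#'   calls (default 0.5, matching the screen default).
#' @return A list: `alignment` (tibble), `truth` (tibble `taxon`,
#'   `expected_call`, `coverage`, list column `mutations` with `kind`,
#'   `aln_nt_pos`, `length`, `certainty`) and `locus`.
#' @export
apply_scenarios <- function(locus, scenarios, reference_id = "reference",
                            coverage_threshold = 0.5) {
  stopifnot(inherits(locus, "reference_locus"))
  if (is.null(names(scenarios)) && length(scenarios) > 0) {
    abort("scenarios must be a named list (taxon -> lesion list)")
  }
  L <- locus$exonic_length
  for (tx in names(scenarios)) {
    spans <- purrr::map(scenarios[[tx]], lesion_span, locus = locus)
    if (any(unlist(spans) > L) || any(unlist(spans) < 1)) {
      abort(paste0("conflicting lesions: position outside exonic reference",
                   " for taxon '", tx, "'"))
    }
    all_pos <- unlist(spans)
    if (anyDuplicated(all_pos)) {
      abort(paste0("conflicting lesions: overlapping lesions on taxon '",
                   tx, "'"))
    }
  }

  ref_chars <- strsplit(locus$sequence, "", fixed = TRUE)[[1]]
  G <- length(ref_chars)
  # genomic (1-based) index of each exonic reference position 1..L
  exonic_gpos <- unlist(purrr::map2(locus$exons$start, locus$exons$end,
                                    function(s, e) seq(s + 1L, e)))

  # shared insertion keys: (exonic pos, sequence)
  ins_keys <- list()
  for (tx in names(scenarios)) {
    for (les in scenarios[[tx]]) {
      if (les$type == "insertion") {
        key <- paste0(les$pos, ":", les$seq)
        ins_keys[[key]] <- list(pos = les$pos, seq = les$seq)
      }
    }
  }
  if (length(ins_keys)) {
    ins_keys <- ins_keys[order(vapply(ins_keys, `[[`, integer(1), "pos"),
                               names(ins_keys))]
  }

  # column layout: genomic position g gets slot 2g; insertion block after
  # exonic pos p hangs off slot 2*g(p)+1 (ordered by key within a slot)
  build_row <- function(chars, ins_seqs) {
    pieces <- character(G + length(ins_keys))
    pieces[seq_len(G)] <- chars
    if (length(ins_keys)) {
      for (k in seq_along(ins_keys)) {
        width <- nchar(ins_keys[[k]]$seq)
        pieces[G + k] <- if (!is.null(ins_seqs[[names(ins_keys)[k]]])) {
          ins_seqs[[names(ins_keys)[k]]]
        } else {
          strrep("-", width)
        }
      }
    }
    pieces
  }
  # order of pieces: genomic chars interleaved with insertion blocks
  piece_order <- order(c(seq_len(G),
                         vapply(ins_keys, function(k)
                           exonic_gpos[k$pos] + 0.5, numeric(1))))

  mask_gspan <- function(les) {
    ex <- locus$exons
    from_g <- if (les$exon_from == 1L) 1L else ex$start[les$exon_from] + 1L -
      0L
    to_g <- if (les$exon_to == nrow(ex)) G else ex$end[les$exon_to]
    # extend through flanking introns so the run is contiguous
    if (les$exon_from > 1L) from_g <- ex$end[les$exon_from - 1L] + 1L
    if (les$exon_to < nrow(ex)) to_g <- ex$start[les$exon_to + 1L]
    c(from_g, to_g)
  }

  taxa <- c(reference_id, names(scenarios))
  rows <- purrr::map(taxa, function(tx) {
    chars <- ref_chars
    ins_seqs <- list()
    if (tx != reference_id) {
      lesions <- scenarios[[tx]]
      is_mask <- vapply(lesions, function(l) l$type == "mask_unsequenced",
                        logical(1))
      for (les in c(lesions[!is_mask], lesions[is_mask])) {
        if (les$type %in% c("start_codon_substitution", "point_substitution",
                            "ambiguity")) {
          chars[exonic_gpos[les$pos]] <- les$base
        } else if (les$type == "deletion") {
          chars[exonic_gpos[seq(les$pos, les$pos + les$len - 1L)]] <- "-"
        } else if (les$type == "insertion") {
          ins_seqs[[paste0(les$pos, ":", les$seq)]] <- les$seq
        } else if (les$type == "mask_unsequenced") {
          span <- mask_gspan(les)
          chars[span[1]:span[2]] <- "-"
        }
      }
    }
    paste(build_row(chars, ins_seqs)[piece_order], collapse = "")
  })
  alignment <- tibble(taxon = taxa, sequence = unlist(rows))

  truth <- bind_rows(purrr::map(names(scenarios), function(tx) {
    scenario_truth(locus, scenarios[[tx]], tx, coverage_threshold)
  }))
  if (length(scenarios) == 0) {
    truth <- tibble(taxon = character(0), expected_call = character(0),
                    coverage = numeric(0), mutations = list())
  }
  list(alignment = alignment, truth = truth, locus = locus)
}

# Independent truth oracle: applies the lesions to the exonic reference as
# a flat base list, regroups codons from the frame-adjusted start and scans
# them, without using the coding map or frame walk.
scenario_truth <- function(locus, lesions, taxon, coverage_threshold = 0.5) {
  L <- locus$exonic_length
  base <- strsplit(locus$exonic_seq, "", fixed = TRUE)[[1]]
  refpos <- seq_len(L)
  masked <- rep(FALSE, L)

  for (les in lesions) {
    if (les$type %in% c("start_codon_substitution", "point_substitution",
                        "ambiguity")) {
      base[match(les$pos, refpos)] <- les$base
    } else if (les$type == "mask_unsequenced") {
      masked[refpos %in% lesion_span(les, locus)] <- TRUE
    }
  }
  # indels after substitutions: operate on refpos, order irrelevant because
  # lesions never overlap
  for (les in lesions) {
    if (les$type == "deletion") {
      drop <- refpos %in% seq(les$pos, les$pos + les$len - 1L)
      base <- base[!drop]; masked <- masked[!drop]; refpos <- refpos[!drop]
    } else if (les$type == "insertion") {
      at <- match(les$pos, refpos)
      ins <- strsplit(les$seq, "", fixed = TRUE)[[1]]
      base <- append(base, ins, after = at)
      masked <- append(masked, rep(FALSE, length(ins)), after = at)
      refpos <- append(refpos, rep(NA_integer_, length(ins)), after = at)
    }
  }

  n_codons <- L %/% 3L
  term_start <- 3L * (n_codons - 1L) + 1L
  muts <- list()

  # frameshifts straight from the lesion list
  for (les in lesions) {
    if (les$type == "deletion" && les$len %% 3L != 0L) {
      muts <- c(muts, list(tibble(kind = "frameshift_indel",
                                  aln_nt_pos = les$pos,
                                  length = les$len, certainty = "forced")))
    }
    if (les$type == "insertion" && nchar(les$seq) %% 3L != 0L) {
      muts <- c(muts, list(tibble(kind = "frameshift_indel",
                                  aln_nt_pos = les$pos,
                                  length = nchar(les$seq),
                                  certainty = "forced")))
    }
  }

  # codon scan in the taxon's own frame
  n_full <- length(base) %/% 3L
  for (k in seq_len(n_full)) {
    idx <- (3L * (k - 1L) + 1L):(3L * k)
    if (any(masked[idx])) next
    codon <- paste(base[idx], collapse = "")
    rp <- refpos[idx[1]]
    if (is.na(rp)) {
      prior <- refpos[seq_len(idx[1] - 1L)]
      rp <- if (any(!is.na(prior))) max(prior, na.rm = TRUE) else 0L
    }
    if (k == 1L) {
      res <- codon_resolutions(codon)
      if (!all(res == "ATG")) {
        muts <- c(muts, list(tibble(
          kind = "start_loss", aln_nt_pos = rp, length = NA_integer_,
          certainty = if (any(res == "ATG")) "possible" else "forced"
        )))
      }
    }
    if (rp < term_start && is_possible_stop(codon)) {
      muts <- c(muts, list(tibble(
        kind = "premature_stop", aln_nt_pos = rp, length = NA_integer_,
        certainty = if (is_forced_stop(codon)) "forced" else "possible"
      )))
    }
  }

  mutations <- bind_rows(c(
    list(tibble(kind = character(0), aln_nt_pos = integer(0),
                length = integer(0), certainty = character(0))),
    muts
  )) |> arrange(.data$aln_nt_pos, .data$kind)
  coverage <- sum(!is.na(refpos) & !masked & base != "N") / L
  n_forced <- sum(mutations$certainty == "forced")
  n_possible <- sum(mutations$certainty == "possible")
  call <- if (n_forced >= 1L) "pseudogenized" else
    if (n_possible == 0L && coverage >= coverage_threshold) "intact" else
      "indeterminate"
  tibble(taxon = taxon, expected_call = call, coverage = coverage,
         mutations = list(mutations))
}

#' Neutral background-noise lesions for an intact taxon
#'
#' Draws random point substitutions that are guaranteed harmless in the
#' reference reading frame: they never touch the start codon, the terminal
#' stop codon or any `exclude`d position, and a substitution is rejected if
#' the resulting reference-frame codon could resolve to a stop. Applying
#' these to a taxon therefore leaves it intact by construction.
#'
#' @param locus A [make_reference_locus()] result.
#' @param rate Expected substitutions per exonic site (default 0.01).
#' @param seed Integer seed.
#' @param exclude Exonic positions to leave untouched (e.g. positions
#'   claimed by implanted lesions).
#' @return A list of [lesion_point()] lesions.
#' @export
neutral_noise_lesions <- function(locus, rate = 0.01, seed = 1,
                                  exclude = integer(0)) {
  L <- locus$exonic_length
  n_codons <- L %/% 3L
  protected <- c(1:3, seq(3L * (n_codons - 1L) + 1L, L), exclude)
  bases <- strsplit(locus$exonic_seq, "", fixed = TRUE)[[1]]
  withr::with_seed(seed, {
    n <- stats::rbinom(1, L, rate)
    free <- setdiff(seq_len(L), protected)
    pos <- sort(sample(free, min(n, length(free))))
    out <- list()
    used_codons <- integer(0)   # one hit per codon keeps checks independent
    for (p in pos) {
      k <- (p - 1L) %/% 3L + 1L
      if (k %in% used_codons) next
      idx <- (3L * (k - 1L) + 1L):(3L * k)
      slot <- p - idx[1] + 1L
      for (b in sample(setdiff(c("A", "C", "G", "T"), bases[p]))) {
        cd <- bases[idx]
        cd[slot] <- b
        if (!is_possible_stop(paste(cd, collapse = ""))) {
          out <- c(out, list(lesion_point(p, b)))
          used_codons <- c(used_codons, k)
          break
        }
      }
    }
    out
  })
}

# find a single substitution near the requested codon that turns the
# reference codon into a stop (used to implant substitution-only nonsense)
nonsense_substitution <- function(locus, near_codon) {
  n_codons <- locus$exonic_length %/% 3L
  bases <- strsplit(locus$exonic_seq, "", fixed = TRUE)[[1]]
  ks <- order(abs(seq_len(n_codons - 1L) - near_codon))
  for (k in setdiff(ks, 1L)) {
    idx <- (3L * (k - 1L) + 1L):(3L * k)
    cd <- bases[idx]
    for (stop in STOP_CODONS) {
      st <- strsplit(stop, "", fixed = TRUE)[[1]]
      diff <- which(cd != st)
      if (length(diff) == 1L) {
        return(lesion_point(idx[diff], st[diff]))
      }
    }
  }
  abort("no single-substitution nonsense site found")
}

#' Simulate the full murine-style screening fixture
#'
#' Builds the default desk-scale stand-in for a murine pseudogene survey:
#' a 6-exon locus whose exons sum to 626 bp, about 40 taxa, and one
#' designated 10-taxon clade carrying the classic lesion catalogue — an
#' initiation-codon substitution (ATG to ATA) plus a 1-bp deletion at exonic
#' position 6 in one taxon, a shared 4-bp insertion in exon 1 and a shared
#' 4-bp deletion at position 251 in exon 3 across a subgroup, a 1-bp
#' deletion at position 22, substitution-only nonsense in two taxa, an
#' ambiguity code, and a masked (unsequenced) trailing segment in one
#' partial taxon. All other taxa receive only stop-avoiding neutral noise,
#' so they stay intact by construction. A ladder species tree is attached
#' in which the intact `micromys_like` and `maxomys_like` lineages diverge
#' before the lesioned clade, `maxomys_like` being its immediate sister.
#'
#' @param seed Integer seed controlling every random draw.
#' @param n_background Number of intact background taxa outside the focal
#'   tribe (default 26, for 40 taxa in total).
#' @param noise_rate Neutral substitution rate per exonic site on
#'   non-reference taxa (default 0.01).
#' @return A list: `alignment`, `exons`, `tree` (`phylo`), `truth` (per
#'   taxon, from the generator's independent oracle), `loss_clade`
#'   (character vector: tips of the clade whose stem carries the implanted
#'   loss), `locus`, `scenarios`.
#' @export
simulate_murinae_fixture <- function(seed = 1, n_background = 26,
                                     noise_rate = 0.01) {
  locus <- make_reference_locus(seed)
  clade <- c("rnor_like", "rexulans_like", "rrattus_like", "rtanezumi_like",
             "berylmys_like", "bandicota_like", "bunomys_like",
             "diplothrix_like", "niviventer_like", "chiromyscus_like")
  shared_ins <- lesion_insertion(100, "ACCT")
  shared_del <- lesion_deletion(251, 4)
  nonsense1 <- nonsense_substitution(locus, near_codon = 160)
  nonsense2 <- nonsense_substitution(locus, near_codon = 60)

  scenarios <- list(
    rnor_like = list(lesion_start_loss(), lesion_deletion(6, 1),
                     shared_ins, shared_del),
    rexulans_like = list(shared_ins, shared_del, lesion_ambiguity(180, "Y")),
    rrattus_like = list(shared_ins, shared_del),
    rtanezumi_like = list(shared_ins, shared_del),
    berylmys_like = list(lesion_deletion(22, 1)),
    bandicota_like = list(shared_del),
    bunomys_like = list(shared_del),
    diplothrix_like = list(shared_del),
    niviventer_like = list(nonsense1),
    chiromyscus_like = list(nonsense2),
    micromys_like = list(),
    maxomys_like = list(),
    leopoldamys_like = list(lesion_mask(5, 6))
  )
  bg <- sprintf("murinae_%02d", seq_len(n_background))
  for (nm in bg) scenarios[[nm]] <- list()

  # stop-avoiding neutral noise on every non-reference taxon, away from
  # implanted lesions; the exclusion is widened to whole codons so noise can
  # never rewrite another base of a codon a lesion relies on
  for (i in seq_along(scenarios)) {
    nm <- names(scenarios)[i]
    claimed <- unlist(purrr::map(scenarios[[nm]], lesion_span, locus = locus))
    if (length(claimed)) {
      codons <- unique((claimed - 1L) %/% 3L)
      claimed <- unique(c(claimed, claimed + 1L,
                          as.vector(outer(3L * codons, 1:3, `+`))))
    }
    noise <- neutral_noise_lesions(locus, rate = noise_rate,
                                   seed = seed * 1000L + i,
                                   exclude = claimed)
    scenarios[[nm]] <- c(scenarios[[nm]], noise)
  }

  sim <- apply_scenarios(locus, scenarios)

  ladder <- function(tips) {
    out <- tips[1]
    for (t in tips[-1]) out <- paste0("(", out, ",", t, ")")
    out
  }
  clade_nwk <- ladder(clade)
  tribe <- paste0("(micromys_like,(leopoldamys_like,(maxomys_like,",
                  clade_nwk, ")))")
  nwk <- paste0("(", ladder(c("reference", bg)), ",", tribe, ");")
  tree <- ape::read.tree(text = nwk)

  list(alignment = sim$alignment, exons = locus$exons, tree = tree,
       truth = sim$truth, loss_clade = sort(clade), locus = locus,
       scenarios = scenarios)
}

#' Simulate a qPCR Ct table with an implanted group effect
#'
#' Draws threshold-cycle values for a two-group oviduct-style design:
#' per-sample loading offsets, per-gene baseline Ct, triplicate wells with
#' Gaussian per-replicate noise, and a log2 expression effect implanted
#' into every target gene of the test group. The expected fold change
#' (test relative to control, target normalized to any reference gene) is
#' `2^effect_log2`.
#'
#' @param seed Integer seed.
#' @param n_per_group Samples per group (default 3).
#' @param n_replicates Replicate wells per sample and gene (default 3).
#' @param effect_log2 Implanted log2 fold change of every target in the
#'   test group (default 0).
#' @param sd_ct Per-replicate Ct noise in cycles (default 0.2); 0 gives
#'   exact recovery of the implanted effect.
#' @param targets,references Gene panels (defaults mirror a four-chitinase
#'   panel with two endogenous references).
#' @param groups Length-2 character vector `c(control, test)`; the first
#'   entry is the calibrator.
#' @return A list: `records` (tibble `sample`, `group`, `gene`, `ct`) and
#'   `truth` (`effect_log2`, `expected_fold_change`).
#' @export
make_qpcr_table <- function(seed, n_per_group = 3, n_replicates = 3,
                            effect_log2 = 0, sd_ct = 0.2,
                            targets = c("Chia", "Chit1", "Chi3l1", "Chid1"),
                            references = c("Actb1", "Hprt1"),
                            groups = c("postovulatory", "day3")) {
  stopifnot(n_per_group >= 2, length(groups) == 2)
  withr::with_seed(seed, {
    genes <- c(targets, references)
    base_ct <- stats::setNames(stats::runif(length(genes), 18, 28), genes)
    design <- tidyr::expand_grid(
      group = groups,
      idx = seq_len(n_per_group)
    ) |>
      mutate(sample = sprintf("%s_%d", .data$group, .data$idx),
             loading = stats::rnorm(dplyr::n(), 0, 0.5))
    records <- tidyr::expand_grid(design, gene = genes,
                                  rep = seq_len(n_replicates)) |>
      mutate(
        shift = ifelse(.data$gene %in% targets & .data$group == groups[2],
                       -effect_log2, 0),
        ct = base_ct[.data$gene] + .data$loading + .data$shift +
          stats::rnorm(dplyr::n(), 0, sd_ct)
      ) |>
      select("sample", "group", "gene", "ct")
    list(records = records,
         truth = tibble(effect_log2 = effect_log2,
                        expected_fold_change = 2^effect_log2))
  })
}

#' Simulate proteins, isoforms and implanted peptides with ground truth
#'
#' Generates per-gene protein sequences with isoforms (N-terminally
#' truncated variants), then draws a set of distinct peptides from each
#' gene's canonical isoform. The truth table records how many distinct
#' peptides were implanted per gene; peptides are checked to be unique to
#' their gene so that [summarize_counts()] can be validated exactly.
#'
#' @param seed Integer seed.
#' @param genes Character vector of gene names.
#' @param n_isoforms Isoforms per gene (default 2).
#' @param protein_length Canonical isoform length (default 300).
#' @param n_peptides Distinct peptides implanted per gene (default 5).
#' @param peptide_lengths Range peptide lengths are drawn from.
#' @return A list: `proteins` (named character vector), `peptides`,
#'   `groupings` (tibble `protein`/`gene`), `truth` (tibble `gene`,
#'   `n_peptides`), `spans` (tibble of implanted spans in the canonical
#'   isoform).
#' @export
make_peptide_set <- function(seed, genes = c("geneA", "geneB", "geneC"),
                             n_isoforms = 2, protein_length = 300,
                             n_peptides = 5, peptide_lengths = 9:15) {
  withr::with_seed(seed, {
    proteins <- character(0)
    groupings <- tibble(protein = character(0), gene = character(0))
    spans <- tibble(gene = character(0), peptide = character(0),
                    start = integer(0), end = integer(0))
    peptides <- character(0)
    for (g in genes) {
      canon <- paste(sample(AA_ALPHABET, protein_length, replace = TRUE),
                     collapse = "")
      ids <- sprintf("%s_iso%d", g, seq_len(n_isoforms))
      seqs <- c(canon, purrr::map_chr(seq_len(n_isoforms - 1), function(i) {
        substr(canon, 1 + 10 * i, protein_length)
      }))
      proteins[ids] <- seqs
      groupings <- bind_rows(groupings, tibble(protein = ids, gene = g))
      starts <- sort(sample(seq(1, protein_length - max(peptide_lengths)),
                            n_peptides))
      for (s in starts) {
        len <- sample(peptide_lengths, 1)
        pep <- substr(canon, s, s + len - 1)
        peptides <- c(peptides, pep)
        spans <- bind_rows(spans, tibble(gene = g, peptide = pep,
                                         start = s, end = s + len - 1L))
      }
    }
    # implanted peptides must be unique and gene-specific for exact truth
    stopifnot(!anyDuplicated(peptides))
    for (i in seq_len(nrow(spans))) {
      others <- proteins[groupings$gene != spans$gene[i]]
      stopifnot(!any(vapply(others, grepl, logical(1),
                            pattern = spans$peptide[i], fixed = TRUE)))
    }
    truth <- spans |> distinct(.data$gene, .data$peptide) |>
      count(.data$gene, name = "n_peptides")
    list(proteins = proteins, peptides = unique(peptides),
         groupings = groupings, truth = truth, spans = spans)
  })
}
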