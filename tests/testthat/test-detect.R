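locus_det <- make_reference_locus(seed = 31, exon_lengths = c(90, 90, 90),
                                  intron_length = 40)

screen_one <- function(scen, taxon = names(scen)[1]) {
  scen$clean_ <- list()
  sim <- apply_scenarios(locus_det, scen)
  cmap <- build_coding_map(sim$alignment, "reference", locus_det$exons)
  list(sim = sim, cmap = cmap,
       muts = detect_disabling_mutations(sim$alignment, cmap, taxon))
}

test_that("a taxon equal to the reference has no disabling mutations", {
  r <- screen_one(list(same = list()))
  expect_equal(nrow(r$muts), 0)
})

test_that("ATG to ATA yields a forced start loss at position 1", {
  r <- screen_one(list(rn = list(lesion_start_loss())))
  sl <- r$muts[r$muts$kind == "start_loss", ]
  expect_equal(nrow(sl), 1)
  expect_equal(sl$certainty, "forced")
  expect_equal(sl$aln_nt_pos, 1)
})

test_that("an ambiguous start codon gives a possible start loss only", {
  # ATG with R at position 3 resolves to {ATA, ATG}: possibly intact
  r <- screen_one(list(amb = list(lesion_ambiguity(3, "R"))))
  sl <- r$muts[r$muts$kind == "start_loss", ]
  expect_equal(sl$certainty, "possible")
  status <- classify_taxon(r$muts, coverage = 1)
  expect_equal(status$call, "indeterminate")
})

test_that("a 4-base deletion is a frameshift whose stops match the oracle", {
  r <- screen_one(list(d4 = list(lesion_deletion(100, 4))))
  fs <- r$muts[r$muts$kind == "frameshift_indel", ]
  expect_equal(fs$length, 4L)
  expect_equal(fs$aln_nt_pos, 100L)
  expect_equal(fs$certainty, "forced")
  ref_seq <- r$sim$alignment$sequence[r$sim$alignment$taxon == "reference"]
  tax_seq <- r$sim$alignment$sequence[r$sim$alignment$taxon == "d4"]
  expected <- oracle_forced_stops(ref_seq, tax_seq, r$cmap$column,
                                  locus_det$exonic_length)
  got <- r$muts$aln_nt_pos[r$muts$kind == "premature_stop" &
                             r$muts$certainty == "forced"]
  expect_gt(length(got), 0)
  expect_equal(sort(got), sort(expected))
})

test_that("a codon resolving only to stops is a forced premature stop", {
  # implant T-R-A in frame at codon 21 (positions 61..63): {TAA, TGA}
  sim <- apply_scenarios(locus_det, list(
    tra = list(lesion_point(61, "T"), lesion_ambiguity(62, "R"),
               lesion_point(63, "A")),
    clean_ = list()
  ))
  cmap <- build_coding_map(sim$alignment, "reference", locus_det$exons)
  muts <- detect_disabling_mutations(sim$alignment, cmap, "tra")
  ps <- muts[muts$kind == "premature_stop" & muts$aln_nt_pos == 61, ]
  expect_equal(nrow(ps), 1)
  expect_equal(ps$certainty, "forced")
})

test_that("a codon with some stop resolutions is only a possible stop", {
  # T-A-Y resolves to {TAC, TAT}; T-R-R resolves to {TAA,TAG,TGA,TGG}
  sim <- apply_scenarios(locus_det, list(
    maybe = list(lesion_point(91, "T"), lesion_ambiguity(92, "R"),
                 lesion_ambiguity(93, "R")),
    clean_ = list()
  ))
  cmap <- build_coding_map(sim$alignment, "reference", locus_det$exons)
  muts <- detect_disabling_mutations(sim$alignment, cmap, "maybe")
  ps <- muts[muts$kind == "premature_stop" & muts$aln_nt_pos == 91, ]
  expect_equal(ps$certainty, "possible")
  expect_equal(classify_taxon(muts, coverage = 1)$call, "indeterminate")
})

test_that("masking bases with N never creates forced calls", {
  locus <- make_reference_locus(seed = 33, exon_lengths = c(90, 90))
  sim <- apply_scenarios(locus, list(a = list(), b = list()))
  aln <- sim$alignment
  withr::with_seed(34, {
    for (rep in 1:20) {
      seq <- strsplit(aln$sequence[aln$taxon == "a"], "")[[1]]
      pos <- sample(which(seq != "-"), 15)
      seq[pos] <- "N"
      masked <- aln
      masked$sequence[masked$taxon == "a"] <- paste(seq, collapse = "")
      cmap <- build_coding_map(masked, "reference", locus$exons)
      muts <- detect_disabling_mutations(masked, cmap, "a")
      expect_true(all(muts$certainty == "possible"))
      w <- classify_taxon(muts, coverage = 0.9)
      expect_true(w$call %in% c("intact", "indeterminate"))
    }
  })
})

test_that("stop positions are strictly increasing and bounded", {
  fix <- simulate_murinae_fixture(seed = 8, n_background = 2)
  st <- suppressWarnings(
    screen_alignment(fix$alignment, "reference", fix$exons)
  )
  for (m in st$mutations) {
    stops <- m$aln_nt_pos[m$kind == "premature_stop"]
    expect_true(all(diff(stops) > 0))
    expect_true(all(stops <= 626))
  }
})

test_that("detection errors on an unknown taxon", {
  sim <- apply_scenarios(locus_det, list(a = list(), b = list()))
  cmap <- build_coding_map(sim$alignment, "reference", locus_det$exons)
  expect_error(detect_disabling_mutations(sim$alignment, cmap, "nosuch"),
               "unknown taxon")
})

test_that("classification follows the forced/possible/coverage rules", {
  none <- tibble::tibble(kind = character(0), aln_nt_pos = integer(0),
                         length = integer(0), certainty = character(0),
                         frame_offset_at_site = integer(0))
  expect_equal(classify_taxon(none, 1.0)$call, "intact")
  expect_equal(classify_taxon(none, 0.4, coverage_threshold = 0.5)$call,
               "indeterminate")
  one_stop <- tibble::tibble(kind = "premature_stop", aln_nt_pos = 478L,
                             length = NA_integer_, certainty = "forced",
                             frame_offset_at_site = 0L)
  expect_equal(classify_taxon(one_stop, 0.6)$call, "pseudogenized")
})
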