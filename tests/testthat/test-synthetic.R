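test_that("reference loci are deterministic and well-formed", {
  a <- make_reference_locus(seed = 9)
  b <- make_reference_locus(seed = 9)
  expect_identical(a$sequence, b$sequence)
  expect_identical(a$exons, b$exons)
  expect_equal(a$exonic_length, 626)
  expect_equal(substr(a$exonic_seq, 1, 3), "ATG")
  expect_error(make_reference_locus(1, exon_lengths = c(4, 4)), "bad spec")
})

test_that("no reference locus carries an internal in-frame stop", {
  stops <- c("TAA", "TAG", "TGA")
  for (seed in 1:1000) {
    locus <- make_reference_locus(seed, exon_lengths = c(51, 42),
                                  intron_length = 10)
    cds <- locus$exonic_seq
    n <- nchar(cds) %/% 3
    codons <- substring(cds, seq(1, 3 * n, 3), seq(3, 3 * n, 3))
    expect_equal(codons[1], "ATG")
    expect_true(codons[n] %in% stops)
    expect_false(any(codons[2:(n - 1)] %in% stops))
  }
})

test_that("exon annotations slice the genomic sequence to the exonic CDS", {
  locus <- make_reference_locus(seed = 13)
  pieces <- purrr::map2_chr(locus$exons$start, locus$exons$end,
                            function(s, e) substr(locus$sequence, s + 1, e))
  expect_equal(paste(pieces, collapse = ""), locus$exonic_seq)
})

test_that("an empty scenario list yields reference copies, all intact", {
  locus <- make_reference_locus(seed = 14, exon_lengths = c(60, 60))
  sim <- apply_scenarios(locus, list(a = list(), b = list(), c = list()))
  expect_true(all(nchar(sim$alignment$sequence) ==
                    nchar(locus$sequence)))
  expect_true(all(sim$truth$expected_call == "intact"))
  st <- screen_alignment(sim$alignment, "reference", locus$exons)
  expect_true(all(st$call == "intact"))
  ev <- dollo_losses(
    ape::read.tree(text = "((a,b),c);"),
    dplyr::filter(tibble::as_tibble(st), taxon != "reference")
  )
  expect_equal(nrow(ev), 0)
})

test_that("overlapping lesions on one taxon are rejected", {
  locus <- make_reference_locus(seed = 15, exon_lengths = c(60, 60))
  expect_error(
    apply_scenarios(locus, list(bad = list(lesion_deletion(10, 4),
                                           lesion_point(12, "A")))),
    "conflicting lesions"
  )
  expect_error(
    apply_scenarios(locus, list(bad = list(lesion_point(500, "A")))),
    "conflicting lesions"
  )
})

test_that("a clade-wide shared deletion pseudogenizes the clade and its stem", {
  locus <- make_reference_locus(seed = 16)
  clade <- paste0("c", 1:4)
  scen <- c(
    stats::setNames(
      purrr::map(clade, ~ list(lesion_deletion(251, 4))), clade
    ),
    list(out1 = list(), out2 = list())
  )
  sim <- apply_scenarios(locus, scen)
  expect_true(all(
    sim$truth$expected_call[sim$truth$taxon %in% clade] == "pseudogenized"
  ))
  st <- suppressWarnings(
    screen_alignment(sim$alignment, "reference", locus$exons)
  )
  tree <- ape::read.tree(
    text = "((out1,(out2,(((c1,c2),c3),c4))),reference);"
  )
  ev <- dollo_losses(tree, st)
  expect_equal(nrow(ev), 1)
  expect_setequal(ev$clade_tips[[1]], clade)
})

test_that("generator outputs are byte-identical under one seed", {
  f1 <- simulate_murinae_fixture(seed = 17, n_background = 4)
  f2 <- simulate_murinae_fixture(seed = 17, n_background = 4)
  expect_identical(f1$alignment, f2$alignment)
  expect_identical(ape::write.tree(f1$tree), ape::write.tree(f2$tree))
  expect_identical(f1$truth, f2$truth)
  q1 <- make_qpcr_table(seed = 18)
  q2 <- make_qpcr_table(seed = 18)
  expect_identical(q1$records, q2$records)
})

test_that("qPCR truth tracks the implanted effect in the noiseless limit", {
  qp <- make_qpcr_table(seed = 19, effect_log2 = 1.5, sd_ct = 0)
  fit <- delta_delta_ct(qp$records, "Chi3l1", "Actb1",
                        "day3", "postovulatory")
  expect_equal(fit$fold_change, qp$truth$expected_fold_change,
               tolerance = 1e-10)
})

test_that("full-pipeline recovery over seeded end-to-end runs", {
  for (seed in 1:8) {
    fix <- simulate_murinae_fixture(seed, n_background = 4)
    st <- suppressWarnings(
      screen_alignment(fix$alignment, "reference", fix$exons)
    )
    merged <- dplyr::left_join(fix$truth, tibble::as_tibble(st),
                               by = "taxon")
    expect_equal(merged$call, merged$expected_call, info = seed)
    ev <- dollo_losses(fix$tree, st)
    expect_equal(nrow(ev), 1, info = seed)
    expect_setequal(ev$clade_tips[[1]], fix$loss_clade)
  }
})
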