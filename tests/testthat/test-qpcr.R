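ct_table <- function(test_dct, ctrl_dct, ref_ct = 20) {
  # one replicate per well, reference gene flat at ref_ct
  dplyr::bind_rows(
    tibble::tibble(sample = paste0("t", seq_along(test_dct)), group = "test",
                   gene = "tg", ct = ref_ct + test_dct),
    tibble::tibble(sample = paste0("t", seq_along(test_dct)), group = "test",
                   gene = "ref", ct = ref_ct),
    tibble::tibble(sample = paste0("c", seq_along(ctrl_dct)), group = "ctrl",
                   gene = "tg", ct = ref_ct + ctrl_dct),
    tibble::tibble(sample = paste0("c", seq_along(ctrl_dct)), group = "ctrl",
                   gene = "ref", ct = ref_ct)
  )
}

test_that("closed-form ddCt cases come out exactly", {
  fit0 <- delta_delta_ct(ct_table(c(4, 4, 4), c(4, 4, 4)),
                         "tg", "ref", "test", "ctrl")
  expect_equal(fit0$ddct, 0)
  expect_equal(fit0$fold_change, 1)

  fit1 <- delta_delta_ct(ct_table(c(5, 5, 5), c(4, 4, 4)),
                         "tg", "ref", "test", "ctrl")
  expect_equal(fit1$ddct, 1)
  expect_equal(fit1$fold_change, 0.5)
})

test_that("a random triplicate table matches longhand recomputation", {
  qp <- make_qpcr_table(seed = 77, effect_log2 = 0.7, sd_ct = 0.3)
  rec <- qp$records
  fit <- delta_delta_ct(rec, "Chit1", "Hprt1", "day3", "postovulatory")
  # longhand: average replicates, per-sample dCt, group means
  long_dct <- function(s) {
    tgt <- mean(rec$ct[rec$sample == s & rec$gene == "Chit1"])
    ref <- mean(rec$ct[rec$sample == s & rec$gene == "Hprt1"])
    tgt - ref
  }
  samples <- unique(rec$sample)
  dct <- vapply(samples, long_dct, numeric(1))
  grp <- rec$group[match(samples, rec$sample)]
  ddct <- mean(dct[grp == "day3"]) - mean(dct[grp == "postovulatory"])
  expect_equal(fit$ddct, ddct)
  expect_equal(fit$fold_change, 2^-ddct)
  welch <- stats::t.test(dct[grp == "day3"], dct[grp == "postovulatory"])
  expect_equal(fit$p_value, welch$p.value)
  expect_equal(dplyr::arrange(tidy(fit), sample)$delta_ct,
               unname(dct[order(samples)]))
})

test_that("fold changes are invariant to a constant Ct shift", {
  qp <- make_qpcr_table(seed = 78, effect_log2 = -0.5)
  f1 <- delta_delta_ct(qp$records, "Chia", "Actb1", "day3", "postovulatory")
  shifted <- dplyr::mutate(qp$records, ct = ct + 3.21)
  f2 <- delta_delta_ct(shifted, "Chia", "Actb1", "day3", "postovulatory")
  expect_equal(f1$fold_change, f2$fold_change)
  expect_equal(f1$ddct, f2$ddct)
})

test_that("target equal to reference gives fold change exactly 1", {
  qp <- make_qpcr_table(seed = 79, effect_log2 = 1)
  fit <- delta_delta_ct(qp$records, "Actb1", "Actb1",
                        "day3", "postovulatory")
  expect_identical(fit$fold_change, 1)
  expect_identical(fit$ddct, 0)
})

test_that("noiseless data recover the implanted effect exactly", {
  qp <- make_qpcr_table(seed = 80, effect_log2 = -1, sd_ct = 0)
  fit <- delta_delta_ct(qp$records, "Chid1", "Hprt1",
                        "day3", "postovulatory")
  expect_equal(fit$fold_change, 0.5, tolerance = 1e-10)
  qp2 <- make_qpcr_table(seed = 80, effect_log2 = 0, sd_ct = 0)
  fit2 <- delta_delta_ct(qp2$records, "Chid1", "Hprt1",
                         "day3", "postovulatory")
  expect_equal(fit2$fold_change, 1, tolerance = 1e-10)
})

test_that("a missing gene raises an incomplete-design error", {
  qp <- make_qpcr_table(seed = 81)
  broken <- dplyr::filter(qp$records,
                          !(gene == "Chia" & sample == "day3_1"))
  expect_error(
    delta_delta_ct(broken, "Chia", "Actb1", "day3", "postovulatory"),
    "incomplete design"
  )
})

test_that("run_panel reports every target-reference pair with flags", {
  qp <- make_qpcr_table(seed = 82, effect_log2 = 2, sd_ct = 0.1)
  panel <- run_panel(qp$records,
                     targets = c("Chia", "Chit1", "Chi3l1", "Chid1"),
                     references = c("Actb1", "Hprt1"),
                     test_group = "day3", control_group = "postovulatory")
  expect_equal(nrow(panel), 8)
  expect_true(all(panel$fold_change > 0))
  combined <- run_panel(qp$records,
                        targets = c("Chia", "Chit1"),
                        references = c("Actb1", "Hprt1"),
                        test_group = "day3",
                        control_group = "postovulatory",
                        combine_refs = "mean")
  expect_equal(nrow(combined), 2)
  expect_true(all(combined$reference == "Actb1+Hprt1"))
})

test_that("glance and tidy expose the broom-style surfaces", {
  qp <- make_qpcr_table(seed = 83)
  fit <- delta_delta_ct(qp$records, "Chia", "Actb1",
                        "day3", "postovulatory")
  g <- glance(fit)
  expect_equal(nrow(g), 1)
  expect_named(g, c("target", "reference", "ddct", "fold_change",
                    "statistic", "df", "p_value", "n_test", "n_control"))
  expect_equal(g$n_test, 3)
  t <- tidy(fit)
  expect_equal(nrow(t), 6)
})
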