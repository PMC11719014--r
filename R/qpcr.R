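#' Relative quantification by the 2^-ddCt method
#'
#' Computes relative expression of a target gene against an endogenous
#' reference gene between two groups. Replicate Ct values are averaged
#' (arithmetic mean) per sample and gene first; per-sample
#' \eqn{\Delta Ct = Ct_{target} - Ct_{reference}}; then
#' \eqn{\Delta\Delta Ct = \overline{\Delta Ct}_{test} -
#' \overline{\Delta Ct}_{control}} and the fold change is
#' \eqn{2^{-\Delta\Delta Ct}}. The control group is the calibrator. Group
#' difference in per-sample \eqn{\Delta Ct} is tested with a two-sided
#' Welch t-test.
#'
#' @param records Tibble with columns `sample`, `group`, `gene`, `ct`
#'   (one row per replicate well).
#' @param target Target gene name.
#' @param reference Endogenous reference gene name, or a character vector of
#'   reference genes whose per-sample mean Ct is used (`combine_refs`
#'   behaviour of [run_panel()]).
#' @param test_group,control_group Group labels; `control_group` is the
#'   calibrator.
#' @return An object of class `ddct_fit`; see [tidy.ddct_fit()] and
#'   [glance.ddct_fit()].
#' @export
#' @examples
#' ct <- make_qpcr_table(seed = 1, effect_log2 = -1)$records
#' fit <- delta_delta_ct(ct, "Chia", "Actb1", "day3", "postovulatory")
#' glance(fit)
delta_delta_ct <- function(records, target, reference,
                           test_group, control_group) {
  stopifnot(all(c("sample", "group", "gene", "ct") %in% names(records)))
  if (any(!is.finite(records$ct)) || any(records$ct <= 0)) {
    abort("Ct values must be finite and > 0")
  }
  records <- filter(records, .data$group %in% c(test_group, control_group))
  per_sample <- records |>
    group_by(.data$sample, .data$group, .data$gene) |>
    summarise(ct = mean(.data$ct), .groups = "drop")

  wide <- per_sample |>
    filter(.data$gene %in% c(target, reference))
  have <- wide |> count(.data$sample, name = "n_genes")
  need <- length(unique(c(target, reference)))
  samples <- unique(per_sample$sample)
  if (any(!samples %in% have$sample) || any(have$n_genes < need)) {
    abort(paste0("incomplete design: target '", target,
                 "' or reference missing in some sample"))
  }

  dct <- per_sample |>
    group_by(.data$sample, .data$group) |>
    summarise(
      delta_ct = mean(.data$ct[.data$gene == target]) -
        mean(.data$ct[.data$gene %in% reference]),
      .groups = "drop"
    )
  m_test <- mean(dct$delta_ct[dct$group == test_group])
  m_ctrl <- mean(dct$delta_ct[dct$group == control_group])
  ddct <- m_test - m_ctrl
  test <- tryCatch(
    stats::t.test(dct$delta_ct[dct$group == test_group],
                  dct$delta_ct[dct$group == control_group],
                  var.equal = FALSE),
    error = function(e) NULL
  )
  structure(list(
    target = target,
    reference = paste(reference, collapse = "+"),
    test_group = test_group,
    control_group = control_group,
    delta_ct = dct,
    ddct = ddct,
    fold_change = 2^(-ddct),
    statistic = if (is.null(test)) NA_real_ else unname(test$statistic),
    df = if (is.null(test)) NA_real_ else unname(test$parameter),
    p_value = if (is.null(test)) NA_real_ else test$p.value
  ), class = "ddct_fit")
}

#' @export
print.ddct_fit <- function(x, ...) {
  cat(sprintf(
    "2^-ddCt fit: %s vs %s (%s relative to %s)\n  ddCt = %.4f, fold change = %.4f, Welch p = %s\n",
    x$target, x$reference, x$test_group, x$control_group,
    x$ddct, x$fold_change,
    ifelse(is.na(x$p_value), "NA", format.pval(x$p_value, digits = 3))
  ))
  invisible(x)
}

#' Per-sample delta-Ct values of a ddCt fit
#'
#' @param x A `ddct_fit` object.
#' @param ... Unused.
#' @return Tibble with one row per sample: `sample`, `group`, `delta_ct`.
#' @method tidy ddct_fit
#' @export
tidy.ddct_fit <- function(x, ...) {
  x$delta_ct
}

#' One-row summary of a ddCt fit
#'
#' @param x A `ddct_fit` object.
#' @param ... Unused.
#' @return One-row tibble: `target`, `reference`, `ddct`, `fold_change`,
#'   `statistic`, `df`, `p_value`, `n_test`, `n_control`.
#' @method glance ddct_fit
#' @export
glance.ddct_fit <- function(x, ...) {
  tibble(
    target = x$target, reference = x$reference,
    ddct = x$ddct, fold_change = x$fold_change,
    statistic = x$statistic, df = x$df, p_value = x$p_value,
    n_test = sum(x$delta_ct$group == x$test_group),
    n_control = sum(x$delta_ct$group == x$control_group)
  )
}

#' Run a ddCt panel over target and reference gene sets
#'
#' Computes one [delta_delta_ct()] result per (target, reference) pair —
#' the default when two endogenous reference genes were measured — or one
#' per target against the per-sample mean of the references
#' (`combine_refs = "mean"`). Each row carries a `significant` flag
#' (`p < alpha`).
#'
#' @inheritParams delta_delta_ct
#' @param targets Character vector of target genes.
#' @param references Character vector of endogenous reference genes.
#' @param combine_refs `"separate"` (default) or `"mean"`.
#' @param alpha Significance level for the `significant` flag (default
#'   0.05).
#' @return A tibble of class `ddct_panel`: the [glance.ddct_fit()] rows of
#'   every analysis plus `significant`.
#' @export
run_panel <- function(records, targets, references,
                      test_group, control_group,
                      combine_refs = c("separate", "mean"),
                      alpha = 0.05) {
  combine_refs <- match.arg(combine_refs)
  ref_sets <- if (combine_refs == "separate") {
    as.list(references)
  } else {
    list(references)
  }
  grid <- tidyr::expand_grid(target = targets, ref = ref_sets)
  out <- purrr::pmap(grid, function(target, ref) {
    glance(delta_delta_ct(records, target, ref, test_group, control_group))
  }) |>
    bind_rows() |>
    mutate(significant = !is.na(.data$p_value) & .data$p_value < alpha)
  class(out) <- c("ddct_panel", class(out))
  attr(out, "alpha") <- alpha
  out
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance
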