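#' Correct a thickness grid to a reference age (and covariates)
#'
#' Applies the per-cluster aging model as an additive age correction: each
#' valid square's value is shifted by `model_k(ref_age) - model_k(age)`
#' for the cluster `k` containing that square, plus, for each supplied
#' covariate correction, `estimate * (ref_value - value)`.
#'
#' @param grid A participant's [thickness_grid()].
#' @param demo_row The participant's one-row demographics data.frame.
#' @param clusters A `cluster_model` with fitted `models`.
#' @param ref_age Reference age-equivalent (years); must lie within the
#'   models' fitted age range.
#' @param covariate_corrections Optional named list, e.g.
#'   `list(refraction = list(estimate = .201, ref_value = -0.7), sex =
#'   list(estimate = .594, ref_value = 0.4))`; `value` is taken from
#'   `demo_row` (sex coded M=0/F=1).
#' @param age_range Fitted age range used for the `ref_age` check.
#' @return A corrected `thickness_grid`.
#' @export
correct_to_reference <- function(grid, demo_row, clusters, ref_age,
                                 covariate_corrections = list(),
                                 age_range = c(20, 85)) {
  stopifnot(inherits(grid, "thickness_grid"), nrow(demo_row) == 1,
            inherits(clusters, "cluster_model"), !is.null(clusters$models))
  if (ref_age < age_range[1] || ref_age > age_range[2])
    stop("ref_age outside the fitted age range")
  lab <- clusters$labels
  if (any(grid$valid & lab == 0))
    stop("valid grid square without a cluster label")
  shift <- matrix(0, grid$grid$n, grid$grid$n)
  for (k in seq_len(clusters$k)) {
    m <- clusters$models[[k]]
    shift[lab == k] <- predict(m, ref_age) - predict(m, demo_row$age_years)
  }
  for (v in names(covariate_corrections)) {
    cc <- covariate_corrections[[v]]
    val <- switch(v,
                  sex = as.numeric(demo_row$sex == "F"),
                  refraction = demo_row$refraction_D,
                  ethnicity = as.numeric(demo_row$ethnicity == "Asian"),
                  bcva = demo_row$bcva_logmar,
                  stop("unknown covariate: ", v))
    shift <- shift + cc$estimate * (cc$ref_value - val)
  }
  out <- grid
  out$values_um <- ifelse(grid$valid, grid$values_um + shift, NA_real_)
  out
}

#' Square-wise cohort summary
#'
#' Per-square summary (median by default) across a cohort's grids; squares
#' not valid in every grid are dropped (`NA`).
#'
#' @param grids List of [thickness_grid()]s.
#' @param fun Summary function (default `median`).
#' @return Numeric vector of length `n^2` (grid column-major order).
#' @export
squarewise_summary <- function(grids, fun = stats::median) {
  vals <- vapply(grids, function(g) as.vector(g$values_um),
                 numeric(grids[[1]]$grid$n^2))
  apply(vals, 1, function(x) if (anyNA(x)) NA_real_ else fun(x))
}

#' Hodges-Lehmann estimator of a location difference
#'
#' Median of all pairwise differences `x_i - y_j` between two unpaired
#' samples.
#'
#' @param x,y Numeric samples.
#' @return The Hodges-Lehmann estimate.
#' @export
hodges_lehmann <- function(x, y) {
  stats::median(outer(x, y, `-`))
}

#' Agreement battery between two square-wise cohorts
#'
#' Runs the full agreement analysis between per-square summaries of a
#' corrected cohort (`a`) and a reference cohort (`b`): Hodges-Lehmann
#' difference in medians with 95% CI and an unpaired Mann-Whitney test;
#' Bland-Altman bias and 1.96-SD limits of agreement on the square-wise
#' (difference, mean) pairs; an OLS regression of difference on mean with
#' its F-test, R^2, 95% prediction-interval width (evaluated at the
#' midpoint of the observed mean range) and the maximum predicted
#' difference (max |fitted| over the observed mean range plus half the
#' prediction-interval width).
#'
#' @param a,b Square-wise value vectors (paired by square; `NA`s dropped
#'   pairwise). At least 3 complete squares required.
#' @param exact_hl Use the O(n^2) pairwise HL estimator directly (default);
#'   the CI comes from [stats::wilcox.test()].
#' @return Object of class `agreement_report`.
#' @export
agreement_battery <- function(a, b, exact_hl = TRUE) {
  stopifnot(length(a) == length(b))
  ok <- is.finite(a) & is.finite(b)
  a <- a[ok]; b <- b[ok]
  if (length(a) < 3) stop("need at least 3 complete squares")
  wt <- suppressWarnings(stats::wilcox.test(a, b, conf.int = TRUE,
                                            exact = FALSE))
  hl <- if (exact_hl) hodges_lehmann(a, b) else unname(wt$estimate)
  d <- a - b; m <- (a + b) / 2
  bias <- mean(d); sdd <- stats::sd(d)
  loa <- bias + c(-1.96, 1.96) * sdd
  fit <- stats::lm(d ~ m)
  sm <- summary(fit)
  fstat <- sm$fstatistic
  reg_p <- stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
  mid <- mean(range(m))
  pi_band <- stats::predict(fit, newdata = data.frame(m = mid),
                            interval = "prediction", level = 0.95)
  pi_width <- unname(pi_band[1, "upr"] - pi_band[1, "lwr"])
  pred_ends <- stats::predict(fit, newdata = data.frame(m = range(m)))
  max_pred <- max(abs(pred_ends)) + pi_width / 2
  structure(list(hl_median_diff_um = hl,
                 hl_ci = unname(wt$conf.int),
                 mann_whitney_p = wt$p.value,
                 ba_bias_um = bias, ba_loa_um = loa,
                 frac_within_loa = mean(d >= loa[1] & d <= loa[2]),
                 reg_slope = unname(stats::coef(fit)[2]),
                 reg_intercept = unname(stats::coef(fit)[1]),
                 reg_p = unname(reg_p), r_squared = sm$r.squared,
                 pi_width_um = pi_width,
                 max_predicted_diff_um = max_pred,
                 n_squares = length(a)),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("Agreement over %d squares\n", x$n_squares))
  cat(sprintf("  HL median diff %.3f um (95%% CI %.3f to %.3f), MW p = %.3g\n",
              x$hl_median_diff_um, x$hl_ci[1], x$hl_ci[2], x$mann_whitney_p))
  cat(sprintf("  Bland-Altman bias %.3f um, LoA %.3f to %.3f (%.1f%% within)\n",
              x$ba_bias_um, x$ba_loa_um[1], x$ba_loa_um[2],
              100 * x$frac_within_loa))
  cat(sprintf("  diff ~ mean: slope %.3f, intercept %.3f, R2 %.3f, p %.3g\n",
              x$reg_slope, x$reg_intercept, x$r_squared, x$reg_p))
  cat(sprintf("  95%% PI width %.2f um; max predicted diff %.2f um\n",
              x$pi_width_um, x$max_predicted_diff_um))
  invisible(x)
}
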