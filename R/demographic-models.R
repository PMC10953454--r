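demographics_design <- function(demo) {
  data.frame(age = demo$age_years,
             refraction = demo$refraction_D,
             sex = as.numeric(demo$sex == "F"),
             ethnicity = as.numeric(demo$ethnicity == "Asian"),
             bcva = demo$bcva_logmar)
}

#' Global multiple linear regression of mean macular thickness on demographics
#'
#' The dependent variable is each participant's mean thickness over all
#' valid grid squares; main effects are age, refraction, sex (M=0/F=1),
#' ethnicity (White=0/Asian=1) and best-corrected visual acuity, fit by
#' ordinary least squares. If age is significant (p < .05), a standard
#' (age-only) regression is also fit and the percentage difference between
#' the two age coefficients is reported; a difference exceeding 10% in
#' magnitude flags a meaningful contribution of the other demographics.
#'
#' @param grids List of [thickness_grid()]s, one per participant (same
#'   order as `demo`).
#' @param demo Demographics data.frame (see [generate_demographics()] for
#'   the schema); no missing values allowed.
#' @param alpha Significance threshold.
#' @return Object of class `regression_report`: per-variable `estimate`,
#'   `se`, `p_value`; `age_simple_estimate` and `age_coefficient_diff_pct`
#'   (NA unless age is significant in the multiple model);
#'   `corrected_estimates` from [backward_corrected_estimates()]; the
#'   fitted `model`; and `layer`.
#' @export
fit_global_model <- function(grids, demo, alpha = 0.05) {
  stopifnot(length(grids) == nrow(demo), nrow(demo) >= 10)
  if (anyNA(demo)) stop("missing demographics are not allowed")
  dat <- demographics_design(demo)
  dat$thickness <- vapply(grids, grid_mean, numeric(1))
  X <- cbind(intercept = 1,
             as.matrix(dat[c("age", "refraction", "sex", "ethnicity",
                             "bcva")]))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[-seq_len(qrX$rank)]]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  fit <- stats::lm(thickness ~ age + refraction + sex + ethnicity + bcva,
                   data = dat)
  sm <- summary(fit)$coefficients
  vars <- c("age", "refraction", "sex", "ethnicity", "bcva")
  tab <- data.frame(variable = vars,
                    estimate = sm[vars, 1], se = sm[vars, 2],
                    p_value = sm[vars, 4], row.names = NULL)
  age_simple <- NA_real_; diff_pct <- NA_real_
  if (tab$p_value[tab$variable == "age"] < alpha) {
    sfit <- stats::lm(thickness ~ age, data = dat)
    age_simple <- stats::coef(sfit)[["age"]]
    age_mult <- tab$estimate[tab$variable == "age"]
    diff_pct <- 100 * (age_mult - age_simple) / abs(age_simple)
  }
  rep <- structure(list(layer = grids[[1]]$layer, coefficients = tab,
                        age_simple_estimate = age_simple,
                        age_coefficient_diff_pct = diff_pct,
                        alpha = alpha, model = fit, data = dat),
                   class = "regression_report")
  rep$corrected_estimates <- backward_corrected_estimates(rep)
  rep
}

#' @export
print.regression_report <- function(x, ...) {
  cat(sprintf("Global %s thickness regression (n = %d)\n",
              x$layer, nrow(x$data)))
  print(x$coefficients, digits = 3)
  if (is.finite(x$age_coefficient_diff_pct))
    cat(sprintf("  age coefficient, multiple vs standard: %.3f vs %.3f (%.2f%%)\n",
                x$coefficients$estimate[x$coefficients$variable == "age"],
                x$age_simple_estimate, x$age_coefficient_diff_pct))
  if (length(x$corrected_estimates))
    cat("  corrected estimates:",
        paste(names(x$corrected_estimates),
              sprintf("%.3f", unlist(x$corrected_estimates)),
              collapse = "; "), "\n")
  invisible(x)
}

#' Corrected coefficients after removal of nonsignificant demographics
#'
#' Refits the multiple regression retaining age plus the demographics that
#' were significant (p < alpha) in the full model, akin to one round of
#' backward stepwise elimination, and returns the refitted estimates of the
#' retained non-age variables.
#'
#' @param report A `regression_report` from [fit_global_model()].
#' @return Named list mapping variable name to corrected estimate (empty
#'   when no non-age variable is significant).
#' @export
backward_corrected_estimates <- function(report) {
  tab <- report$coefficients
  keep <- tab$variable[tab$p_value < report$alpha & tab$variable != "age"]
  if (!length(keep)) return(list())
  form <- stats::reformulate(c("age", keep), response = "thickness")
  fit <- stats::lm(form, data = report$data)
  as.list(stats::coef(fit)[keep])
}
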