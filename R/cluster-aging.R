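#' Decade-binned thickness profile field
#'
#' For each macular grid square, the mean thickness per age bin (decades
#' 20-29, 30-39, ..., with 70+ pooled). These per-square decade vectors are
#' the features for hierarchical clustering. Squares invalid for any
#' participant-bin combination, or lying in a bin with no participants, are
#' excluded.
#'
#' @param grids List of [thickness_grid()]s, one per participant.
#' @param demo Matching demographics data.frame.
#' @param breaks Age-bin breakpoints; the final bin is open-ended.
#' @return Object of class `decade_field`: `values` (squares x bins matrix
#'   of bin means), `square_idx` (linear indices into the grid matrix),
#'   `bin_ages` (regression abscissae: bin midpoints, with the open-ended
#'   bin at its members' mean age), `bin_n`, `grid`, `layer`.
#' @export
decade_profile_field <- function(grids, demo,
                                 breaks = c(20, 30, 40, 50, 60, 70, Inf)) {
  stopifnot(length(grids) == nrow(demo))
  grid <- grids[[1]]$grid
  bins <- cut(demo$age_years, breaks, right = FALSE)
  if (any(is.na(bins))) stop("participant ages outside the binning range")
  vals <- t(vapply(grids, function(g) as.vector(g$values_um),
                   numeric(grid$n^2)))          # participants x squares
  nb <- nlevels(bins)
  means <- matrix(NA_real_, grid$n^2, nb)
  for (b in seq_len(nb)) {
    rows <- which(bins == levels(bins)[b])
    if (!length(rows)) next
    sub <- vals[rows, , drop = FALSE]
    cnt <- colSums(is.finite(sub))
    mu <- colSums(ifelse(is.finite(sub), sub, 0)) / cnt
    mu[cnt < length(rows)] <- NA  # square invalid for someone in this bin
    means[, b] <- mu
  }
  keep <- which(rowSums(is.finite(means)) == nb)
  if (!length(keep)) stop("no square is valid across all age bins")
  # regression abscissa: each bin's empirical mean age (the open-ended 70+
  # bin has no midpoint anyway; empirical means keep the pooled fit's
  # coefficient CIs calibrated, since the bin-mean thickness reflects the
  # ages actually sampled, not the nominal midpoint)
  mids <- unname(vapply(levels(bins), function(l) {
    rows <- which(bins == l)
    if (length(rows)) mean(demo$age_years[rows]) else NA_real_
  }, numeric(1)))
  if (anyNA(mids)) stop("every age bin needs at least one participant")
  # second moment per bin: the quadratic term of a bin mean is the bin mean
  # of age^2, not the squared mean age
  mids_sq <- unname(vapply(levels(bins), function(l)
    mean(demo$age_years[bins == l]^2), numeric(1)))
  structure(list(values = means[keep, , drop = FALSE], square_idx = keep,
                 bin_ages = mids, bin_ages_sq = mids_sq,
                 bin_n = as.integer(table(bins)),
                 grid = grid, layer = grids[[1]]$layer),
            class = "decade_field")
}

#' @export
print.decade_field <- function(x, ...) {
  cat(sprintf("%s decade profile field: %d squares x %d age bins\n",
              x$layer, nrow(x$values), ncol(x$values)))
  cat("  bin abscissae (y):", paste(round(x$bin_ages, 1), collapse = ", "), "\n")
  invisible(x)
}

#' Summary statistics of a cluster's feature values
#'
#' @param values Numeric vector (or matrix) of the decade-bin means
#'   belonging to the cluster's member squares.
#' @return List with `mean`, `sd`, `n`.
#' @export
cluster_stats <- function(values) {
  v <- as.numeric(values)
  list(mean = mean(v), sd = stats::sd(v), n = length(v))
}

#' d-prime separability between two clusters
#'
#' `d' = |x1 - x2| / sqrt(0.5 * (s1^2 + s2^2))`: the difference in cluster
#' mean thickness in units of the pooled standard deviation. A threshold of
#' 1 corresponds to one SD of separation.
#'
#' @param s1,s2 Cluster statistics (lists with `mean` and `sd`, as from
#'   [cluster_stats()]).
#' @return Nonnegative separability index; `Inf` when both SDs are zero but
#'   the means differ, `0` when means are equal.
#' @export
dprime <- function(s1, s2) {
  num <- abs(s1$mean - s2$mean)
  den <- sqrt(0.5 * (s1$sd^2 + s2$sd^2))
  if (den == 0) return(if (num == 0) 0 else Inf)
  num / den
}

# Agglomerative clustering with the SPSS "within-groups" linkage: each step
# merges the pair whose union has the smallest average within-cluster
# pairwise squared Euclidean distance. Uses the identity
# sum_{i<j} ||xi-xj||^2 = n * SS (SS = total squared deviation from the
# centroid), so the criterion is 2*SS_union/(n_union - 1) with
# SS_union = SS_A + SS_B + nA*nB/(nA+nB) * ||cA - cB||^2.
# Returns integer labels 1..k.
hclust_within_groups <- function(X, k) {
  n <- nrow(X)
  stopifnot(k >= 1, n >= k)
  cent <- X
  size <- rep(1L, n)
  ss <- rep(0, n)
  active <- rep(TRUE, n)
  comp <- seq_len(n)
  cost_to <- function(i, js) {
    d2 <- rowSums((cent[js, , drop = FALSE] -
                     matrix(cent[i, ], length(js), ncol(X), byrow = TRUE))^2)
    ssu <- ss[i] + ss[js] + size[i] * size[js] / (size[i] + size[js]) * d2
    2 * ssu / (size[i] + size[js] - 1)
  }
  rowmin <- rep(Inf, n); rowarg <- rep(NA_integer_, n)
  recompute_row <- function(i) {
    js <- which(active); js <- js[js != i]
    if (!length(js)) { rowmin[i] <<- Inf; rowarg[i] <<- NA_integer_; return() }
    cc <- cost_to(i, js)
    b <- which.min(cc)
    rowmin[i] <<- cc[b]; rowarg[i] <<- js[b]
  }
  for (i in seq_len(n)) recompute_row(i)
  n_active <- n
  while (n_active > k) {
    i <- which.min(rowmin)
    j <- rowarg[i]
    if (j < i) { tmp <- i; i <- j; j <- tmp }  # deterministic: keep lower id
    ni <- size[i]; nj <- size[j]
    d2 <- sum((cent[i, ] - cent[j, ])^2)
    ss[i] <- ss[i] + ss[j] + ni * nj / (ni + nj) * d2
    cent[i, ] <- (ni * cent[i, ] + nj * cent[j, ]) / (ni + nj)
    size[i] <- ni + nj
    active[j] <- FALSE
    rowmin[j] <- Inf; rowarg[j] <- NA_integer_
    comp[comp == comp[j]] <- i
    comp[comp == j] <- i
    n_active <- n_active - 1L
    if (n_active == k) break
    recompute_row(i)
    stale <- which(active & (rowarg == i | rowarg == j))
    for (s in stale) recompute_row(s)
    others <- which(active); others <- others[others != i]
    if (length(others)) {
      ci <- cost_to(i, others)
      upd <- which(ci < rowmin[others])
      rowmin[others[upd]] <- ci[upd]
      rowarg[others[upd]] <- i
    }
  }
  ids <- which(active)
  match(comp, ids)
}

#' Cluster macular grid squares and pool to statistical separability
#'
#' Stage 1 cuts the per-square decade profiles into `k0` clusters by
#' agglomerative clustering with squared Euclidean dissimilarity and
#' within-groups linkage (UPGMA average linkage available as a fallback).
#' Stage 2 repeatedly merges the least-separable cluster pair failing the
#' separability rule -- `d' >= dprime_min` and a difference in mean
#' thickness of at least `min_mean_diff_um` (one axial pixel) -- until every
#' surviving pair is separable. Cluster statistics are computed over the
#' member squares' decade-bin means. Final labels are renumbered by
#' increasing mean thickness (1 = thinnest, typically peripheral).
#'
#' @param field A [decade_profile_field()].
#' @param k0 Initial number of clusters before pooling.
#' @param linkage `"within"` (SPSS within-groups, the default) or
#'   `"average"` (UPGMA on squared Euclidean distances).
#' @param dprime_min d-prime criterion (default 1).
#' @param min_mean_diff_um Mean-difference criterion in um (default 3.87,
#'   one axial pixel).
#' @return Object of class `cluster_model` with `labels` (grid matrix,
#'   0 = excluded), `labels_vec` (per field row), `stats`, `dprime_matrix`,
#'   `mean_diff_matrix`, `k`, `field`; `models` is filled by
#'   [cluster_aging_models()].
#' @export
cluster_and_pool <- function(field, k0 = 15L,
                             linkage = c("within", "average"),
                             dprime_min = 1, min_mean_diff_um = 3.87) {
  linkage <- match.arg(linkage)
  X <- field$values
  stopifnot(k0 >= 2, nrow(X) >= k0)
  if (linkage == "within") {
    lab <- hclust_within_groups(X, k0)
  } else {
    hc <- stats::hclust(stats::dist(X)^2, method = "average")
    lab <- stats::cutree(hc, k = k0)
  }
  repeat {
    ks <- sort(unique(lab))
    st <- lapply(ks, function(k) cluster_stats(X[lab == k, , drop = FALSE]))
    K <- length(ks)
    if (K == 1) break
    dp <- matrix(Inf, K, K); dm <- matrix(Inf, K, K)
    for (a in seq_len(K - 1)) for (b in (a + 1):K) {
      dp[a, b] <- dp[b, a] <- dprime(st[[a]], st[[b]])
      dm[a, b] <- dm[b, a] <- abs(st[[a]]$mean - st[[b]]$mean)
    }
    fail <- which(upper.tri(dp) & (dp < dprime_min | dm < min_mean_diff_um),
                  arr.ind = TRUE)
    if (!nrow(fail)) break
    o <- order(dp[fail], dm[fail], fail[, 1], fail[, 2])[1]
    a <- fail[o, 1]; b <- fail[o, 2]
    lab[lab == ks[b]] <- ks[a]
  }
  # renumber by increasing cluster mean
  ks <- sort(unique(lab))
  st <- lapply(ks, function(k) cluster_stats(X[lab == k, , drop = FALSE]))
  ord <- order(vapply(st, `[[`, numeric(1), "mean"))
  newlab <- match(lab, ks[ord])
  st <- st[ord]
  K <- length(ks)
  dp <- matrix(0, K, K); dm <- matrix(0, K, K)
  if (K > 1) for (a in seq_len(K - 1)) for (b in (a + 1):K) {
    dp[a, b] <- dp[b, a] <- dprime(st[[a]], st[[b]])
    dm[a, b] <- dm[b, a] <- abs(st[[a]]$mean - st[[b]]$mean)
  }
  labels <- matrix(0L, field$grid$n, field$grid$n)
  labels[field$square_idx] <- newlab
  structure(list(labels = labels, labels_vec = newlab, stats = st,
                 dprime_matrix = dp, mean_diff_matrix = dm, k = K,
                 models = NULL, field = field),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("Cluster model (%s): %d separable clusters over %d squares\n",
              x$field$layer, x$k, length(x$labels_vec)))
  for (k in seq_len(x$k)) {
    s <- x$stats[[k]]
    cat(sprintf("  cluster %d: mean %.2f um, sd %.2f, n %d", k, s$mean, s$sd, s$n))
    if (!is.null(x$models)) {
      m <- x$models[[k]]
      cat(sprintf("; %s", format(m)))
    }
    cat("\n")
  }
  invisible(x)
}

#' Fit a per-cluster aging model (quadratic vs linear)
#'
#' Fits both `thickness ~ age + age^2` and `thickness ~ age` to the pooled
#' (age-bin abscissa, bin-mean thickness) observations and compares them
#' with the extra sum-of-squares F test
#' `F = ((SSE_lin - SSE_quad)/1) / (SSE_quad/(n-3))`. If `p < alpha` the
#' quadratic model is kept and the inflection age `x = -b/(2a)` (the age at
#' which thickness peaks and decline begins) is reported; otherwise the
#' linear model is kept. The annual percentage rate over `age_range` is
#' computed via [annual_rate_pct()].
#'
#' @param age Ages (years) of the pooled observations (bin mean ages for
#'   binned data).
#' @param thickness Thickness values (um).
#' @param age_sq Quadratic regressor. For raw per-participant observations
#'   this is `age^2` (the default); for bin-mean observations supply the
#'   bin mean of age^2, which keeps the quadratic fit exact under binning.
#' @param alpha F-test significance threshold.
#' @param age_range Range for the annual-rate calculation.
#' @return Object of class `aging_model`: `kind` ("quadratic"/"linear"),
#'   coefficients `a`, `b`, `c`, `f_test_p`, `slope_p` (linear-slope t-test),
#'   `inflection_x` (quadratic only), `annual_rate_pct`, `n`.
#' @export
fit_cluster_aging <- function(age, thickness, age_sq = age^2, alpha = 0.05,
                              age_range = c(20, 85)) {
  stopifnot(length(age) == length(thickness), length(age_sq) == length(age))
  if (length(unique(age)) < 4)
    stop("need at least 4 distinct age bins with data")
  d <- data.frame(age = age, age_sq = age_sq, thickness = thickness)
  flin <- stats::lm(thickness ~ age, data = d)
  fquad <- stats::lm(thickness ~ age + age_sq, data = d)
  ft <- stats::anova(flin, fquad)
  f_p <- ft$`Pr(>F)`[2]
  slope_p <- summary(flin)$coefficients["age", 4]
  a2 <- stats::coef(fquad)[["age_sq"]]
  if (is.finite(f_p) && f_p < alpha && a2 != 0) {
    cf <- stats::coef(fquad)
    m <- aging_model("quadratic", a = cf[["age_sq"]], b = cf[["age"]],
                     c = cf[["(Intercept)"]], f_test_p = f_p,
                     slope_p = slope_p, n = length(age),
                     age_range = age_range)
  } else {
    cf <- stats::coef(flin)
    m <- aging_model("linear", a = 0, b = cf[["age"]],
                     c = cf[["(Intercept)"]], f_test_p = f_p,
                     slope_p = slope_p, n = length(age),
                     age_range = age_range)
  }
  m
}

#' Construct an aging model from coefficients
#'
#' Thickness as a function of age: `c + b*age + a*age^2` (quadratic) or
#' `c + b*age` (linear). The inflection age of a quadratic model is
#' `-b/(2a)`, the age at which predicted thickness peaks and decline
#' begins.
#'
#' @param kind `"quadratic"` or `"linear"`.
#' @param a,b,c Coefficients (um/y^2, um/y, um); `a` is ignored (0) for
#'   linear models.
#' @param f_test_p,slope_p,n Optional fit metadata.
#' @param age_range Range over which the annual rate is evaluated.
#' @return Object of class `aging_model`.
#' @export
aging_model <- function(kind = c("quadratic", "linear"), a = 0, b, c,
                        f_test_p = NA_real_, slope_p = NA_real_,
                        n = NA_integer_, age_range = c(20, 85)) {
  kind <- match.arg(kind)
  if (kind == "quadratic" && a == 0) kind <- "linear"
  m <- structure(list(kind = kind, a = if (kind == "linear") 0 else a,
                      b = b, c = c, f_test_p = f_test_p, slope_p = slope_p,
                      inflection_x = NA_real_, annual_rate_pct = NA_real_,
                      n = n),
                 class = "aging_model")
  if (kind == "quadratic") m$inflection_x <- inflection_age(a, b)
  m$annual_rate_pct <- annual_rate_pct(m, age_range)
  m
}

#' Inflection age of a quadratic aging model
#'
#' @param a,b Quadratic and linear coefficients.
#' @return `-b / (2 * a)` in years.
#' @export
inflection_age <- function(a, b) {
  if (a == 0) stop("inflection is undefined for a = 0 (linear model)")
  -b / (2 * a)
}

#' Predict thickness from an aging model
#'
#' @param object An `aging_model`.
#' @param age Ages (years).
#' @param ... Unused.
#' @return Predicted thickness (um).
#' @export
predict.aging_model <- function(object, age, ...) {
  object$c + object$b * age + object$a * age^2
}

#' @export
format.aging_model <- function(x, ...) {
  if (x$kind == "quadratic")
    sprintf("quadratic a=%.4g b=%.3g c=%.4g (x=%.1f y, %.2f %%/y)",
            x$a, x$b, x$c, x$inflection_x, x$annual_rate_pct)
  else
    sprintf("linear b=%.3g c=%.4g (%.2f %%/y)", x$b, x$c, x$annual_rate_pct)
}

#' @export
print.aging_model <- function(x, ...) { cat(format(x), "\n"); invisible(x) }

#' Average annual percentage rate of change
#'
#' The rate of thickness change expressed as a percentage of the peak
#' thickness predicted by the model over `age_range`: with the peak `P`
#' attained at age `a*`, the rate is
#' `100 * (predict(hi) - P) / (P * (hi - a*))` %/year. For models whose
#' peak lies at the upper end of the range (non-declining), the rate is
#' referenced to the range start:
#' `100 * (predict(hi) - predict(lo)) / (predict(lo) * (hi - lo))`.
#'
#' @param model An [aging_model()].
#' @param age_range Numeric `c(lo, hi)`, default 20-85 years.
#' @return Signed rate in percent per year.
#' @export
annual_rate_pct <- function(model, age_range = c(20, 85)) {
  lo <- age_range[1]; hi <- age_range[2]
  stopifnot(hi > lo)
  cand <- c(lo, hi)
  if (model$kind == "quadratic") {
    xv <- -model$b / (2 * model$a)
    if (model$a < 0 && xv > lo && xv < hi) cand <- c(cand, xv)
  }
  pv <- predict(model, cand)
  peak <- max(pv)
  if (peak <= 0) stop("peak predicted thickness is non-positive")
  astar <- cand[which.max(pv)]
  if (astar < hi) {
    100 * (predict(model, hi) - peak) / (peak * (hi - astar))
  } else {
    p_lo <- predict(model, lo)
    100 * (predict(model, hi) - p_lo) / (p_lo * (hi - lo))
  }
}

#' Full cluster-aging pipeline
#'
#' Builds the decade profile field, clusters and pools the grid squares,
#' then fits a per-cluster aging model to the pooled (bin abscissa,
#' bin-mean) observations of its member squares.
#'
#' @param grids,demo Cohort thickness grids and demographics.
#' @param k0,linkage,dprime_min,min_mean_diff_um Passed to
#'   [cluster_and_pool()].
#' @param alpha,age_range Passed to [fit_cluster_aging()].
#' @param breaks Age-bin breakpoints for [decade_profile_field()].
#' @return A `cluster_model` with `models` filled (one [aging_model()] per
#'   cluster).
#' @export
cluster_aging_models <- function(grids, demo, k0 = 15L,
                                 linkage = c("within", "average"),
                                 dprime_min = 1, min_mean_diff_um = 3.87,
                                 alpha = 0.05, age_range = c(20, 85),
                                 breaks = c(20, 30, 40, 50, 60, 70, Inf)) {
  field <- decade_profile_field(grids, demo, breaks)
  cm <- cluster_and_pool(field, k0, linkage, dprime_min, min_mean_diff_um)
  cm$models <- lapply(seq_len(cm$k), function(k) {
    members <- cm$labels_vec == k
    Y <- field$values[members, , drop = FALSE]
    age <- rep(field$bin_ages, each = sum(members))
    age_sq <- rep(field$bin_ages_sq, each = sum(members))
    fit_cluster_aging(age, as.vector(Y), age_sq = age_sq, alpha = alpha,
                      age_range = age_range)
  })
  cm
}
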