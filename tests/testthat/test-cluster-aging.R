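stats_of <- function(mean, sd, n = 10) list(mean = mean, sd = sd, n = n)

test_that("d-prime matches hand evaluations and the printed formula", {
  expect_equal(dprime(stats_of(10, 2), stats_of(10, 5)), 0)
  expect_equal(dprime(stats_of(20, 5), stats_of(25, 5)), 1.0)
  expect_equal(dprime(stats_of(30, 3), stats_of(36, 4)), 6 / sqrt(12.5),
               tolerance = 1e-12)
  expect_equal(round(dprime(stats_of(30, 3), stats_of(36, 4)), 3), 1.697)
  # degenerate: zero spread
  expect_identical(dprime(stats_of(1, 0), stats_of(2, 0)), Inf)
  expect_identical(dprime(stats_of(1, 0), stats_of(1, 0)), 0)
})

test_that("d-prime agrees with a brute-force evaluation on random stats", {
  set.seed(10)
  for (i in 1:50) {
    s1 <- stats_of(runif(1, 0, 50), runif(1, 0.1, 6))
    s2 <- stats_of(runif(1, 0, 50), runif(1, 0.1, 6))
    brute <- abs(s1$mean - s2$mean) / sqrt(0.5 * (s1$sd^2 + s2$sd^2))
    expect_equal(dprime(s1, s2), brute, tolerance = 1e-12)
    expect_equal(dprime(s2, s1), dprime(s1, s2))
  }
})

# a decade field with planted bands: n_sq squares per band, constant band
# means plus small noise across the 6 bins
planted_field <- function(band_means, n_sq = 40, sd = 1, seed = 1) {
  set.seed(seed)
  vals <- do.call(rbind, lapply(band_means, function(m)
    matrix(rnorm(n_sq * 6, m, sd), n_sq, 6)))
  structure(list(values = vals,
                 square_idx = seq_len(nrow(vals)),
                 bin_ages = c(25, 35, 45, 55, 65, 76),
                 bin_ages_sq = c(25, 35, 45, 55, 65, 76)^2 + 8.3,
                 bin_n = rep(40L, 6), grid = macular_grid(60),
                 layer = "GCL"),
            class = "decade_field")
}

test_that("well-separated planted bands are recovered exactly", {
  f <- planted_field(c(20, 40, 60), sd = 1)
  cm <- cluster_and_pool(f, k0 = 10)
  expect_equal(cm$k, 3L)
  truth <- rep(1:3, each = 40)
  expect_equal(cm$labels_vec, truth)
  # post-pooling separability invariant
  off <- upper.tri(cm$dprime_matrix)
  expect_true(all(cm$dprime_matrix[off] >= 1))
  expect_true(all(cm$mean_diff_matrix[off] >= 3.87))
})

test_that("bands 1 um apart collapse under the axial-resolution criterion", {
  # d' would pass (sd 0.1) but |dmean| = 1 < 3.87
  f <- planted_field(c(30, 31), sd = 0.1)
  cm <- cluster_and_pool(f, k0 = 6)
  expect_equal(cm$k, 1L)
})

test_that("sub-SD separation collapses under the d-prime criterion", {
  f <- planted_field(c(30, 35), sd = 10, seed = 3)
  cm <- cluster_and_pool(f, k0 = 6)
  expect_equal(cm$k, 1L)
})

test_that("within-groups and average linkage agree on planted bands", {
  f <- planted_field(c(20, 40, 60), sd = 1, seed = 2)
  cw <- cluster_and_pool(f, k0 = 12, linkage = "within")
  ca <- cluster_and_pool(f, k0 = 12, linkage = "average")
  expect_equal(cw$labels_vec, ca$labels_vec)
})

test_that("inflection age is -b/(2a)", {
  expect_equal(round(inflection_age(-0.0023, 0.18), 1), 39.1)
  expect_equal(inflection_age(-1, 2), 1.0)
  expect_equal(inflection_age(0.00089, -0.12), 67.41573, tolerance = 1e-5)
  expect_error(inflection_age(0, 1), "linear")
})

test_that("aging model fits prefer the true functional form", {
  ages <- rep(c(25, 35, 45, 55, 65, 76), each = 30)
  set.seed(20)
  yq <- 27.79 + 0.18 * ages - 0.0023 * ages^2 + rnorm(length(ages), 0, 0.3)
  mq <- fit_cluster_aging(ages, yq)
  expect_equal(mq$kind, "quadratic")
  expect_equal(mq$a, -0.0023, tolerance = 0.15)
  expect_equal(mq$inflection_x, 39.1, tolerance = 3)
  yl <- 76.77 - 0.01 * ages + rnorm(length(ages), 0, 0.3)
  ml <- fit_cluster_aging(ages, yl)
  expect_equal(ml$kind, "linear")
  expect_equal(ml$b, -0.01, tolerance = 0.02)
  expect_error(fit_cluster_aging(rep(c(25, 35, 45), each = 5), rnorm(15)),
               "4 distinct")
})

test_that("the F test keeps the linear model at about the alpha rate", {
  ages <- rep(c(25, 35, 45, 55, 65, 76), each = 10)
  set.seed(21)
  picks <- replicate(300, {
    y <- 30 - 0.05 * ages + rnorm(length(ages))
    fit_cluster_aging(ages, y)$kind == "quadratic"
  })
  expect_gt(mean(picks), 0.015)
  expect_lt(mean(picks), 0.10)
})

test_that("annual rate follows the peak-referenced definition", {
  lin <- aging_model("linear", b = -0.01, c = 76.77)
  expect_equal(round(lin$annual_rate_pct, 2), -0.01)
  expect_equal(lin$annual_rate_pct,
               100 * (-0.01 * 65) / ((76.77 - 0.01 * 20) * 65),
               tolerance = 1e-12)
  flat <- aging_model("linear", b = 0, c = 50)
  expect_equal(flat$annual_rate_pct, 0)
  quad <- aging_model("quadratic", a = -0.0034, b = 0.25, c = 37.88)
  expect_equal(round(quad$annual_rate_pct, 2), -0.39)
  # declining-model oracle: peak at x* = -b/2a, rate from peak to 85
  xs <- -0.25 / (2 * -0.0034)
  pk <- 37.88 + 0.25 * xs - 0.0034 * xs^2
  p85 <- 37.88 + 0.25 * 85 - 0.0034 * 85^2
  expect_equal(quad$annual_rate_pct, 100 * (p85 - pk) / (pk * (85 - xs)),
               tolerance = 1e-12)
  expect_error(aging_model("linear", b = -2, c = 30), "non-positive")
})

test_that("a zero quadratic coefficient degrades to a linear model", {
  m <- aging_model("quadratic", a = 0, b = -0.05, c = 40)
  expect_equal(m$kind, "linear")
  expect_true(is.na(m$inflection_x))
})

test_that("decade fields bin by decade with a pooled 70+ bin", {
  set.seed(30)
  truth <- slab_truth(c_um = 40, noise_sd_um = 0)
  demo <- generate_demographics(60)
  grids <- generate_thickness_grids(demo, truth)
  f <- decade_profile_field(grids, demo)
  expect_equal(ncol(f$values), 6)
  expect_equal(sum(f$bin_n), 60)
  expect_true(all(abs(f$values - 40) < 1e-9))
  b <- cut(demo$age_years, c(20, 30, 40, 50, 60, 70, Inf), right = FALSE)
  expect_equal(f$bin_ages[6], mean(demo$age_years[b == levels(b)[6]]))
  # squares invalid anywhere are dropped
  grids[[1]]$values_um[5, 5] <- NA
  grids[[1]]$valid[5, 5] <- FALSE
  f2 <- decade_profile_field(grids, demo)
  expect_equal(nrow(f2$values), 3599)
})

test_that("planted concentric rings are recovered end-to-end", {
  truth <- three_ring_truth(noise_sd_um = 2)
  set.seed(31)
  demo <- generate_demographics(250)
  grids <- generate_thickness_grids(demo, truth)
  cm <- cluster_aging_models(grids, demo, k0 = 15)
  expect_equal(cm$k, 3L)
  # labels match the planted rings at >99% of squares
  gr <- grids[[1]]$grid
  xy <- expand.grid(y = gr$y_centers_um, x = gr$x_centers_um)
  planted <- truth$label_fun(xy$x, xy$y)
  expect_gt(mean(cm$labels_vec == planted), 0.99)
  # every pair separable after pooling
  off <- upper.tri(cm$dprime_matrix)
  expect_true(all(cm$dprime_matrix[off] >= 1 &
                    cm$mean_diff_matrix[off] >= 3.87))
  # fitted inflection close to planted (cluster 2: 39.1 y)
  expect_equal(cm$models[[2]]$inflection_x, 39.1, tolerance = 3)
})
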