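test_that("identical meridians give a rotationally symmetric field", {
  gc <- generate_meridian_profiles("GC", peak = 30000)
  pf <- interpolate_between_meridians(gc)
  r <- c(0.5, 1, 2)
  for (th in c(13, 97, 211, 305))
    expect_equal(polar_density_at(pf, r, th), polar_density_at(pf, r, 0),
                 tolerance = 1e-10)
})

test_that("angular interpolation is linear between flanking meridians", {
  ecc <- seq(0, 2, by = 0.1)
  vals <- cbind(T = rep(500, 21), N = rep(1000, 21),
                S = rep(2000, 21), I = rep(800, 21))
  pf <- interpolate_between_meridians(meridian_profile_set(ecc, vals, "GC"))
  # midway between N (180) and S (90): mean of 1000 and 2000
  expect_equal(polar_density_at(pf, 1, 135), 1500)
  # quarter-way from T (0) toward S (90)
  expect_equal(polar_density_at(pf, 1, 22.5), 0.75 * 500 + 0.25 * 2000)
  # along each principal meridian the input profile is recovered exactly
  expect_equal(polar_density_at(pf, 1.5, 0), 500)
  expect_equal(polar_density_at(pf, 1.5, 270), 800)
  # period 360
  expect_equal(polar_density_at(pf, 1, 360 + 45), polar_density_at(pf, 1, 45))
  # beyond support: refused
  expect_true(is.na(polar_density_at(pf, 2.5, 10)))
})

test_that("grid averaging reproduces constant fields and analytic rings", {
  ecc <- seq(0, 5, by = 0.01)
  flat <- meridian_profile_set(ecc, matrix(1234, length(ecc), 4), "GC")
  dg <- grid_average_density(interpolate_between_meridians(flat))
  expect_true(all(abs(dg$values - 1234) < 1e-9))
  expect_true(all(dg$valid))
  # radial ramp d = 1000 * r: quadrature oracle on one square
  ramp <- meridian_profile_set(ecc, matrix(1000 * ecc, length(ecc), 4), "GC")
  dgr <- grid_average_density(interpolate_between_meridians(ramp),
                              n_sub = 48)
  gr <- dgr$grid
  i <- 10; j <- 40
  f <- function(y, x) 1000 * sqrt(x^2 + y^2) / 1000
  # two-level numerical integral over the square
  xs <- gr$x_centers_um[j] + seq(-0.5, 0.5, length.out = 201) * gr$square_um
  ys <- gr$y_centers_um[i] + seq(-0.5, 0.5, length.out = 201) * gr$square_um
  oracle <- mean(outer(ys, xs, f))
  expect_equal(unname(dgr$values[i, j]), oracle, tolerance = 1e-4)
})

test_that("volumetric conversion is exact unit arithmetic and round-trips", {
  g <- macular_grid()
  areal <- density_grid(matrix(30000, 60, 60), "areametric", "GC")
  th <- thickness_grid(matrix(50, 60, 60), "GCL")
  vol <- to_volumetric(areal, th)
  expect_equal(unname(vol$values[1, 1]), 600000)
  back <- to_areametric(vol, th)
  expect_true(max(abs(back$values - areal$values)) < 1e-9)
  # thinner layer => higher volumetric density at fixed areal density
  th2 <- thickness_grid(matrix(25, 60, 60), "GCL")
  expect_true(all(to_volumetric(areal, th2)$values > vol$values))
  # non-positive thickness invalidates
  bad <- thickness_grid(matrix(c(0, rep(50, 3599)), 60, 60), "GCL")
  expect_false(to_volumetric(areal, bad)$valid[1, 1])
})

test_that("INL totals apply the DAPI correction and conserve proportions", {
  # components engineered to sum to 89,400 at every eccentricity
  ecc <- seq(0, 1, by = 0.1)
  n <- length(ecc)
  dens <- cbind(amacrine_glycinergic = rep(10000, n),
                amacrine_gabaergic = rep(10000, n),
                bipolar_off_midget = rep(15000, n),
                bipolar_on = rep(15000, n),
                bipolar_db3a = rep(5000, n),
                bipolar_db3b = rep(5000, n),
                horizontal = rep(9400, n),
                muller = rep(20000, n))
  tot <- inl_total_and_components(list(ecc_mm = ecc, densities = dens))
  expect_equal(tot$total, rep(89400 / 0.894, n), tolerance = 1e-12)
  expect_equal(tot$total[1], 100000)
  expect_equal(unname(rowSums(tot$proportions)), rep(0.894, n),
               tolerance = 1e-12)
  # fraction 0: total equals the DAPI-stained sum
  tot0 <- inl_total_and_components(list(ecc_mm = ecc, densities = dens),
                                   dapi_unlabeled_fraction = 0)
  expect_equal(tot0$total, rep(89400, n))
  dens[1, 1] <- -1
  expect_error(inl_total_and_components(list(ecc_mm = ecc,
                                             densities = dens)), "negative")
})

test_that("INL grids extrapolate the temporal profile and conserve components", {
  inl <- generate_meridian_profiles("INL_components")
  tot <- inl_total_and_components(inl)
  # symmetric thickness: symmetric areametric maps
  th <- thickness_grid(matrix(35, 60, 60), "INL")
  ig <- inl_grid_densities(tot, th)
  v <- ig$areal_total$values
  expect_equal(v, v[, 60:1], tolerance = 1e-9)     # temporal-nasal mirror
  expect_equal(v, t(v), tolerance = 1e-9)          # diagonal symmetry
  # components (including the unlabeled remainder) sum to the total
  s <- Reduce(`+`, lapply(ig$components, function(g) g$values))
  expect_lt(max(abs(s - ig$areal_total$values)), 1e-9)
  # volumetric x thickness recovers areametric at every square
  expect_lt(max(abs(ig$volumetric_total$values * 35 / 1000 -
                      ig$areal_total$values)), 1e-9)
  # a nasally thicker INL produces nasally denser areametric maps
  vals <- matrix(30, 60, 60)
  vals[, 31:60] <- 40
  ig2 <- inl_grid_densities(tot, thickness_grid(vals, "INL"))
  expect_gt(ig2$areal_total$values[30, 45], ig2$areal_total$values[30, 16])
})

test_that("hexagonal packing gives equivalent-cone = cone wherever rods vanish", {
  cone <- generate_meridian_profiles("cone")
  cd <- generate_meridian_profiles("cone_diameter")
  rod0 <- meridian_profile_set(cone$ecc_mm,
                               matrix(0, length(cone$ecc_mm), 4), "rod")
  pp <- equivalent_cone_profile(cone, cd, rod0)
  expect_equal(pp$equivalent_cone, pp$cone_density, tolerance = 1e-12)
  rod <- generate_meridian_profiles("rod", rod_free_radius_um = 150)
  pp2 <- equivalent_cone_profile(cone, cd, rod)
  inside <- pp2$ecc_mm * 1000 <= 150
  expect_equal(pp2$equivalent_cone[inside, ], pp2$cone_density[inside, ])
  expect_true(all(pp2$cone_area_fraction >= 0 & pp2$cone_area_fraction <= 1))
  # adding rods only increases equivalent density
  expect_true(all(pp2$equivalent_cone >= pp2$cone_density - 1e-9))
})

test_that("equal rod and cone areas double the converted density", {
  # engineered: constant diameters, f_c = 0.5, rod area == cone area
  ecc <- seq(0, 4, by = 0.005)
  n <- length(ecc)
  w <- 5  # um
  cone_d <- 0.5 / hex_area_mm2(w)
  rod_d <- (1 - 0.5) / hex_area_mm2(w)   # same area per rod as per cone
  cone <- meridian_profile_set(ecc, matrix(cone_d, n, 4), "cone")
  rod <- meridian_profile_set(ecc, matrix(rod_d, n, 4), "rod")
  diam <- meridian_profile_set(ecc, matrix(w, n, 4), "cone_diameter",
                               unit = "um")
  pp <- equivalent_cone_profile(cone, diam, rod, rod_free_radius_um = 126)
  outside <- pp$ecc_mm * 1000 > 300
  expect_equal(pp$equivalent_cone[outside, 1],
               rep(cone_d + rod_d, sum(outside)), tolerance = 1e-6)
})

test_that("a planted linear rod diameter is recovered by the packing round-trip", {
  ecc <- seq(0, 4, by = 0.005)
  n <- length(ecc)
  w_c <- 4
  cone_d <- 0.4 / hex_area_mm2(w_c)           # f_c = 0.4 everywhere
  w_r_true <- 2 + 0.5 * ecc                   # um, linear in eccentricity
  rod_d <- (1 - 0.4) / hex_area_mm2(w_r_true) # exact hexagonal tiling
  cone <- meridian_profile_set(ecc, matrix(cone_d, n, 4), "cone")
  rod <- meridian_profile_set(ecc, rod_d %o% rep(1, 4), "rod")
  diam <- meridian_profile_set(ecc, matrix(w_c, n, 4), "cone_diameter",
                               unit = "um")
  pp <- equivalent_cone_profile(cone, diam, rod)
  outside <- pp$ecc_mm * 1000 > 300
  expect_lt(max(abs(pp$rod_diameter_um[outside, 1] -
                      (2 + 0.5 * pp$ecc_mm[outside]))), 1e-6)
})

test_that("inconsistent cone data (coverage above 1) is rejected", {
  ecc <- seq(0, 1, by = 0.01)
  n <- length(ecc)
  cone <- meridian_profile_set(ecc, matrix(2e5, n, 4), "cone")
  rod <- meridian_profile_set(ecc, matrix(1e4, n, 4), "rod")
  diam <- meridian_profile_set(ecc, matrix(9, n, 4), "cone_diameter", "um")
  expect_error(equivalent_cone_profile(cone, diam, rod), "exceeds 1")
})

test_that("cell counts are volumetric density times volume", {
  th <- thickness_grid(matrix(50, 60, 60), "GCL")
  vol <- density_grid(matrix(600000, 60, 60), "volumetric", "GC")
  one <- predict_cell_count(th, vol, region = 1810)
  expect_equal(as.numeric(one), 600000 * 0.05 * (6880 / 60 / 1000)^2,
               tolerance = 1e-12)
  expect_equal(round(as.numeric(one), 1), 394.5)
  # zero thickness => zero count; doubling thickness doubles the count
  th0 <- thickness_grid(matrix(0, 60, 60), "GCL")
  expect_equal(as.numeric(predict_cell_count(th0, vol, region = 1810)), 0)
  th2 <- thickness_grid(matrix(100, 60, 60), "GCL")
  expect_equal(as.numeric(predict_cell_count(th2, vol, region = 1:100)),
               2 * as.numeric(predict_cell_count(th, vol, region = 1:100)),
               tolerance = 1e-12)
  # invalid squares are excluded with a warning and reported coverage
  vals <- matrix(50, 60, 60); vals[1, 1] <- NA
  thna <- thickness_grid(vals, "GCL")
  expect_warning(cnt <- predict_cell_count(thna, vol, region = 1:10),
                 "invalid")
  expect_equal(attr(cnt, "coverage"), 0.9)
})

test_that("thickness grid CSV round-trips with validity mask", {
  vals <- matrix(rnorm(3600, 40, 5), 60, 60)
  vals[c(3, 100, 700)] <- NA
  tg <- thickness_grid(vals, "INL")
  f <- tempfile(fileext = ".csv")
  write_thickness_grid(tg, f)
  back <- read_thickness_grid(f)
  expect_equal(back$values_um, tg$values_um, tolerance = 1e-6)
  expect_identical(back$valid, tg$valid)
  expect_equal(back$layer, "INL")
})
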