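#' Density grid over the macular grid
#'
#' @param values `n x n` matrix of cell densities.
#' @param kind `"areametric"` (cells/mm^2) or `"volumetric"` (cells/mm^3).
#' @param cell_class Cell class label (e.g. `"GC"`, `"INL_total"`,
#'   `"equivalent_cone"`).
#' @param valid Logical validity matrix (default finite values).
#' @param grid A [macular_grid()].
#' @param source_thickness Optional [thickness_grid()] a volumetric grid
#'   was derived from.
#' @return Object of class `density_grid`.
#' @export
density_grid <- function(values, kind = c("areametric", "volumetric"),
                         cell_class = "GC", valid = NULL,
                         grid = macular_grid(), source_thickness = NULL) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  stopifnot(nrow(values) == grid$n, ncol(values) == grid$n)
  if (is.null(valid)) valid <- is.finite(values)
  values[!valid] <- NA_real_
  if (any(values[valid] < 0)) stop("negative densities are not allowed")
  structure(list(values = values, valid = valid, kind = kind,
                 cell_class = cell_class, grid = grid,
                 source_thickness = source_thickness),
            class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  unit <- if (x$kind == "areametric") "cells/mm2" else "cells/mm3"
  cat(sprintf("%s %s density grid (%s): %d/%d valid, peak %.3g\n",
              x$cell_class, x$kind, unit, sum(x$valid), length(x$valid),
              max(x$values, na.rm = TRUE)))
  invisible(x)
}

# angular positions of the principal meridians, right-eye en face frame
MERIDIAN_ANGLES <- c(T = 0, S = 90, N = 180, I = 270)

#' Interpolate a density field between the principal meridians
#'
#' Builds a polar density field from four principal-meridian profiles:
#' profiles are first resampled onto a common radial grid (`step_um`
#' intervals, linear interpolation), then density at angle `theta` is
#' linear in angle between the two flanking principal meridians
#' (T = 0 deg, S = 90, N = 180, I = 270; right-eye en face convention).
#'
#' @param profiles A [meridian_profile_set()].
#' @param step_um Radial resampling step (um).
#' @return Object of class `polar_field` with `r_mm` and a 4-column value
#'   matrix; evaluate it with [polar_density_at()].
#' @export
interpolate_between_meridians <- function(profiles, step_um = 5) {
  stopifnot(inherits(profiles, "meridian_profile_set"))
  r <- seq(0, max(profiles$ecc_mm), by = step_um / 1000)
  vals <- apply(profiles$values, 2, function(v)
    stats::approx(profiles$ecc_mm, v, xout = r, rule = 1)$y)
  structure(list(r_mm = r, values = vals, kind = profiles$kind,
                 unit = profiles$unit),
            class = "polar_field")
}

#' Evaluate a polar density field
#'
#' @param field A `polar_field` from [interpolate_between_meridians()].
#' @param r_mm Radii (mm).
#' @param theta_deg Angles (degrees, T = 0 / S = 90 / N = 180 / I = 270).
#' @return Densities; `NA` beyond the radial support (no extrapolation).
#' @export
polar_density_at <- function(field, r_mm, theta_deg) {
  n <- max(length(r_mm), length(theta_deg))
  r_mm <- rep_len(r_mm, n); th <- rep_len(theta_deg %% 360, n)
  # radial interpolation for each meridian at the requested radii
  rad <- matrix(vapply(1:4, function(m)
    stats::approx(field$r_mm, field$values[, m], xout = r_mm, rule = 1)$y,
    numeric(n)), nrow = n)
  colnames(rad) <- colnames(field$values)
  sector <- pmin(floor(th / 90), 3)            # 0:T-S 1:S-N 2:N-I 3:I-T
  w <- (th - 90 * sector) / 90
  lower <- c("T", "S", "N", "I")[sector + 1]
  upper <- c("S", "N", "I", "T")[sector + 1]
  (1 - w) * rad[cbind(seq_len(n), match(lower, colnames(rad)))] +
    w * rad[cbind(seq_len(n), match(upper, colnames(rad)))]
}

#' Average a polar density field over the macular grid squares
#'
#' Each square's value is the mean of the field over an `n_sub x n_sub`
#' lattice of sample points inside the square (default 24, about 5 um
#' spacing). Squares containing points beyond the field's radial support
#' are marked invalid.
#'
#' @param field A `polar_field`.
#' @param grid A [macular_grid()].
#' @param cell_class Cell class label for the output.
#' @param n_sub Sub-samples per square side (>= 23 approximates 5 um).
#' @return An areametric [density_grid()].
#' @export
grid_average_density <- function(field, grid = macular_grid(),
                                 cell_class = field$kind, n_sub = 24L) {
  stopifnot(n_sub >= 2)
  sq <- grid$square_um
  off <- (seq_len(n_sub) - 0.5) / n_sub * sq - sq / 2
  xs <- rep(grid$x_centers_um, each = n_sub) +
    rep(off, times = grid$n)                       # all sample columns
  ys <- rep(grid$y_centers_um, each = n_sub) + rep(off, times = grid$n)
  X <- matrix(rep(xs, times = length(ys)), nrow = length(ys), byrow = TRUE)
  Y <- matrix(rep(ys, times = length(xs)), nrow = length(ys))
  r <- sqrt(X^2 + Y^2) / 1000
  theta <- atan2(Y, X) * 180 / pi
  d <- polar_density_at(field, as.vector(r), as.vector(theta))
  dm <- matrix(d, nrow = nrow(X))
  # collapse sub-lattice blocks to square means
  rowg <- rep(seq_len(grid$n), each = n_sub)
  colg <- rep(seq_len(grid$n), each = n_sub)
  vals <- rowsum(t(rowsum(dm, rowg)), colg) / n_sub^2
  vals <- t(vals)
  density_grid(ifelse(is.finite(vals), pmax(vals, 0), NA_real_),
               kind = "areametric", cell_class = cell_class, grid = grid)
}

#' Convert between areametric and volumetric density
#'
#' `to_volumetric` divides an areametric grid (cells/mm^2) by the layer
#' thickness in mm; `to_areametric` multiplies back. Squares invalid in
#' either input, or with non-positive thickness, are invalid.
#'
#' @param areal An areametric [density_grid()].
#' @param thickness The matching [thickness_grid()] (um).
#' @return A [density_grid()] of the other kind.
#' @export
to_volumetric <- function(areal, thickness) {
  stopifnot(areal$kind == "areametric",
            inherits(thickness, "thickness_grid"),
            areal$grid$n == thickness$grid$n)
  ok <- areal$valid & thickness$valid & thickness$values_um > 0
  vals <- ifelse(ok, areal$values / (thickness$values_um / 1000), NA_real_)
  density_grid(vals, "volumetric", areal$cell_class, valid = ok,
               grid = areal$grid, source_thickness = thickness)
}

#' @rdname to_volumetric
#' @param volumetric A volumetric [density_grid()].
#' @export
to_areametric <- function(volumetric, thickness) {
  stopifnot(volumetric$kind == "volumetric",
            inherits(thickness, "thickness_grid"))
  ok <- volumetric$valid & thickness$valid & thickness$values_um > 0
  vals <- ifelse(ok, volumetric$values * (thickness$values_um / 1000),
                 NA_real_)
  density_grid(vals, "areametric", volumetric$cell_class, valid = ok,
               grid = volumetric$grid, source_thickness = thickness)
}

#' Total INL density and component proportions
#'
#' Sums the component profiles into class totals (glycinergic + GABAergic
#' amacrine; OFF midget + ON + DB3a + DB3b bipolar; horizontal; Mueller),
#' corrects for the fraction of INL cells unlabeled by DAPI (default
#' 10.6%), and computes each class's proportion of the total INL density
#' at every eccentricity. Proportions therefore sum to `1 - fraction`.
#'
#' @param inl Output of `generate_meridian_profiles("INL_components")`, or
#'   any list with `ecc_mm` and a `densities` matrix whose column names
#'   include the eight component profiles.
#' @param dapi_unlabeled_fraction Fraction of INL cells unlabeled by DAPI.
#' @return List with `ecc_mm`, `total` (cells/mm^2), `class_densities`
#'   (matrix: amacrine, bipolar, horizontal, muller), `proportions`
#'   (same shape, relative to `total`), `dapi_unlabeled_fraction`.
#' @export
inl_total_and_components <- function(inl, dapi_unlabeled_fraction = 0.106) {
  stopifnot(dapi_unlabeled_fraction >= 0, dapi_unlabeled_fraction < 1)
  d <- inl$densities
  if (any(d < 0)) stop("negative component density")
  cls <- cbind(
    amacrine = d[, "amacrine_glycinergic"] + d[, "amacrine_gabaergic"],
    bipolar = d[, "bipolar_off_midget"] + d[, "bipolar_on"] +
      d[, "bipolar_db3a"] + d[, "bipolar_db3b"],
    horizontal = d[, "horizontal"],
    muller = d[, "muller"])
  dapi_total <- rowSums(cls)
  total <- dapi_total / (1 - dapi_unlabeled_fraction)
  list(ecc_mm = inl$ecc_mm, total = total, class_densities = cls,
       proportions = cls / total,
       dapi_unlabeled_fraction = dapi_unlabeled_fraction)
}

# thickness vs radius along the temporal meridian: mean of the two central
# rows over the temporal (x < 0) half, as a function of |x|
temporal_thickness_profile <- function(thickness) {
  g <- thickness$grid
  rows <- c(g$n / 2, g$n / 2 + 1)
  cols <- which(g$x_centers_um < 0)
  v <- colMeans(thickness$values_um[rows, cols, drop = FALSE])
  if (anyNA(v)) stop("radial gap: missing temporal squares in the thickness grid")
  r <- abs(g$x_centers_um[cols]) / 1000
  o <- order(r)
  list(r_mm = r[o], thickness_um = v[o])
}

#' INL cell density grids from the temporal-meridian profile
#'
#' INL histological densities are available along the temporal meridian
#' only, so volumetric INL density is derived there -- areametric density
#' divided by the temporal INL thickness profile -- and extrapolated across
#' all angular eccentricities as a function of radius alone. Areametric
#' grids for the total and each component are then recovered by
#' multiplying by the (asymmetric) INL thickness grid and the component
#' proportions, so thickness asymmetries reappear in the areametric maps.
#' An `unlabeled` component (the DAPI-unlabeled fraction) is included so
#' the returned components sum exactly to the total.
#'
#' @param inl Output of [inl_total_and_components()].
#' @param inl_thickness INL [thickness_grid()] (reference cohort mean).
#' @return List of [density_grid()]s: `volumetric_total`, `areal_total`,
#'   and `components` (amacrine, bipolar, horizontal, muller, unlabeled).
#' @export
inl_grid_densities <- function(inl, inl_thickness) {
  tp <- temporal_thickness_profile(inl_thickness)
  g <- inl_thickness$grid
  th_t <- stats::approx(tp$r_mm, tp$thickness_um,
                        xout = pmin(pmax(inl$ecc_mm, min(tp$r_mm)),
                                    max(tp$r_mm)))$y
  areal_t <- stats::approx(inl$ecc_mm, inl$total, xout = inl$ecc_mm)$y
  vol_profile <- areal_t / (th_t / 1000)
  r_sq <- sqrt(outer(g$y_centers_um^2, g$x_centers_um^2, `+`)) / 1000
  vol_sq <- matrix(stats::approx(inl$ecc_mm, vol_profile,
                                 xout = pmin(as.vector(r_sq),
                                             max(inl$ecc_mm)))$y,
                   g$n, g$n)
  ok <- inl_thickness$valid & inl_thickness$values_um > 0
  vol_grid <- density_grid(ifelse(ok, vol_sq, NA_real_), "volumetric",
                           "INL_total", valid = ok, grid = g,
                           source_thickness = inl_thickness)
  areal_total <- to_areametric(vol_grid, inl_thickness)
  prop_sq <- function(p) matrix(stats::approx(inl$ecc_mm, p,
                                              xout = pmin(as.vector(r_sq),
                                                          max(inl$ecc_mm)))$y,
                                g$n, g$n)
  comps <- lapply(colnames(inl$proportions), function(cl) {
    pv <- prop_sq(inl$proportions[, cl])
    density_grid(ifelse(ok, areal_total$values * pv, NA_real_),
                 "areametric", paste0("INL_", cl), valid = ok, grid = g)
  })
  names(comps) <- colnames(inl$proportions)
  comps$unlabeled <- density_grid(
    ifelse(ok, areal_total$values * inl$dapi_unlabeled_fraction, NA_real_),
    "areametric", "INL_unlabeled", valid = ok, grid = g)
  list(volumetric_total = vol_grid, areal_total = areal_total,
       components = comps)
}

#' Area of a hexagonal cell cross-section
#'
#' Hexagon metric used throughout the packing model: `w` is the
#' flat-to-flat diameter (um) and the area is `sqrt(3)/2 * w^2`, returned
#' in mm^2.
#'
#' @param w_um Flat-to-flat diameter (um).
#' @return Cross-section area (mm^2).
#' @export
hex_area_mm2 <- function(w_um) {
  sqrt(3) / 2 * (w_um / 1000)^2
}

#' Equivalent-cone photoreceptor packing profile
#'
#' Converts rod density into cone-equivalent density via a hexagonal
#' maximum-packing model, per meridian at 5 um eccentricity steps:
#' cone diameters are Akima-splined onto the density grid, the en face
#' area fraction covered by cone inner segments is
#' `f_c = cone_density * hex_area(w_c)` (clamped to 1); the remaining
#' fraction is shared among rods, giving a per-rod area
#' `A_r = (1 - f_c) / rod_density` and a raw rod diameter
#' `w_r = sqrt(2 * A_r / sqrt(3))`. Because sparse central rods make the
#' raw diameter unreliable, `w_r` is replaced by its linear-in-eccentricity
#' OLS fit (central `central_exclude_um` excluded). Equivalent cone density
#' adds the area-converted rods to the cones:
#' `cone + rod * A_r_fit / hex_area(w_c)`; inside the rod-free zone it
#' equals the cone density.
#'
#' @param cone A `meridian_profile_set` of cone densities (cells/mm^2).
#' @param cone_diameter A `meridian_profile_set` of cone diameters (um),
#'   possibly sampled coarsely; Akima-splined with nearest-value extension.
#' @param rod A `meridian_profile_set` of rod densities.
#' @param rod_free_radius_um Rod-free zone radius (um), in `[126, 200]`.
#' @param central_exclude_um Eccentricity below which raw rod diameters are
#'   excluded from the regression.
#' @param clamp_tol Allowed overshoot of the cone area fraction above 1
#'   before the inputs are declared inconsistent.
#' @param step_um Common eccentricity step (um).
#' @return Object of class `packing_profile`: `ecc_mm` plus per-meridian
#'   matrices `cone_density`, `cone_diameter_um`, `cone_area_fraction`,
#'   `rod_density`, `rod_diameter_um` (regression-fitted),
#'   `equivalent_cone` ; and `equivalent_cone_set`, a
#'   [meridian_profile_set()] ready for meridian interpolation.
#' @export
equivalent_cone_profile <- function(cone, cone_diameter, rod,
                                    rod_free_radius_um = 150,
                                    central_exclude_um = 300,
                                    clamp_tol = 0.02, step_um = 5) {
  stopifnot(rod_free_radius_um >= 126, rod_free_radius_um <= 200)
  rmax <- min(max(cone$ecc_mm), max(rod$ecc_mm))
  r <- seq(0, rmax, by = step_um / 1000)
  res <- function(set) apply(set$values, 2, function(v)
    stats::approx(set$ecc_mm, v, xout = r, rule = 1)$y)
  cd <- res(cone); rd <- res(rod)
  # Akima spline for cone diameter, nearest-value extension outside support;
  # pracma leaves the outermost interval undefined, so patch any remaining
  # points linearly from the samples
  akima_eval <- function(x, y, xi) {
    xic <- pmin(pmax(xi, min(x)), max(x))
    out <- suppressWarnings(pracma::akimaInterp(x, y, xic))
    bad <- !is.finite(out)
    if (any(bad)) out[bad] <- stats::approx(x, y, xout = xic[bad],
                                            rule = 2)$y
    out
  }
  wc <- apply(cone_diameter$values, 2, function(v)
    akima_eval(cone_diameter$ecc_mm, v, r))
  fc <- cd * hex_area_mm2(wc)
  if (any(fc > 1 + clamp_tol, na.rm = TRUE))
    stop("cone area fraction exceeds 1: inconsistent density/diameter data")
  fc <- pmin(fc, 1)
  rodfree <- r * 1000 <= rod_free_radius_um
  wr_fit <- matrix(NA_real_, length(r), 4)
  eq <- cd
  for (m in 1:4) {
    usable <- !rodfree & rd[, m] > 0 & fc[, m] < 1
    Ar_raw <- ifelse(usable, (1 - fc[, m]) / rd[, m], NA_real_)
    wr_raw <- sqrt(2 * Ar_raw / sqrt(3)) * 1000
    fit_pts <- usable & r * 1000 >= central_exclude_um
    if (sum(fit_pts) >= 2) {
      fit <- stats::lm(w ~ e, data = data.frame(w = wr_raw[fit_pts],
                                                e = r[fit_pts]))
      wr_fit[, m] <- pmax(stats::predict(fit, data.frame(e = r)), 0)
      Ar_fit <- hex_area_mm2(wr_fit[, m])
      eq[, m] <- cd[, m] +
        ifelse(rd[, m] > 0, rd[, m] * Ar_fit / hex_area_mm2(wc[, m]), 0)
    } # rods absent on this meridian: equivalent cone = cone
    eq[rodfree | rd[, m] == 0, m] <- cd[rodfree | rd[, m] == 0, m]
  }
  colnames(wr_fit) <- colnames(eq) <- c("T", "N", "S", "I")
  structure(list(ecc_mm = r, cone_density = cd, cone_diameter_um = wc,
                 cone_area_fraction = fc, rod_density = rd,
                 rod_diameter_um = wr_fit, equivalent_cone = eq,
                 rod_free_radius_um = rod_free_radius_um,
                 equivalent_cone_set = meridian_profile_set(
                   r, eq, "equivalent_cone")),
            class = "packing_profile")
}

#' @export
print.packing_profile <- function(x, ...) {
  cat(sprintf("Photoreceptor packing profile: ecc 0-%.2f mm, rod-free %g um\n",
              max(x$ecc_mm), x$rod_free_radius_um))
  cat(sprintf("  equivalent cone density range %.3g-%.3g cells/mm2\n",
              min(x$equivalent_cone), max(x$equivalent_cone)))
  invisible(x)
}

#' Predict a cell count from an individual thickness grid
#'
#' `count = sum over squares of volumetric_density (cells/mm^3) x
#' thickness (mm) x square_area (mm^2)`. Squares invalid in either input
#' are excluded with a warning; the returned value carries the coverage
#' fraction as an attribute.
#'
#' @param thickness An individual's [thickness_grid()].
#' @param volumetric A reference volumetric [density_grid()].
#' @param region Optional integer vector of (column-major) square indices;
#'   default all squares valid in both inputs.
#' @return Estimated cell count with attribute `coverage` (fraction of the
#'   requested region that was usable).
#' @export
predict_cell_count <- function(thickness, volumetric, region = NULL) {
  stopifnot(inherits(thickness, "thickness_grid"),
            inherits(volumetric, "density_grid"),
            volumetric$kind == "volumetric",
            thickness$grid$n == volumetric$grid$n)
  ok <- thickness$valid & volumetric$valid
  if (is.null(region)) region <- which(ok)
  usable <- region[ok[region]]
  if (length(usable) < length(region))
    warning(sprintf("%d of %d squares in region invalid; excluded",
                    length(region) - length(usable), length(region)))
  area_mm2 <- (thickness$grid$square_um / 1000)^2
  cnt <- sum(volumetric$values[usable] *
               (thickness$values_um[usable] / 1000) * area_mm2)
  attr(cnt, "coverage") <- length(usable) / length(region)
  cnt
}
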