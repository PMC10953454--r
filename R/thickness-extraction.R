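layer_surfaces <- function(layer) {
  switch(layer,
         GCL = c("RNFL_GCL", "GCL_INL"),
         INL = c("GCL_INL", "INL_OPL"),
         ISOS = c("ELM", "RPE"),
         stop("unknown layer: ", layer))
}

# rolling least-squares slope of v over u within a centered window;
# returns NA where the window is incomplete or contains non-finite values
rolling_slope <- function(u, v, window) {
  w <- rep(1, window)
  f <- function(x) as.numeric(stats::filter(x, w, sides = 2))
  su <- f(u); sv <- f(v); suu <- f(u * u); suv <- f(u * v)
  (suv - su * sv / window) / (suu - su^2 / window)
}

#' B-scan tilt from the RPE tangent
#'
#' Estimates the local tilt of a B-scan as the angle between the tangent to
#' the retinal pigment epithelium (RPE) boundary and the horizontal. The
#' tangent slope is a least-squares fit over a centered window of A-scans,
#' computed in physical units (lateral and axial pixel sizes applied before
#' the arctangent). Positive tilt means the RPE deepens with increasing
#' lateral index.
#'
#' @param rpe_curve Numeric vector of RPE axial pixel positions per A-scan.
#' @param at A-scan index (or vector of indices) at which to evaluate;
#'   default all.
#' @param window Window width in A-scans (odd, >= 3).
#' @param geometry A [scan_geometry()] supplying the pixel scales.
#' @return Tilt angle(s) in degrees; `NA` where fewer than `window` finite
#'   samples are available.
#' @export
bscan_tilt <- function(rpe_curve, at = seq_along(rpe_curve), window = 21L,
                       geometry = scan_geometry()) {
  stopifnot(window >= 3)
  u <- (seq_along(rpe_curve) - 1) * geometry$lateral_px_um
  v <- rpe_curve * geometry$axial_px_um
  slope <- rolling_slope(u, v, window)
  atan(slope[at]) * 180 / pi
}

# Distance t along the inward normal (sin(theta), -cos(theta)) in (u, v)
# (v positive deeper) from anchor points (u0, v0) to a boundary curve given
# as (cu, cv) in physical um. Solved by fixed-point iteration
# t <- (v0 - c(u0 + t sin(theta))) / cos(theta); contraction requires
# |c' * tan(theta)| < 1, satisfied for slab-like anatomy below ~45 degrees.
normal_intersection_t <- function(cu, cv, u0, v0, theta_rad,
                                  tol = 1e-10, max_iter = 100L) {
  ct <- cos(theta_rad); st <- sin(theta_rad)
  t <- (v0 - stats::approx(cu, cv, xout = u0, rule = 1)$y) / ct
  for (k in seq_len(max_iter)) {
    cz <- stats::approx(cu, cv, xout = u0 + t * st, rule = 1)$y
    t_new <- (v0 - cz) / ct
    if (all(abs(t_new - t) < tol, na.rm = TRUE)) { t <- t_new; break }
    t <- t_new
  }
  t
}

#' Tilt-corrected perpendicular layer thickness
#'
#' Measures the distance along the normal to the local RPE tangent between
#' its intersections with the inner and outer boundary curves of a layer,
#' in micrometers. For a uniformly tilted slab this equals the axial
#' boundary separation multiplied by `cos(tilt)`.
#'
#' @param inner_curve,outer_curve Axial pixel positions per A-scan for the
#'   layer's inner and outer boundary.
#' @param rpe_curve RPE axial pixel positions (anchor surface for the
#'   normal); defaults to `outer_curve`.
#' @param at A-scan index (or vector) at which to evaluate.
#' @param tilt_deg Local tilt in degrees (scalar or per-`at` vector); if
#'   `NULL`, computed from `rpe_curve` via [bscan_tilt()].
#' @param window Tangent-fit window passed to [bscan_tilt()].
#' @param geometry A [scan_geometry()].
#' @return Perpendicular thickness(es) in um; `NA` where the normal leaves
#'   the B-scan or boundary data are missing.
#' @export
perpendicular_thickness <- function(inner_curve, outer_curve,
                                    rpe_curve = outer_curve,
                                    at = seq_along(inner_curve),
                                    tilt_deg = NULL, window = 21L,
                                    geometry = scan_geometry()) {
  u <- (seq_along(inner_curve) - 1) * geometry$lateral_px_um
  vi <- inner_curve * geometry$axial_px_um
  vo <- outer_curve * geometry$axial_px_um
  vr <- rpe_curve * geometry$axial_px_um
  if (is.null(tilt_deg))
    tilt_deg <- bscan_tilt(rpe_curve, at, window, geometry)
  if (any(abs(tilt_deg) >= 90, na.rm = TRUE))
    stop("|tilt_deg| must be < 90")
  th <- rep_len(tilt_deg, length(at)) * pi / 180
  u0 <- u[at]; v0 <- vr[at]
  t_in <- normal_intersection_t(u, vi, u0, v0, th)
  t_out <- normal_intersection_t(u, vo, u0, v0, th)
  t_in - t_out
}

#' Extract a tilt-corrected 60 x 60 thickness grid from a boundary volume
#'
#' Computes per-A-scan perpendicular layer thicknesses across every B-scan,
#' places each A-scan at its en face position relative to the fovea
#' (rotating by the fovea-to-disc axis angle), and averages valid samples
#' within each square of the macular grid. Left eyes are mirrored so that
#' columns read temporal to nasal in right-eye format. A-scans under the
#' exclusion mask and B-scans with signal quality below `quality_min_db`
#' are dropped; squares with fewer than `min_samples` valid samples are
#' marked invalid.
#'
#' @param volume A `boundary_volume`.
#' @param layer `"GCL"`, `"INL"` or `"ISOS"`.
#' @param grid A [macular_grid()].
#' @param convert_to_od Mirror OS volumes into right-eye format.
#' @param window Tangent-fit window (A-scans).
#' @param min_samples Minimum valid samples per square.
#' @param quality_min_db B-scan signal-quality cutoff (dB).
#' @param method `"intersect"` uses the RPE-normal boundary intersections;
#'   `"axial"` skips tilt correction (for tilt-effect analyses).
#' @return A [thickness_grid()].
#' @export
extract_grid <- function(volume, layer = c("GCL", "INL", "ISOS"),
                         grid = macular_grid(), convert_to_od = TRUE,
                         window = 21L, min_samples = 1L,
                         quality_min_db = 15, method = c("intersect", "axial")) {
  layer <- match.arg(layer)
  method <- match.arg(method)
  g <- volume$geometry
  surf <- layer_surfaces(layer)
  for (s in c(surf, "RPE"))
    if (is.null(volume$boundaries[[s]]))
      stop("boundary volume is missing surface: ", s)
  half <- grid$extent_um / 2
  if (abs(g$fovea_xy_um[1]) + half > g$scan_width_um / 2 ||
      abs(g$fovea_xy_um[2]) + half > (g$n_bscans - 1) * g$bscan_spacing_um / 2 +
        g$bscan_spacing_um)
    stop("macular grid does not fit inside the scan area around the fovea")
  sums <- matrix(0, grid$n, grid$n)
  counts <- matrix(0L, grid$n, grid$n)
  alpha <- -g$disc_fovea_angle_deg * pi / 180
  ca <- cos(alpha); sa <- sin(alpha)
  u_all <- ascan_x_um(g, seq_len(g$n_ascans))
  for (i in seq_len(g$n_bscans)) {
    if (volume$quality_db[i] < quality_min_db) next
    inner <- volume$boundaries[[surf[1]]][i, ]
    outer <- volume$boundaries[[surf[2]]][i, ]
    rpe <- volume$boundaries$RPE[i, ]
    if (method == "intersect") {
      th <- perpendicular_thickness(inner, outer, rpe, tilt_deg = NULL,
                                    window = window, geometry = g)
    } else {
      th <- (outer - inner) * g$axial_px_um
    }
    th[volume$exclusion_mask[i, ]] <- NA
    ok <- is.finite(th)
    if (!any(ok)) next
    x <- u_all[ok] - g$fovea_xy_um[1]
    y <- bscan_y_um(g, i) - g$fovea_xy_um[2]
    if (convert_to_od && volume$eye == "OS") x <- -x
    xr <- ca * x - sa * y
    yr <- sa * x + ca * y
    col <- floor((xr + half) / grid$square_um) + 1
    row <- floor((half - yr) / grid$square_um) + 1
    inside <- col >= 1 & col <= grid$n & row >= 1 & row <= grid$n
    if (!any(inside)) next
    idx <- cbind(row[inside], col[inside])
    tv <- th[ok][inside]
    # accumulate via linear index aggregation
    lin <- (idx[, 2] - 1L) * grid$n + idx[, 1]
    agg_s <- rowsum(tv, lin)
    agg_n <- rowsum(rep(1L, length(lin)), lin)
    pos <- as.integer(rownames(agg_s))
    sums[pos] <- sums[pos] + agg_s[, 1]
    counts[pos] <- counts[pos] + agg_n[, 1]
  }
  valid <- counts >= min_samples
  vals <- ifelse(valid, sums / pmax(counts, 1L), NA_real_)
  thickness_grid(vals, layer = layer, valid = valid, grid = grid)
}
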