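#' Ground-truth model for synthetic cohorts
#'
#' Encodes the "true" spatial aging structure a synthetic cohort is built
#' from: an en face cluster label field and, per cluster, quadratic aging
#' coefficients so that true thickness at age A is `c + b*A + a*A^2`,
#' plus additive covariate effects (applied to the INL by default), subject
#' variability and measurement noise, and a global B-scan tilt.
#'
#' @param layer Target layer, `"GCL"`, `"INL"` or `"ISOS"`.
#' @param clusters List of numeric vectors `c(a, b, c)` (um/y^2, um/y, um),
#'   one per cluster, cluster `k` being the k-th entry.
#' @param label_fun Function `(dx_um, dy_um) -> integer` mapping en face
#'   offsets from the fovea (right-eye frame, + nasal / + superior) to a
#'   cluster label in `1..length(clusters)`. Default: concentric rings.
#' @param ring_radii_um Ring outer radii used by the default `label_fun`;
#'   must have `length(clusters)` entries, last covering the grid diagonal.
#' @param sex_effect_um Additive thickness shift for female participants (um).
#' @param refraction_effect_um_per_D Additive shift per diopter of mean
#'   spherical equivalent refraction (um/D).
#' @param covariates_apply Logical; apply the sex/refraction effects. The
#'   default applies them only when `layer == "INL"`.
#' @param noise_sd_um Measurement noise SD (um), i.i.d. per A-scan (rendered
#'   volumes) or per grid square (fast grid generation).
#' @param between_sd_um Between-participant random thickness offset SD (um).
#' @param tilt_deg Global B-scan tilt (degrees, in-plane rotation).
#' @param rpe_shape `"planar"` (uniform tilt) or `"spherical"` (curved RPE,
#'   for stress tests).
#' @param rpe_radius_um Radius of curvature for `rpe_shape = "spherical"`.
#' @return Object of class `ground_truth_model`.
#' @export
ground_truth_model <- function(layer = c("GCL", "INL", "ISOS"),
                               clusters = list(c(-0.0023, 0.18, 27.79)),
                               label_fun = NULL,
                               ring_radii_um = NULL,
                               sex_effect_um = 0,
                               refraction_effect_um_per_D = 0,
                               covariates_apply = NULL,
                               noise_sd_um = 2,
                               between_sd_um = 2,
                               tilt_deg = 0,
                               rpe_shape = c("planar", "spherical"),
                               rpe_radius_um = 12e3) {
  layer <- match.arg(layer)
  rpe_shape <- match.arg(rpe_shape)
  stopifnot(length(clusters) >= 1, all(vapply(clusters, length, 1L) == 3))
  if (is.null(covariates_apply)) covariates_apply <- (layer == "INL")
  # every cluster polynomial must stay positive over the supported age range
  ages <- seq(18, 95, by = 0.5)
  for (k in seq_along(clusters)) {
    cf <- clusters[[k]]
    if (min(cf[3] + cf[2] * ages + cf[1] * ages^2) <= 0)
      stop(sprintf("cluster %d implies non-positive thickness within ages 18-95", k))
  }
  if (is.null(label_fun)) {
    K <- length(clusters)
    if (is.null(ring_radii_um))
      ring_radii_um <- seq_len(K) / K * 3440 * sqrt(2) + 1
    stopifnot(length(ring_radii_um) == K)
    radii <- ring_radii_um
    # label 1 = central disc, K = outermost ring, per the supplied radii
    label_fun <- function(dx_um, dy_um) {
      r <- sqrt(dx_um^2 + dy_um^2)
      pmin(findInterval(r, c(0, radii[-length(radii)])), length(radii))
    }
  }
  structure(list(layer = layer, clusters = clusters, label_fun = label_fun,
                 sex_effect_um = sex_effect_um,
                 refraction_effect_um_per_D = refraction_effect_um_per_D,
                 covariates_apply = covariates_apply,
                 noise_sd_um = noise_sd_um, between_sd_um = between_sd_um,
                 tilt_deg = tilt_deg, rpe_shape = rpe_shape,
                 rpe_radius_um = rpe_radius_um),
            class = "ground_truth_model")
}

#' Evaluate the noiseless true thickness field
#'
#' @param truth A [ground_truth_model()].
#' @param dx_um,dy_um En face offsets from the fovea (right-eye frame).
#' @param age_years Participant age.
#' @param female 0/1 indicator (M = 0, F = 1).
#' @param refraction_D Mean spherical equivalent refraction (D).
#' @return Vector of true thicknesses (um), recycled over positions.
#' @export
true_thickness <- function(truth, dx_um, dy_um, age_years,
                           female = 0, refraction_D = 0) {
  lab <- truth$label_fun(dx_um, dy_um)
  cf <- matrix(unlist(truth$clusters), nrow = 3)  # rows a, b, c
  v <- cf[3, lab] + cf[2, lab] * age_years + cf[1, lab] * age_years^2
  if (truth$covariates_apply)
    v <- v + truth$sex_effect_um * female +
      truth$refraction_effect_um_per_D * refraction_D
  v
}

#' Generate a demographics table
#'
#' Draws a synthetic cohort with the composition of a healthy adult clinic
#' population: ages uniform on `age_range`, balanced sex, a White/Asian
#' ethnicity mix, mildly myopic refraction truncated to the +3.00 to -6.00 D
#' inclusion range, and near-zero logMAR acuity.
#'
#' @param n Number of participants.
#' @param age_range Age range (years), sampled uniformly.
#' @param prop_female,prop_asian,prop_os Category proportions.
#' @param refraction_mean_D,refraction_sd_D Refraction distribution (D),
#'   truncated to `[-6, +3]`.
#' @return A data.frame with columns `participant_id`, `age_years`, `sex`
#'   (M/F), `ethnicity` (White/Asian), `refraction_D`, `bcva_logmar`, `eye`.
#' @export
generate_demographics <- function(n, age_range = c(20, 85),
                                  prop_female = 0.45, prop_asian = 0.4,
                                  prop_os = 0.5,
                                  refraction_mean_D = -0.5,
                                  refraction_sd_D = 1.75) {
  stopifnot(n >= 1, age_range[1] >= 18, age_range[2] <= 95)
  rx <- stats::rnorm(n, refraction_mean_D, refraction_sd_D)
  rx <- pmin(pmax(rx, -6), 3)
  data.frame(
    participant_id = sprintf("P%04d", seq_len(n)),
    age_years = stats::runif(n, age_range[1], age_range[2]),
    sex = ifelse(stats::runif(n) < prop_female, "F", "M"),
    ethnicity = ifelse(stats::runif(n) < prop_asian, "Asian", "White"),
    refraction_D = rx,
    bcva_logmar = stats::rnorm(n, 0.004, 0.1),
    eye = ifelse(stats::runif(n) < prop_os, "OS", "OD"),
    stringsAsFactors = FALSE)
}

#' Fast grid-level synthetic cohort
#'
#' Generates per-participant [thickness_grid()]s directly from the truth
#' model, bypassing boundary-volume rendering and extraction: each square's
#' value is the true thickness at the square center plus a participant
#' offset (`between_sd_um`) and i.i.d. square-level noise (`noise_sd_um`).
#' This is the workhorse for statistical validation at cohort scale; the
#' rendered-volume path ([generate_cohort()]) exercises the full geometry.
#'
#' @param demo Demographics data.frame from [generate_demographics()].
#' @param truth A [ground_truth_model()].
#' @param grid A [macular_grid()].
#' @param seed Optional integer seed for reproducibility.
#' @return List of `thickness_grid`s, one per row of `demo`.
#' @export
generate_thickness_grids <- function(demo, truth, grid = macular_grid(),
                                     seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  xy <- expand.grid(y = grid$y_centers_um, x = grid$x_centers_um)
  lab <- truth$label_fun(xy$x, xy$y)
  cf <- matrix(unlist(truth$clusters), nrow = 3)
  n <- nrow(demo)
  female <- as.numeric(demo$sex == "F")
  base_c <- matrix(cf[3, lab], grid$n, grid$n)
  base_b <- matrix(cf[2, lab], grid$n, grid$n)
  base_a <- matrix(cf[1, lab], grid$n, grid$n)
  lapply(seq_len(n), function(i) {
    A <- demo$age_years[i]
    v <- base_c + base_b * A + base_a * A^2
    if (truth$covariates_apply)
      v <- v + truth$sex_effect_um * female[i] +
        truth$refraction_effect_um_per_D * demo$refraction_D[i]
    v <- v + stats::rnorm(1, 0, truth$between_sd_um) +
      matrix(stats::rnorm(grid$n^2, 0, truth$noise_sd_um), grid$n, grid$n)
    thickness_grid(v, layer = truth$layer, grid = grid)
  })
}

# Perpendicular offset of a boundary curve from a reference surface.
# u: lateral positions (um); v: reference axial positions (um, + deeper);
# d: perpendicular distance (um) toward the inner retina, per point.
# Returns axial positions resampled onto the original u grid.
offset_surface <- function(u, v, d) {
  n <- length(u)
  fw <- pmin(seq_len(n) + 1L, n)
  bw <- pmax(seq_len(n) - 1L, 1L)
  phi <- atan((v[fw] - v[bw]) / (u[fw] - u[bw]))
  up <- u + d * sin(phi)
  vp <- v - d * cos(phi)
  stats::approx(up, vp, xout = u, rule = 2)$y
}

#' Render a segmented boundary volume for one participant
#'
#' Builds per-B-scan boundary curves (axial pixel position vs lateral pixel
#' index) for the five surfaces RNFL_GCL, GCL_INL, INL_OPL, ELM and RPE,
#' such that the perpendicular distance between the surfaces bounding each
#' layer equals the true layer thickness while the whole retina is tilted
#' by the truth model's `tilt_deg` (or follows a spherical RPE). Boundary
#' positions are continuous (sub-pixel) unless `quantize = TRUE`.
#'
#' @param demo_row One-row demographics data.frame.
#' @param truth A [ground_truth_model()] for the target layer.
#' @param geometry A [scan_geometry()].
#' @param other_layers_um Named constants (um) for the non-target layers and
#'   the outer nuclear/plexiform spacer between INL_OPL and ELM.
#' @param quantize Round axial positions to whole pixels (emulates discrete
#'   segmentation output).
#' @param quality_db Per-B-scan signal strength (dB), recycled.
#' @return Object of class `boundary_volume` with elements `geometry`,
#'   `participant_id`, `eye`, `boundaries` (list of 5 matrices, B-scans x
#'   A-scans, axial px), `quality_db`, `exclusion_mask`.
#' @export
render_boundary_volume <- function(demo_row, truth,
                                   geometry = scan_geometry(),
                                   other_layers_um = c(GCL = 35, INL = 32,
                                                       ISOS = 70, spacer = 80),
                                   quantize = FALSE, quality_db = 30) {
  stopifnot(nrow(demo_row) == 1)
  eye <- demo_row$eye
  female <- as.numeric(demo_row$sex == "F")
  nb <- geometry$n_bscans; na <- geometry$n_ascans
  u <- ascan_x_um(geometry, seq_len(na))
  base_px <- 400
  theta <- truth$tilt_deg * pi / 180
  b_off <- stats::rnorm(1, 0, truth$between_sd_um)
  surf <- c("RNFL_GCL", "GCL_INL", "INL_OPL", "ELM", "RPE")
  bnd <- lapply(surf, function(s) matrix(NA_real_, nb, na))
  names(bnd) <- surf
  for (i in seq_len(nb)) {
    y <- bscan_y_um(geometry, i)
    dx_native <- u - geometry$fovea_xy_um[1]
    dy <- y - geometry$fovea_xy_um[2]
    dx_od <- if (eye == "OS") -dx_native else dx_native
    # layer thicknesses (um) at each A-scan
    t_target <- true_thickness(truth, dx_od, dy, demo_row$age_years,
                               female, demo_row$refraction_D) + b_off +
      stats::rnorm(na, 0, truth$noise_sd_um)
    if (any(t_target <= 0))
      stop("truth model implies non-positive thickness; adjust coefficients/noise")
    th <- list(GCL = rep(other_layers_um[["GCL"]], na),
               INL = rep(other_layers_um[["INL"]], na),
               ISOS = rep(other_layers_um[["ISOS"]], na))
    th[[truth$layer]] <- t_target
    # RPE in physical axial um (+ deeper)
    if (truth$rpe_shape == "planar") {
      v_rpe <- base_px * geometry$axial_px_um + tan(theta) * u
    } else {
      R <- truth$rpe_radius_um
      v_rpe <- base_px * geometry$axial_px_um - (R - sqrt(pmax(R^2 - u^2, 0)))
    }
    spacer <- other_layers_um[["spacer"]]
    v_elm  <- offset_surface(u, v_rpe, th$ISOS)
    v_iopl <- offset_surface(u, v_rpe, th$ISOS + spacer)
    v_gin  <- offset_surface(u, v_rpe, th$ISOS + spacer + th$INL)
    v_rgc  <- offset_surface(u, v_rpe, th$ISOS + spacer + th$INL + th$GCL)
    px <- function(v) v / geometry$axial_px_um
    bnd$RPE[i, ] <- px(v_rpe); bnd$ELM[i, ] <- px(v_elm)
    bnd$INL_OPL[i, ] <- px(v_iopl); bnd$GCL_INL[i, ] <- px(v_gin)
    bnd$RNFL_GCL[i, ] <- px(v_rgc)
  }
  if (quantize) bnd <- lapply(bnd, round)
  # enforce the anatomical surface ordering
  ok <- bnd$RNFL_GCL <= bnd$GCL_INL & bnd$GCL_INL <= bnd$INL_OPL &
    bnd$INL_OPL <= bnd$ELM & bnd$ELM <= bnd$RPE
  if (!all(ok)) stop("surface ordering violated during rendering")
  structure(list(geometry = geometry,
                 participant_id = demo_row$participant_id, eye = eye,
                 boundaries = bnd,
                 quality_db = rep_len(quality_db, nb),
                 exclusion_mask = matrix(FALSE, nb, na)),
            class = "boundary_volume")
}

#' @export
print.boundary_volume <- function(x, ...) {
  cat(sprintf("Boundary volume %s (%s): %d B-scans x %d A-scans, 5 surfaces\n",
              x$participant_id, x$eye, x$geometry$n_bscans, x$geometry$n_ascans))
  invisible(x)
}

#' Generate a full synthetic cohort with rendered boundary volumes
#'
#' @param n Cohort size.
#' @param truth A [ground_truth_model()].
#' @param geometry A [scan_geometry()].
#' @param seed Optional integer seed; the same seed reproduces the cohort
#'   bit-for-bit.
#' @param ... Passed to [render_boundary_volume()] and
#'   [generate_demographics()] (matched by name).
#' @return List with `demographics` (data.frame) and `volumes` (list of
#'   `boundary_volume`).
#' @export
generate_cohort <- function(n, truth, geometry = scan_geometry(),
                            seed = NULL, ...) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  dots <- list(...)
  demo_args <- dots[names(dots) %in% names(formals(generate_demographics))]
  rend_args <- dots[names(dots) %in% names(formals(render_boundary_volume))]
  demo <- do.call(generate_demographics, c(list(n = n), demo_args))
  vols <- lapply(seq_len(n), function(i)
    do.call(render_boundary_volume,
            c(list(demo_row = demo[i, , drop = FALSE], truth = truth,
                   geometry = geometry), rend_args)))
  list(demographics = demo, volumes = vols)
}

#' Write / read cohort tables
#'
#' `write_demographics` writes the demographics CSV (coding documented in a
#' header comment: sex M=0/F=1, ethnicity White=0/Asian=1).
#' `write_boundary_volume` writes a long-format CSV (participant_id,
#' bscan_index, ascan_index, surface_name, axial_px) with a JSON geometry
#' sidecar at `<path>.json`.
#'
#' @param demo Demographics data.frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_demographics <- function(demo, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("# synthetic cohort demographics",
               "# indicator coding: sex M=0/F=1; ethnicity White=0/Asian=1"), con)
  utils::write.csv(demo, con, row.names = FALSE, quote = FALSE, eol = "\n")
  invisible(path)
}

#' @rdname write_demographics
#' @param vol A `boundary_volume`.
#' @export
write_boundary_volume <- function(vol, path) {
  b <- vol$boundaries
  nb <- vol$geometry$n_bscans; na <- vol$geometry$n_ascans
  df <- do.call(rbind, lapply(names(b), function(s)
    data.frame(participant_id = vol$participant_id,
               bscan_index = rep(seq_len(nb), times = na),
               ascan_index = rep(seq_len(na), each = nb),
               surface_name = s,
               axial_px = round(as.vector(b[[s]]), 6))))
  df <- df[order(df$surface_name, df$bscan_index, df$ascan_index), ]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, eol = "\n")
  g <- vol$geometry
  jsonlite::write_json(
    list(geometry = unclass(g)[c("n_bscans", "bscan_spacing_um",
                                 "lateral_px_um", "axial_px_um",
                                 "scan_width_um", "scan_height_um",
                                 "fovea_xy_um", "disc_fovea_angle_deg")],
         eye = vol$eye, participant_id = vol$participant_id,
         quality_db = vol$quality_db),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_demographics
#' @export
read_boundary_volume <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  g <- do.call(scan_geometry, as.list(meta$geometry))
  df <- utils::read.csv(path)
  bnd <- lapply(split(df, df$surface_name), function(d) {
    m <- matrix(NA_real_, g$n_bscans, g$n_ascans)
    m[cbind(d$bscan_index, d$ascan_index)] <- d$axial_px
    m
  })
  structure(list(geometry = g, participant_id = meta$participant_id,
                 eye = meta$eye,
                 boundaries = bnd[c("RNFL_GCL", "GCL_INL", "INL_OPL",
                                    "ELM", "RPE")],
                 quality_db = meta$quality_db,
                 exclusion_mask = matrix(FALSE, g$n_bscans, g$n_ascans)),
            class = "boundary_volume")
}
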