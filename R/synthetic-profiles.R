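#' Meridian profile set
#'
#' Cell density (cells/mm^2) or cone diameter (um) as a function of
#' eccentricity along the four principal meridians, in right-eye en face
#' convention (T = temporal, N = nasal, S = superior, I = inferior).
#'
#' @param ecc_mm Strictly increasing eccentricities starting at 0 (mm).
#' @param values Matrix `length(ecc_mm) x 4` with columns `T, N, S, I`.
#' @param kind Profile kind label.
#' @param unit `"cells/mm2"` or `"um"`.
#' @return Object of class `meridian_profile_set`.
#' @export
meridian_profile_set <- function(ecc_mm, values, kind, unit = "cells/mm2") {
  values <- as.matrix(values)
  stopifnot(ecc_mm[1] == 0, all(diff(ecc_mm) > 0),
            nrow(values) == length(ecc_mm), ncol(values) == 4)
  colnames(values) <- c("T", "N", "S", "I")
  if (any(values < 0)) stop("negative profile values are not allowed")
  structure(list(ecc_mm = ecc_mm, values = values, kind = kind, unit = unit),
            class = "meridian_profile_set")
}

#' @export
print.meridian_profile_set <- function(x, ...) {
  cat(sprintf("%s meridian profiles (%s): 4 meridians, ecc 0-%.2f mm (%d pts)\n",
              x$kind, x$unit, max(x$ecc_mm), length(x$ecc_mm)))
  invisible(x)
}

# gamma-shaped ring profile: 0 at r = 0, peak `peak` at r = r_peak,
# monotone decline beyond
ring_profile <- function(r, peak, r_peak, shape = 2) {
  s <- r / r_peak
  peak * s^shape * exp(shape * (1 - s))
}

#' Evaluate a sum-of-decaying-exponentials density profile
#'
#' `d(e) = sum_i A_i * exp(-e / tau_i)`, the functional form used for INL
#' component densities.
#'
#' @param ecc_mm Eccentricities (mm).
#' @param A Amplitudes (cells/mm^2).
#' @param tau Decay constants (mm), same length as `A`.
#' @return Densities (cells/mm^2).
#' @export
sum_exponentials <- function(ecc_mm, A, tau) {
  stopifnot(length(A) == length(tau), all(tau > 0))
  rowSums(matrix(vapply(seq_along(A),
                        function(i) A[i] * exp(-ecc_mm / tau[i]),
                        numeric(length(ecc_mm))),
                 nrow = length(ecc_mm)))
}

# default INL component sum-of-exponential parameters (cells/mm^2, mm);
# magnitudes chosen to give realistic central-human-retina totals
default_inl_components <- function() {
  list(
    amacrine_glycinergic = list(A = 6000,  tau = 2.0),
    amacrine_gabaergic   = list(A = 8000,  tau = 2.2),
    bipolar_off_midget   = list(A = 12000, tau = 1.2),
    bipolar_on           = list(A = 16000, tau = 1.5),
    bipolar_db3a         = list(A = 2500,  tau = 2.5),
    bipolar_db3b         = list(A = 2500,  tau = 2.5),
    horizontal           = list(A = 5000,  tau = 2.5),
    muller               = list(A = 14000, tau = 3.0))
}

#' Generate synthetic histological meridian profiles
#'
#' Emulates the shapes of published human retinal density data: ring-shaped
#' ganglion cell profiles (zero at the foveola, peak within 0.4-1 mm),
#' monotonically declining cone density peaking at the foveal center,
#' rod profiles that vanish inside a rod-free zone and peak at 1.2-1.7 mm,
#' sum-of-exponential INL component profiles (temporal meridian), and
#' smoothly increasing cone diameters. Real published tables in the same
#' CSV schema can be supplied to the downstream operations instead.
#'
#' @param kind One of `"GC"`, `"cone"`, `"rod"`, `"INL_components"`,
#'   `"cone_diameter"`.
#' @param ecc_max_mm,step_mm Eccentricity grid (starting at 0).
#' @param peak Peak density per meridian (recycled to 4; order T, N, S, I).
#' @param r_peak_mm Peak eccentricity (GC/rod kinds).
#' @param rod_free_radius_um Rod-free zone radius (um), in `[126, 200]`.
#' @param components Named list of `list(A =, tau =)` for
#'   `kind = "INL_components"`; see [sum_exponentials()].
#' @param diam_range_um Foveal and asymptotic cone diameters (um).
#' @return For `"INL_components"`, a list with `ecc_mm` and a named matrix
#'   `densities` of per-component temporal-meridian profiles; otherwise a
#'   [meridian_profile_set()].
#' @export
generate_meridian_profiles <- function(kind = c("GC", "cone", "rod",
                                                "INL_components",
                                                "cone_diameter"),
                                       ecc_max_mm = 5, step_mm = 0.005,
                                       peak = NULL, r_peak_mm = NULL,
                                       rod_free_radius_um = 150,
                                       components = default_inl_components(),
                                       diam_range_um = c(2.4, 9)) {
  kind <- match.arg(kind)
  r <- seq(0, ecc_max_mm, by = step_mm)
  if (kind == "GC") {
    if (is.null(peak)) peak <- c(T = 32000, N = 38000, S = 34000, I = 33000)
    if (is.null(r_peak_mm)) r_peak_mm <- 0.8
    peak <- rep_len(peak, 4)
    vals <- sapply(1:4, function(m) ring_profile(r, peak[m], r_peak_mm))
    return(meridian_profile_set(r, vals, "GC"))
  }
  if (kind == "cone") {
    if (is.null(peak)) peak <- 190000
    peak <- rep_len(peak, 4)
    # steep foveal falloff keeps cone coverage below full hexagonal tiling
    # when paired with the default diameter profile
    vals <- sapply(1:4, function(m)
      3000 + (peak[m] - 3000) * exp(-(r / 0.18)^0.9))
    return(meridian_profile_set(r, vals, "cone"))
  }
  if (kind == "rod") {
    stopifnot(rod_free_radius_um >= 126, rod_free_radius_um <= 200)
    if (is.null(peak)) peak <- 150000
    if (is.null(r_peak_mm)) r_peak_mm <- 1.5
    peak <- rep_len(peak, 4)
    r0 <- rod_free_radius_um / 1000
    s <- pmax((r - r0) / (r_peak_mm - r0), 0)
    vals <- sapply(1:4, function(m) peak[m] * s^2 * exp(2 * (1 - s)))
    return(meridian_profile_set(r, vals, "rod"))
  }
  if (kind == "cone_diameter") {
    w <- diam_range_um[1] +
      (diam_range_um[2] - diam_range_um[1]) * (1 - exp(-r / 1.2))
    return(meridian_profile_set(r, matrix(w, length(r), 4),
                                "cone_diameter", unit = "um"))
  }
  # INL components: temporal meridian only (the published form)
  dens <- vapply(components,
                 function(p) sum_exponentials(r, p$A, p$tau),
                 numeric(length(r)))
  if (any(dens < 0)) stop("negative component density")
  list(ecc_mm = r, densities = dens)
}

#' Write / read meridian profiles as CSV
#'
#' Long format: `meridian` (T/N/S/I), `eccentricity_mm`, and either
#' `density_cells_per_mm2` or `diameter_um`.
#'
#' @param x A `meridian_profile_set`.
#' @param path Output CSV path.
#' @return The path (write) or a `meridian_profile_set` (read).
#' @export
write_meridian_profiles <- function(x, path) {
  stopifnot(inherits(x, "meridian_profile_set"))
  valcol <- if (x$unit == "um") "diameter_um" else "density_cells_per_mm2"
  df <- data.frame(meridian = rep(colnames(x$values), each = length(x$ecc_mm)),
                   eccentricity_mm = rep(x$ecc_mm, 4),
                   value = as.vector(x$values))
  names(df)[3] <- valcol
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, eol = "\n")
  invisible(path)
}

#' @rdname write_meridian_profiles
#' @param kind Kind label for the reconstructed set.
#' @export
read_meridian_profiles <- function(path, kind = "GC") {
  df <- utils::read.csv(path)
  valcol <- intersect(c("density_cells_per_mm2", "diameter_um"), names(df))[1]
  ecc <- sort(unique(df$eccentricity_mm))
  vals <- sapply(c("T", "N", "S", "I"), function(m) {
    d <- df[df$meridian == m, ]
    d[[valcol]][order(d$eccentricity_mm)]
  })
  meridian_profile_set(ecc, vals, kind,
                       unit = if (valcol == "diameter_um") "um" else "cells/mm2")
}
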