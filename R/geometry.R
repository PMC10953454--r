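#' Scan geometry for a posterior-pole OCT volume
#'
#' Describes the physical layout of a raster OCT acquisition: number and
#' spacing of B-scans, pixel scales, overall field of view, the en face
#' position of the foveal center and the fovea-to-optic-disc axis angle.
#' Defaults follow a standard 61-line posterior-pole protocol
#' (61 B-scans spaced 120 um, 8600 um x 7167 um field, 3.87 um axial pixel).
#'
#' @param n_bscans Number of B-scans in the volume.
#' @param bscan_spacing_um Vertical spacing between adjacent B-scans (um).
#' @param lateral_px_um Lateral (within B-scan) pixel size (um). The default
#'   gives 768 A-scans over the 8600 um scan width.
#' @param axial_px_um Axial pixel size (um).
#' @param scan_width_um,scan_height_um En face extent of the volume (um).
#' @param fovea_xy_um Length-2 numeric, en face position of the foveal
#'   center relative to the scan center (um); `c(0, 0)` centers the fovea.
#' @param disc_fovea_angle_deg Angle of the fovea-to-disc axis relative to
#'   the horizontal (degrees); the extraction grid is rotated by this angle.
#' @return An object of class `scan_geometry`.
#' @export
scan_geometry <- function(n_bscans = 61L,
                          bscan_spacing_um = 120,
                          lateral_px_um = 8600 / 768,
                          axial_px_um = 3.87,
                          scan_width_um = 8600,
                          scan_height_um = 7167,
                          fovea_xy_um = c(0, 0),
                          disc_fovea_angle_deg = 0) {
  stopifnot(axial_px_um > 0, lateral_px_um > 0, n_bscans >= 1,
            bscan_spacing_um > 0, length(fovea_xy_um) == 2)
  if (abs(n_bscans * bscan_spacing_um - scan_height_um) > 2 * bscan_spacing_um)
    stop("n_bscans x bscan_spacing_um must cover scan_height_um (within one spacing)")
  g <- list(n_bscans = as.integer(n_bscans),
            bscan_spacing_um = bscan_spacing_um,
            lateral_px_um = lateral_px_um,
            axial_px_um = axial_px_um,
            scan_width_um = scan_width_um,
            scan_height_um = scan_height_um,
            n_ascans = as.integer(round(scan_width_um / lateral_px_um)),
            fovea_xy_um = as.numeric(fovea_xy_um),
            disc_fovea_angle_deg = disc_fovea_angle_deg)
  class(g) <- "scan_geometry"
  g
}

#' @export
print.scan_geometry <- function(x, ...) {
  cat(sprintf("OCT scan geometry: %d B-scans x %d A-scans, %g um spacing\n",
              x$n_bscans, x$n_ascans, x$bscan_spacing_um))
  cat(sprintf("  field %g x %g um; lateral px %.3f um; axial px %g um\n",
              x$scan_width_um, x$scan_height_um, x$lateral_px_um, x$axial_px_um))
  invisible(x)
}

# En face y position (um, + superior) of B-scan i (1 = superior-most)
bscan_y_um <- function(geometry, i) {
  (geometry$n_bscans - 1) / 2 * geometry$bscan_spacing_um -
    (i - 1) * geometry$bscan_spacing_um
}

# En face lateral position (um) of A-scan j within a B-scan, relative to the
# scan center. In the native frame of an OD eye this is the OD x axis
# (+ nasal); OS volumes are mirrored at extraction.
ascan_x_um <- function(geometry, j) {
  (j - (geometry$n_ascans + 1) / 2) * geometry$lateral_px_um
}

#' Macular grid constants
#'
#' The high-density extraction grid: `n` x `n` squares spanning
#' `extent_um` x `extent_um` centered on the fovea. The default 60 x 60 grid
#' over 6880 um gives squares of 114.67 um.
#'
#' @param n Squares per side.
#' @param extent_um Total grid side length (um).
#' @return List with `n`, `extent_um`, `square_um` and square-center
#'   coordinate vectors `x_centers_um` (temporal -> nasal, right-eye format)
#'   and `y_centers_um` (superior -> inferior, i.e. row 1 superior).
#' @export
macular_grid <- function(n = 60L, extent_um = 6880) {
  sq <- extent_um / n
  list(n = as.integer(n), extent_um = extent_um, square_um = sq,
       x_centers_um = -extent_um / 2 + (seq_len(n) - 0.5) * sq,
       y_centers_um = extent_um / 2 - (seq_len(n) - 0.5) * sq)
}

#' Sampling-density fold increase between square grids
#'
#' How many times denser an `grid_n` x `grid_n` sampling grid is than a
#' `reference_n` x `reference_n` grid over the same area: `(grid_n/reference_n)^2`.
#' A 60 x 60 grid is 56.25-fold denser than the standard 8 x 8 grid.
#'
#' @param grid_n,reference_n Squares per side of the two grids.
#' @return The fold increase in sampling density.
#' @export
sampling_density_fold <- function(grid_n, reference_n) {
  stopifnot(grid_n >= 1, reference_n >= 1)
  (grid_n / reference_n)^2
}
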