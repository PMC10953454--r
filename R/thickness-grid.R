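#' Construct a macular thickness grid
#'
#' A 60 x 60 (by default) field of layer thicknesses (um) in right-eye
#' format: row 1 is superior, column 1 temporal. Invalid squares (no valid
#' samples, artifact exclusions, low-quality B-scans) carry `NA` and
#' `valid = FALSE`.
#'
#' @param values_um Numeric `n x n` matrix of mean thicknesses (um).
#' @param layer One of `"GCL"`, `"INL"`, `"ISOS"`.
#' @param valid Logical matrix, same shape; defaults to `is.finite(values_um)`.
#' @param grid A [macular_grid()] description.
#' @return Object of class `thickness_grid`.
#' @export
thickness_grid <- function(values_um, layer = c("GCL", "INL", "ISOS"),
                           valid = NULL, grid = macular_grid()) {
  layer <- match.arg(layer)
  values_um <- as.matrix(values_um)
  stopifnot(nrow(values_um) == grid$n, ncol(values_um) == grid$n)
  if (is.null(valid)) valid <- is.finite(values_um)
  stopifnot(identical(dim(valid), dim(values_um)))
  values_um[!valid] <- NA_real_
  if (any(!is.finite(values_um[valid])))
    stop("thickness values must be finite wherever valid")
  structure(list(values_um = values_um, valid = valid, layer = layer,
                 eye_format = "OD", grid = grid),
            class = "thickness_grid")
}

#' @export
print.thickness_grid <- function(x, ...) {
  cat(sprintf("%s thickness grid (%dx%d, %.2f um squares, right-eye format)\n",
              x$layer, x$grid$n, x$grid$n, x$grid$square_um))
  cat(sprintf("  valid squares: %d/%d; mean %.2f um\n",
              sum(x$valid), length(x$valid),
              mean(x$values_um[x$valid])))
  invisible(x)
}

#' Mean thickness over the valid macular grid
#'
#' @param x A `thickness_grid`.
#' @return Mean of all valid squares (um).
#' @export
grid_mean <- function(x) {
  stopifnot(inherits(x, "thickness_grid"))
  mean(x$values_um[x$valid])
}

#' Write / read a thickness grid as CSV plus JSON sidecar
#'
#' The CSV holds the 60 x 60 value matrix (row 1 superior, column 1
#' temporal, right-eye format); the sidecar carries layer, eye format and
#' the validity mask (run-length encoded over the column-major mask).
#'
#' @param x A `thickness_grid`.
#' @param path CSV path; the sidecar is written at `<path>.json`.
#' @return `write_thickness_grid` returns `path` invisibly;
#'   `read_thickness_grid` returns a `thickness_grid`.
#' @export
write_thickness_grid <- function(x, path) {
  stopifnot(inherits(x, "thickness_grid"))
  utils::write.table(round(x$values_um, 6), path, sep = ",", na = "",
                     row.names = FALSE, col.names = FALSE, eol = "\n")
  r <- rle(as.logical(x$valid))
  meta <- list(layer = x$layer, eye_format = x$eye_format,
               n = x$grid$n, grid_extent_um = x$grid$extent_um,
               square_um = x$grid$square_um,
               valid_rle = list(lengths = r$lengths, values = r$values))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_thickness_grid
#' @param path CSV path written by `write_thickness_grid`.
#' @export
read_thickness_grid <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  vals <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
  dimnames(vals) <- NULL
  valid <- matrix(inverse.rle(list(lengths = meta$valid_rle$lengths,
                                   values = meta$valid_rle$values)),
                  nrow = meta$n)
  thickness_grid(vals, layer = meta$layer, valid = valid,
                 grid = macular_grid(meta$n, meta$grid_extent_um))
}
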