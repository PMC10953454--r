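# Shared fixtures, all generated in code.

# compact geometry for rendered-volume tests: full 61 B-scans but coarser
# lateral sampling keeps extraction fast without changing the physics
small_geometry <- function(...) {
  scan_geometry(lateral_px_um = 8600 / 160, ...)
}

# flat slab truth: constant thickness everywhere, no aging
slab_truth <- function(layer = "GCL", c_um = 30, tilt_deg = 0,
                       noise_sd_um = 0, ...) {
  ground_truth_model(layer, clusters = list(c(0, 0, c_um)),
                     noise_sd_um = noise_sd_um, between_sd_um = 0,
                     tilt_deg = tilt_deg, ...)
}

one_participant <- function(eye = "OD", age = 50) {
  data.frame(participant_id = "P0001", age_years = age, sex = "M",
             ethnicity = "White", refraction_D = 0, bcva_logmar = 0,
             eye = eye, stringsAsFactors = FALSE)
}

# three concentric aging regimes, well separated in thickness
three_ring_truth <- function(noise_sd_um = 2, between_sd_um = 0) {
  ground_truth_model(
    "GCL",
    clusters = list(c(-0.0010, 0.08, 19.80),
                    c(-0.0023, 0.18, 27.79),
                    c(-0.0034, 0.25, 37.88)),
    ring_radii_um = c(1200, 2400, 5000),
    noise_sd_um = noise_sd_um, between_sd_um = between_sd_um)
}

# synthetic slab boundary curves in pixel units, built directly (no
# renderer): an independent oracle for the tilt-correction geometry.
# Perpendicular thickness t_um, tilt theta => axial separation
# t_um / cos(theta).
slab_curves <- function(t_um, tilt_deg, geometry = scan_geometry(),
                        base_px = 400) {
  u <- (seq_len(geometry$n_ascans) - 1) * geometry$lateral_px_um
  th <- tilt_deg * pi / 180
  rpe <- base_px + tan(th) * u / geometry$axial_px_um
  inner <- rpe - (t_um / cos(th)) / geometry$axial_px_um
  list(inner = inner, outer = rpe, rpe = rpe)
}
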