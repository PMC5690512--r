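# Shared fixtures: a small fast phantom for integration-style tests and a
# minimal structure set for unit tests. Everything is built in code.

tiny_spec <- function(seed = 1L) {
  phantom_spec(grid_shape = c(32L, 32L), voxel_size_mm = 4,
               ptv_radius_mm = 12,
               oar_specs = list(list(name = "oar", shape = "circle",
                                     offset_mm = c(32, 0), size_mm = 8)),
               external_radius_mm = 55,
               beam_angles_deg = seq(0, 288, by = 72),
               beamlets_per_beam = 13L, beamlet_spacing_mm = 8,
               prescription_gy = 50, seed = seed)
}

# 16x16 grid, 2 mm voxels: external disc, small target, one OAR.
mini_set <- function() {
  gs <- c(16L, 16L); vox <- 2
  structure_set(gs, vox, list(
    make_structure("external", "external", circle_contour(c(16, 16), 14),
                   gs, vox),
    make_structure("ptv", "target", circle_contour(c(16, 16), 4), gs, vox),
    make_structure("oar", "oar", circle_contour(c(24, 16), 3), gs, vox)))
}

# brute-force order-statistics oracle for Dx (smallest dose received by
# the hottest x percent of the voxels)
oracle_dx <- function(doses, x) {
  n <- length(doses)
  k <- ceiling(n * x / 100)
  sort(doses)[n - k + 1]
}

# brute-force Vx oracle: percent of voxels with dose >= x
oracle_vx <- function(doses, x) 100 * mean(doses >= x)

seg_vec <- function(structure, fractions, doses) {
  structure(list(structure = structure, volume_fractions = fractions,
                 dose_gy = doses), class = "segment_vector")
}

# reference case built from a planning case's own converged plan
self_reference <- function(case, id = "self", supersample = 3L) {
  params <- default_plan_params(case$structures, case$prescription$dose_gy)
  fit <- optimize_fluence(params, case$influence, case$structures)
  dose <- compute_dose(fit$fluence, case$influence)
  sampler <- dvh_sampler(case$structures,
                         roles = c("target", "oar", "external"),
                         factor = supersample)
  reference_case(id = id, site = case$prescription$site,
                 structures = case$structures,
                 prescription = case$prescription, params = params,
                 dvh = sampler(dose), fluence = fit$fluence)
}
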