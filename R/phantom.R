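# Synthetic planning cases: a 2D slice phantom (external contour, one PTV,
# 1-3 OARs of controllable proximity), a pencil-beam dose-influence matrix,
# and reference libraries built by jittering the geometry and planning each
# jittered case to convergence. Everything downstream is testable on these
# without patient data.

#' Specify a synthetic phantom
#'
#' The phantom is a single 2D slice: a circular external (body) contour
#' centered on the grid, a circular PTV, and circular or elliptical OARs at
#' configurable offsets, so the PTV-OAR gap is controllable. Beam geometry
#' and the surrogate pencil-beam physics parameters live here too.
#'
#' @param grid_shape integer pair, at least 16 x 16 voxels.
#' @param voxel_size_mm voxel edge length (mm).
#' @param ptv_radius_mm PTV radius (mm).
#' @param ptv_center_offset_mm PTV center offset from the grid center (mm).
#' @param oar_specs list of OAR descriptors, each a list with \code{name},
#'   \code{shape} ("circle" or "ellipse"), \code{offset_mm} (length-2 center
#'   offset from the grid center), \code{size_mm} (radius, or semi-axes for
#'   an ellipse).
#' @param external_radius_mm body-contour radius (mm).
#' @param beam_angles_deg beam directions (degrees, counterclockwise from
#'   +x; the beam points from the source toward the isocenter).
#' @param beamlets_per_beam beamlets per beam (>= 1).
#' @param beamlet_spacing_mm beamlet spacing at the isocenter plane (mm).
#' @param attenuation_per_mm exponential depth-attenuation coefficient
#'   (1/mm); the default 0.005/mm mimics a 6 MV photon beam in water.
#' @param penumbra_sigma_mm lateral Gaussian penumbra sigma (mm).
#' @param source_distance_mm source-to-isocenter distance (mm); beamlet
#'   rays fan out from the source, giving a mildly divergent beam.
#' @param prescription_gy,fractions prescription dose and fractionation.
#' @param site anatomical-site label used by reference filtering.
#' @param seed integer seed; phantom generation is deterministic given it.
#' @return Object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(grid_shape = c(64L, 64L), voxel_size_mm = 2.5,
                         ptv_radius_mm = 15, ptv_center_offset_mm = c(0, 0),
                         oar_specs = default_oar_specs(),
                         external_radius_mm = 70,
                         beam_angles_deg = seq(0, 320, by = 40),
                         beamlets_per_beam = 15L, beamlet_spacing_mm = 5,
                         attenuation_per_mm = 0.005, penumbra_sigma_mm = 4,
                         source_distance_mm = 1000,
                         prescription_gy = 50, fractions = 25L,
                         site = "phantom", seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (any(grid_shape < 16L)) stop("grid_shape must be at least 16 x 16")
  if (voxel_size_mm <= 0) stop("voxel_size_mm must be positive")
  if (ptv_radius_mm <= 0) stop("ptv_radius_mm must be positive")
  if (beamlets_per_beam < 1L) stop("beamlets_per_beam must be >= 1")
  if (!length(beam_angles_deg)) stop("at least one beam angle required")
  if (prescription_gy <= 0) stop("prescription must be positive")
  structure(list(grid_shape = grid_shape, voxel_size_mm = voxel_size_mm,
                 ptv_radius_mm = ptv_radius_mm,
                 ptv_center_offset_mm = ptv_center_offset_mm,
                 oar_specs = oar_specs,
                 external_radius_mm = external_radius_mm,
                 beam_angles_deg = beam_angles_deg,
                 beamlets_per_beam = as.integer(beamlets_per_beam),
                 beamlet_spacing_mm = beamlet_spacing_mm,
                 attenuation_per_mm = attenuation_per_mm,
                 penumbra_sigma_mm = penumbra_sigma_mm,
                 source_distance_mm = source_distance_mm,
                 prescription_gy = prescription_gy,
                 fractions = as.integer(fractions),
                 site = site, seed = as.integer(seed)),
            class = "phantom_spec")
}

#' Default OAR layout: two circular OARs near the PTV
#' @return List of OAR descriptors (see [phantom_spec()]).
#' @export
default_oar_specs <- function() {
  list(list(name = "oar_a", shape = "circle", offset_mm = c(40, 0),
            size_mm = 10),
       list(name = "oar_b", shape = "circle", offset_mm = c(-36, 26),
            size_mm = 12))
}

grid_center_mm <- function(spec)
  spec$grid_shape * spec$voxel_size_mm / 2

oar_contour <- function(os, center) {
  switch(os$shape,
    circle  = circle_contour(center, os$size_mm),
    ellipse = ellipse_contour(center, os$size_mm),
    stop("unknown OAR shape '", os$shape, "'"))
}

# Build the structure set for a spec, with optional per-structure
# perturbations (named list: center_shift_mm, radius_shift_mm).
build_structures <- function(spec, perturb = NULL) {
  ctr <- grid_center_mm(spec)
  shift <- function(nm) {
    p <- perturb[[nm]]
    if (is.null(p)) list(center = c(0, 0), radius = 0) else p
  }
  p <- shift("ptv")
  ptv_ctr <- ctr + spec$ptv_center_offset_mm + p$center
  ptv_r <- spec$ptv_radius_mm + p$radius
  sl <- list(
    make_structure("external", "external",
                   circle_contour(ctr, spec$external_radius_mm),
                   spec$grid_shape, spec$voxel_size_mm),
    make_structure("ptv", "target", circle_contour(ptv_ctr, ptv_r),
                   spec$grid_shape, spec$voxel_size_mm))
  for (os in spec$oar_specs) {
    po <- shift(os$name)
    os2 <- os
    os2$size_mm <- os$size_mm + po$radius
    octr <- ctr + os$offset_mm + po$center
    sl[[length(sl) + 1L]] <-
      make_structure(os$name, "oar", oar_contour(os2, octr),
                     spec$grid_shape, spec$voxel_size_mm)
    # geometric sanity: inside the body, clear of the target
    if (sqrt(sum((octr - ctr)^2)) + max(os2$size_mm) >=
        spec$external_radius_mm)
      stop("geometry error: OAR '", os$name,
           "' extends outside the external contour")
    if (sqrt(sum((octr - ptv_ctr)^2)) <= ptv_r + max(os2$size_mm))
      stop("degenerate geometry: OAR '", os$name, "' overlaps the PTV")
  }
  structure_set(spec$grid_shape, spec$voxel_size_mm, sl)
}

#' Generate a synthetic planning case
#'
#' Builds the structure set, the pencil-beam dose-influence matrix, and the
#' prescription for a phantom spec. Deterministic for a fixed spec.
#'
#' The influence model is a divergent pencil beam: each beamlet ray fans
#' out from a point source through its isocenter-plane position; the dose a
#' beamlet deposits at a voxel is exp(-mu * depth) * exp(-lateral^2 /
#' (2 sigma^2)), with depth measured from the ray's entry into the external
#' contour and lateral the perpendicular distance to the ray. The matrix is
#' scaled so unit fluence on all beamlets gives a mean PTV dose equal to
#' the prescription.
#'
#' @param spec a \code{phantom_spec}.
#' @param perturb optional named list of per-structure perturbations, each
#'   a list with \code{center} (length-2 shift, mm) and \code{radius}
#'   (radius change, mm); used by [generate_reference_library()].
#' @return List with \code{structures} (a \code{structure_set}),
#'   \code{influence} (matrix, n_voxels x n_beamlets, with a
#'   \code{grid_shape} attribute), and \code{prescription} (list with
#'   \code{dose_gy}, \code{fractions}, \code{site}).
#' @export
generate_phantom <- function(spec, perturb = NULL) {
  stopifnot(inherits(spec, "phantom_spec"))
  ss <- build_structures(spec, perturb)
  D <- influence_matrix(spec)
  # calibrate against the nominal (unperturbed) PTV disc so the dose
  # scale does not depend on contour jitter
  ctr <- grid_center_mm(spec) + spec$ptv_center_offset_mm
  pts <- voxel_centers(spec$grid_shape, spec$voxel_size_mm)
  ptv <- (pts[, 1] - ctr[1])^2 + (pts[, 2] - ctr[2])^2 <=
    spec$ptv_radius_mm^2
  mean_ptv <- mean((D %*% rep(1, ncol(D)))[ptv])
  D <- D * (spec$prescription_gy / mean_ptv)
  attr(D, "grid_shape") <- spec$grid_shape
  list(structures = ss, influence = D,
       prescription = list(dose_gy = spec$prescription_gy,
                           fractions = spec$fractions, site = spec$site))
}

# Raw (unscaled) pencil-beam influence matrix.
influence_matrix <- function(spec) {
  ctr <- grid_center_mm(spec)
  pts <- voxel_centers(spec$grid_shape, spec$voxel_size_mm)
  n_vox <- nrow(pts)
  K <- spec$beamlets_per_beam
  offs <- spec$beamlet_spacing_mm * (seq_len(K) - (K + 1) / 2)
  cols <- vector("list", length(spec$beam_angles_deg) * K)
  ci <- 0L
  for (ang in spec$beam_angles_deg) {
    th <- ang * pi / 180
    u <- c(cos(th), sin(th))          # beam direction, source -> isocenter
    perp <- c(-u[2], u[1])
    src <- ctr - spec$source_distance_mm * u
    for (k in seq_len(K)) {
      q <- ctr + offs[k] * perp       # beamlet position at isocenter
      v <- q - src; v <- v / sqrt(sum(v^2))
      rel <- cbind(pts[, 1] - src[1], pts[, 2] - src[2])
      t_along <- rel %*% v
      lat2 <- (rel[, 1] - t_along * v[1])^2 + (rel[, 2] - t_along * v[2])^2
      # entry of this ray into the external circle
      oc <- src - ctr
      b <- sum(oc * v); cc <- sum(oc^2) - spec$external_radius_mm^2
      disc <- b * b - cc
      col <- numeric(n_vox)
      if (disc > 0) {
        t_entry <- -b - sqrt(disc)
        depth <- t_along - t_entry
        hit <- depth >= 0
        col[hit] <- exp(-spec$attenuation_per_mm * depth[hit]) *
          exp(-lat2[hit] / (2 * spec$penumbra_sigma_mm^2))
      }
      ci <- ci + 1L
      cols[[ci]] <- col
    }
  }
  D <- do.call(cbind, cols)
  if (any(colSums(D) == 0))
    stop("influence matrix has an empty beamlet column; widen the beam ",
         "or enlarge the external contour")
  D
}

#' Generate a library of reference cases
#'
#' Each case is the base phantom with its PTV and OAR contours perturbed by
#' at most \code{jitter_mm} (random center shift plus radius change, split
#' so the total boundary displacement cannot exceed the bound) and then
#' planned to convergence with the default plan parameters, so every
#' reference DVH is achievable on its own geometry.
#'
#' @param base_spec a \code{phantom_spec}.
#' @param n_cases number of cases (>= 1).
#' @param jitter_mm maximal contour perturbation (mm, >= 0).
#' @param seed integer seed; the library is reproducible given it.
#' @param dvh_supersample DVH supersampling factor used when tabulating
#'   the reference DVHs (default 3, matching [autopilot_config()]).
#' @param inner_control control list passed to [optimize_fluence()].
#' @return List of \code{reference_case} objects.
#' @export
generate_reference_library <- function(base_spec, n_cases, jitter_mm,
                                       seed = base_spec$seed,
                                       dvh_supersample = 3L,
                                       inner_control = list()) {
  stopifnot(n_cases >= 1, jitter_mm >= 0)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  lapply(seq_len(n_cases), function(i) {
    nm <- c("ptv", vapply(base_spec$oar_specs, `[[`, "", "name"))
    perturb <- lapply(nm, function(s) {
      a <- stats::runif(1, 0, 2 * pi)
      m <- stats::runif(1, 0, jitter_mm / 2)
      list(center = m * c(cos(a), sin(a)),
           radius = stats::runif(1, -jitter_mm / 2, jitter_mm / 2))
    })
    names(perturb) <- nm
    case <- generate_phantom(base_spec, perturb)
    params <- default_plan_params(case$structures,
                                  case$prescription$dose_gy)
    fit <- optimize_fluence(params, case$influence, case$structures,
                            control = inner_control)
    dose <- compute_dose(fit$fluence, case$influence)
    sampler <- dvh_sampler(case$structures,
                           roles = c("target", "oar", "external"),
                           factor = dvh_supersample)
    reference_case(
      id = sprintf("ref%03d", i), site = base_spec$site,
      structures = case$structures, prescription = case$prescription,
      params = params, dvh = sampler(dose), fluence = fit$fluence)
  })
}

# Preserve the caller's RNG state around library generation.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Construct a reference case
#'
#' A previously planned case: structure set, prescription, the plan
#' parameters that produced it, its per-structure DVH curves, and
#' optionally the beamlet fluence.
#'
#' @param id case identifier.
#' @param site anatomical-site label.
#' @param structures a \code{structure_set}.
#' @param prescription list with \code{dose_gy} (> 0) and \code{fractions}.
#' @param params a \code{plan_params}.
#' @param dvh named list of \code{dvh_curve}s; names must be a subset of
#'   the structure names.
#' @param fluence optional fluence vector.
#' @return Object of class \code{reference_case}.
#' @export
reference_case <- function(id, site, structures, prescription, params, dvh,
                           fluence = NULL) {
  stopifnot(inherits(structures, "structure_set"))
  if (!is.numeric(prescription$dose_gy) || prescription$dose_gy <= 0)
    stop("reference prescription dose must be positive")
  if (!all(names(dvh) %in% names(structures$structures)))
    stop("reference DVH names must be a subset of its structure names")
  structure(list(id = id, site = site, structures = structures,
                 prescription = prescription, params = params, dvh = dvh,
                 fluence = fluence),
            class = "reference_case")
}

#' @export
print.reference_case <- function(x, ...) {
  cat(sprintf("reference_case '%s' (%s): %.1f Gy / %d fx, %d structures\n",
              x$id, x$site, x$prescription$dose_gy, x$prescription$fractions,
              length(x$structures$structures)))
  invisible(x)
}
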