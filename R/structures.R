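# Structure sets: named voxel masks + polygon contours on a shared grid,
# with roles target / oar / external, plus the planning geometry actions
# (Boolean combinations, isodose conversion, center of mass).

#' Construct a structure set
#'
#' A structure set holds every segmented structure of a planning case on a
#' common 2D voxel grid. Each structure carries a boolean mask, a closed
#' polygon contour (mm), and a role. Exactly one structure must have role
#' \code{"external"} (the body/skin outline); every other mask must lie
#' inside it and at least one structure must be a target.
#'
#' @param grid_shape integer pair, grid dimension in voxels (>= 16 each).
#' @param voxel_size_mm positive voxel edge length (mm).
#' @param structures list of structures as returned by [make_structure()].
#' @return An object of class \code{structure_set}.
#' @export
structure_set <- function(grid_shape, voxel_size_mm, structures) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 2L, all(grid_shape >= 16L),
            voxel_size_mm > 0, length(structures) >= 2L)
  nm <- vapply(structures, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("structure names must be unique")
  names(structures) <- nm
  roles <- vapply(structures, `[[`, "", "role")
  if (sum(roles == "external") != 1L)
    stop("exactly one structure must have role 'external'")
  if (!any(roles == "target")) stop("at least one target structure required")
  ext <- structures[[which(roles == "external")]]$mask
  for (s in structures) {
    if (!identical(dim(s$mask), grid_shape))
      stop("mask of '", s$name, "' is not on the shared grid")
    if (s$role == "target" && !any(s$mask))
      stop("target mask of '", s$name, "' is empty")
    if (any(s$mask & !ext))
      stop("structure '", s$name, "' extends outside the external contour")
  }
  structure(list(grid_shape = grid_shape, voxel_size_mm = voxel_size_mm,
                 structures = structures),
            class = "structure_set")
}

#' Build a single structure from a contour
#'
#' The mask is rasterized from the contour so that mask and contour are
#' consistent by construction on the generating grid.
#'
#' @param name structure name.
#' @param role one of \code{"target"}, \code{"oar"}, \code{"external"}.
#' @param contour closed polygon, x,y vertices in mm.
#' @param grid_shape,voxel_size_mm grid the mask is rasterized on.
#' @return A list with fields \code{name}, \code{role}, \code{mask},
#'   \code{contour}.
#' @export
make_structure <- function(name, role, contour, grid_shape, voxel_size_mm) {
  role <- match.arg(role, c("target", "oar", "external"))
  contour <- close_polygon(as.matrix(contour))
  mask <- rasterize_contour(contour, grid_shape, voxel_size_mm)
  list(name = name, role = role, mask = mask, contour = contour)
}

#' @export
print.structure_set <- function(x, ...) {
  cat(sprintf("structure_set: %d x %d grid, %.3g mm voxels\n",
              x$grid_shape[1], x$grid_shape[2], x$voxel_size_mm))
  for (s in x$structures)
    cat(sprintf("  %-12s %-8s %5d voxels\n", s$name, s$role, sum(s$mask)))
  invisible(x)
}

#' Boolean combination of two structure masks
#'
#' Set algebra on voxel masks, mirroring the planning-system structure
#' operations \code{and}, \code{or}, \code{xor}, \code{sub} and \code{not}.
#' \code{not} ignores \code{b} and complements \code{a} within the external
#' mask: clinical structures are anatomy-bounded, so the complement of a
#' structure is "everything else inside the patient", not the whole grid.
#' Every result is clipped to the external mask.
#'
#' @param a,b logical mask matrices on the same grid.
#' @param op one of \code{"and"}, \code{"or"}, \code{"xor"}, \code{"sub"},
#'   \code{"not"}.
#' @param external external-contour mask defining the anatomy bound.
#' @return Logical mask matrix.
#' @export
boolean_structure <- function(a, b = NULL, op, external) {
  op <- as.character(op)
  if (!op %in% c("and", "or", "xor", "sub", "not"))
    stop("unknown Boolean op '", op, "'")
  if (!identical(dim(a), dim(external)))
    stop("mask and external grid shapes differ")
  if (op != "not") {
    if (is.null(b)) stop("op '", op, "' needs two masks")
    if (!identical(dim(a), dim(b))) stop("mask grid shapes differ")
  }
  out <- switch(op,
    and = a & b,
    or  = a | b,
    xor = xor(a, b),
    sub = a & !b,
    not = !a)
  out & external
}

#' Convert an isodose level to a structure mask
#'
#' Returns the mask of voxels receiving at least \code{level_gy}; the
#' threshold is inclusive (dose >= level).
#'
#' @param dose dose matrix (Gy) on the structure grid.
#' @param level_gy positive dose level (Gy).
#' @return Logical mask matrix.
#' @export
isodose_to_structure <- function(dose, level_gy) {
  if (!is.numeric(level_gy) || length(level_gy) != 1L || level_gy <= 0)
    stop("isodose level must be a positive dose in Gy")
  dose >= level_gy
}

#' Center of mass of a structure mask
#'
#' Unweighted centroid of the voxel centers, in physical mm.
#'
#' @param mask nonempty logical mask matrix.
#' @param voxel_size_mm voxel edge length (mm).
#' @return Length-2 numeric, (x_mm, y_mm).
#' @export
center_of_mass <- function(mask, voxel_size_mm) {
  if (!any(mask)) stop("center of mass of an empty mask is undefined")
  idx <- which(mask, arr.ind = TRUE)
  c(mean((idx[, 1] - 0.5) * voxel_size_mm),
    mean((idx[, 2] - 0.5) * voxel_size_mm))
}

# Accessors used throughout the package.
get_structure <- function(ss, name) {
  s <- ss$structures[[name]]
  if (is.null(s)) stop("structure '", name, "' not found in structure set")
  s
}

external_mask <- function(ss) {
  roles <- vapply(ss$structures, `[[`, "", "role")
  ss$structures[[which(roles == "external")]]$mask
}

structure_names <- function(ss, roles = c("target", "oar", "external")) {
  keep <- vapply(ss$structures, function(s) s$role %in% roles, TRUE)
  names(ss$structures)[keep]
}

#' Physical volume of a structure in cc
#'
#' 2D phantoms are a single slice; the volume assigns each voxel an
#' implicit slice thickness of one voxel edge, so a mask of n voxels has
#' volume n * voxel_size^3 / 1000 cc.
#'
#' @param ss a \code{structure_set}.
#' @param name structure name.
#' @return Volume in cc.
#' @export
structure_volume_cc <- function(ss, name) {
  s <- get_structure(ss, name)
  sum(s$mask) * ss$voxel_size_mm^3 / 1000
}
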