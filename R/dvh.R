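# Cumulative DVH computation, Vx/Dx statistics, and the fixed
# volume-fraction segment discretization the autopilot's constraint check
# consumes. Convention: cumulative DVH with the ">= dose" rule, the
# universal clinical one — V(d) is the percent volume receiving at least d.

#' Compute a cumulative DVH for one structure
#'
#' The curve is tabulated on a uniform dose grid from 0 to just past the
#' maximum voxel dose. Bin width is capped at 0.001 Gy by default (the
#' maximal export resolution); header statistics Dmin, Dmax, Dmean come
#' from the raw voxel doses, not from the binned curve, mirroring the dual
#' header/table representation of clinical DVH exports.
#'
#' @param dose dose matrix or vector (Gy).
#' @param mask nonempty logical mask selecting the structure's voxels.
#' @param resolution_gy dose bin width (Gy), 0 < resolution <= cap.
#' @param resolution_cap_gy maximal allowed bin width (default 0.001 Gy).
#' @param structure structure name stored on the curve.
#' @return Object of class \code{dvh_curve}: fields \code{structure},
#'   \code{dose_gy}, \code{volume_pct}, \code{dmin}, \code{dmax},
#'   \code{dmean}, \code{resolution_gy}.
#' @export
compute_dvh <- function(dose, mask, resolution_gy = 0.001,
                        resolution_cap_gy = 0.001, structure = "structure") {
  if (!any(mask)) stop("cannot compute a DVH for an empty mask")
  if (resolution_gy <= 0 || resolution_gy > resolution_cap_gy)
    stop("resolution_gy must be in (0, ", resolution_cap_gy, "] Gy")
  dv <- as.vector(dose)[as.vector(mask)]
  if (any(dv < 0)) stop("negative voxel doses")
  n <- length(dv)
  sv <- sort(dv)
  dmax <- sv[n]
  bins <- seq(0, dmax + resolution_gy, by = resolution_gy)
  # voxels with dose >= b  =  n - #(dose < b); findInterval with
  # left.open counts strict inequalities on the sorted doses.
  n_lt <- findInterval(bins, sv, left.open = TRUE)
  vol <- 100 * (n - n_lt) / n
  structure(list(structure = structure, dose_gy = bins, volume_pct = vol,
                 dmin = sv[1], dmax = dmax, dmean = mean(dv),
                 resolution_gy = resolution_gy),
            class = "dvh_curve")
}

#' @export
print.dvh_curve <- function(x, ...) {
  cat(sprintf(
    "dvh_curve '%s': %d bins at %.4g Gy, Dmin %.3f / Dmean %.3f / Dmax %.3f Gy\n",
    x$structure, length(x$dose_gy), x$resolution_gy, x$dmin, x$dmean, x$dmax))
  invisible(x)
}

#' DVH dose-volume statistics Vx and Dx
#'
#' \code{Vx}: percent of the structure volume receiving at least
#' \code{value} Gy (linear interpolation between bins). \code{Dx}: the
#' smallest dose received by the hottest \code{value}\% of the volume,
#' obtained by inverse interpolation of the cumulative curve; D100 equals
#' Dmin.
#'
#' @param curve a \code{dvh_curve}.
#' @param kind \code{"Vx"} or \code{"Dx"}.
#' @param value dose in Gy for Vx (within the curve's dose range), volume
#'   percent in (0, 100] for Dx.
#' @return The statistic as a single number (percent for Vx, Gy for Dx).
#' @export
dvh_statistic <- function(curve, kind = c("Vx", "Dx"), value) {
  kind <- match.arg(kind)
  d <- curve$dose_gy; v <- curve$volume_pct
  if (kind == "Vx") {
    if (value < 0) stop("Vx dose must be nonnegative")
    if (value > d[length(d)]) return(0)
    stats::approx(d, v, xout = value, rule = 2)$y
  } else {
    if (value <= 0 || value > 100)
      stop("Dx volume fraction must be in (0, 100]")
    invert_dvh(d, v, value)
  }
}

# Dose at which the cumulative curve crosses volume percent `x`.
# The curve is nonincreasing with plateaus; take the last bin still at or
# above x and interpolate into the next one.
invert_dvh <- function(dose, vol, x) {
  i <- max(which(vol >= x))
  if (i == length(vol) || vol[i] == x) return(dose[i])
  # vol[i] > x > vol[i+1]
  dose[i] + (vol[i] - x) / (vol[i] - vol[i + 1]) * (dose[i + 1] - dose[i])
}

#' Sample DVH segment doses at fixed volume fractions
#'
#' Operationalizes the "DVH segment": the dose of segment j is the Dx
#' statistic at the j-th volume-fraction control point. With control points
#' ordered by increasing volume fraction the segment doses are
#' nonincreasing. Defaults place 20 segments evenly from 2.5\% to 97.5\%.
#'
#' @param curve a \code{dvh_curve}.
#' @param volume_fractions strictly increasing percentages in (0, 100).
#' @return Object of class \code{segment_vector}: \code{structure},
#'   \code{volume_fractions}, \code{dose_gy}.
#' @export
sample_segments <- function(curve,
                            volume_fractions = default_segment_fractions()) {
  if (!length(volume_fractions)) stop("empty volume-fraction list")
  if (any(diff(volume_fractions) <= 0) ||
      any(volume_fractions <= 0 | volume_fractions >= 100))
    stop("volume fractions must be strictly increasing within (0, 100)")
  d <- vapply(volume_fractions,
              function(x) dvh_statistic(curve, "Dx", x), 0)
  structure(list(structure = curve$structure,
                 volume_fractions = volume_fractions, dose_gy = d),
            class = "segment_vector")
}

#' Default DVH segment control points
#'
#' 20 volume fractions evenly spaced from 2.5\% to 97.5\%.
#' @return Numeric vector of percentages.
#' @export
default_segment_fractions <- function() seq(2.5, 97.5, by = 5)

#' Write / read DVH curves in the per-structure tabular dialect
#'
#' One block per structure: header lines \code{Structure:}, \code{Dmin:},
#' \code{Dmax:}, \code{Dmean:} (Gy), then the line \code{dose_gy,volume_pct}
#' and a two-column comma-separated table of the binned curve. Blocks are
#' separated by a blank line. The round trip is lossless at the stored
#' resolution.
#'
#' @param curves list of \code{dvh_curve} objects with unique names.
#' @param path file path.
#' @return \code{write_dvh_file}: the path, invisibly.
#' @export
write_dvh_file <- function(curves, path) {
  if (inherits(curves, "dvh_curve")) curves <- list(curves)
  nm <- vapply(curves, `[[`, "", "structure")
  if (anyDuplicated(nm)) stop("duplicate structure names in DVH file")
  con <- file(path, "w")
  on.exit(close(con))
  for (cv in curves) {
    writeLines(c(paste("Structure:", cv$structure),
                 sprintf("Dmin: %.9g", cv$dmin),
                 sprintf("Dmax: %.9g", cv$dmax),
                 sprintf("Dmean: %.9g", cv$dmean),
                 "dose_gy,volume_pct",
                 sprintf("%.9g,%.9g", cv$dose_gy, cv$volume_pct),
                 ""), con)
  }
  invisible(path)
}

#' @rdname write_dvh_file
#' @return \code{read_dvh_file}: a named list of \code{dvh_curve} objects.
#' @export
read_dvh_file <- function(path) {
  lines <- readLines(path)
  curves <- list()
  i <- 1L
  n <- length(lines)
  header_num <- function(line, key, lineno) {
    if (!startsWith(line, paste0(key, ":")))
      stop("DVH parse error at line ", lineno, ": expected '", key,
           ":' header, got '", line, "'")
    val <- suppressWarnings(as.numeric(sub(paste0("^", key, ":\\s*"), "", line)))
    if (is.na(val))
      stop("DVH parse error at line ", lineno, ": non-numeric ", key)
    val
  }
  while (i <= n) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    if (!startsWith(lines[i], "Structure:"))
      stop("DVH parse error at line ", i, ": expected 'Structure:' header")
    name <- trimws(sub("^Structure:\\s*", "", lines[i]))
    if (name %in% names(curves))
      stop("DVH parse error at line ", i, ": duplicate structure '", name, "'")
    if (i + 4L > n) stop("DVH parse error at line ", i, ": truncated block")
    dmin <- header_num(lines[i + 1L], "Dmin", i + 1L)
    dmax <- header_num(lines[i + 2L], "Dmax", i + 2L)
    dmean <- header_num(lines[i + 3L], "Dmean", i + 3L)
    if (trimws(lines[i + 4L]) != "dose_gy,volume_pct")
      stop("DVH parse error at line ", i + 4L,
           ": expected column header 'dose_gy,volume_pct'")
    j <- i + 5L
    while (j <= n && nzchar(trimws(lines[j]))) j <- j + 1L
    if (j == i + 5L)
      stop("DVH parse error at line ", j, ": empty DVH table for '", name, "'")
    tab <- utils::read.csv(text = lines[(i + 5L):(j - 1L)], header = FALSE,
                           col.names = c("dose_gy", "volume_pct"))
    if (anyNA(tab))
      stop("DVH parse error near line ", i + 5L, ": non-numeric table entry")
    res <- if (nrow(tab) > 1L) tab$dose_gy[2] - tab$dose_gy[1] else 0.001
    curves[[name]] <- structure(
      list(structure = name, dose_gy = tab$dose_gy,
           volume_pct = tab$volume_pct, dmin = dmin, dmax = dmax,
           dmean = dmean, resolution_gy = res),
      class = "dvh_curve")
    i <- j
  }
  if (!length(curves)) stop("DVH parse error: no structure blocks in ", path)
  curves
}

# DVH curves for every structure of a case (internal helper).
dvh_for_set <- function(dose, ss, roles = c("target", "oar", "external"),
                        resolution_gy = 0.001) {
  nm <- structure_names(ss, roles)
  out <- lapply(nm, function(s)
    compute_dvh(dose, get_structure(ss, s)$mask,
                resolution_gy = resolution_gy, structure = s))
  names(out) <- nm
  out
}

#' Build a (optionally supersampled) DVH evaluator for a structure set
#'
#' Returns a function mapping a dose grid to the per-structure DVH curves.
#' With \code{factor > 1} the dose is bilinearly interpolated onto a
#' \code{factor}-times finer grid and the contours re-rasterized there
#' before the cumulative DVH is taken; this partial-volume refinement
#' reduces the voxelization noise that coarse planning grids imprint on
#' DVH quantiles. Fine masks and interpolation weights are precomputed, so
#' repeated evaluation inside the planning loop is cheap.
#'
#' @param ss a \code{structure_set}.
#' @param roles structure roles to include.
#' @param factor integer supersampling factor (1 = evaluate on the native
#'   grid).
#' @param resolution_gy DVH bin width (Gy).
#' @return A function \code{f(dose)} returning a named list of
#'   \code{dvh_curve}s.
#' @export
dvh_sampler <- function(ss, roles = c("target", "oar"), factor = 3L,
                        resolution_gy = 0.001) {
  factor <- as.integer(factor)
  stopifnot(factor >= 1L)
  nm <- structure_names(ss, roles)
  if (factor == 1L)
    return(function(dose) dvh_for_set(dose, ss, roles = roles,
                                      resolution_gy = resolution_gy))
  gs <- ss$grid_shape
  vox <- ss$voxel_size_mm
  nf <- gs * factor
  vf <- vox / factor
  xc <- (seq_len(gs[1]) - 0.5) * vox
  yc <- (seq_len(gs[2]) - 0.5) * vox
  xf <- (seq_len(nf[1]) - 0.5) * vf
  yf <- (seq_len(nf[2]) - 0.5) * vf
  ix <- pmin(pmax(findInterval(xf, xc), 1L), gs[1] - 1L)
  iy <- pmin(pmax(findInterval(yf, yc), 1L), gs[2] - 1L)
  tx <- pmin(pmax((xf - xc[ix]) / vox, 0), 1)
  ty <- pmin(pmax((yf - yc[iy]) / vox, 0), 1)
  TX <- matrix(tx, nf[1], nf[2])
  TY <- matrix(ty, nf[1], nf[2], byrow = TRUE)
  masks <- lapply(nm, function(s)
    rasterize_contour(get_structure(ss, s)$contour, nf, vf))
  names(masks) <- nm
  function(dose) {
    d11 <- dose[ix, iy]; d21 <- dose[ix + 1L, iy]
    d12 <- dose[ix, iy + 1L]; d22 <- dose[ix + 1L, iy + 1L]
    df <- d11 * (1 - TX) * (1 - TY) + d21 * TX * (1 - TY) +
      d12 * (1 - TX) * TY + d22 * TX * TY
    out <- lapply(nm, function(s)
      compute_dvh(df, masks[[s]], resolution_gy = resolution_gy,
                  structure = s))
    names(out) <- nm
    out
  }
}
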