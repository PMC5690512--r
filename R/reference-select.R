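# Knowledge-based reference-plan retrieval: candidate filtering by site,
# target volume, structure names and prescription; the signed radial
# contour-difference metric; and threshold-based accept/reject selection.

#' Signed radial contour difference between two cases for one structure
#'
#' A polar coordinate system is placed at the structure's center of mass in
#' each case separately (the polygon area centroid, so the metric is
#' invariant under rigid translation of either case). Rays are cast at a
#' fixed angular resolution; at every angle the boundary-crossing radii of
#' the two contours are matched by sorted index and the signed difference
#' of each matched pair is the reference radius minus the current radius —
#' positive where the reference structure extends farther out. Angles where
#' the two contours have different crossing counts are flagged as
#' mismatches and treated as exceeding any threshold.
#'
#' @param current,reference \code{structure_set}s containing the structure.
#' @param structure structure name, present in both sets.
#' @param angle_resolution_deg angular resolution in degrees; must divide
#'   360 evenly (default 2.5, i.e. 144 rays).
#' @return List of class \code{signed_difference}: \code{structure},
#'   \code{points} (data.frame: angle_deg, intercept_index,
#'   signed_diff_mm), \code{max_abs_mm}, \code{rms_mm},
#'   \code{n_mismatched_angles}.
#' @export
signed_difference <- function(current, reference, structure,
                              angle_resolution_deg = 2.5) {
  if (360 %% angle_resolution_deg != 0)
    stop("angle resolution must divide 360 evenly")
  cur <- get_structure(current, structure)
  ref <- get_structure(reference, structure)
  angles <- seq(0, 360 - angle_resolution_deg, by = angle_resolution_deg)
  o_cur <- polygon_centroid(cur$contour)$centroid_mm
  o_ref <- polygon_centroid(ref$contour)$centroid_mm
  all_cur <- ray_intercepts_multi(cur$contour, o_cur, angles)
  all_ref <- ray_intercepts_multi(ref$contour, o_ref, angles)
  rows <- vector("list", length(angles))
  mism <- 0L
  for (i in seq_along(angles)) {
    r_cur <- all_cur[[i]]
    r_ref <- all_ref[[i]]
    if (length(r_cur) != length(r_ref)) {
      mism <- mism + 1L
      rows[[i]] <- data.frame(angle_deg = angles[i], intercept_index = NA_integer_,
                              signed_diff_mm = NA_real_)
    } else if (length(r_cur)) {
      rows[[i]] <- data.frame(angle_deg = angles[i],
                              intercept_index = seq_along(r_cur),
                              signed_diff_mm = r_ref - r_cur)
    }
  }
  pts <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  sd_ok <- pts$signed_diff_mm[!is.na(pts$signed_diff_mm)]
  structure(list(structure = structure, points = pts,
                 max_abs_mm = if (length(sd_ok)) max(abs(sd_ok)) else 0,
                 rms_mm = if (length(sd_ok)) sqrt(mean(sd_ok^2)) else 0,
                 n_mismatched_angles = mism),
            class = "signed_difference")
}

#' @export
print.signed_difference <- function(x, ...) {
  cat(sprintf(
    "signed_difference '%s': max |diff| %.3f mm, rms %.3f mm, %d mismatched angles\n",
    x$structure, x$max_abs_mm, x$rms_mm, x$n_mismatched_angles))
  invisible(x)
}

#' Filter a reference library by site, volume, names and prescription
#'
#' Keeps cases whose anatomical-site label equals the query's, whose
#' physical target volume is within a relative band of the query's, whose
#' structure-name set matches after normalization (lower case, spaces and
#' underscores stripped), and whose prescription dose is within a relative
#' band of the query's.
#'
#' @param library nonempty list of \code{reference_case}s.
#' @param case query case: list with \code{structures} (a
#'   \code{structure_set}), \code{prescription}, and optionally
#'   \code{site} (defaults to the prescription's site).
#' @param volume_band,dose_band relative half-widths of the acceptance
#'   bands (defaults 0.25 and 0.10).
#' @return The retained subset of \code{library} (possibly empty).
#' @export
filter_candidates <- function(library, case, volume_band = 0.25,
                              dose_band = 0.10) {
  if (!length(library)) stop("reference library is empty")
  site <- if (!is.null(case$site)) case$site else case$prescription$site
  q_names <- sort(normalize_name(names(case$structures$structures)))
  tgt <- structure_names(case$structures, "target")
  q_vol <- sum(vapply(tgt, function(s)
    structure_volume_cc(case$structures, s), 0))
  q_dose <- case$prescription$dose_gy
  keep <- vapply(library, function(rc) {
    if (!identical(rc$site, site)) return(FALSE)
    if (!identical(sort(normalize_name(names(rc$structures$structures))),
                   q_names)) return(FALSE)
    rtgt <- structure_names(rc$structures, "target")
    r_vol <- sum(vapply(rtgt, function(s)
      structure_volume_cc(rc$structures, s), 0))
    if (abs(r_vol - q_vol) / q_vol > volume_band) return(FALSE)
    abs(rc$prescription$dose_gy - q_dose) / q_dose <= dose_band
  }, TRUE)
  library[keep]
}

normalize_name <- function(x) tolower(gsub("[ _-]", "", x))

#' Default per-structure similarity thresholds
#'
#' Small structures (volume below \code{small_volume_cc}) get the small
#' threshold, large structures (including the external/skin contour) the
#' large one. The defaults, 2 mm and 10 mm, sit inside the clinically
#' quoted 1-3 mm (small structure) and 5-15 mm (skin contour) ranges.
#'
#' @param ss a \code{structure_set}.
#' @param small_mm,large_mm thresholds (mm).
#' @param small_volume_cc volume cutoff separating small from large (cc).
#' @return Named numeric vector of thresholds, one per structure.
#' @export
default_thresholds <- function(ss, small_mm = 2, large_mm = 10,
                               small_volume_cc = 10) {
  vols <- vapply(names(ss$structures), function(s)
    structure_volume_cc(ss, s), 0)
  roles <- vapply(ss$structures, `[[`, "", "role")
  thr <- ifelse(roles == "external" | vols >= small_volume_cc,
                large_mm, small_mm)
  names(thr) <- names(ss$structures)
  thr
}

#' Select the best reference plan from a library
#'
#' Filters the library ([filter_candidates()]), computes the signed radial
#' difference for every structure of each surviving candidate, rejects any
#' candidate whose |signed difference| exceeds its per-structure threshold
#' at any ray (or that has mismatched crossing counts), and among accepted
#' candidates returns the one minimizing the maximum over structures of
#' max |signed difference|; ties break by smaller RMS, then by case id.
#'
#' @param library nonempty list of \code{reference_case}s.
#' @param case query case (list with \code{structures}, \code{prescription},
#'   optionally \code{site}).
#' @param thresholds named per-structure thresholds in mm (default
#'   [default_thresholds()] on the query's structures).
#' @param angle_resolution_deg ray resolution (default 2.5 degrees).
#' @param ... passed to [filter_candidates()].
#' @return List of class \code{reference_selection}: \code{reference} (the
#'   chosen \code{reference_case}, or NULL if none qualifies),
#'   \code{found}, and \code{reports}, one similarity report per evaluated
#'   candidate (fields \code{id}, \code{accepted}, \code{score_mm},
#'   \code{rms_mm}, \code{per_structure}, \code{rejection_reasons}).
#' @export
select_reference <- function(library, case, thresholds = NULL,
                             angle_resolution_deg = 2.5, ...) {
  if (is.null(thresholds)) thresholds <- default_thresholds(case$structures)
  if (any(thresholds <= 0)) stop("thresholds must be positive")
  cands <- filter_candidates(library, case, ...)
  reports <- lapply(cands, function(rc) {
    per <- lapply(names(case$structures$structures), function(s)
      signed_difference(case$structures, rc$structures, s,
                        angle_resolution_deg))
    names(per) <- names(case$structures$structures)
    reasons <- character()
    for (s in names(per)) {
      thr <- thresholds[[s]]
      if (is.null(thr) || is.na(thr)) thr <- max(thresholds)
      if (per[[s]]$n_mismatched_angles > 0)
        reasons <- c(reasons, sprintf(
          "%s: %d rays with mismatched crossing counts", s,
          per[[s]]$n_mismatched_angles))
      if (per[[s]]$max_abs_mm > thr)
        reasons <- c(reasons, sprintf(
          "%s: max |signed difference| %.2f mm exceeds %.2f mm threshold",
          s, per[[s]]$max_abs_mm, thr))
    }
    list(id = rc$id, accepted = !length(reasons),
         score_mm = max(vapply(per, `[[`, 0, "max_abs_mm")),
         rms_mm = max(vapply(per, `[[`, 0, "rms_mm")),
         per_structure = per, rejection_reasons = reasons)
  })
  names(reports) <- vapply(cands, `[[`, "", "id")
  acc <- which(vapply(reports, `[[`, TRUE, "accepted"))
  if (!length(acc)) {
    out <- list(reference = NULL, found = FALSE, reports = reports)
  } else {
    sc <- vapply(reports[acc], `[[`, 0, "score_mm")
    rms <- vapply(reports[acc], `[[`, 0, "rms_mm")
    ids <- names(reports)[acc]
    best <- acc[order(sc, rms, ids)[1L]]
    out <- list(reference = cands[[best]], found = TRUE, reports = reports)
  }
  class(out) <- "reference_selection"
  out
}

#' @export
print.reference_selection <- function(x, ...) {
  if (x$found)
    cat(sprintf("reference_selection: '%s' selected (score %.3f mm) of %d candidates\n",
                x$reference$id,
                x$reports[[x$reference$id]]$score_mm, length(x$reports)))
  else
    cat(sprintf("reference_selection: no acceptable reference among %d candidates\n",
                length(x$reports)))
  invisible(x)
}

#' Overlay plot of query and reference contours
#'
#' Writes the visual-inspection artifact for a selection: the query case's
#' contours overlaid with the chosen (or given) reference's.
#'
#' @param case query case.
#' @param reference a \code{reference_case}.
#' @param file optional path to a PNG; plots to the active device if NULL.
#' @return Invisibly, NULL.
#' @export
plot_overlay <- function(case, reference, file = NULL) {
  if (!is.null(file)) {
    grDevices::png(file, width = 800, height = 800)
    on.exit(grDevices::dev.off())
  }
  ext <- get_structure(case$structures, "external")$contour
  graphics::plot(ext, type = "l", asp = 1, xlab = "x (mm)", ylab = "y (mm)",
                 main = sprintf("query vs reference '%s'", reference$id))
  for (s in case$structures$structures)
    graphics::lines(s$contour, col = "black")
  for (s in reference$structures$structures)
    graphics::lines(s$contour, col = "red", lty = 2)
  graphics::legend("topright", legend = c("query", "reference"),
                   col = c("black", "red"), lty = c(1, 2), bty = "n")
  invisible(NULL)
}
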