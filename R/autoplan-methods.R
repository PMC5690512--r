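# Methods for the fitted "autoplan" object.

#' @export
print.autoplan <- function(x, ...) {
  cat("Autopiloted plan\n")
  cat(sprintf("  reference: '%s'  prescription: %.1f Gy\n",
              x$reference$id, x$case$prescription$dose_gy))
  cat(sprintf("  outer iterations: %d (%s)\n", x$iterations,
              if (x$converged)
                sprintf("all DVH segment constraints met at iteration %d",
                        x$satisfied_at)
              else "iteration cap hit, best iterate returned"))
  acc <- sum(x$trial_log$accepted)
  cat(sprintf("  trial movements: %d accepted of %d tried\n", acc,
              nrow(x$trial_log)))
  cat(sprintf("  max relative segment deviation: %.2f%%\n",
              100 * utils::tail(x$history$max_rel_deviation, 1)))
  invisible(x)
}

#' @export
summary.autoplan <- function(object, ...) {
  dev <- residuals(object)
  out <- list(converged = object$converged,
              iterations = object$iterations,
              satisfied_at = object$satisfied_at,
              weights = coef(object),
              deviations = dev,
              trial_log = object$trial_log)
  class(out) <- "summary.autoplan"
  out
}

#' @export
print.summary.autoplan <- function(x, ...) {
  cat(sprintf("Autopiloted plan: %d outer iterations, %s\n", x$iterations,
              if (x$converged) "converged" else "not converged"))
  cat("Final weighting factors:\n")
  print(round(x$weights, 4))
  cat("Per-structure DVH segment deviations vs reference (Gy):\n")
  agg <- stats::aggregate(deviation_gy ~ structure, data = x$deviations,
                          FUN = function(d) max(abs(d)))
  names(agg)[2] <- "max_abs_deviation_gy"
  print(agg, row.names = FALSE)
  invisible(x)
}

#' Final weighting factors of an autopiloted plan
#' @param object an \code{autoplan}.
#' @param ... unused.
#' @return Named numeric vector of per-structure weights.
#' @export
coef.autoplan <- function(object, ...) {
  w <- object$params$weight
  names(w) <- object$params$structure
  w
}

#' DVH segment deviations of the final plan from the reference
#' @param object an \code{autoplan}.
#' @param ... unused.
#' @return data.frame: structure, volume_fraction, current_gy,
#'   reference_gy, deviation_gy (current minus reference).
#' @export
residuals.autoplan <- function(object, ...) {
  rows <- lapply(names(object$segments), function(s) {
    cu <- object$segments[[s]]; rf <- object$reference_segments[[s]]
    data.frame(structure = s, volume_fraction = cu$volume_fractions,
               current_gy = cu$dose_gy, reference_gy = rf$dose_gy,
               deviation_gy = cu$dose_gy - rf$dose_gy)
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Plot an autopiloted plan
#'
#' Two panels: the outer-loop convergence trace (maximal constraint
#' violation per iteration) and the final DVHs of the constrained
#' structures overlaid on the reference DVHs.
#'
#' @param x an \code{autoplan}.
#' @param ... unused.
#' @export
plot.autoplan <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(x$history$iteration, x$history$max_violation_gy,
                 type = "b", pch = 16, xlab = "outer iteration",
                 ylab = "max violation (Gy)", main = "outer-loop convergence")
  nm <- names(x$segments)
  cols <- grDevices::hcl.colors(length(nm), "Dark 3")
  curves <- dvh_for_set(x$dose, x$case$structures,
                        roles = x$cfg$constraint_roles)[nm]
  graphics::plot(NA, xlim = c(0, max(vapply(curves, `[[`, 0, "dmax")) * 1.05),
                 ylim = c(0, 100), xlab = "dose (Gy)", ylab = "volume (%)",
                 main = "final vs reference DVH")
  for (i in seq_along(nm)) {
    cv <- curves[[i]]
    graphics::lines(cv$dose_gy, cv$volume_pct, col = cols[i])
    rf <- x$reference$dvh[[nm[i]]]
    graphics::lines(rf$dose_gy, rf$volume_pct, col = cols[i], lty = 2)
  }
  graphics::legend("bottomleft", legend = nm, col = cols, lty = 1, bty = "n")
  invisible(x)
}
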