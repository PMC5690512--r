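# Surrogate inner-loop optimizer: linear dose from beamlet fluence plus a
# weighted quadratic dose objective minimized by projected gradient descent
# with backtracking. This stands in for the commercial TPS optimizer the
# autopilot drives; it is deliberately convex so the outer loop sees the
# monotone weight-to-dose tradeoff the method relies on.

#' Per-structure plan parameters (the knobs the autopilot turns)
#'
#' One row per structure: the weighting factor (structure priority in the
#' inner objective), the objective dose, and the objective type. Targets use
#' a two-sided uniform-dose penalty, OARs and the external contour a
#' one-sided upper-dose penalty.
#'
#' @param structure character vector of structure names.
#' @param weight nonnegative weighting factors; at least one target weight
#'   must be positive.
#' @param objective_dose_gy objective dose per structure (Gy): prescription
#'   dose for targets, upper-dose goal for OARs.
#' @param objective_type \code{"uniform"} (two-sided) or \code{"max"}
#'   (one-sided upper penalty).
#' @return A data.frame of class \code{plan_params}.
#' @export
plan_params <- function(structure, weight, objective_dose_gy, objective_type) {
  stopifnot(length(structure) == length(weight),
            length(structure) == length(objective_dose_gy),
            length(structure) == length(objective_type))
  if (any(weight < 0)) stop("weighting factors must be nonnegative")
  if (!all(objective_type %in% c("uniform", "max")))
    stop("objective_type must be 'uniform' or 'max'")
  out <- data.frame(structure = as.character(structure),
                    weight = as.numeric(weight),
                    objective_dose_gy = as.numeric(objective_dose_gy),
                    objective_type = as.character(objective_type),
                    stringsAsFactors = FALSE)
  class(out) <- c("plan_params", "data.frame")
  out
}

#' Default plan parameters for a structure set
#'
#' Targets get a uniform-dose objective at the prescription with weight 1;
#' OARs an upper-dose objective placed below the ambient transit-dose
#' level (0.15 of the prescription) with weight 0.3, so the penalty is
#' active across most of the OAR volume and the weighting factor has
#' monotone influence on the OAR DVH; the external contour a max-dose
#' objective at the prescription with a small weight, acting as a
#' normal-tissue/hotspot objective.
#'
#' @param ss a \code{structure_set}.
#' @param prescription_gy prescription dose (Gy).
#' @return A \code{plan_params} data.frame.
#' @export
default_plan_params <- function(ss, prescription_gy) {
  roles <- vapply(ss$structures, `[[`, "", "role")
  plan_params(
    structure = names(ss$structures),
    weight = c(target = 1, oar = 0.3, external = 0.02)[roles],
    objective_dose_gy = c(target = 1, oar = 0.15, external = 1)[roles] *
      prescription_gy,
    objective_type = ifelse(roles == "target", "uniform", "max"))
}

#' Dose from beamlet fluence
#'
#' The dose-influence matrix maps beamlet fluences linearly to voxel doses:
#' dose = D x.
#'
#' @param x nonnegative fluence vector, one entry per beamlet.
#' @param D influence matrix, n_voxels x n_beamlets, column-major voxel
#'   order with a \code{grid_shape} attribute.
#' @return Dose matrix (Gy) of the grid shape.
#' @export
compute_dose <- function(x, D) {
  if (length(x) != ncol(D))
    stop("fluence length ", length(x), " does not match ", ncol(D),
         " beamlets")
  if (any(x < 0)) stop("fluence must be nonnegative")
  d <- as.vector(D %*% x)
  gs <- attr(D, "grid_shape")
  if (is.null(gs)) return(d)
  matrix(d, nrow = gs[1], ncol = gs[2])
}

# Objective value and voxel-space residual for a dose vector.
# F(x) = sum_s w_s / |s| * sum_{v in s} pen(d_v), pen two-sided for
# "uniform" objectives and one-sided upper for "max".
plan_objective <- function(dose_vec, obj_terms) {
  f <- 0
  for (tm in obj_terms) {
    dv <- dose_vec[tm$idx] - tm$dose
    if (tm$type == "max") dv <- pmax(dv, 0)
    f <- f + tm$w_over_n * sum(dv * dv)
  }
  f
}

plan_gradient_voxel <- function(dose_vec, obj_terms, n_vox) {
  r <- numeric(n_vox)
  for (tm in obj_terms) {
    dv <- dose_vec[tm$idx] - tm$dose
    if (tm$type == "max") dv <- pmax(dv, 0)
    r[tm$idx] <- r[tm$idx] + 2 * tm$w_over_n * dv
  }
  r
}

# Open-field conformal fluence template: beamlet weight proportional to
# its mean influence on the target voxels, scaled so the template alone
# delivers the target objective dose on average.
conformal_anchor <- function(params, D, ss) {
  roles <- vapply(ss$structures, `[[`, "", "role")
  tnames <- names(roles)[roles == "target"]
  tidx <- which(as.vector(Reduce(`|`, lapply(tnames, function(s)
    get_structure(ss, s)$mask))))
  w <- colMeans(D[tidx, , drop = FALSE])
  d_obj <- mean(params$objective_dose_gy[params$structure %in% tnames])
  mt <- mean(as.vector(D[tidx, , drop = FALSE] %*% w))
  if (mt <= 0) return(numeric(ncol(D)))
  w * (d_obj / mt)
}

build_objective_terms <- function(params, ss) {
  terms <- list()
  for (k in seq_len(nrow(params))) {
    if (params$weight[k] == 0) next
    s <- get_structure(ss, params$structure[k])
    idx <- which(as.vector(s$mask))
    if (!length(idx)) next
    terms[[length(terms) + 1L]] <- list(
      idx = idx, dose = params$objective_dose_gy[k],
      type = if (params$objective_type[k] == "uniform") "uniform" else "max",
      w_over_n = params$weight[k] / length(idx))
  }
  terms
}

#' Optimize beamlet fluence for a set of plan parameters
#'
#' Minimizes the weighted quadratic dose objective over nonnegative
#' fluences by monotone accelerated projected gradient descent (FISTA with
#' a monotone safeguard and Armijo backtracking), so the recorded
#' objective trace is monotone nonincreasing while convergence stays fast
#' on the ill-conditioned problems realistic influence matrices produce.
#' The run is deterministic given the warm start and tolerances. Stops
#' when the relative objective decrease stays below \code{tol} or after
#' \code{max_iter} iterations (the latter sets \code{converged = FALSE}
#' and returns the best iterate).
#'
#' @param params a \code{plan_params} data.frame; at least one target must
#'   have positive weight.
#' @param D influence matrix (n_voxels x n_beamlets).
#' @param ss the \code{structure_set} the parameters refer to.
#' @param x0 optional warm-start fluence; zero fluence when omitted.
#' @param control list with \code{max_iter} (default 3000), \code{tol}
#'   (relative objective decrease, default 1e-9), \code{ridge} (relative
#'   strength of the Tikhonov fluence-regularization term, default 1e-2)
#'   and \code{anchor} (\code{"conformal"}, the default, or \code{"zero"}).
#'   The regularizer penalizes deviation from an anchor fluence: with the
#'   conformal anchor that is an open-field template whose beamlet weights
#'   are proportional to each beamlet's mean influence on the target,
#'   scaled to the target objective dose — the fluence a forward-planned
#'   conformal setup would use. Anchored regularization makes the optimum
#'   unique and stabilizes the soft (near-degenerate) fluence modes
#'   against small geometry changes without shrinking the plan toward
#'   zero dose.
#' @return List with \code{fluence}, \code{trace} (objective per accepted
#'   iteration, element 1 is the starting objective), \code{converged},
#'   \code{iterations}.
#' @export
optimize_fluence <- function(params, D, ss, x0 = NULL,
                             control = list()) {
  ctl <- utils::modifyList(list(max_iter = 3000L, tol = 1e-9, ridge = 1e-2,
                                anchor = "conformal"),
                           control)
  roles <- vapply(ss$structures, `[[`, "", "role")
  tgt <- params$structure %in% names(roles)[roles == "target"]
  if (!any(params$weight > 0))
    stop("all weighting factors are zero")
  if (!any(params$weight[tgt] > 0))
    stop("at least one target objective must have positive weight")
  n_vox <- nrow(D)
  terms <- build_objective_terms(params, ss)
  x <- if (is.null(x0)) numeric(ncol(D)) else as.numeric(x0)
  if (length(x) != ncol(D)) stop("warm-start fluence has wrong length")
  if (any(x < 0)) stop("fluence must be nonnegative")

  # Lipschitz step from the largest eigenvalue of D'D and the largest
  # per-voxel penalty curvature; backtracking safeguards it.
  lam <- max(eigen(crossprod(D), symmetric = TRUE,
                   only.values = TRUE)$values)
  curv <- numeric(n_vox)
  for (tm in terms) curv[tm$idx] <- curv[tm$idx] + 2 * tm$w_over_n
  hess_scale <- max(lam * max(curv), 1e-12)
  lam_ridge <- ctl$ridge * hess_scale / 2
  step <- 1 / (hess_scale + 2 * lam_ridge)

  x_anchor <- if (identical(ctl$anchor, "conformal"))
    conformal_anchor(params, D, ss) else numeric(ncol(D))

  obj <- function(dose_vec, xv)
    plan_objective(dose_vec, terms) + lam_ridge * sum((xv - x_anchor)^2)
  grad <- function(dose_vec, xv)
    as.vector(crossprod(D, plan_gradient_voxel(dose_vec, terms, n_vox))) +
      2 * lam_ridge * (xv - x_anchor)

  dose <- as.vector(D %*% x)
  f <- obj(dose, x)
  trace <- f
  converged <- FALSE
  y <- x
  dose_y <- dose
  x_prev <- x
  tk <- 1
  stall <- 0L
  for (it in seq_len(ctl$max_iter)) {
    g <- grad(dose_y, y)
    # backtracked projected-gradient step from the extrapolated point
    t_try <- step
    repeat {
      z <- pmax(0, y - t_try * g)
      dose_z <- as.vector(D %*% z)
      fz <- obj(dose_z, z)
      fy_quad <- obj(dose_y, y) + sum(g * (z - y)) +
        sum((z - y)^2) / (2 * t_try)
      if (fz <= fy_quad + 1e-12 * abs(fz) || t_try < 1e-18) break
      t_try <- t_try / 2
    }
    stationary <- sqrt(sum((z - y)^2)) <= 1e-6 * (1 + sqrt(sum(y * y)))
    # monotone safeguard with adaptive restart: an objective increase
    # means the momentum has overshot, so drop it and retake the step
    # from the current iterate
    if (fz <= f) {
      x_new <- z; dose_new <- dose_z; f_new <- fz
      t_next <- (1 + sqrt(1 + 4 * tk * tk)) / 2
      y <- x_new + (tk / t_next) * (z - x_new) +
        ((tk - 1) / t_next) * (x_new - x_prev)
      dose_y <- as.vector(D %*% y)
      tk <- t_next
    } else {
      x_new <- x; dose_new <- dose; f_new <- f
      y <- x; dose_y <- dose
      tk <- 1
    }
    x_prev <- x
    x <- x_new; dose <- dose_new; f <- f_new
    trace <- c(trace, f)
    # stationarity: the projected gradient step did not move the point
    if (stationary) {
      converged <- TRUE
      break
    }
    # stop on stagnation over a window: accelerated methods alternate
    # flat stretches with progress bursts, so a single-step test is
    # unreliable
    win <- 40L
    if (it >= win) {
      f_then <- trace[length(trace) - win]
      if ((f_then - f) / max(f_then, .Machine$double.xmin) < win * ctl$tol) {
        converged <- TRUE
        break
      }
    }
  }
  if (!converged)
    warning("fluence optimization hit the iteration cap (", ctl$max_iter,
            "); returning best iterate")
  list(fluence = x, trace = trace, converged = converged,
       iterations = length(trace) - 1L)
}
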