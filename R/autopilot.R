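# The outer-loop autopilot: alternate inner fluence optimizations with a
# segment-by-segment DVH comparison against the reference plan, adjust the
# per-structure weighting factors toward decreasing discrepancy, stop when
# every DVH segment matches the reference within tolerance (or at the
# iteration cap), then refine with Pareto-safe trial movements.

#' Autopilot configuration
#'
#' @param epsilon_fraction per-segment tolerance as a fraction of the
#'   reference segment dose (default 0.03, i.e. 3\% of the reference).
#' @param epsilon_floor_gy tolerance floor for near-zero reference segment
#'   doses, where a relative tolerance would be vacuous (default 0.1 Gy).
#' @param max_outer_iterations outer-loop iteration cap (default 50).
#' @param learning_rate initial step size of the multiplicative weight
#'   update (default 10; the per-iteration change is clipped to a factor
#'   of e). The loop adapts it: whenever an update fails to decrease the
#'   maximal violation the rate is halved, and it recovers by 10\% per
#'   successful iteration, so the final approach to the tolerance band
#'   takes progressively finer steps.
#' @param segment_fractions DVH segment control points (volume percent).
#' @param trial_step relative objective-dose perturbation used by trial
#'   movements (default 0.05).
#' @param trial_passes number of refinement passes (default 1).
#' @param constraint_roles structure roles entering the DVH constraints
#'   (default target and OAR; the external contour carries no reference
#'   constraint, its weight stays at the warm-start value).
#' @param dvh_resolution_gy DVH bin width used in the loop (default
#'   0.001 Gy, the maximal export resolution).
#' @param dvh_supersample integer supersampling factor for loop DVH
#'   evaluation (default 3; see [dvh_sampler()]). Reference libraries are
#'   built with the same factor so current and reference DVHs share the
#'   same discretization.
#' @param inner_control control list passed to [optimize_fluence()].
#' @param seed integer seed; the loop itself is deterministic, the seed is
#'   recorded for provenance.
#' @return List of class \code{autopilot_config}.
#' @export
autopilot_config <- function(epsilon_fraction = 0.03, epsilon_floor_gy = 0.1,
                             max_outer_iterations = 50L, learning_rate = 10,
                             segment_fractions = default_segment_fractions(),
                             trial_step = 0.05, trial_passes = 1L,
                             constraint_roles = c("target", "oar"),
                             dvh_resolution_gy = 0.001,
                             dvh_supersample = 3L,
                             inner_control = list(), seed = 1L) {
  if (epsilon_fraction <= 0 || epsilon_fraction >= 1)
    stop("epsilon_fraction must be in (0, 1)")
  if (max_outer_iterations < 1) stop("max_outer_iterations must be >= 1")
  if (learning_rate <= 0) stop("learning_rate must be positive")
  if (trial_step < 0) stop("trial_step must be nonnegative")
  structure(list(epsilon_fraction = epsilon_fraction,
                 epsilon_floor_gy = epsilon_floor_gy,
                 max_outer_iterations = as.integer(max_outer_iterations),
                 learning_rate = learning_rate,
                 segment_fractions = segment_fractions,
                 trial_step = trial_step,
                 trial_passes = as.integer(trial_passes),
                 constraint_roles = constraint_roles,
                 dvh_resolution_gy = dvh_resolution_gy,
                 dvh_supersample = as.integer(dvh_supersample),
                 inner_control = inner_control, seed = as.integer(seed)),
            class = "autopilot_config")
}

#' Check the DVH segment constraints against the reference
#'
#' The plan is acceptable when every DVH segment of every constrained
#' structure matches the reference segment within tolerance:
#' |d_sj - d_sj_ref| < eps_sj with eps_sj = max(epsilon_fraction *
#' d_sj_ref, epsilon_floor_gy). The inequality is strict; a deviation
#' exactly at tolerance counts as a violation.
#'
#' @param current,reference named lists of \code{segment_vector}s over the
#'   same structures and control points.
#' @param cfg an \code{autopilot_config}.
#' @return List with \code{satisfied} (logical) and \code{violations}, a
#'   data.frame (structure, j, volume_fraction, current_gy, reference_gy,
#'   tolerance_gy, excess_gy) with one row per failing segment;
#'   \code{excess_gy} is the signed amount by which the deviation exceeds
#'   tolerance (positive = hotter than the reference).
#' @export
check_constraints <- function(current, reference, cfg) {
  if (!setequal(names(current), names(reference)))
    stop("current and reference segment sets cover different structures")
  rows <- list()
  for (s in names(current)) {
    cu <- current[[s]]; rf <- reference[[s]]
    if (length(cu$dose_gy) != length(rf$dose_gy) ||
        any(cu$volume_fractions != rf$volume_fractions))
      stop("segment control points differ between current and reference ('",
           s, "')")
    eps <- pmax(cfg$epsilon_fraction * rf$dose_gy, cfg$epsilon_floor_gy)
    dev <- cu$dose_gy - rf$dose_gy
    bad <- abs(dev) >= eps
    if (any(bad)) {
      rows[[s]] <- data.frame(
        structure = s, j = which(bad),
        volume_fraction = cu$volume_fractions[bad],
        current_gy = cu$dose_gy[bad], reference_gy = rf$dose_gy[bad],
        tolerance_gy = eps[bad],
        excess_gy = sign(dev[bad]) * (abs(dev[bad]) - eps[bad]))
    }
  }
  viol <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
          else data.frame(structure = character(), j = integer(),
                          volume_fraction = numeric(), current_gy = numeric(),
                          reference_gy = numeric(), tolerance_gy = numeric(),
                          excess_gy = numeric())
  list(satisfied = nrow(viol) == 0L, violations = viol)
}

#' Update the weighting factors toward decreasing DVH discrepancy
#'
#' Multiplicative exponentiated-gradient-style update on each structure's
#' aggregate signed violation V_s: the sum of the full signed deviations
#' (current minus reference, Gy) of its failing segments, positive =
#' overdosed relative to the reference. Using the full deviation rather
#' than only the suprathreshold excess keeps the update step finite as a
#' segment approaches the tolerance band, so the loop crosses the strict
#' inequality instead of creeping toward it.
#' An overdosed OAR gets a larger weight (more sparing pressure); a target
#' falling below its reference gets a larger weight (more coverage
#' pressure). Updates are clipped to a factor of e per iteration and
#' structures without violations keep their weight; structures carrying no
#' reference constraint (e.g. the external contour) are never updated.
#'
#' @param params current \code{plan_params}.
#' @param violations violation data.frame from [check_constraints()].
#' @param cfg an \code{autopilot_config}.
#' @param prescription_gy prescription dose, the scale of the update.
#' @param ss the \code{structure_set} (for structure roles).
#' @return Updated \code{plan_params}.
#' @export
update_weights <- function(params, violations, cfg, prescription_gy, ss) {
  if (!nrow(violations)) return(params)
  roles <- vapply(ss$structures, `[[`, "", "role")
  agg <- tapply(violations$current_gy - violations$reference_gy,
                violations$structure, sum)
  for (s in names(agg)) {
    k <- which(params$structure == s)
    if (!length(k)) next
    v <- agg[[s]] / prescription_gy
    # OARs: overdose (v > 0) raises the weight. Targets: the symmetric
    # rule — underdose (v < 0) raises the weight.
    expo <- if (roles[[s]] == "target") -cfg$learning_rate * v
            else cfg$learning_rate * v
    params$weight[k] <- params$weight[k] * exp(max(-1, min(1, expo)))
  }
  params
}

#' Run the autopiloted planning loop
#'
#' Warm-starts from the reference plan's parameters (and fluence, when its
#' beamlet layout matches), then loops: inner fluence optimization, DVH
#' computation, segment-constraint check against the reference DVHs,
#' weighting-factor update. Stops as soon as every constraint is satisfied
#' or after \code{max_outer_iterations} iterations (returning the best
#' iterate by maximal violation, flagged as not converged), then applies
#' the trial-movement refinement. Deterministic given the configuration.
#'
#' @param case planning case: list with \code{structures}
#'   (\code{structure_set}), \code{influence} (influence matrix) and
#'   \code{prescription}; [generate_phantom()] returns this shape.
#' @param reference a \code{reference_case} that passed selection (or that
#'   the caller supplies deliberately).
#' @param cfg an \code{autopilot_config}.
#' @param output_dir optional directory; when given, per-iteration DVH
#'   files (\code{dvh_iter_NNN.csv}, in the package's DVH dialect), a
#'   comma-separated history table and the final parameters are written
#'   there.
#' Weights are kept within an order of magnitude of their warm-start
#' values: when a reference segment is unreachable (e.g. the reference
#' asks for more OAR dose than the geometry ever delivers), the
#' multiplicative updates would otherwise drive that weight to zero and
#' remove the structure from the objective entirely, which no planner
#' would do.
#'
#' @return Object of class \code{autoplan} with fields \code{fluence},
#'   \code{params}, \code{dose}, \code{converged},
#'   \code{iterations}, \code{satisfied_at} (first iteration with all
#'   constraints met, NA if never), \code{history} (data.frame: iteration,
#'   one weight column per structure, n_violations, max_violation_gy,
#'   max_rel_deviation, inner_objective), \code{segments},
#'   \code{reference_segments}, \code{trial_log}, \code{cfg}, \code{case},
#'   \code{reference}.
#' @export
run_autopilot <- function(case, reference, cfg = autopilot_config(),
                          output_dir = NULL) {
  stopifnot(inherits(reference, "reference_case"),
            inherits(cfg, "autopilot_config"))
  ss <- case$structures
  tgt <- structure_names(ss, "target")
  oar <- structure_names(ss, "oar")
  for (s in tgt) for (o in oar)
    if (any(get_structure(ss, s)$mask & get_structure(ss, o)$mask))
      stop("infeasible geometry: target '", s, "' overlaps OAR '", o, "'")
  cons <- intersect(structure_names(ss, cfg$constraint_roles),
                    names(reference$dvh))
  if (!length(cons)) stop("no structures shared with the reference DVHs")
  ref_seg <- lapply(reference$dvh[cons], sample_segments,
                    volume_fractions = cfg$segment_fractions)
  sampler <- dvh_sampler(ss, roles = cfg$constraint_roles,
                         factor = cfg$dvh_supersample,
                         resolution_gy = cfg$dvh_resolution_gy)

  if (!is.null(output_dir) &&
      !dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)

  # warm start from the reference plan
  params <- reference$params
  x <- if (!is.null(reference$fluence) &&
           length(reference$fluence) == ncol(case$influence))
    reference$fluence else NULL

  rx <- case$prescription$dose_gy
  hist_rows <- list()
  best <- NULL
  satisfied_at <- NA_integer_
  eta <- cfg$learning_rate
  prev_viol <- Inf
  w_start <- params$weight
  clamp_weights <- function(p) {
    p$weight <- pmin(pmax(p$weight, w_start / 10), w_start * 10)
    p
  }
  # decision-function state: exponentiated-gradient steps until they
  # stall, then derivative-free pattern search on the weights, accepting
  # only moves that reduce the maximal violation
  mode <- "eg"
  stall <- 0L
  pat <- NULL
  for (it in seq_len(cfg$max_outer_iterations)) {
    fit <- optimize_fluence(params, case$influence, ss, x0 = x,
                            control = cfg$inner_control)
    x <- fit$fluence
    dose <- compute_dose(x, case$influence)
    curves <- sampler(dose)[cons]
    segs <- lapply(curves, sample_segments,
                   volume_fractions = cfg$segment_fractions)
    chk <- check_constraints(segs, ref_seg, cfg)
    max_viol <- if (nrow(chk$violations)) max(abs(chk$violations$excess_gy))
                else 0
    dev_rel <- max_relative_deviation(segs, ref_seg, cfg)
    w <- params$weight; names(w) <- params$structure
    hist_rows[[it]] <- data.frame(
      iteration = it, as.list(w), n_violations = nrow(chk$violations),
      max_violation_gy = max_viol, max_rel_deviation = dev_rel,
      inner_objective = fit$trace[length(fit$trace)],
      check.names = FALSE)
    if (!is.null(output_dir))
      write_dvh_file(curves, file.path(output_dir,
                                       sprintf("dvh_iter_%03d.csv", it)))
    if (is.null(best) || max_viol < best$max_viol)
      best <- list(x = x, params = params, dose = dose, segs = segs,
                   max_viol = max_viol, iteration = it)
    if (chk$satisfied) { satisfied_at <- it; break }
    if (mode == "eg") {
      stall <- if (max_viol >= prev_viol - 1e-9) stall + 1L else 0L
      if (stall >= 4L) {
        # updates have stopped helping: probe weights one structure at a
        # time around the best iterate found so far
        mode <- "pattern"
        pat <- list(base_params = best$params, base_viol = best$max_viol,
                    cands = expand.grid(structure = cons,
                                        dir = c(1, -1),
                                        stringsAsFactors = FALSE),
                    idx = 1L, delta = 0.05)
        params <- clamp_weights(pattern_trial(pat, ss))
      } else {
        # bold-driver adaptation: back off when the last update overshot
        eta <- if (max_viol > prev_viol) max(eta / 2, 1e-3)
               else min(eta * 1.1, cfg$learning_rate)
        cfg_it <- cfg
        cfg_it$learning_rate <- eta
        params <- clamp_weights(
          update_weights(params, chk$violations, cfg_it, rx, ss))
      }
      prev_viol <- max_viol
    } else {
      if (max_viol < pat$base_viol - 1e-12) {
        # keep the improvement and push further in the same direction
        pat$base_params <- params
        pat$base_viol <- max_viol
      } else {
        pat$idx <- pat$idx + 1L
        if (pat$idx > nrow(pat$cands)) {
          pat$idx <- 1L
          pat$delta <- max(pat$delta / 2, 0.004)
        }
      }
      params <- clamp_weights(pattern_trial(pat, ss))
    }
  }
  converged <- !is.na(satisfied_at)
  if (!converged) {
    # cap hit: fall back to the best iterate by maximal violation
    x <- best$x; params <- best$params; dose <- best$dose; segs <- best$segs
  }

  trial <- trial_refinement(
    list(fluence = x, params = params, segments = segs), case, ref_seg, cfg,
    sampler = sampler)
  x <- trial$fluence; params <- trial$params; segs <- trial$segments
  dose <- compute_dose(x, case$influence)

  history <- do.call(rbind, c(hist_rows, make.row.names = FALSE))
  out <- structure(
    list(fluence = x, params = params, dose = dose, converged = converged,
         iterations = length(hist_rows), satisfied_at = satisfied_at,
         history = history, segments = segs, reference_segments = ref_seg,
         trial_log = trial$log, cfg = cfg, case = case,
         reference = reference),
    class = "autoplan")
  if (!is.null(output_dir)) {
    utils::write.csv(history, file.path(output_dir, "history.csv"),
                     row.names = FALSE)
    write_plan_params(params, file.path(output_dir, "final_parameters.yaml"))
    write_dvh_file(dvh_for_set(dose, ss, resolution_gy =
                                 cfg$dvh_resolution_gy),
                   file.path(output_dir, "dvh_final.csv"))
  }
  out
}

# Next pattern-search trial: one structure's weight scaled by (1 +/- delta).
pattern_trial <- function(pat, ss) {
  p <- pat$base_params
  cand <- pat$cands[pat$idx, ]
  k <- which(p$structure == cand$structure)
  fac <- if (cand$dir > 0) 1 + pat$delta else 1 / (1 + pat$delta)
  p$weight[k] <- p$weight[k] * fac
  p
}

max_relative_deviation <- function(segs, ref_seg, cfg) {
  mx <- 0
  for (s in names(segs)) {
    r <- ref_seg[[s]]$dose_gy
    ok <- cfg$epsilon_fraction * r >= cfg$epsilon_floor_gy  # floor-exempt
    if (any(ok))
      mx <- max(mx, abs(segs[[s]]$dose_gy[ok] - r[ok]) / r[ok])
  }
  mx
}

#' Trial-movement refinement of a terminated autopilot run
#'
#' So that planning does not stop at the reference when there is room for
#' improvement, each structure's objective makes a trial movement toward
#' better target coverage or OAR sparing (targets first, then OARs by
#' descending weight): an OAR's objective dose is lowered by
#' \code{trial_step} (fraction), a target's raised by it, the inner
#' optimizer is re-run, and all DVH segments recomputed. The move is
#' accepted only if no segment of any other structure worsens by more than
#' one DVH bin width (dose increase for OARs, dose decrease for targets);
#' otherwise it is reverted. Every accepted move is logged.
#'
#' @param state list with \code{fluence}, \code{params}, \code{segments}
#'   from a terminated run.
#' @param case the planning case.
#' @param ref_seg reference segment vectors (named list); used only to keep
#'   the constrained-structure list consistent.
#' @param cfg an \code{autopilot_config}.
#' @param sampler optional DVH evaluator from [dvh_sampler()]; built from
#'   the config when omitted.
#' @return List with \code{fluence}, \code{params}, \code{segments} and
#'   \code{log}, a data.frame of trials (pass, structure, accepted,
#'   worst_worsening_gy).
#' @export
trial_refinement <- function(state, case, ref_seg, cfg, sampler = NULL) {
  ss <- case$structures
  if (is.null(sampler))
    sampler <- dvh_sampler(ss, roles = cfg$constraint_roles,
                           factor = cfg$dvh_supersample,
                           resolution_gy = cfg$dvh_resolution_gy)
  roles <- vapply(ss$structures, `[[`, "", "role")
  x <- state$fluence; params <- state$params; segs <- state$segments
  log_rows <- list()
  if (cfg$trial_step == 0 || cfg$trial_passes == 0)
    return(list(fluence = x, params = params, segments = segs,
                log = empty_trial_log()))
  tol <- cfg$dvh_resolution_gy
  order_idx <- order(match(roles[params$structure], c("target", "oar")),
                     -params$weight)
  order_idx <- order_idx[roles[params$structure][order_idx] %in%
                           c("target", "oar")]
  for (pass in seq_len(cfg$trial_passes)) {
    for (k in order_idx) {
      s <- params$structure[k]
      trial_params <- params
      fac <- if (roles[[s]] == "target") 1 + cfg$trial_step
             else 1 - cfg$trial_step
      trial_params$objective_dose_gy[k] <-
        trial_params$objective_dose_gy[k] * fac
      fit <- optimize_fluence(trial_params, case$influence, ss, x0 = x,
                              control = cfg$inner_control)
      dose <- compute_dose(fit$fluence, case$influence)
      new_segs <- lapply(sampler(dose)[names(segs)], sample_segments,
                         volume_fractions = cfg$segment_fractions)
      worst <- 0
      for (s2 in names(segs)) {
        delta <- new_segs[[s2]]$dose_gy - segs[[s2]]$dose_gy
        wors <- if (roles[[s2]] == "target") -delta else delta
        worst <- max(worst, max(wors))
      }
      accepted <- worst <= tol
      log_rows[[length(log_rows) + 1L]] <- data.frame(
        pass = pass, structure = s, accepted = accepted,
        worst_worsening_gy = worst)
      if (accepted) {
        x <- fit$fluence; params <- trial_params; segs <- new_segs
      }
    }
  }
  list(fluence = x, params = params, segments = segs,
       log = if (length(log_rows))
         do.call(rbind, c(log_rows, make.row.names = FALSE))
       else empty_trial_log())
}

empty_trial_log <- function()
  data.frame(pass = integer(), structure = character(),
             accepted = logical(), worst_worsening_gy = numeric())
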