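test_that("constraint checking applies the 3% band with a floor", {
  cfg <- autopilot_config()
  ref <- list(s = seg_vec("s", c(25, 50, 75), c(50, 50, 0)))

  same <- check_constraints(ref, ref, cfg)
  expect_true(same$satisfied)
  expect_equal(nrow(same$violations), 0)

  # 3% of 50 Gy = 1.5 Gy band
  ok <- list(s = seg_vec("s", c(25, 50, 75), c(51.4, 50, 0.05)))
  expect_true(check_constraints(ok, ref, cfg)$satisfied)
  bad <- list(s = seg_vec("s", c(25, 50, 75), c(51.6, 50, 0.05)))
  chk <- check_constraints(bad, ref, cfg)
  expect_false(chk$satisfied)
  expect_equal(nrow(chk$violations), 1)
  expect_equal(chk$violations$excess_gy, 0.1, tolerance = 1e-12)
  # a deviation exactly at tolerance counts as a violation
  tie <- list(s = seg_vec("s", c(25, 50, 75), c(51.5, 50, 0)))
  expect_false(check_constraints(tie, ref, cfg)$satisfied)

  expect_error(check_constraints(
    list(s = seg_vec("s", c(10, 50), c(1, 2))), ref, cfg), "control points")
  expect_error(check_constraints(
    list(t = seg_vec("t", c(25, 50, 75), c(1, 2, 3))), ref, cfg),
    "different structures")
})

test_that("weight updates move against the discrepancy and clip", {
  ss <- mini_set()
  params <- default_plan_params(ss, 50)
  cfg <- autopilot_config(learning_rate = 1)

  no_viol <- check_constraints(
    list(oar = seg_vec("oar", 50, 10)),
    list(oar = seg_vec("oar", 50, 10)), cfg)$violations
  expect_identical(update_weights(params, no_viol, cfg, 50, ss), params)

  # OAR overdosed by 5 Gy: V/Rx = 0.1, learning rate 1 -> factor e^0.1
  viol <- data.frame(structure = "oar", j = 1L, volume_fraction = 50,
                     current_gy = 55, reference_gy = 50, tolerance_gy = 1.5,
                     excess_gy = 3.5)
  up <- update_weights(params, viol, cfg, 50, ss)
  k <- which(params$structure == "oar")
  expect_equal(up$weight[k], params$weight[k] * exp(0.1), tolerance = 1e-12)
  expect_gt(up$weight[k], params$weight[k])

  # target underdosed -> weight goes up; huge violation clips at e
  tviol <- data.frame(structure = "ptv", j = 1L, volume_fraction = 95,
                      current_gy = 10, reference_gy = 50, tolerance_gy = 1.5,
                      excess_gy = -38.5)
  cfg_hot <- autopilot_config(learning_rate = 100)
  up2 <- update_weights(params, tviol, cfg_hot, 50, ss)
  kp <- which(params$structure == "ptv")
  expect_equal(up2$weight[kp], params$weight[kp] * exp(1), tolerance = 1e-12)
})

test_that("autopilot is a fixed point at the case's own optimum", {
  ph <- generate_phantom(tiny_spec())
  case <- c(ph, list(site = "phantom"))
  ref <- self_reference(case)
  fit <- run_autopilot(case, ref, autopilot_config())
  expect_true(fit$converged)
  expect_equal(fit$satisfied_at, 1L)
  expect_equal(coef(fit), setNames(ref$params$weight, ref$params$structure))
  expect_equal(sum(fit$trial_log$accepted), 0)
  expect_s3_class(fit, "autoplan")
})

test_that("autopilot validates its inputs", {
  ph <- generate_phantom(tiny_spec())
  case <- c(ph, list(site = "phantom"))
  ref <- self_reference(case)
  expect_error(autopilot_config(max_outer_iterations = 0), ">= 1")
  expect_error(autopilot_config(epsilon_fraction = 1.5), "epsilon_fraction")

  # target overlapping an OAR is infeasible geometry
  bad_case <- case
  bad_case$structures$structures$oar$mask <-
    bad_case$structures$structures$ptv$mask
  expect_error(run_autopilot(bad_case, ref, autopilot_config()),
               "infeasible")
})

test_that("trial movements with zero step change nothing", {
  ph <- generate_phantom(tiny_spec())
  case <- c(ph, list(site = "phantom"))
  ref <- self_reference(case)
  cfg <- autopilot_config(trial_step = 0)
  fit <- run_autopilot(case, ref, cfg)
  expect_equal(nrow(fit$trial_log), 0)
  expect_equal(coef(fit), setNames(ref$params$weight, ref$params$structure))
})

test_that("run artifacts are written when an output directory is given", {
  ph <- generate_phantom(tiny_spec())
  case <- c(ph, list(site = "phantom"))
  ref <- self_reference(case)
  out <- withr::local_tempdir()
  fit <- run_autopilot(case, ref, autopilot_config(), output_dir = out)
  expect_true(file.exists(file.path(out, "dvh_iter_001.csv")))
  expect_true(file.exists(file.path(out, "history.csv")))
  expect_true(file.exists(file.path(out, "final_parameters.yaml")))
  expect_true(file.exists(file.path(out, "dvh_final.csv")))
  h <- utils::read.csv(file.path(out, "history.csv"))
  expect_equal(nrow(h), fit$iterations)
  curves <- read_dvh_file(file.path(out, "dvh_iter_001.csv"))
  expect_true(all(c("ptv", "oar") %in% names(curves)))
})

test_that("autoplan methods summarise the fitted plan", {
  ph <- generate_phantom(tiny_spec())
  case <- c(ph, list(site = "phantom"))
  ref <- self_reference(case)
  fit <- run_autopilot(case, ref, autopilot_config())
  expect_output(print(fit), "Autopiloted plan")
  s <- summary(fit)
  expect_output(print(s), "weighting factors")
  r <- residuals(fit)
  expect_true(all(c("structure", "deviation_gy") %in% names(r)))
  expect_true(all(abs(r$deviation_gy) <
                  pmax(0.03 * r$reference_gy, 0.1)))
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("degraded references are outperformed by refinement", {
  ph <- generate_phantom(tiny_spec())
  case <- c(ph, list(site = "phantom"))
  ref <- self_reference(case)
  worse <- ref
  for (s in names(worse$dvh)) {
    if (s != "oar") next
    worse$dvh[[s]]$dose_gy <- worse$dvh[[s]]$dose_gy + 5
    worse$dvh[[s]]$dmin <- worse$dvh[[s]]$dmin + 5
    worse$dvh[[s]]$dmax <- worse$dvh[[s]]$dmax + 5
    worse$dvh[[s]]$dmean <- worse$dvh[[s]]$dmean + 5
  }
  fit_ref <- suppressWarnings(run_autopilot(case, ref, autopilot_config()))
  fit_deg <- suppressWarnings(run_autopilot(case, worse, autopilot_config()))
  seg_ref <- fit_ref$segments$oar$dose_gy
  seg_deg <- fit_deg$segments$oar$dose_gy
  # the final plan under the inflated reference stays below that
  # reference's OAR curve and moves by less than the degradation
  expect_true(all(seg_deg - seg_ref < 5))
  worse_seg <- sample_segments(worse$dvh$oar)$dose_gy
  expect_true(all(seg_deg <= worse_seg))
})
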