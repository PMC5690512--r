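test_that("cumulative DVHs follow the >= dose convention", {
  m <- matrix(TRUE, 2, 2)
  u <- matrix(10, 2, 2)
  cv <- compute_dvh(u, m)
  expect_equal(cv$volume_pct[cv$dose_gy <= 10], rep(100, sum(cv$dose_gy <= 10)))
  expect_equal(cv$volume_pct[cv$dose_gy > 10], rep(0, sum(cv$dose_gy > 10)))
  expect_equal(c(cv$dmin, cv$dmax, cv$dmean), c(10, 10, 10))

  cv2 <- compute_dvh(matrix(c(1, 2, 3, 4), 2, 2), m)
  expect_equal(dvh_statistic(cv2, "Vx", 2.0), 75)
  expect_equal(cv2$dmean, 2.5)

  cv0 <- compute_dvh(matrix(0, 2, 2), m)
  expect_equal(cv0$volume_pct[1], 100)
  expect_equal(cv0$volume_pct[length(cv0$volume_pct)], 0)
  expect_equal(cv0$dmax, 0)

  expect_error(compute_dvh(u, matrix(FALSE, 2, 2)), "empty")
  expect_error(compute_dvh(u, m, resolution_gy = 0.01), "resolution")
})

test_that("Vx and Dx statistics match order-statistics arithmetic", {
  m <- matrix(TRUE, 2, 2)
  uni <- compute_dvh(matrix(10, 2, 2), m)
  expect_equal(dvh_statistic(uni, "Vx", 5), 100)
  expect_equal(dvh_statistic(uni, "Dx", 95), 10, tolerance = 1e-3)

  cv <- compute_dvh(matrix(c(1, 2, 3, 4), 2, 2), m)
  expect_equal(dvh_statistic(cv, "Dx", 50), 3, tolerance = 1e-3)
  expect_equal(dvh_statistic(cv, "Dx", 100), cv$dmin, tolerance = 1e-3)
  expect_error(dvh_statistic(cv, "Dx", 0), "volume fraction")
  expect_error(dvh_statistic(cv, "Dx", 101), "volume fraction")
})

test_that("segment sampling inverts the DVH at fixed volume fractions", {
  m <- matrix(TRUE, 2, 2)
  uni <- compute_dvh(matrix(10, 2, 2), m)
  sv <- sample_segments(uni)
  expect_equal(sv$dose_gy, rep(10, 20), tolerance = 1e-2)

  cv <- compute_dvh(matrix(c(1, 2, 3, 4), 2, 2), m)
  expect_equal(sample_segments(cv, 50)$dose_gy, 3, tolerance = 1e-3)

  sv2 <- sample_segments(cv, c(5, 95))
  expect_gte(sv2$dose_gy[1], sv2$dose_gy[2])
  expect_error(sample_segments(cv, numeric()), "empty")
  expect_error(sample_segments(cv, c(40, 30)), "increasing")
})

test_that("random-grid DVH invariants hold and match brute force", {
  set.seed(99)
  for (i in 1:10) {
    doses <- runif(60, 0, 30)
    m <- matrix(TRUE, 6, 10)
    cv <- compute_dvh(matrix(doses, 6, 10), m)
    expect_true(all(diff(cv$volume_pct) <= 0))
    expect_equal(cv$volume_pct[1], 100)
    expect_equal(cv$dmean, mean(doses), tolerance = 1e-9)
    expect_equal(dvh_statistic(cv, "Vx", cv$dmax + 0.01), 0)
    # segment samples against the order-statistics oracle
    sv <- sample_segments(cv)
    srt <- sort(doses)
    for (j in seq_along(sv$volume_fractions)) {
      x <- sv$volume_fractions[j]
      k <- ceiling(60 * x / 100)
      lo <- srt[max(60 - k, 1)]
      hi <- srt[min(60 - k + 2, 60)]
      expect_gte(sv$dose_gy[j], lo - 0.0011)
      expect_lte(sv$dose_gy[j], hi + 0.0011)
      expect_lt(abs(sv$dose_gy[j] - oracle_dx(doses, x)),
                max(0.002, hi - lo))
    }
  }
})

test_that("coarse and fine DVH resolutions agree within a bin share", {
  set.seed(3)
  doses <- runif(200, 0, 10)
  m <- matrix(TRUE, 10, 20)
  fine <- compute_dvh(matrix(doses, 10, 20), m, resolution_gy = 0.001)
  coarse <- compute_dvh(matrix(doses, 10, 20), m, resolution_gy = 0.01,
                        resolution_cap_gy = 0.01)
  for (x in c(2.2, 5.01, 7.77)) {
    share <- 100 * mean(abs(doses - x) <= 0.01)
    expect_lte(abs(dvh_statistic(fine, "Vx", x) -
                   dvh_statistic(coarse, "Vx", x)), share + 1e-9)
  }
})

test_that("DVH files round-trip and malformed files fail loudly", {
  m <- matrix(TRUE, 2, 2)
  curves <- list(compute_dvh(matrix(c(1, 2, 3, 4), 2, 2), m,
                             structure = "ptv"),
                 compute_dvh(matrix(c(5, 5, 7, 9), 2, 2), m,
                             structure = "oar"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_dvh_file(curves, path)
  back <- read_dvh_file(path)
  expect_named(back, c("ptv", "oar"))
  for (i in 1:2) {
    expect_equal(back[[i]]$dose_gy, curves[[i]]$dose_gy, tolerance = 1e-8)
    expect_equal(back[[i]]$volume_pct, curves[[i]]$volume_pct,
                 tolerance = 1e-8)
    expect_equal(back[[i]]$dmean, curves[[i]]$dmean, tolerance = 1e-8)
  }

  # hand-written block with known values
  hand <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("Structure: rect", "Dmin: 1", "Dmax: 4", "Dmean: 2.5",
               "dose_gy,volume_pct", "0,100", "2,75", "4,25", ""), hand)
  hb <- read_dvh_file(hand)
  expect_equal(hb$rect$dmin, 1)
  expect_equal(hb$rect$dmean, 2.5)
  expect_equal(hb$rect$volume_pct, c(100, 75, 25))

  # missing Dmean header
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("Structure: rect", "Dmin: 1", "Dmax: 4",
               "dose_gy,volume_pct", "0,100", ""), bad)
  expect_error(read_dvh_file(bad), "Dmean")

  # duplicate structure names
  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(rep(c("Structure: a", "Dmin: 1", "Dmax: 2", "Dmean: 1.5",
                   "dose_gy,volume_pct", "0,100", ""), 2), dup)
  expect_error(read_dvh_file(dup), "duplicate")
  expect_error(write_dvh_file(list(curves[[1]], curves[[1]]),
                              withr::local_tempfile()), "duplicate")
})

test_that("supersampled DVH evaluation agrees with the native grid", {
  ph <- generate_phantom(tiny_spec())
  gs <- ph$structures$grid_shape
  vox <- ph$structures$voxel_size_mm
  # smooth planar dose field: partial-volume differences are bounded by
  # the gradient times one voxel
  grad <- c(0.2, 0.1)  # Gy per mm
  pts <- outer((seq_len(gs[1]) - 0.5) * vox * grad[1],
               (seq_len(gs[2]) - 0.5) * vox * grad[2], "+")
  s1 <- dvh_sampler(ph$structures, roles = c("target", "oar"), factor = 1L)
  s3 <- dvh_sampler(ph$structures, roles = c("target", "oar"), factor = 3L)
  c1 <- s1(pts); c3 <- s3(pts)
  bound <- sqrt(sum(grad^2)) * vox
  for (s in names(c1)) {
    expect_lt(abs(c1[[s]]$dmean - c3[[s]]$dmean), bound)
    expect_lt(abs(c1[[s]]$dmax - c3[[s]]$dmax), bound)
    expect_lt(abs(dvh_statistic(c1[[s]], "Dx", 50) -
                  dvh_statistic(c3[[s]], "Dx", 50)), bound)
  }
})
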