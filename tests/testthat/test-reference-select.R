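test_that("ray casting returns sorted boundary crossings", {
  circ <- circle_contour(c(0, 0), 1)
  for (a in c(0, 33.5, 90, 210))
    expect_equal(ray_intercepts(circ, c(0, 0), a), 1, tolerance = 1e-3)

  # origin outside a unit square, ray through it: entry then exit
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0, 0))
  r <- ray_intercepts(sq, c(-1, 0.5), 0)
  expect_equal(r, c(1, 2), tolerance = 1e-9)
  # ray missing the contour
  expect_length(ray_intercepts(sq, c(-1, 0.5), 90), 0)
  # degenerate contour
  expect_error(ray_intercepts(rbind(c(0, 0), c(1, 1), c(2, 2), c(0, 0)),
                              c(0, 0), 10), "degenerate")
})

test_that("signed differences are zero for identical cases", {
  ss <- generate_phantom(tiny_spec())$structures
  for (s in names(ss$structures)) {
    sd <- signed_difference(ss, ss, s)
    expect_equal(nrow(sd$points), 144)
    expect_true(all(sd$points$signed_diff_mm == 0))
    expect_identical(sd$max_abs_mm, 0)
  }
})

test_that("concentric circles give the analytic radial difference", {
  gs <- c(32L, 32L); vox <- 4
  mk <- function(r_ptv) structure_set(gs, vox, list(
    make_structure("external", "external", circle_contour(c(64, 64), 55),
                   gs, vox),
    make_structure("ptv", "target", circle_contour(c(64, 64), r_ptv),
                   gs, vox)))
  cur <- mk(18); ref <- mk(20)
  sd <- signed_difference(cur, ref, "ptv")
  expect_equal(nrow(sd$points), 144)          # 360 / 2.5
  expect_equal(sd$points$signed_diff_mm, rep(2, 144), tolerance = 1e-2)
  expect_error(signed_difference(cur, ref, "ptv", angle_resolution_deg = 7),
               "divide")
})

test_that("signed difference is antisymmetric and translation invariant", {
  gs <- c(32L, 32L); vox <- 4
  set.seed(21)
  for (i in 1:5) {
    th <- sort(runif(10, 0, 2 * pi))
    rad <- runif(10, 8, 14)
    poly <- cbind(64 + rad * cos(th), 64 + rad * sin(th))
    mkset <- function(shift) structure_set(gs, vox, list(
      make_structure("external", "external", circle_contour(c(64, 64), 55),
                     gs, vox),
      make_structure("ptv", "target",
                     sweep(poly, 2, -shift), gs, vox)))
    a <- mkset(c(0, 0))
    b <- mkset(c(-3.7, 2.2))   # rigidly translated polygon
    fwd <- signed_difference(a, b, "ptv")
    bwd <- signed_difference(b, a, "ptv")
    expect_equal(fwd$points$signed_diff_mm, -bwd$points$signed_diff_mm)
    # per-case centroids make the metric blind to rigid translation
    expect_equal(fwd$max_abs_mm, 0, tolerance = 1e-9)
  }
})

test_that("isotropic expansion shifts every signed difference by -delta", {
  gs <- c(32L, 32L); vox <- 4
  mk <- function(r) structure_set(gs, vox, list(
    make_structure("external", "external", circle_contour(c(64, 64), 55),
                   gs, vox),
    make_structure("ptv", "target", circle_contour(c(64, 64), r), gs, vox)))
  base <- mk(15)
  grown <- mk(15 + 2.5)
  sd0 <- signed_difference(base, base, "ptv")
  sd1 <- signed_difference(grown, base, "ptv")
  expect_equal(sd1$points$signed_diff_mm - sd0$points$signed_diff_mm,
               rep(-2.5, 144), tolerance = 1e-2)
})

test_that("candidate filtering applies site, names, volume and dose bands", {
  sp <- tiny_spec()
  lib <- generate_reference_library(sp, 1, jitter_mm = 0, seed = 1)
  case <- c(generate_phantom(sp), list(site = sp$site))
  expect_length(filter_candidates(lib, case), 1)

  other_site <- lib
  other_site[[1]]$site <- "head and neck"
  expect_length(filter_candidates(other_site, case), 0)

  hot <- lib
  hot[[1]]$prescription$dose_gy <- 78   # |78-50|/50 > 10%
  expect_length(filter_candidates(hot, case), 0)

  renamed <- lib
  names(renamed[[1]]$structures$structures)[2] <- "gtv"
  renamed[[1]]$structures$structures[[2]]$name <- "gtv"
  expect_length(filter_candidates(renamed, case), 0)

  expect_error(filter_candidates(list(), case), "empty")
})

test_that("reference selection enforces thresholds and ranks by score", {
  sp <- tiny_spec()
  case <- c(generate_phantom(sp), list(site = sp$site))
  identical_ref <- generate_reference_library(sp, 1, jitter_mm = 0, seed = 1)[[1]]

  sel <- select_reference(list(identical_ref), case)
  expect_true(sel$found)
  expect_equal(sel$reports[[sel$reference$id]]$score_mm, 0)

  # a candidate whose skin contour is 20 mm off against a 15 mm threshold
  sp_big <- sp; sp_big$external_radius_mm <- sp$external_radius_mm + 20
  bad <- identical_ref
  bad$id <- "bad"
  bad$structures <- generate_phantom(sp_big)$structures
  thr <- default_thresholds(case$structures, large_mm = 15)
  sel2 <- select_reference(list(bad), case, thresholds = thr)
  expect_false(sel2$found)
  expect_null(sel2$reference)
  expect_match(paste(sel2$reports$bad$rejection_reasons, collapse = " "),
               "external")

  # two admissible candidates: the closer one wins
  lib2 <- list(
    local({ r <- identical_ref; r$id <- "near"
            sp2 <- sp; sp2$ptv_radius_mm <- sp$ptv_radius_mm + 1
            r$structures <- generate_phantom(sp2)$structures; r }),
    local({ r <- identical_ref; r$id <- "far"
            sp3 <- sp; sp3$ptv_radius_mm <- sp$ptv_radius_mm + 4
            r$structures <- generate_phantom(sp3)$structures; r }))
  sel3 <- select_reference(lib2, case,
                           thresholds = default_thresholds(case$structures,
                                                           small_mm = 5,
                                                           large_mm = 10),
                           volume_band = 2)
  expect_true(sel3$found)
  expect_identical(sel3$reference$id, "near")
})
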