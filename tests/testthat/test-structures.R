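test_that("boolean structure operations follow set algebra", {
  ss <- mini_set()
  ext <- ss$structures$external$mask
  A <- ss$structures$ptv$mask
  B <- ss$structures$oar$mask
  expect_identical(boolean_structure(A, A, "and", ext), A & ext)
  expect_false(any(boolean_structure(A, A, "sub", ext)))
  expect_identical(boolean_structure(A, B, "or", ext), (A | B) & ext)

  # enumerated xor on a hand-built pair of two-voxel masks
  m1 <- matrix(FALSE, 16, 16); m2 <- m1
  m1[c(100, 101)] <- TRUE          # voxels {v1, v2}
  m2[c(101, 102)] <- TRUE          # voxels {v2, v3}
  full <- matrix(TRUE, 16, 16)
  out <- boolean_structure(m1, m2, "xor", full)
  expect_identical(which(out), c(100L, 102L))

  expect_error(boolean_structure(A, matrix(FALSE, 8, 8), "and", ext),
               "grid")
  expect_error(boolean_structure(A, B, "nand", ext), "unknown")
})

test_that("boolean op identities hold on random masks", {
  ss <- mini_set()
  ext <- ss$structures$external$mask
  set.seed(42)
  for (i in 1:20) {
    A <- matrix(runif(256) < 0.3, 16, 16) & ext
    B <- matrix(runif(256) < 0.3, 16, 16) & ext
    not_a <- boolean_structure(A, op = "not", external = ext)
    not_b <- boolean_structure(B, op = "not", external = ext)
    # de Morgan: not(A or B) == not A and not B (within the external)
    expect_identical(
      boolean_structure(boolean_structure(A, B, "or", ext), op = "not",
                        external = ext),
      boolean_structure(not_a, not_b, "and", ext))
    # xor = or minus and
    expect_identical(
      boolean_structure(A, B, "xor", ext),
      boolean_structure(boolean_structure(A, B, "or", ext),
                        boolean_structure(A, B, "and", ext), "sub", ext))
    # sub(A, B) = and(A, not B)
    expect_identical(boolean_structure(A, B, "sub", ext),
                     boolean_structure(A, not_b, "and", ext))
  }
})

test_that("isodose conversion thresholds inclusively and monotonically", {
  z <- matrix(0, 4, 4)
  expect_false(any(isodose_to_structure(z, 1)))
  u <- matrix(10, 4, 4)
  expect_true(all(isodose_to_structure(u, 10)))  # >= is inclusive
  d <- matrix(c(5, 9.9, 10.0, 12), 2, 2)
  expect_identical(as.vector(isodose_to_structure(d, 10)),
                   c(FALSE, FALSE, TRUE, TRUE))
  expect_error(isodose_to_structure(d, 0), "positive")
  set.seed(7)
  r <- matrix(runif(64, 0, 20), 8, 8)
  for (lv in list(c(3, 9), c(1, 15))) {
    hi <- isodose_to_structure(r, lv[2]); lo <- isodose_to_structure(r, lv[1])
    expect_true(all(!hi | lo))  # mask(L2) subset of mask(L1)
  }
})

test_that("center of mass is the unweighted centroid of voxel centers", {
  m <- matrix(FALSE, 16, 16)
  m[3, 5] <- TRUE
  expect_equal(center_of_mass(m, 2), c((3 - 0.5) * 2, (5 - 0.5) * 2))
  m2 <- matrix(FALSE, 16, 16); m2[4:7, 9:12] <- TRUE
  expect_equal(center_of_mass(m2, 2), c(mean(c(3.5, 6.5)) * 2,
                                        mean(c(8.5, 11.5)) * 2))
  # L-shaped: voxels (1,1), (2,1), (1,2) at 2 mm
  m3 <- matrix(FALSE, 16, 16); m3[1, 1] <- m3[2, 1] <- m3[1, 2] <- TRUE
  expect_equal(center_of_mass(m3, 2), c(5 / 3, 5 / 3))
  expect_error(center_of_mass(matrix(FALSE, 4, 4), 2), "empty")
})

test_that("structure sets enforce their invariants", {
  gs <- c(16L, 16L); vox <- 2
  ext <- make_structure("external", "external", circle_contour(c(16, 16), 14),
                        gs, vox)
  tgt <- make_structure("ptv", "target", circle_contour(c(16, 16), 4), gs, vox)
  expect_error(structure_set(gs, vox, list(ext, tgt, tgt)), "unique")
  expect_error(structure_set(gs, vox, list(tgt, tgt)), "unique")
  expect_error(structure_set(gs, vox, list(
    ext, make_structure("ptv2", "target", circle_contour(c(16, 16), 4),
                        gs, vox),
    make_structure("ext2", "external", circle_contour(c(16, 16), 13),
                   gs, vox))), "exactly one")
  # structure poking outside the external contour
  out <- make_structure("oar", "oar", circle_contour(c(29, 16), 4), gs, vox)
  expect_error(structure_set(gs, vox, list(ext, tgt, out)), "outside")
})

test_that("rasterizing a structure's contour reproduces its mask", {
  ss <- generate_phantom(tiny_spec())$structures
  for (s in ss$structures)
    expect_identical(rasterize_contour(s$contour, ss$grid_shape,
                                       ss$voxel_size_mm), s$mask)
})
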