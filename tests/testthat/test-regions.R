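test_that("fovea centre is the FAZ centroid", {
  m <- matrix(FALSE, 64, 64); m[10, 20] <- TRUE
  expect_equal(unname(fovea_center(m)), c(10, 20))

  sq <- rect_mask(c(101, 101), 45:55, 45:55)   # 11x11 centred at (50, 50)
  expect_equal(unname(fovea_center(sq)), c(50, 50))

  two <- matrix(FALSE, 8, 16); two[1, 1] <- TRUE; two[1, 11] <- TRUE
  expect_equal(unname(fovea_center(two)), c(1, 6))

  expect_error(fovea_center(matrix(FALSE, 4, 4)), "no fovea reference")
})

test_that("ATC of a solid square doubles linearly and excludes lesion and FAZ", {
  shape <- c(64, 64)
  amn <- rect_mask(shape, 30:39, 30:39)               # 100 px, centroid 34.5
  atc <- build_atc(amn, scale = 2)
  expect_identical(sum(atc), 300L)                    # 20x20 - 10x10
  expect_false(any(atc & amn))
  # scaled footprint is rows/cols 25..44; carve 50 px of FAZ from the band
  faz <- rect_mask(shape, 25:29, 30:39)
  expect_identical(sum(faz), 50L)
  expect_false(any(faz & amn))
  atc2 <- build_atc(amn, faz, scale = 2)
  expect_identical(sum(atc2), 250L)
  expect_false(any(atc2 & faz))
})

test_that("ATC matches the exhaustive inverse-mapping oracle on irregular lesions", {
  withr::local_seed(7)
  for (i in 1:5) {
    amn <- random_blob_mask(c(96, 96), c(48, 48) + runif(2, -10, 10), 9)
    expect_gt(sum(amn), 30)
    expect_identical(build_atc(amn, scale = 2), atc_brute(amn, scale = 2))
    # with a FAZ in play
    faz <- disk_at(c(96, 96), c(30, 30), 8)
    if (!any(faz & amn))
      expect_identical(build_atc(amn, faz, scale = 2),
                       atc_brute(amn, faz, scale = 2))
  }
})

test_that("degenerate ATC carries diagnostics", {
  amn <- rect_mask(c(32, 32), 15:18, 15:18)
  faz <- matrix(TRUE, 32, 32)   # FAZ swallows the whole band
  expect_error(build_atc(amn, faz), "degenerate ATC.*lesion 16 px")
})

test_that("ring segment is the closed annulus through the lesion extremes", {
  shape <- c(64, 64); ctr <- c(32, 32)
  amn <- matrix(FALSE, 64, 64)
  amn[32, 42] <- TRUE   # distance 10
  amn[32, 52] <- TRUE   # distance 20
  rs <- build_ring_segment(amn, ctr)
  d <- sqrt(outer((1:64 - 32)^2, (1:64 - 32)^2, "+"))
  expect_identical(rs, d >= 10 & d <= 20 & !amn)

  # a lesion filling the whole disk around the centre leaves nothing
  disk <- disk_at(shape, ctr, 12)
  expect_error(build_ring_segment(disk, ctr), "degenerate RS")

  # single-pixel lesion: thin annulus plus warning
  one <- matrix(FALSE, 64, 64); one[32, 42] <- TRUE
  expect_warning(rs1 <- build_ring_segment(one, ctr), "degenerate")
  expect_identical(rs1, d == 10 & !one)
})

test_that("ring segment matches the brute-force distance oracle", {
  withr::local_seed(21)
  for (i in 1:4) {
    shape <- c(128, 128)
    ctr <- c(64, 64) + runif(2, -2, 2)
    amn <- random_blob_mask(shape, c(64, 64) + 60 * c(cos(i), sin(i)) * 0.9, 8)
    amn <- amn & !disk_at(shape, ctr, 12)
    expect_gt(sum(amn), 20)
    expect_identical(build_ring_segment(amn, ctr), rs_brute(amn, ctr))
  }
})

test_that("region sets satisfy the exclusion and tangency invariants", {
  withr::local_seed(33)
  for (i in 1:25) {
    shape <- c(96, 96)
    fov <- c(48, 48)
    faz <- disk_at(shape, fov, 8)
    ang <- runif(1, 0, 2 * pi)
    amn <- random_blob_mask(shape, fov + 24 * c(cos(ang), sin(ang)), 7)
    amn <- amn & !faz
    if (sum(amn) < 20) next
    rs <- region_set(label_mask(matrix(1L * amn + 2L * (faz & !amn),
                                       shape[1], shape[2])))
    expect_false(any(rs$atc & rs$amn))
    expect_false(any(rs$atc & rs$faz))
    expect_false(any(rs$rs & rs$amn))
    # tangency: annulus radii are achieved by lesion pixels
    d <- sqrt(outer((1:96 - rs$fovea_center[["row"]])^2,
                    (1:96 - rs$fovea_center[["col"]])^2, "+"))
    d_amn <- d[rs$amn]
    expect_true(all(d[rs$rs] >= min(d_amn) & d[rs$rs] <= max(d_amn)))
  }
})

test_that("ATC grows monotonically with the scale factor", {
  withr::local_seed(5)
  for (i in 1:5) {
    amn <- random_blob_mask(c(96, 96), c(48, 48), 8)
    a <- build_atc(amn, scale = 1.4)
    b <- build_atc(amn, scale = 2)
    expect_lte(sum(a), sum(b))
    expect_true(all(b[a] | amn[a]))            # ATC(1.4) within ATC(2) u lesion
  }
  # area-doubling option: sqrt(2) linear scale
  sq <- rect_mask(c(64, 64), 29:36, 29:36)
  expect_lt(sum(build_atc(sq, scale = sqrt(2))), sum(build_atc(sq, scale = 2)))
})

test_that("region construction is translation-equivariant away from borders", {
  withr::local_seed(12)
  shape <- c(128, 128)
  amn <- random_blob_mask(shape, c(60, 60), 6)
  faz <- disk_at(shape, c(75, 78), 7)
  amn <- amn & !faz
  shift <- function(m, dr, dc) {
    out <- matrix(FALSE, nrow(m), ncol(m))
    idx <- which(m, arr.ind = TRUE)
    out[cbind(idx[, 1] + dr, idx[, 2] + dc)] <- TRUE
    out
  }
  a1 <- build_atc(amn, faz, scale = 2)
  a2 <- build_atc(shift(amn, 5, -3), shift(faz, 5, -3), scale = 2)
  expect_identical(a2, shift(a1, 5, -3))
  r1 <- build_ring_segment(amn, c(75, 78))
  r2 <- build_ring_segment(shift(amn, 5, -3), c(80, 75))
  expect_identical(r2, shift(r1, 5, -3))
})

test_that("region sets export as a QC label map", {
  eye <- generate_eye(synthetic_config(seed = 3, shape = c(64, 64)))
  p <- withr::local_tempfile(fileext = ".nii.gz")
  regions_to_nifti(eye$regions, p)
  lab <- octavad:::read_nifti_matrix(p)
  expect_identical(sum(lab == 1L), sum(eye$regions$amn))
  expect_identical(sum(lab == 2L), sum(eye$regions$faz))
  expect_setequal(unique(as.vector(lab)), 0:4)
})
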