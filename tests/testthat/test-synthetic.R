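test_that("phantom generation is a pure function of its seed", {
  cfg <- synthetic_config(seed = 123, shape = c(96, 96),
                          lesion_deficit = c(CC = 0.2))
  e1 <- generate_eye(cfg)
  e2 <- generate_eye(cfg)
  for (layer in names(e1$slabs))
    expect_identical(e1$slabs[[layer]]$pixels, e2$slabs[[layer]]$pixels)
  expect_identical(e1$label_mask$labels, e2$label_mask$labels)
  expect_identical(e1$ground_truth, e2$ground_truth)
  e3 <- generate_eye(synthetic_config(seed = 124, shape = c(96, 96),
                                      lesion_deficit = c(CC = 0.2)))
  expect_false(identical(e1$slabs$CC$pixels, e3$slabs$CC$pixels))
  # generation does not disturb the caller's RNG stream
  set.seed(1); before <- rnorm(1)
  set.seed(1); invisible(generate_eye(cfg)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("lesion deficits scale the perfused fraction as configured", {
  # binomial oracle: the texture marginal is Bernoulli(p), so the lesion-mean
  # fraction should sit near (1 - deficit) * base within sampling error
  fracs <- sapply(1:6, function(i) {
    eye <- generate_eye(synthetic_config(seed = 400 + i, shape = c(384, 384),
                                         lesion_deficit = c(CC = 0.27)))
    gt <- eye$ground_truth
    gt$true_fraction[gt$layer == "CC" & gt$region == "AMN"]
  })
  expect_lt(abs(mean(fracs) - 0.73 * 0.42), 0.05)
})

test_that("zero-deficit phantoms have matched lesion and control perfusion", {
  # per-eye differences are sampling noise of the correlated texture (sd up
  # to ~0.08 for a ~3000 px lesion); the mean over eyes must sit near zero
  diffs <- sapply(1:5, function(i) {
    eye <- generate_eye(synthetic_config(seed = 520 + i))   # 512 x 512
    gt <- eye$ground_truth
    expect_gt(sum(eye$regions$amn), 2000)
    sapply(c("ICP", "DCP", "CC"), function(layer)
      gt$true_fraction[gt$layer == layer & gt$region == "AMN"] -
        gt$true_fraction[gt$layer == layer & gt$region == "ATC"])
  })
  expect_true(all(abs(rowMeans(diffs)) < 0.1))
})

test_that("increasing the deficit strictly lowers lesion perfusion", {
  lesion_frac <- function(deficit) {
    eye <- generate_eye(synthetic_config(seed = 77, shape = c(128, 128),
                                         lesion_deficit = c(CC = deficit)))
    gt <- eye$ground_truth
    gt$true_fraction[gt$layer == "CC" & gt$region == "AMN"]
  }
  f <- vapply(c(0, 0.3, 0.6, 1), lesion_frac, numeric(1))
  expect_true(all(diff(f) < 0))
  expect_identical(f[4], 0)        # full deficit leaves no perfusion
})

test_that("the FAZ is avascular in retinal but not choroidal layers", {
  eye <- generate_eye(synthetic_config(seed = 9, shape = c(128, 128),
                                       noise_sd = 0,
                                       svp_large_vessels = list(count = 0)))
  faz <- eye$regions$faz
  bg <- eye$config$background_intensity
  for (layer in c("SVP", "ICP", "DCP"))
    expect_true(all(eye$slabs[[layer]]$pixels[faz] == bg))
  expect_gt(mean(eye$slabs$CC$pixels[faz] > bg), 0.2)
})

test_that("invalid lesion placement is a config error", {
  cfg <- synthetic_config(seed = 1, shape = c(96, 96),
                          lesion = list(eccentricity_px = 5))
  expect_error(generate_eye(cfg), "lesion overlaps the FAZ")
  expect_error(generate_enface(cfg), "lesion overlaps the FAZ")
  cfg2 <- synthetic_config(seed = 1, shape = c(96, 96),
                           opl_displacement_px = 60)
  expect_error(generate_enface(cfg2), "out of frame")
})

test_that("en-face displacement calibration hits a target Dice", {
  r <- 24
  d89 <- displacement_for_dice(r, 0.89)
  d65 <- displacement_for_dice(r, 0.65)
  expect_gt(d65, d89)
  cfg <- synthetic_config(seed = 6, shape = c(256, 256),
                          lesion = list(axes = c(r, r)),
                          ez_displacement_px = d89,
                          opl_displacement_px = d65)
  enf <- generate_enface(cfg)
  recs <- enface_overlap_analysis(enf$ir, enf$ez, enf$opl)
  # displacements are snapped to integer pixel offsets, so compare against
  # the analytic lens Dice at the offset actually realised
  realized <- function(m) {
    ci <- colMeans(which(enf$ir, arr.ind = TRUE))
    cm <- colMeans(which(m, arr.ind = TRUE))
    sqrt(sum((cm - ci)^2))
  }
  ez <- recs$dice[recs$pair == "EZ_vs_IR"]
  opl <- recs$dice[recs$pair == "OPL_vs_IR"]
  expect_lt(abs(ez - circle_dice(realized(enf$ez), r)), 0.02)
  expect_lt(abs(opl - circle_dice(realized(enf$opl), r)), 0.02)
  expect_lt(abs(ez - 0.89), 0.05)
  expect_lt(abs(opl - 0.65), 0.05)
})

test_that("cohorts jitter geometry but stay analyzable", {
  co <- generate_cohort(4, synthetic_config(seed = 2, shape = c(96, 96)),
                        seed = 55)
  expect_length(co$eyes, 4)
  areas <- vapply(co$eyes, function(e) sum(e$regions$amn), integer(1))
  expect_gt(length(unique(areas)), 1)     # geometry actually varies
  for (e in co$eyes) {
    expect_false(any(e$regions$amn & e$regions$faz))
    expect_gt(sum(e$regions$atc), 0)
  }
  # determinism at the cohort level
  co2 <- generate_cohort(4, synthetic_config(seed = 2, shape = c(96, 96)),
                         seed = 55)
  expect_identical(co$eyes[[3]]$slabs$CC$pixels, co2$eyes[[3]]$slabs$CC$pixels)
  expect_error(generate_cohort(1, synthetic_config(shape = c(96, 96))),
               "n_eyes >= 2")
})

test_that("a minimal two-eye cohort runs end to end with a df = 1 warning", {
  co <- generate_cohort(2, synthetic_config(seed = 13, shape = c(96, 96)))
  v <- quantify_cohort(co, quantify_config(svp_sigmas = c(2, 3)))
  expect_identical(nrow(v), 30L)
  w <- testthat::capture_warnings(res <- summarize_cohort(v))
  expect_true(any(grepl("n = 2", w)))
  expect_identical(unique(res$n_eyes), 2L)
})
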