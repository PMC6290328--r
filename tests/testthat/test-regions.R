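# region_quantification: labels, geometric partition, regional means,
# tip-vs-core comparisons.

test_that("load_region_labels: contract errors and degenerate tip", {
  ph <- generate_confocal_volume(small_phantom_spec(seed = 1))
  m <- ph$organ_mask
  # tip mask covering no organ voxel -> error
  far <- array(FALSE, dim(m$mask)); far[1, 1, 1] <- TRUE
  expect_error(load_region_labels(m, far), "does not intersect")
  expect_error(load_region_labels(m, array(FALSE, c(2, 2, 2))), "grid")
  # tip mask = entire organ -> core empty, ratio undefined and flagged NA
  lab <- load_region_labels(m, m$mask)
  expect_equal(sum(lab$labels == 1L), 0)
  s <- summarize_regions(ph$volume, lab)
  expect_true(is.na(s$tip_core_ratio))
  expect_true(is.na(s$core_mean))
  expect_equal(s$core_n, 0)
})

test_that("ground-truth tip mask reproduces the generator labels exactly", {
  ph <- generate_confocal_volume(small_phantom_spec(seed = 2))
  tip_mask <- ph$region_labels$labels == 2L
  lab <- load_region_labels(ph$organ_mask, tip_mask)
  expect_identical(lab$labels, ph$region_labels$labels)
})

test_that("label partition invariant holds after every labeling operation", {
  ph <- generate_confocal_volume(small_phantom_spec(seed = 3))
  m <- ph$organ_mask$mask
  for (lab in list(load_region_labels(ph$organ_mask, ph$region_labels$labels == 2L),
                   default_tip_partition(ph$organ_mask,
                                         ph$truth$cord_landmark_um, 0.3,
                                         ph$volume$spacing_um))) {
    expect_true(all(lab$labels[!m] == 0L))
    expect_true(all(lab$labels[m] %in% 1:2))
  }
})

test_that("geometric partition: fraction limits and landmark distance check", {
  ph <- generate_confocal_volume(small_phantom_spec(seed = 4))
  sp <- ph$volume$spacing_um
  lm <- ph$truth$cord_landmark_um
  lab0 <- default_tip_partition(ph$organ_mask, lm, 0, sp)
  expect_equal(sum(lab0$labels == 2L), 0)
  lab1 <- default_tip_partition(ph$organ_mask, lm, 1, sp)
  expect_equal(sum(lab1$labels == 1L), 0)
  expect_error(default_tip_partition(ph$organ_mask, c(0, 0, 0), 0.25, sp,
                                     max_landmark_dist_um = 5), "landmark")
  expect_error(default_tip_partition(ph$organ_mask, lm, 1.5, sp), "fraction")
})

test_that("geometric partition agrees with generator truth at fraction 0.25", {
  for (s in c(1, 5)) {
    ph <- generate_confocal_volume(small_phantom_spec(seed = s))
    lab <- default_tip_partition(ph$organ_mask, ph$truth$cord_landmark_um,
                                 0.25, ph$volume$spacing_um)
    m <- ph$organ_mask$mask
    agree <- mean(lab$labels[m] == ph$region_labels$labels[m])
    expect_gte(agree, 0.95)
  }
})

test_that("regional means: constant field, hand-computed toy, oracle equality", {
  # constant AR channel c -> tip mean = core mean = c, ratio 1
  ph <- generate_confocal_volume(small_phantom_spec(
    seed = 1, ar_levels = c(core = 777, tip = 777, muscle = 777,
                            background = 777), noise_sigma = 0))
  s <- summarize_regions(ph$volume, ph$region_labels)
  expect_equal(s$tip_mean, 777); expect_equal(s$core_mean, 777)
  expect_equal(s$tip_core_ratio, 1)

  # 4-voxel toy: tip {10, 20}, core {5, 15} -> 15, 10, ratio 1.5
  ar <- array(0, c(1, 2, 2))
  ar[1, 1, 1] <- 10; ar[1, 2, 1] <- 20; ar[1, 1, 2] <- 5; ar[1, 2, 2] <- 15
  labs <- array(c(2L, 2L, 1L, 1L), c(1, 2, 2))
  v <- confocal_volume(list(ar * 0, ar), c("nuclear", "ar"), c(1, 1, 1))
  s <- summarize_regions(v, region_labels(labs))
  expect_equal(s$tip_mean, 15); expect_equal(s$core_mean, 10)
  expect_equal(s$tip_core_ratio, 1.5)

  # brute-force sum/count oracle on a random phantom
  ph <- generate_confocal_volume(small_phantom_spec(seed = 9))
  arr <- get_channel(ph$volume, "ar")
  lab <- ph$region_labels$labels
  s <- summarize_regions(ph$volume, ph$region_labels)
  expect_equal(s$tip_mean, sum(arr[lab == 2]) / sum(lab == 2), tolerance = 1e-12)
  expect_equal(s$core_mean, sum(arr[lab == 1]) / sum(lab == 1), tolerance = 1e-12)
})

test_that("contrast phantom ratio is recovered within 5% at 10% noise", {
  for (s in 1:3) {
    ph <- generate_confocal_volume(contrast_phantom_spec(
      seed = s, shape = c(z = 24, y = 48, x = 48),
      spacing_um = c(z = 2, y = 1.5, x = 1.5),
      organ_semiaxes_um = c(z = 18, y = 14, x = 14),
      cord_length_um = 8, cord_radius_um = 4))
    expect_equal(ph$truth$tip_core_ratio, 1.5, tolerance = 1e-9)
    s1 <- summarize_regions(ph$volume, ph$region_labels)
    expect_lt(abs(s1$tip_core_ratio - 1.5) / 1.5, 0.05)
  }
})

test_that("compare_regions: exact-null p, grouping, and skip behaviour", {
  co <- generate_intensity_cohort(n_specimens = 6, tip_core_ratio = 1,
                                  noise_rel = 0, seed = 3)
  res <- compare_regions(co, method = "permutation")
  expect_equal(res[["LE/wt:E21"]]$p, 1)   # tip = core exactly
  co2 <- rbind(generate_intensity_cohort(n_specimens = 5, seed = 1),
               generate_intensity_cohort(n_specimens = 5, strain = "LE/orl",
                                         tip_core_ratio = 1, seed = 2))
  res2 <- compare_regions(co2)
  expect_named(res2, c("LE/wt:E21", "LE/orl:E21"))
  expect_warning(compare_regions(generate_intensity_cohort(n_specimens = 1)),
                 "skipped")
})

test_that("tip:core ratio estimator bias is below 2% over repeated phantoms", {
  ratios <- vapply(1:8, function(s) {
    ph <- generate_confocal_volume(contrast_phantom_spec(
      seed = 100 + s, noise_frac = 0.05,
      shape = c(z = 24, y = 48, x = 48),
      spacing_um = c(z = 2, y = 1.5, x = 1.5),
      organ_semiaxes_um = c(z = 18, y = 14, x = 14),
      cord_length_um = 8, cord_radius_um = 4))
    summarize_regions(ph$volume, ph$region_labels)$tip_core_ratio
  }, 0)
  expect_lt(abs(mean(ratios) - 1.5) / 1.5, 0.02)
})
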