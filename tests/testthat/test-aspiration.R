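# aspiration_mechanics: wall function, modulus inversion, position bands,
# regional comparisons. Arithmetic oracles are computed independently here.

phi_oracle <- function(a, w, form = "product") {
  r <- w / a
  if (form == "product") (1 / 2) * (1 + r) * (1 + r / 2) * log(8 / r)
  else (1 + r / 2) * log(8 / r) / (2 * (1 + r))
}

test_that("wall function matches the arithmetic oracle on the fixed points", {
  expect_equal(wall_function(40, 8), 0.5 * 1.2 * 1.1 * log(40), tolerance = 1e-12)
  expect_equal(wall_function(40, 8), 2.4347, tolerance = 1e-4)
  expect_equal(wall_function(40, 20), 0.5 * 1.5 * 1.25 * log(16), tolerance = 1e-12)
  expect_equal(wall_function(40, 20), 2.5993, tolerance = 1e-4)
})

test_that("wall function: scale invariance, both forms, domain errors", {
  set.seed(5)
  for (form in c("product", "ratio")) {
    a <- runif(50, 10, 100); w <- a * runif(50, 0.02, 0.99)
    expect_equal(wall_function(a, w, form), phi_oracle(a, w, form),
                 tolerance = 1e-12)
    k <- runif(50, 0.1, 10)
    expect_equal(wall_function(a, w, form), wall_function(k * a, k * w, form),
                 tolerance = 1e-12)
    expect_true(all(is.finite(wall_function(a, w, form))))
  }
  expect_error(wall_function(40, 320), "w < 8a")
  expect_error(wall_function(-1, 2), "a > 0")
  expect_error(wall_function(40, 0), "w > 0")
})

test_that("apparent modulus reproduces the protocol-value example and scalings", {
  m <- data.frame(a_um = 40, w_um = 8, dp_kpa = 70, L_um = 100)
  res <- apparent_modulus(m)
  expect_equal(res$E_app_kpa, 8400 / (2 * pi * 100 * phi_oracle(40, 8)),
               tolerance = 1e-12)
  expect_equal(res$E_app_kpa, 5.491, tolerance = 1e-3)
  # linear in dp, inverse in L
  m2 <- m; m2$dp_kpa <- 140
  expect_equal(apparent_modulus(m2)$E_app_kpa, 2 * res$E_app_kpa, tolerance = 1e-12)
  m3 <- m; m3$L_um <- 200
  expect_equal(apparent_modulus(m3)$E_app_kpa, res$E_app_kpa / 2, tolerance = 1e-12)
  expect_error(apparent_modulus(data.frame(a_um = 40, w_um = 8, dp_kpa = 70,
                                           L_um = 0)), "L_um")
  expect_error(apparent_modulus(data.frame(a_um = 40, w_um = 8, L_um = 1)),
               "dp_kpa")
})

test_that("E_app is monotone in dp, L and Phi", {
  set.seed(6)
  base <- data.frame(a_um = 40, w_um = 8, dp_kpa = 70, L_um = 150)
  e0 <- apparent_modulus(base)$E_app_kpa
  for (i in 1:10) {
    up <- base; up$dp_kpa <- base$dp_kpa * (1 + runif(1))
    expect_gt(apparent_modulus(up)$E_app_kpa, e0)
    dn <- base; dn$L_um <- base$L_um * (1 + runif(1))
    expect_lt(apparent_modulus(dn)$E_app_kpa, e0)
    # larger w -> larger Phi (product form) -> smaller E
    wd <- base; wd$w_um <- base$w_um * (1 + runif(1))
    expect_lt(apparent_modulus(wd)$E_app_kpa, e0)
  }
})

test_that("position bands follow the height-fraction protocol", {
  expect_equal(assign_position(0.10), "base")
  expect_equal(assign_position(0.50), "midportion")
  expect_equal(assign_position(0.30), NA_character_)
  expect_equal(assign_position(c(0, 0.25, 0.40, 0.60, 0.75, 1)),
               c("base", "base", "midportion", "midportion", "tip", "tip"))
  expect_equal(assign_position(c(0.26, 0.39, 0.61, 0.74)),
               rep(NA_character_, 4))
  expect_error(assign_position(1.2), "\\[0, 1\\]")
  expect_error(assign_position(-0.1), "\\[0, 1\\]")
})

test_that("regional analysis: null F, hand-computed F, and skip behaviour", {
  mk <- function(vals, pos, day = "E19") {
    data.frame(E_app_kpa = vals, strain = "LE/wt", day = day, position = pos)
  }
  # identical position groups -> F = 0, p = 1
  r <- mk(rep(2, 9), rep(c("base", "midportion", "tip"), each = 3))
  out <- suppressWarnings(regional_analysis(r))
  expect_equal(out$region_tests[["LE/wt:E19"]]$statistic, 0)
  expect_equal(out$region_tests[["LE/wt:E19"]]$p, 1)
  # the fixed toy groups -> F = 3 exactly
  r <- mk(c(1, 2, 3, 2, 3, 4, 3, 4, 5),
          rep(c("base", "midportion", "tip"), each = 3))
  out <- suppressWarnings(regional_analysis(r))
  expect_equal(out$region_tests[["LE/wt:E19"]]$statistic, 3.0)
  expect_equal(nrow(out$pairwise), 3)
  # day contrast runs on both days; single-observation cells are skipped
  r2 <- rbind(mk(c(1, 2, 3, 2, 3, 4, 3, 4, 5),
                 rep(c("base", "midportion", "tip"), each = 3), "E19"),
              mk(c(2, 3, 4, 4, 5, 6, 4, 5, 6),
                 rep(c("base", "midportion", "tip"), each = 3), "E21"))
  out2 <- regional_analysis(r2)
  expect_length(out2$day_tests, 3)
  expect_s3_class(out2$day_tests[["LE/wt:midportion"]], "group_comparison")
  out3 <- regional_analysis(r2, day_test = "mann_whitney")
  expect_match(out3$day_tests[["LE/wt:tip"]]$test, "Mann-Whitney")
  expect_warning(regional_analysis(mk(c(1, 2), c("base", "tip"))), "skipped")
})

test_that("forward generator + apparent_modulus is the identity without noise", {
  spec <- aspiration_cohort_spec(n_per_group = 4, noise_rel = 0, seed = 3)
  cohort <- generate_aspiration_cohort(spec)
  expect_true(all(cohort$L_um > 0))
  res <- apparent_modulus(cohort)
  expect_equal(res$E_app_kpa, cohort$true_modulus_kpa, tolerance = 1e-12)
  # doubling E_true halves L, all else fixed
  tab <- default_modulus_table()
  s1 <- aspiration_cohort_spec(moduli = tab, n_per_group = 2, noise_rel = 0,
                               pipette_radius_um = c(mean = 40, sd = 0), seed = 9)
  tab2 <- tab; tab2$modulus_kpa <- tab$modulus_kpa * 2
  s2 <- aspiration_cohort_spec(moduli = tab2, n_per_group = 2, noise_rel = 0,
                               pipette_radius_um = c(mean = 40, sd = 0), seed = 9)
  expect_equal(generate_aspiration_cohort(s1)$L_um,
               2 * generate_aspiration_cohort(s2)$L_um, tolerance = 1e-12)
  # both wall-function readings invert consistently
  for (form in c("product", "ratio")) {
    sp <- aspiration_cohort_spec(n_per_group = 2, noise_rel = 0,
                                 phi_form = form, seed = 5)
    co <- generate_aspiration_cohort(sp)
    expect_equal(apparent_modulus(co, phi_form = form)$E_app_kpa,
                 co$true_modulus_kpa, tolerance = 1e-12)
  }
})

test_that("aspiration cohort: determinism, validation, position bands", {
  spec <- aspiration_cohort_spec(n_per_group = 3, seed = 3)
  a <- generate_aspiration_cohort(spec)
  b <- generate_aspiration_cohort(spec)
  expect_identical(a, b)
  expect_true(all(a$height_fraction >= 0 & a$height_fraction <= 1))
  expect_identical(assign_position(a$height_fraction), a$position)
  bad <- default_modulus_table(); bad$modulus_kpa[1] <- -1
  expect_error(aspiration_cohort_spec(moduli = bad), "positive")
})
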