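test_that("ring weights tile the disc with the closed-form area fractions", {
  p <- canonical_profile(15)
  d <- ring_weights(p, ring_thickness = 0.1)
  expect_length(d$weights, 90)
  expect_lt(abs(sum(d$weights) - 1), 1e-9)
  expect_equal(d$weights[1], 0.1^2 / 9^2, tolerance = 1e-12)
  expect_true(all(d$weights >= 0))

  two <- ring_weights(p, ring_thickness = 4.5)
  expect_equal(two$weights, c(0.25, 0.75), tolerance = 1e-12)

  set.seed(11)
  for (i in 1:10)
    expect_lt(abs(sum(ring_weights(random_profile())$weights) - 1), 1e-9)

  expect_error(ring_weights(p, ring_thickness = 10), "exceeds r_max")
  expect_error(ring_weights(p, ring_thickness = 0), "> 0 mm")
})

test_that("grid survival reduces to uniform-field survival on a flat profile", {
  flat <- make_single_hole_profile(canonical_geometry(), 8,
                                   profile_model_params(valley_fraction = 1))
  semi <- derive_lq_params(0.4, 10)
  expect_equal(grid_survival(ring_weights(flat), semi), sf_lq(semi, 8),
               tolerance = 1e-14)
  hk <- fit_hk_params(semi)
  expect_equal(grid_survival(ring_weights(flat), hk), sf_hk(hk, 8),
               tolerance = 1e-14)
})

test_that("grid survival equals the hand-computed two-ring mixture", {
  # step profile: 20 Gy inside 4.5 mm, 4.4 Gy outside, rings split at 4.5 mm
  radii <- c(0, 4.4999, 4.5001, 9)
  doses <- c(20, 20, 4.4, 4.4)
  p <- read_profile_csv({
    f <- tempfile(fileext = ".csv")
    writeLines(c("r_mm,dose_Gy", paste(radii, doses, sep = ",")), f)
    f
  })
  semi <- derive_lq_params(0.4, 10)
  got <- grid_survival(ring_weights(p, ring_thickness = 4.5), semi)
  hand <- 0.25 * exp(-semi$alpha * 20 - semi$beta * 400) +
    0.75 * exp(-semi$alpha * 4.4 - semi$beta * 4.4^2)
  expect_equal(got, hand, tolerance = 1e-12)
})

test_that("model/parameter mismatches are rejected", {
  p <- canonical_profile(15)
  semi <- derive_lq_params(0.4, 10)
  d <- ring_weights(p)
  expect_error(grid_survival(d, semi, model = "HK"), "requires hk_params")
  expect_error(grid_survival(d, fit_hk_params(semi), model = "LQ"),
               "requires lq_params")
  expect_error(grid_survival(d, list()), "lq_params or hk_params")
})

test_that("ring refinement from 0.1 mm to 0.05 mm leaves survival unchanged", {
  p <- make_single_hole_profile(canonical_geometry(), 15,
                                profile_model_params(radial_step = 0.05))
  semi <- derive_lq_params(0.4, 10)
  s1 <- grid_survival(ring_weights(p, 0.1), semi)
  s2 <- grid_survival(ring_weights(p, 0.05), semi)
  expect_lt(abs(s1 - s2) / s2, 0.001)
})

test_that("EUD inverts uniform-field survival for both models", {
  semi <- derive_lq_params(0.4, 10)
  expect_equal(solve_eud(sf_lq(semi, 10), semi), 10, tolerance = 1e-9)
  expect_equal(solve_eud(semi$sf2, semi), 2, tolerance = 1e-9)
  hk <- fit_hk_params(semi)
  for (E in c(1.7, 6, 14, 22))
    expect_equal(solve_eud(sf_hk(hk, E), hk), E, tolerance = 1e-7)
  expect_error(solve_eud(1, semi), "\\(0, 1\\)")
  expect_error(solve_eud(0, semi), "\\(0, 1\\)")
})

test_that("EUD is bracketed by the profile's minimum and maximum dose", {
  set.seed(13)
  for (i in 1:15) {
    p <- random_profile()
    tum <- derive_lq_params(runif(1, 0.15, 0.7), 10)
    for (model in c("LQ", "HK")) {
      res <- therapeutic_ratio(p, tum, model = model)
      expect_gte(res$eud, min(p$doses) - 1e-9)
      expect_lte(res$eud, max(p$doses) + 1e-9)
      expect_lte(res$eud, res$peak_dose + 1e-9)
    }
  }
})

test_that("a flat field has therapeutic ratio 1 for every line and model", {
  flat <- make_single_hole_profile(canonical_geometry(), 15,
                                   profile_model_params(valley_fraction = 1))
  for (i in seq_len(nrow(table1_printed))) {
    tum <- derive_lq_params(table1_printed$sf2[i],
                            table1_printed$alpha_beta[i])
    expect_equal(therapeutic_ratio(flat, tum, model = "LQ")$tr, 1,
                 tolerance = 1e-12)
    expect_equal(therapeutic_ratio(flat, tum, model = "HK")$tr, 1,
                 tolerance = 1e-9)
  }
})

test_that("ring sums agree with the continuous-integration oracle", {
  set.seed(17)
  nor <- derive_lq_params(0.4, 2.5)
  for (i in 1:50) {
    p <- random_profile()
    tum <- derive_lq_params(runif(1, 0.15, 0.7), 10)
    sf_rings <- grid_survival(ring_weights(p), tum)
    sf_oracle <- trapz_grid_sf(p, tum$alpha, tum$beta)
    expect_lt(abs(sf_rings - sf_oracle) / sf_oracle, 0.005)
  }
  # and through the full TR pipeline on the canonical field
  p20 <- canonical_profile(20)
  res <- derive_lq_params(0.5, 10)
  expect_lt(abs(therapeutic_ratio(p20, res)$tr - trapz_tr(p20, res, nor)) /
              trapz_tr(p20, res, nor), 0.005)
})

test_that("TR grows with tumour SF2 and, for SF2 >= 0.4, with peak dose", {
  nor <- derive_lq_params(0.4, 2.5)
  sf2_grid <- seq(0.2, 0.64, by = 0.04)
  for (P in c(10, 15, 20)) {
    p <- canonical_profile(P)
    trs <- vapply(sf2_grid, function(s)
      therapeutic_ratio(p, derive_lq_params(s, 10), nor)$tr, numeric(1))
    expect_true(all(diff(trs) > 0))
  }
  for (s2 in c(0.4, 0.5, 0.55)) {
    trs <- vapply(c(10, 15, 20), function(P)
      therapeutic_ratio(canonical_profile(P),
                        derive_lq_params(s2, 10), nor)$tr, numeric(1))
    expect_true(all(diff(trs) > 0))
  }
})

test_that("TR results expose consistent intermediate quantities", {
  res <- therapeutic_ratio(canonical_profile(20), derive_lq_params(0.5, 10))
  expect_equal(res$tr, res$sf_normal_grid / res$sf_normal_eud,
               tolerance = 1e-12)
  expect_gt(res$eud, 0)
  expect_lte(res$eud, res$peak_dose)
})
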