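test_that("site_rate reproduces the band-model arithmetic", {
  est <- site_rate(0.09)
  expect_equal(est$point, 0.72)
  # "about three-quarters": the linear estimate rounds to 3/4
  expect_lte(abs(est$point - 0.75), 0.03 + 1e-12)
  expect_equal(est$inputs$band_fraction, 0.125)
  pois <- site_rate(0.09, method = "poisson_inversion")
  expect_equal(pois$point, -log(0.91) / 0.125, tolerance = 1e-12)
  expect_equal(pois$point, 0.7544854, tolerance = 1e-6)
  expect_equal(site_rate(0)$point, 0)
  expect_equal(site_rate(0, method = "poisson_inversion")$point, 0)
})

test_that("site_rate propagates Wilson uncertainty and validates input", {
  est <- site_rate(0.09, n_cells = 100)
  w <- prop.test(9, 100, correct = FALSE)$conf.int  # Wilson oracle
  expect_equal(est$ci_low, w[1] / 0.125, tolerance = 1e-9)
  expect_equal(est$ci_high, w[2] / 0.125, tolerance = 1e-9)
  expect_error(site_rate(1, method = "poisson_inversion"), "divergence")
  expect_error(site_rate(-0.1), "invalid input")
  expect_error(site_rate(0.09, pancake_cell(24, 0), band_height = 0),
               "band fraction is zero")
})

test_that("linear and poisson inversion agree to first order at small f", {
  for (f in c(1e-5, 1e-4, 1e-3)) {
    ratio <- site_rate(f)$point /
      site_rate(f, method = "poisson_inversion")$point
    expect_lt(abs(ratio - 1), 2 * f)
  }
})

test_that("the profile-span correction has the closed form and edge cases", {
  # 0.38 profiles per section at the default geometry corrects to 1.0
  expect_equal(mvbs_per_mcmv(0.38, 1080, 367, 70)$point, 1.0)
  expect_equal(mvbs_per_mcmv(0, 1080, 367, 70)$point, 0)
  # container and object of equal size span equally many sections
  expect_equal(mvbs_per_mcmv(0.7, 500, 500, 70)$point, 0.7)
  expect_error(mvbs_per_mcmv(0.4, 367, 1080, 70), "invalid geometry")
})

test_that("estimators are invariant to uniform length rescaling", {
  withr::with_seed(3, {
    for (i in 1:10) {
      s <- runif(1, 0.2, 50)
      expect_equal(site_rate(0.09, pancake_cell(24 * s, 4 * s),
                             band_height = 2 * s)$point, 0.72)
      expect_equal(mvbs_per_mcmv(0.38, 1.08 * s, 0.367 * s, 0.07 * s)$point,
                   mvbs_per_mcmv(0.38, 1080, 367, 70)$point,
                   tolerance = 1e-12)
    }
  })
})

test_that("proportion_ci matches the Wilson score interval", {
  cases <- list(c(9, 100), c(1, 30), c(25, 60), c(43, 100), c(65, 100))
  for (cs in cases) {
    est <- proportion_ci(cs[1], cs[2])
    w <- prop.test(cs[1], cs[2], correct = FALSE)$conf.int
    expect_equal(est$point, cs[1] / cs[2])
    expect_equal(est$ci_low, w[1], tolerance = 1e-9)
    expect_equal(est$ci_high, w[2], tolerance = 1e-9)
  }
  # frozen closed-form values for the headline 9/100 survey
  est <- proportion_ci(9, 100)
  expect_equal(est$ci_low, 0.0480725, tolerance = 1e-6)
  expect_equal(est$ci_high, 0.1622621, tolerance = 1e-6)
  # boundary and symmetry
  zero <- proportion_ci(0, 50)
  expect_equal(zero$point, 0)
  expect_equal(zero$ci_low, 0)
  half <- proportion_ci(50, 100)
  expect_equal(half$ci_low + half$ci_high, 1, tolerance = 1e-12)
  expect_error(proportion_ci(5, 0), "invalid input")
  expect_error(proportion_ci(11, 10), "invalid input")
})

test_that("bootstrap interval for the correction brackets the estimate", {
  withr::with_seed(5, {
    pm <- data.frame(mcmv_id = 1:200,
                     n_mcmv_profiles = 16 + rpois(200, 1),
                     n_mvb_profiles = rpois(200, 6))
  })
  nbar <- sum(pm$n_mvb_profiles) / sum(pm$n_mcmv_profiles)
  est1 <- mvbs_per_mcmv(nbar, 1080, 367, 70, profile_counts = pm, seed = 11)
  est2 <- mvbs_per_mcmv(nbar, 1080, 367, 70, profile_counts = pm, seed = 11)
  expect_identical(est1, est2)
  expect_lte(est1$ci_low, est1$point)
  expect_gte(est1$ci_high, est1$point)
  expect_lt(est1$ci_high - est1$ci_low, est1$point)  # informative width
})

test_that("estimate containers enforce ordering invariants", {
  expect_error(ev_estimate("proportion", -0.1), "point >= 0")
  expect_error(ev_estimate("proportion", 0.5, 0.6, 0.7), "ci_low <= point")
})
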