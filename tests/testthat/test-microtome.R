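test_that("an empty scene sections to empty observations with NaN summaries", {
  obs <- section_scene(fake_scene(), mode = "serial")
  expect_identical(nrow(obs$profiles), 0L)
  cnt <- tabulate_counts(obs)
  expect_true(is.nan(cnt$summary$f_sites))
  expect_true(is.nan(cnt$summary$mvb_per_mcmv_profile))
  expect_true(is.nan(cnt$summary$omega_fraction))
  expect_true(is.nan(cnt$summary$ilv_fraction))
})

test_that("the worked single-body case gives 6 MVB slabs of 16 MCMV slabs", {
  # MCMV d = 1.08 um with its bottom exactly at the coverslip, concentric
  # MVB D = 367 nm; 70-nm serial sections cut at phase 0. An independent
  # interval-membership oracle fixes the slab sets before asserting on the
  # microtome: MCMV in slabs 0..15, MVB in slabs 5..10.
  expect_identical(scan_sphere_slabs(0.54, 1.08, 0.07), 0:15)
  expect_identical(scan_sphere_slabs(0.54, 0.367, 0.07), 5:10)
  bodies <- data.frame(body_id = 1:2, kind = c("MCMV", "MVB"),
                       parent_id = c(NA, 1L), x = 0, y = 0, z = 0.54,
                       diameter = c(1.08, 0.367))
  cnt <- tabulate_counts(section_scene(fake_scene(bodies = bodies),
                                       mode = "serial"))
  expect_identical(cnt$summary$n_mcmv_profiles, 16L)
  expect_identical(cnt$summary$n_mvb_profiles, 6L)
  expect_equal(cnt$summary$mvb_per_mcmv_profile, 6 / 16)
  expect_false(any(cnt$rows$orphan))
})

test_that("serial slab counts match sections_spanned for every body", {
  withr::with_seed(31, {
    n <- 40
    d <- runif(n, 0.05, 1.2)
    z <- d / 2 + runif(n, 0, 0.4)
    bodies <- data.frame(body_id = 1:n, kind = "MCMV", parent_id = NA,
                         x = 0, y = 0, z = z, diameter = d)
  })
  obs <- section_scene(fake_scene(bodies = bodies), mode = "serial",
                       min_profile = 0)
  got <- table(factor(obs$profiles$body_id, levels = 1:40))
  want <- sapply(1:40, function(i) {
    z0 <- z[i] - d[i] / 2
    sections_spanned(d[i], 0.07, z0 - 0.07 * floor(z0 / 0.07))
  })
  expect_equal(as.integer(got), want)
})

test_that("a site entirely inside one slab is sighted in exactly that slab", {
  sites <- data.frame(site_id = 1L, cell_id = 1L, on_lateral = TRUE,
                      z_lo = 0.155, z_hi = 0.165, azimuth = 0)
  obs <- section_scene(fake_scene(cells = one_cell(), sites = sites),
                       mode = "serial")
  expect_identical(obs$sightings,
                   data.frame(cell_id = 1L, slab_index = 2L))
})

test_that("a 2-um band is sighted in 2 um worth of serial sections", {
  sites <- data.frame(site_id = 1L, cell_id = 1L, on_lateral = TRUE,
                      z_lo = 1.013, z_hi = 3.013, azimuth = 0)
  obs <- section_scene(fake_scene(cells = one_cell(), sites = sites),
                       mode = "serial")
  # majority-overlap scoring: the number of scored sections times the
  # section thickness equals the band extent to within one section
  expect_true(nrow(obs$sightings) %in% c(28L, 29L))
})

test_that("face sites are never sighted en face", {
  sites <- data.frame(site_id = 1L, cell_id = 1L, on_lateral = FALSE,
                      z_lo = NA_real_, z_hi = NA_real_, azimuth = 0)
  sc <- fake_scene(cells = one_cell(), sites = sites)
  expect_identical(nrow(section_scene(sc, mode = "serial")$sightings), 0L)
  sv <- section_scene(sc, mode = "single_random_per_cell", seed = 3)
  expect_false(any(sv$sightings$sighted))
})

test_that("single-section sighting probability matches the band model", {
  sc <- generate_scene(culture_params(n_cells = 5000, n_mcmv = 0,
                                      site_rate = 0.72), 37)
  sv <- tabulate_counts(section_scene(sc, mode = "single_random_per_cell",
                                      seed = 38))
  # exact survey probability from the independent integral oracle; the
  # band approximation 1 - exp(-lambda p) sits ~1.5% above it because all
  # sites of a cell are scored against the same shared section
  f_exact <- oracle_sighting_fraction(0.72)
  f_band <- 1 - exp(-0.72 * 0.125)
  expect_lt(abs(f_exact - f_band) / f_band, 0.02)
  expect_lt(abs(sv$summary$f_sites - f_exact),
            3 * sqrt(f_exact * (1 - f_exact) / 5000))
  # the package's own forward-probability function agrees with the oracle
  expect_equal(expected_sighting_fraction(0.72), f_exact, tolerance = 1e-5)
})

test_that("forward mean MVB profiles per MCMV slab follows (D+T)/(d+T)", {
  sc <- generate_scene(culture_params(n_cells = 0, n_mcmv = 800,
                                      mvb_per_mcmv_mean = 1,
                                      mcmv_diameter_cv = 0), 41)
  cnt <- tabulate_counts(section_scene(sc, mode = "serial"))
  pm <- per_mcmv_profiles(cnt)
  nbar <- cnt$summary$mvb_per_mcmv_profile
  expected <- (0.367 + 0.07) / (1.08 + 0.07)
  # ratio-of-sums cluster SE over MCMVs
  res <- pm$n_mvb_profiles - nbar * pm$n_mcmv_profiles
  se <- sqrt(sum(res^2) * nrow(pm) / (nrow(pm) - 1)) / sum(pm$n_mcmv_profiles)
  expect_lt(abs(nbar - expected), 3 * se)
})

test_that("omega figures are scored per MCMV profile, spanning 1 or 2 slabs", {
  bodies <- data.frame(body_id = 1L, kind = "MCMV", parent_id = NA,
                       x = 0, y = 0, z = 0.54, diameter = 1.08)
  # one mark per slab of the MCMV: every profile carries an omega
  omegas <- data.frame(mcmv_id = 1L, z = seq(0.035, 1.085, by = 0.07))
  cnt <- tabulate_counts(section_scene(fake_scene(bodies = bodies,
                                                  omegas = omegas),
                                       mode = "serial"))
  expect_equal(cnt$summary$omega_fraction, 1.0)
  # a single mark near a boundary: 1 slab by default, 2 with the span option
  om1 <- data.frame(mcmv_id = 1L, z = 0.069)
  sc1 <- fake_scene(bodies = bodies, omegas = om1)
  cnt1 <- tabulate_counts(section_scene(sc1, mode = "serial"))
  expect_identical(sum(cnt1$rows$n_omega, na.rm = TRUE), 1L)
  cnt2 <- tabulate_counts(section_scene(sc1, mode = "serial",
                                        omega_span_slabs = 2L))
  expect_identical(sum(cnt2$rows$n_omega, na.rm = TRUE), 2L)
})

test_that("ILV co-sighting requires both profiles in the same slab", {
  bodies <- data.frame(body_id = 1:3,
                       kind = c("MCMV", "MVB", "ILV"),
                       parent_id = c(NA, 1L, 2L),
                       x = 0, y = 0,
                       z = c(0.54, 0.54, 0.54 + 0.12),
                       diameter = c(1.08, 0.367, 0.08))
  obs <- section_scene(fake_scene(bodies = bodies), mode = "serial")
  mvb <- obs$profiles[obs$profiles$kind == "MVB", ]
  ilv <- obs$profiles[obs$profiles$kind == "ILV", ]
  expect_gt(nrow(ilv), 0)
  expect_identical(mvb$slab_index[mvb$contains_ilv], ilv$slab_index)
  expect_true(any(!mvb$contains_ilv))
})

test_that("tabulate_counts pools runs and rejects mixed thickness or mode", {
  sc <- generate_scene(culture_params(n_cells = 20, n_mcmv = 5), 43)
  a <- section_scene(sc, mode = "serial")
  b <- section_scene(sc, thickness = 0.05, mode = "serial")
  expect_error(tabulate_counts(list(a, b)), "mixed section thicknesses")
  d <- section_scene(sc, mode = "single_random_per_cell", seed = 1)
  expect_error(tabulate_counts(list(a, d)), "mixed sectioning modes")
  pooled <- tabulate_counts(list(a, a))
  expect_identical(pooled$summary$n_mcmv_profiles,
                   2L * tabulate_counts(a)$summary$n_mcmv_profiles)
})

test_that("an observed 9 of 100 cells tabulates to f_sites = 0.09", {
  obs <- structure(list(mode = "single_random_per_cell", thickness = 0.07,
                        min_profile = 0.02, n_cells = 100L,
                        cell_ids = 1:100,
                        sightings = data.frame(cell_id = 1:100,
                                               slab_z = 0,
                                               sighted = rep(c(TRUE, FALSE),
                                                             c(9, 91))),
                        profiles = evstereo:::empty_profiles(),
                        seed_used = NA_integer_),
                   class = "ev_sections")
  expect_equal(tabulate_counts(obs)$summary$f_sites, 0.09)
})

test_that("sectioning and tabulation are deterministic; counts round-trip CSV", {
  sc <- generate_scene(culture_params(n_cells = 15, n_mcmv = 8), 47)
  a <- tabulate_counts(section_scene(sc, mode = "serial"))
  b <- tabulate_counts(section_scene(sc, mode = "serial"))
  expect_identical(a, b)
  s1 <- section_scene(sc, mode = "single_random_per_cell", seed = 9)
  s2 <- section_scene(sc, mode = "single_random_per_cell", seed = 9)
  expect_identical(s1, s2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_counts(a, path)
  back <- read_counts(path)
  expect_equal(back$summary, a$summary, tolerance = 1e-12)
  expect_equal(nrow(back$rows), nrow(a$rows))
})
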