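test_that("scene generation is deterministic and respects degenerate rates", {
  p <- culture_params(n_cells = 30, n_mcmv = 10)
  expect_identical(generate_scene(p, 7), generate_scene(p, 7))
  expect_false(identical(generate_scene(p, 7), generate_scene(p, 8)))
  p0 <- culture_params(n_cells = 25, n_mcmv = 0, site_rate = 0)
  expect_identical(nrow(generate_scene(p0, 1)$sites), 0L)
})

test_that("per-cell site counts have the configured Poisson rate", {
  p <- culture_params(n_cells = 10000, n_mcmv = 0, site_rate = 0.72)
  sc <- generate_scene(p, 11)
  mean_sites <- nrow(sc$sites) / p$n_cells
  expect_lt(abs(mean_sites - 0.72), 3 * sqrt(0.72 / 10000))
})

test_that("site, MVB and omega counts are Poisson (chi-square GOF)", {
  gof_p <- function(obs_counts, lambda, n) {
    kmax <- max(obs_counts, qpois(0.9999, lambda))
    obs <- tabulate(factor(obs_counts, levels = 0:kmax), nbins = kmax + 1)
    pr <- dpois(0:kmax, lambda)
    pr[kmax + 1] <- pr[kmax + 1] + ppois(kmax, lambda, lower.tail = FALSE)
    # pool sparse upper bins so expected counts stay above 5
    while (length(pr) > 2 && n * pr[length(pr)] < 5) {
      k <- length(pr)
      pr[k - 1] <- pr[k - 1] + pr[k]
      obs[k - 1] <- obs[k - 1] + obs[k]
      pr <- pr[-k]; obs <- obs[-k]
    }
    suppressWarnings(chisq.test(obs, p = pr)$p.value)
  }
  sc <- generate_scene(culture_params(n_cells = 10000, n_mcmv = 0,
                                      site_rate = 0.75), 13)
  site_counts <- tabulate(factor(sc$sites$cell_id, levels = 1:10000),
                          nbins = 10000)
  expect_gt(gof_p(site_counts, 0.75, 10000), 0.01)

  # fixed sizes: the feasibility cap on counts is then far in the tail and
  # the count distributions are exactly Poisson
  scb <- generate_scene(culture_params(n_cells = 0, n_mcmv = 10000,
                                       ilv_occupancy = 0,
                                       mcmv_diameter_cv = 0,
                                       omega_rate = 1.5), 17)
  b <- scb$bodies
  mvb_counts <- tabulate(factor(b$parent_id[b$kind == "MVB"],
                                levels = 1:10000), nbins = 10000)
  expect_gt(gof_p(mvb_counts, 1, 10000), 0.01)
  om_counts <- tabulate(factor(scb$omegas$mcmv_id, levels = 1:10000),
                        nbins = 10000)
  expect_gt(gof_p(om_counts, 1.5, 10000), 0.01)
})

test_that("containment and non-overlap hold for every generated scene", {
  p <- culture_params(n_cells = 0, n_mcmv = 4, mvb_per_mcmv_mean = 2)
  for (seed in 1:100) {
    b <- generate_scene(p, seed)$bodies
    mcmv <- b[b$kind == "MCMV", ]
    # never intersecting the coverslip plane
    expect_true(all(mcmv$z >= mcmv$diameter / 2 - 1e-12))
    nested <- b[!is.na(b$parent_id), ]
    if (nrow(nested) > 0) {
      par <- b[match(nested$parent_id, b$body_id), ]
      dist <- sqrt((nested$x - par$x)^2 + (nested$y - par$y)^2 +
                     (nested$z - par$z)^2)
      expect_true(all(dist <= (par$diameter - nested$diameter) / 2 + 1e-9))
    }
    # sibling MVBs inside one MCMV do not overlap
    mvb <- b[b$kind == "MVB", ]
    for (pid in unique(mvb$parent_id)) {
      sib <- mvb[mvb$parent_id == pid, ]
      if (nrow(sib) > 1) {
        dd <- as.matrix(dist(sib[, c("x", "y", "z")]))
        req <- outer(sib$diameter, sib$diameter, `+`) / 2
        expect_true(all(dd[upper.tri(dd)] >= req[upper.tri(req)] - 1e-9))
      }
    }
  }
})

test_that("ILV occupancy converges to its configured probability", {
  sc <- generate_scene(culture_params(n_cells = 0, n_mcmv = 3000), 19)
  b <- sc$bodies
  mvb_ids <- b$body_id[b$kind == "MVB"]
  occupied <- mvb_ids %in% b$parent_id[b$kind == "ILV"]
  n <- length(mvb_ids)
  expect_gt(n, 2000)
  expect_lt(abs(mean(occupied) - 0.65), 3 * sqrt(0.65 * 0.35 / n))
})

test_that("nested diameter ordering is enforced at construction", {
  expect_error(culture_params(mvb_diameter_mean = 2), "nest")
  expect_error(culture_params(ilv_diameter_range = c(0.3, 0.4)), "nest")
})

test_that("infeasible packings fail loudly naming the parent", {
  expect_error(
    evstereo:::pack_children(3, rep(0.7, 3), c(0, 0, 1), 1.08, 300,
                             "MCMV 42"),
    "packing error.*MCMV 42")
})

test_that("rendered patches have the requested grey-level structure", {
  p <- render_patch(180, 120, 10, 367, seed = 5)
  n_in <- sum(p$inside_mask)
  n_out <- sum(p$outside_mask)
  expect_lt(abs(mean(p$pixels[p$inside_mask]) - 180), 3 * 10 / sqrt(n_in))
  expect_lt(abs(mean(p$pixels[p$outside_mask]) - 120), 3 * 10 / sqrt(n_out))
  # identical distributions: means agree within 4 SE
  q <- render_patch(140, 140, 10, 300, seed = 6)
  se <- 10 * sqrt(1 / sum(q$inside_mask) + 1 / sum(q$outside_mask))
  expect_lt(abs(mean(q$pixels[q$inside_mask]) -
                  mean(q$pixels[q$outside_mask])), 4 * se)
  # determinism
  expect_identical(render_patch(180, 120, 10, 367, seed = 5)$pixels,
                   p$pixels)
  expect_error(render_patch(180, 120, 10, 5000, nm_per_px = 4,
                            margin_px = -200), "disk larger than patch")
})

test_that("scenes round-trip through JSON", {
  sc <- generate_scene(culture_params(n_cells = 8, n_mcmv = 4), 23)
  path <- withr::local_tempfile(fileext = ".json")
  write_scene(sc, path)
  back <- read_scene(path)
  expect_equal(back$bodies, sc$bodies, tolerance = 1e-12)
  expect_equal(back$sites, sc$sites, tolerance = 1e-12)
  expect_equal(unclass(back$params), unclass(sc$params), tolerance = 1e-12)
})
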