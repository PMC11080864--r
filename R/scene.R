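#' Culture generator parameters
#'
#' Parameters of the synthetic 3D culture: pancake-shaped adherent cells
#' bearing rare lateral-wall protrusion sites, plus free spherical MCMVs
#' resting on the coverslip that contain non-overlapping MVB-like spheres,
#' which in turn may contain 50-100 nm ILV-like spheres; omega figures are
#' point marks on the MCMV limiting membrane. Defaults are the endothelial
#' culture geometry the estimators assume: 24 x 4 um cells, ~3/4 protrusion
#' sites per cell with a 2-um z-extent, 1.08-um MCMVs with 367-nm MVBs, 65%
#' ILV occupancy, and an omega mark rate calibrated so ~43% of 70-nm MCMV
#' profiles show at least one omega figure (see the methods vignette).
#'
#' @param n_cells Number of cells.
#' @param cell_diameter_mean,cell_height_mean Cell size in um.
#' @param site_rate Mean protrusion sites per cell (Poisson rate).
#' @param site_z_extent Vertical extent of a protrusion site in um.
#' @param n_mcmv Number of free MCMVs.
#' @param mcmv_diameter_mean MCMV diameter mean in um.
#' @param mcmv_diameter_cv Lognormal coefficient of variation of body
#'   diameters (applies to MCMVs and MVBs); 0 gives fixed sizes for
#'   exact-arithmetic tests.
#' @param mvb_per_mcmv_mean Mean MVBs per MCMV (Poisson rate).
#' @param mvb_diameter_mean MVB diameter mean in um.
#' @param ilv_occupancy Probability an MVB contains at least one ILV.
#' @param ilv_extra_mean Occupied MVBs carry `1 + Poisson(ilv_extra_mean)`
#'   ILVs.
#' @param ilv_diameter_range ILV diameter range in um (uniform).
#' @param omega_rate Mean omega marks per MCMV. The default inverts the
#'   single-section geometry: `-(d + T)/T * log(1 - 0.43)` at d = 1.08 um,
#'   T = 70 nm, so that about 43% of MCMV profiles carry an omega figure.
#' @param settle_z_jitter MCMVs rest on the coverslip plus a uniform
#'   settling offset on `[0, settle_z_jitter]` um, randomising the phase of
#'   body bottoms relative to the section grid (default one section
#'   thickness, 0.07 um).
#' @param field_um Side of the square field in which cells and bodies are
#'   scattered, um.
#' @param max_attempts Rejection-sampling cap per nested body before a
#'   packing error is raised.
#' @return An object of class `culture_params`.
#' @export
culture_params <- function(n_cells = 100L,
                           cell_diameter_mean = 24,
                           cell_height_mean = 4,
                           site_rate = 0.75,
                           site_z_extent = 2,
                           n_mcmv = 100L,
                           mcmv_diameter_mean = 1.08,
                           mcmv_diameter_cv = 0.2,
                           mvb_per_mcmv_mean = 1,
                           mvb_diameter_mean = 0.367,
                           ilv_occupancy = 0.65,
                           ilv_extra_mean = 2,
                           ilv_diameter_range = c(0.05, 0.10),
                           omega_rate = -(1.08 + 0.07) / 0.07 * log(1 - 0.43),
                           settle_z_jitter = 0.07,
                           field_um = 500,
                           max_attempts = 1000L) {
  p <- list(n_cells = as.integer(n_cells),
            cell_diameter_mean = cell_diameter_mean,
            cell_height_mean = cell_height_mean,
            site_rate = site_rate,
            site_z_extent = site_z_extent,
            n_mcmv = as.integer(n_mcmv),
            mcmv_diameter_mean = mcmv_diameter_mean,
            mcmv_diameter_cv = mcmv_diameter_cv,
            mvb_per_mcmv_mean = mvb_per_mcmv_mean,
            mvb_diameter_mean = mvb_diameter_mean,
            ilv_occupancy = ilv_occupancy,
            ilv_extra_mean = ilv_extra_mean,
            ilv_diameter_range = ilv_diameter_range,
            omega_rate = omega_rate,
            settle_z_jitter = settle_z_jitter,
            field_um = field_um,
            max_attempts = as.integer(max_attempts))
  validate_culture_params(p)
  structure(p, class = "culture_params")
}

validate_culture_params <- function(p) {
  stopifnot(p$n_cells >= 0, p$n_mcmv >= 0,
            p$cell_diameter_mean > 0, p$cell_height_mean >= 0,
            p$site_rate >= 0, p$site_z_extent >= 0,
            p$mcmv_diameter_mean > 0, p$mcmv_diameter_cv >= 0,
            p$mvb_per_mcmv_mean >= 0, p$mvb_diameter_mean > 0,
            p$ilv_occupancy >= 0, p$ilv_occupancy <= 1,
            p$ilv_extra_mean >= 0,
            length(p$ilv_diameter_range) == 2L,
            all(p$ilv_diameter_range > 0),
            p$ilv_diameter_range[1] <= p$ilv_diameter_range[2],
            p$omega_rate >= 0, p$settle_z_jitter >= 0,
            p$field_um > 0, p$max_attempts >= 1)
  # nested scales must be strictly decreasing: MCMV > MVB > ILV
  if (!(p$mcmv_diameter_mean > p$mvb_diameter_mean &&
        p$mvb_diameter_mean > p$ilv_diameter_range[2])) {
    stop("invalid parameters: diameters must nest (MCMV > MVB > ILV)")
  }
  invisible(p)
}

# uniform draw in the ball of radius `r` about the origin
runif_ball <- function(k, r) {
  u <- matrix(stats::rnorm(3 * k), k, 3)
  u <- u / sqrt(rowSums(u^2))
  u * r * stats::runif(k)^(1 / 3)
}

# Sequential rejection placement: each child center uniform in its allowed
# concentric ball, rejecting sibling overlaps; NULL on failure. Candidates
# for each child are drawn in one batch and the first admissible one kept
# (equivalent to one-at-a-time rejection).
pack_reject <- function(diam, pd, tries_per_child) {
  k <- length(diam)
  centers <- matrix(NA_real_, k, 3)
  for (i in seq_len(k)) {
    allow <- (pd - diam[i]) / 2
    if (allow < 0) return(NULL)
    if (i == 1L) {
      centers[1L, ] <- runif_ball(1L, allow)
      next
    }
    cand <- runif_ball(tries_per_child, allow)
    prev <- centers[seq_len(i - 1L), , drop = FALSE]
    req2 <- ((diam[seq_len(i - 1L)] + diam[i]) / 2)^2
    ok <- rep(TRUE, tries_per_child)
    for (j in seq_len(i - 1L)) {
      ok <- ok & ((cand[, 1] - prev[j, 1])^2 +
                    (cand[, 2] - prev[j, 2])^2 +
                    (cand[, 3] - prev[j, 3])^2 >= req2[j])
      if (!any(ok)) return(NULL)
    }
    centers[i, ] <- cand[which.max(ok), ]
  }
  centers
}

# Repulsion relaxation with diameter inflation for dense-but-feasible
# packings: children start at 40% of their target diameters, are grown to
# full size in stages, and after each growth step overlapping pairs are
# pushed apart and centers re-projected into their allowed balls. Several
# random restarts; NULL if every restart leaves overlaps.
pack_relax <- function(diam, pd, restarts = 8L, stages = 60L,
                       sweeps = 30L) {
  k <- length(diam)
  if (any(diam >= pd)) return(NULL)
  req_full <- outer(diam, diam, `+`) / 2
  allow_full <- (pd - diam) / 2
  for (rs in seq_len(restarts)) {
    ctr <- runif_ball(k, 1) * (pd - 0.4 * diam) / 2
    for (s in seq(0.4, 1, length.out = stages)) {
      diam_s <- diam * s
      allow <- (pd - diam_s) / 2
      req <- req_full * s
      for (it in seq_len(sweeps)) {
        d2 <- as.matrix(stats::dist(ctr))
        bad <- which(d2 < req & upper.tri(req), arr.ind = TRUE)
        if (nrow(bad) == 0L) break
        for (b in seq_len(nrow(bad))) {
          i <- bad[b, 1]; j <- bad[b, 2]
          v <- ctr[j, ] - ctr[i, ]
          nv <- sqrt(sum(v^2))
          if (nv < 1e-12) {
            v <- stats::rnorm(3)
            nv <- sqrt(sum(v^2))
          }
          push <- (req[i, j] * 1.02 - nv) / 2
          ctr[i, ] <- ctr[i, ] - v / nv * push
          ctr[j, ] <- ctr[j, ] + v / nv * push
        }
        nr <- sqrt(rowSums(ctr^2))
        over <- nr > allow
        if (any(over)) {
          ctr[over, ] <- ctr[over, ] * (allow[over] / nr[over])
        }
      }
    }
    d2 <- as.matrix(stats::dist(ctr))
    ok <- all(d2[upper.tri(d2)] >= req_full[upper.tri(req_full)]) &&
      all(sqrt(rowSums(ctr^2)) <= allow_full + 1e-12)
    if (ok) return(ctr)
  }
  NULL
}

# Largest number of children of diameter `d_child` that can realistically
# be packed into a parent of diameter `d_parent`: known radius-ratio limits
# for small counts (with a 3% working margin), volume-scaled beyond 12.
.ratio_max <- c(1, 0.5, 0.4641, 0.4495, 0.4142, 0.4142, 0.3859, 0.3780,
                0.3660, 0.3530, 0.3445, 0.3445)
feasible_children <- function(d_parent, d_child) {
  ratio <- d_child / d_parent
  limit <- function(k) {
    0.97 * if (k <= 12L) .ratio_max[k] else
      .ratio_max[12] * (12 / k)^(1 / 3)
  }
  if (ratio > limit(1L)) return(0L)
  k <- 1L
  while (ratio <= limit(k + 1L) && k < 1000L) k <- k + 1L
  k
}

# Poisson(`lambda`) draw conditioned on not exceeding the geometric packing
# bound `k_max` (exact truncated-Poisson sampling).
rpois_capped <- function(lambda, k_max) {
  if (lambda == 0 || k_max <= 0L) return(0L)
  kk <- 0:k_max
  sample(kk, 1L, prob = stats::dpois(kk, lambda))
}

# Place `k` non-overlapping child spheres of diameters `diam` inside a
# parent sphere (center `pc`, diameter `pd`). Strategy: sequential
# rejection sampling (uniform conditional placement), falling back to a
# repulsion relaxation for dense-but-feasible sets; as a last resort the
# diameters are redrawn via `redraw` (size scatter inside a crowded body
# is feasibility-limited). A packing error naming the parent is raised
# when all of this fails within the attempt budget.
pack_children <- function(k, diam, pc, pd, max_attempts, parent_label,
                          redraw = NULL) {
  if (k == 0L) {
    return(list(centers = matrix(numeric(0), ncol = 3), diam = numeric(0)))
  }
  diam <- sort(diam, decreasing = TRUE)
  # diameter cap at which k spheres remain packable by relaxation
  # (random-packing fraction ~0.35, never above a 0.46 radius ratio)
  cap <- if (k == 1L) pd * (1 - 1e-9) else
    pd * min(0.46, (0.35 / k)^(1 / 3))
  rounds <- max(1L, max_attempts %/% 100L)
  for (round in seq_len(rounds)) {
    ctr <- pack_reject(diam, pd, tries_per_child = 100L)
    if (is.null(ctr) && k > 1L) {
      ctr <- pack_relax(diam, pd)
    }
    if (!is.null(ctr)) {
      return(list(centers = sweep(ctr, 2, pc, `+`), diam = diam))
    }
    if (!is.null(redraw)) {
      # crowded parent: redraw sizes, preferring draws under the cap
      diam <- sort(vapply(seq_len(k), function(i) {
        d <- redraw()
        for (t in seq_len(100L)) {
          if (d <= cap) break
          d <- redraw()
        }
        d
      }, 0), decreasing = TRUE)
    }
  }
  stop("packing error: could not place ", k, " bodies inside ",
       parent_label, " within the attempt budget")
}

#' Generate a ground-truthed synthetic culture
#'
#' Draws a full 3D scene under a [culture_params()] specification: per-cell
#' protrusion-site counts are Poisson(`site_rate`), with each site landing
#' on the lateral wall with probability equal to the wall's share of the
#' total membrane area (face sites are kept but flagged undetectable in
#' en-face sections); MVB counts per MCMV are Poisson, packed without
#' overlap by rejection sampling; each MVB carries at least one ILV with
#' probability `ilv_occupancy`; omega marks per MCMV are Poisson with z
#' uniform over the limiting membrane (uniform in z by the hat-box
#' theorem). The same `params` and `seed` always reproduce the identical
#' scene.
#'
#' @param params A [culture_params()].
#' @param seed Integer seed.
#' @return An object of class `ev_scene`: a list with data frames `cells`,
#'   `sites`, `bodies`, `omegas`, plus `params` and `seed_used`. Lengths in
#'   um.
#' @examples
#' sc <- generate_scene(culture_params(n_cells = 10, n_mcmv = 5), seed = 1)
#' table(sc$bodies$kind)
#' @export
generate_scene <- function(params, seed) {
  stopifnot(inherits(params, "culture_params"))
  validate_culture_params(params)
  with_seed(seed, {
    cells <- generate_cells(params)
    sites <- generate_sites(params, cells)
    bod <- generate_bodies(params)
  })
  structure(list(params = params,
                 cells = cells,
                 sites = sites,
                 bodies = bod$bodies,
                 omegas = bod$omegas,
                 seed_used = as.integer(seed)),
            class = "ev_scene")
}

generate_cells <- function(p) {
  n <- p$n_cells
  data.frame(cell_id = seq_len(n),
             x = stats::runif(n, 0, p$field_um),
             y = stats::runif(n, 0, p$field_um),
             diameter = rep(p$cell_diameter_mean, n),
             height = rep(p$cell_height_mean, n))
}

generate_sites <- function(p, cells) {
  n_sites <- stats::rpois(nrow(cells), p$site_rate)
  total <- sum(n_sites)
  if (total == 0L) {
    return(data.frame(site_id = integer(0), cell_id = integer(0),
                      on_lateral = logical(0), z_lo = numeric(0),
                      z_hi = numeric(0), azimuth = numeric(0)))
  }
  cell_id <- rep(cells$cell_id, n_sites)
  d <- cells$diameter[cell_id]
  H <- cells$height[cell_id]
  # lateral share of the membrane: pi*d*H / (2*pi*(d/2)^2 + pi*d*H)
  p_lat <- (d * H) / (d^2 / 2 + d * H)
  on_lateral <- stats::runif(total) < p_lat
  # full site extent kept on the wall: z-center uniform on [e/2, H - e/2]
  # (extent capped at the wall height), so the detectable z-window always
  # has length min(e, H) and the band-fraction arithmetic is exact
  e <- pmin(p$site_z_extent, H)
  zc <- ifelse(e >= H, H / 2,
               stats::runif(total, e / 2, H - e / 2))
  z_lo <- ifelse(on_lateral, zc - e / 2, NA_real_)
  z_hi <- ifelse(on_lateral, zc + e / 2, NA_real_)
  data.frame(site_id = seq_len(total), cell_id = cell_id,
             on_lateral = on_lateral, z_lo = z_lo, z_hi = z_hi,
             azimuth = stats::runif(total, 0, 2 * pi))
}

generate_bodies <- function(p) {
  n <- p$n_mcmv
  empty_bodies <- data.frame(body_id = integer(0), kind = character(0),
                             parent_id = integer(0), x = numeric(0),
                             y = numeric(0), z = numeric(0),
                             diameter = numeric(0))
  empty_omegas <- data.frame(mcmv_id = integer(0), z = numeric(0))
  if (n == 0L) {
    return(list(bodies = empty_bodies, omegas = empty_omegas))
  }
  d_mcmv <- rlnorm_mean_cv(n, p$mcmv_diameter_mean, p$mcmv_diameter_cv)
  mcmv <- data.frame(body_id = seq_len(n),
                     kind = "MCMV",
                     parent_id = NA_integer_,
                     x = stats::runif(n, 0, p$field_um),
                     y = stats::runif(n, 0, p$field_um),
                     # resting on the coverslip plus a sub-section settling
                     # offset so section phases are uniform; z >= r always
                     z = d_mcmv / 2 + stats::runif(n, 0, p$settle_z_jitter),
                     diameter = d_mcmv)
  acc <- list()
  push <- function(ids, kind, parent, ctr, diam) {
    acc[[length(acc) + 1L]] <<-
      list(id = ids, kind = rep(kind, length(ids)),
           parent = rep(parent, length(ids)),
           x = ctr[, 1], y = ctr[, 2], z = ctr[, 3], diam = diam)
  }
  next_id <- n + 1L
  mvb_redraw <- if (p$mcmv_diameter_cv > 0) {
    function() rlnorm_mean_cv(1, p$mvb_diameter_mean, p$mcmv_diameter_cv)
  }  # fixed sizes are a contract: no feasibility redraw, fail loudly
  for (i in seq_len(n)) {
    # MVB count: Poisson conditioned on the parent's geometric capacity
    # (evaluated at the mean MVB size; truncated mass is < 2% at defaults)
    k <- rpois_capped(p$mvb_per_mcmv_mean,
                      feasible_children(d_mcmv[i], p$mvb_diameter_mean))
    if (k == 0L) next
    dm <- rlnorm_mean_cv(k, p$mvb_diameter_mean, p$mcmv_diameter_cv)
    packed <- pack_children(k, dm, c(mcmv$x[i], mcmv$y[i], mcmv$z[i]),
                            d_mcmv[i], p$max_attempts,
                            paste0("MCMV ", i), redraw = mvb_redraw)
    ctr <- packed$centers
    dm <- packed$diam
    ids <- seq.int(next_id, length.out = k)
    push(ids, "MVB", i, ctr, dm)
    next_id <- next_id + k
    # ILVs: occupied MVBs carry 1 + Poisson(extra) vesicles
    occupied <- stats::runif(k) < p$ilv_occupancy
    for (j in which(occupied)) {
      hi <- min(p$ilv_diameter_range[2], dm[j] * 0.9)
      lo <- min(p$ilv_diameter_range[1], hi)
      m_max <- feasible_children(dm[j], (lo + hi) / 2)
      m <- 1L + rpois_capped(p$ilv_extra_mean, max(0L, m_max - 1L))
      di <- stats::runif(m, lo, hi)
      pk <- pack_children(m, di, ctr[j, ], dm[j], p$max_attempts,
                          paste0("MVB ", ids[j], " (MCMV ", i, ")"),
                          redraw = function() stats::runif(1, lo, hi))
      push(seq.int(next_id, length.out = m), "ILV", ids[j], pk$centers,
           pk$diam)
      next_id <- next_id + m
    }
  }
  col <- function(f) unlist(lapply(acc, `[[`, f), use.names = FALSE)
  nested <- if (length(acc)) {
    data.frame(body_id = as.integer(col("id")), kind = col("kind"),
               parent_id = as.integer(col("parent")),
               x = col("x"), y = col("y"), z = col("z"),
               diameter = col("diam"))
  } else {
    empty_bodies
  }
  bodies <- rbind(mcmv, nested)
  rownames(bodies) <- NULL
  # omega figures: Poisson marks, z uniform over the limiting membrane
  n_om <- stats::rpois(n, p$omega_rate)
  omegas <- if (sum(n_om) == 0L) {
    empty_omegas
  } else {
    id <- rep(seq_len(n), n_om)
    data.frame(mcmv_id = id,
               z = stats::runif(sum(n_om),
                                mcmv$z[id] - mcmv$diameter[id] / 2,
                                mcmv$z[id] + mcmv$diameter[id] / 2))
  }
  list(bodies = bodies, omegas = omegas)
}

#' @export
print.ev_scene <- function(x, ...) {
  cat(sprintf(paste0("<ev_scene> %d cells (%d sites), %d MCMVs, %d MVBs, ",
                     "%d ILVs, %d omega marks; seed %d\n"),
              nrow(x$cells), nrow(x$sites),
              sum(x$bodies$kind == "MCMV"), sum(x$bodies$kind == "MVB"),
              sum(x$bodies$kind == "ILV"), nrow(x$omegas), x$seed_used))
  invisible(x)
}

#' Write / read a scene as JSON
#'
#' Scenes serialise to a documented JSON schema (lengths in um, one record
#' per cell/site/body/omega mark) and round-trip exactly to the stored
#' precision.
#'
#' @param scene An `ev_scene`.
#' @param path Output / input file path.
#' @return `write_scene` returns `path` invisibly; `read_scene` an
#'   `ev_scene`.
#' @export
write_scene <- function(scene, path) {
  stopifnot(inherits(scene, "ev_scene"))
  obj <- list(schema = "evstereo/scene/v1",
              units = "um",
              seed_used = scene$seed_used,
              params = unclass(scene$params),
              cells = scene$cells,
              sites = scene$sites,
              bodies = scene$bodies,
              omegas = scene$omegas)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", na = "null")
  invisible(path)
}

#' @rdname write_scene
#' @export
read_scene <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "evstereo/scene/v1")) {
    stop("not an evstereo scene file: ", path)
  }
  pr <- obj$params
  params <- culture_params(n_cells = pr$n_cells,
                           cell_diameter_mean = pr$cell_diameter_mean,
                           cell_height_mean = pr$cell_height_mean,
                           site_rate = pr$site_rate,
                           site_z_extent = pr$site_z_extent,
                           n_mcmv = pr$n_mcmv,
                           mcmv_diameter_mean = pr$mcmv_diameter_mean,
                           mcmv_diameter_cv = pr$mcmv_diameter_cv,
                           mvb_per_mcmv_mean = pr$mvb_per_mcmv_mean,
                           mvb_diameter_mean = pr$mvb_diameter_mean,
                           ilv_occupancy = pr$ilv_occupancy,
                           ilv_extra_mean = pr$ilv_extra_mean,
                           ilv_diameter_range = pr$ilv_diameter_range,
                           omega_rate = pr$omega_rate,
                           settle_z_jitter = pr$settle_z_jitter,
                           field_um = pr$field_um,
                           max_attempts = pr$max_attempts)
  as_df <- function(x, template) {
    if (length(x) == 0 || (is.data.frame(x) && nrow(x) == 0)) template
    else as.data.frame(x)
  }
  structure(list(params = params,
                 cells = as.data.frame(obj$cells),
                 sites = as_df(obj$sites,
                               data.frame(site_id = integer(0),
                                          cell_id = integer(0),
                                          on_lateral = logical(0),
                                          z_lo = numeric(0),
                                          z_hi = numeric(0),
                                          azimuth = numeric(0))),
                 bodies = as.data.frame(obj$bodies),
                 omegas = as_df(obj$omegas,
                                data.frame(mcmv_id = integer(0),
                                           z = numeric(0))),
                 seed_used = obj$seed_used),
            class = "ev_scene")
}
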