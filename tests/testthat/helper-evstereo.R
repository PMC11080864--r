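# Shared fixtures: everything is built in code at test time.

huvec <- pancake_cell(24, 4)

# Assemble an ev_scene directly from its component tables, for tests that
# need exact hand-placed geometry rather than random generation.
fake_scene <- function(cells = NULL, sites = NULL, bodies = NULL,
                       omegas = NULL, params = culture_params()) {
  structure(list(
    params = params,
    cells = cells %||% data.frame(cell_id = integer(0), x = numeric(0),
                                  y = numeric(0), diameter = numeric(0),
                                  height = numeric(0)),
    sites = sites %||% data.frame(site_id = integer(0), cell_id = integer(0),
                                  on_lateral = logical(0), z_lo = numeric(0),
                                  z_hi = numeric(0), azimuth = numeric(0)),
    bodies = bodies %||% data.frame(body_id = integer(0), kind = character(0),
                                    parent_id = integer(0), x = numeric(0),
                                    y = numeric(0), z = numeric(0),
                                    diameter = numeric(0)),
    omegas = omegas %||% data.frame(mcmv_id = integer(0), z = numeric(0)),
    seed_used = 0L), class = "ev_scene")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

one_cell <- function(diameter = 24, height = 4) {
  data.frame(cell_id = 1L, x = 0, y = 0, diameter = diameter,
             height = height)
}

# Independent integral oracle for the single-section survey: probability a
# cell shows >= 1 site when all its Poisson(lambda) sites are scored
# against one shared random section (lateral fraction 1/4, site z-centers
# uniform on [e/2, H - e/2], majority-overlap window shifted by T/2).
oracle_sighting_fraction <- function(lambda, e = 2, H = 4, T = 0.07,
                                     p_lat = 0.25, n = 100001) {
  z <- seq(0, H, length.out = n)
  lo <- pmax(z + T / 2 - e / 2, e / 2)
  hi <- pmin(z + T / 2 + e / 2, H - e / 2)
  cz <- pmax(0, hi - lo) / (H - e)
  mean(1 - exp(-lambda * p_lat * cz))
}

# Independent slab-counting oracle: fine z-scan membership of the interval
# [z0, z0 + d) over half-open slabs of thickness T.
scan_sections_spanned <- function(d, T, z0, step = d / 5000) {
  zz <- seq(z0, z0 + d - step / 2, by = step)
  length(unique(floor(zz / T + 1e-9)))
}

# Independent oracle for sphere-in-slab membership: does the open z-extent
# of the sphere meet the half-open slab?
scan_sphere_slabs <- function(cz, diam, T, k_max = 40) {
  r <- diam / 2
  as.integer(which(sapply(0:k_max, function(k) (k * T < cz + r) && ((k + 1) * T > cz - r))) - 1L)
}
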