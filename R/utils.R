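# Internal numeric and RNG helpers.

# Relative tolerance used when snapping z-coordinates onto the section grid.
# Section thickness (0.07 um) is not exactly representable in binary, so raw
# floor()/ceiling() on z/T can be off by one at exact slab boundaries.
.grid_tol <- 1e-9

floor_fuzzy <- function(x) floor(x + .grid_tol * pmax(1, abs(x)))

ceiling_fuzzy <- function(x) ceiling(x - .grid_tol * pmax(1, abs(x)))

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# Deterministic per-stage sub-seeds derived from one master seed, kept well
# inside 32-bit integer range. Stage names are fixed and documented in the
# run manifest so any stage can be replayed in isolation.
derive_seed <- function(seed, stage) {
  offsets <- c(scene = 11L, section = 23L, patch = 37L, boot = 53L,
               validate = 71L)
  if (!stage %in% names(offsets)) {
    stop("unknown seed stage: ", stage)
  }
  (as.integer(seed) + offsets[[stage]] * 1000003L) %% 2147483399L
}

# Lognormal draws parameterised by arithmetic mean and coefficient of
# variation; cv = 0 degenerates to the constant mean (exact-arithmetic mode).
rlnorm_mean_cv <- function(n, mean, cv) {
  stopifnot(mean > 0, cv >= 0)
  if (cv == 0) {
    return(rep(mean, n))
  }
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- log(mean) - sdlog^2 / 2
  stats::rlnorm(n, meanlog = meanlog, sdlog = sdlog)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
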