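#' Run configuration
#'
#' Assembles and validates the configuration for an end-to-end simulation
#' run. Lengths follow the field's mixed conventions at the interface —
#' nanometres for section/organelle scales (`thickness_nm`,
#' `min_profile_nm`, classifier sizes), micrometres inside
#' [culture_params()] for cell-scale geometry — and are normalised to um
#' internally; the run manifest records the normalised values, with every
#' defaulted field echoed explicitly.
#'
#' @param culture A [culture_params()].
#' @param thickness_nm Section thickness in nm (default 70).
#' @param min_profile_nm Minimum detectable profile diameter in nm
#'   (default 20).
#' @param band_height_um Lateral band height used by the site-rate
#'   estimator, um (default the site z-extent).
#' @param site_rate_method `"linear"` or `"poisson_inversion"`.
#' @param classifier A [classifier_params()].
#' @param n_patches Number of demonstration patches to render and classify
#'   (0 disables the classifier stage).
#' @param seed Master integer seed; per-stage streams are derived
#'   deterministically and recorded in the manifest.
#' @param out_dir Output directory.
#' @return An object of class `run_config`.
#' @export
run_config <- function(culture = culture_params(),
                       thickness_nm = 70,
                       min_profile_nm = 20,
                       band_height_um = culture$site_z_extent,
                       site_rate_method = "linear",
                       classifier = classifier_params(),
                       n_patches = 0L,
                       seed = 1L,
                       out_dir = tempfile("evstereo_run_")) {
  stopifnot(inherits(culture, "culture_params"),
            thickness_nm > 0, min_profile_nm >= 0, band_height_um >= 0,
            inherits(classifier, "classifier_params"), n_patches >= 0)
  site_rate_method <- match.arg(site_rate_method,
                                c("linear", "poisson_inversion"))
  structure(list(culture = culture,
                 thickness_nm = thickness_nm,
                 min_profile_nm = min_profile_nm,
                 band_height_um = band_height_um,
                 site_rate_method = site_rate_method,
                 classifier = classifier,
                 n_patches = as.integer(n_patches),
                 seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

#' Read / write a run configuration (YAML or JSON)
#'
#' The on-disk format mirrors [run_config()]: a `culture` block plus
#' top-level scalar options. Parsing then serialising then parsing is the
#' identity on the normalised configuration.
#'
#' @param path File path; `.yaml`/`.yml` is read and written as YAML,
#'   anything else as JSON.
#' @param config A `run_config`.
#' @return `read_run_config` returns a `run_config`; `write_run_config`
#'   returns `path` invisibly.
#' @export
read_run_config <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  cu <- obj$culture %||% list()
  defaults <- culture_params()
  cu_args <- utils::modifyList(unclass(defaults), cu)
  culture <- do.call(culture_params, cu_args)
  cl <- obj$classifier %||% list()
  classifier <- do.call(classifier_params,
                        utils::modifyList(unclass(classifier_params()), cl))
  run_config(culture = culture,
             thickness_nm = obj$thickness_nm %||% 70,
             min_profile_nm = obj$min_profile_nm %||% 20,
             band_height_um = obj$band_height_um %||% culture$site_z_extent,
             site_rate_method = obj$site_rate_method %||% "linear",
             classifier = classifier,
             n_patches = obj$n_patches %||% 0L,
             seed = obj$seed %||% 1L,
             out_dir = obj$out_dir %||% tempfile("evstereo_run_"))
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  obj <- list(culture = unclass(config$culture),
              thickness_nm = config$thickness_nm,
              min_profile_nm = config$min_profile_nm,
              band_height_um = config$band_height_um,
              site_rate_method = config$site_rate_method,
              classifier = unclass(config$classifier),
              n_patches = config$n_patches,
              seed = config$seed,
              out_dir = config$out_dir)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(obj, path, precision = 15L)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Run the full simulation-and-estimation pipeline
#'
#' Executes generate scene -> section (serial, plus a single-random-section
#' site survey) -> tabulate -> estimators (-> classifier on rendered
#' patches when `n_patches > 0`), writing into `config$out_dir`:
#'
#' * `config.json` — the normalised configuration;
#' * `scene.json` — the ground-truth scene;
#' * `counts.csv` (+ `.json` sidecar) — serial-section profile rows and
#'   summaries;
#' * `survey.csv` — the per-cell single-section site survey;
#' * `estimates.json` — site rate, corrected MVBs per MCMV, and the Wilson
#'   interval on the observed site fraction (entries are flagged
#'   `undefined` when the simulated survey is empty);
#' * `decisions.csv` — classifier calls on the rendered patches (if any);
#' * `manifest.json` — seeds, derived per-stage seeds, package version,
#'   normalised parameter echo (including the band fraction p), the md5 of
#'   `config.json`, and the output file list.
#'
#' Identical configuration and seed reproduce byte-identical outputs.
#'
#' @param config A [run_config()].
#' @return The manifest, invisibly (a named list).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  thickness_um <- config$thickness_nm / 1000
  min_profile_um <- config$min_profile_nm / 1000
  seeds <- list(scene = derive_seed(config$seed, "scene"),
                section = derive_seed(config$seed, "section"),
                patch = derive_seed(config$seed, "patch"),
                boot = derive_seed(config$seed, "boot"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  write_run_config(config, out("config.json"))

  scene <- stage("generate_scene",
                 generate_scene(config$culture, seeds$scene))
  write_scene(scene, out("scene.json"))

  serial <- stage("section_scene(serial)",
                  section_scene(scene, thickness_um, "serial",
                                min_profile_um))
  counts <- stage("tabulate", tabulate_counts(serial))
  write_counts(counts, out("counts.csv"))

  survey <- stage("section_scene(single)",
                  section_scene(scene, thickness_um,
                                "single_random_per_cell",
                                min_profile_um, seed = seeds$section))
  utils::write.csv(survey$sightings, out("survey.csv"), row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  survey_counts <- tabulate_counts(survey)

  cell <- pancake_cell(config$culture$cell_diameter_mean,
                       config$culture$cell_height_mean)
  estimates <- list()
  f <- survey_counts$summary$f_sites
  if (is.finite(f) && f < 1) {
    estimates$site_rate <- site_rate(f, cell, config$band_height_um,
                                     config$site_rate_method,
                                     n_cells = survey_counts$n_cells)
    estimates$site_fraction <-
      proportion_ci(survey_counts$summary$n_cells_sighted,
                    survey_counts$n_cells)
  } else {
    estimates$site_rate <- list(quantity = "sites_per_cell",
                                undefined = TRUE,
                                reason = "no cells surveyed or all sighted")
  }
  nbar <- counts$summary$mvb_per_mcmv_profile
  if (is.finite(nbar)) {
    estimates$mvbs_per_mcmv <-
      mvbs_per_mcmv(nbar, config$culture$mcmv_diameter_mean * 1000,
                    config$culture$mvb_diameter_mean * 1000,
                    config$thickness_nm,
                    profile_counts = per_mcmv_profiles(counts),
                    seed = seeds$boot)
  } else {
    estimates$mvbs_per_mcmv <- list(quantity = "mvbs_per_mcmv",
                                    undefined = TRUE,
                                    reason = "no MCMV profiles observed")
  }
  jsonlite::write_json(lapply(estimates, unclass), out("estimates.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")

  files <- c("config.json", "scene.json", "counts.csv", "counts.csv.json",
             "survey.csv", "estimates.json")
  if (config$n_patches > 0L) {
    decisions <- stage("classifier",
                       demo_classifications(config, seeds$patch))
    utils::write.csv(decisions, out("decisions.csv"), row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
    files <- c(files, "decisions.csv")
  }

  manifest <- list(schema = "evstereo/manifest/v1",
                   package_version =
                     as.character(utils::packageVersion("evstereo")),
                   master_seed = config$seed,
                   derived_seeds = seeds,
                   thickness_um = thickness_um,
                   min_profile_um = min_profile_um,
                   band_height_um = config$band_height_um,
                   band_fraction = band_fraction(cell,
                                                 config$band_height_um),
                   site_rate_method = config$site_rate_method,
                   culture = unclass(config$culture),
                   config_md5 = unname(tools::md5sum(out("config.json"))),
                   outputs = files)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest)
}

# Render alternating lucent/dense-lumen patches at the default MVB profile
# size and classify them; one row per patch.
demo_classifications <- function(config, seed) {
  n <- config$n_patches
  lucent <- rep(c(TRUE, FALSE), length.out = n)
  rows <- lapply(seq_len(n), function(i) {
    inner <- if (lucent[i]) 170 else 90
    p <- render_patch(inner_mean = inner, outer_mean = 120, noise_sd = 12,
                      profile_diameter_nm =
                        config$culture$mvb_diameter_mean * 1000,
                      seed = (seed + i) %% 2147483399)
    d <- classify_mvb_like(p, config$culture$mvb_diameter_mean * 1000,
                           config$classifier)
    data.frame(patch = i, true_lucent = lucent[i],
               mvb_call = d$mvb_like,
               separation_D = d$features$separation_D,
               inside_mean = d$features$inside_mean,
               outside_mean = d$features$outside_mean)
  })
  do.call(rbind, rows)
}

#' Recovery validation over a parameter grid
#'
#' Monte-Carlo check that the estimators recover known ground truth: for
#' each site rate in `lambda` a culture of `n_cells` cells is generated,
#' surveyed with one random section per cell, and inverted with
#' `poisson_inversion`; for each MVB rate in `mu` a population of `n_mcmv`
#' MCMVs is serial-sectioned and corrected with [mvbs_per_mcmv()]. Site
#' rates must land within 3 Monte-Carlo SE; the corrected MVB count within
#' `mu_tol` (default 10%, covering small-cap detection loss at the 20-nm
#' threshold). Infeasible grid points (packing failures) are reported per
#' point and the run continues.
#'
#' @param lambda Numeric vector of true site rates (may be empty).
#' @param mu Numeric vector of true MVBs-per-MCMV means (may be empty).
#' @param n_cells Cells per site-rate point (default 20000).
#' @param n_mcmv MCMVs per MVB point (default 2000).
#' @param mu_tol Relative tolerance for the MVB recovery (default 0.1).
#' @param seed Master seed.
#' @param ... Further [culture_params()] overrides applied to every grid
#'   point (e.g. `mcmv_diameter_cv = 0` for fixed-size validation).
#' @return A data frame with one row per grid point: `quantity`, `true`,
#'   `estimate`, `se`, `tolerance`, `pass`, `note`. Attribute `"ok"` is
#'   `TRUE` iff every feasible point passed.
#' @export
validate_recovery <- function(lambda = numeric(0), mu = numeric(0),
                              n_cells = 20000L, n_mcmv = 2000L,
                              mu_tol = 0.1, seed = 1L, ...) {
  rows <- list()
  vseed <- derive_seed(seed, "validate")
  for (i in seq_along(lambda)) {
    lam <- lambda[i]
    res <- tryCatch({
      params <- culture_params(n_cells = n_cells, n_mcmv = 0L,
                               site_rate = lam, ...)
      sc <- generate_scene(params, (vseed + i) %% 2147483399)
      sv <- section_scene(sc, mode = "single_random_per_cell",
                          seed = (vseed + 7 * i + 1) %% 2147483399)
      cnt <- tabulate_counts(sv)
      f <- cnt$summary$f_sites
      est <- site_rate(f, pancake_cell(params$cell_diameter_mean,
                                       params$cell_height_mean),
                       params$site_z_extent, "poisson_inversion",
                       n_cells = n_cells)
      p <- est$inputs$band_fraction
      se <- sqrt(f * (1 - f) / n_cells) / ((1 - f) * p)
      # within-cell correlation bias of the band inversion, known exactly
      # from the generative model (see expected_sighting_fraction)
      f_star <- expected_sighting_fraction(lam,
                                           pancake_cell(
                                             params$cell_diameter_mean,
                                             params$cell_height_mean),
                                           params$site_z_extent)
      bias <- abs(-log(1 - f_star) / p - lam)
      tol <- 3 * se + bias
      data.frame(quantity = "sites_per_cell", true = lam,
                 estimate = est$point, se = se, tolerance = tol,
                 pass = abs(est$point - lam) <= tol, note = "")
    }, error = function(e) {
      data.frame(quantity = "sites_per_cell", true = lam,
                 estimate = NA_real_, se = NA_real_, tolerance = NA_real_,
                 pass = NA, note = conditionMessage(e))
    })
    rows[[length(rows) + 1L]] <- res
  }
  for (i in seq_along(mu)) {
    m <- mu[i]
    res <- tryCatch({
      params <- culture_params(n_cells = 0L, n_mcmv = n_mcmv,
                               mvb_per_mcmv_mean = m, ...)
      sc <- generate_scene(params, (vseed + 1000 + i) %% 2147483399)
      cnt <- tabulate_counts(section_scene(sc, mode = "serial"))
      est <- mvbs_per_mcmv(cnt$summary$mvb_per_mcmv_profile,
                           params$mcmv_diameter_mean * 1000,
                           params$mvb_diameter_mean * 1000, 70,
                           profile_counts = per_mcmv_profiles(cnt),
                           seed = vseed)
      tol <- mu_tol * m
      data.frame(quantity = "mvbs_per_mcmv", true = m,
                 estimate = est$point, se = NA_real_, tolerance = tol,
                 pass = abs(est$point - m) <= tol, note = "")
    }, error = function(e) {
      data.frame(quantity = "mvbs_per_mcmv", true = m,
                 estimate = NA_real_, se = NA_real_, tolerance = NA_real_,
                 pass = NA, note = conditionMessage(e))
    })
    rows[[length(rows) + 1L]] <- res
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(quantity = character(0), true = numeric(0),
               estimate = numeric(0), se = numeric(0),
               tolerance = numeric(0), pass = logical(0),
               note = character(0))
  attr(out, "ok") <- all(out$pass[!is.na(out$pass)]) &&
    !any(is.na(out$pass))
  out
}
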