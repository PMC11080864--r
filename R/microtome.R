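#' Section a scene with the virtual microtome
#'
#' Converts a ground-truthed [generate_scene()] culture into the per-section
#' observations a microscopist scoring en-face serial sections would record.
#' Two survey designs are supported:
#'
#' * `"serial"` — contiguous half-open slabs from the coverslip (z = 0)
#'   upward until the tallest object is exhausted; every spherical body
#'   whose profile at some in-slab plane reaches `min_profile` yields one
#'   profile row per slab.
#' * `"single_random_per_cell"` — one section per cell at a uniformly
#'   random depth in `[0, cell height)`, emulating a single-section survey
#'   of the fraction of cells showing a protrusion site; body profiles are
#'   not scored in this mode.
#'
#' A lateral-wall protrusion site is scored in a section when the section
#' majority-overlaps the site's z-band (overlap at least half the section
#' thickness, or half the site extent for sub-thickness sites). Under this
#' scoring rule a band of extent h on a wall of height H is seen in exactly
#' h worth of sections, so the detection probability of one random section
#' is h/H — the identity the band-sampling estimator relies on (see the
#' methods vignette). Sites on the top/bottom cell faces are never visible
#' en face.
#'
#' @param scene An `ev_scene`.
#' @param thickness Section thickness in um (default 0.07).
#' @param mode `"serial"` or `"single_random_per_cell"`.
#' @param min_profile Minimum detectable profile diameter in um (default
#'   0.02, i.e. 20 nm); polar caps thinner than this are missed, the main
#'   small-cap bias of real surveys.
#' @param omega_span_slabs Number of consecutive slabs an omega mark is
#'   visible in (default 1; fusion profiles can smear across 2).
#' @param seed Integer seed for the random per-cell sections (required for
#'   `single_random_per_cell`; unused in serial mode).
#' @return An object of class `ev_sections`: list with `mode`, `thickness`,
#'   `min_profile`, `n_cells`, `sightings` (per-cell site sightings),
#'   `profiles` (one row per body profile: `slab_index`, `body_id`, `kind`,
#'   `parent_id`, `profile_nm`, `contains_ilv`, `n_omega`, `orphan`).
#' @examples
#' sc <- generate_scene(culture_params(n_cells = 5, n_mcmv = 3), seed = 1)
#' obs <- section_scene(sc, mode = "serial")
#' head(obs$profiles)
#' @export
section_scene <- function(scene, thickness = 0.07,
                          mode = c("serial", "single_random_per_cell"),
                          min_profile = 0.02, omega_span_slabs = 1L,
                          seed = NULL) {
  stopifnot(inherits(scene, "ev_scene"), thickness > 0, min_profile >= 0,
            omega_span_slabs %in% c(1L, 2L))
  mode <- match.arg(mode)
  if (mode == "single_random_per_cell") {
    if (is.null(seed)) {
      stop("single_random_per_cell mode needs a seed for the random sections")
    }
    sightings <- with_seed(seed, single_section_sightings(scene, thickness))
    profiles <- empty_profiles()
  } else {
    sightings <- serial_sightings(scene, thickness)
    profiles <- serial_profiles(scene, thickness, min_profile,
                                omega_span_slabs)
  }
  structure(list(mode = mode,
                 thickness = thickness,
                 min_profile = min_profile,
                 n_cells = nrow(scene$cells),
                 cell_ids = scene$cells$cell_id,
                 sightings = sightings,
                 profiles = profiles,
                 seed_used = if (is.null(seed)) NA_integer_
                             else as.integer(seed)),
            class = "ev_sections")
}

empty_profiles <- function() {
  data.frame(slab_index = integer(0), body_id = integer(0),
             kind = character(0), parent_id = integer(0),
             profile_nm = numeric(0), contains_ilv = logical(0),
             n_omega = integer(0), orphan = logical(0))
}

# majority-overlap threshold for a site band of extent e in sections of
# thickness T: the site is scored when the in-slab overlap reaches
# min(T, e) / 2
site_overlap_threshold <- function(extent, thickness) {
  pmin(thickness, extent) / 2
}

single_section_sightings <- function(scene, thickness) {
  cells <- scene$cells
  n <- nrow(cells)
  z_s <- stats::runif(n, 0, cells$height)
  sighted <- rep(FALSE, n)
  s <- scene$sites[scene$sites$on_lateral, , drop = FALSE]
  if (nrow(s) > 0) {
    idx <- match(s$cell_id, cells$cell_id)
    lo <- z_s[idx]
    overlap <- pmin(s$z_hi, lo + thickness) - pmax(s$z_lo, lo)
    thr <- site_overlap_threshold(s$z_hi - s$z_lo, thickness)
    hit <- overlap >= thr - 1e-12
    sighted[sort(unique(idx[hit]))] <- TRUE
  }
  data.frame(cell_id = cells$cell_id, slab_z = z_s, sighted = sighted)
}

serial_sightings <- function(scene, thickness) {
  s <- scene$sites[scene$sites$on_lateral, , drop = FALSE]
  empty <- data.frame(cell_id = integer(0), slab_index = integer(0))
  if (nrow(s) == 0) {
    return(empty)
  }
  k_lo <- pmax(0L, floor_fuzzy(s$z_lo / thickness) - 1L)
  k_hi <- ceiling_fuzzy(s$z_hi / thickness)
  counts <- k_hi - k_lo + 1L
  k <- sequence(counts) - 1L + rep(k_lo, counts)
  i <- rep(seq_len(nrow(s)), counts)
  overlap <- pmin(s$z_hi[i], (k + 1) * thickness) -
    pmax(s$z_lo[i], k * thickness)
  thr <- site_overlap_threshold(s$z_hi[i] - s$z_lo[i], thickness)
  keep <- overlap >= thr - 1e-12
  if (!any(keep)) {
    return(empty)
  }
  out <- unique(data.frame(cell_id = s$cell_id[i][keep],
                           slab_index = as.integer(k[keep])))
  out <- out[order(out$cell_id, out$slab_index), , drop = FALSE]
  rownames(out) <- NULL
  out
}

serial_profiles <- function(scene, thickness, min_profile, omega_span) {
  b <- scene$bodies
  if (nrow(b) == 0) {
    return(empty_profiles())
  }
  z_bot <- b$z - b$diameter / 2
  z_top <- b$z + b$diameter / 2
  k_lo <- pmax(0L, floor_fuzzy(z_bot / thickness))
  k_hi <- pmax(k_lo, ceiling_fuzzy(z_top / thickness) - 1L)
  counts <- k_hi - k_lo + 1L
  k <- sequence(counts) - 1L + rep(k_lo, counts)
  i <- rep(seq_len(nrow(b)), counts)
  prof <- profile_in_slab(b$z[i], b$diameter[i], k * thickness, thickness)
  keep <- !is.na(prof) & prof >= min_profile
  df <- data.frame(slab_index = as.integer(k[keep]),
                   body_id = b$body_id[i][keep],
                   kind = b$kind[i][keep],
                   parent_id = b$parent_id[i][keep],
                   profile_nm = prof[keep] * 1000)
  seen <- paste(df$body_id, df$slab_index)
  # an ILV profile is attributed to its MVB only when both are in the slab
  ilv <- df[df$kind == "ILV", , drop = FALSE]
  ilv_key <- paste(ilv$parent_id, ilv$slab_index)
  df$contains_ilv <- ifelse(df$kind == "MVB",
                            paste(df$body_id, df$slab_index) %in% ilv_key,
                            NA)
  # orphan: nested body visible in a slab where its parent's cap is below
  # the detection threshold
  df$orphan <- ifelse(is.na(df$parent_id), FALSE,
                      !(paste(df$parent_id, df$slab_index) %in% seen))
  # omega marks per (MCMV, slab); a mark can smear into the slab above
  om <- scene$omegas
  df$n_omega <- ifelse(df$kind == "MCMV", 0L, NA_integer_)
  if (nrow(om) > 0) {
    ks <- floor_fuzzy(om$z / thickness)
    id <- om$mcmv_id
    if (omega_span == 2L) {
      ks <- c(ks, ks + 1L)
      id <- c(id, om$mcmv_id)
    }
    tab <- table(paste(id, ks))
    key <- paste(df$body_id, df$slab_index)
    hit <- df$kind == "MCMV" & key %in% names(tab)
    df$n_omega[hit] <- as.integer(tab[key[hit]])
  }
  df <- df[order(df$slab_index, df$body_id), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Tabulate sectioning observations into a counts table
#'
#' Collapses one sectioning run (or a list of runs with identical thickness
#' and mode) into the counting-table summaries of a thin-section survey:
#'
#' * `f_sites` — fraction of cells showing at least one protrusion-site
#'   profile (per random section in single-section mode; in any section in
#'   serial mode);
#' * `mvb_per_mcmv_profile` — mean MVB profiles per MCMV profile (orphan
#'   MVB profiles excluded), the raw input to the profile-count correction;
#' * `omega_fraction` — fraction of MCMV profiles with >= 1 omega figure;
#' * `ilv_fraction` — fraction of (non-orphan) MVB profiles containing an
#'   ILV profile in the same section.
#'
#' Undefined fractions (no qualifying profiles) are reported as `NaN`.
#' Summaries are always recomputed from the profile rows, never stored
#' independently.
#'
#' @param observations An `ev_sections` object or a list of them.
#' @return An object of class `ev_counts`: list with `rows` (profile
#'   table), `sightings`, `summary`, `thickness`, `mode`, `n_cells`.
#' @export
tabulate_counts <- function(observations) {
  if (inherits(observations, "ev_sections")) {
    observations <- list(observations)
  }
  stopifnot(length(observations) >= 1,
            all(vapply(observations, inherits, TRUE, "ev_sections")))
  th <- vapply(observations, `[[`, 0, "thickness")
  md <- vapply(observations, `[[`, "", "mode")
  if (length(unique(th)) != 1L) {
    stop("inconsistent observations: mixed section thicknesses (",
         paste(unique(th), collapse = ", "), ")")
  }
  if (length(unique(md)) != 1L) {
    stop("inconsistent observations: mixed sectioning modes")
  }
  rows <- do.call(rbind, lapply(observations, `[[`, "profiles"))
  sightings <- do.call(rbind, lapply(observations, `[[`, "sightings"))
  n_cells <- sum(vapply(observations, `[[`, 0L, "n_cells"))
  mode <- md[1]
  n_sighted <- if (mode == "single_random_per_cell") {
    sum(sightings$sighted)
  } else {
    length(unique(sightings$cell_id))
  }
  summary <- counts_summary(rows, n_cells, n_sighted)
  structure(list(rows = rows, sightings = sightings, summary = summary,
                 thickness = th[1], mode = mode, n_cells = n_cells),
            class = "ev_counts")
}

counts_summary <- function(rows, n_cells, n_sighted) {
  mcmv <- rows[rows$kind == "MCMV", , drop = FALSE]
  mvb <- rows[rows$kind == "MVB" & !rows$orphan, , drop = FALSE]
  list(n_cells = n_cells,
       n_cells_sighted = n_sighted,
       f_sites = if (n_cells > 0) n_sighted / n_cells else NaN,
       n_mcmv_profiles = nrow(mcmv),
       n_mvb_profiles = nrow(mvb),
       mvb_per_mcmv_profile = if (nrow(mcmv) > 0) nrow(mvb) / nrow(mcmv)
                              else NaN,
       omega_fraction = if (nrow(mcmv) > 0) mean(mcmv$n_omega >= 1L)
                        else NaN,
       ilv_fraction = if (nrow(mvb) > 0) mean(mvb$contains_ilv) else NaN)
}

#' @export
print.ev_counts <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<ev_counts> %s mode, T = %g um\n", x$mode, x$thickness))
  cat(sprintf("  cells: %d, with site profile: %d (f_sites = %.4f)\n",
              s$n_cells, s$n_cells_sighted, s$f_sites))
  cat(sprintf("  MCMV profiles: %d, MVB profiles: %d (%.4f per MCMV profile)\n",
              s$n_mcmv_profiles, s$n_mvb_profiles, s$mvb_per_mcmv_profile))
  cat(sprintf("  omega fraction: %.4f, ILV co-sighting fraction: %.4f\n",
              s$omega_fraction, s$ilv_fraction))
  invisible(x)
}

#' Per-MCMV profile counts
#'
#' Per-MCMV totals of MCMV profile rows and attributed MVB profile rows
#' from a serial counts table — the bootstrap unit for the uncertainty of
#' the vesicles-per-body correction.
#'
#' @param counts An `ev_counts` from serial sectioning.
#' @return Data frame with `mcmv_id`, `n_mcmv_profiles`, `n_mvb_profiles`.
#' @export
per_mcmv_profiles <- function(counts) {
  stopifnot(inherits(counts, "ev_counts"))
  rows <- counts$rows
  mcmv <- rows[rows$kind == "MCMV", , drop = FALSE]
  mvb <- rows[rows$kind == "MVB" & !rows$orphan, , drop = FALSE]
  ids <- sort(unique(mcmv$body_id))
  data.frame(mcmv_id = ids,
             n_mcmv_profiles = as.integer(table(factor(mcmv$body_id,
                                                       levels = ids))),
             n_mvb_profiles = as.integer(table(factor(mvb$parent_id,
                                                      levels = ids))))
}

#' Write / read a counts table as CSV with a JSON summary sidecar
#'
#' The profile rows go to `<path>` as plain comma-separated UTF-8 with a
#' header (`slab_index, body_id, kind, parent_id, profile_nm, contains_ilv,
#' n_omega, orphan`); the summary block and run metadata go to
#' `<path>.json`.
#'
#' @param counts An `ev_counts`.
#' @param path CSV output path.
#' @return `write_counts` returns `path` invisibly; `read_counts` an
#'   `ev_counts` (sightings are not round-tripped; `f_sites` is restored
#'   from the sidecar).
#' @export
write_counts <- function(counts, path) {
  stopifnot(inherits(counts, "ev_counts"))
  utils::write.csv(counts$rows, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  jsonlite::write_json(list(schema = "evstereo/counts/v1",
                            thickness = counts$thickness,
                            mode = counts$mode,
                            n_cells = counts$n_cells,
                            summary = counts$summary),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_counts
#' @export
read_counts <- function(path) {
  rows <- utils::read.csv(path, stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  if (!identical(meta$schema, "evstereo/counts/v1")) {
    stop("not an evstereo counts sidecar: ", path, ".json")
  }
  summary <- counts_summary(rows, meta$n_cells,
                            meta$summary$n_cells_sighted)
  structure(list(rows = rows,
                 sightings = NULL,
                 summary = summary,
                 thickness = meta$thickness,
                 mode = meta$mode,
                 n_cells = meta$n_cells),
            class = "ev_counts")
}
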