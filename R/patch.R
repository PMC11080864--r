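#' Grey-scale patch with inside/outside masks
#'
#' A region of interest drawn around a candidate vesicle profile: an 8-bit
#' grey-level pixel matrix with congruent logical masks for pixels inside
#' and outside the candidate. The masks must be disjoint and each contain
#' at least 50 pixels, so both histogram modes are estimated from many
#' pixels. Grey convention: higher value = lighter (more electron-lucent);
#' see [histogram_separation()] for the inverted-acquisition flag.
#'
#' @param pixels Numeric matrix of grey levels on the 0-255 scale.
#' @param inside_mask,outside_mask Logical matrices, same dimension as
#'   `pixels`.
#' @param nm_per_px Pixel calibration in nm per pixel (> 0).
#' @return An object of class `patch_roi`.
#' @export
patch_roi <- function(pixels, inside_mask, outside_mask, nm_per_px) {
  stopifnot(is.matrix(pixels), is.numeric(pixels))
  if (!is.logical(inside_mask) || !is.logical(outside_mask) ||
      !identical(dim(inside_mask), dim(pixels)) ||
      !identical(dim(outside_mask), dim(pixels))) {
    stop("invalid patch: masks must be logical matrices congruent with pixels")
  }
  if (any(inside_mask & outside_mask)) {
    stop("invalid patch: inside and outside masks overlap")
  }
  if (sum(inside_mask) < 50L || sum(outside_mask) < 50L) {
    stop("invalid patch: each mask needs at least 50 pixels")
  }
  if (!is.numeric(nm_per_px) || length(nm_per_px) != 1L || nm_per_px <= 0) {
    stop("invalid patch: nm_per_px must be positive")
  }
  structure(list(pixels = pixels, inside_mask = inside_mask,
                 outside_mask = outside_mask, nm_per_px = nm_per_px),
            class = "patch_roi")
}

#' Render a synthetic vesicle patch
#'
#' Draws a two-mean disk fixture emulating a vesicle profile in a thin
#' section: pixels inside a centred disk of the stated profile diameter are
#' Normal(`inner_mean`, `noise_sd`), outside pixels Normal(`outer_mean`,
#' `noise_sd`), clipped to `[0, 255]`. A one-pixel guard ring around the
#' disk boundary is excluded from both masks so neither mode is
#' contaminated by partial-coverage pixels.
#'
#' @param inner_mean,outer_mean Grey levels in `[0, 255]`.
#' @param noise_sd Grey-level noise standard deviation.
#' @param profile_diameter_nm Disk diameter in nm.
#' @param nm_per_px Calibration (default 4 nm/px).
#' @param margin_px Clear margin around the disk (default 8 px).
#' @param seed Integer seed; identical seed reproduces the pixel array.
#' @return A [patch_roi()].
#' @examples
#' p <- render_patch(180, 120, 10, 367, seed = 1)
#' mean(p$pixels[p$inside_mask])
#' @export
render_patch <- function(inner_mean, outer_mean, noise_sd,
                         profile_diameter_nm, nm_per_px = 4,
                         margin_px = 8L, seed = 1L) {
  stopifnot(inner_mean >= 0, inner_mean <= 255,
            outer_mean >= 0, outer_mean <= 255,
            noise_sd >= 0, profile_diameter_nm > 0, nm_per_px > 0)
  r_px <- profile_diameter_nm / nm_per_px / 2
  side <- ceiling(2 * r_px) + 2L * as.integer(margin_px)
  if (side < 16L) side <- 16L
  if (2 * r_px > side) {
    stop("invalid geometry: disk larger than patch")
  }
  cx <- (side + 1) / 2
  idx <- seq_len(side)
  dist <- sqrt(outer(idx - cx, idx - cx, function(a, b) a^2 + b^2))
  inside <- dist <= r_px - 1
  outside <- dist >= r_px + 1
  with_seed(seed, {
    px <- matrix(stats::rnorm(side * side, outer_mean, noise_sd), side, side)
    px[dist <= r_px] <- stats::rnorm(sum(dist <= r_px), inner_mean, noise_sd)
  })
  px[] <- pmin(255, pmax(0, px))
  patch_roi(px, inside, outside, nm_per_px)
}

#' Write / read a patch as 8-bit grey TIFF
#'
#' The pixel array and its two masks are written as separate single-channel
#' TIFFs (`<stem>.tif`, `<stem>_inside.tif`, `<stem>_outside.tif`); the
#' calibration is stored in a JSON sidecar `<stem>.json`.
#'
#' @param patch A [patch_roi()].
#' @param stem Output path stem (no extension).
#' @return `write_patch` returns `stem` invisibly; `read_patch` a
#'   [patch_roi()].
#' @export
write_patch <- function(patch, stem) {
  stopifnot(inherits(patch, "patch_roi"))
  tiff::writeTIFF(round(patch$pixels) / 255, paste0(stem, ".tif"),
                  bits.per.sample = 8L)
  tiff::writeTIFF(patch$inside_mask * 1, paste0(stem, "_inside.tif"),
                  bits.per.sample = 8L)
  tiff::writeTIFF(patch$outside_mask * 1, paste0(stem, "_outside.tif"),
                  bits.per.sample = 8L)
  jsonlite::write_json(list(nm_per_px = patch$nm_per_px),
                       paste0(stem, ".json"), auto_unbox = TRUE)
  invisible(stem)
}

#' @rdname write_patch
#' @export
read_patch <- function(stem) {
  px <- tiff::readTIFF(paste0(stem, ".tif")) * 255
  inside <- tiff::readTIFF(paste0(stem, "_inside.tif")) > 0.5
  outside <- tiff::readTIFF(paste0(stem, "_outside.tif")) > 0.5
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  patch_roi(px, inside, outside, meta$nm_per_px)
}
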