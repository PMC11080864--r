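#' Classifier parameters for the MVB-like call
#'
#' The morphological rule for counting a vesicle profile as MVB-like: size
#' above `min_diameter` (strictly greater), and an electron-lucent lumen,
#' i.e. the grey-value histogram of the region of interest resolves into
#' two modes with the inside lighter than the outside. "Clear separation of
#' two peaks" is operationalised as Ashman's D on the mask statistics
#' reaching `separation_D_threshold`; D >= 2 is the classical bound at
#' which a two-Gaussian mixture is resolvable as bimodal, and is
#' bin-width-free unlike literal peak finding on a binned histogram.
#'
#' @param min_diameter Minimum profile major axis in nm (default 200).
#' @param separation_D_threshold Ashman's D threshold (default 2).
#' @param inverted Set `TRUE` for acquisitions where higher grey value =
#'   darker; flips the lighter-inside comparison.
#' @return An object of class `classifier_params`.
#' @export
classifier_params <- function(min_diameter = 200,
                              separation_D_threshold = 2,
                              inverted = FALSE) {
  stopifnot(min_diameter > 0, separation_D_threshold > 0,
            is.logical(inverted), length(inverted) == 1L)
  structure(list(min_diameter = min_diameter,
                 separation_D_threshold = separation_D_threshold,
                 inverted = inverted),
            class = "classifier_params")
}

#' Histogram separation of inside vs outside grey levels
#'
#' Ashman's D between the inside- and outside-mask pixel populations,
#' \eqn{D = \sqrt{2}\,|\mu_{in}-\mu_{out}| / \sqrt{\sigma_{in}^2 +
#' \sigma_{out}^2}}, with `separated = (D >= threshold)` and
#' `lighter_inside = (mu_in > mu_out)` under the convention that higher
#' grey value = lighter (electron-lucent). Two identical degenerate
#' (zero-variance, equal-mean) populations give D = 0; distinct means with
#' zero variance give D = Inf.
#'
#' @param patch A [patch_roi()].
#' @param params A [classifier_params()].
#' @return A list with `separated`, `D`, `lighter_inside`, `inside_mean`,
#'   `outside_mean`.
#' @examples
#' p <- render_patch(180, 120, 10, 367, seed = 1)
#' histogram_separation(p)
#' @export
histogram_separation <- function(patch, params = classifier_params()) {
  stopifnot(inherits(patch, "patch_roi"),
            inherits(params, "classifier_params"))
  xin <- patch$pixels[patch$inside_mask]
  xout <- patch$pixels[patch$outside_mask]
  mu_in <- mean(xin)
  mu_out <- mean(xout)
  pooled <- stats::var(xin) + stats::var(xout)
  diff <- abs(mu_in - mu_out)
  D <- if (pooled > 0) {
    sqrt(2) * diff / sqrt(pooled)
  } else if (diff > 0) {
    Inf
  } else {
    0
  }
  lighter <- if (params$inverted) mu_in < mu_out else mu_in > mu_out
  list(separated = D >= params$separation_D_threshold,
       D = D,
       lighter_inside = lighter,
       inside_mean = mu_in,
       outside_mean = mu_out)
}

#' Call a vesicle profile MVB-like
#'
#' Applies the full morphological rule: the measured profile major axis
#' must exceed `min_diameter` (strictly), and the region of interest must
#' show a separated grey-value histogram with the inside lighter than the
#' outside. The major axis is supplied by the caller (measured on the
#' micrograph at the same calibration as the patch), not derived from mask
#' geometry. All features are returned for audit.
#'
#' @param patch A [patch_roi()].
#' @param major_axis_nm Measured profile major axis in nm.
#' @param params A [classifier_params()].
#' @return An object of class `mvb_decision`: list with `mvb_like` and a
#'   `features` list (`major_axis_nm`, `inside_mean`, `outside_mean`,
#'   `separation_D`, `lighter_inside`, `size_ok`).
#' @examples
#' p <- render_patch(180, 120, 10, 367, seed = 1)
#' classify_mvb_like(p, 367)$mvb_like
#' @export
classify_mvb_like <- function(patch, major_axis_nm,
                              params = classifier_params()) {
  if (!is.numeric(major_axis_nm) || length(major_axis_nm) != 1L ||
      !is.finite(major_axis_nm) || major_axis_nm < 0) {
    stop("invalid input: major_axis_nm must be a non-negative number")
  }
  sep <- histogram_separation(patch, params)
  size_ok <- major_axis_nm > params$min_diameter
  structure(list(mvb_like = size_ok && sep$separated && sep$lighter_inside,
                 features = list(major_axis_nm = major_axis_nm,
                                 inside_mean = sep$inside_mean,
                                 outside_mean = sep$outside_mean,
                                 separation_D = sep$D,
                                 lighter_inside = sep$lighter_inside,
                                 size_ok = size_ok)),
            class = "mvb_decision")
}

#' @export
print.mvb_decision <- function(x, ...) {
  f <- x$features
  cat(sprintf(paste0("<mvb_decision> %s (major axis %.0f nm, D = %.2f, ",
                     "inside %.1f vs outside %.1f)\n"),
              if (x$mvb_like) "MVB-like" else "not MVB-like",
              f$major_axis_nm, f$separation_D, f$inside_mean,
              f$outside_mean))
  invisible(x)
}
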