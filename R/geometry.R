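#' Pancake cell model
#'
#' An adherent endothelial cell is idealised as a flat cylinder ("pancake"):
#' two circular faces of diameter `diameter` joined by a lateral wall of
#' height `height`. All lengths are in micrometres; z = 0 is the coverslip
#' plane and z increases away from it.
#'
#' @param diameter Cell diameter in um (must be positive).
#' @param height Cell height in um (non-negative; 0 gives a degenerate disk).
#' @return An object of class `pancake_cell`.
#' @examples
#' huvec <- pancake_cell(24, 4)
#' pancake_surface_area(huvec)
#' @export
pancake_cell <- function(diameter, height) {
  if (!is.numeric(diameter) || length(diameter) != 1L || !is.finite(diameter) ||
      diameter <= 0) {
    stop("invalid geometry: cell diameter must be a positive number")
  }
  if (!is.numeric(height) || length(height) != 1L || !is.finite(height) ||
      height < 0) {
    stop("invalid geometry: cell height must be non-negative")
  }
  structure(list(diameter = diameter, height = height),
            class = "pancake_cell")
}

#' @export
print.pancake_cell <- function(x, ...) {
  cat(sprintf("<pancake_cell> diameter %.3g um, height %.3g um, area %.5g um^2\n",
              x$diameter, x$height, pancake_surface_area(x)))
  invisible(x)
}

#' Total membrane area of a pancake cell
#'
#' Area of both circular faces plus the lateral wall:
#' \eqn{A = 2\pi (d/2)^2 + \pi d H}. For the default endothelial geometry
#' (d = 24 um, H = 4 um) this is 1206.4 um^2, i.e. about 1200 um^2.
#'
#' @param cell A [pancake_cell()].
#' @return Area in um^2.
#' @export
pancake_surface_area <- function(cell) {
  stopifnot(inherits(cell, "pancake_cell"))
  2 * pi * (cell$diameter / 2)^2 + pi * cell$diameter * cell$height
}

#' Lateral band area sampled by a z-band of the cell wall
#'
#' Area of a band of height `band_height` on the lateral wall,
#' \eqn{\pi d h}; for d = 24 um and h = 2 um this is ~150 um^2. The ratio of
#' this band to the total membrane area is the detection probability used by
#' the site-rate estimator (see [band_fraction()]).
#'
#' @param cell A [pancake_cell()].
#' @param band_height Band height in um, between 0 and `cell$height`.
#' @return Area in um^2.
#' @export
lateral_band_area <- function(cell, band_height) {
  stopifnot(inherits(cell, "pancake_cell"))
  if (!is.numeric(band_height) || length(band_height) != 1L ||
      !is.finite(band_height) || band_height < 0) {
    stop("invalid geometry: band height must be non-negative")
  }
  if (band_height > cell$height) {
    stop("invalid geometry: band height exceeds cell height")
  }
  pi * cell$diameter * band_height
}

#' Band fraction p = A_band / A_total
#'
#' The dimensionless fraction of the cell membrane sampled by a lateral
#' z-band; equal to \eqn{dh / (d^2/2 + dH)}. Invariant to uniform rescaling
#' of all lengths. For d = 24, H = 4, h = 2 it is exactly 1/8.
#'
#' @inheritParams lateral_band_area
#' @return A probability in `[0, 1]`.
#' @export
band_fraction <- function(cell, band_height) {
  lateral_band_area(cell, band_height) / pancake_surface_area(cell)
}

#' Spherical body
#'
#' A sphere used to model MCMVs, the MVB-like vesicles nested inside them,
#' and ILV-like vesicles nested inside those. Coordinates in um with z
#' measured from the coverslip. If `parent` is given the body must lie
#' entirely inside it.
#'
#' @param center Numeric length-3 (x, y, z) in um.
#' @param diameter Sphere diameter in um.
#' @param kind One of `"MCMV"`, `"MVB"`, `"ILV"`, `"generic"`.
#' @param parent Optional enclosing `sphere_body`.
#' @return An object of class `sphere_body`.
#' @export
sphere_body <- function(center, diameter, kind = "generic", parent = NULL) {
  if (!is.numeric(center) || length(center) != 3L || any(!is.finite(center))) {
    stop("invalid geometry: center must be a finite (x, y, z) triple")
  }
  if (!is.numeric(diameter) || length(diameter) != 1L || !is.finite(diameter) ||
      diameter <= 0) {
    stop("invalid geometry: sphere diameter must be positive")
  }
  kind <- match.arg(kind, c("MCMV", "MVB", "ILV", "generic"))
  if (!is.null(parent)) {
    stopifnot(inherits(parent, "sphere_body"))
    gap <- (parent$diameter - diameter) / 2
    if (gap < 0 || sqrt(sum((center - parent$center)^2)) > gap + 1e-12) {
      stop("invalid geometry: body is not contained in its parent sphere")
    }
  }
  structure(list(center = center, diameter = diameter, kind = kind,
                 parent = parent),
            class = "sphere_body")
}

#' Section slab
#'
#' One 70-nm-style section, the `index`-th slab cut from the coverslip:
#' the half-open z-interval `[index * thickness, (index + 1) * thickness)`.
#' Half-open slabs partition z without double counting, which makes "the
#' first section in which a structure appears" unambiguous.
#'
#' @param index Non-negative integer slab index (0 = at the coverslip).
#' @param thickness Section thickness in um (default 0.07, i.e. 70 nm).
#' @return An object of class `section_slab`.
#' @export
section_slab <- function(index, thickness = 0.07) {
  if (!is.numeric(index) || length(index) != 1L || index < 0 ||
      index != round(index)) {
    stop("invalid geometry: slab index must be a non-negative integer")
  }
  if (!is.numeric(thickness) || length(thickness) != 1L || thickness <= 0) {
    stop("invalid geometry: slab thickness must be positive")
  }
  structure(list(index = as.integer(index),
                 z_lo = index * thickness,
                 thickness = thickness),
            class = "section_slab")
}

# Vectorised workhorse: diameter of the largest circular cross-section of a
# sphere (center z `cz`, diameter `d`) attained inside slab [z_lo, z_lo + T).
# NA when the sphere's z-extent misses the slab (tangential contact counts
# as a miss; measure-zero contact is excluded for consistency with half-open
# slabs). If the equatorial plane is inside the slab the full diameter is
# returned; otherwise the chord circle 2*sqrt(r^2 - delta^2) at the nearest
# in-slab plane, delta being the center-to-plane distance.
profile_in_slab <- function(cz, d, z_lo, thickness) {
  r <- d / 2
  z_hi <- z_lo + thickness
  hit <- (cz - r < z_hi) & (cz + r > z_lo)
  delta <- pmax(0, pmax(z_lo - cz, cz - z_hi))
  prof <- 2 * sqrt(pmax(0, r^2 - delta^2))
  prof[!hit] <- NA_real_
  prof
}

#' Profile diameter of a sphere in a section
#'
#' The diameter of the circular profile a microscopist would measure for a
#' spherical body in one thin section: the widest circular cross-section of
#' the sphere attained at any z inside the slab. `NA` when the sphere does
#' not enter the slab.
#'
#' @param body A [sphere_body()].
#' @param slab A [section_slab()].
#' @return Profile diameter in um, or `NA` if the body misses the slab.
#' @examples
#' mvb <- sphere_body(c(0, 0, 0.5), 0.367, "MVB")
#' sphere_slab_profile(mvb, section_slab(7))
#' @export
sphere_slab_profile <- function(body, slab) {
  stopifnot(inherits(body, "sphere_body"), inherits(slab, "section_slab"))
  profile_in_slab(body$center[3], body$diameter, slab$z_lo, slab$thickness)
}

#' Number of serial sections spanned by an object
#'
#' Count of contiguous half-open slabs of the given thickness intersected by
#' the z-interval `[z_offset, z_offset + diameter)`. Over all offsets this
#' takes exactly the two values `ceiling(d / T)` and `ceiling(d / T) + 1`;
#' its mean over a uniform offset is `(d + T) / T`, the Abercrombie factor
#' underlying the profile-count correction.
#'
#' @param diameter Object extent in z (any length unit).
#' @param thickness Section thickness (same unit).
#' @param z_offset Offset of the object bottom above the nearest lower slab
#'   boundary; `0 <= z_offset < thickness`.
#' @return Integer number of sections.
#' @examples
#' sections_spanned(1080, 70, 0)   # a 1.08-um MCMV cut at phase 0: 16
#' sections_spanned(630, 70, 35)   # a 630-nm body can span 10 sections
#' @export
sections_spanned <- function(diameter, thickness, z_offset = 0) {
  stopifnot(is.numeric(diameter), diameter > 0,
            is.numeric(thickness), thickness > 0,
            is.numeric(z_offset), z_offset >= 0, z_offset < thickness)
  as.integer(ceiling_fuzzy((z_offset + diameter) / thickness) -
               floor_fuzzy(z_offset / thickness))
}
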