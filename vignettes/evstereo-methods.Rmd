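---
title: "Stereological models behind evstereo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stereological models behind evstereo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evstereo)
```

## The problem

Endothelial cells in culture release multi-compartmented microvesicles
(MCMVs): plasma-membrane-derived vesicles, pinched off from clustered
surface protrusions, that themselves contain multivesicular bodies (MVBs)
with intraluminal vesicles (ILVs). The structures are characterised by
transmission EM of 70-nm serial sections cut *en face* — parallel to the
coverslip — and the interesting quantities are three-dimensional (sites
per cell, MVBs per MCMV) while the observations are two-dimensional
profiles in thin sections. `evstereo` implements the estimators that
bridge that gap, and a ground-truthed synthetic culture plus virtual
microtome to validate them end to end without requiring annotated
micrographs.

Conventions used throughout: z = 0 at the coverslip, increasing into the
culture; sections are contiguous half-open slabs $[kT, (k+1)T)$ with
$T = 70$ nm, so "the first section in which a structure appears" is
unambiguous and no structure is double-counted at a boundary; internal
lengths are in micrometres; grey levels are 8-bit with higher = lighter
(electron-lucent).

## The pancake cell and the site-rate estimator

A cultured endothelial cell is modelled as a flat cylinder of diameter
$d = 24\ \mu m$ and height $H = 4\ \mu m$, giving a membrane area

$$A_{total} = 2\pi (d/2)^2 + \pi d H \approx 1206\ \mu m^2 \approx 1200\ \mu m^2 .$$

A protrusion site is treated as a band on the lateral wall with a
conservative vertical extent of $h = 2\ \mu m$, so one random en-face
section samples a band of area $\pi d h \approx 150\ \mu m^2$, a fraction

$$p = \frac{\pi d h}{A_{total}} = \frac{dh}{d^2/2 + dH} = 0.125$$

of the membrane. If a fraction $f$ of surveyed cells shows a site
profile, the mean number of sites per cell is estimated as

* **linear** (the default): $\hat\lambda = f/p$ — with $f = 0.09$ this
  gives $0.72 \approx 3/4$;
* **poisson_inversion**: $\hat\lambda = -\log(1-f)/p$, which undoes the
  saturation effect that a cell with two sites in the band still counts
  once ($(1-e^{-\lambda p})/(\lambda p) \approx 0.956$ at
  $\lambda p = 0.09$, i.e. the linear estimate sits ~4.4% low).

Uncertainty comes from a Wilson score interval on $f$ (appropriate for
small observed fractions), mapped through the chosen inversion. Wilson
rather than Wald because the survey fractions of interest are near zero.

### Site placement and the scoring rule

Three coupled choices make the band arithmetic *exact* in the generator,
so that estimator validation tests the estimator and not an accident of
the simulation:

1. **Placement.** Sites land on the lateral wall with probability
   $\pi dH / A_{total}$ (area-proportional allocation; top/bottom-face
   sites are generated but can never be seen en face). Lateral z-centers
   are uniform on $[h/2, H - h/2]$, so the full band always sits on the
   wall. Truncating bands that cross the wall edges instead would shrink
   the mean detectable window from $h$ to $h(1 - h/(4H)) = 1.75\ \mu m$
   and silently bias every downstream estimate.
2. **Scoring.** A site is scored in a section when the section
   majority-overlaps the band: overlap at least $\min(T, h)/2$. Under
   this rule a band of extent $h$ is scored in exactly $h$ worth of
   sections, so the single-section detection probability is exactly
   $h/H$ per lateral site; plain interval intersection would add a $+T$
   smear ($p_{eff} = 0.129$ instead of $0.125$) that the band
   arithmetic does not include. A band narrower than a section is still scored in
   the section that contains (most of) it.
3. **Survey design.** `single_random_per_cell` mode draws one random
   section depth per cell, as a microscopist scores one section through
   each cell.

Because all sites of one cell are compared against the *same* random
section, detections within a cell are positively correlated and the
sighting probability is exactly

$$f(\lambda) = \mathbb{E}_z\!\left[1 - e^{-\lambda\, p_{lat}\, c(z)}\right],$$

with $c(z)$ the probability that a site's band covers depth $z$. This is
slightly below the independent-thinning value $1 - e^{-\lambda p}$:
0.0881 vs 0.0895 at $\lambda = 3/4$ (−1.5%), growing to −3% at
$\lambda = 1.5$. The package exposes the exact value as
`expected_sighting_fraction()`; `validate_recovery()` adds this known
model term to its Monte-Carlo tolerance, so recovery checks have correct
coverage at any seed. The estimators themselves keep the simple band
inversions — the correlation term is well below the sampling error of
any realistic survey.

```{r}
site_rate(0.09)
expected_sighting_fraction(0.75)   # vs 1 - exp(-0.75 * 0.125) = 0.0895
```

## Sphere–slab geometry and the profile-count correction

A spherical body of diameter $D$ whose bottom sits at a uniform random
phase relative to the section grid intersects on average $(D+T)/T$
sections; `sections_spanned()` gives the per-offset count, which takes
only the values $\lceil D/T\rceil$ and $\lceil D/T\rceil + 1$. The
profile a microscopist measures in one section is the widest circular
cross-section attained inside the slab (`sphere_slab_profile()`): the
full diameter if the equator lies in the slab, else the chord circle
$2\sqrt{r^2 - \delta^2}$ at the nearest in-slab plane.

Counting MVB profiles per MCMV profile in single sections undercounts
MVBs because a small sphere appears in fewer sections than its large
container. For an idealised spherical MCMV of diameter $d$ holding $N$
MVBs of diameter $D$,

$$\bar n = N\,\frac{D+T}{d+T}, \qquad
  \hat N = \bar n\,\frac{d+T}{D+T},$$

an Abercrombie-type correction. At $d = 1.08\ \mu m$, $D = 367$ nm,
$T = 70$ nm the per-MVB factor is $437/1150 = 0.38$: one MVB per MCMV
yields 0.38 MVB profiles per MCMV section. The correction is derived
here from first principles and validated against the virtual microtome
on scenes with known $N$ (recovered within a few percent; the method
metadata labels it "reconstructed" to flag that provenance). A bootstrap over MCMVs supplies the interval when
per-MCMV profile counts are available. The measured 367-nm mean major
axis is used directly as the MVB diameter — no Wicksell unfolding of the
profile-size distribution is attempted, matching how the measurement was
made.

A deliberately simple worked case: an MCMV with its bottom exactly at
the coverslip and a concentric MVB, cut at phase 0, shows the MCMV in 16
sections and the MVB in 6 (the MVB's z-extent crosses five interior
boundaries); exhaustive enumeration fixes these counts in the tests.

## The synthetic culture

`generate_scene()` draws, under one master seed (per-stage sub-seeds are
derived deterministically and recorded in the run manifest):

* cells of fixed 24 × 4 μm pancake geometry, scattered in a 500-μm
  field;
* per-cell site counts ~ Poisson(λ), default λ = 0.75;
* free MCMVs resting on the coverslip (diameter lognormal, mean 1.08 μm,
  CV 0.2 by default, `mcmv_diameter_cv = 0` for exact-arithmetic runs)
  plus a uniform settling offset of one section thickness in z — without
  it every body bottom would sit exactly on a slab boundary and slab
  counts would be pinned at $\lceil d/T\rceil$ instead of averaging
  $(d+T)/T$, biasing the correction oracle by ~2.6%;
* MVB counts per MCMV ~ Poisson(μ), packed without overlap; each MVB
  carries ≥1 ILV with probability 0.65 (occupied MVBs hold
  1 + Poisson(2) ILVs of 50–100 nm — the count distribution is our
  assumption; only the occupancy is constrained);
* omega figures as point marks on the MCMV limiting membrane, uniform
  over the sphere surface (hence uniform in z), counts ~ Poisson with
  default rate $-\tfrac{d+T}{T}\log(1-0.43) \approx 9.23$ per MCMV,
  the geometric inversion chosen so that ~43% of 70-nm MCMV profiles
  show at least one omega figure. Polar caps and diameter scatter
  depress the realised fraction slightly (~0.01–0.02) relative to this
  equal-allocation calibration.

**Packing.** Nested spheres are placed by sequential rejection sampling
(uniform conditional placement); dense-but-feasible sets fall back to a
repulsion relaxation that grows the children from 40% to full size while
pushing overlapping pairs apart (several random restarts). When sizes
are random, an unplaceable set has its diameters redrawn from the same
distribution truncated at a packing-fraction cap — size scatter inside a
crowded body is feasibility-limited, as for real vesicles. With fixed
sizes no redraw is allowed and an infeasible configuration raises a
packing error naming the offending parent. Counts are drawn as truncated
Poisson conditioned on the parent's geometric capacity evaluated at the
mean child size; at the default geometry the truncated mass is under 2%,
and in fixed-size mode the cap lies so far in the tail that counts are
Poisson to numerical accuracy (where the goodness-of-fit property is
tested). Consequence worth knowing: at CV = 0.2 the realised MVB count
and size distributions deviate measurably from unconditioned
Poisson/lognormal in heavily-loaded small MCMVs.

**What the generator does not emulate:** membrane texture and organelle
ultrastructure (patches are two-mean disks plus Gaussian noise), section
loss, folds, wrinkles, compression, tilt, ellipsoidal bodies, cell
migration, and field-of-view edge effects (simulated cells are whole, so
the partial-cell exclusion rule of real surveys has nothing to remove).
Passing tests therefore demonstrate that the estimators invert the
stated geometric sampling model, not that they are robust to every
artefact of real micrographs.

## The lumen classifier

A candidate vesicle is called MVB-like when (i) its measured major axis
strictly exceeds 200 nm, and (ii) a region of interest around it shows a
grey-value histogram resolving into two modes with the inside lighter
(electron-lucent). "Clear separation of two peaks" is operationalised as
Ashman's
$D = \sqrt{2}\,|\mu_{in}-\mu_{out}| / \sqrt{\sigma_{in}^2+\sigma_{out}^2} \ge 2$
computed from the mask statistics — the classical resolvability bound
for a two-Gaussian mixture — rather than literal peak-finding on a
binned histogram, which is bin-width fragile; the threshold is a
parameter. Degenerate zero-variance patches get $D = 0$ (equal means) or
$D = \infty$ (distinct means). The decision is invariant to adding a
constant to all pixels, and an `inverted` flag serves acquisitions where
higher grey value means darker. The size comes from the caller's
measurement, not from mask geometry, because that is how profiles are
measured on micrographs.

```{r}
p <- render_patch(180, 120, 10, 367, seed = 1)
classify_mvb_like(p, 367)
```

## Numerical choices

* Slab arithmetic adds a relative guard of $10^{-9}$ before
  floor/ceiling so that exact multiples of the (binary-inexact) 70-nm
  thickness land on the intended side of a boundary.
* A sphere tangent to a slab from outside does not intersect it
  (measure-zero contact excluded, consistent with half-open slabs).
* Minimum detectable profile diameter defaults to 20 nm; sub-membrane
  polar caps are invisible in practice, and this is the main small-cap
  loss knob of the correction (≈0.1% at the default sizes).
* The rejection/relaxation attempt budget is 1000 per body
  (`max_attempts`); exhaustion is an error, never a silent omission.
* Bootstrap intervals use 1000 replicates; percentile bounds are clamped
  to bracket the point estimate.

## Problem sizes used in validation

The packaged checks run at sizes chosen to keep Monte-Carlo error well
below the quantities tested: 20,000 cells for survey fractions and
site-rate recovery (binomial SE ≈ 0.2 percentage points), 2000 MCMVs per
point for the correction oracle (cluster SE ≈ 2%, recovery asserted
within 10%), 10,000 draws for count goodness-of-fit, 1000 patches for
the classifier operating test (≥99% accuracy at true $D \ge 3$).

## Known limitations

* The correction assumes spherical bodies and a known true MVB diameter;
  ellipsoids and Wicksell-type unfolding are out of scope.
* The 43% omega fraction and 65% ILV occupancy are calibration targets
  for the generator — survey magnitudes it emulates, not measurements it
  can reproduce.
* A survey quoting "about one MVB per MCMV" may mean either the raw
  per-section mean or the corrected count; both readings are computable
  here (`mvbs_per_mcmv()` reports the correction factor alongside the
  estimate), so record which one is intended when comparing studies.
* The classifier operates on provided masks; segmentation of real
  micrographs is out of scope.
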