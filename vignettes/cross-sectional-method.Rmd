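---
title: "The cross-sectional method: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The cross-sectional method: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossvol)
```

## The estimation problem

Volumetric-density approaches estimate an animal's mass by reconstructing
its body volume and multiplying by an assumed density. Classical 2D
variants approximate every cross-section with an ellipse (Graphic Double
Integration) or bracket it with superellipses; both fail when real sections
are far from (super)elliptical — fins, flippers, keeled or boxy trunks. The
cross-sectional method (CSM) implemented here instead consumes the *true*
sectional profiles: a single silhouette view supplies the identity-segment
length `d` at dense axial stations, and measured cross-sections at slab
boundaries supply area `S` and perimeter `C`.

## Model and assumptions

The body axis is partitioned into slabs with parallel planar boundaries;
each slab into `n` equal subslabs of length `L_n = L/n`. Writing
`phi = S/d^2` and `psi = C/d`, the model assumes:

1. **Linear shape-ratio drift across a slab.** `phi` and `psi` vary
   linearly between the two measured bases. Shape changes slowly relative
   to size, so this is mild; it is exact whenever all sections are scaled
   copies of one shape (any body of revolution, any constant-shape loft).
2. **Locally linear identity segments.** `d` is *not* assumed linear across
   a slab — body height fluctuates irregularly — but is read off the
   silhouette at every subslab boundary and interpolated linearly only
   within each subslab.
3. **Parallel, vertical sections.** Curved bodies must either be
   straightened first or sectioned vertically; the engine applies no
   curvature correction (a stated non-goal).

Within subslab `k`, `S(l) = (alpha l + phi)(beta l + d)^2` is cubic and
`C(l) = (gamma l + psi)(beta l + d)` quadratic in the axial offset `l`, so
volume, lateral area and the centroid's first moment all have exact
polynomial antiderivatives. These closed forms are evaluated in Horner form
to limit cancellation; the suite verifies them against adaptive quadrature
at 1e-10 relative tolerance on randomised slabs, and the spot values
`∫₀¹(1+l)³ dl = 3.75`, `∫₀¹(1+l)² dl = 7/3`, `∫₀¹ l(1+l)³ dl = 2.45` pin
the coefficient layout.

Terminal slabs may be **cones**: `d` tapers to 0 at the apex, where
`phi = S/d^2` and `psi = C/d` are undefined, so both ratios are held at the
measured base's values. Because the cone-mode integrands are then quadratic
(volume) and linear (area) in `l`, the closed forms are *exact for circular
cones at any subslab count*, as they are for cylinders and circular frusta
— the package's strongest internal consistency checks. The apex may be at
either end of the slab (snout or tail), one generalisation beyond the usual
anterior-cone presentation.

### What "surface area" means here

The method's lateral area is the axial integral of section circumference,
`∫ C dl`. On tapering solids this understates the true slant area — for a
cone of radius 1 and length 3 it gives `3*pi` against the true
`pi*sqrt(10)`, about −5.1%. Fixtures therefore carry *both* quantities
(`method_area` and `exact_lateral_area`), and area accuracy is asserted
against `method_area` except for cylinders, where the two coincide. Users
comparing against 3D-software surface areas should expect this bias on
strongly tapering parts.

## Mass and the centre-of-mass plane

A `density_model` carries a default density, optional per-slab overrides,
and zero-density ellipsoidal voids (axial semi-axis `p`, transverse `q`,
`r`) that stand in for lungs or air sacs. Void overlap with each subslab
interval is resolved analytically — the ellipsoid's sectional area is
quadratic in the axial offset, so the segment volume
`pi q r [u - u^3/(3p^2)]` and its first moment are exact — rather than by
sampling; an interior void therefore removes exactly `rho * (4/3) pi p q r`
of mass regardless of how the subslab grid cuts it.

Because the method deliberately carries no transverse coordinate system,
only the *vertical plane containing* the centre of mass is resolved,
reported as an axial station: the mass-weighted mean of the closed-form
subslab centroids. A full uniform cone balances at `L/4` from its base, and
a fore-aft symmetric body at its midpoint to 1e-10 — both tested.
Appendages contribute volume, area and mass (at the default density) but
are excluded from the CM plane, since their axial placement is not part of
the measurement model.

## Comparators

**GDI** slices the body into equal slabs (default 120, the conventional
count for validation work) and treats each as an elliptical cylinder with
averaged semi-axes from two orthogonal views. Its ellipse perimeter uses
Ramanujan's second approximation (relative error below 1e-5 even at 5:1
aspect). On a constant superellipse loft GDI's volume bias is the pure area
ratio `pi/4` over `Gamma(1+1/k)^2/Gamma(1+2/k)` — about +10.7% at k = 1.6 —
which the tests verify to 1e-9, making this fixture a sharp discriminator
between the methods.

**Superellipse bracketing** models each section as `|x/a|^k + |y/b|^k = 1`
with the half-width and half-height as semi-axes. Area
(`4ab Γ(1+1/k)²/Γ(1+2/k)`) and perimeter (adaptive quadrature of the
parametric speed) are strictly increasing in `k`, so evaluating all
sections at `k_min` and `k_max` brackets volume and area; the point
estimate is the arithmetic mean of the bounds (the natural reading of
bound averaging; no other convention suggests itself). Axial integration is
trapezoidal over the profile's stations rather than voxel counting on a 3D
mesh; with ~200 stations the difference is far below the bracket widths
(the in-range coverage property is asserted with a 0.2% axial-integration
allowance). Default `k` ranges: 2–2.3 (near-elliptical marine bodies) and
1.6–2.4 (general). Hydrodynamic-foil treatment of fins is deliberately not
implemented; fins are ordinary bodies here.

## Mask measurement

Masks are binary images with a physical scale; foreground is any nonzero
pixel, the sagittal axis runs along columns, and a station maps to the
nearest pixel-centre column (0-based indices, centres at
`(j + 0.5) * scale`). Identity segments use the inclusive span
`(max row − min row + 1)` pixels: a disk of radius `r` then measures
`2r ± 1` px instead of systematically `2r − 1`. Interior holes are filled
before measurement (the method's `S` and `C` refer to the outer profile)
and multi-component masks are rejected.

Perimeter is the delicate quantity: counting pixel edges overestimates
smooth boundaries by up to ~27% on average, and even a marching-squares
contour of the *raw* binary mask overestimates by several percent because
all level crossings sit at cell midpoints. The package therefore smooths
the mask with a small Gaussian (sigma = 1.5 px) and contours the smoothed
field at level 0.5, which restores sub-pixel crossing positions: a
rasterised disk of radius 200 px measures within 0.2% of `2*pi*r`, radius
100 px within 0.2%, and a 300 px square within 0.5% (corner rounding costs
a few pixels of the 1200 px total). For regions too small to survive
smoothing the raw contour is used as a fallback. The sigma is a geometric
compromise — large enough to interpolate the staircase, small enough not to
round real corners — fixed before the accuracy tests were frozen and not
revisited.

## Synthetic fixtures: what they do and do not show

`make_solid()` builds cylinders, cones, frusta, constant-section
superellipse lofts and bodies of revolution (default profile
`r(l) = 0.5 + 0.1 sin(2*pi*l)`, emulating irregular height fluctuation)
with exact volume, slant area and method area; `sample_measurements()`
emulates data collection with optional multiplicative Gaussian noise under
a caller-supplied seed (no hidden randomness), and `render_masks()`
rasterises silhouette and section masks for end-to-end round trips.

The standard protocol — 12 slabs × 10 subslabs, the partition at which
estimates stabilise across body forms — achieves volume and method-area
errors below 0.5% on every fixture, and the noise study (1% measurement
noise, 100 replicates) keeps the volume-error spread under ~2%. These
results validate the *integration machinery*, not biology: real
measurement error is not multiplicative Gaussian, real sections are not
exactly superelliptical, and real bodies bend. Passing fixtures show the
method is exact where it claims exactness and stable under perturbation —
they cannot certify accuracy on a particular animal whose sections were
measured badly.

Problem sizes used throughout the tests and the acceptance script were
chosen as the smallest that exercise each property cleanly: 12 × 10 for
end-to-end runs (matching the stabilisation protocol), 120 GDI slabs,
1500 × 1000 px mask round trips (the measurement properties hold from
roughly 100 px of section radius upward; the conventional 6000 × 4000
working resolution is supported but adds nothing at fixture scale).

## Numerical choices and degenerate inputs

* Closed forms in Horner form; oracle-equivalence tolerance 1e-10.
* Adjacent slabs must share boundary stations and agree on `d`, `S`, `C`
  within 1% (re-measurement allowance); worse disagreement is an error.
* `d = 0` anywhere except a cone apex is rejected with a pointer to cone
  mode; zero-volume subslabs have undefined centroids and are excluded
  from the CM aggregation.
* Measurement sanity checks — the chord bound `C ≥ 2d` and the
  isoperimetric inequality `C² ≥ 4πS` — warn (not fail) with 0.5%
  rasterisation slack, since they indicate suspect data rather than
  unusable input.
* Units are caller-defined and never converted; `body_rescale()` offers
  normalisation to unit length for cross-model comparison.

## Known limitations

* Lateral area is `∫ C dl`, biased low on tapering parts (documented
  above).
* No curvature handling: sections must be parallel.
* The CM plane is 1D; transverse CM coordinates are out of scope, as are
  density gradients within a section.
* Appendages need their own measurement tables; their axial placement (and
  hence CM contribution) is not modelled.
* Silhouette reading assumes the identity segment is the full vertical
  extent at a station — true for convex-ish profiles, wrong if the
  silhouette contains overhangs that the sectioning plane would not see.
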