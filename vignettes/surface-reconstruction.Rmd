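---
title: "Reconstructing raised skin lesions from radial cross-sections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing raised skin lesions from radial cross-sections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radialsurf)
```

## The problem

Raised cutaneous lesions such as hemangiomas are irregular: planning their
resection from a single photograph and an assumed round footprint
misestimates the area, volume and skin needed for closure. A practical
alternative to volumetric imaging is rotational silhouette capture: the
lesion (or a phantom standing in for it) is photographed against a
contrasting background at fixed rotation angles, each photograph yielding a
*radial section* — the diametral height profile $z(x)$ in the vertical
plane at that angle, with $x$ the signed distance from the rotation axis.
Because $x$ is signed, a half-turn of sections ($0°, 30°, \dots, 150°$ by
default) covers the whole object.

## The two-layer polynomial model

Each section $k$, at angle $y_k$, is fitted by least squares with a
polynomial of degree $N$:

$$z_k(x) = \sum_{i=0}^{N} a_{ki}\, x^i.$$

Stacking the rows $a_{k0} \dots a_{kN}$ gives the per-section coefficient
matrix $A$. The second layer treats each column of $A$ — the values of one
coefficient across section angles — as a function $a_i(y)$ and fits it with
a polynomial of degree $M$:

$$a_i(y) = \sum_{j=0}^{M} b_{ij}\, y^j,$$

so the surface is available in closed form everywhere:

$$z(x, y) = \sum_{i=0}^{N} \sum_{j=0}^{M} b_{ij}\, y^j x^i,$$

a $(N{+}1)\times(M{+}1)$ coefficient matrix $B$. With the defaults $N=12$,
$M=5$ and six sections, $B$ is $13 \times 6$; $N=8$ gives $9 \times 6$. The
defaults were kept deliberately small relative to the sample counts: six
sections exactly determine a degree-5 second layer, and 41 samples per
section leave the degree-12 first layer well over-determined.

Two numerical choices matter here and are the package's own:

* **Coordinate scaling.** Both $x$ and $y$ are affinely rescaled to
  $[-1, 1]$ before any fit. A raw Vandermonde matrix at degree 12 over a
  span of tens of millimetres is numerically singular in double precision;
  the scaled fit keeps the condition number modest and results reproducible
  across platforms. The scalings are stored in the model, so evaluation in
  the original millimetre coordinates is unchanged. Fitting raw coordinates
  remains available behind `raw = TRUE` for comparison.
* **Solver.** All least-squares stages use QR (orthogonal) decomposition,
  minimising $\lVert z - V a \rVert_2$; a rank-deficient design is an
  error rather than a silently regularised solution, because with distinct
  sample abscissae it indicates an ill-posed configuration.

The degree of the first layer is configurable; 12 is the default, with 13
equally supported — at these sample sizes the two give visually identical
reconstructions, and 12 pairs with the $13\times 6$ matrix shape used
throughout the documentation. No continuity constraint ties the sections
together at $x = 0$; the phantom tests quantify the resulting seam error
instead (it stays below the noise floor for the bundled phantoms).

## From model to measures

The height field is triangulated structurally: over a disc, rings of
vertices at the target element spacing (0.4 mm is a typical choice for
clinical resolution; the tests use 0.02–0.2 mm on phantoms where closed
forms are known), each parameter point mapped to the Cartesian vertex
$(x\cos y,\ x\sin y,\ z)$. The full turn is meshed from the fitted
half-turn via the signed-$x$ symmetry $z(r, \varphi{+}\pi) = z(-r, \varphi)$.
The mesh yields:

* **Area** $\int dS$ as the sum of triangle areas, and the corrected skin
  area $S = k \int dS$ with a dimensionless elasticity coefficient $k$
  (age-dependent; no standard lookup exists, so $k$ is a user input with
  default 1).
* **Volume** between surface and base plane, by two independent routes
  that must agree: per-triangle prisms (projected area × mean height) and
  the divergence-theorem signed volume of the mesh closed with vertical
  walls and a base cap. On graph-like meshes the two coincide to machine
  precision, which the test suite asserts as a structural invariant.
* **Mass, mean density and centroid** by midpoint quadrature on vertical
  sub-layers of each prism, at most one element size tall. A single
  midpoint per prism would bias depth-weighted moments (for a density
  proportional to depth on a unit slab it gives a centroid of 1/2 instead
  of 2/3); sub-layering restores the $O(h^2)$ error the tests verify.
* **Two-point resection measures**: straight-line distance, edge-path
  (Dijkstra) distance along the mesh as an upper bound on the surface
  geodesic, and per-point depth over the base plane. Points snap to the
  nearest vertex within one element size.

The base plane $z = 0$ represents healthy skin; `base_z` is configurable.

## Silhouette extraction

Profiles can come directly from images: after polarity normalisation the
image is thresholded (Otsu's between-class-variance maximiser on a 256-bin
histogram by default; with well-separated modes the criterion is flat
across the gap, and the plateau midpoint is used), the largest 4-connected
component is kept, and the column-wise upper envelope gives $z(x)$ with
$x$ measured from the symmetry axis (default: the foreground centroid
column, overridable). An object touching the top border is rejected as
clipped rather than silently truncated. Holes below the upper envelope are
ignored by construction — the profile describes the outer surface seen in
side view.

## The synthetic phantom

No physical phantom or clinical dataset ships with the package, so a
generator emulates the acquisition: an analytic surface, rotated virtually,
sampled at six sections of 41 points by default with additive Gaussian
height noise of 0.1 mm (a realistic digitisation error of a few tenths of
a pixel at typical scales; set `noise_sd = 0` for exact-recovery work).
All noise flows through one seeded generator, so identical seeds give
bit-identical sections — the determinism the CLI and tests rely on.

Three shapes are bundled. The hemisphere has closed forms for every
measure ($2\pi R^2$, $\tfrac23 \pi R^3$, centroid $3R/8$) and anchors the
accuracy tests. The three-bump Gaussian surface is the irregular,
asymmetric case. The ellipsoid cap sits between. What the phantom does
*not* emulate: lighting artefacts, specular highlights, perspective and
lens distortion, patient motion. Tests passing on phantoms therefore
validate the mathematics of reconstruction and measurement, not the
robustness of photography — image-quality effects enter only through the
simple binary silhouettes of `render_silhouette()`.

## Error budget and screening

The navigation error budget combines component errors with the standard
correlated rule $\sqrt{\delta_1^2 + \delta_2^2 + 2K\delta_1\delta_2}$.
Image-derived components (representation $\delta_T$, boundary $\delta_C$,
methodological $\delta_M$) are treated as fully correlated and summed
linearly — equivalent to iterating the rule at $K = 1$; an RSS mode exists
for sensitivity analysis. Mechanical positioning components combine
linearly per axis and in quadrature across the three axes; visualization
and positioning combine at $K = 0$. With the bundled reference components
($\delta_{Tx} = \delta_{Ty} = 0.25$, $\delta_{Tz} = 0.5$,
$\delta_C = 1.13$, $\delta_M = 0.5$, $\delta_P = 0.41$ mm) the chain gives
$\delta_T = 0.612$, $\delta_V = 2.242$, $\delta_R = 2.280$ mm; values are
kept at full precision internally and conventionally displayed to two
decimals.

Parameter screening uses a per-parameter Mahalanobis separation with the
conservative $\sigma_i = \max(\sigma_i^{(0)}, \sigma_i^{(1)})$. The
default is the standard squared form
$\delta = \sum_i (m_i^{(0)} - m_i^{(1)})^2 / \sigma_i^2$; a signed
"as-printed" variant without the square is selectable because legacy
reports sometimes omit it. The decision-error bound is
$P_{err} \le 1 - \Phi(\delta/2)$ with $\Phi$ the standard normal CDF
(default) or, selectably, the textbook Laplace function $\Phi - 1/2$ —
included because published bound tables exceeding 0.5 are only consistent
with that reading. The bundled `resection_reference_table()` carries the
five screened parameters with their reported separations as reference
data; the standard deviations behind them are not public, so those printed
values are data to compare against, never targets the formulas are tuned
to reproduce.

## Model-quality metrics

`fit_regression()` regresses calculated on actual resection parameters and
reports the residual SD $S = \sqrt{RSS/(n-2)}$ (the $n-2$ denominator is
the regression convention), the average approximation error
$\bar A = \tfrac{100}{n}\sum |e_i / y_i|$ (zeros excluded with a count —
$\bar A$ is undefined at $y_i = 0$), $R^2$, and F/t statistics with
critical values at a chosen level. The "good model" gate fires at
$\bar A \le 10\%$ by default and is configurable.

## Problem sizes and limitations

The test suite runs phantoms at hemisphere radius 1–10 mm with element
sizes 0.02–0.5 mm (up to ~31k triangles) and completes in a few seconds;
these sizes put discretisation error comfortably inside the 1–2%
tolerances of the closed-form checks. Known limitations: polynomial
surfaces cannot represent overhangs or re-entrant geometry (the height
field is single-valued); very high polynomial orders on noisy data
oscillate near the support edge, which shows up as rim error in the
hemisphere phantom; edge-path distances overestimate true geodesics by up
to the mesh anisotropy; and the elasticity coefficient $k$ is a scalar
multiplier, not a mechanical skin model.
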