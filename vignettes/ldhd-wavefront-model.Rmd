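---
title: "Modeling corneal wavefront changes of aspheric ablations in the Zernike and LD/HD bases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling corneal wavefront changes of aspheric ablations in the Zernike and LD/HD bases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ldhdwave)
```

## The model

The anterior cornea is represented by a rotationally symmetric conic
section: apical radius of curvature $R$ (mm) and conic constant
(asphericity) $Q$, with sagittal elevation

$$z(r) = \frac{r^2}{R\left(1 + \sqrt{1 - (1+Q)\,r^2/R^2}\right)},$$

positive toward the retina. $Q = 0$ is a sphere, $Q < 0$ prolate
(peripheral flattening; $Q = -1$ a paraboloid), $Q > 0$ oblate. The normal
human cornea is mildly prolate ($Q \approx -0.2$, $R \approx 7.8$ mm), and
those are the package defaults.

A laser ablation is the static subtraction of tissue over an optical zone
of diameter $S$: the post-operative surface is another conic $(R_1, Q_1)$.
The paraxial defocus correction $D$ (diopters, at the corneal plane)
determines $R_1$ through the thin-surface power change

$$\frac{1}{R_1} = \frac{1}{R_0} + \frac{D}{n' - 1}, \qquad n' = 1.376,$$

radii in meters. $Q_1$ is either set directly (conventional profiles keep
$Q_1 = Q_0$; custom aspheric profiles target a $\Delta Q$) or solved so
that the ablation delivers a prescribed change of fourth-order Zernike
spherical aberration.

Surface elevation (µm) is expanded over the zone by scalar products onto
the rotationally symmetric Zernike modes up to radial order six,

$$c_n = 2\int_0^1 W(\rho S/2)\, Z_n(\rho)\, \rho\, d\rho,
\qquad n \in \{0, 2, 4, 6\},$$

and the wavefront change of the ablation is the coefficient difference
scaled by the refractive index step across the new air–stroma interface,
$\Delta z_n = (c_{n,\text{post}} - c_{n,\text{pre}}) \times 0.376$.

## The two bases and the exact conversion

The Zernike spherical-aberration modes mix degrees:
$Z_4^0 = \sqrt{5}(6\rho^4 - 6\rho^2 + 1)$ carries a quadratic term, so an
ablation that only changes asphericity still moves the Zernike defocus
coefficient. The LD/HD decomposition removes this ambiguity: its
high-degree modes are built by Gram–Schmidt orthonormalization of
$(\rho^4, \rho^6)$ under the disc inner product, giving
$G_4^0 = \sqrt{5}\rho^4$ and $G_6^0 = \sqrt{7}(6\rho^6 - 5\rho^4)$ — unit
RMS, mutually orthogonal, and free of constant/quadratic monomials — while
the low-degree members keep the Zernike analytic structure
($G_0^0 = 1$, $G_2^0 = \sqrt{3}(2\rho^2 - 1)$).

Because both sets span the same even polynomials of degree $\le 6$, the
conversion is an exact linear map. The package derives it at build time by
monomial collection (solving $M_G\,g = M_Z\,c$ for the two monomial
matrices) rather than hard-coding floats; the resulting closed forms, used
as the test oracle, are

$$g_6 = \tfrac{10}{3} c_6,\qquad
g_4 = 6 c_4 - \tfrac{40}{3}\sqrt{7/5}\, c_6,\qquad
g_2 = c_2 - \sqrt{15}\, c_4 + 2\sqrt{21}\, c_6,$$
$$g_0 = c_0 - 2\sqrt{5}\, c_4 + 5\sqrt{7}\, c_6.$$

The $g_0$ expression is fixed uniquely by requiring the low-degree part to
carry the entire constant and quadratic monomial content (so that the two
expansions reconstruct the same polynomial pointwise); piston never enters
any reported delta or spherical equivalent. The $\sqrt{15}$ term in $g_2$
is the clinically important coupling: each micrometer of Zernike SA drags
$\sqrt{15} \approx 3.9$ µm of Zernike defocus with it, and with $c_6 = 0$
the fourth-order LD/HD SA is exactly six times its Zernike counterpart.

Dioptric readings use the spherical equivalent of a unit-RMS defocus
coefficient, $SE = 4\sqrt{3}\,c_2^0/(S/2)^2$ (positive = corneal power
gain); the subjective refraction shift is its negative.

## Parameters that matter

| parameter | unit | default | meaning |
|---|---|---|---|
| `r0` | mm | 7.8 | pre-op apical radius (normal cornea; also behind the sweep experiments) |
| `q0` | — | −0.2 (presbyopia table), 0 (spherical sweeps) | pre-op asphericity |
| `zone` | mm | 6 | analysis/ablation zone diameter; coefficients are zone-specific |
| `n_stroma` | — | 1.376 | stromal index; 0.376 converts elevation to optical path |
| `dz4_target_um` | µm | −0.40 | SA change targeted by the presbyopia solver |
| `quad_nodes` | — | 64 | Gauss–Legendre nodes of the projection rule |
| `solver_tol` | — | 1e-10 | convergence tolerance on the solved $Q_1$ |

Sweep grids default to $D \in \{-10, \dots, +6\}$ D in 1 D steps,
$S \in \{5.0, \dots, 8.0\}$ mm in 0.5 mm steps, and $\Delta Q$ in 0.1
steps — desk-scale problems (a full suite runs in roughly a second), so no
downscaling is needed anywhere.

## Numerical choices

**Quadrature.** Projections use a fixed 64-node Gauss–Legendre rule on
$\rho \in [0,1]$ with the area weight folded in: deterministic,
bit-stable, and exact to rounding for the polynomial integrands that occur
here. Doubling the node count moves conic coefficients by less than
$10^{-9}$ µm (tested).

**$Q_1$ solver.** The SA objective
$0.376\,[c_4(R_1, Q_1) - c_4(R_0, Q_0)] - \Delta z_4^{\text{target}}$ is
monotone increasing in $Q_1$, so a bracketing root finder (`uniroot`) on
$Q_1 \in [-3, 1]$ is used; an unreachable target fails loudly with the
offending parameter set rather than returning a boundary value.

**Degenerate inputs.** Conic surfaces validate $(1+Q)r^2 < R^2$ over the
closed zone and raise a domain error otherwise (oblate conics end at
finite radius); `postop_radius` rejects corrections that flatten the
surface to non-positive power; pre/post coefficient vectors must share a
zone. The ablation-thickness map auto-centers $t_0$ so tissue removal is
non-negative with minimum exactly zero; it is diagnostic only and never
enters the coefficient pipeline.

**Sign conventions.** Sagitta is positive toward the retina; a hyperopic
correction ($D > 0$) steepens the apex, adds sagitta, and yields positive
$\Delta z_2$ / positive $\Delta SE$ (power gain). The refraction-direction
reading negates the power change.

## The order-6 truncation, honestly

A conic is not a polynomial: its Taylor series continues beyond $r^6$
($a_8 = 5(1+Q)^3/(128 R^7)$, ...). The order-6 scalar-product fit is
therefore an approximation of the surface, and the tail leaks a little
into every fitted coefficient. Three consequences are worth stating
because they bound what "exact" claims can mean for this model:

- For a pure asphericity change at constant apical radius ($D = 0$), the
  LD/HD defocus delta is not identically zero but of order 0.01 µm
  (≈ 0.008 D) at the largest $|\Delta Q|$ studied — two orders of
  magnitude below the Zernike defocus drift it is contrasted with, and
  below the 0.01 µm display resolution, but not machine zero. Exact zero
  would require projecting the degree-6 Taylor truncation of the surface
  instead of the surface itself, which demonstrably degrades agreement
  with the reference outcomes (e.g. the hyperprolate $\Delta z_2$ at
  $\Delta Q = +0.8$ moves from 2.49 to 2.47 µm).
- For the same reason the LD/HD-derived $\Delta SE$ of a purely spherical
  correction equals $D$ to better than 0.01 D on the 6 mm zone but drifts
  up to ≈ 0.05 D at $S = 8$ mm and $|D| = 6$–10 D — still ~20× smaller
  than the Zernike-side overshoot it is compared against.
- The fourth- and sixth-order deltas grow as $S^4$ and $S^6$ only to
  leading order: over $S \in [5, 8]$ mm the next-order series term (11–28%
  of the leading one on the default geometry) biases the log–log slopes
  up to ≈ 4.4 and ≈ 6.6. The tests assert the leading-order exponents
  with this quantified bias band.

## What the scenario engine emulates — and what it does not

The sweeps reproduce idealized planning arithmetic: static shape
subtraction between two conics over a fixed zone. Real ablations add
transition zones outside $S$, laser-efficiency losses at oblique incidence
(the "cosine effect"), epithelial and biomechanical remodeling, and
measured corneas are not exact conics (the two-descriptor model is weakest
for sixth-order terms). Passing tests therefore validate the basis
algebra, the projection and the planning arithmetic — not the clinical
accuracy of any delivered profile. Non-rotationally-symmetric modes (coma,
astigmatism pairs), pupil rescaling of coefficients between zones, and
mixed LD+HD RMS aggregation (which is not meaningful, as the two parts are
not mutually orthogonal) are out of scope.

## Design choices that were genuinely open

- **Normalization.** Unit-RMS modes throughout, because the
  $SE = 4\sqrt{3} c_2/(S/2)^2$ formula and the reproduced table values are
  only consistent with RMS-normalized defocus coefficients.
- **Paraxial formula.** Stated by name only in the source material; the
  thin-surface form with $n' - 1 = 0.376$ is adopted because it reproduces
  every reference $R_1$ (7.49, 7.20, 6.94 mm), while alternatives such as
  the keratometric index 1.3375 do not.
- **Sweep $R_0$.** The sweep experiments need an apical radius that the
  scenario definitions leave implicit; 7.8 mm (the presbyopia-table value)
  is the default and reproduces the −10 D and +6 D overshoot figures.
- **$\Delta$SE from deltas.** Spherical equivalents of changes are
  computed from the $\Delta$-coefficients directly (identical to
  subtracting absolute SEs by linearity, but stated for determinism).
- **Conversion matrix at build time.** The Zernike↔LD/HD map is derived
  from the monomial matrices at load, with the hand-derived closed forms
  serving as an independent oracle in the tests, not as the
  implementation.

## Worked check

```{r}
scenario_table(presbyopia_table())[, c("D", "Q1", "R1", "dz2", "dg2",
                                       "dSE_z", "dSE_g")]
```

Each row solves $Q_1$ for $\Delta z_4^0 = -0.40$ µm on $R_0 = 7.8$ mm,
$Q_0 = -0.2$, $S = 6$ mm: the LD/HD column recovers the planned correction
exactly, the Zernike column underestimates it by ≈ 1.14 D of SA-coupled
defocus ($\sqrt{15}\,|\Delta z_4|$ less a small sixth-order term,
converted by the SE formula).
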