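---
title: "Ear-augmented BEM forward models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ear-augmented BEM forward models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Scope

`earfield` builds volume-conduction forward models for ear-EEG: four nested
tissue boundaries (scalp, outer skull, inner skull, brain) whose scalp surface
is carved by 3D-scanned ear impressions, so that electrodes can sit inside the
concha and ear canal. On top of the forward model it provides single
equivalent-current-dipole fitting of component maps, the evaluation metrics
used for ear-EEG validation (group-wise Pearson correlation, residual
variance, PVAF), and lead field sensitivity distributions for arbitrary
electrode configurations. Because no subject data are distributable, a
synthetic-head module generates concentric-sphere and ear-augmented fixtures
with known ground truth, and an analytic multilayer-sphere series acts as the
independent oracle for the numerical solver.

## The forward model

Quasi-static volume conduction in a piecewise-homogeneous, isotropic
conductor is solved with a boundary element method. For a current dipole with
moment $\mathbf q$ at $\mathbf r_0$, the potential satisfies the classical
surface integral equation: on each interface $S_i$ with conductivities
$\sigma_i^-$ (inside) and $\sigma_i^+$ (outside),

$$\frac{\sigma_i^- + \sigma_i^+}{2}\, v(\mathbf r)
  = g(\mathbf r) + \frac{1}{4\pi}\sum_j (\sigma_j^- - \sigma_j^+)
    \;\mathrm{PV}\!\!\int_{S_j} v(\mathbf r')\,
    \frac{(\mathbf r'-\mathbf r)\cdot \mathbf n'}{|\mathbf r'-\mathbf r|^3}
    \, dS', \qquad
  g(\mathbf r) = \frac{\mathbf q \cdot (\mathbf r - \mathbf r_0)}
                      {4\pi |\mathbf r-\mathbf r_0|^3}.$$

Discretization is vertex collocation with linear (hat-function) basis on
triangulated surfaces. The double-layer element integrals are computed
analytically: for a triangle seen from a collocation point, the weight of
vertex $i$ is

$$w_i = a_i\,\Omega - z\, \nabla \lambda_i \cdot \sum_e L_e\, \mathbf m_e,$$

with $\Omega$ the signed solid angle (van Oosterom–Strackee arctangent
formula), $z$ the signed distance to the triangle plane, $\lambda_i$ the
barycentric coordinate ($a_i$ its value at the projection of the collocation
point, $\nabla\lambda_i$ its constant in-plane gradient), $L_e$ the
logarithmic edge potential integrals and $\mathbf m_e$ the in-plane outward
edge normals. The weights sum exactly to $\Omega$, so the Gauss closure
identity holds row-wise and the operator's null space is exactly the
constants; a rank-one deflation removes it and solutions are reported with
zero mean over the collocation nodes. Exact integrals matter here because the
CSF layer is only 2 mm thick while triangle edges are several mm: numerical
quadrature of near-singular kernels would dominate the error budget.

At a mesh vertex the surface is not smooth; the factor $(\sigma^-+\sigma^+)/2$
is replaced by $[\sigma^-\Omega_{in} + \sigma^+(4\pi-\Omega_{in})]/4\pi$ with
the interior solid angle $\Omega_{in}$ obtained from the own-surface row sum,
which keeps the constant-potential identity exact on the discrete level.

### Isolated problem approach (IPA)

With $\sigma_{skull}/\sigma_{CSF}\approx 1/136$, the plain collocation
solution on the scalp is the small residue of a large cancellation and its
accuracy collapses. The isolated problem approach first solves the
sub-problem isolated at the inner skull — the conductor consisting of the CSF
and brain compartments with vacuum outside the inner skull — and then solves
the full operator for a correction $w$, with $v = w + \tilde u_0$:

* on the inner-skull and brain rows the source term cancels against the
  isolated solution *exactly in the discrete algebra*, leaving terms
  proportional to $\sigma_{skull}$;
* on the scalp and outer-skull rows the cancellation uses the *continuous*
  exterior representation identity of the isolated problem
  ($0 = g + \tfrac{1}{4\pi}\sum_j \Delta\sigma_j^{(0)} \int v_0\, d\Omega$ for
  points outside the isolated conductor), so the residual of that identity —
  pure discretization error of $u_0$ — enters the right-hand side scaled by
  $\sigma_{skull}$ rather than at full strength.

This second point is what makes IPA a genuinely different (and better)
discretization rather than an algebraic identity. A consequence worth
recording: if the formulation instead cancelled the outer-surface source term
with the exact *discrete* identity, the IPA solution would be bit-identical
to the plain solve and could not improve accuracy. For the same reason, when
the skull conductivity equals its neighbours the two routes agree only at
discretization level (shape error below 0.01 on the test meshes), not to
machine precision; the corresponding test asserts exactly that. The
formulation is invariant to the deflation constant of the isolated solve (the
induced right-hand-side shift lies in the range of the full operator and
cancels).

On the four-shell benchmark (radii 78/80/86/92 mm, conductivities
0.33/0.0132/1.79/0.33 S/m, 3000 faces per shell) the IPA solution reaches
RDM < 0.05 and MAG within [0.85, 1.15] against the analytic series for
eccentricities up to 0.8; the plain solve is 3–5 times worse in RDM.

### Lead fields by transfer matrices

The lead field matrix (electrodes × sources × 3 moment axes, V per A·m) is
computed with per-electrode transfer rows: one transposed solve per electrode
against the (deflated) operator, and for IPA a second set against the
isolated operator, after which each source costs only the evaluation of the
infinite-medium source terms. The cost is therefore independent of the source
count beyond a dense matrix product, and a 30 000-node 4 mm grid takes
seconds. Electrodes are snapped to the nearest scalp-surface point and
interpolated barycentrically; an electrode farther than 10 mm from the
surface is refused by name. The raw reference tag denotes the deflated BEM
potential with no electrode subtracted; this is what the electrode-vs-infinity
sensitivity configuration uses, since any physical reference would subtract a
row.

## The analytic oracle

For concentric spheres the potential has a Legendre-series solution. Each
degree $n$ couples the layer coefficients $A_k (r/R_k)^n + B_k (R_k/r)^{n+1}$
through continuity of $v$ and $\sigma\,\partial_r v$ and the insulating outer
boundary; the resulting 7×7 system per degree is solved directly with
per-layer scaling so no term under- or overflows. The angular part is written
with $P_n$ and $P'_n$ and the tangential geometry vector
$\hat{\mathbf t} = \hat{\mathbf x} - \cos\gamma\, \hat{\mathbf r}_0$, which
avoids associated-Legendre phase conventions altogether. In the equal-
conductivity limit the series must collapse to the homogeneous-sphere closed
form; the generating-function sums give

$$v = \frac{1}{4\pi\sigma b R}\left\{ q_r\left[\frac{2x(c-x)}{\tilde d^3} +
  \frac{1}{\tilde d} - 1\right] + q_t\left[\frac{2x}{\tilde d^3} +
  \frac{(x-c)/\tilde d + c}{1-c^2}\right]\right\},$$

with $x=b/R$, $c=\cos\gamma$, $\tilde d=|\mathbf r-\mathbf r_0|/R$; the
package implements this closed form separately and the tests require
agreement to 1e-10, a genuinely independent check of both routes. Series
truncation defaults to degree 100 (convergence factor $\le b/R_{scalp}$; at
the accuracy-claim limit of eccentricity 0.8 the degree-100 truncation error
is below 1e-8 relative).

## Geometry processing choices

**Carving.** The ear impressions are subtracted from the scalp as an implicit
boolean: node signs of "inside scalp and not inside any impression" on a
0.8 mm lattice (parity ray casting with column rays; coincident hits through
shared triangle edges are collapsed, and the ray origin is placed outside
every input so subtrahends protruding from the scalp do not flip parity),
then marching tetrahedra with *exact* edge–surface intersection points, so
the extracted boundary interpolates the true boolean boundary and the volume
error is second order in the lattice spacing. Marching tetrahedra is
guaranteed watertight for any sign field; a two-pass majority filter removes
single-voxel spikes and tunnels that would otherwise appear as spurious
handles. The dense output (~1.7 M faces) is decimated by quadric edge
collapse with a link-condition check, no-flip and sliver-quality guards, a
final pass that eliminates faces too degenerate to survive the package's
merge tolerances, and a cost penalty that keeps the carved "ear" region about
`density_ratio` times denser than the rest — mirroring the construction
practice of meshing the ear region more finely. The lattice spacing trades
fidelity for cost; 0.8 mm resolves the thin wedge where the impression rim
grazes the scalp sphere (coarser lattices leave genus artifacts there, which
the validation of Euler characteristic 2 would flag).

**Minimum-distance rule.** After carving, surfaces are processed from the
scalp inward; each inner surface must clear the previous one by 1 mm. The
displacement scheme is a stated design choice (the construction procedure
only states the constraint): per round, required clearances are gathered both
from the moving surface's vertices and from the fixed surface's vertices
(whose resolution catches a carved canal passing *between* coarse inner-mesh
vertices — the requirement is then radial: every vertex radially aligned with
an intruding point must sink below it, which is well-defined because all
surfaces here are star-shaped), capped at 2 mm per round, spread by decayed
dilation, smoothed with five Laplacian iterations over the displaced patch,
and applied along the radial direction toward the surface centroid. Vertex
normals are *not* used as the displacement direction: once a dent forms they
point into the carved tube and trap vertices there. A model that already
satisfies the rule is returned bitwise-unchanged, which also makes the
operation idempotent.

## Synthetic world

The synthetic ear head reproduces the *properties* the real construction
relies on, not the anatomy: a concha bowl (radius 14 mm, depth 6 mm) tapering
into a blunt-ended canal (radius 4.5 mm, depth 7 mm) revolved about the
inter-aural axis, 15 in-ear electrodes per ear placed on canal rings, a
concha ring and the canal tip (spanning a volume; smallest singular value of
the centered positions > 1 mm), 10 periauricular electrodes on rings around
the carves, and a 128-channel quasi-uniform scalp cap. Default shell radii
are 78/80/86/92 mm — plausible CSF/skull/scalp thicknesses; no canonical
values exist for them — and conductivities 0.33/0.0132/1.79/0.33 S/m. The
carve depth (13 mm) deliberately exceeds the scalp–outer-skull gap: the ear
canal dents the skull and brain surfaces through the minimum-distance rule,
as in a real head where the canal passes medial to where an inflated
spherical "skull" would be. Mesh budgets default to 3000 faces per surface:
the construction practice uses ~10 000, which remains available through
`sphere_spec(faces =)`, but a 6000-unknown dense BEM system is what a
1-CPU/8 GB evaluation box solves comfortably, and the accuracy criteria are
met at this resolution. All layout randomness is derived from one integer
seed and layouts are byte-identical per seed.

What a green test on this world does establish: solver correctness against
an independent analytic solution, metric identities, recovery of known
sources, and the qualitative sensitivity structure of in-ear montages (the
between-ears vs within-ear contrast and decay slopes). What it does not:
anything anatomical — real concha geometry, skull holes, tissue anisotropy,
real electrode-skin coupling — nor the published per-subject numbers, whose
underlying MRI and EEG data are not available.

## Dipole fitting and evaluation metrics

Fitting is scalp-only (in-ear rows are excluded), as in the validation
procedure that motivated it: a coarse scan over the 4 mm source grid — the
moment at each node is a linear least-squares problem, solved from
precomputed 3×3 Gram inverses — followed by Nelder–Mead refinement of the
location with trilinear interpolation of the lead field over the eight
enclosing nodes. Both the map and the lead fields are average-referenced over
the fitted electrodes, making the objective reference-independent. The
objective is the residual variance $RV = 100\,\mathrm{var}(c-f)/
\mathrm{var}(c)$; since the moment is free, $f$ is automatically
least-squares-scaled to $c$, which is what makes $RV=0$ attainable for a
perfect shape match (the correlation metric is scale-invariant, RV is not —
an asymmetry worth remembering when comparing the two). Fitted locations are
quantized to the nearest grid node (ties to the lowest index); locations
beyond half a lattice diagonal from any node are flagged as outside the grid
hull but still quantized to the nearest node — fitted optima can lie slightly
outside the hull, which is also why reported mean quantization distances can
exceed the half-diagonal bound of an in-hull point. Component selection
filters to in-brain dipoles and keeps the 12 of lowest RV (ties by component
index); "in-brain" uses the brain surface when available and grid-hull
membership otherwise.

Refinement failure modes are handled conservatively: if the local search
leaves the grid hull the fit falls back to the best scan node and is flagged.
Degenerate maps (all-zero) and zero-variance groups are errors or NA-with-
reason, never silent numbers.

## Recording preprocessing

Multi-amplifier merging estimates the true rate ratio from the sample spans
between the first and last shared trigger, FFT-resamples every channel to the
common 500 Hz clock (band-limited sinc interpolation, which is also the
anti-alias filter), aligns first triggers to within one sample, and
re-references each amplifier to its own common reference channel. The filter
chain is zero-phase: average reference, a 4th-order Butterworth high-pass at
1 Hz realised as two biquad sections, and 4th-order notches at 50/100/150/200
Hz (two cascaded biquad notches each, 2 Hz bandwidth); notch frequencies at
or above Nyquist are dropped with a warning. Saturation flagging requires a
dwell of consecutive samples within 1 % of the rail, so single-sample spikes
survive.

The steady-state-response test epochs the data on the 8 Hz trigger (one
trigger period per epoch, integer-truncated), averages epochs, and computes a
spectral F statistic: power at the modulation frequency against the mean
power of K = 12 neighbouring bins excluding the two adjacent bins on each
side, referred to F(2, 2K). The exact statistic in the cited methodology is
not printed; this standard form is a documented stand-in and K is
configurable. No multiple-comparison correction is applied across bipolar
pairs — the selection rule is deliberately liberal (any significant pair
keeps a channel), and channels in overlapping groups are kept if significant
in any of them. The type-I calibration of this statistic is itself a test
(rejection rate within the binomial confidence band of the nominal 0.05 over
1000 white-noise trials).

## Numerical conventions and tolerances

* Geometry in mm externally, SI internally; potentials are volts per A·m.
* Coordinate frame: right-handed, +X toward the right pre-auricular point,
  +Y toward the nasion, +Z up, origin midway between the pre-auricular
  points.
* Mesh load tolerances: vertices within 1e-4 mm merged, faces below
  1e-6 mm² dropped; meshes must be closed, 2-manifold and consistently
  wound (outward, positive signed volume; a consistently inverted mesh is
  flipped silently).
* Dipoles must be strictly inside the brain surface; within 1 mm of it a
  near-boundary warning is raised, and grid nodes within one spacing of the
  surface are kept but flagged. Accuracy claims are restricted to
  eccentricity 0.8.
* BEM assembly refuses surfaces closer than 0.5 mm and points to
  `enforce_min_distance()`.
* Ties (quantization, component selection) break to the lowest index for
  determinism.

## Known limitations

* Single-dipole models only; maps generated by extended or bilateral sources
  fit poorly by design (and the tests assert they fit *worse* than point
  sources — the evaluation depends on that honesty).
* Dense direct linear algebra bounds practical problem sizes to roughly 25 k
  boundary vertices.
* The implicit boolean carve resolves features down to the lattice spacing
  only; undercuts narrower than 0.8 mm are smoothed over.
* No anisotropic conductivity, no skull foramina, no MEG.
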