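---
title: "Rescoring docking decoys with simulated single-particle scattering: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rescoring docking decoys with simulated single-particle scattering: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spidock)
```

## The problem

Protein complexes resist crystallization, and X-ray free electron laser
(XFEL) single-particle imaging (SPI) can in principle record scattering from
individual non-crystalline particles — but each exposure catches the
particle at an unknown orientation, and complete orientation-classified
datasets large enough for direct 3D reconstruction remain hard to collect.
`spidock` implements the complementary *hybrid* route: candidate complex
structures (docking decoys, built from known subunit structures) are ranked
by how well their predicted scattering matches a modest set of measured
patterns.  The package provides the full loop on synthetic data: a forward
simulator, decoy generation, chi-square scoring with and without known
orientations, reduced pattern representations for fast orientation search,
and ranking-power evaluation.

## Forward model

A structure is an element-typed point set.  Its structure factor is the
direct coherent sum

$$F(\mathbf q) = \sum_j f_j(q)\, e^{i \mathbf q \cdot \mathbf r_j},$$

with $f_j(q)$ the atomic scattering factor from the standard four-Gaussian
parameterization and $\mathbf r_j$ the atom position.  A flat detector at
distance $D$ with the beam along $+z$ maps each pixel to the Ewald sphere:
the unit scattered direction $\hat k_0$ gives
$\mathbf q = (2\pi/\lambda)(\hat k_0 - \hat k_i)$, whose magnitude satisfies
$q = 4\pi\sin\theta/\lambda$ with $2\theta$ the scattering angle.  The
recorded intensity is $I(\mathbf q) = |F(\mathbf q)|^2$.  No polarization,
solid-angle, or detector-efficiency corrections are applied, and resolution
is quoted crystallographically as $d = 2\pi/q$, so the 4 Å shell sits at
$q \approx 1.5708$ Å$^{-1}$.

**Orientations.**  Euler angles $(\alpha, \beta, \gamma)$ in degrees, active
extrinsic z-y-z: the model is rotated by $\alpha$ about $z$, then $\beta$
about $y$, then $\gamma$ about $z$.  Because the beam is the $z$ axis, the
*last* angle $\gamma$ rotates the detector pattern in its own plane, and
$\beta$ is the tilt.  Two samplers are provided: uniform on SO(3) (the
physical model of tumbling particles; $\cos\beta$ uniform) and per-angle
uniform within bounds (matching confined-subspace experiments; *not*
SO(3)-uniform).

**Photon budget.**  Experimental intensity scales with the incident fluence,
which here acts only through one global factor: `scale_to_photons()` fixes
the mean count over all pixels of all patterns in the 4 Å resolution shell
(relative half-width 3%) at exactly one photon.  Per-pixel standard
deviations are the Poisson $\sigma = \sqrt I$, floored at 1 photon — the
sigma of the smallest countable signal — so chi-scores never divide by zero
at empty pixels.  Optional noise: a per-pixel Poisson draw, then an additive
Gaussian background with variance $\mathrm{Var}(signal)/\mathrm{SNR}$,
clipped at zero (SNR is defined as signal variance over noise variance).

## Scores

**SPI chi-score (matched orientations).**  When the $n$-th model pattern
shares the $n$-th data pattern's orientation,

$$\chi^2_{\rm spi} = \frac1N \sum_{n=1}^N \frac1M \sum_{m=1}^M
  \left(\frac{I^{(n,m)}_{\rm model} - I^{(n,m)}_{\rm data}}
             {\sigma^{(n,m)}_{\rm data}}\right)^2 .$$

**SPI chi-score (orientation matching).**  With orientations unknown, each
data pattern is compared against a bank of model patterns on a discretized
Euler grid and the per-pattern *minimum* chi is averaged.  This value equals
the matched score when the true orientations lie on the grid, and can never
exceed the chi of any fixed orientation assignment (both properties are
tested).  Ties in the argmin break to the lowest flat grid index.

**Reduced representations.**  Matching raw patterns against an $n^3$ bank
costs $n^3$ comparisons per pattern.  Two reductions remove the in-plane
angle $\gamma$ and shrink the bank to $n^2$: the radial profile (per-ring
angular mean), and the per-ring angular auto-correlation
$AC(q, \Delta\phi) = \sum_\phi I(q,\phi)\,I(q,\phi{+}\Delta\phi)\,
\Delta\phi_{\rm bin}$, computed by FFT and exactly equal to the direct sum.
Comparison counters are exposed so the $n^3 M \to n^2 M$ accounting is
verifiable.  The chi denominator always derives from the experimental side,
mapped through the same reduction (profile sigmas from pooled photon
statistics; for AC features, $\sqrt{|AC|}$ floored — the same
photon-statistics functional form carried through the quadratic reduction).

**SAXS chi-score.**  The data side aggregates all patterns into one radial
profile (the discrete angular/pattern average); the model side is the exact
rotational average via the Debye formula
$I(q) = \sum_{ij} f_i f_j \sin(q r_{ij})/(q r_{ij})$, evaluated at every
usable pixel's $|q|$ and averaged in the same radial bins, so both sides are
reduced identically (the pattern-averaging route is retained and
cross-validated in the tests).  Note the comparison is only consistent when
the data orientations are SO(3)-uniform; under confined per-angle sampling
the data profile is not a spherical average.

**s-score.**  A sequence-blind structure-difference measure: both models are
rasterized as sums of per-atom Gaussians (fixed 1.5 Å standard deviation for
every element, amplitude proportional to atomic number, truncated at
4 sigma), centered at their electron-weighted centers of mass on one common
grid, and the Pearson correlation of the two maps is maximized over a grid
of relative rotations; $s = 1 - \max cc$.  No translational search is
performed — the centering fixes it.  The rotation grid nests on refinement,
so the maximal correlation is monotone in grid fineness (tested).

**Ranking evaluation.**  For the $n$ lowest-scoring decoys, the
structure-difference values (RMSD or s-score) are histogrammed on 25
equal-width bins spanning $[0, \max]$ of the *full* set; the cumulative
curve is integrated by the trapezoid rule on the difference axis normalized
to the largest difference, giving an AUC in $[0,1]$ that equals 1 exactly
when every selected decoy is identical to the native.  Pearson correlation
is the default score-difference summary (Spearman available).
`combine_zscores()` implements the standardized-sum joint score and is
labeled experimental.

## Synthetic systems: what they emulate and what they do not

`make_toy_complex()` builds two tangent spheres of uniformly placed points
with protein-like C/N/O composition (63/16/21%) and heavy-atom density
0.05 Å$^{-3}$; each subunit is recentered so its center of mass is exactly
at its nominal position.  `generate_decoys()` perturbs the mobile subunit by
a random rotation about its center (angle uniform up to `rot_max`) plus a
random translation (magnitude uniform up to `trans_max`) — a seedable,
controllable sampler, deliberately *not* a physical docking sampler (no
energies, no clash checking).  `make_decoy_ladder()` hits requested RMSD
values exactly, using the fact that rotations about the (unweighted) mobile
centroid and translations contribute orthogonally to the mean-square
deviation; its `"rigid"` mode is rotation-first, adding translation only for
targets rotation cannot reach, which emulates docking output (pose changes
at roughly constant subunit contact) far better than pure separation.

RMSD is full-atom and *not* re-superposed: the fixed subunit defines the
frame, so superposition would hide genuine displacement of the mobile
partner.

Three findings from these synthetic systems qualify what passing tests mean
for real data:

* **SPI vs SAXS ranking power grows with system size.**  On an 80-atom toy
  the two scores are statistically tied (AUC differences ~0.02): a small
  near-spherical complex has little structure at 4 Å beyond its rotational
  average.  At 300 atoms SPI separates cleanly (Spearman with RMSD ~0.9 vs
  ~0.8; higher top-25 AUC in every seed).  Real complexes are 10–100 times
  larger still; the package's comparisons are run at the 300-atom scale.
* **Decoy geometry matters.**  Translation-only ladders inflate the radius
  of gyration, which the rotationally averaged profile tracks directly, and
  make SAXS look artificially strong; rigid-body pose ladders are the
  faithful emulation.
* **Chi-scores carry the photon calibration.**  Each dataset's global scale
  factor multiplies its chi-scores, so batch-to-batch comparisons must
  propagate the calibration uncertainty (the standard error of the shell
  mean) alongside the per-pattern sampling error.

## Orientation grids and the Euler chart

`make_grid()` spans full SO(3) with $\alpha,\gamma \in [0,360)$ half-open
and $\beta \in [0,180]$ inclusive, or a confined subspace (default
$\pm 22.5^\circ$ per angle, both endpoints included; a 3° step gives
$16^3 = 4096$ triples, dropping to $16^2 = 256$ for the reduced
representations).  The z-y-z chart is degenerate at $\beta = 0$: only
$\alpha + \gamma$ is identifiable there, and the confined subspace straddles
that pole.  Recovery is therefore asserted geodesically: a match succeeds
when the rotation-group distance between true and recovered orientations is
at most the largest distance attainable by a one-grid-step perturbation of
each angle (`one_step_radius()`).  Measured per-angle agreement understates
accuracy near the pole (about 62% at a 3° step for noise-free native
patterns whose recovered *rotations* are all within one step); the tilt
$\beta$ is recovered more faithfully than $\alpha$ or $\gamma$ individually,
which is a property of the chart, not of the data.

Bank patterns are noise-free and share the experimental set's photon scale
factor, so chi values are unit-consistent; the experimental sigma (not the
model's) is the denominator throughout, as the matched-score definition
requires.

## Numerical choices and scales

* Detector default: 128×128 pixels of 0.2 mm at 49 mm, $\lambda = 1$ Å —
  the edge just passes 4 Å.  Tests and the acceptance script use 32–48 px
  geometries with the same q-range (pixel sizes 0.55–0.75 mm), which keep
  every simulation exact while making thousands of pattern simulations
  cheap; study sizes are 150–1000 patterns, 4096-orientation banks, 20–50
  decoy ladders.
* Polar resampling: bilinear interpolation onto rings of constant $|q|$
  (radial-bin centers mapped through the Ewald geometry), azimuth origin on
  the fast axis, counter-clockwise; rings touching masked or off-detector
  pixels are dropped.  Radial profiles use direct pixel binning by $|q|$,
  which is unbiased against the Debye limit (interpolation would introduce
  a smoothing bias larger than the Monte-Carlo error at large N).
* The sigma floor (1 photon), the 3% shell width, 25 ranking bins, and the
  10° default s-score rotation step are package defaults chosen once and
  documented here; all are configurable.
* Degenerate inputs: empty models, unreachable resolution shells, zero
  scattering-factor coverage, constant density maps and zero-variance score
  columns raise errors rather than propagate silently; unknown elements
  drop atoms with a warning.
* `pattern_simulator()` / `amplitude_simulator()` factor
  orientation-independent work out of pattern loops; amplitudes of rigid
  parts are additive, so a decoy series shares its fixed subunit's
  amplitudes (`spi_score_decoy_set()`), with results identical to the
  per-decoy path.

## Persistence and interfaces

PDB files are read and written through `bio3d` (waters excluded by default,
elements inferred from the element column with an atom-name fallback).
Decoy sets persist as numbered PDB files plus a TSV manifest whose RMSDs
re-verify from the coordinates.  Pattern sets persist as single RDS files
carrying intensities, sigmas, orientations, the q map, noise metadata, the
scale factor, and the generating configuration (including the seed), so
every output is reproducible from its own header.  Score tables and AUC
summaries are TSV with commented metadata headers.  A thin command-line
wrapper (`inst/cli/spidock.R`) exposes the `simulate`, `decoys`, `score`,
`rank` and `all` verbs over a flat key=value configuration with CLI
overrides.

## Known limitations

* The forward model omits shot-to-shot fluence jitter, detector point
  spread, incoherent scattering, solvation layers, and multi-particle hits.
* The decoy generator knows no physics; it produces controllable geometric
  ladders, not docking-plausible interfaces.
* Orientation matching is brute force over the grid (no coarse-to-fine
  search); full-SO(3) fine grids are expensive by design, which is exactly
  the cost the reduced representations address.
* SAXS scoring assumes SO(3)-uniform data orientations; confined-subspace
  data should be scored with the SPI routes.
* At the 4 Å photon budget the matched chi of a noisy native dataset is
  dominated by bright low-q pixels; conclusions about high-resolution
  sensitivity require a brighter budget than one photon per edge pixel.
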