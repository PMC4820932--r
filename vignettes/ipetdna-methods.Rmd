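---
title: "Methods: individual-particle tomography of DNA-nanogold conjugates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: individual-particle tomography of DNA-nanogold conjugates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The system and the questions

`ipetdna` models a single molecular object: an 84-bp double-stranded DNA
whose two 5'-thiolated ends each carry a ~5-nm (63 Å) gold nanoparticle.
Such conjugates are imaged by negative-staining electron tomography, one
particle at a time, and each tilt series is reconstructed on its own —
individual-particle electron tomography (IPET) — because DNA is flexible
and no two conjugates share a conformation. The package implements the
full analysis chain as testable code:

1. **Synthetic ground truth** — worm-like-chain (WLC) DNA conformations,
   density phantoms, and noisy tilt series.
2. **IPET reconstruction** — ab-initio back-projection followed by
   iterative translational projection matching, with Fourier shell
   correlation (FSC) resolution and signal-to-noise (SNR) diagnostics.
3. **Metrology** — gold diameters (geometric mean of the longest and
   perpendicular extents), centre-to-centre distances, the Pearson
   linking statistic, histogram peak statistics, and the π/4
   isotropic-projection correction.
4. **Conformation tracing** — gold localisation in the 3D map, minimum-cost
   centerline tracing, smooth-curve fitting, and placement of base-pair
   frames along the curve.
5. **Bending energetics** — the two discrete bend-angle constructions
   (θ from cylinder centres, φ from cylinder axes), the harmonic WLC
   energy, windowed (central-42-bp) energies, ensemble Monte-Carlo
   statistics and persistence-length recovery.

## The worm-like chain, discretised

A conformation is an ordered list of base-pair centres $C_i$ spaced
$d = 3.4$ Å apart (the B-DNA rise), with unit step axes between
consecutive centres. An $n$-bp chain has $n-1$ steps and $n-2$ bend
joints. The WLC bending energy is harmonic in the local bend angle:

$$E_\mathrm{bend} = \frac{k_B T\, l_p}{2 d} \sum_j \alpha_j^2,$$

with persistence length $l_p = 50$ nm (the canonical dsDNA value),
$k_B = 1.9872\times10^{-3}$ kcal mol$^{-1}$ K$^{-1}$ and $T = 298$ K
unless configured otherwise. The energy's algebraic form is pinned by
equipartition: each joint has two bending degrees of freedom, so the
thermal mean energy per joint is $k_B T$ and an 84-bp chain carries
$82\,k_B T \approx 48.6$ kcal/mol — the "about 50 kcal/mol at room
temperature" WLC prediction that the Monte-Carlo sampler reproduces.

The sampler draws each joint's polar bend angle from the exact density
$p(\theta) \propto \sin\theta\, e^{-(l_p/2d)\,\theta^2}$ on $[0,\pi]$
(rejection sampling from the Rayleigh envelope $\theta e^{-\alpha\theta^2/2}$,
valid since $\sin\theta \le \theta$), with the azimuth uniform. The exact
$\sin\theta$ weighting keeps the large-angle tail correct; the familiar
small-angle identity $\langle\theta^2\rangle = 2d/l_p$ then holds to
better than 1% at dsDNA stiffness and is the basis of the
persistence-length estimator $\hat l_p = 2d/\langle\varphi^2\rangle$.
Two end-to-end oracles validate the chain geometry: the continuous
Kratky–Porod closed form and the exact discrete freely-rotating-chain sum
$\langle R^2\rangle = d^2\sum_{i,j} c^{|i-j|}$ with
$c = \langle\cos\theta\rangle$ from numerical quadrature.

### Two bend-angle constructions

Each pair of consecutive base pairs is represented by a cylinder (centre
at the midpoint, axis along the step, length $d$, width 20 Å; the source
workflow never states the cylinder dimensions, so these are the assumed
values). Then

* $\theta_i$ — the angle formed by the centres of three consecutive
  cylinders, measured as deviation from collinearity;
* $\varphi_i$ — the angle between the axes of two consecutive cylinders.

An 84-bp chain yields 83 cylinders, hence 82 φ angles and 81 θ angles;
these counts are a package convention (the end handling is not specified
upstream) and all energy totals depend on them. θ is defined so a
straight chain scores exactly zero — the only reading under which the
straight-model control has zero energy. For smooth, gently bent chains
the two energies agree (both are discrete curvature measures); on rough
per-joint conformations they diverge, which is why both are always
reported. The central-42-bp window (bp 22–63, keeping 40 φ and 39 θ
joints) discounts end fluctuations.

## The synthetic world

The generator's defaults are the stated acquisition conditions: tilt
series from −60° to +60° in 1.5° steps (81 images), 0.94 Å/pixel in
512² boxes, two 63-Å gold spheres tethered at the chain ends (each centre
offset outward along the terminal axis by one radius), a 20-Å-wide DNA
tube, and white Gaussian noise calibrated so the DNA-region SNR of each
image — gold area excluded, the metrology definition — hits a target of
0.31 on average (the observed per-image range being roughly 0.2–0.6).
Random per-image translations up to ±15 px emulate stage drift and are
recorded as ground truth.

Free choices, made once: the gold:DNA density contrast is 5:1 (the
stain/gold ratio is not documented anywhere); gold spheres are hard and
uniform; the PEG passivation shell is not modelled (it is visible in
stained images but contributes nothing to the measured quantities); no
contrast transfer function (CTF correction sits upstream of this
pipeline and the synthetic data are generated CTF-free); no
dose-dependent damage. Simulated projections use exactly the projection
operator of the reconstruction, so a green reconstruction test
establishes internal consistency of the operators plus noise/shift
robustness — it does not establish robustness to stain artefacts, CTF,
or tilt-angle error, which real data carry.

## Reconstruction

The projector rotates sampling rays about the vertical (y) tilt axis and
integrates with bilinear interpolation in the x–z plane, zero outside the
grid; the back-projector scatters with the *same* weights, making the
pair exact matrix adjoints (verified to float precision, required at
1e-4). Reconstruction is back-projection of the un-shifted images, by
default ramp-weighted (R-weighting along the in-image direction
perpendicular to the tilt axis); the unweighted variant is available and
recorded in the output metadata, since the upstream workflow does not
name a weighting.

Refinement iterates: reconstruct with current shifts → re-project at
every tilt angle → low-pass both reference and raw image at the
iteration's cutoff → apply a circular mask with a Gaussian boundary →
take the Fourier cross-correlation peak with 3-point parabolic sub-pixel
refinement (ties toward the smaller shift; peaks on the search boundary
are flagged and clamped). The published description says only
"automatically generated dynamic filters"; the package's documented
stand-in is a linear cutoff ramp from 40 Å to 16 Å (final maps being
low-pass filtered to 16–20 Å) and a mask radius shrinking from the box
edge toward 1.2× the particle extent. Both schedules are arguments.
Alignment is translational only: goniometer angles are trusted, as in
the source workflow.

Because an ab-initio reconstruction has no absolute origin, a common
volume translation $(\delta_x,\delta_y,\delta_z)$ moves every image's
shift by $(\cos a\,\delta_x + \sin a\,\delta_z,\ \delta_y)$ without
changing the structure. The loop pins this gauge each iteration
(projecting it out of the shift estimates — the "global centre"), and
`alignment_error()` removes the same 3-parameter family before comparing
recovered to true shifts.

**SNR tracking.** `snr_history[1]` is the raw per-image DNA-region SNR
(the input level); subsequent entries are the SNR of the average of all
images un-shifted by the current estimates, against a DNA mask fixed
from the initial map so values are comparable across iterations.
Averaging $N$ aligned images boosts SNR by about $\sqrt N$, so the
history rises from the input level to a several-fold gain as alignment
converges. The acceptance test reads "monotone SNR improvement" as: every
post-alignment value exceeds the input level, alignment lifts the SNR to
at least 1.5 times that level, and the converged plateau never falls
below 90% of its peak — the last allowance because, once converged,
sharper filter cutoffs let image noise jitter the shift estimates by a
fraction of a pixel, which shaves a few percent off the plateau without
any loss of alignment.

**Resolution and masks.** FSC is computed between reconstructions from
the odd- and even-indexed aligned images, one Fourier voxel per shell;
the reported resolution is the first, linearly interpolated, crossing of
0.5 (never crossing returns Nyquist with a flag). Particle masks low-pass
the map to ~25–30 Å and keep exactly the brightest voxels totalling
three times the molecular weight at 1.21 Å³/Da — the standard
macromolecular packing value, chosen because "three times its molecular
weight" needs a mass-to-volume conversion the source does not give.

## Tracing and the smooth DNA model

The all-atom route used upstream (targeted MD into the map, then MDFF) is
out of scope; the package implements the alternative that the upstream
work itself validates: mark the DNA between the gold particles, fit a
smooth quadratic or cubic curve, and lay a canonical helix along it.
Concretely: gold blobs are the two strongest connected components above
half the map maximum (centroids and three principal-axis extents; their
geometric mean is the 3D diameter); the centerline is the minimum-cost
path over supra-threshold voxels (cost 1/(density + ε), ε = 1% of the
map maximum, 26-connectivity) from one gold centre to the other,
resampled to one point per 10 Å; the curve is a least-squares B-spline of
degree 2 or 3 — piecewise Bézier with C¹ (indeed C^{degree−1}) joins —
with segments added until the maximum residual is within tolerance
(default 3 Å); base-pair frames are spaced equally in arc length with
rotation-minimizing (parallel-transport) normals, twist decoupled from
bending as in the WLC itself.

A 20-Å-wide density tube cannot encode single-joint wiggles whose lateral
displacements are fractions of an Ångström, so the traced model recovers
the *smooth component* of the true conformation. The round-trip test
therefore checks (a) DNA contour length within 5% and (b) that the traced
bends match those of the same smooth model fitted directly to the true
centres within 5° RMS. Against the raw per-joint angles of a thermal
l_p = 50 nm chain the RMS difference is bounded below by the chain's own
white bend component (RMS ≈ 6.7° per joint), a physical floor, not a
tracing defect.

On noisy reconstructions the opposite bias appears: centerline jitter
from map noise adds spurious bends, inflating the measured bending
energy. The two biases compete, so a traced conformation's energy can
sit above or below the true chain's depending on noise level and fit
tolerance — which is why map-derived bending energies should be read
against the thermal ensemble scale rather than joint by joint.

## Numerical choices and conventions

* Volumes are cubic with even edge; the centre is the 0-based voxel
  N/2; shifts are (x, y) pixel offsets of image content.
* Sub-pixel translations use the Fourier shift theorem (exact identity
  at zero shift); periodic wrap-around is harmless because phantoms keep
  a margin to the box edge and the simulator rejects phantoms that do
  not fit.
* The 2D/3D Gaussian low-pass has its half-maximum at the cutoff
  frequency; in 3D it runs as a separable real-space convolution with
  zero padding.
* Histogram peaks use fixed-width bins centred on
  `min(value) + k * width`, so a peak reads "centre ± half-width" (2 Å
  bins for diameters, 20 Å for distances, inferred from the ±1.0 Å /
  ±10 Å notation of reported peak populations); ties go to the lower bin.
* Seeds: one root seed; every stochastic stage derives a child seed from
  it with a fixed affine map, so stages are individually reproducible.
* MRC files are mode 2 (float32), pixel size in the header; angle lists
  are plain-text .tlt.

## Scale-downs in the test suite

The shift-recovery acceptance property runs at the stated 81 images and
256² boxes but at 1.88 Å/px (2× binning) so the ~410 Å conjugate fits the
field of view, and with 6 refinement iterations, which the early-stop
criterion shows is past convergence. Phantom-based tests use boxes of
64–192 voxels at 2–8 Å/px; the paper-scale 512²/0.94 Å geometry remains
the pipeline default. All Monte-Carlo sample sizes in tests match the
stated criteria (10⁴ chains, 10⁶ orientations).

## Known limitations

* No CTF, stain granularity, uneven staining, or radiation damage in the
  simulator; real micrograph SNR structure is more complex than white
  noise.
* Tilt angles are trusted; angular errors and missing-wedge artefacts
  beyond the ±60° geometry are not corrected.
* The centerline tracer assumes a connected supra-threshold path; on
  very noisy maps (up to ~30% of fabric densities can be invisible at
  working contour levels) manual point picking may outperform it, and
  the error message suggests lowering the threshold.
* The energy model is bending-only: twist and stretch elasticity,
  sequence dependence, and kinks are out of scope, as are all-atom MD
  energies.
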