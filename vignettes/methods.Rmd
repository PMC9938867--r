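---
title: "Methods: indexing, anisotropy and missing-cone restoration for 2D protein lattices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: indexing, anisotropy and missing-cone restoration for 2D protein lattices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the science behind its
operations: the models, the tunable parameters and why their defaults are
what they are, what the synthetic-data generator does and does not emulate,
and the numerical choices made where the design was genuinely open. It
states no empirical result beyond what the test-suite and
`scripts/acceptance.R` compute.

## The system

Phage-nucleus enclosure (PhuN) proteins self-assemble into two-dimensional
crystalline shells around the replicating genome of jumbo bacteriophages.
The ~66 kDa subunit forms quasi-symmetric tetramers that tile the sheet
with p2 symmetry (unit cell about 120 Å with a ~100° inter-axis angle in
vitro) and, in a minor population, p4 symmetry (square ~120 Å cell);
isolated shell fragments show the same two symmetries at slightly different
cells (120 Å/120° and 110 Å/90°). All four are available as lattice presets.
Because 2D sheets can only be imaged at stage tilts up to ~60°, their
reconstructions miss a double cone of Fourier space of half-angle
90° − 60° = 30° about the sheet normal, and the density is smeared along z.

The package implements the downstream computational chain: simulate the
data with known ground truth, index and classify the lattices, quantify the
directional resolution anisotropy, restore the missing cone, and compare
structures.

## Synthetic data

**Motifs and phantoms.** The 2D motif (`make_motif2d`) is a random
Gaussian-blob constellation with a ~60 × 40 Å footprint — the size of a
single subunit — with 12 blobs of 4.5–8 Å width by default. The blob count
matters: it sets the number of significant lattice reflections a rendering
carries, and a two-domain ~600-residue protein projection has
secondary-structure-scale features at roughly this density; with
substantially fewer blobs a random draw can be so information-poor that no
statistic could classify its symmetry at realistic noise. Motif asymmetry
is a postcondition, enforced by deterministically rejecting draws whose
180°-rotated copy correlates above 0.7 (a near-centrosymmetric motif would
make a p2 lattice look period-halved, which is an ambiguity of the pattern
itself, not of the indexer). The 3D subunit phantom
(`make_subunit_phantom`) uses the same construction with absolute blob
widths of 4–8 Å.

**Lattice renderings.** A rendering places the motif according to the
plane-group operators — p2: the motif on the lattice nodes and its
180°-rotated copy at the cell centre; p4: four 90°-rotated copies about the
node — and evaluates the tiling by NUFFT-style Gaussian gridding: each
lattice point is splatted with a small Gaussian kernel whose transform is
divided out again in Fourier space before convolution with the analytically
rasterized motif. This keeps the rendering spectrally exact to near machine
precision; simple bilinear splatting leaves ~1% phase artifacts at high
orders, which is enough to corrupt weak-reflection statistics in noiseless
tests. White Gaussian noise is added at a stated SNR (signal variance over
noise variance); the detector noise model of real micrographs is not
emulated, nor are the contrast transfer function, beam-induced motion, or
ice gradients — CTF estimation and motion correction are out of scope, and
the in-scope computations are exercised identically without them. Lattice
curvature ("bends and waves") is available as a smooth bounded displacement
field (`distortion_amplitude`), off by default so that clean-lattice
accuracy contracts are tested in isolation.

**Missing-cone volumes.** `make_missing_cone_volume` zeroes the signal's
Fourier amplitudes inside the double cone implied by the maximum tilt and
then adds independent white reconstruction noise to the two half-maps —
noise is present at all frequencies, as in a real-space reconstruction from
noisy projections. The ordering is essential: if noise were added before
cone-zeroing, the cone would be exactly zero in both half-maps and the
directional FSC would be blind to it (zeroes drop out of both sums), which
would defeat the OTF construction downstream.

**Projections.** `project_volume` rotates spectrally (exact quarter-turns
plus a three-shear Paeth decomposition implemented as Fourier phase ramps)
and sums along z, so the Fourier projection theorem holds to high accuracy
for band-limited compact content; edge content wraps circularly.

## Lattice indexing

`index_lattice` estimates the unit cell from the whitened autocorrelation:
the image power spectrum is flattened by its radial mean (collapsing the
broad motif self-correlation into near-delta lattice peaks on a flat
background) with a mild Gaussian roll-off so peaks stay ~2 px wide for
stable parabolic interpolation. Peak significance is judged against robust
(median/MAD) annulus statistics; with no peak above a z-score of 5 a
no-lattice error is raised. The two strongest short non-collinear peaks
seed a basis, Lagrange reduction canonicalizes it (shortest two independent
vectors; `a_len >= b_len`; angle reported in [90°, 150°]), and a sublattice
guard augments the basis with any strong detected peak whose indices are
non-integer (otherwise a heuristic seed can span an index-2 sublattice).
The final basis is a weighted least squares over every predicted
autocorrelation peak out to the image edge, located with sub-pixel
parabolic interpolation and outlier-trimmed once. On 2048-px synthetic
micrographs at SNR 0.3 this recovers the preset cells to ~0.05%.

## Plane-group scoring

`score_plane_group` lattice-averages the image and measures how well the
averaged motif's significant Fourier orders agree in phase with their
copies transformed by the group generator (180° for p2, 90° for p4) — the
significant-reflection practice of 2D electron crystallography. Decisions
of record:

* **Averaging by cell-wise interpolation.** The motif is sampled at the
  same fractional grid in every unit cell by bilinear interpolation and
  averaged over cells. Accumulating image pixels into fractional bins
  instead introduces an asymmetric sampling error per bin that corrupts
  weak-order phases and destroys the symmetry of even noiseless folds.
* **Focus polish.** A residual isotropic scale error in the basis (~0.1–0.3%
  on noisy data) blurs the fold; the scale maximizing the fold's band power
  is picked by a three-point parabola (±0.25% bracket) before scoring. For
  the p4 generator the basis is additionally symmetrized to an exactly
  square cell when near-square, which removes the anisotropic part of the
  drift — that part is invisible to the p2 score (centrosymmetric blur) but
  depresses only the p4 score.
* **Phase-only scoring with a calibrated null.** Reflections are selected
  in a 1.5–16 cycles-per-cell band against a high-order noise floor and
  equal-weighted; the unknown symmetry-axis position is handled by
  maximizing over the phase origin (circular cross-correlation plus
  continuous refinement). Because a maximum over origins of a
  finite-reflection statistic is biased upward, the raw maximum is
  calibrated against phase-randomized copies: an asymmetric motif scores
  near 0 rather than at the chance level (~0.3–0.5) of the raw statistic.
  Amplitude-weighted correlation was rejected: smooth blob motifs correlate
  ~0.8 with their own rotations through the envelope alone.
* **Assignment.** The highest-order group whose score clears τ = 0.5 and
  whose cell constraints hold (p4 requires a near-square cell) is assigned;
  otherwise p1. A winner-versus-runner-up margin is deliberately not used:
  p4 contains the p2 generator, so on a genuine p4 lattice both scores are
  legitimately high and the comparison between them carries no information.

The seeded-trials property (assignment matches the generating group in at
least 95% of 100 trials at SNR 0.3) is run at 1024 px for p1/p2 and
1280 px for p4: superimposing four rotated motif copies lowers the spectral
contrast of the p4 average, so reliable discrimination needs
proportionally more unit cells — at 1024 px a few p4 draws sit just below
threshold even when scored with the ground-truth basis, i.e. the limit is
information content, not estimator accuracy.

## Directional FSC and the OTF

`global_fsc` computes the standard shell correlation
FSC(s) = Re Σ F₁F₂* / sqrt(Σ|F₁|² Σ|F₂|²) over one-voxel shells;
`directional_fsc` restricts it to cones about Fibonacci-sampled hemisphere
directions (default 48 directions, 20° half-angle), counting Friedel mates
once via a Fourier half-space, allowing cone overlap, and reporting empty
cone–shell bins as undefined rather than zero. Resolution is reported at
FSC = 0.143 by linear interpolation of the crossing; both the threshold and
the cone parameters are free parameters of the method.

`build_otf_from_dfsc` assigns every Fourier voxel the dFSC value at its
direction and radius: shell curves are interpolated radially, undefined
bins filled from the nearest defined shell (logged), and directions blended
with a cubed cone window, which concentrates the blend on the nearest
direction samples and keeps the OTF's angular response sharper than the
aperture. Negatives clamp to zero, the result is Friedel-symmetrized
exactly, and H(0) = 1. For resolving a 30° missing cone the deconvolution
pipeline samples more finely than the dFSC defaults (10° cones, 192
directions); with a 20° aperture the leakage of high out-of-cone FSC into
the cone reaches ~0.6–0.9 and no downstream floor can separate the two.

## Entropy-regularized deconvolution

`er_decon` minimizes a data misfit plus `smoothing` times a saturating
(entropy-type) penalty on the Hessian magnitude of the restored density,
P(g) = Σ log(1 + q(x)/μ) with q the squared Hessian norm and μ the inverse
of the `nonlinearity` parameter, by preconditioned projected gradient
descent with a backtracking line search. The defaults are the parameters of the
original ER-Decon II protocol, smoothing = 0.5 and nonlinearity = 10,000. Decisions of record:

* **Forward model.** The default data term is the OTF-confidence-weighted
  misfit ‖H(ĝ − f̂)‖²: for a volume whose unsampled cone was zeroed, H is a
  confidence mask, and inverting it as an attenuation (‖Hĝ − f̂‖², available
  as `forward = "attenuation"`) amplifies noise without bound wherever H is
  small. The attenuation form is the right model only when the map's
  amplitudes were genuinely attenuated anisotropically.
* **Non-negativity on by default.** Positivity of scattering density is the
  physical prior that makes missing-cone recovery possible: the data term
  carries no information inside the cone, and the positivity projection is
  what generates in-cone Fourier content (the classic
  alternating-projection mechanism). Without it the solver can only smooth.
* **Missing-data floor 0.3.** OTF weights below the floor are treated as
  missing (never inverted). The floor must exceed the angular leakage of
  the dFSC aperture into truly unsampled regions; the value is set by the
  geometry of the 10°/192-direction sampling used in the pipeline.
* **Beyond-band anchoring.** Shells with almost no directional coverage
  (beyond the resolution band) are anchored to the Wiener-limit estimate of
  zero instead of drifting freely; with ~97% of Fourier space unconstrained
  the positivity mechanism cannot function.
* **Scale of the smoothing dial.** The nominal smoothing value is a
  dimensionless dial of the original software whose absolute scale is not
  recoverable; it is mapped onto the per-voxel objective by a fixed
  normalization κ = 10⁻⁴ so that at the default setting the penalty
  regularizes the background without overpowering the data term.
* **Optimizer.** Fourier-diagonal preconditioning by the data curvature
  (2H² plus a small ridge), restricted to the measured subspace — modes the
  data does not constrain are driven only by the projection and the
  penalty's real-space action, never by amplified near-zero gradient
  components. Under non-negativity the conjugate-direction update collapses
  to plain projected gradient (conjugacy does not survive the projection).
  Acceptance is simple decrease with a 10⁻⁶ plateau tolerance; the trace is
  monotone to that tolerance and a genuine increase raises an optimization
  error. Default cap 100 iterations, convergence on 30 consecutive
  relative decreases below 10⁻⁷ — elongation recovery saturates by ~80
  iterations on 64³ phantoms.

Elongation is quantified by `autocorrelation_widths`: half-maximum widths
of the volume autocorrelation along the axes, with the zero-lag value
estimated by linear extrapolation from lags one and two so that the white
noise spike does not shrink every width, and the z over in-plane-mean ratio
reported. The restoration property suite runs 20 seeded 64³ phantoms (30°
cone, SNR 3) through the full dFSC → OTF → er_decon chain at the default
parameters and asks for a ≥30% median reduction of the elongation excess
over each phantom's own ground-truth ratio, with no phantom's
ground-truth L2 error increasing.

## Structural comparison

`superpose_kabsch` is the standard SVD solution with a determinant
correction; `rmsd_on_selection` aligns on one residue selection and reports
over others without re-fitting (the protocol behind core-domain
comparisons of quasi-equivalent subunits). `simulate_density` sums per-atom
Gaussians with σ = resolution/π and atomic-number weights, so the shell
amplitude at the target frequency has decayed by e⁻². `fit_model_in_map`
maximizes a soft-masked real-space correlation (mask: simulated density at
the start pose, 1σ threshold, 6-voxel soft edge) by a coarse orientational
grid with FFT-solved translations, then Nelder–Mead refinement of all six
rigid degrees of freedom. `channel_geometry` measures diagonals between
Cα centroids of four corner selections — corner definitions ship as
editable selections, since where exactly a reported channel width is
measured on a deposited model is a protocol choice. `inter_assembly_rotation`
superposes anchor chains and reports the full residual rotation angle,
axis, and the axis angle to the lattice normal, so either in-plane or
out-of-plane conventions can be read off. `contact_map` tags heavy-atom
residue contacts with region annotations (N-tail 1–37, β-hairpin 111–126,
loop 272–291, structured loop 245–258, C-tail 556–602) and groups them into
the four lattice interfaces by region-pair rules. `sequence_mass` uses
average residue masses plus one water. Comparisons against deposited
entries (tetramer models, tomography maps) require those public files
locally; the test-suite verifies all operations against synthetic
assemblies with known ground truth instead.

## Problem sizes and limitations

The test-suite indexes 2048-px micrographs for the reference-cell recoveries,
640-px fields for the 50-lattice indexing/oracle comparison, and
1024/1280-px fields for the 100-trial assignment property; restoration
properties use 64³ volumes. These sizes are chosen so each statistic
operates in the regime it needs (enough unit cells, enough Fourier
voxels per cone) while the whole suite remains desk-scale.

Known limitations: plane groups beyond p1/p2/p4 are out of scope, as are
CTF handling, tilt-series merging into 3D reconstructions, masked-FSC
phase-randomization corrections, and flexible fitting. The deconvolution is
a global volume operation (no local or per-particle restoration), its
penalty scale mapping is a documented interpretation rather than a claim of
equivalence to the original implementation, and renderings wrap circularly
at image edges (margins exclude affected lattice nodes).
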