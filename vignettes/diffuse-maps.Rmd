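---
title: "Methods: from rotation frames to anisotropic diffuse maps and motion models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from rotation frames to anisotropic diffuse maps and motion models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette explains the science implemented by `diffusemap`: the
processing model that turns rotation-series diffraction frames into 3D
anisotropic diffuse scattering maps, the correlation statistics used to
judge those maps, the liquid-like motions (LLM) and rigid-body
translation (RBT) models fitted to them, and the design decisions taken
where the methodology is genuinely open. It also states precisely what
the synthetic data generator does and does not emulate, so that the test
results are read with the right scope.

## Conventions

Scattering vectors use the crystallographic convention |q| = 2 sin(θ)/λ =
1/d (Å⁻¹, no 2π). All resolution statements are d-spacings. The LLM and
RBT closed forms are written in the physics convention q_rad = 2π/d;
the code forms q_rad explicitly wherever σ²q² appears, so σ and γ are in
Å. Pixel indices are 0-based with the fast axis along detector x; the
incident beam is +z, the spindle axis y, and the polarization axis x
(all configurable). Miller-index voxel grids are odd-edged and centered
on the origin, sampled at integers for all production work.

## Frame preprocessing

Each crystal frame is cleaned in the standard order; every step can be
toggled, and Bragg cleaning always precedes scaling and radial-variance
removal:

1. **Static mask** — user regions plus pixels with counts ≤ 0 or above a
   saturation threshold (default 10 000 photons, a photon-counting-PAD
   scale choice).
2. **Windowed outlier mask** — pixels more than `nsigma` (default 5)
   sample standard deviations from the mean of their 11×11 window,
   computed over currently unmasked pixels. Windows are truncated at the
   borders rather than padded (no invented data); the center pixel is
   included in its own window; zero-variance windows mask nothing
   (constant regions are clean by construction); windows with fewer than
   two usable pixels leave the pixel alone.
3. **Background subtraction** — the paired non-crystal frame, scaled by
   the exposure-time ratio (crystal 0.3 s versus background 1 s in the
   synthetic defaults), is subtracted pixel-by-pixel with the masks
   combined. Negative differences are retained: clipping would bias the
   voxel means that the merge computes later.
4. **Intensity and position corrections** — raw counts are divided by
   the polarization factor `f(1−(ŝ·x̂)²) + (1−f)(1−(ŝ·ŷ)²)` (fraction f
   of horizontal polarization, default 0.99, a typical synchrotron
   value; f = 0.5 reduces to the unpolarized Thomson form
   (1+cos²2θ)/2), by the flat-detector solid-angle factor cos³θ_pix, and
   by the relative sensor efficiency (1−e^{−t/(ℓ cos θ)})/(1−e^{−t/ℓ})
   (sensor thickness t = 0.32 mm, attenuation length ℓ configurable).
   The polarization and solid-angle factors are ≤ 1 and equal 1 at the
   beam center; the absorption factor is ≥ 1 off-normal because the
   oblique path through the sensor captures more photons — normalizing
   it into (0, 1] would misstate the physics, so the package does not.
   Pixel positions are shifted inward by the parallax displacement
   t_eff·tanθ with t_eff = ℓ(1−(1+t/ℓ)e^{−t/ℓ})/(1−e^{−t/ℓ}), the mean
   absorption depth, before the reciprocal-space mapping.
5. **Bragg cleaning** — pixels whose fractional Miller indices are all
   within 0.25 of integers (boundary inclusive) are Bragg signal. They
   can be median-replaced from the unflagged pixels of an 11×11 window
   or simply masked; the default is to mask, because the merge rejects
   the same reciprocal-space box regardless and replacement only matters
   for visually continuous frames. Both modes are implemented and
   tested.
6. **Scaling and radial-variance removal** — each frame is scaled to the
   first frame of the series. The default method minimizes the L2
   distance between radial intensity profiles, giving the closed form
   s = ⟨p_frame, p_ref⟩/⟨p_frame, p_frame⟩; water-ring (5–1.82 Å) and
   overall mean-ratio factors and imported Bragg scale factors are
   alternatives. Radial profiles use uniform |q| bins (200 to the 1.4 Å
   cutoff by default; the bin count is a configurable, since no single
   value is canonical). The frames × bins profile matrix is then
   mean-centered across frames and each frame's projection onto the top
   three principal components is subtracted from its pixels, with the
   correction interpolated linearly in |q| between bin centers to avoid
   ring artifacts (nearest-bin lookup is available). Centering is
   deliberate: the removed subspace captures frame-to-frame profile
   differences, while the mean isotropic profile survives to be removed
   later, once, in reciprocal space.

## Merging, symmetrization, isotropic subtraction

Usable non-Bragg pixels contribute to the voxel at their rounded Miller
indices; the voxel value is the mean of its contributions and the
observation count is retained. |q| per voxel always comes from the
reciprocal metric tensor of the cell, never an orthorhombic
approximation, so monoclinic cells are exact. Symmetrization replaces
each voxel by the count-weighted mean of its Friedel pair or 2/m orbit
{(h,k,l), (−h,k,−l), (−h,−k,−l), (h,−k,l)}; count weighting equals
pooling the underlying pixel observations, which a plain mean of orbit
means would not. Unobserved orbit members are simply absent.

The isotropic component is estimated as the count-weighted radial
average on fine |q| shells, interpolated linearly to each voxel's |q|,
and subtracted; a final exact centering pass then removes the residual
per-shell weighted means. The two-stage design keeps the subtracted
profile smooth (no shell-boundary ridges) while making every shell's
weighted mean zero to machine precision, which the test suite asserts at
1e−8 of the intensity scale.

## Quality statistics

All metrics are Pearson correlations over common observed voxels,
reported overall and in 15 equal-volume (|q|³) shells to 1.4 Å.
CC_Friedel and CC_Laue correlate the unsymmetrized anisotropic map with
its own symmetrized image; because the symmetrized voxel contains the
unsymmetrized one, an i.i.d. random map scores 1/√2 ≈ 0.707 (orbit 2) or
0.50 (orbit 4), a floor the tests verify. CC_1/2 randomly splits the
symmetry-related observations of each unique voxel into halves and
correlates the count-weighted half means; voxels with fewer than two
distinct observed orbit members are excluded, and coinciding orbit
members on special positions (e.g. the k = 0 plane in 2/m) are
deduplicated so a voxel is never split against itself. The half-split
protocol is per unique voxel under a caller-supplied seed; across seeds
the overall CC_1/2 is stable to well under 0.01 on the synthetic
fixture. CC_Rep and CC_Cross average pairwise CCs against replicate or
cross-form Laue anisotropic maps. Undefined shells are reported as
missing, never as zero.

## Reference intensities and motion models

Reference (Bragg) intensities are squared structure factors over the
full unit cell — the P2₁ screw mate is generated explicitly so the model
map carries the correct 2/m symmetry before any explicit symmetrization.
Atomic form factors use the standard four-Gaussian coefficient tables;
hydrogens are included only if present in the model. Multi-conformer
models are reduced to the A conformer with occupancies set to 1 before
calculation. Three ADP treatments are supported: zero (T = 1), isotropic
(T = e^{−B_eq q²/4}, with B_eq = (8π²/3)·tr U when ANISOU is present) and
anisotropic (T = e^{−2π² qᵀUq}, Cartesian convention). No bulk-solvent
model is included, so model-data comparisons exclude d > 10 Å by
default.

The LLM kernel is the 3D Fourier transform of the exponential
displacement correlation e^{−r/γ}: Γ_γ(q) = 8πγ³/(1+γ²q_rad²)². This
functional form is the standard liquid-like-motions choice; the package
documents it explicitly because only the correlation function, not its
transform, is usually stated. The model intensity is
σ²q_rad²e^{−σ²q_rad²}(I₀ ⊛ Γ_γ) with the overall Debye–Waller factor, or
σ²q_rad²(I_B ⊛ Γ_γ) without it when individual ADPs already carry the
damping. Fitting the with-DW form to data whose reference holds
individual ADPs is the consistency probe: σ should refine toward zero,
and does in the tests. The convolution is circular on the periodic index
grid by FFT, with the kernel normalized to unit grid sum so total
intensity is preserved; wraparound is negligible because the kernel
width 1/(2πγ) is far smaller than the grid extent for physical γ. The
RBT model is I₀(q)(1−e^{−σ²q_rad²}), the standard uncorrelated
rigid-translation expression (again the closed form is rarely printed);
it needs no kernel.

**Optimization.** Fits maximize the Pearson correlation between the
processed model map (Laue-symmetrized and isotropic-subtracted exactly
like the data) and the data map. The objective is scale-free, so the
proportionality constants in the model equations are irrelevant, and the
tests assert invariance of the fit under rescaling of the data. The
search is a Powell direction-set method with Brent line minimizations,
bounded to σ ∈ [0, 3] Å and γ ∈ [0.5, 100] Å, with convergence at 1e−4
on the CC. Because the CC surface is smooth with a single broad optimum
in practice, the 3×3 screening grid (σ ∈ {0.2, 0.4, 0.8}, γ ∈ {4, 8,
16}) is evaluated first and Powell refinement starts from the best
screening points (two by default); this screening-then-refine reading of
multi-start keeps a 121³ fit to a few minutes on one CPU. The RBT fit is
a one-dimensional Brent search.

**ADP utilities.** Anisotropy ratio λ_min/λ_max of U (indefinite tensors
are flagged and clipped), B_eq, and rescaling by an overall anisotropic
difference scale matrix made traceless (subtracting tr/3 from the
diagonal) so that every atom's B_eq is provably unchanged — the suite
checks preservation to 1e−10.

## The synthetic generator: what it emulates, and what it does not

`make_toy_model()` draws pseudo-atoms uniformly in the asymmetric unit
of a monoclinic P2₁ cell with B_eq in 8–20 Å² and anisotropy ratios from
a Beta distribution centered on 0.45 with spread 0.1 — the bell-shaped
distribution typical of refined protein ADPs. `render_frames()` slices a
noiseless truth volume onto Ewald spheres by trilinear interpolation and
adds, in order: a water-ring-like isotropic background (broad hump near
3.3 Å), a detector-fixed anisotropic background blob emulating mount
scatter, Bragg spikes at reciprocal-lattice points, polarization and
solid-angle modulation (which the pipeline must undo), a per-frame
smooth radial drift of the crystal signal emulating illuminated-volume
and beam variation, Poisson counting noise, and random dead/hot pixels.
Background frames carry the background-only signal at 1 s exposure
versus 0.3 s crystal exposures, exercising the exposure-ratio path. Each
dataset receives a random crystal mounting orientation so that
detector-frame artifacts map into reciprocal space differently for
replicate datasets — without this, systematic artifacts would correlate
between replicates and CC_Rep would not respond to omitted corrections.

Chosen study conditions: a 512² pixel detector (0.172 mm pixels) at
0.7749 Å (16 keV) and 70 mm distance, so the detector edge reaches
≈1.35 Å and the Ewald blind cusp at 1.4 Å stays below 5% of a shell —
with a longer wavelength the cusp alone would cap per-shell completeness
under 95%. 180 frames of 0.5° for processing studies and a 180° sweep
for completeness. The default per-pixel diffuse rate (500 photons/s) is
set so the per-voxel redundancy-noise product matches a full-size
PAD experiment: the desk-scale detector has ~40× fewer pixels per voxel
than a 6M-pixel detector, and the rate compensates so that CC_1/2 lands
in the realistic 0.85–0.97 range rather than being dominated by desk
-scale shot noise. Artifact amplitudes (background ~600 photons/s with a
25% anisotropic component, 8% radial drift) are set so omitting a
correction degrades the map measurably, mirroring the qualitative
behavior of real capillary-mounted crystals.

What the generator does **not** emulate: detector point-spread, parallax
broadening (the correction is implemented and tested through its closed
form and thin-sensor limit, but frames are rendered without it), mosaic
spread and finite Bragg peak shape, absolute intensities, and radiation
damage. Passing tests therefore demonstrate the pipeline's correctness
and its artifact-removal behavior under these specific artifact classes,
not performance on every failure mode of real data.

**Voxelization transfer.** A merged voxel is the average of Ewald-sampled
interpolated values over the ±0.5 index box (minus the Bragg box), while
the truth and model maps are point samples at voxel centers. This
box-averaging attenuates diffuse features comparable in width to one
voxel, which has two visible consequences in the tests: the noise-free
end-to-end identity saturates near CC ≈ 0.96 rather than 1, and the
through-stack correlation length refines a few percent short of the
generating γ (within 15% at the protein-sized 90 Å cell, but ~20% short
at a 50 Å toy cell where γ = 7 Å features are sub-voxel). Direct
volume-level fits, which share the grid discretization between data and
model, recover σ and γ essentially exactly. Real experiments carry the
same transfer; reported γ values should be read with that in mind.

## Numerical choices and degenerate inputs

Empty radial-profile bins are recorded and excluded from the
least-squares scale; frames whose profile is entirely degenerate raise
an error. Merging silently drops (but counts) pixels outside the grid.
Voxels with zero observations propagate as missing through every
operation and metric. The boundary of the Bragg box (offset exactly
0.25) is rejected, matching the flag rule. The oversampling option on
reference volumes (>1 sample per Miller index) exists for visualization
and for reducing the generator's interpolation floor; production metrics
always use integer sampling. Kernel normalization uses the grid sum, so
convolution preserves total intensity exactly regardless of γ and grid.

## Known limitations

Only Laue groups −1 and 2/m are implemented (monoclinic focus);
higher-symmetry groups would need additional index maps. Space-group
expansion supports P1 and P2₁. The Bragg scale-factor method only
imports externally computed factors. CC significance is not assessed.
Rigid-body rotations and inter-molecular coupled motions are out of
scope, as is refinement of atomic coordinates or per-atom ADPs against
diffuse data.
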