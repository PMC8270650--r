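# diffusemap

Tools for extracting, validating and modeling macromolecular x-ray
**diffuse scattering**: the weak, continuous intensity between Bragg peaks
that encodes spatially correlated deviations from a crystal's average
structure. The package is aimed at structural biologists and beamline
scientists who collect rotation-series diffraction data and want
three-dimensional anisotropic diffuse maps, honest quality statistics for
them, and phenomenological models of the underlying correlated motions.

## What it does

**Frames to maps.** Raw detector frames are cleaned (static masking of
non-positive and saturated pixels, 11×11 windowed 5σ outlier rejection),
paired non-crystal background frames are subtracted after exposure-time
scaling, and pixel intensities are corrected for polarization, solid angle
and detector absorption, with a parallax correction of pixel positions.
Pixels whose fractional Miller indices (h, k, l) all fall within 0.25 of
integers are treated as Bragg signal and rejected (or median-replaced).
Frames are then scaled to a common reference — by radial-profile least
squares, water-ring or overall intensity ratios, or imported Bragg scale
factors — and residual frame-to-frame radial variation is removed by
principal-component analysis of the radial profile matrix. The corrected
pixels are merged onto an integer-Miller voxel grid (default 121³),
symmetrized over the Friedel or Laue (2/m) group, and the radially
averaged isotropic component is subtracted, leaving the anisotropic
diffuse map.

**Quality metrics.** Per resolution shell and overall, the package
computes the symmetry correlations CC_Friedel and CC_Laue (map versus its
own symmetrized image), the internal-consistency statistic CC_1/2 from
random half-splits of symmetry-related observations, and the
reproducibility statistics CC_Rep / CC_Cross against replicate or
cross-form datasets, all as Pearson correlations

    CC(X, Y) = Σ (Xᵢ − X̄)(Yᵢ − Ȳ) / sqrt( Σ (Xᵢ − X̄)² Σ (Yᵢ − Ȳ)² )

over common observed voxels. On independent random maps the symmetry
metrics inflate to 1/sqrt(orbit size) — about 0.71 for Friedel pairs and
0.50 for 2/m — which is why reproducibility across crystals is the more
trustworthy signal of data quality.

**Motion models.** The liquid-like motions (LLM) model treats atomic
displacement correlations as decaying exponentially with distance,
exp(−r/γ), giving model diffuse intensity

    I_d(q) ∝ σ² q² e^(−σ² q²) · [ I₀(q) ⊛ Γ_γ(q) ],
    Γ_γ(q) = 8 π γ³ / (1 + γ² q²)²,

with amplitude σ (Å) and correlation length γ (Å); when individual ADPs
are kept in the reference intensity I_B the overall Debye–Waller factor is
replaced by unity and I_d ∝ σ² q² (I_B ⊛ Γ_γ). The independent rigid-body
translation (RBT) model is I_d(q) = I₀(q)(1 − e^(−σ² q²)). Reference
intensities support zero, isotropic (B_eq) and anisotropic (ANISOU) ADP
treatments; fits maximize the correlation with the data map by a Powell
direction-set search and report the best CC (CC_LLM, CC_RBT). ADP
utilities include B_eq, anisotropy ratios, and traceless anisotropic
rescaling that provably preserves every atom's B_eq.

**Synthetic data.** A generator builds toy atomic models in a monoclinic
P2₁ cell, noiseless ground-truth diffuse volumes, and complete artificial
rotation series — Ewald-sphere slices with isotropic and
detector-anisotropic background, Bragg spikes, polarization/solid-angle
modulation, per-frame radial drift, Poisson noise and bad pixels — so the
entire pipeline is testable without any experimental download.

## Worked example

```r
library(diffusemap)

model  <- make_toy_model(n_atoms = 60, cell = c(50, 60, 40, 90, 105, 90), seed = 1)
truth  <- make_truth_volume(model, sigma = 0.4, gamma = 7, hmax = 36)
series <- render_frames(truth, synthetic_spec(n_frames = 60, step_deg = 3, seed = 2),
                        synthetic_geometry(384))
result <- run_pipeline_series(series, pipeline_config(hmax = 34, d_min = 1.8))
print(result$laue_anisotropic)
m <- result$metrics
cat(sprintf("Compl %.1f%%  CC_Friedel %.3f  CC_Laue %.3f  CC_1/2 %.3f\n",
            m$completeness, m$cc_friedel, m$cc_laue, m$cc_half))
fit <- fit_diffuse_model(result$laue_anisotropic, model,
                         kind = "llm", adp_mode = "zero", d_min = 1.8)
print(fit)
```

Output:

```
Diffuse volume: 69 x 69 x 69 voxels (|H| <= 34, oversample 1)
  cell 50.00 60.00 40.00  90.0 105.0 90.0, Laue 2/m
  observed voxels: 135791 (41.3%)
Compl 100.0%  CC_Friedel 0.989  CC_Laue 0.983  CC_1/2 0.977
LLM fit (zero ADPs)
  sigma = 0.403 A, gamma = 5.50 A
  CC_LLM = 0.9880 over 82770 voxels (10.0-1.80 A)
```

The pipeline recovers the generating displacement amplitude (σ = 0.403 Å
against a ground truth of 0.4 Å) with a high model correlation. The
fitted correlation length is shorter than the generating 7 Å because the
small 50 Å toy cell puts the kernel width near one voxel, where
voxel-averaging in the merge damps the sharpest diffuse features; with a
protein-sized 90 Å cell (as used in the test suite) γ is recovered within
about 10–15%. The completeness, CC_Friedel/CC_Laue near 0.99 and CC_1/2
near 0.98 say the merged map is internally consistent and essentially
complete at this resolution.

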