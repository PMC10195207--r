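# dbsir

Multi-compartment analysis of diffusion-weighted brain MRI for
distinguishing **tumor progression from treatment effect** in high-grade
glioma, built around diffusion basis spectrum imaging (DBSI). The package
is aimed at imaging scientists who want a tested, scriptable
implementation of the full chain: forward multi-tensor signal model,
per-voxel spectral fit, lesion ROI quantification and classification, and
the small-cohort statistics used to compare imaging metrics and diagnosis
timing.

## The model

Each voxel's normalized signal is modeled as discrete anisotropic
tensors plus a spectrum of isotropic tensors,

```
S_k/S_0 = Σ_i f_i · exp(-b_k λ⊥i) · exp(-b_k (λ∥i − λ⊥i) cos² φ_ik)
        + ∫ f(D) exp(-b_k D) dD ,
```

with the isotropic spectrum collapsed into restricted (0 ≤ D ≤ 1.0
µm²/ms, cellularity), hindered (1.0 < D ≤ 1.5, edema/necrosis) and
nonrestricted (D > 1.5, free water) signal fractions; the summed
anisotropic weight is the fiber fraction. The per-voxel inverse problem
is solved by compiled Lawson–Hanson non-negative least squares with
orientation screening, joint nonlinear refinement of fiber parameters and
compartment diffusivities, and BIC model selection; see the methods
vignette (`vignettes/dbsi-methods.Rmd`) for the design and its
identifiability analysis.

The hindered fraction is the diagnostic readout: within new or enlarging
contrast-enhancing lesions it is elevated in treatment-related change
(edema/necrosis) and depressed in viable tumor, relative to surrounding
parenchyma.

## Worked example

Simulate a treatment-effect-like voxel on the DBSI acquisition scheme
(q-space grid, r = 3, b_max = 1500 s/mm²) and fit it:

```r
library(dbsir)
table <- build_grid_scheme(3, 1500)      # 61 directions + b = 0
params <- dbsi_archetype("treatment_effect")
signal <- dbsi_signal(table, params)
fit_voxel(signal, table)
#> DBSI voxel: fiber 0.100 | restricted 0.171 | hindered 0.359 | nonrestricted 0.370 (rms 1.34e-06)
```

The generative composition was fiber 0.10, restricted 0.20, hindered
0.35, free 0.35: the fit recovers the hindered edema fraction that drives
the classification, with small restricted/free cross-talk typical for
b ≤ 1.5 ms/µm² data.

The cohort timing analysis on the published 12-patient table:

```r
time_to_diagnosis(table1_fixture())
#> Time to diagnosis, assisted vs standard of care (n = 9 analyzed):
#>   earlier with assistance: 6 (66.7%)
#>   overall: median 7.7 weeks (IQR 0.0-20.1)
#>   progression: n = 5, median 7.7 (IQR 0.0-15.0)
#>   treatment_effect: n = 4, median 29.2 (IQR 5.8-51.0)
```

Diagnosis assisted by the hindered-fraction map precedes
standard-of-care diagnosis by a median of 7.7 weeks, in 6 of 9 analyzed
patients.

End-to-end phantom classification (treatment-effect and progression
lesions on parenchyma, Rician SNR 30, clinical fit preset on smoothed
data):

```r
r <- classification_replicate(seed = 1)
r$treatment_effect$label   # "treatment_effect"
r$progression$label        # "progression"
```

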