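---
title: "Multi-compartment diffusion modeling with dbsir: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-compartment diffusion modeling with dbsir: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dbsir)
```

## The signal model

`dbsir` models the normalized diffusion-weighted MR signal of one voxel as
a linear combination of a small number of discrete anisotropic diffusion
tensors and a spectrum of isotropic diffusion tensors:

$$
\frac{S_k}{S_0} \;=\; \sum_{i=1}^{N_{aniso}} f_i\,
e^{-b_k \lambda_{\perp i}}\,
e^{-b_k (\lambda_{\parallel i}-\lambda_{\perp i})\cos^2\varphi_{ik}}
\;+\; \int_a^b f(D)\, e^{-b_k D}\, dD ,
$$

where $b_k$ is the b-value of the $k$-th diffusion gradient,
$\varphi_{ik}$ the angle between that gradient and the principal direction
of the $i$-th anisotropic tensor, $\lambda_{\parallel i} \ge
\lambda_{\perp i}$ its axial and radial diffusivities under cylindrical
symmetry, $f_i$ its signal fraction, and $f(D)$ the signal-fraction
density of isotropic diffusivity $D$ over the spectrum limits $[a, b]$.
All diffusivities are in µm²/ms; b-values are accepted in s/mm² at the
interfaces and converted to ms/µm² internally so that $b\,D$ is
dimensionless (1500 s/mm² = 1.5 ms/µm²).

The isotropic spectrum is collapsed into three diagnostic bands:

* **restricted**, $0 \le D \le 1.0$: high-cellularity water
  (tumor or inflammatory cells);
* **hindered**, $1.0 < D \le 1.5$: vasogenic edema or necrosis — the
  discriminating metric for distinguishing treatment effect from tumor
  progression;
* **nonrestricted (free)**, $D > 1.5$: CSF-like free water.

Band edges are inclusive on the right: a compartment at exactly
$D = 1.0$ is restricted, and one at exactly $1.5$ is hindered. The summed
anisotropic weight is the **fiber fraction**; the four fractions are
renormalized to sum to one.

The forward model (`dbsi_signal()`) discretizes the integral as a weighted
sum over the spectrum grid; the weights *are* the discrete fractions. For
a smooth $f(D)$ the discretization converges: at a grid step of 0.01
µm²/ms, halving the step changes signals by less than $10^{-6}$.

## The acquisition scheme

`build_grid_scheme(r, b_max)` enumerates the DSI-style q-space lattice
$(q_x, q_y, q_z)$ with $q_x^2+q_y^2+q_z^2 \le r^2$. With $r = 3$ this
gives 123 lattice points including the origin; collapsing antipodal pairs
(which measure the same attenuation) leaves 61 directions plus one
$b = 0$ entry. Each point $q$ is acquired at $b = b_{max}\,|q|^2/r^2$
(q-space convention, $b \propto |q|^2$), so the maximum b-value is
reached on the sphere $|q| = r$. Published protocols sometimes quote a
reduced vendor direction table (e.g. 99 directions) whose exact
derivation from the lattice is not public; such tables can be supplied
directly through `gradient_table()`.

## The inverse problem and why it is solved in three stages

Recovering $\{f_i, \lambda_{\parallel i}, \lambda_{\perp i},
\hat{u}_i\}$ and $f(D)$ from 62 measurements with $b \le 1.5$ ms/µm² is
severely ill-posed. Two facts drive the design of `fit_voxel()`:

1. **The dense spectrum solution is not unique.** A mid-band exponential
   (say $D = 1.14$) is reproducible to within $10^{-6}$ relative residual
   by a mixture of a slower and a faster exponential. A plain non-negative
   least-squares (NNLS) solve on a dense diffusivity grid therefore picks
   one of many near-exact solutions — differing by up to ~0.3 in band
   fractions — essentially by solver tie-breaking.
2. **Adjacent-band mixtures are noise-limited.** At a clinical SNR of 30,
   the information bound for the mixing fraction of a
   restricted-plus-hindered voxel with unknown compartment diffusivities
   exceeds the fraction scale itself; band attribution of such mixtures is
   a property of the estimator's constraints, not of the data.

The default fit therefore proceeds as:

* **Stage 1 — orientation screening.** Anisotropic basis functions on a
  fixed 60-point antipodally symmetric (Fibonacci) hemisphere, at nominal
  diffusivity priors (1.5, 0.25) and (1.8, 0.4) µm²/ms, plus a coarse
  isotropic basis (step 0.3), are fit by NNLS. Orientations carrying more
  than 5% of the total weight are retained, nearly collinear duplicates
  (|dot| > 0.95) dropped, up to `max_aniso` (default 2). The NNLS core is
  a compiled Lawson–Hanson active-set solver.
* **Stage 2 — dense spectrum solve.** Retained components' diffusivities
  are refined by bounded search
  ($\lambda_\parallel \in [0.5, 2.5]$, $\lambda_\perp \in [0, 1]$), then
  NNLS is solved over the anisotropic columns plus $e^{-bD_j}$ on the full
  grid (default $[0, 3]$, step 0.1). An optional ridge penalty
  (`ridge_rel`, relative to the squared largest singular value of the
  design) is available; the default is 0 because stage 3 provides the
  stabilization, and because even modest ridge weights visibly bias
  noise-free recovery.
* **Stage 3 — compartment consolidation and model selection.** The dense
  spectrum's peaks (single-linkage clusters of non-zero weights, split at
  gaps > 0.35 µm²/ms) seed discrete isotropic compartments. For each
  candidate compartment count (up to 4, with canonical inits 0.3, 1.25,
  2.7 µm²/ms as additional starts), the compartment diffusivities are
  refined jointly with every fiber's axial/radial diffusivity *and
  orientation* (as spherical angles) by bounded quasi-Newton search; the
  candidate-orientation grid alone leaves a residual floor (a ~7°
  mismatch) that would otherwise swamp the model comparison. The
  compartment count is chosen by BIC, with the residual floored at
  $n \times 10^{-12}$ so that noise-free exact fits prefer the most
  parsimonious exact model. Anisotropic components below 3% final weight
  are pruned and the voxel re-fit.

This collapses the effective degrees of freedom to the few physical
compartments present, which is what makes band fractions reproducible:
noise-free, 200 random archetype voxels are recovered with a mean
absolute four-fraction error below 0.005.

### The anchored clinical preset

`fit_config_clinical()` replaces the dense grid and model selection with
one fixed anchor diffusivity per band (restricted 0.3, hindered 1.25,
free 2.7 µm²/ms), keeping stage-1 screening and per-voxel fiber
refinement. At clinical SNR this trades unresolvable spectral freedom
for a large variance reduction — absolute band fractions acquire a
model-mismatch bias, but the relative contrasts the classification uses
(lesion versus surrounding parenchyma) are preserved with severalfold
less per-voxel scatter — and it runs an order of magnitude faster; it is
the preset used for lesion-classification maps. `fit_map()` can additionally
box-smooth the signal (`smooth_radius = 1` gives the usual 3×3×3
average), the standard clinical preprocessing step; smoothing raises
per-voxel SNR roughly five-fold, which suppresses the non-negativity
rectification bias that otherwise inflates small band fractions near
zero, at the cost of spatial resolution and spatially correlated noise.

### Degenerate inputs and numerical conventions

Non-positive measured signals are floored at machine epsilon before
normalization (magnitude data can underflow after preprocessing); the
count of floored samples is reported per voxel. The $b=0$ normalization
uses the mean of all $b=0$ volumes. All-zero signals, empty masks and
zero-weight fits raise errors rather than returning silent zeros. The fit
contains no random element: given the same signals and configuration the
result is bit-identical, and candidate orientations are a fixed
deterministic set.

## Conventional DTI comparator

`dti_fit()` performs the standard log-linear least-squares fit of the six
unique tensor elements, reporting ADC (mean eigenvalue) and FA
($\sqrt{3/2}\,\lVert\lambda-\bar\lambda\rVert / \lVert\lambda\rVert$).
Negative eigenvalues (possible under noise) are clamped at zero with a
warning. On noise-free single-tensor signals the generating eigenvalues
are recovered to $10^{-4}$.

## Synthetic data: what it emulates and what it does not

`make_phantom()` builds rectangular DWI volumes from the forward model
with Rician noise ($\sqrt{(s+n_1)^2+n_2^2}$, $n_i \sim N(0, 1/\mathrm{SNR})$),
with spherical lesions on a parenchyma background. The fixed archetypes
place the generative hindered fraction at 0.35 for treatment-effect
lesions, 0.12 for background parenchyma and 0.04 for progression lesions,
mirroring the qualitative reading rule (treatment effect hyperintense,
progression hypointense against surrounding parenchyma).

`random_voxel_params()` draws validation voxels as 2–3 compartment
mixtures of the four tissue archetypes, with compartment diffusivities at
canonical values (restricted 0.2–0.5, hindered 1.15–1.35, free 2.5–3.0
µm²/ms; fibers $\lambda_\parallel$ 1.4–2.0, $\lambda_\perp$ 0.15–0.4) and
uniform mixing weights. This mirrors validation-phantom practice —
compartments sit at representative diffusivities and the *fractions*
vary. It deliberately does **not** probe continuously varying mid-band
diffusivities: as discussed above, band membership of an off-archetype
compartment (e.g. $D = 1.05$) is not decidable from $b \le 1.5$ data at
any SNR, so passing round-trip tests demonstrate fraction recovery for
archetypal tissue, not spectral super-resolution. The phantoms likewise
contain no partial-volume gradients, susceptibility artifacts, motion, or
anatomically realistic geometry; eddy-current and motion correction are
assumed done upstream.

`make_cohort()` draws per-patient lesion-ROI metric means from
group-specific normals. The defaults give the hindered fraction a genuine
group difference (0.17 ± 0.02 treatment effect vs 0.08 ± 0.03
progression) and leave all other metrics overlapping, so that exactly one
metric should survive Bonferroni correction in a typical draw. The
diagnosis-timing model is a mixture: with probability 1/3 the
assisted and standard-of-care diagnoses coincide (a point mass at zero,
reproducing observed ties), otherwise the standard-of-care diagnosis lags
by a log-normal delay (meanlog 2.8, sdlog 0.9 weeks, median ≈ 16 weeks,
matching the spread of observed positive lead times).

## The lesion ROI pipeline

The quantification chain applies, in order: rigid resampling of all maps
onto the reference grid (`apply_rigid()`, trilinear for intensities,
nearest-neighbour for labels; transforms are inputs, estimated upstream);
selection of new or enlarging contrast-enhancing tissue
(`new_enhancement_mask()`: per 26-connected 3D component, a component
qualifies if its overlap with the prior lesion is smaller than the
component, and contributes its voxels outside the prior); the
every-third-axial-slice sampling rule (`sample_slices()`, starting from
the lowest occupied slice); per-metric ROI means (`roi_means()`, pooled
over all sampled voxels per patient); and classification
(`classify_lesion()`): a lesion whose mean hindered fraction exceeds that
of the surrounding parenchyma is called treatment effect, below it
progression, and exactly equal means return `indeterminate` rather than
an arbitrary side.

"Surrounding parenchyma" defaults to a shell 2–6 voxels outside the
lesion in Chebyshev distance (iterated 26-neighbour dilation), excluding
prior-lesion voxels and, when a nonrestricted map is available, CSF-like
voxels (nonrestricted > 0.8); a user-supplied reference mask overrides.

`classification_replicate()` packages the end-to-end experiment: a
26×26×9 phantom with one treatment-effect and one progression lesion
(radius 3.5 voxels), maps fit with the clinical preset on 3×3×3-smoothed
data over the sampled lesion and shell voxels, and both lesions
classified against their shells.

## The statistical layer

Group comparisons use Welch's unequal-variances $t$-test (two-tailed, via
`stats::t.test`), with a Bonferroni-adjusted threshold $\alpha/m$ over
the $m = 9$ metrics. Matched samples use an exact two-tailed Wilcoxon
signed-rank test: zero differences are dropped (and counted), and for up
to 12 non-zero differences the null distribution is built by full
enumeration of all $2^n$ sign assignments of the ranked absolute
differences — which remains valid under tied differences, where classical
exact tables do not apply — with a tie-corrected normal approximation
above. Categorical comparisons use Fisher's exact test
(`stats::fisher.test`), whose two-sided p-value sums hypergeometric
probabilities no larger than the observed table's.

Time-to-diagnosis summaries report the per-patient difference
(standard-of-care minus assisted, in weeks), with medians and
interquartile ranges by linear interpolation of order statistics at
position $1+(n-1)p$ (`stats::quantile` type 7); this convention — rather
than Tukey hinges — reproduces the interquartile ranges printed in the
source cohort table, which pins the choice. Stable and excluded patients
are dropped from timing analysis. P-values are reported to four decimals;
significance flags are computed on unrounded values.

## Validation scale and known limitations

The shipped validation uses 200 random voxels for round-trip error and
100 seeded phantom replicates for end-to-end classification — sizes
chosen to give stable estimates (binomial se ≈ 1.4% at 100 replicates)
while keeping a full run on a laptop in the tens of minutes.

Known limitations, in the package's own assessment:

* Per-voxel band fractions at clinical SNR are dominated by the
  restricted/hindered/free cross-talk of the exponential kernel at
  $b \le 1.5$ ms/µm²; single-voxel hindered estimates carry errors of
  ~0.1–0.2 for mixed voxels, and only ROI-level averages (the unit of
  analysis in the intended application) are stable.
* The fitted spectrum is a discrete compartment representation, not a
  continuous density; reported compartment diffusivities inside a band
  should not be over-interpreted.
* Registration, eddy-current/motion correction, enhancement segmentation
  and the clinical ground-truth labels are all inputs, not outputs, of
  this package.
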