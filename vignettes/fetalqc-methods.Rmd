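---
title: "Detecting motion-corrupted connectivity in fetal fMRI: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting motion-corrupted connectivity in fetal fMRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fetalqc)
```

## The problem

Fetal head movement is unconstrained, episodic, and often large. Motion and
the physiological environment of in-utero imaging inject shared variance
into regional BOLD signals, inflating functional connectivity (FC)
estimates with artifact rather than neural synchrony. Group-level quality
metrics built for adult cohorts — above all the QC–FC correlation, which
relates each edge's FC to subjects' mean framewise displacement (FD) across
a cohort — assume that motion influences edges uniformly across subjects
and that FC retains enough cross-subject variance to correlate with motion.
In heavily moving fetuses, motion-inflated FC saturates for nearly everyone
(the ceiling effect), so QC–FC can approach its chance baseline precisely
when the data are most corrupted.

`fetalqc` implements a subject-level alternative. The idea: fetal movement
is non-stationary, so if FC fluctuations over time track the
motion content of the data over time, that coupling is evidence of residual
artifact in that subject's connectome — edge by edge.

## The statistic

For a region pair with zero-mean signals $x, y$ of length $N$ volumes, the
time-varying FC is the windowed Pearson correlation

$$ cc_n = \mathrm{corr}\left(x_{n:n+w-1},\, y_{n:n+w-1}\right), \qquad
   n = 1, \dots, L,$$

with window length $w$ TR (default 46, i.e. 138 s at TR = 3 s) and stride 1,
giving $L = N - w + 1$ positions (51 for $N = 96$). The same windows average
the FD series into $fd_n$. The association of interest is the Pearson
correlation $r$ between $(cc_n)$ and $(fd_n)$.

Two significance procedures are provided:

* **Parametric** (`fcfd_test`): $t = r\sqrt{L-2}/\sqrt{1-r^2}$ against a
  Student $t$ distribution with $L-2$ degrees of freedom. This reference
  distribution assumes serially independent samples. Overlapping windows
  violate that badly — neighbouring windows share $w-1$ of $w$ samples, so
  the windowed series carry only a handful of effective degrees of freedom
  and the parametric test rejects far above its nominal level on null data.
  It is retained for serially independent inputs and for comparison.
* **Surrogate** (`surrogate_null`, the default): the FD series is
  phase-randomized — the amplitude spectrum of its discrete Fourier
  transform is kept exactly, phases are drawn uniformly with Hermitian
  symmetry — and the *entire* pipeline (window averaging, correlation with
  the observed $cc$ series) is re-run per surrogate. The null therefore
  inherits the serial dependence of the windowed statistics and stays
  calibrated where the $t$ test does not; this differential is asserted in
  the test suite. The two-sided empirical p-value uses the add-one
  correction $p = (1 + \#\{|r_0| \ge |r|\})/(n_{\mathrm{surr}} + 1)$, with
  1000 surrogates by default.

An edge is *corrupted* when $p < \alpha$ (default $\alpha = 0.05$,
uncorrected; Benjamini–Hochberg correction is available). Subject-level
summaries are the corrupted-edge fraction, the median $|r|$, per-region
counts of corrupted incident edges (an "uncertainty map"), and the Spearman
correlation between $r$ and inter-centroid Euclidean distance (distance
dependence of the residual artifact).

A practical note on power: with $N = 96$ and $w = 46$ the windowed series
resolve only about two independent features per scan, so the surrogate null
of $r$ is wide and single-scan detections require strong coupling. Power
grows with scan length and with the number of distinct movement episodes,
not with the number of surrogates.

## Framewise displacement

FD is computed from six rigid-body realignment parameters (translations mm,
rotations degrees). Because fetal brain size changes several-fold over
gestation, the rotational lever arm is estimated per subject by a linear
least-squares sphere fit to head-surface or brain-mask coordinates
(`fit_sphere`; the algebraic expansion of $|p-c|^2 = r^2$, exact on
noiseless spheres). For each volume-to-volume transition the two rigid
transforms are applied to points on the fitted sphere surface (or to
explicit voxel coordinates) and the root-mean-square displacement is
returned, with a leading zero to align with volumes. Euler convention:
extrinsic x–y–z, rotations about the sphere center; both are configurable
and recorded. A Power-style $\ell_1$ summary
($|\Delta t|_1 + r|\Delta\theta|_1$) is available for comparison.

Censoring combines two flags by logical OR: volumes whose FD exceeds a
threshold (default 0.5 mm — there is no universal value; it is config-level
and recorded in outputs), and volumes where more than 5% of in-mask voxels
deviate from the volume's bulk intensity by more than 3 robust standard
deviations (median/MAD; a non-robust estimate would let heavy contamination
mask itself).

## Nuisance regression strategies

The benchmark registry covers the families commonly evaluated in fetal and
adult denoising studies: `6HMP`, `24HMP` (parameters, backward-difference
derivatives, squares of both), `2Phys`/`8Phys` (WM and CSF means and
expansions), `GSR`/`2GSR`/`4GSR`, `aCompCor` (top principal components of
WM+CSF voxel time series; 5 components by default, the usual convention),
`tCompCor` (PCs of the top 2% highest-temporal-variance voxels), `localWM`
(per-region mean of white-matter voxels within 25 mm of the region
centroid, in the ANATICOR spirit), a combined `4GSR+8Phys+24HMP`, and
`none`. Published strategy tables that combine these differently can be
declared at run time with `register_strategy()` — the composition of such
tables varies between papers, so it is data, not code.

Removal is ordinary least squares on retained (non-censored) frames, with
residuals orthogonal to the design there; rank-deficient designs fall back
to a pseudoinverse with a warning. Order of operations follows standard
practice for this benchmark: nuisance regression first, then demeaning,
detrending and discrete-cosine high-pass filtering at 0.008 Hz.

## The generative simulator

Because no ground truth exists for fetal FC, the detector is validated on a
parametric model of corrupted BOLD pairs (`simulate_pair`,
`simulate_dataset`):

1. **Neural events**: a binary train at $\nu_g = 20$ Hz from a two-state
   first-order Markov chain with stationary active probability 5% and an
   active-state self-transition of 0.5 (short bursts); both exposed in
   `sim_params()`.
2. **Hemodynamics**: convolution with a double-gamma HRF whose positive
   lobe peaks at exactly 6 s (gamma shapes are parameterized so the mode
   sits at the stated delay) and whose undershoot peaks at 16 s with weight
   1/6.
3. **Neural coupling**: a target correlation matrix $R$ is imposed by
   multiplying the standardized ideal signals with the Cholesky factor of
   $R$.
4. **Observation**: (i) each active latent bin is deleted with probability
   0.1 in the observed branch only (observation-side event loss; the ideal
   branch keeps all events); (ii) a *shared* physiological noise process is
   added at an RMS amplitude ratio `snr_phys`; (iii) block averaging over
   $d = \nu_g/\nu_o = 60$ latent bins yields $N$ = 96 volumes at TR = 3 s
   (decimation is available); (iv) white thermal noise is added at RMS
   ratio `snr_scan`; (v) signals are z-scored.

The ground-truth displacement proxy is the absolute value of the
downsampled physiological noise — displacement is a magnitude, while the
noise is signed.

**The noise process is episodic by design.** A stationary low-pass noise
(carrier cutoff 0.3 Hz) has an essentially constant amplitude envelope at
the 138-s window scale: window-averaged FD then barely varies, the FC–FD
coupling vanishes, and contamination would not raise the corrupted count at
all — contradicting the defining behaviour of motion corruption. Fetal
movement is not stationary: it alternates between quiescence and movement
epochs on minute scales. The carrier is therefore amplitude-modulated by a
slow nonnegative envelope. Two envelope models are exposed:

* `"lowpass"` (default): $|$Gaussian noise low-passed at 0.01 Hz$|$ — a
  generic slow modulation used for the population-level validation study;
* `"burst"`: a small number of discrete movement episodes (default 3
  Gaussian bumps of 15 s width, stratified over the acquisition with
  jitter, over a 5% quiescent baseline) — used by the end-to-end fixture,
  where distinct, well-separated episodes make the planted effect
  identifiable at single-scan length.

What the simulator does *not* model: image-space rigid-body rendering
(signals are simulated at the region level, as the validation requires),
fetal cardiac/respiratory spectral lines, spin-history effects, and any
spatial structure of the noise beyond "fully shared within a pair"
(partial sharing is config-exposed). Passing tests on this generator
demonstrate calibration and recovery under these assumptions, not under
every mechanism present in real scans.

## Validation study and its scale

The package's acceptance script (`scripts/acceptance.R`) regenerates the
simulation study: two datasets of 5000 uncorrelated pairs at low
(SNRphys, SNRscan) = (12, 18) and high (2, 3) contamination, 96 volumes
each, 46-TR windows, surrogate test at $\alpha = .05$ (100 surrogates per
pair, which puts the effective level at $5/101 \approx 0.0495$). It reports
the corrupted-pair counts, the centers of the FC–FD correlation
distributions, and the centers of the observed-FC distributions at both
levels. With the RMS-ratio reading of the SNRs, the noise variance share at
(2, 3) caps the attainable spurious FC below what stronger contamination
conventions would give; the qualitative signatures — more corrupted pairs,
a right-shifted FC–FD correlation distribution, and inflated FC under
contamination — are the validated content, and the monotone orderings
across contamination levels are asserted strictly in the test suite.

The test suite runs scaled-down versions of everything stochastic: type-I
calibration uses 10,000 null replicates (100 surrogates each for the
surrogate arm), the fixture recovery averages four seeds of a 12-region,
192-volume subject, the ceiling-effect cohort uses 24 synthetic subjects
with 8 regions each. These sizes were chosen to keep Monte-Carlo error
comfortably below the asserted margins.

## The end-to-end fixture

`make_fixture_subject()` writes a complete synthetic subject to disk — 4D
BOLD NIfTI painted from simulated region signals, parcellation and tissue
masks, a motion-parameter file whose FD reproduces the simulated
displacement proxy, and a JSON ground-truth sidecar. Half the regions share
the episodic noise process; edges between two contaminated regions are the
planted corrupted set. The fixture emulates a *heavily* moving fetus over a
longer acquisition (192 volumes, `snr_phys = 0.5`, burst envelope): a
power analysis during design showed that at 96 volumes the surrogate null
is so wide that even near-perfect coupling ($r > 0.9$) is not reliably
significant, so a recovery contract at moderate contamination would test
luck, not correctness. Planted-edge recovery above 80% sensitivity is part
of the acceptance suite.

## Degenerate inputs and numerical choices

* Windows with zero variance yield `NA` FC values; they are excluded from
  $r$ with a reported count.
* A constant FD series makes every FC–FD correlation undefined; the report
  flags FD as degenerate rather than failing.
* Zero-variance regions are excluded and listed.
* $|r| \ge 1 - 10^{-12}$ maps to an infinite $t$ and $p = 0$.
* Correlation matrices that fail the Cholesky factorization are rejected
  with an eigenvalue report.
* Sphere fits require at least 4 non-coplanar points (rank check on the
  algebraic system).
* Windowed statistics are computed from running sums after global
  centering; agreement with naive per-window evaluation to $10^{-12}$ is
  asserted in the suite.
* All randomness flows through explicit seeds; dataset pairs use
  deterministic per-pair substreams so results do not depend on the number
  of pairs generated.

## Known limitations

* The subject-level test has low power at single-scan length (96 volumes)
  with the default 46-TR window; it is a detector of strong residual
  coupling, not a certificate of cleanliness.
* The surrogate null conditions on the observed FC series and randomizes
  FD only (the default; randomizing both is available). It tests the
  *timing* relation between FC and FD, not whether FC amplitude is
  plausible.
* QC–FC and the pooled distance-dependence summaries inherit the usual
  caveats of cross-subject correlational metrics; they are provided for
  benchmarking against the subject-level method, which is the point of the
  package.
* Real-data preprocessing upstream of this package (motion correction,
  reconstruction, segmentation) is out of scope; the package starts from
  realigned 4D data, label images, and realignment parameters.
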