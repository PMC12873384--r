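---
title: "Methods: multimodal analysis of silk-fibroin gelation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal analysis of silk-fibroin gelation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(silkgel)
```

## The problem

Reconstituted silk fibroin (RSF) from *Bombyx mori* can be driven through a
sol--gel transition either slowly, by acidification with glucono-δ-lactone
(GdL, whose hydrolysis lowers the pH from 7.5 toward ~3.6 over hours), or
abruptly with methanol. Time-resolved small-angle neutron scattering (SANS)
recorded every 5 minutes on q ∈ 0.002–0.5 Å⁻¹, acquired simultaneously with
thioflavin-T (ThT) fluorescence, a 450 nm turbidity proxy and off-line pH,
resolves how the network forms: during pH-triggered gelation a transient
mid-q correlation peak appears near q₀ ≈ 0.015 Å⁻¹ — regularly spaced
protein-rich domains — before a β-sheet-rich network consolidates, whereas
methanol-induced aggregation shows a continuous intensity rise with no such
peak. `silkgel` implements the quantitative machinery for this analysis:
model fitting, model-free metrics, density-based phase mapping, joint
curve resolution, and kinetics, together with a seeded synthetic-data
generator that emulates the full experiment so every stage is testable
without beamline access.

## The hierarchical scattering model

Frames are fitted sequentially with two nested composite models. Stage 1
("gel"):

$$ I(q) = \frac{a}{q^{\,n}} + \frac{c}{1 + (\eta q)^{m}} + b $$

a power law for the large-scale fractal network (amplitude $a$, exponent
$n$), a Lorentzian (Ornstein–Zernike-like) term for correlated domains of
size $\eta$ (amplitude $c$, internal exponent $m$), and a flat incoherent
background $b$. Stage 2 ("peak") adds a finite-size cut-off on the power
law and a Gaussian correlation peak:

$$ I(q) = \frac{a}{q^{\,n}} e^{-(\eta q)^{m}} + \frac{c}{1 + (\eta q)^{m}}
   + d\, e^{-\frac{(q - q_0)^2}{2\sigma^2}} + b $$

with $\eta$ and $m$ deliberately shared between the cut-off and the
Lorentzian — there is one correlation length in the model, not two. The
inter-domain spacing is derived, never fitted: $d^* = 2\pi/q_0$.

GdL-triggered series are fitted with stage 1 first; its parameters seed the
stage-2 fit of the same frame. Methanol series are fitted with stage 1
only: the correlation peak never develops, and the extra terms would
overfit.

### Numerical choices

* **Loss.** Unweighted least squares on $\log_{10} I$ over points with
  $I > 0$. The curves span four decades in both axes; a log-space loss
  balances the power-law and background regions. An
  uncertainty-weighted loss is not offered — on absolute-scaled reduced
  data the relative errors are roughly uniform in the fitted range, which
  is what the log loss assumes. Non-positive intensities are *flagged at
  read time and excluded by the fit*, never deleted from the data.
* **Bounds.** $a, c, d, b \ge 0$; $n, m \in [0, 6]$;
  $\eta \in [1, 10^3]$ Å; $q_0 \in [0.013, 0.025]$ Å⁻¹ (the same window
  used for peak detection); $\sigma \in [5\times10^{-4}, 0.02]$ Å⁻¹.
* **Multi-start.** The Gaussian term creates local minima in $q_0$ and
  $\sigma$. Stage 2 starts from the detected peak position (window centre
  if no peak) plus both window edges, crossed with two width starts
  (0.002, 0.006 Å⁻¹). Runs whose residuals agree within 2% (relative) are
  treated as equivalent minima and resolve to the earliest start in the
  deterministic order, with the previous frame's solution (warm start,
  default on for series) placed first. This matters when the Gaussian is
  weak: its width is then unidentified, the minima are equivalent, and
  preferring the warm start keeps the parameter trajectory smooth instead
  of hopping between flat minima. Cold-start mode exists for independence
  checks.
* **Convergence.** Levenberg–Marquardt with box bounds
  (`minpack.lm::nls.lm`), relative tolerance $10^{-10}$, at most 500
  iterations; optimiser failure returns the best-so-far parameters with
  `converged = FALSE`. The reported stage-2 residual never exceeds that
  of any start evaluated under the stage-2 model.
* **Identifiability.** When the power law dominates through the
  Lorentzian shoulder, only the tail combination $c/\eta^m$ is determined
  and $(c, \eta)$ trade off along a ridge; the tests assert function-space
  recovery in that regime rather than pretending the individual values
  are measurable. Similarly, frames with a weak Gaussian leave $\sigma$
  ill-determined; the tie-break rule above turns that into a stable
  convention rather than noise.

## Model-free metrics

Per frame: the *apparent* scattering invariant
$Q^* = \int I(q)\, q^2\, \mathrm{d}q$ by trapezoid over the measured grid
only (no Porod/Guinier extrapolation, hence "apparent"); the correlation
peak $q^+$ as the most prominent strict local maximum of $I(q)$ inside the
0.013–0.025 Å⁻¹ window (topographic prominence; ties break to the smallest
q; optional 3-point smoothing for noisy data; minimum prominence default 0);
and the mean low-q intensity over $[q_{\min}, 0.003]$ Å⁻¹ — chosen to sit
well below the peak window, in the power-law regime. On the $I(q^+)$ time
trace the package reports $t(q^+)$, the time of maximum peak intensity
(earliest frame on plateaus), and $t(q_{on})$, the onset of the second
rise: the first time after the post-peak minimum at which the trace exceeds
that minimum by 10% of its total range. The onset definition is our own
operationalisation of a plotted but undefined landmark, and both the
fraction and the rule are configurable.

## Phase mapping

The eight fitted parameters $(a, n, c, \eta, m, d, q_0, \sigma)$ — the
background is not part of the set — are z-scored (population standard
deviation, the standard scaler convention; a zero-variance column becomes
zeros with a warning) and clustered with DBSCAN, Euclidean metric,
eps = 1.0, min_samples = 5, closed-ball neighbourhoods with the point
itself counted. These conventions are stated because DBSCAN
implementations differ in all three. Clusters are labelled Initiation,
Pre-assembly, Network Assembly and Maturation in order of their median
member time; extra clusters (beyond the four most populous) are demoted to
noise, and fewer than four are reported as such, never padded.

Each phase's envelope is summarised by the volume of its 3-D convex hull
in the z-scored $(n, m, d)$ subspace — the most correlated triple and the
space in which the envelopes are visualised — as a percentage of the
summed volumes. Phases with fewer than 4 points or coplanar geometry get
volume 0. Hull volumes come from an in-package incremental (beneath–beyond)
convex-hull construction, cross-checked in the tests against closed-form
polyhedra and an independent quickhull implementation; no installed R
package provides 3-D hull volumes. An 8-D hull option was considered and
rejected: on trajectories of this length (~60–80 frames) high-dimensional
hulls are dominated by noise, and the package does not pretend otherwise.
Per-phase statistics (mean ± sd of $\eta$ and $d^*$) use the population
standard deviation, so a single-member phase reports "± 0" rather than NA.

## Kinetics

ThT fluorescence follows a 4-parameter logistic
$v(t) = \text{baseline} + A/(1 + e^{-(t - t_m)/\tau})$, fitted with
deterministic quantile-based initialisation; a trace the logistic fits no
better than a flat model is flagged. The logistic is not an arbitrary
choice: the onset convention "two time constants before the midpoint"
pins the onset level at $1/(1+e^2) = 11.92\%$ of $A$ — the "roughly 12%"
level — *exactly* for this functional form, so the onset time
$t_{on} = t_m - 2\tau$ and the 12% definition coincide. The plateau time
has no closed-form convention; the default rule takes the first time the
3-point-smoothed measured trace enters and stays within 2% of $A$ of the
median of its final 10% of samples, and a fit-based alternative
($t_m + 2\tau$) is available. The two rules genuinely differ (for the
reference trace: ~208 min vs ~169 min) and neither is privileged; both are
exposed.

The ThT channel is the mean emission within 2 nm of 485 nm; the turbidity
proxy is the attenuated 450 nm excitation signal at 90°, read the same
way. The ±2 nm (and ±2 cm⁻¹ for FTIR) band averaging makes read-outs
robust to the instrument grid.

FTIR amide-I processing: 1:1 buffer subtraction (a scalar-scaled option
exists), isolation of 1590–1720 cm⁻¹, subtraction of the straight line
through the window endpoints (output anchored at zero at both ends), and
division by the trapezoidal area. Band kinetics at 1620 cm⁻¹ (crystalline
β-sheet) and 1695 cm⁻¹ (antiparallel β contacts) are min–max normalised
over the time course; a constant band is returned as zeros with a warning
rather than 0/0.

pH traces are measured off-line and pass through untouched apart from
time alignment; no hydrolysis model is fitted to data.

## Joint curve resolution (MCR-ALS)

SANS frames and emission spectra share the time dimension, so they are
arranged as one augmented matrix $D$ (rows = SANS frame times; columns =
q-grid block then wavelength block, the fluorescence resampled to frame
times by linear interpolation and truncated to the overlap). Each block is
max-normalised to 1 and the blocks are then rescaled to equal summed
variance — otherwise the larger block owns the least-squares objective.
$D \approx C S^\top$ is solved by alternating non-negativity-constrained
least squares: non-negativity on $C$ and on both signature blocks, no
closure (the components are not an exhaustive mass balance) and no
unimodality. Both subproblems are solved exactly — for small component
counts by enumerating the $2^k$ candidate active sets vectorised across
columns, with Lawson–Hanson as the general fallback — so the lack of fit
$100\sqrt{\mathrm{SSE}/\sum D^2}$ is provably non-increasing and is
asserted at every iteration. Signatures are renormalised to unit maximum
each iteration with the scale moved into $C$, pinning the scale
indeterminacy without changing the reconstruction.

Initialisation uses purest-row selection (largest-norm row, then
repeatedly the row with the largest residual after projection onto the
span of the chosen rows); a seeded random init is the fallback. The
component count defaults to 3, and `select_rank()` always reports the
full singular-value scree so the choice is auditable: on the reference
sample the 99.5% threshold alone would choose k = 2, and the third
component is retained on the strength of the resolved signatures, not the
scree. Restart envelopes re-run the ALS from seeded perturbed
initialisations, keep solutions within 5% relative lack of fit of the
best, match components by profile correlation, and report pointwise
min/max bands; the bands contain the best fit by construction.

Pearson correlations between the concentration profiles and ten signals
(the eight fitted parameters, ThT, turbidity) are computed at matched time
points after min–max normalisation and linear resampling onto the profile
grid; a constant signal is reported as missing rather than as a
correlation.

## The synthetic-data generator

The generator is first-class, tested code, and its defaults *are* the
study conditions: frames every 5 min from t = 5 to 400 min, 120 log-spaced
q points on 0.002–0.5 Å⁻¹, pH decaying 7.5 → 3.6 with the rate
proportional to GdL concentration (calibrated so 1% w/v reaches pH 4.5 at
35 min — doubling the concentration halves the time to any level), ThT
midpoint 128 min and τ = 20.5 min (onset 87 min), and phase boundaries at
35, 180 and 300 min.

Each structural parameter follows a sum of logistic steps between
per-phase anchor plateaus. Anchors follow the reported per-phase levels:
η 100 → 50 → 70 → 62 Å, d* 365 → 380 → 295 → 235 Å (q₀ = 2π/d*),
d 0.05 → 0.35 → 0.15 → 0.08, n peaking near 4 and settling at 2.5,
m near 2.7 then 2.5. The power-law amplitude is parameterised through the
low-q intensity `i_ref` at q = 0.002 Å⁻¹ (so absolute intensities stay
realistic while n varies), and the Lorentzian amplitude carries a
transient high level in Initiation — the early mid-q intensity maximum —
chosen by forward simulation so the model-free $I(q^+)$ trace shows the
observed early-maximum-then-decline shape with the peak becoming
detectable just after the Initiation boundary (t(q⁺) ≈ 40 min in the
reference run).

Superimposed on the plateaus is a deterministic two-tone "wobble" (sines
of 60 and 97 min periods with fixed phase offsets), with per-phase
amplitudes encoding the reported structural plasticity: large in
Pre-assembly (n ± ~0.55, m ± 0.15, d ± 0.08), small elsewhere. Two
incommensurate periods make the within-phase excursion non-repeating, so
the Gaussian-amplitude crest early in Pre-assembly is the unique global
one. Fixed phases (rather than seeded random ones) keep the reference
phenomenology — four separable clusters, Pre-assembly hull dominance, the
early I(q⁺) maximum — a property of the simulated conditions rather than of a
lucky seed; the measurement noise remains fully seeded. Transitions are
sharp (3–4 min widths) relative to the 5-min sampling: regime switches,
not drifts, which is also what makes the phases separable at eps = 1.

Noise: multiplicative Gaussian with relative sd 1% by default (reduced
SANS data at these count rates carry ~1–3% relative errors; recovery tests
use 2%) plus an additive floor of sd background/50 at high q. The floor
belongs to the noise model and vanishes when noise is set to 0, so the
noiseless inverse crime is exact. The `dI` column carries the noise-model
sd.

The FTIR generator conserves the amide backbone: the random-coil band
shrinks by exactly the integrated area the two β bands gain, so the total
amide-I area is constant over time and the area normalisation is neutral
to the band kinetics — which is also why the injected waveforms are
recoverable to r > 0.99. The emission generator keeps the 450 nm scatter
channel narrow (sd 3 nm) and the 485 nm ThT band at sd 12 nm so the two
channels do not bleed into each other's ±2 nm read-out windows.

### What the generator does not emulate

Instrument resolution smearing, q-dependent error correlations, detector
dead-time or transmission drifts, multiple scattering, the saturating
UV-vis channel, and any physically detailed (coarse-grained) fibroin
model. Trajectories are smooth blends, not stochastic processes — real
Pre-assembly fluctuations are not band-limited sinusoids. Passing the
recovery tests therefore demonstrates that the estimators are correct and
well-conditioned under the assumed noise model, not that they are robust
to every artefact of real beamline data; the external-data check against
the deposited CSVs is the stronger test and requires a download.

## Problem sizes

The shipped analyses and tests use the 80-frame reference series at 120 q
points for the end-to-end runs, 40 frames for the trajectory-recovery
study, 50 seeded point sets for the clustering oracle comparison, and an
80 × 194 joint matrix for the factorisation study — sizes at which the
full workflow (simulate → fit → cluster → resolve) completes in well under
two minutes on one CPU while matching the scale of a real beamtime
dataset.

## Known limitations

* The Maturation-phase spacing anchor (d* = 235 Å) implies q₀ ≈ 0.0267
  Å⁻¹, just outside the 0.013–0.025 Å⁻¹ detection window and fit bound —
  late-frame peaks are consequently often undetected and the fitted q₀
  saturates at the bound. This mirrors a tension in the underlying measurements
  themselves (the reported late-phase spacings vs the stated window) and
  is deliberately left visible.
* The default reference does not produce a marked second rise of I(q⁺)
  during Network Assembly (t(q_on) is NA there); the second-rise onset
  rule is exercised on constructed traces instead.
* DBSCAN phase recovery depends on fit scatter: at 2% noise the 7-frame
  Initiation cluster falls apart (its members scatter more than eps = 1
  in z-units) while at 1% all four phases are recovered. Real data sit
  wherever their error bars put them; the phase-mapping functions report
  honestly in either case.
* `fit_series` warm-starting assumes temporal smoothness; for data with
  genuine frame-to-frame jumps use `warm_start = FALSE`.
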