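# silkgel

Multimodal analysis of silk-fibroin gelation from time-resolved
small-angle neutron scattering (SANS), thioflavin-T (ThT) fluorescence,
turbidity, pH and FTIR.

Reconstituted silk fibroin (RSF) gels either gradually, when
glucono-δ-lactone (GdL) hydrolysis drives the pH from 7.5 toward ~3.6, or
abruptly with methanol. Time-resolved SANS (a frame every 5 minutes on
q ∈ 0.002–0.5 Å⁻¹) recorded simultaneously with optical probes resolves
the pathway: pH-triggered gelation passes through a transient state with a
mid-q correlation peak near q₀ ≈ 0.015 Å⁻¹ — regularly spaced protein-rich
domains — before a β-sheet-rich network matures, while methanol-induced
aggregation shows no such intermediate. `silkgel` is for scattering and
biophysics researchers who want that whole analysis as tested, reusable
code.

## What it computes

* **Hierarchical model fits.** Sequential two-stage fitting in log space:
  stage 1, `I(q) = a/qⁿ + c/(1+(ηq)ᵐ) + b` (fractal network + correlated
  domains + background); stage 2 adds a finite-size cut-off and a Gaussian
  correlation peak,
  `I(q) = (a/qⁿ)e^(−(ηq)ᵐ) + c/(1+(ηq)ᵐ) + d·e^(−(q−q₀)²/2σ²) + b`,
  with η and m shared between terms and the inter-domain spacing derived
  as d\* = 2π/q₀ (never fitted). GdL series get both stages; methanol
  series stage 1 only.
* **Model-free metrics.** Apparent invariant Q\* = ∫I(q)q²dq over the
  measured range, the most prominent correlation peak q⁺ in
  0.013–0.025 Å⁻¹, low-q intensity, and the landmark times of the I(q⁺)
  trace.
* **Phase mapping.** DBSCAN (eps = 1.0, min_samples = 5) over the
  z-scored eight-parameter space (a, n, c, η, m, d, q₀, σ) labels the four
  gelation phases — Initiation, Pre-assembly, Network Assembly,
  Maturation — by dominant time, with convex-hull phase volumes in the
  (n, m, d) subspace and per-phase η / d\* statistics.
* **Kinetics.** 4-parameter logistic ThT fits: midpoint ThT_m at 50% of
  the amplitude, onset ThT_on = t_m − 2τ (analytically the ~12% level),
  plateau by a trace-based rule; 485 nm ThT and 450 nm turbidity channels
  from emission spectra; amide-I FTIR band kinetics at 1620/1695 cm⁻¹
  after buffer subtraction, baseline correction and area normalisation.
* **Joint MCR-ALS.** The row-augmented SANS + fluorescence matrix is
  factorised into non-negative concentration profiles and per-block
  component signatures, with exact NNLS subproblems (monotone lack of
  fit), restart-based uncertainty envelopes, and the 3 × 10 Pearson
  correlation map against the fitted parameters, ThT and turbidity.
* **Synthetic data.** A seeded generator reproduces the full experiment
  (SANS series with four-phase parameter trajectories, pH, ThT, emission
  spectra, FTIR) so the entire pipeline is testable offline; see the
  methods vignette (`vignettes/silkgel-methods.Rmd`) for what it does and
  does not emulate.

## Worked example

The `analysis/` directory is a numbered workflow over the package
(`01_simulate.R` … `06_mcr.R`) writing its tables under `results/`. The
same end-to-end run is one call:

```r
library(silkgel)
report <- run_gelation_pipeline(default_run_config(seed = 1))
print(report)
```

```
<run_report>
  input         simulated reference sample
  metrics       ok
  fit           ok (80 frames, 0 failed)
  phases        ok (4 phases)
  kinetics      ok
  mcr           ok (lack of fit 2.67%)
  correlations  ok
  landmarks: t(q+)=40, ThT_on=87.0, ThT_m=128.0, ThT_p=212 min
  phase volumes (%):
    Initiation         0.04
    Pre-assembly      96.68
    NetworkAssembly    3.13
    Maturation         0.15
```

Reading the output: the correlation-peak intensity maximum (40 min) falls
at the Initiation → Pre-assembly transition and precedes the ThT onset
(87 min) and midpoint (128 min) — structural ordering leads β-sheet
formation. All four phases are recovered in time order, and Pre-assembly
dominates the parameter-space envelope (>90% of the summed hull volumes),
the signature of its structural plasticity; the MCR lack of fit sits near
the injected noise level. Per-frame fits, phase tables, landmarks, MCR
profiles and the correlation map are returned in the report (and written
as CSVs when `out_dir` is set).

Real data are consumed through the same interface: per-frame `q,I,dI`
CSVs listed in a YAML/JSON manifest (`read_series()`), 2-column kinetic
traces (`read_trace()`) and wide spectra (`read_spectra()`), with a column
dialect map for deposited files whose headers differ.

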