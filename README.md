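# ecgcmf

ECG biometric identification from single-lead recordings, using **dual-level
features** — the raw 1D amplitude series of each heartbeat and a 2D
*relative position matrix* encoding of the same beat — embedded into a shared
discriminative latent space by **collective matrix factorization** with
dimensional attention weights and out-of-sample projection matrices.

The package is aimed at biometric / biosignal researchers who want a fully
reproducible, download-free testbed for factorization-based ECG recognition:
every stage, from R-peak detection to EER curves, runs on a seeded synthetic
ECG generator with known ground truth.

## The model

Given `n` training heartbeats with 1D features `X1 ∈ R^{d1×n}`, 2D features
`X2 ∈ R^{d2×n}` and a label matrix `L ∈ {0,1}^{n×c}` over `c` subjects, the
model learns loadings `U1, U2`, projections `W1, W2`, a diagonal attention
matrix `A` and shared latent codes `V ∈ R^{r×n}` by minimizing

```
α‖X1 − U1 V‖²_F + β‖X2 − U2 V‖²_F          (collaborative embedding)
+ η‖W1 X1 − V‖²_F + γ‖W2 X2 − V‖²_F        (out-of-sample projection)
+ ‖S − VᵀA V‖²_F                           (dimensional attention, S = GᵀG)
+ ζ (‖U1‖²_F + ‖U2‖²_F + ‖W1‖²_F + ‖W2‖²_F)
s.t.  V Vᵀ = n I_r ,  V 1_n = 0_r
```

where `G` is the column-normalized label factor, so the `n×n` similarity
`S` is never materialized. Optimization alternates six closed-form /
constrained sub-problems per iteration (`U1, U2, A, W1, W2, V`); the
constrained `V` step is an orthogonality-constrained trace maximization
solved through the eigendecomposition of `Z J Zᵀ` with the centering matrix
`J = I − (1/n)11ᵀ`. At test time, enrollment and probe beats are projected
as `W1 X1` and `W2 X2` and matched by fused Euclidean distance.

The 2D feature of a beat is the row-major flattening of the antisymmetric
matrix `x_i − x_j` of its piecewise-aggregate-approximated (PAA) series:
a 260-sample beat downsampled to 26 segments yields a 676-dimensional
feature; a 460-sample beat with 39 segments yields 1521.

## Worked example

```r
library(ecgcmf)

cfg <- pipeline_config(seed = 1L)   # 10 subjects, 40 beats each, 360 Hz
report <- run_pipeline(cfg)
report
#> <ecg_eval> 40 probes vs 120 enrolled beats (10 subjects, fusion 'sum')
#>   accuracy 100.00%  EER 0.00%  AUC 1.0000

generics::glance(report$model)
#> # A tibble: 1 x 5
#>       r     n     c iterations objective
#>   <int> <int> <int>      <int>     <dbl>
#> 1    16   240    10          5     5837.
```

The pipeline generated 400 synthetic beats, split them 60/30/10 per subject
into train/enroll/probe, fitted the factorization on the 240 training beats
(converging in 5 iterations), and identified all 40 probe beats correctly;
the verification sweep separated genuine from impostor claims perfectly at
this seed. `plot_objective(report$model)`, `plot_roc(report)` and
`plot_far_frr(report)` visualize the fit and the operating curves, and
`generics::tidy(report$model)` returns the objective trace as a tibble.

Lower-level entry points mirror the pipeline stages: `detect_r_peaks()` /
`segment_beats()` for Pan–Tompkins segmentation of continuous records,
`extract_features()` for the dual-level features, `cmf_fit()` for the
learner, and `evaluate_model()` for matching. A thin command-line wrapper
with `synth`, `synth-record`, `segment` and `run` verbs is installed at
`inst/cli/ecgcmf.R`.

Ablations are configuration flags: `features = "1d"` / `"2d"` (single-level
embedding), `attention = FALSE`, `projection = FALSE`.

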