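---
title: "The evolutionary hybrid ECG classifier: model, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The evolutionary hybrid ECG classifier: model, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecgkelm)
```

`ecgkelm` implements a complete arrhythmia-classification pipeline for
fixed-length ECG fragments. This vignette explains the statistical model,
the parameters that matter, what the synthetic-data generator does and does
not emulate, and the numerical and design decisions baked into the code.

## The classification model

A sample is a 1-D amplitude sequence (a beat fragment, or in the parametric
variant a vector of ECG measurements). Classification runs in three stages.

**Cumulant features.** After centring the signal, the package computes the
diagonal slices of its 2nd-, 3rd- and 4th-order cumulants over a symmetric
lag range $\varepsilon \in [-m_l, m_l]$:

$$K_2(\varepsilon) = n_2(\varepsilon), \qquad
  K_3(\varepsilon,\varepsilon) = n_3(\varepsilon,\varepsilon), \qquad
  K_4(\varepsilon,\varepsilon,\varepsilon) =
    n_4(\varepsilon,\varepsilon,\varepsilon) - 3\,n_2(\varepsilon)\,n_2(0),$$

with $n_k$ the biased (divide by $N$) lagged sample moments of the centred
signal, summed over valid overlapping indices only. These capture lagged
autocovariance, skewness structure and kurtosis structure — the asymmetry
and peakedness signatures that differ between beat morphologies. The three
slices are concatenated, so the feature vector has $3(2 m_l + 1)$ entries;
$m_l = 450$ gives 2703 features, $m_l = 25$ gives 153.

Centring before estimation makes every entry exactly invariant to mean
shifts and exactly scale-equivariant (an order-$k$ entry scales as $a^k$),
both of which the test suite asserts. The diagonal slice (equal lags) is the
standard 1-D reduction of the 2-D/3-D cumulants in higher-order-statistics
feature work; it is what makes the per-order length $2 m_l + 1$.

**Kernel extreme learning machine.** With training kernel matrix
$\chi_{jk} = \psi(x_j, x_k)$ and one-hot class indicators $\Gamma$ (1 for
the true class, 0 otherwise), training solves the single regularised linear
system

$$\left(\frac{I}{C_R} + \chi\right) M = \Gamma,$$

and a new sample $y$ scores $[\psi(y, x_1), \dots, \psi(y, x_W)]\,M$, taking
the class of the maximum score (ties go to the lowest class index —
deterministic and logged in the design). Five kernels are provided (RBF,
polynomial, Laplacian, sigmoid, wavelet); the pipeline tunes the RBF
parameter $P_K$ in $\psi(x,y) = \exp(-P_K\|x-y\|^2)$.

**Genetic tuning.** The triple $(m_l, C_R, P_K)$ is optimised by a GA with
tournament selection (size 3), uniform crossover (each gene independently
swapped with probability 1/2), random-reset mutation, and one elite
survivor. Fitness is the classification error rate. The run stops at the
generation cap or when the generation's best fitness equals its mean within
a tolerance — a converged, homogeneous population.

## Parameters that matter

| parameter | meaning | default | why |
|---|---|---|---|
| `m_l` | maximum cumulant lag (samples) | GA-tuned, bounds `[1, (n-1)/2]` | controls feature length $3(2m_l+1)$; clamped to the data with a warning |
| `c_r` | KELM regularisation coefficient | GA-tuned, bounds `[-100, 200]` | identity shrinkage in the solve; negative values are accepted (published optima include them) but may make the system singular, which surfaces as a solver-failure error rather than silent re-regularisation |
| `p_k` | RBF width (1/amplitude² units) | GA-tuned, bounds `(0, 10]` | upper bound configurable upward; published optima span 8e-5 to ~484 |
| `wavelet`, `level` | denoising basis and depth | `db6`, 10 | the db6 shape tracks the QRS complex; the level is reduced to `floor(log2(n / (filter_len - 1)))` when the fragment is too short (188-sample rows support level 4) |
| `drop_details` | detail bands zeroed | `1, 2` | the two finest bands carry muscle/electrode noise |
| `drop_approximation` | zero the final approximation | `TRUE` | the lowest band carries drift; for short signals this is the approximation at the effective level |
| `baseline_window_sec` | moving-average window | 0.75 s | spans one period of the slowest respiration-band wander (0.15–0.8 Hz) |
| `notch_frequency` | powerline notch | 60 Hz | second-order zero-phase band-stop; skipped when the sampling rate cannot represent it |
| `train_fraction` | split | 0.7 | test size is `round(n (1 - f))`, apportioned across classes by largest remainder — the only rounding scheme consistent with 1003-row splits of 301 (30%) and 50 (5%) test rows |

## The synthetic generator

`beat_template()` + `synth_dataset()` emulate what the pipeline needs from
real recordings: multi-class P-QRS-T morphology (five Gaussian bumps at
fixed phase fractions, periodic at the beat rate), additive baseline wander
(a sinusoid constrained to 0.15–0.8 Hz), 60 Hz powerline interference,
wideband Gaussian noise, and strong class imbalance (e.g. 283:10). Per-row
noise seeds derive from the master seed by a fixed counter (`seed + row
index`), so any subset regenerates identically regardless of order.

A Gaussian-bump model was chosen over a dynamical-system ECG simulator
because it is the simplest shape with the P-QRS-T structure needed to give
classes controllably different morphologies; it is sufficient for testing
every pipeline stage. It does **not** reproduce beat-to-beat variability,
heart-rate dynamics, ectopic timing, recording artefacts beyond the three
noise sources, or realistic spectral content. Passing tests on this
generator therefore demonstrate the *software* contracts (shapes, counts,
determinism, estimator correctness, optimiser behaviour) and that the method
separates controllably distinct morphologies — not clinical-grade accuracy
on real arrhythmia recordings.

## Numerical choices

- **Wavelet transform**: an orthonormal filter bank with circular extension;
  synthesis is the transpose of the orthogonal analysis operator, so perfect
  reconstruction is exact to machine precision (tested at 1e-8). Odd lengths
  are handled by repeating one end sample before a level and truncating
  after synthesis, preserving exactness at every length.
- **Cumulant estimators**: biased ($1/N$) with valid-index windows, no zero
  padding. Exactness of scale equivariance is the payoff; the cost is an
  $O(1/n)$ edge term at nonzero lags (a whole-period sinusoid's third-order
  slice is exactly zero at lag 0 but decays as $1/n$ elsewhere, which the
  tests assert as such). Negative lags are computed directly except the
  second order, where evenness is exact.
- **KELM solve**: a factorised linear solve (`solve(A, G)`), not an explicit
  inverse; one-hot 1/0 coding (the coding does not change the arg-max for
  this linear solve, and 1/0 keeps test expectations simple).
- **Imputation**: a missing cell in a class-$c$ row is replaced by the
  population standard deviation (divide by $N$) of all non-missing attribute
  values pooled over class $c$; the population convention is stated because
  either could be defended. A class with no observed values is an explicit
  imputation-failure error.
- **GA**: fitness values are memoised per chromosome; a fitness that errors
  or returns a non-finite value scores as worst and the run continues.
  Chromosome bounds are enforced at initialisation, crossover and mutation.
- **Degenerate inputs**: constant signals normalise to all zeros; `m_l = 0`
  yields the three lag-0 statistics; balanced inputs pass through all three
  resamplers unchanged (up to row order).

## Design decisions that were genuinely open

- **IRST target count**: the importance-resampling literature does not fix
  the per-class target; `ceil(n / n_classes)` is adopted because it exactly
  reproduces all published balanced-database sizes this package checks
  (59/class from 1000 rows over 17 classes; 35/class from 452 over 13;
  7276/class from 14,552 over 2). Importance weights default to uniform with
  an optional per-row vector, since no weighting formula is published.
- **Fitness fold**: tuning hyperparameters against the final test fold leaks
  information. The default (`leakage_mode = "validation"`) carves an inner
  validation fold from the training rows; `leakage_mode = "paper"` scores
  candidates on the test fold to mirror the protocol that produced the
  published error tables, and the report flags which fold drove the GA.
  Likewise balancing-before-splitting (the published order) can duplicate
  oversampled rows across folds; `balance_after_split = TRUE` gives the
  leak-free variant.
- **Selection scheme**: tournament selection (size 3) among the many listed
  options, for simple seeding and controllable selection pressure.
- **Parametric rows** (attribute vectors rather than time series) skip
  denoising/baseline/normalisation and receive only imputation — set
  `preprocess = FALSE` in `run_pipeline()`.

## Problem sizes

The test suite and examples run on scaled-down problems chosen to exercise
every code path while keeping the suite fast: 2 s fragments at 100 Hz,
50–100 rows, GA populations of 8 over ≤ 5 generations for end-to-end runs;
Monte-Carlo checks use $10^5$ draws; brute-force oracle comparisons use
vectors of ≤ 30 samples where the $O(n\,m_l)$ direct sums are instant.
Published-scale inputs (3600-sample fragments, $m_l = 450$) are used where
only arithmetic is being verified (feature sizing, resampling totals, split
counts).

## Known limitations

- The generator's beats are strictly periodic and identically shaped within
  a class; classifiers can exploit regularities absent from real ECG.
- Only the diagonal cumulant slices are implemented; full bispectrum /
  trispectrum surfaces are out of scope.
- The explicit random-hidden-layer ELM is not implemented — only the
  kernelised form.
- `ga_optimize()` evaluates fitness serially; large populations on large
  kernel matrices are the dominant cost.
- The wavelet-kernel mother function is fixed to the Morlet-style
  $\cos(1.75u)\,e^{-u^2/2}$.
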