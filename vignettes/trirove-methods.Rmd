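---
title: "Cross-modally conditioned roving sequences and their fMRI analysis: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-modally conditioned roving sequences and their fMRI analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trirove)
```

## The stimulus model

`trirove` simulates and analyses a tri-modal roving-oddball experiment:
auditory (A), somatosensory (S) and visual (V) stimuli are presented
simultaneously on every trial, each at one of two intensities (low/high).
The joint intensity pattern is a state $s_t \in \{0,\dots,7\}$, encoded as
$s = 4\,o_A + 2\,o_S + o_V$ with $o_m \in \{0,1\}$. The sequence evolves as
a first-order Markov chain $p(s_t \mid s_{t-1})$ in which **at most one
modality changes per trial**: entries for transitions differing in two or
three modalities are exactly zero.

The probability that modality $m$ changes depends on the *cross-modal
context*: whether the other two modalities were congruent (both low or both
high) or incongruent on the previous trial. The three condition settings
are

| condition | $p(\text{change}\mid\text{congruent})$ | $p(\text{change}\mid\text{incongruent})$ |
|---|---|---|
| C1 | 0.150 | 0.025 |
| C2 | 0.025 | 0.150 |
| C3 | 0.0875 | 0.0875 |

with the diagonal (tri-modal repetition) absorbing the remaining mass.
Because a single-bit flip leaves the flipping modality's context unchanged,
the matrix is symmetric, hence doubly stochastic, and its stationary
distribution is uniform over the eight states; each modality's implied
marginal change probability is $(p_{cc} + p_{ci})/2 = 0.0875$ and the
high-intensity probability is $1/2$.

A note on marginals: descriptions of this family of designs sometimes quote
a per-trial repetition probability of .825 (change .175) and a mean train
length of about 5. Those numbers are not consistent with the conditional
entries above, which imply a marginal change probability of 0.0875 and a
mean train length near 10 under the uniform stationary distribution. The
package follows the conditional entries — they are what the transition
matrix is built from — and does not hard-code the other figures anywhere.

## Sampling, the minimum-repetition rule, and validation

`sample_run()` draws 400-trial sequences. A *minimum of one repetition*
between deviants of the same modality is enforced during sampling: a
proposed transition that would change a modality which changed on the
immediately preceding transition is rejected and redrawn. This is the
minimal reading that guarantees every binned deviant has train length
$\ge 1$; rejection operates per proposed transition (trials are redrawn,
whole sequences are not discarded).

### Why change statistics exclude forced repetitions

The rejection rule makes a change *impossible* on roughly 8% of
(modality, transition) slots. Counting those slots in the empirical
conditional change probabilities biases them about 11% below the
generative values (e.g. 0.133 instead of 0.150 for C1/congruent) — far
outside the ±0.005 validation band, which would make validation
unsatisfiable. `compute_stats()` therefore excludes constraint-forced
repetitions from the change statistics by default (`exclude_forced =
TRUE`); the literal all-transitions count remains available. Intensity
balance always uses all trials.

### Why validation pools across modalities

`validate_stats()` accepts a run when the pooled-across-modalities
statistics are within ±0.005 (conditional change probabilities) and ±0.025
(overall change probability against the matrix-implied 0.0875, and
high-intensity proportion against 0.5) of nominal. We measured the
per-modality variant (each of the three modalities checked separately,
available via `tolerance_spec(per_modality = TRUE)`): with ~200
context-specific transitions per modality in a 400-trial run, the joint
acceptance probability is of the order $10^{-6}$–$10^{-8}$, i.e. millions
of draws per accepted run — unusable, and incompatible with any plausible
generation procedure for this design. Pooled validation accepts roughly one
in 20–25 draws and concentrates the pooled empirical probabilities on the
nominal values, which is exactly the property the downstream analyses rely
on. The alternative ±0.005 reading — deviation of the congruent-minus-
incongruent *difference* from its nominal — is implemented behind
`tolerance_spec(use_difference = TRUE)`.

Catch trials (6 per run, <1% of trials) are placed uniformly at random
over trials 2..400 and balanced 2/2/2 over the three modalities; the
balance is this package's choice, as is the exclusion of trial 1 (a "most
recent stimulus" must exist).

## Trial annotation

Per trial and modality: *role* (first/standard/deviant, deviance =
intensity change from the previous trial), *train length* (number of
standard repetitions since the previous deviant; the run-initial trial
counts as neither), *train bin* (1, 2, 3, 4–5, 6–8, >8), and
*predictability*. A realized transition is **predicted** when its
conditional probability under the actual context exceeds its probability
under the opposite context, **mispredicted** when lower, **unpredictable**
when equal (all of C3). The within-context comparison (change vs repetition
under the same context) was rejected because it reproduces the
deviant/standard factor exactly and would be collinear with the mismatch
regressor. Deviants closing the run's first train have no preceding deviant;
they are binned from the run start and flagged `first_train`, with an
exclusion switch. Predictability is coded on all trials by default
(modulators: mispredicted +1, predicted −1, unpredictable 0); a
deviants-only option exists because the original analyses do not say which
was used.

## Synthetic BOLD

Region-level time series stand in for the study's unavailable fMRI data:
6 runs × 475 volumes at TR 1.5 s, trials at ISI 1.75 s, both multiples of
the 0.05 s microtime grid. Every region has a neural impulse per trial
whose height is linear in the ground-truth amplitudes (baseline, intensity,
mismatch, train-length slope on the centered bin index, misprediction),
convolved with a canonical double-gamma HRF (mode 5 s, undershoot minimum
near 15–16 s, peak normalized to 1) and sampled at the volume times. Noise
is AR(1) (default $\rho = 0.3$, innovation sd 1) plus random polynomial
drift (order 2, coefficient sd 0.5). The default 20-region map contains
bilateral sensory mismatch regions, four shared fronto-parietal regions, an
IPS-like misprediction region, three PPI targets and six null regions.

Default amplitudes (baseline 1, intensity 0.8, mismatch 1.0, train slope
0.2/bin, misprediction 0.6, PPI coupling 0.8 base / 0.6 mismatch-modulated)
were fixed once to give per-subject contrast t-values in the 5–15 range
typical of strong region-of-interest effects; they are the package's
"default SNR" world and are not tuned against test outcomes.

PPI ground truth is injected at the **neural** level — the target receives
`base * seed_neural + mod * (seed_neural × mismatch-code)` before
convolution — so that BOLD-level estimators recover it only approximately,
mirroring the known deconvolution problem. Two limitations follow. First,
the generator's seed neural signal is noiseless (deterministic given the
events); if the seed carried only a mismatch effect, the injected
interaction would be event-locked and fully spanned by the task
regressors, making the coupling unidentifiable. Identification rests on
seed variance beyond the psychological code (in the defaults, the seed's
intensity effect); real seeds additionally have endogenous fluctuations.
Second, no spatial structure, physiological noise or motion is simulated —
green tests establish statistical correctness of the estimators under this
generative model, not robustness to real-data artifacts. Motion parameters
can be supplied as nuisance regressors but are never generated.

## GLM analyses

Two first-level designs, runs concatenated with per-run intercept and
polynomial drift blocks:

* **modulator**: one all-trials onset regressor plus nine parametric
  modulators (intensity, mismatch, predictability × A/S/V), coded ±1,
  mean-centered and *not* serially orthogonalized. Centering uses the grand
  mean over all runs: the removed component is then exactly spanned by the
  single onset regressor, which keeps noiseless recovery exact; per-run
  centering would leak run-mean differences into the modulators. An
  all-zero modulator (predictability in a C3-only session) is dropped with
  a warning, or errors under `drop_degenerate = FALSE`.
* **trainbins**: eighteen deviant regressors (six train-length bins × three
  modalities) plus one regressor for every remaining trial.

Fitting is OLS with optional (default) AR(1) prewhitening using one pooled
lag-1 coefficient estimated from the OLS residuals. Contrasts are
$c^\top\beta$ with $t = c^\top\beta / \sqrt{\hat\sigma^2\, c^\top (X^\top
X)^{-1} c}$. The train-length contrast uses the centered ramp
$(1{:}6) - 3.5$ (the analysis it mirrors does not state its weights); a
missing bin re-centers the remaining weights with a warning. Second-level
inference is a one-sample t across subjects (with a repeated-measures
reduction over the modality factor), replacing the original flexible-
factorial ANOVA. Conjunction against the global null is the
minimum-statistic test: statistic $\min_k t_k$, p-value
$[P(T_{df} > \min_k t_k)]^k$ under independence, with a sign-flip
permutation alternative for dependent components. Note the global-null p
can be *smaller* than each component p — that is what makes the test more
sensitive than the conjunction-null (max-p) test. Family-wise error across
regions uses Bonferroni or sign-flip max-statistic permutation;
random-field theory is deliberately out of scope at region level.

## PPI

For a seed region and modality, the psychological regressor is the ±1
deviant/standard code convolved to the volume grid; the physiological
regressor is the centered seed series; the interaction is formed either as
the BOLD-level product or (default, closer to SPM's implementation) at the
neural level: the seed is deconvolved through the HRF by ridge regression
with the penalty chosen by generalized cross-validation, multiplied by the
trial-level psychological impulses, and re-convolved. The deconvolution is
solved at TR resolution in observation space
($\hat x = C^\top (CC^\top + \lambda I)^{-1} y$, eigendecomposition cached),
then linearly interpolated to microtime for the product. The first-level
PPI model contains the interaction, the seed signal, and all task
regressors of the modulator design.

## Numerical choices and degenerate inputs

* Stationary distributions come from the left unit eigenvector, checked to
  1e-10; a reducible chain (multiple unit eigenvalues) errors unless
  non-uniqueness is explicitly allowed.
* Row sums of transition matrices are exact to 1e-12; multi-modality-change
  entries are exact zeros, not small numbers.
* `sample_valid_run()` caps attempts (default 10,000) and errors with the
  best-so-far validation report.
* Zero residual variance flags the contrast as degenerate rather than
  producing spurious p-values; identical second-level estimates yield an
  infinite t flagged the same way.
* Empty context cells in sequence statistics are NaN, never 0.

## What the acceptance machinery establishes

`reproduce_targets()` and `scripts/acceptance.R` regenerate ≥200 validated
runs per condition and check the pooled empirical probabilities against the
generative values (conditionals, repetition complements, intensity
balance). The test suite additionally verifies oracle equivalences
(eigenvector vs power iteration, OLS vs closed form, HRF mode), exact
noiseless recovery of all injected amplitudes, estimator bias and power at
the default SNR, and type-I control at null regions for first-level,
group, conjunction and PPI tests. Replicated simulations fix the designs
and redraw only noise between replicates; this conditions the Monte-Carlo
statements on one realized set of sequences, which is standard for
estimator calibration but does not average over sequence realizations.
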