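---
title: "Methods: estimating and explaining multi-timescale structure in spiking activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: estimating and explaining multi-timescale structure in spiking activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurotau)
```

`neurotau` estimates how long the spiking activity of single neurons
stays correlated with itself — its intrinsic timescales — and provides
the statistical and theoretical machinery to ask three questions about
a population of such estimates: do the slow timescales follow a power
law; do timescales relate to what a neuron encodes during behavior; and
what kind of recurrent network produces a power-law distribution of
timescales in the first place. This vignette documents the models, the
tunable parameters, the numerical choices, and what the synthetic data
do and do not emulate.

## Timescale estimation from spike counts

Spikes are counted in bins of width $\Delta t = 5$ ms over a
recording of duration $T$ (default 600 s of spontaneous activity). The
autocorrelogram uses a lag-dependent pair of windowed means rather than
a single global mean: at lag $j$,

$$AC(t_j) = \frac{1}{\hat\sigma^2\,(N-j)} \sum_{i=1}^{N-j}
  \bigl(A_i - \hat\mu_1(j)\bigr)\bigl(A_{i+j} - \hat\mu_2(j)\bigr),$$

with $\hat\mu_1(j)$, $\hat\mu_2(j)$ the means of the leading and
trailing windows and $\hat\sigma^2$ the unbiased sample variance of the
full series. This normalization gives the exact identity
$AC(0) = (N-1)/N$, which the test suite uses as an algebraic anchor,
and the whole estimator is checked against a literal double-loop
evaluation. Cross-products are computed by FFT, so long recordings cost
$O(N\log N)$.

The autocorrelation between lag zero and lag one drops by the Poisson
(irregularity) variance, which carries no information about the
underlying rate dynamics, so fitting never includes lag zero. Some
neurons additionally show refractory-like dips over the first few lags;
the fit starts at the *argmax* of the autocorrelation over the first 20
lags (100 ms), so monotonically decaying neurons start at lag one and
refractory neurons start where decay actually begins. The argmax rule is one concrete operationalization of “the lag
where decay begins”; the horizon is configurable.

The decay is modeled as a mixture of $M \in \{1,\dots,4\}$
exponentials, $AC(t) = \sum_i c_i e^{-t/\tau_i}$, fitted by unweighted
nonlinear least squares in linear AC space over lags up to 5 s
(log-space fitting is not possible because the AC estimate can be
negative at long lags). Fitting uses Levenberg–Marquardt with box
constraints and ten multi-start initializations (timescales log-spaced
between $\Delta t$ and the fitted window, coefficients uniform on the
simplex). Model order is selected by the least-squares BIC,
$n\ln(\mathrm{RSS}/n) + 2M\ln n$, with ties broken toward fewer
components, and a selected model is demoted whenever any component
contributes less than 1% of $\sum_i c_i$ — a complexity guard that
keeps only timescales with a material contribution. A fit qualifies for
population analyses when $R^2 > 0.5$; a single-exponential pathway (no
QC, fit from lag one) is available for comparability with the
conventional single-timescale method.

**Identifiability bound.** Timescales are constrained to
$[\Delta t, 5\,\mathrm{s}]$ — the fitted lag window — rather than to
the recording duration. A decay constant longer than the window is not
identifiable from it: leaving the bound at the duration lets noise
drive such fits toward arbitrarily slow values, which visibly inflates
the slow tail of population estimates (in our end-to-end simulations it
biases the fitted tail exponent of a planted $\gamma = 2$ population
down to roughly 1.6). With the bound at the window the planted exponent
is recovered. Estimates at the bound should be read as "at least this
slow".

The effective timescale summarises a mixture as
$\tau_\mathrm{eff} = \sum_i c_i\tau_i / \sum_i c_i$; it is the decay
constant of the single exponential with the same area as the fitted
mixture, is invariant to rescaling the coefficients, and is the
quantity all population analyses use.

## Power-law tails

Power-law scaling is only expected above a lower cutoff. The fit
follows the standard continuous maximum-likelihood recipe: for every
candidate cutoff $\theta$ (the ascending order statistics, optionally
decimated), the exponent has the closed form
$\hat\gamma = 1 + N_\theta\,[\sum \ln(x_i/\theta)]^{-1}$, and the
cutoff minimizing the Kolmogorov–Smirnov distance between the empirical
tail and the fitted truncated power law is kept. No upper cutoff is
imposed. Goodness of fit is a parametric bootstrap: synthetic datasets
of $N_\theta$ points from the fitted tail are refitted identically and
the p-value is the fraction whose KS distance reaches the observed one,
with the conventional conservative acceptance threshold of 0.1.

Alternatives are compared on the same tail by likelihood ratios:
$R_0 = \ln L_\mathrm{PL} - \ln L_\mathrm{alt}$, normalized as
$R = R_0 / (\sqrt{N}\,\sigma_{R_0})$ where $\sigma_{R_0}$ is the
standard deviation of the pointwise log-likelihood differences, with a
two-sided normal test (the threshold, 0.05, is a package choice; the
normalized-LLR method itself does not prescribe one). The exponential alternative
has a closed-form MLE on the tail; the truncated log-normal does not,
and its likelihood surface is nearly flat along a ridge where
$\mu \to -\infty$ with growing $\sigma$ — the regime in which a
log-normal shadows a power law. The optimizer therefore multi-starts
from several points along that ridge; without the deep-$\mu$ starts the
log-normal likelihood is systematically underestimated and the LLR is
biased toward the power law. A control simulation
(`llr_control_simulation`) reproduces the expected behavior under a
true power law: the normalized LLR against the log-normal is small,
more often negative than positive, and significant only in rare cases.

When pooling groups with different cutoffs, the maximum group cutoff is
used so the pooled tail is power-law-consistent within every group.
`cutoff_percentile` reports where a cutoff sits within a sample and
splits it into fast and slow subsets.

## Task-variable selectivity

Selectivity of a neuron to stimulus side, choice, or reward is the
condition-combined Mann–Whitney statistic: trials are stratified by the
two variables *not* under test (contrast is deliberately not a
conditioning variable), ranks are computed within each stratum (average
ranks for ties, the standard Mann–Whitney convention), and

$$U_j = \min\!\Bigl(R_1 - \tfrac{n_1(n_1+1)}{2},\;
                    R_2 - \tfrac{n_2(n_2+1)}{2}\Bigr), \qquad
  P = \frac{\sum_j U_j}{\sum_j n_{1,j}n_{2,j}},$$

with strata lacking either value excluded from both sums. $P$ lies in
$[0, \tfrac12]$ and *small* values indicate separation. The null is a
permutation distribution in which the tested variable's labels are
shuffled only within cells defined by block identity crossed with the
held-fixed variables: because the stimulus-side prior switches in
blocks, slow rate drifts correlate with the task variables over the
session, and an unrestricted shuffle would convert that drift into
false selectivity. The within-cell shuffle preserves each block's label
counts exactly, which is the property the type-I calibration test
checks under planted block-correlated drift.

One directionality note: since small $P$ is the extreme direction of
the min-form statistic, the p-value counts the permutations *more
extreme* than the data, i.e. the fraction with
$P_\mathrm{perm} < P_\mathrm{obs}$ (strict, no add-one smoothing);
counting the larger-$P$ permutations instead would invert the test and
assign p ≈ 1 to strongly selective neurons. Windows default to
[0, 100] ms from stimulus onset, [−100, 0] ms from first movement, and
[0, 200] ms from feedback (two conventions for the feedback window are in
circulation — [0, 200] ms from feedback and [0, 150] ms from movement —
the former is the default and both are configurable). Downstream, selective and non-selective neurons are
compared on $\tau_\mathrm{eff}$ by two-sided Wilcoxon rank-sum tests
with Benjamini–Hochberg correction across brain structures (FDR 0.01).

## Anatomy regression

Per-neuron timescales are regressed on the anatomical features of the
200 µm voxel containing the neuron; all neurons in a voxel share a
predictor row. Features are optionally reduced to the principal
components reaching 95% cumulative variance. The regression is ridge
with the intercept unpenalized, solved by the penalized normal
equations on centered data; the penalty is chosen by 5-fold
cross-validation over a log grid when not supplied. Two deliberate
package choices: the regression target is
$\log_{10}\tau_\mathrm{eff}$ (timescales are heavy-tailed, so raw-scale
least squares would be dominated by the few slowest neurons;
configurable to raw), and both in-sample and cross-validated $R^2$ are
reported, with the cross-validated one treated as the headline.

The spatial null is phase randomization: each feature field is Fourier
transformed in 3-D, every coefficient's phase is replaced by a random
one while amplitudes are kept, and the field is inverted. Hermitian
symmetry is obtained by construction — the random phases are taken from
the FFT of a real white-noise field — so the surrogate is exactly real,
and the DC coefficient is preserved so means are unchanged. Surrogates
therefore have identical power spectra (hence identical spatial
autocovariance) but no relationship to the timescale map; the
surrogate p-value is the fraction of surrogate fits whose in-sample
$R^2$ reaches the observed one, with the penalty fixed at the original
fit's value so all fits have equal flexibility. Unique explained
variance of one feature is the drop in $R^2$ after permuting that
feature's values across voxels; duplicated features correctly show
near-zero unique contribution.

## Linear networks: why timescales can follow a power law

An Ornstein–Uhlenbeck network $\tau_\mathrm{syn}\dot x = -Mx + \eta$
with effective connectivity $M = I - gW$ has lagged correlations given
by a double sum over eigenmodes,

$$C(t) = D \sum_{p,q} \frac{u_q^\top u_p}{\lambda_p + \lambda_q}
  v_p v_q^\top e^{-\lambda_p t},$$

so each unit's autocorrelation is a mixture of decays at the inverse
eigenvalues $1/\lambda_p$. The implementation is validated against the
Lyapunov-equation solution and against Euler–Maruyama simulation. If
the eigenvalue density behaves as $f(\lambda)\propto\lambda^\zeta$ near
zero, the reciprocal change of variables
$g(\tau) = f(1/\tau)/\tau^2$ makes slow timescales power-law with
exponent $\gamma = 2+\zeta$: uniform spectra give $\gamma = 2$ over the
whole range, the semicircle gives $\zeta = \tfrac12$, $\gamma = 2.5$
above $\tau \approx 1/(2R)$, and a gamma-distributed spectrum with
shape $\alpha$ gives $\gamma = \alpha+1$ above $\tau \approx 1/\ln 2$.

“Edge of instability” is implemented as a one-parameter support shift:
eigenvalues are shifted so the lower support edge sits at $\epsilon$
(default $10^{-4}$), which caps the slowest timescale at
$\tau_\mathrm{syn}/\epsilon$. Tuning the gain is the equivalent
physiological control — it moves
$\lambda_{\min} = 1 - g\lambda_{W,\max}$ — and a multiplicative variant
of the shift is available. Raising $\epsilon$ collapses the power law from above;
$\tau_\mathrm{syn}$ rescales every timescale (and the cutoff and
median) without touching the exponent — both directions are asserted in
the tests, the latter exactly for inverse-eigenvalue sampling.

Timescale distributions are computed from inverse eigenvalues by
default; the SDE simulation exists for validation. One nuance found
during validation: the claim that *fitted single-unit* timescales
reproduce the inverse-eigenvalue distribution holds when eigenmodes are
unit-localized (e.g. a diagonal or weakly mixed $M$). With a dense
random orthogonal eigenbasis every unit's autocorrelation mixes all
modes with similar weights, fitted single-exponential summaries
concentrate, and the correspondence fails. The validation test
therefore uses localized modes, and inverse-eigenvalue sampling should
be preferred over per-unit refitting whenever eigenvectors are
delocalized.

## Nonlinear networks with heavy-tailed connectivity

The rate network $\tau_\mathrm{syn}\dot x_i = -x_i + g\sum_j J_{ij}
\tanh x_j$ with i.i.d. symmetric $\alpha$-stable weights (tail exponent
$1+\alpha$, sampled by the Chambers–Mallows–Stuck construction; no
installed package provides stable RNG) is integrated by Euler steps of
$0.1\,\tau_\mathrm{syn}$ for 14,400 steps. The connectivity scale
defaults to $N^{-1/\alpha}$, the convention under which recurrent input
stays $O(1)$ as $N$ grows; the literal $1/N$ is available (for fixed
$N$ the two differ only by an effective gain). Chaos is verified
empirically — a repetition whose activity variance collapses is counted
and skipped, not assumed chaotic from $g$ alone, because with
heavy-tailed weights the effective spectral radius varies markedly
between realizations at moderate $N$.

Two numerical findings shaped the defaults:

* **Burn-in 30%.** In the chaotic regime the slowest units have
  timescales up to roughly a tenth of the simulated span. With a 10%
  burn-in their initial transients survive into the analyzed traces and
  inflate the slow tail, dragging the fitted pooled exponent well below
  the connectivity prediction $1+\alpha$; with 30% discarded the
  exponent plateaus at the predicted value.
* **Control scale.** The Gaussian ($\alpha = 2$) control is only a
  clean negative control when $N$ is large enough that realization-to-
  realization variability of the spectral radius no longer fattens the
  pooled distribution; the control suite runs at $N = 400$.

Each unit's timescale is a single-exponential fit to its activity
autocorrelation (FFT-based, fit window adapted to ten times the $1/e$
crossing); near-constant units are excluded with a reported count.
Repetitions with fresh connectivity and initial conditions are pooled
before tail fitting. At the reduced scales used in testing
($N = 250$–$400$, 10–20 repetitions vs. 1,000 units and 100 repetitions
at full scale), the pooled KS-cutoff exponent approximates
$1+\alpha$ and is insensitive to $g$, while $\tau_\mathrm{syn}$ moves
the median; the extreme tail steepens from finite-size truncation, so
reduced-scale exponents carry a few-hundredths downward bias relative
to the asymptotic prediction.

## Synthetic data: what it emulates, and what it does not

* `gen_multiscale_spike_train` builds a doubly stochastic Poisson
  train whose rate is a base rate plus independent OU modulators; the
  count autocorrelation beyond lag zero is then a mixture of
  exponentials at the planted timescales with weights $\propto a_i^2$
  (for modulator timescales well above the bin width). Rates are
  rectified at zero; keeping $\sum_i a_i \le 0.5\,r_0$ keeps the
  rectified fraction near 2% and the mixture approximation accurate,
  and the generator warns beyond 20%. The two-timescale benchmark used
  in tests plants $\tau = (0.05, 0.5)$ s at base rate 30 Hz with
  per-component modulation 0.35 $r_0$ — conditions chosen by a power
  analysis of the estimator (signal-to-noise of the autocorrelogram
  scales as $a^2/r_0$) before the recovery thresholds were frozen.
* `gen_population` plants one timescale per neuron from a power law
  (default base rate 20 Hz), providing ground truth for end-to-end
  exponent recovery.
* `gen_trial_table` reproduces the task's block structure (20–100
  trial blocks, 80/20 stimulus-side priors, the five contrast levels).
  Reward is deterministic given the correctness of the reported side.
  The recorded `choice` is the *first wheel movement*, which matches
  the report with probability 0.9: if choice and reward were both
  deterministic functions of the stimulus and report, the stimulus
  would be exactly collinear with (choice, reward) and the stratified
  stimulus test would have no usable strata — the inconsistency between
  first movement and final report is what makes the three-variable
  design testable, in the generator as in the real task.
* `gen_voxel_world` synthesizes smooth Gaussian random fields
  (spectral amplitude $(1+|k|^2)^{-s/2}$) and plants a linear map from
  features to $\log_{10}\tau$ with known signal fraction.

None of these emulate refractory periods, bursting, oscillations,
non-Poisson dispersion, session/lab structure, or realistic anatomical
covariance between features; passing tests demonstrate correctness of
the estimators under their stated generative assumptions, not
robustness to every property of real recordings.

## Problem sizes and runtime choices

Test and acceptance runs use deliberately desk-scale sizes: 10-minute
recordings for single-neuron recovery (50 seeds), two replicate
350-neuron populations for end-to-end exponent recovery, $10^3$
eigenvalues per linear-network fit (10 seeds), nonlinear networks of
150 units with 40 pooled repetitions, replicated twice per gain (plus
single-realization Gaussian controls at $N = 400$), 1,000 datasets of
1,000 samples for the LLR
control (with the candidate cutoff grid decimated tenfold, documented
as an approximation), 500 permutation-test replicates for type-I
calibration, and 40–100 spatial surrogates per surrogate test.
Stochastic end-points are averaged over replicate experiments because
at these scales single-run estimates of tail exponents scatter with a
standard deviation comparable to the tolerances being checked.

## Known limitations

* The argmax fit-start rule can select a noise-displaced early lag for
  nearly flat autocorrelograms; this mostly affects neurons whose
  modulation is weak relative to their Poisson noise, which tend to
  fail QC anyway.
* Timescales at the 5 s identifiability bound are censored, not
  estimated; population tail fits treat them as observed values.
* The normalized-LLR significance rule assumes approximate normality
  of the pointwise log-likelihood differences; for very small tails
  ($N_\theta$ in the tens) the normal approximation is rough.
* Phase randomization assumes (circular) stationarity of the feature
  fields; strongly nonstationary anatomical maps violate the surrogate
  exchangeability it provides.
* The nonlinear-network exponent comparison is asymptotic in $N$ and
  the pooled sample size; reduced-scale runs carry a small downward
  bias and a bistable cutoff choice between the distribution body and
  tail, which is why acceptance checks fit the slow half of the pooled
  distribution.
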