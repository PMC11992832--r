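---
title: "Implicit probabilistic learning in the ASRT task: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Implicit probabilistic learning in the ASRT task: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asrtlearn)
```

## The task and its probability structure

The Alternating Serial Reaction Time (ASRT) task presents a stimulus in one
of four screen positions, and the participant presses the matching key. The
stream follows an eight-element sequence that alternates a fixed pattern
permutation with uniformly random elements, e.g. `2 - r - 4 - r - 3 - r -
1 - r`. Because the random elements intervene, the regularity is a
*second-order non-adjacent dependency*: the position at trial $n-2$ predicts
the position at trial $n$.

Every trial from the third one of a block is the final element of a
*triplet* (the positions at $n-2$, $n-1$, $n$). A triplet is
*high-probability* when its third position is the cyclic successor of its
first under the pattern; otherwise it is *low-probability*. Since roles
alternate, a trial and the trial two back share a role, which gives the
exact budget computed by `expected_triplet_probabilities()`:

```{r budget}
expected_triplet_probabilities(asrt_pattern(c(2, 4, 3, 1)))
```

Pattern-ending trials complete a high-probability triplet with certainty
(50% of interior trials); random-ending trials do so with probability 1/4
(12.5%), and the remaining 37.5% end low-probability triplets, so 62.5% of
interior trials are high-probability overall.

Two layouts are built in. `study1` is 25 blocks of 80 stimuli under one
sequence A. `study2` is a Learning phase (blocks 1-15, sequence A, 1200
trials) and an Interference phase: blocks 16-20 under A, blocks 21-25 under
the *reversal* B of A introduced without warning, and blocks 26-30 under A
again. Relabelling triplets by their status under A and B partitions them
into `HL` (high under A only), `LH` (high under B only) and `LL` (low under
both). Because the successor map of the reversal is the predecessor map of
the original and a 4-cycle contains no 2-cycles, `HH` is impossible —
`validate_interference()` proves this by enumerating all 16 position pairs
(4 HL, 4 LH, 8 LL):

```{r interference}
validate_interference(asrt_pattern(c(2, 4, 3, 1)))
```

Performance contrasts during the reversed blocks define *Old knowledge*
(HL vs LL: resistance of the trained regularity) and *New knowledge* (LH vs
LL: acquisition of the reversed one), with LL as a practice-controlled
baseline.

## The synthetic participant model

`simulate_cohort()` generates cohorts with known, recoverable parameters.
Per trial the mean RT is

$$\mu_{RT}(n) = \mu - A_p\!\left(1 - e^{-(b-1)/\tau_p}\right)
 + \Delta(t)\,\mathbb{1}[\text{low}] - m\,\mathbb{1}[\text{trill/rep}],$$

with $b$ the block, $t$ the 5-block epoch, $\mu$ the baseline (population
mean 375 ms), $A_p$ the practice speed-up (26 ms, time constant $\tau_p$ = 8
blocks), $m$ the motor facilitation on trills/repetitions (15 ms), and the
learning trajectory

$$\Delta(t) = \alpha\,(1 + \theta_{RT}\, z)\left(1 - e^{-t/\tau_\ell}\right),$$

where $\alpha$ is the asymptotic high-vs-low advantage (10 ms), $\tau_\ell$
= 2 epochs, and $z$ the standardized OCI-R score with moderation
$\theta_{RT}$ (zero by default — OC tendencies leave learning untouched
unless explicitly switched on). Accuracy is Bernoulli with log-odds
$\beta_0 - \beta_d (b - 1) + a(t)\,\mathbb{1}[\text{high}]$, the analogous
trajectory $a(t)$ on the log-odds scale. Defaults were set once to emulate
the observed task statistics — block means drifting from roughly 375 ms to
349 ms, accuracy declining from about 92% to 90% over 25 blocks with a
triplet advantage growing to ~3.5 percentage points — and OCI-R totals are
drawn normal with the study-specific moments (20.72 ± 11.30 or
14.24 ± 11.73), rounded and clamped to the attainable 0-72 range.

Residual noise has median zero by construction, so the median-based
difference score is an exact functional of $\Delta(t)$. The default family
is a shifted lognormal (log-scale SD 0.4, rescaled to the participant's
residual SD, population mean 60 ms), giving realistically right-skewed RTs;
a normal family is available for exactness tests. RTs are floored at 1 ms.
During reversed-sequence blocks $\Delta(t)$ applies to the B-defined
categories (LH trials are the B-high trials) while a retention fraction
(default 1, i.e. full retention, matching the observed resistance of old
knowledge) of the A-trained advantage still applies to HL triplets, so Old
and New knowledge have known generative values. The epoch index continues
across phases rather than restarting.

What the generator does *not* emulate: post-error slowing, sequential
(trial-to-trial autocorrelated) noise, fatigue beyond the linear accuracy
drift, awareness, and any RT-accuracy tradeoff — correctness and RT are
conditionally independent given the design cells. Passing calibration tests
therefore certifies the pipeline's arithmetic and its statistical
calibration under a plausible generative model, not distributional claims
about real participants.

## Trial exclusion

`filter_trials()` applies, in a configurable order with a per-rule audit:
practice trials; non-first responses (the simulator only emits first
responses; the task itself re-prompts until correct); RTs below 150 ms or
above 1000 ms (strict inequalities — boundary values are retained); RTs
outside each participant's median ± 3 raw median absolute deviations
(unscaled MAD, computed per participant on that participant's trials
surviving the earlier rules); repetitions (`a-a-a`) and trills (`a-b-a`),
which carry motor-level facilitation and, by the cycle's lack of fixed
points, are always low-probability; and the first two trials of each block,
which belong to no identified triplet. Incorrect responses are additionally
excluded from the RT dataset only, so the RT dataset is always a subset of
the accuracy dataset. A removed trial is counted once, at the first rule
that removes it; totals are order-robust (the attribution is a convention),
and only the MAD rule is order-sensitive at all, through its input set.

Numerical note: iterating the filter is not exactly idempotent. Truncation
at ±3 raw MAD (≈ 2.02 σ for normal noise) shrinks the recomputed MAD to
≈ 0.641 σ, so a second pass re-removes about 1.2% of trials via the MAD
rule (more under skewed noise) and nothing via any other rule. Under the
default generator the overall removal fractions land close to the
empirically reported ones (roughly 18% of trials for accuracy analyses and
25% for RT analyses, excluding practice blocks).

## Scores and statistics

`aggregate_cells()` builds participant × epoch × triplet-category cells
(per-cell median RT from the RT dataset, mean accuracy from the accuracy
dataset; empty cells stay absent and propagate as missing scores rather
than being imputed). Learning scores are `median RT(low) - median RT(high)`
and `accuracy(high) - accuracy(low)` per 5-block epoch, averaged over
epochs with an unweighted mean, so positive always means learning in the
conventional direction; Old/New knowledge scores contrast HL and LH against
LL the same way over the three interference-phase epochs (LL cells contain
only triplets low under both sequences). The difference-score analysis is a
Pearson correlation between the averaged learning score and the OCI-R
total, with the exact t test on $n-2$ degrees of freedom.

The trial-level models mirror the standard analysis:
`log(RT) ~ Time * TripletType * OCIR + (Time + TripletType | participant)`
fit by REML with Type III F tests (Satterthwaite denominator df by default;
Wald chi-square as a fast asymptotic option), and the binomial-logit
counterpart for accuracy with likelihood-ratio tests per fixed term.
Factors are coded sum-to-zero — required for Type III validity — and the
OCI-R covariate is mean-centered at the participant level; the Time factor
keeps its natural order and the reference level only affects the reporting
parameterization, not the marginal tests. For the LRTs, each reduced model
is built by deleting the term's columns from the sum-to-zero model matrix;
a formula update would be re-absorbed by the remaining interactions and
test nothing. On non-convergence a fixed ladder is descended and recorded:
drop the random-effect correlations, then the Time slope, then all slopes.
Singular fits are flagged but kept, as is conventional. Cell contrasts
re-grid the estimated marginal means to the response scale (milliseconds,
or probability of a correct response) before differencing, with Šidák
adjustment $p_{adj} = 1 - (1-p)^m$ over the pairwise family, computed via
`expm1`/`log1p` for accuracy near 0 and 1. Nakagawa's marginal and
conditional $R^2$ use the variance of the fixed-effect predictor, the mean
per-observation random-effect variance $z_i^\top \Sigma z_i$ (which
accommodates random slopes), and $\pi^2/3$ as the latent residual variance
of logit models; the adjusted ICC is the random share of the non-fixed
variance.

## Calibration by simulation

`run_design_sim()` repeats simulate → filter → score → test over an effect
grid and reports rejection rates with exact binomial confidence intervals.
Two standing checks anchor the pipeline:

* **Parameter recovery.** With moderation off, the cohort-mean
  epoch-averaged learning score is compared with the generative
  $\overline{\Delta}$ computed from the sampled parameters (40 participants,
  25 blocks, $\alpha$ = 10 ms, 10 cohorts; agreement within 1 ms). The
  residual discrepancy is dominated by the MAD filter clipping the two
  shifted distributions asymmetrically.
* **Type-I error.** With $\theta_{RT} = \theta_{acc} = 0$, the OCI-R
  correlation tests and the TripletType × OCIR model terms are rejected at
  a rate whose 95% binomial interval covers 0.05 (replicates of 30
  participants × 10 blocks — sizes chosen to make a few hundred full
  pipeline replicates routine on a laptop; 300 replicates for the RT model
  term and 600, pooled over two batches, for the cheaper score-level
  correlations and the aggregated accuracy likelihood-ratio term; the
  correlations' null p-values are additionally checked for uniformity). In the harness the RT model
  uses the Wald chi-square Type III tests and a
  `(TripletType | participant)` random structure, and the accuracy model
  uses binomial cell aggregation with the fast `nAGQ = 0` approximation;
  these are the documented fast settings, asymptotically equivalent to the
  defaults at these sample sizes.

Power for the TripletType main effect is essentially 1 at the default
effect sizes, and rises monotonically in $\alpha$ up to Monte-Carlo error.

One calibration caveat is worth stating plainly: at the reduced harness
size the accuracy model's TripletType × OCIR test runs mildly conservative
(rejection around 3% rather than 5%, stable across replicate batches and
identical under Wald testing, `nAGQ` settings, and with slope
heterogeneity switched off). The triplet-slope variance component is
weakly identified against binomial cell noise with 30 participants and two
epochs, which inflates the interaction's standard error — familiar
finite-sample mixed-model behavior that recedes as participants and blocks
grow toward the published design's size. The corresponding RT-model test
and the score-level correlation tests are calibrated at nominal level.

## Design choices where the design was open

* Triplet windows never cross block boundaries; the first two trials of a
  block are `undefined` and removed.
* Every block starts with a pattern element at the same point of the cycle
  (10 repetitions of 8 close the cycle exactly); the starting role is
  configurable, and neither the starting phase nor the pattern permutation
  is counterbalanced by default — both are plain configuration.
* Random elements may duplicate their neighbours; the resulting trills and
  repetitions are generated faithfully and removed by preprocessing, not
  avoided at generation time.
* Practice blocks are all-random, carry non-positive block indices and a
  `practice` phase tag, so analyzable blocks are numbered 1..N exactly as
  the analysis block factor expects.
* The between-phase delay is metadata only.
* The RT range and MAD filters apply to the accuracy dataset too; each
  score uses its matching dataset (RT scores from the RT-filtered trials,
  accuracy scores from the accuracy-filtered trials).
* The mixed-model backend contract is the model structure plus the test
  type, not an optimizer; `lme4` stands behind it, with the convergence
  ladder fixed and logged.

## Known limitations

The package analyzes and simulates at the desk scale of the published
design; it does not model participant-level exclusion, awareness reports,
or cognitive-process accounts of the RT distributions (e.g. diffusion
models). The log-RT linear model is a deliberate approximation to the
additive-in-milliseconds generative model; recovery is therefore defined on
the difference score, with the mixed model checked for sign, detection and
calibration rather than for unbiased coefficient recovery.
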