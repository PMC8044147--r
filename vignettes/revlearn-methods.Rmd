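---
title: "Models and methods behind revlearn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind revlearn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(revlearn)
```

revlearn simulates and analyses a two-alternative reversal learning task in
which the same volatile hidden state can be inferred either from observed
cues (the "cue-based", Cb, framing: which category is the computer drawing
from?) or from the outcomes of one's own actions (the "outcome-based", Ob,
framing: which key draws from the target category?). This vignette explains
the generative task, the observer models, the fitting machinery, and the
neural-code simulators, together with the design choices that were
genuinely open and how we resolved them.

## The task generator

Each block has 72 trials. On every trial a sequence of 2, 4, 6 or 8
oriented stimuli is drawn from one of two categories whose generative
distributions are von Mises on the orientation domain, centered on
orthogonal means a quarter-turn apart, with concentration $\kappa = 0.5$
(orientations are $\pi$-periodic, so all trigonometry works on doubled
angles). The hidden state $s_t \in \{1, 2\}$ selects the drawn category
(directly in Cb; jointly with the previous response in Ob) and reverses
between episodes whose lengths are drawn from a truncated exponential
distribution on 4–24 trials. "More stable" blocks contain 6 episodes
(hazard rate $1/12$), "more volatile" blocks 12 episodes (hazard $1/6$).

Two design points deserve comment:

* **Episode-length conditioning.** The marginal law of episode lengths is
  stated (truncated exponential), but lengths must also sum to the block
  length. We draw i.i.d. lengths from a discrete truncated exponential
  whose rate makes the mean equal `total / n_episodes`, and reject until
  the sum is exact. Because the lengths form an exponential family, the
  conditional distribution given the sum does not depend on the rate at
  all (the tilt cancels), so this scheme is equivalent to sampling
  uniformly over feasible compositions; the mean-matched rate only buys
  rejection efficiency.
* **Evidence matching.** Sequences are pre-generated as *tilts* $\delta_i$
  from the generative mean rather than as orientations. The per-stimulus
  log-odds evidence is $\ell_i = \pm 2\kappa\cos(2\delta_i)$ with the sign
  set by the hidden state, so a Cb block and an Ob block built from the
  same tilts provide *identical* evidence streams for any response
  history, even though the realized orientations in Ob depend on the
  previous response. `realize_block_pair()` constructs such matched pairs;
  Ob orientations are materialized lazily once responses exist.
* **Trial-wise category axes.** The category-A mean is redrawn uniformly
  on $[0, \pi)$ every trial. The uniform choice is the maximally
  uninformative one and is what decorrelates the stimulus characteristics
  used by the encoding analyses.

## The observer models

Beliefs are posterior log-odds $L_t$ between the two hidden-state values.
Between trials the belief leaks towards zero through

$$F(L) = L + \log\!\big(\tfrac{1-h}{h} + e^{-L}\big) -
             \log\!\big(\tfrac{1-h}{h} + e^{+L}\big),$$

the optimal discount induced by a reversal probability $h$: it preserves
the sign of $L$ for $h < 1/2$, collapses to 0 at $h = 1/2$, and tends to
the identity as $h \to 0$. Within a trial, $L_t = F(L_{t-1}) +
\mathcal{L}_t$ with $\mathcal{L}_t = \sum_i \ell_i$.

The noisy observer (`simulate_responses()`) has four parameters:

| parameter | meaning | units | default |
|---|---|---|---|
| `h` | perceived hazard rate | probability/trial | 0.125 (optimal) |
| `sigma_inf` | inference noise SD per stimulus update | log-odds | 0 |
| `sigma_sel` | selection noise SD on the decision variable | log-odds | 0 |
| `p_lapse` | probability of blindly repeating the previous response | probability | 0 |

Each of the $n$ per-stimulus updates receives independent
$N(0, \sigma_{\mathrm{inf}}^2)$ noise, so the trial-level belief is a
$N(F(L_{t-1}) + \mathcal{L}_t,\, n\sigma_{\mathrm{inf}}^2)$ draw — the
trial-level description is the marginal of the stimulus-level one, which
keeps the "stimulus-level" and "response-level" belief schemes mutually
consistent. Responses follow the sign of $N(L_t, \sigma_{\mathrm{sel}}^2)$;
an exactly zero decision variable (possible only in noise-free corner
cases) is resolved by a fair coin flip. Lapses replace the response but do
not freeze the belief update; the behavioural data constrain only the
response stream, so this is an assumption, made explicit here.

## Fitting: particle MCMC

The response likelihood under inference noise has no closed form;
`particle_filter()` provides the standard unbiased estimate (bootstrap
filter over the latent belief, systematic resampling every trial — the
resampling scheme is our choice; none is prescribed) and
`pmcmc_sample()` embeds it in a pseudo-marginal random-walk Metropolis
sampler. The walk operates on scaled-logit-transformed parameters, with
the proposal covariance adapted only during a 20% burn-in and frozen
afterwards, which keeps the invariant distribution intact. Priors are
truncated normals (`prior_spec()`). Reduced model variants fix parameters
at zero through the `free` argument so one sampler serves all models.

Defaults are sized for desk-scale work: 1000 particles (the validation
property that posterior means agree between 200 and 2000 particles on the
same data is what justifies the reduction) and a few thousand iterations.

For Bayesian model selection, `marginal_likelihood()` estimates
$p(r_{1:T} \mid \Theta_{1:T})$ by prior importance sampling of the
particle-filter estimate — unbiased by construction since the filter
estimate is. The exact extraction used historically for this quantity is
under-specified in the literature this package follows, so we document
ours and validate it on synthetic data rather than claim numerical
equivalence. `bms()` implements both fixed-effects sums and the
variational Dirichlet random-effects scheme with Monte-Carlo exceedance
probabilities.

## Psychometrics

`fit_reversal_curve()` fits the saturating exponential
$p(r_k = s) = p_0 + (p_{\mathrm{rev}} - p_0)(1 - e^{-k/t_{\mathrm{rev}}})$
by trial-level Bernoulli maximum likelihood (not least squares on binned
means), with the episode-initial rate $p_0$ chained across episodes (0.5
for a block's first episode, otherwise one minus the previous episode's
final value). `fit_repetition_curve()` fits the three-parameter sigmoid
for the probability of repeating the previous response as a function of
the evidence $\mathcal{L}_{\mathrm{rep}}$ signed in favour of that
response. The criterion parameter is reported as the PSE — the magnitude
of *conflicting* evidence at which repeating and switching are
equiprobable, matching the directional language used for this quantity
(the raw sigmoid crossing sits at negative evidence for any
belief-carrying observer).

One bound was widened relative to the obvious parameterization: the
sigmoid slope is allowed to be negative ($\beta \in [-20, 20]$). With a
non-negative slope and an asymmetric lower asymptote the family is not
closed under mirroring the evidence axis, so the natural invariance test
(flip all evidence signs, expect the PSE to negate) would be
unsatisfiable; a signed slope restores closure in the $p_{\mathrm{rep}} =
0$ regime in which that property is tested.

## Stimulus characteristics and the neural hazard rate

`stimulus_characteristics()` computes, per stimulus: the orientation pair
$(\cos 2\theta, \sin 2\theta)$; the change $|\theta_i - \theta_{i-1}|$ as
a circular distance on the $\pi$-periodic circle (range $[0, \pi/2]$); the
evidence strength as the tilt from the nearest category boundary
(boundaries sit $\pm\pi/4$ from the means, so the range is $[0, \pi/4]$);
and the consistency — evidence strength signed by the agreement between
the stimulus's evidence $\ell_i$ and the current belief $L_{t,i}$. At an
exactly neutral belief the sign of $\ell_i$ is used; under any noise this
event has probability zero, but a documented rule is needed for
deterministic tests. Under the stimulus-level scheme $L_{t,i}$ is the
belief after stimuli $1..i{-}1$ of the trial; under the response-level
scheme it is frozen at the trial's prior — the two differ exactly on
trials with a mid-sequence belief reversal.

`hazard_tuning()` recomputes the consistency variable under a grid of 13
log-spaced hazard rates spanning $1/32$ to $1/2$, measures cross-validated
coding precision for each variant, smooths precision against $\log h$ with
a quadratic, and reports the vertex (clipped to the grid) as the neural
hazard rate $h^\ast$; a concave-up fit falls back to the grid argmax with
a warning. Beliefs for this analysis default to the fast noise-free
recursion (which depends only on the stimuli, because the matched design
makes the evidence stream response-independent); response-conditioned
particle-filter trajectories are available through `particle_filter()`
when inference noise should be integrated over.

## Linear coding units and coding similarity

`coding_population()` defines $n = 300$ linear units of which
$n_{\mathrm{sel}} = 100$ respond to a standardized characteristic with
unit gain plus i.i.d. Gaussian background noise of SD $\sigma$
(heterogeneous gains are deliberately excluded). Two conditions share a
fraction $\omega$ of selective units. `encode_cv()` mirrors the encoding
analysis: per interleaved fold (12 by default; samples are standardized
and weights estimated on training folds only), univariate least-squares
weights per feature, test-set projection, predictions concatenated across
folds before a single correlation, Fisher-transformed, with the
correlation capped at $1 - 10^{-12}$ so noiseless codes stay finite.
`precision_scores()` adds the two cross-condition directions computed with
identical train/test volumes, and `fit_similarity()` recovers
$(\omega, \sigma_a, \sigma_b)$ from the four precision values by least
squares against simulated quadruples, using common random numbers so the
objective is smooth and a data-driven start (between/within precision
ratio for $\omega$, inverted matched-filter precision for $\sigma$). A
jackknife wrapper over datasets is available (`jackknife_similarity()`).

## The synthetic cohort

`generate_cohort()` draws per-subject parameters from truncated normals
whose means are the fitted group values (hazard rate 0.191/0.115 and
inference noise 0.512/0.550 for Cb/Ob) and whose SDs are the printed SEMs
scaled by $\sqrt{24}$; subject-level distributions are not otherwise
published, so matched moments are the principled choice. The inference
noise is correlated across conditions (target $r = 0.63$) through a
shared latent Gaussian factor — the simplest mechanism achieving the
printed correlation. Each subject performs 8 blocks: four matched Cb/Ob
pairs, two stable and two volatile. `generate_meg_features()` then builds
feature matrices from disjoint coding subpopulations per characteristic,
with the consistency channel generated at condition-specific "true"
hazard rates; it is synthetic plumbing that reproduces the statistical
structure the analyses assume (decorrelated characteristics, linear
codes, condition overlap), not sensor data — real recordings add
autocorrelation, sensor covariance and artifacts that this generator
deliberately omits, so passing tests demonstrate the *analyses*, not
properties of real measurements.

## Problem sizes and numerical choices

Simulation sizes used in the test-suite and acceptance analyses are our
own trade-off between Monte-Carlo error and desk-scale runtime: 50
sessions (28,800 trials) for accuracy summaries, $\ge 10^4$ trials per
condition for belief-magnitude contrasts, 8 blocks per fitted condition
with 1000 particles and ~1200 MCMC iterations for parameter recovery,
1440 samples per condition for the coding analyses (matching the 12-fold
scheme of 1320 training and 120 test samples per fold). Log-odds are
clipped at $\pm 50$ before exponentials; probabilities are floored at
$10^{-9}$ inside Bernoulli likelihoods; curve fits use 5 starting points
to dodge local minima.

## Known limitations

* A noteworthy discrepancy: with the stated generative parameters
  ($\kappa = 0.5$, sequences of 2–8 stimuli, 6/12 episodes per block),
  the noise-free observer at the true hazard rate attains ~82–83%
  accuracy in our simulations (and a run-length-aware ideal observer
  ~85%), not the ~88% sometimes quoted for comparable designs; the
  package reports what the implemented design actually yields.
* Group-level statistics of human cohorts (paired t-tests across
  subjects) are out of scope; the package provides per-dataset fits.
* The MEG-like generator makes no attempt at temporal structure; latency
  profiles are cosmetic metadata.
* Hierarchical (group-level) fitting is not implemented; subjects are fit
  independently.
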