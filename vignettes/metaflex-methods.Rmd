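---
title: "Models and methods behind metaflex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind metaflex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

metaflex analyzes two task batteries that are administered together in
studies of metacognition and behavioral adaptation: a confidence-rated
two-choice task (here: mental rotation of 3-D block shapes) and a
rule-reversal trading game. This vignette describes the models, the
defaults and the design decisions in enough detail to audit or extend
them.

## The type-2 SDT model

Each trial produces a latent evidence value $x$; "identical" stimuli have
mean $+d'/2$, "different" stimuli $-d'/2$, unit variance. The subject
responds "identical" when $x > c$. From hit and false-alarm rates,

$$d' = z(\mathrm{HR}) - z(\mathrm{FAR}), \qquad
  c = -\tfrac12\,[z(\mathrm{HR}) + z(\mathrm{FAR})].$$

Rates of exactly 0 or 1 are replaced by $1/(2N)$ and $1 - 1/(2N)$ per
stimulus class before the probit — the standard correction; the source
analyses are silent on the point, so standard practice is followed.

At the metacognitive level the same geometry is re-scaled: evidence means
$\pm\,\mathrm{meta}\text{-}d'/2$ and a carried-over criterion
$c_2 = c \cdot \mathrm{meta}\text{-}d'/d'$. On each side of $c_2$, three
additional type-2 criteria partition the axis into the four confidence
bins; confidence grows with distance from $c_2$. Only the
*response-conditional* bin probabilities enter the likelihood — one
multinomial per (stimulus, response) cell — so type-1 performance is
conditioned on, not re-fit. meta-d′ is the type-1 sensitivity that would
produce the observed confidence-accuracy coupling if confidence used the
full decision signal; the M-ratio meta-d′/d′ is efficiency relative to
the subject's own performance, which is what makes subjects and groups
with different d′ comparable. Metacognitive bias is simply the mean
confidence; on a 1–4 scale the midpoint is 2.5 and subjects above it are
labeled overconfident.

### Maximum-likelihood fit

The MLE maximizes the response-conditional multinomial likelihood over
meta-d′ and the six type-2 criteria. Numerical choices:

* criteria are parameterized as *positive increments in log-space* away
  from $c_2$, which enforces the monotone ordering by construction;
* cell probabilities are floored at $10^{-10}$ inside the log — no count
  padding is applied anywhere;
* the bounded quasi-Newton optimizer (`L-BFGS-B`, tolerance $10^{-8}$,
  meta-d′ bounded to $[-5, 5]$) is run from five deterministic starting
  points and the best likelihood is kept; the convergence flag is
  reported, never swallowed;
* $d' = 0$ makes the criterion ratio (and the M-ratio) undefined; the fit
  is returned with `m_ratio = NA` and a flag rather than an error.

The test suite checks this engine against an exhaustive profile
grid search (meta-d′ over $[0, 5]$ in steps of 0.01 with nested
criterion-only optimization, written with its own probability arithmetic),
against expected counts generated by the model itself, and for parameter
recovery from simulated subjects.

### Hierarchical Bayesian fit

With 72 trials per subject the single-subject MLE is noisy (SD of the
M-ratio estimate around 0.3–0.5 depending on confidence usage), which is
why hierarchical estimation is the field's preferred route at this trial
count. Subject log M-ratios are partially pooled within groups:

$$\mu_g \sim \mathcal N(0, 1),\quad
  \sigma_g \sim \mathrm{HalfNormal}(1),\quad
  \log M_s \sim \mathcal N(\mu_{g(s)}, \sigma_{g(s)}^2),$$

with $\mathrm{meta}\text{-}d'_s = e^{\log M_s} d'_s$ and the subject's
type-1 parameters and response rates held fixed at their corrected
empirical values. The likelihood is one 8-bin multinomial per stimulus
class (response × confidence), so empty confidence cells never need
padding. Sampling is by JAGS: 4 chains × 2000 retained draws after 1000
warm-up iterations by default, with per-chain RNG seeds derived from the
user's seed, so identical data and seed reproduce the posterior exactly.
The subject effects use a *non-centered* parameterization
($\log M_s = \mu + \sigma \eta_s$, $\eta_s \sim \mathcal N(0,1)$): in
early testing the centered form left chains stuck in the hierarchical
funnel (split-$\hat R$ up to 17 on some cohorts); non-centering brought
$\hat R$ below 1.05 at the same chain lengths. A fit with any
$\hat R > 1.1$ is flagged `converged = FALSE`. One quantitative caution:
at 72 trials and 4 confidence levels the posterior of a two-group
contrast in mean log M-ratio has a standard deviation near 0.2 even with
33 subjects per group, so a true 0.6-vs-0.4 difference
($\Delta \log M \approx 0.41$) yields a 95% credible interval that can
straddle zero in a sizable minority of cohorts; the tests therefore
check CI *coverage* and sign recovery of the contrast, not guaranteed
separation.

Both pathways to a subject-level M-ratio are provided. The default for
downstream ANOVA is the per-subject MLE, because a subject-level factorial
ANOVA is most interpretable on independently estimated values. The
hierarchical posterior means are available behind a flag
(`run_config(hierarchical = TRUE)`); note that shrinkage toward
group-specific means makes the subsequent ANOVA anticonservative in a
known way (within-group variance is deflated by pooling), which is
plausibly how very large M-ratio F statistics arise in practice when this
two-step route is used. The package exposes the choice and documents it
rather than resolving it silently. At the study's own scale (33 + 33
subjects, 72 trials, mean confidence near 3.5) the MLE route has little
power for a 0.6-vs-0.4 group difference (measured at roughly 15% across
simulated cohorts), while the hierarchical route detects it reliably —
the recovery studies below therefore use the hierarchical pathway.

## The trading game

The reward matrix (aliens × minerals, coins):

|        | m1 | m2 | m3 | m4 |
|--------|----|----|----|----|
| alien1 |  5 | 10 | 20 | 10 |
| alien2 | 20 |  5 | 10 | 10 |
| alien3 | 10 | 20 |  5 | 10 |

Each of minerals 1–3 offers {5, 10, 20} across the aliens; mineral 4 pays
10 to everyone and exists to probe alien preference. The reversal swaps
all 5s and 20s and fixes the 10s (an involution). The schedule presents
each mineral 12 times in the 48 pre-reversal trials and 5 times in the 20
post-reversal trials, in a seed-frozen random order shared by all
subjects of a cohort.

Learning is complete at the earliest trial satisfying
(1) three consecutive 20-coin transactions among 20-eligible trials, with
mineral-4 trials neither counting toward nor interrupting the run, and
(2) no two consecutive 5-coin transactions at any later point of the
phase. Decisions taken where the rule is underspecified, all configurable:

* the learning point is the position of the trial *completing* the run
  (`convention = "run_start"` gives the first trial instead);
* positions count mineral-4 trials in the index but exclude them from run
  eligibility;
* the "afterwards" horizon of condition (2) is the remainder of the
  phase, and the double-5 check also skips mineral-4 trials (they can
  never pay 5), keeping it symmetric with condition (1);
* non-learners are censored with the phase length reported. In
  correlations they enter tied at the worst rank (re-learning 21 on a
  20-trial phase, learning 49 on a 48-trial phase) by default;
  `censoring = "exclude"` drops them.

## The synthetic cohort generator

The generator exists so that every pipeline stage is testable without the
unreleased participant data; it emulates the statistical structure of the
study frame, not any cognitive mechanism.

**Confidence data** are drawn from exactly the generative model the
estimator fits: type-1 responses from the equal-variance model at the
subject's $d'$, confidence from the response-conditional bin
probabilities at $\mathrm{meta}\text{-}d' = M \cdot d'$. The six type-2
criteria are placed symmetrically with geometrically growing offsets
(ratio 2) whose base spacing is solved by root-finding so that the
*expected mean confidence equals the subject's target bias*. The
geometric spacing is a realism choice: with equal spacing, pushing the
mean to 3.5 collapses the intermediate bins into slivers next to the
criterion (a 75/8/8/8 histogram), whereas graded human ratings at that
mean look like the 5/9/18/68 pattern the geometric layout produces.
An unreachable bias target raises an error in the single-subject
simulator rather than silently clipping; the cohort generator, whose
Beta tail can graze the scale ends, clamps its bias draws to
[1.05, 3.95] — the range every subject can realize under the meta
model's criterion placement.

**Trading behavior** comes from a value-tracking agent: per
(alien, mineral) values start optimistic at 20, move toward observed
rewards with the subject's learning rate, and drive greedy choice with a
small exploration rate and seeded random tie-breaks. Once a mineral's
20-coin buyer has been experienced, the agent exploits that remembered
pairing; a sub-maximal reward on it is *denied* (no value update) and
counts toward a disappointment counter. After `agent_switch_threshold`
consecutive disappointments the agent abandons the whole mapping (values
reset, memory cleared) and re-learns. The threshold is the
perseveration/overconfidence knob: re-learning speed is monotone in it,
and `Inf` gives a fully perseverative, censored agent. The agent makes no
claim of modeling any clinical mechanism; it exists to give re-learning
speed a tunable, monotone driver.

**Cohort structure.** Defaults mirror the study frame: 33 subjects per
group (ASD, TD), split 18/15 across two regions; group mean d′ 1.5 (ASD)
vs 1.8 (TD) with SD 0.3 (TD more accurate); group mean M-ratio 0.6 (ASD)
vs 0.4 (TD) with SD 0.15 (ASD more metacognitively efficient); subject
bias on [2.5, 4] with mean 3.5 (a scaled Beta(4, 2)), matching a cohort
in which nobody averages below the scale midpoint and the group mean is
3.5. d′ values correspond to 77–82% accuracy, typical of a hard
visuospatial discrimination. Learning rates are Uniform(0.45, 0.8) and
exploration Uniform(0.01, 0.03) — nuisance heterogeneity.

**The bias–flexibility coupling** is a Gaussian copula between the
subject's bias and the perseveration threshold (mapped onto levels 1–8 by
quantile), because the association of interest is reported in the
literature as a correlation, not a mechanism. The latent correlation is
the requested Spearman target divided by an attenuation constant of
0.646 — the realized/latent ratio measured once in a 1500-subject pilot
of the default agent, reflecting dilution by agent stochasticity and the
discreteness of the threshold map. At the default target of −0.5 the
realized cohort-level Spearman(bias, re-learning trials) is −0.51 on
average with about 90% of cohorts within ±0.2. The sign convention is on
the measured trial count; the "overconfident people re-learn more slowly"
direction of the narrative corresponds to a positive correlation with
trial counts and is obtained by flipping the target's sign.

All randomness flows from one root seed through documented stream
splitting (`split_seed`), so cohorts, subjects and MCMC chains are
individually reproducible.

## The inference layer

* **Factorial ANOVA**: Type-III sums of squares under sum-to-zero
  contrasts (via `car::Anova`), partial
  $\eta_p^2 = SS_e/(SS_e + SS_{err})$ per effect; an optional numeric
  covariate turns it into the ANCOVA used for re-learning speed with
  learning speed regressed out.
* **Mixed ANOVA**: the two accuracy-conditioned confidence means per
  subject are analyzed through the multivariate linear model route with a
  two-level within factor; subjects missing a level (no correct or no
  incorrect trials) are excluded with a warning.
* **Spearman**: Pearson on average ranks; p from the t approximation
  $t = \rho\sqrt{(n-2)/(1-\rho^2)}$, appropriate at the n ≈ 33–66 this
  layer targets; an exact-permutation p is available behind a flag.
  Partial Spearman is the first-order partial Pearson correlation on
  ranks (p on $n-3$ df).
* **Correlation comparison**: $z_{obs} = (\mathrm{atanh}\,\rho_1 -
  \mathrm{atanh}\,\rho_2)/\sqrt{1/(n_1-3) + 1/(n_2-3)}$ with a
  *one-sided* p — the directional question "is the stronger correlation
  reliably stronger", which is how such comparisons are conventionally
  read in this literature.
* **Sensitivity**: the minimal detectable Cohen's f solves
  $\mathrm{power}(\lambda = n f^2) = 0.80$ (default) by root-finding to
  $10^{-4}$ on the noncentral-F tail. For the study frame (n = 66,
  α = .05, 1 numerator df, 4 cells) this gives f ≈ 0.345. Note that
  f = 0.35 corresponds to $\eta_p^2 = f^2/(1+f^2) \approx 0.11$, not
  .06; quoted pairings of f = 0.35 with $\eta_p^2 = .06$ mix two
  different conversions, so the η² form is reported but not asserted
  against.

## What the simulations do and do not show

The recovery studies in the test suite and acceptance script operate at
the study's own scale — 66 subjects, 72 confidence trials, 68 game trials
— and problem sizes chosen for a laptop-class single CPU: 20 random
tables for the grid-search oracle, 1000 random sequences for the
learning-detector equivalence, 40 replicates × 3 meta-d′ levels at 1000
trials for recovery (at the canonical recovery design: d′ = 1.5, c = 0,
equally spaced type-2 criteria ±0.5, ±1, ±1.5, counts drawn from the
model itself — recovery of meta-d′ at n = 1000 has a median absolute
error intrinsically near 0.09, so the study is run where the design is
informative), 10–20 seeded cohort replications for the two end-to-end
detection rates, 500 replications for ANOVA null calibration, and
hierarchical fits at 3 chains × 1000–1200 retained draws. Passing them
shows the estimators recover the generative structure they assume. Real
confidence data violate that structure in known ways — unequal variances,
criterion drift, serial dependence of confidence, lapses — so these
results certify the machinery, not the model's adequacy for any given
dataset. The agent likewise produces realistic *marginal* learning
statistics but, by default, no learning–re-learning correlation beyond
what the shared schedule induces; users who need that coupling can widen
the learning-rate spread or couple it to the threshold.

## Known limitations

* Meta-d′ assumes the equal-variance type-1 model; strongly unequal
  variances bias it.
* The hierarchical priors follow the field's standard choices and are
  documented above, but no claim is made of replicating any specific
  published posterior, whose software settings are rarely printed.
* At mean confidence near 3.5 on a 4-point scale, 72 trials contain
  little metacognitive information per subject; group-level conclusions
  should lean on the hierarchical fit, and subject-level M-ratio values
  should be treated as noisy.
* Reaction times, stimulus geometry, and mixed-effects formulations with
  region as a random factor are out of scope.
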