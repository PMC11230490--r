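---
title: "Estimating risk and ambiguity attitudes for ordinal outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating risk and ambiguity attitudes for ordinal outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Many consequential decisions — medical ones in particular — offer outcomes
that can be ranked but not priced: "slight improvement" is clearly worse
than "recovery", yet neither has an intrinsic cardinal value. Classical
decision models multiply an outcome's value by a probability weight, so they
need a number for the outcome. `ordival` implements a task design and a
modeling pipeline built around a simple resolution: use the outcome's rank
in the current choice set as its value.

The task offers, on every trial, a choice between a certain reference (a
fixed $500 gain, or a guaranteed "slight improvement") and a lottery paying
a better outcome with some probability — or nothing. Uncertainty comes in
two forms: *risk*, a fully known winning probability (25%, 50%, 75%), and
*ambiguity*, a 50% lottery whose probability display is partially occluded
(24%, 50% or 74% hidden). Each domain contributes 49 trials: the full
crossing of the 6 uncertainty levels with the 3 above-reference outcomes and
both winning colors (36), six additional value trials (one per level, fixed
outcome assignment), and 7 reference-equal catch trials. Notes on that
layout are in the design-choices section below.

## The model

Each option is mapped to a subjective value

$$SV = \left(P - \beta \frac{A}{2}\right) V^{\alpha},$$

where $P$ is the winning probability (1 for the certain reference), $A$ the
ambiguity level (0 when the probability is fully known), and $V$ the outcome
value. An occluder hiding the fraction $A$ of the display leaves the winning
probability anywhere in an interval of width $A$ centered on 50%; a
decision-maker who linearly discounts the ambiguous probability by
$\beta A / 2$ behaves as if the winning chance were $0.5 - \beta A/2$.
Thus $\beta > 0$ is ambiguity aversion, $\beta = 0$ ambiguity neutrality
(every ambiguous lottery treated exactly as its 50% risky twin — the
package's central analytic anchor), and $\beta < 0$ ambiguity seeking. The
curvature $\alpha$ captures risk attitude: $\alpha < 1$ concave (risk
averse), $\alpha > 1$ convex. For reporting, the ambiguity attitude is also
carried as $-\beta$ so that negative means averse in both conventions; the
fits table holds both columns, explicitly labeled.

Two variants differ only in $V$:

* **Ordinal**: $V$ is the outcome's rank (null 0, reference 1, then 2-4).
* **Rating**: $V$ is the participant's own 0-10 pleasantness rating of the
  outcome, elicited separately per domain and phase.

Choices follow a softmax (logistic) rule on the subjective-value difference,

$$P_V = \frac{1}{1 + e^{-\gamma (SV_L - SV_C)}},$$

with $\gamma > 0$ an individual inverse-temperature: the larger $\gamma$,
the more deterministic the chooser. Equal subjective values give exactly
$P_V = 1/2$. Note a reference-equal catch lottery is *not* value-equal to
the certain reference ($SV_L = 0.5$ vs $SV_C = 1$ at $\beta = 0$), so a
coherent agent chooses its uncertain side at a rate strictly below one half
— which is what makes frequent uncertain-catch choices a usable
misunderstanding signal.

## Estimation

Per participant, domain and phase, the package minimizes the Bernoulli
negative log-likelihood of the observed choices over
$(\alpha, \beta, \gamma)$ with a derivative-free Nelder-Mead simplex,
restarted from a full grid of starting points: $\alpha$ starts at
$\{0.01, 0.51, \ldots, 3.51\}$, $\beta$ at $\{-2, -1.5, \ldots, 2\}$ and
$\gamma$ start magnitudes at $\{0.01, 0.51\}$ — 144 starts. The lowest
negative log-likelihood wins; exact ties go to the lowest grid index, so
fitting is fully deterministic. Numerical choices:

* $\alpha$ and $\gamma$ are optimized on the log scale (positivity without
  penalty kinks); $\beta$ is unconstrained.
* Choice probabilities are clipped to $[10^{-9}, 1 - 10^{-9}]$ so saturated
  predictions cannot produce an infinite objective.
* Simplex tolerances are $10^{-6}$ on both the objective spread and the
  parameter spread, with at most 2,000 evaluations per start.
* Trials sharing a $(P, A, V)$ cell enter the likelihood through their
  choice counts, which makes the objective's cost independent of the raw
  trial count.
* Estimates with $\alpha > 10$, $|\beta| > 4$, $\gamma > 100$, or an
  $\alpha$/$\gamma$ that collapsed to (machine-) zero are flagged as
  boundary fits. The $\alpha \to \infty$, $\gamma \to 0$ likelihood ridge
  is left unconstrained during optimization; predictions cap the exponent
  only where `V^alpha` would overflow, beyond which every probability is
  already saturated.

The simplex itself is implemented in compiled code because the package's
cross-validation analyses perform hundreds of thousands of restarts;
`stats::optim`'s Nelder-Mead serves as an independent cross-check in the
test suite and is consistently matched or beaten.

## Model comparison

Variants are arbitrated per domain and phase by two criteria averaged over
participants: BIC ($2\,\mathrm{NLL} + 3 \ln n$, natural log, $k = 3$) and
5-fold cross-validated mean squared error. The 49 trials are randomly
partitioned into folds of 9 or 10 trials; each fold is predicted by a model
fitted to the other four, and the residual is the squared gap between the
predicted choice *probability* and the binary choice (a Brier-style score —
thresholding would discard the fitted $\gamma$). A fold whose training set
contains no uncertain choice cannot be fitted and is skipped with a log
message. When the two criteria disagree the selection is flagged discordant
rather than silently resolved.

## Exclusion rules

Four rules mirror standard online-cohort hygiene, each with a documented
edge convention:

1. **Duplicate worker IDs** — all sharers excluded everywhere.
2. **Age gap** — phase-2 data dropped when |age₂ − age₁| strictly exceeds
   2 years; a gap of exactly 2 is retained ("exceeding" is strict, and a
   9-month interval legitimately spans 0-1 birthdays).
3. **Catch trials** — a (participant, phase, domain) unit is dropped when
   the uncertain reference-equal option was chosen on strictly more than
   50% of catch trials: 4 of 7 fires, 3 of 7 does not.
4. **Never uncertain** — units with zero lottery choices are excluded from
   model *fitting* only (their likelihood is maximized on the noise
   boundary and carries no attitude information); model-free summaries
   retain them.

Catch and never-uncertain rules are scoped per domain; duplicate-ID and
age-gap rules per participant. The retained sets are idempotent and
order-insensitive under re-application.

## Model-free measures

Choice proportions (lottery over reference) are computed per outcome level
and per uncertainty level, always excluding catch trials — they are
manipulation checks, and mixing them in would conflate attitude with
indifference noise. Risk attitude is the unweighted mean proportion over the
three risk levels. Because choices under ambiguity confound risk and
ambiguity attitudes, ambiguity is summarized by the *corrected* proportion:
the proportion at each ambiguity level minus the proportion at 50% risk
(the behavior an ambiguity-neutral agent would show), averaged over levels.
Empty cells propagate as missing, never as zero — zero is a meaningful
attitude value.

## The synthetic cohort

No participant-level dataset is distributed with a retrievable accession,
so the package ships a generator that produces cohorts with *known*
parameters, making every downstream stage testable end to end. Each agent
carries an $(\alpha, \beta, \gamma)$ triple per domain and phase; the four
copies of each parameter are coupled by a Gaussian copula whose correlation
matrix is the Kronecker product of a phase block and a domain block, with
latent correlations $2\sin(\pi\rho_s/6)$ so the planted Spearman targets
hold exactly in expectation on the direct (same-phase or same-domain)
edges. Choices are then drawn from the softmax model itself; ratings are
$10\,(\mathrm{ordinal}/4)^{e}$ plus Gaussian noise (sd 0.8), clipped to
$[0, 10]$ and stored at survey-scale precision, with exponent $e = 1$ (a
linear map) by default.

Defaults, chosen once and fixed:

* $\alpha \sim$ lognormal(median 0.7, sdlog 0.5): a typically risk-averse
  population with realistic spread.
* $\beta \sim N(0.3, 0.5)$: mild average ambiguity aversion, with a seeking
  minority.
* $\gamma \sim$ lognormal(median 4.5, sdlog 0.5). The noise scale is the
  one generative quantity with a usable empirical anchor: on real data the
  rank correlation between fitted $\alpha$ and the risky-choice proportion
  is reported in the 0.90-0.98 range, and simulated cohorts reproduce that
  band at a median $\gamma$ near 4.5 (at a median of 1.5 the simulated
  correlation collapses to ~0.65, i.e. choices far noisier than the
  population being emulated).
* Cross-domain and cross-phase Spearman targets 0.4 and 0.5: the moderate
  persistence range reported for these attitudes.

Aberrant agents are planted deterministically: catch failers choose the
uncertain side of every catch trial, never-uncertain agents always take the
reference, duplicate-ID agents reuse another agent's worker ID. Each
guarantees its exclusion rule fires, so filter tests never depend on chance.

What the generator does *not* emulate: reaction times, attrition that
depends on covariates, demographic structure beyond age, within-session
learning or fatigue, and any deviation of real choice behavior from the
softmax subjective-value family. Passing recovery and calibration tests
therefore shows the pipeline is correct and well-posed under the model's
own assumptions — not that the model is true of human beings.

## Consistency analyses

For each attitude measure — risk proportion, corrected ambiguity
proportion, fitted $\alpha$, fitted $\beta$ — the package computes Spearman
correlations across domains (within phase), across phases (within domain,
i.e. test-retest), and between model-based and model-free measures of the
same construct. Ranks use midranks for ties; p-values come from the
two-sided t approximation; pairs are deleted listwise with the dropped
count reported so every cell's n is auditable. Model-based rows use the raw
$\beta$ (aversion positive); no multiplicity correction is applied, matching
the raw-p reporting convention of the analyses the grid mirrors.

## Design choices made where the design was open

* **Trial-set arithmetic.** The published counts (49 trials per domain, 7
  reference-equal, risk and ambiguity evenly split, all levels crossed with
  all outcomes, colors randomized) do not pin down a unique layout: the
  full unique crossing of 6 levels × 3 above-reference outcomes × 2 colors
  yields only 36 value trials, not 42. The package completes the set with
  one extra value trial per uncertainty level with a *fixed* outcome
  assignment (25%→2, 50%→3, 75%→4 and likewise for ambiguity), marked by a
  `replicate` column, and one extra catch trial at 50% risk. This honors
  every stated count, keeps the crossing complete, makes value trials split
  21/21 between risk and ambiguity, and gives each uncertainty level
  exactly 7 value trials; only winning colors depend on the seed.
* **Ambiguity levels** are 24/50/74% throughout (the display geometry of
  the occluder), even though prose sometimes rounds the top level to 75%.
* **Monetary labels** follow the task description ($500-$2500); scaling
  them ×10 would change nothing in an ordinal model.
* **Sign of γ.** A printed start range of [−1, −0.01] for γ is incompatible
  with the softmax as written (negative γ would make choices *anti*-follow
  value). The package treats γ as positive and reads the printed range as
  start magnitudes, giving the two starts {0.01, 0.51}.
* **Age-gap scope**: only the follow-up record is dropped, since the rule
  exists to catch inconsistent self-report at re-contact.
* **Catch trials in proportions**: excluded (manipulation checks); whether
  the original analyses included them is unstated.
* **Ratings enter raw** on the 0-10 scale in the rating variant; no
  normalization before exponentiation.

## Problem sizes used in the shipped checks

The package's own verification suite exercises: 200 default agents at the task's 49
trials/domain for rank-recovery of $\alpha$ and $\beta$; 20 replicate
agents at 5,000 trials for point recovery at $(\alpha, \beta, \gamma) =
(0.8, 0.6, 3)$, where the attitude parameters' mean absolute error is
bounded by 0.05 (the information limit at that size: the MLE sampling SDs
are ≈0.015 for $\alpha$, 0.028 for $\beta$, and 0.107 for $\gamma$, so a
per-replicate ±0.05 bound is meaningful only for the attitudes); 50
cohorts of 30 agents for ordinal-vs-rating arbitration under nonlinearly
distorted ratings (exponent 2); 500 agents for the ambiguity-neutrality
population anchor and for recovering planted consistency targets of 0,
0.3 and 0.6 within ±0.1.

## Known limitations

* β is informed by only ~21 ambiguous value trials per unit, so its
  single-unit estimates are markedly noisier than α's; rank-level
  conclusions are robust, individual point estimates at 49 trials are not.
* The γ–α ridge means near-deterministic choosers get precise attitude
  ranks but poorly identified γ.
* The corrected ambiguity proportion is exactly neutral-calibrated only
  under the model's linear-discount reading of the occluder.
* The generator's copula couples parameters marginally; it does not model
  joint dependence between α and γ within an agent.

## A minimal run

```{r, eval = FALSE}
library(ordival)
trials <- build_trialset(seed = 0)
cohort <- simulate_cohort(cohort_spec(n_agents = 40, seed = 1), trials)
dataset <- c(list(trials = trials),
             cohort[c("choices", "ratings", "participants")])
filtered <- apply_exclusions(dataset)
modelfree <- model_free_summary(filtered$modelfree_choices, trials)
fits <- fit_cohort(c(dataset, list(choices = filtered$modeling_choices)),
                   prefiltered = TRUE)
run_consistency_suite(modelfree, fits)
```
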