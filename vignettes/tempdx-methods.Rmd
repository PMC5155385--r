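---
title: "Temporal Bayesian differential diagnosis: model and methods"
author: "tempdx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Temporal Bayesian differential diagnosis: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tempdx)
```

## Overview

`tempdx` models a class of diagnostic decision-support engines that rank
candidate diseases by Bayesian pattern matching against a curated
disease–finding knowledge base, with explicit temporal structure: every
finding in every disease carries a frequency, an onset-age interval, and
optionally a disappearance-age interval. This lets the engine exploit three
kinds of evidence that flat naive-Bayes matchers cannot: *when* a finding
appeared, *pertinent negatives* (findings examined and found absent), and
the *acuity of onset* of the illness as a whole (whether manifestations
emerged over minutes, days or years). The package also implements the
evaluation framework used to study such engines in before/after designs —
diagnostic error and relevance metrics against expert gold standards,
change classification, grouped summary tables, and a logistic GEE for the
clustered binary error outcome — together with a synthetic knowledge-base
and patient simulator so that every component is testable without any
proprietary content.

## The diagnostic model

### Knowledge base

A `KnowledgeBase` holds findings, diseases and disease–finding
associations. Each disease has an incidence profile: contiguous half-open
age bins over [0, 120) years with relative weights, and multiplicative
gender factors. Each association carries a frequency $f \in (0, 1]$, a
closed onset interval $[o_{lo}, o_{hi}]$ and optionally a disappearance
interval $[d_{lo}, d_{hi}]$, all in years of age. Ages are real-valued,
birth is 0, and patient ages are capped at 120 (the top incidence bin is
treated as closed at 120 so that boundary age is admissible).

Two curation conventions matter for inference. An association whose
frequency is explicitly near zero (e.g. 0.01) encodes "characteristically
absent"; the *absence of an association* instead means "not curated", which
the engine treats with a background rate rather than as evidence. This
distinction is why the completeness report (`completenessReport`) exposes
both the count of checklist findings with *any* association and the count
with informative frequency (> 0.05): curation audits may use either
reading. The shipped audit checklist size follows the rheumatology review
practice of a 46-item core finding list, but any checklist can be supplied.

### Priors and temporal likelihoods

For a patient of age $a$ and gender $g$, the prior weight of disease $d$ is
the incidence weight of the bin containing $a$ times the gender multiplier
(the mean of the two multipliers when gender is unspecified). Weights are
relative; the engine normalizes over diseases.

The probability that finding $i$ of disease $d$ is expressed and observable
at age $a$ is

$$ p_{d,i}(a) \;=\; f_{d,i}\; F_{on}(a)\,\bigl(1 - F_{dis}(a)\bigr), $$

where $F_{on}$ is a linear ramp from 0 to 1 across the onset interval (a
step function for a point interval) and $F_{dis}$ the analogous
disappearance ramp (identically 0 when no disappearance is curated). The
two ramps are independent linear CDFs; disappearance is *not* conditioned
on the sampled onset — the curated intervals specify marginal endpoints and
nothing more, so the simpler model is used.

Observation likelihoods, per disease:

* **present, no onset age**: $p_{d,i}(a)$;
* **present with onset age $o$**: $f_{d,i} \cdot m(o) \cdot (1 -
  F_{dis}(a))$, where $m(o)$ is the mass of the onset ramp inside the bin
  $[o - w/2,\, o + w/2]$ with bin width $w$ (default 0.25 y). A reported
  onset age is thus scored against the *density* of the onset model, which
  is what makes temporal evidence discriminating;
* **absent** (pertinent negative): $1 - p_{d,i}(a)$;
* **uncurated pair**: background frequency $f_0$ (default 0.005) plays the
  role of $p_{d,i}$; when an onset age is reported the onset is taken
  uniform over $[0, a]$, giving $f_0 \cdot \min(w/a, 1)$.

Every likelihood is floored at $\epsilon$ (default $10^{-4}$). The floor is
what keeps a single contradicted finding — a curation gap, or one of the
data-entry errors observed in practice — from vetoing a disease outright.

Findings are conditionally independent given the disease (naive Bayes); the
posterior is the normalized product, accumulated in log space, with ties in
the ranking broken lexicographically by disease id for determinism. An
observed acuity class acts as one extra categorical observation on the
log-time scale minutes–hours–days–weeks–months–years: likelihood 1.0 for an
exact class match, 0.5 for an adjacent class, 0.1 otherwise, and a neutral
1 for diseases whose acuity was never curated — missing acuity data must
not penalize a disease. Category-level results (`expandCategories`) sum
posterior mass over category members; a disease in $k$ categories
contributes to all $k$.

Defaults ($\epsilon = 10^{-4}$, $f_0 = 0.005$, $w = 0.25$ y, acuity
1.0/0.5/0.1) are package choices — the modelled engine class publishes no
such constants — and all are configurable through `engineParams()`.

### Test suggestions

`rankSuggestions` scores every unobserved finding, and every test bundle
whose members are all unobserved, by myopic one-step value of information:

$$ \textit{usefulness} \;=\; \frac{\text{expected entropy reduction (bits)}
   \times \text{urgency}}{\text{cost}}, \qquad
   \text{urgency} = 1 + w_t \textstyle\sum_d P(d)\,t_d
   + w_s \sum_d P(d)\,s_d + w_a \sum_{d\,\text{acute}} P(d), $$

with treatability $t_d$, severity $s_d$, and "acute" meaning acuity class
days or faster. Expected entropy reduction is Shannon entropy of the
current differential minus the predictive-weighted entropy after observing
the finding; for bundles the full $2^k$ outcome tree is enumerated, capped
at $k = 4$ members for tractability. Entropy being concave, the expected
reduction is nonnegative whenever the branch likelihoods and the mixture
weight are consistent; the implementation clamps per-disease presence
probabilities into $[\epsilon, 1-\epsilon]$ in this computation precisely
to preserve that consistency, and snaps gains below $10^{-12}$ bits to
exactly 0 so that non-discriminating findings report zero usefulness.
Whether deployed engines use an entropy criterion is not public; entropy is
this package's choice, and the weights $w_t = 1.0$, $w_s = 0.5$,
$w_a = 1.0$ are defaults with no claimed provenance. Findings that cannot
yet have appeared at the patient's age are still scored — as pertinent
negatives they can carry information.

## The synthetic generator

`generateKB` emulates the scale of a mature curated database: the defaults
are 5405 diseases with a mean of 22 curated findings per disease (the scale
of the deployed system the engine class models), 800 findings, frequencies
drawn Beta(2, 2) (mid-heavy, like curated often/sometimes grades), 20% of
associations with disappearance intervals, and log-normal incidence weights
creating rare-versus-common contrast. Each disease receives a peak age;
its incidence weights are shaped by a Gaussian kernel (sd 10 y) around that
peak over a fixed 13-bin age grid, and its findings' onset intervals are
anchored 1–15 y below the peak with widths drawn from
`onset_span_years` (default 0.5–8 y; the realistic distribution of
onset-interval widths is unreported anywhere, so these are explicitly
placeholder choices). About 40% of lab findings are grouped into reporting
bundles of 2–4. The fraction of findings flagged as core defaults to
0.0575, which at the default 800 findings yields an expected checklist of
46 — the size used in rheumatology curation reviews.

`simulatePatient` is the generative mirror of the engine's model: age from
the disease's incidence profile, gender from its multipliers, each curated
finding present with its frequency provided its sampled onset (uniform over
the onset interval) precedes the patient's age and its sampled
disappearance (if any) has not; onset ages are recorded, and a Poisson(2)
sample of curated-but-absent findings is recorded as pertinent negatives
(vignette negative density is unreported; Poisson(2) is a package choice).
One deliberate departure from a plain generative draw: the simulation is
rejection-sampled (up to 100 attempts) until at least one finding is
present, because the framework emulates case *vignettes* — descriptions of
patients who presented precisely because findings were observable. An
asymptomatic draw has no analogue in that setting. Determinism is
preserved: every simulator entry point consumes one explicitly seeded
stream and restores the caller's RNG state, so identical seeds give
byte-identical output.

`corruptProfile` reproduces the four data-entry error modes observed when
clinicians use such tools: onset ages dropped, findings omitted entirely,
findings misinterpreted (present/absent flipped), and spurious findings not
in the vignette entered. Each mode applies independently per observation at
its configured probability.

What passing tests on this generator do and do not show: the simulator
draws from the same family the engine assumes (independent findings, linear
ramps), so recovery results validate the inference machinery, not the
model's adequacy for real patients — real findings are correlated, curation
is biased toward the literature, and real input errors are not independent
across observations. The generator is a test bed, not a claim about
clinical data.

## Evaluation framework

A response log holds one ranked differential per tester, case and phase
(baseline vs aided). A response is a *diagnostic error* when the
differential contains neither the correct diagnosis nor any of its
categories; *relevance* is the fraction of listed diagnoses that appear in
the expert's gold differential (which lists the proven diagnosis first).
Matching is exact identifier equality after case-insensitive normalization
— no fuzzy matching, since logs use controlled tokens. Baseline/aided pairs
are classified as fixed error, added error, or unchanged;
`aggregateChanges` tabulates counts and percentages per group with
percentages rounded half-up to whole percent (82.5 → 83), matching printed
study tables. Workup lists run through the same operations, though workup
prioritization has no comparable objective gold standard.

`buildFixtureLog` inverts a printed change table: given per-group or
per-case margins (baseline, fixed, added error counts) it constructs a
deterministic 26-tester × 8-case × 2-phase log, allocating error instances
greedily in tester-id order, whose aggregation reproduces the table
exactly. The two shipped margin sets (`table4Margins()`,
`table5Margins()`) are transcriptions of the published change tables by
tester group and by case; margins are checked for internal consistency
(fixed ≤ baseline errors; baseline + added ≤ instances) before allocation.
The per-group and per-case tables are reconstructed as *separate* fixture
logs — the joint tester-by-case error layout is not published, so no single
log is claimed to satisfy both margins simultaneously.

### GEE analysis

Diagnostic error is a clustered binary outcome — 16 responses per tester —
so the phase effect is estimated by logistic generalized estimating
equations with an exchangeable working correlation: Fisher-scoring updates
of $\beta$ alternate with moment updates of the intra-cluster correlation
$\alpha$ and dispersion $\phi$ from Pearson residuals; standard errors are
robust (sandwich); each coefficient's Wald statistic
$(\hat\beta/SE)^2$ is referred to $\chi^2_1$. No GEE fitting is delegated:
the estimating equations are implemented directly (R/gee.R), with the
exchangeable $R(\alpha)^{-1}$ applied in closed form per cluster. With
$\alpha$ fixed at 0 the estimating equation is the ordinary logistic score,
which the tests exploit as an exact cross-check against `glm()`.
Non-convergence after the iteration cap, and separation (fitted
probabilities numerically 0 or 1), are reported through an explicit status
rather than silently. The published per-instance data behind the original
Wald statistics are not available, so those statistics are out of scope;
what the package validates instead is *calibration*: under a null
simulation with the study's geometry (26 clusters × 16 observations) the
Wald test rejects at the nominal 5% level within Monte Carlo error.

The design matrix is exposed rather than fixed: the primary contrast is
phase with tester as cluster, and specialty/seniority enter as ordinary
covariates or interactions at the caller's discretion, since the original
covariate set is not documented.

## Numerical and design notes

* Point onset intervals are steps; their bin mass is 1 whenever the point
  lies inside the query bin (including its boundary).
* Posterior products are accumulated in log space; underflow of *all*
  diseases raises an explicit "no admissible disease" error rather than
  returning a normalized garbage vector.
* Heritability is stored and may be curated as an ordinary boolean finding,
  but does not modify the prior — no mechanism for family-history priors is
  documented for the modelled engine class.
* Ranking ties (equal posterior, equal usefulness) break lexicographically
  by identifier, using C-locale byte order, for cross-platform determinism.
* Canonical KB serialization sorts all records by id and writes full
  numeric precision, so save→load→save is byte-identical.

## Problem sizes used in the shipped tests

The test suite validates the engine on generated knowledge bases of 8–200
diseases: the direct-product oracle comparisons use 10-disease KBs with
dyadic-rational parameters (so reference arithmetic is exact in doubles,
and the 1e-9 agreement bound is meaningful); normalization runs 1,000
random cases on a 100-disease KB; generative recovery runs 500 noise-free
simulations on a 200-disease KB, requiring the true disease in the
posterior top 5 at least 90% of the time (a package property, not a
published claim); and GEE calibration uses 500 null replicates of the
26 × 16 study geometry. `scripts/acceptance.R` recomputes the study-table
metrics and these two simulation rates from scratch at any seed.

## Known limitations

* Naive-Bayes independence of findings given disease; no interaction model.
* Disappearance is not conditioned on onset; a finding can nominally
  "disappear" during its own onset window if curated that way.
* Myopic one-step suggestion lookahead; no sequential workup planning and
  no monetary cost-effectiveness modelling.
* The engine is a faithful reconstruction of the described *inputs and
  behaviours* of temporal Bayesian diagnostic engines, not a clone of any
  proprietary likelihood algebra.
* The synthetic generator's distributional defaults (onset widths, negative
  density, bundle structure) are placeholders where no empirical values are
  published.
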