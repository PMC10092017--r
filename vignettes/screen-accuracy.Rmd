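---
title: "Evaluating gated screening items and projecting prevalence from PPV"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating gated screening items and projecting prevalence from PPV}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screenval)
```

## The design being modelled

Multi-informant diagnostic interviews used in child and adolescent
mental-health surveys open each disorder module with a handful of
screening items and a skip rule: respondents endorsing fewer items than a
threshold skip the detailed module entirely. `screenval` models the
eating-disorder variant of this design: five binary items answered by a
parent and (from age 11) by the young person, a threshold of two endorsed
items for parents and one for young people, and verification — the full
module plus clinical rating under DSM-5 and ICD-10 — administered exactly
to subjects screening positive under the *either-positive* rule (any
reporting informant above threshold).

Two features of this design drive everything in the package.

**The reference standard is conditioned on the screen.** Because
screen-negatives skip the module, no diagnosis can be observed for them;
treating them all as reference-negative yields zero false negatives for
the combined screen *by construction*. Single-informant analyses can
still show false negatives: a child's positive screen can verify a
subject whose parent screened negative. Accuracy under this routing is
therefore reported twice: as observed, and after imposing an external
false-negative rate on the screen-negative pool (see below).

**Informant combination is OR.** The published combined strata are
reproducible only under an either-positive rule — combined specificity
falls below both single informants while sensitivity is at least as
high — so `combine_screens()` adopts OR and documents it as an
assumption. Combined strata are restricted to complete dyads by default
(matching the published stratum sizes); `include_singletons = TRUE`
relaxes this.

## Accuracy measures and interval policy

From the 2x2 table, sensitivity, specificity, PPV, NPV and accuracy are
simple binomial proportions, and each is reported with a 95% interval:

* **Wald**, $p \pm z_{0.975}\sqrt{p(1-p)/n}$, truncated to $[0,1]$, for
  interior proportions;
* **Clopper–Pearson** (beta-quantile exact) at the boundary
  $k \in \{0, n\}$, where Wald collapses to a point. At $k=n$ the exact
  lower bound is $(\alpha/2)^{1/n}$ — this closed form is what lets a
  printed boundary CI identify an exact case count during back-solving.

The source tables this policy was reverse-engineered from are not fully
consistent: a few printed PPV/NPV intervals (e.g. 1.7 (1.6–1.8) for a
7/422 cell) match neither Wald, Wilson nor exact intervals, one
specificity lower bound prints 92.8 where the Wald computation gives
92.9, and one reanalysed sensitivity CI matches the exact rather than
the Wald form. The package always reports its own policy rather than
imitating such cells, and back-solve CI filters are only applied to
intervals the caller explicitly supplies.

Percentages are displayed at one decimal using *half-up* rounding
(`round_half_up()`), the convention of the source tables; base R's
round-half-to-even would disagree on exact .x5 boundaries. Full
precision is retained internally; rounding happens only at display and
when comparing against printed values.

## The false-negative scenario

An external validation of the screen (a clinical sample completing the
full module with skip rules disabled) missed 1/41 ≈ 2.4% of cases.
`apply_fn_rate()` imposes such a rate $r$ on a routed table by moving
$m = \mathrm{round}(r \cdot (tn + fn))$ subjects from TN to FN — the rate
applies to the whole screen-negative pool, and the imputed cases come on
top of any observed false negatives. This reproduces the published
reanalysis (e.g. sensitivity 100% → 36.8% for 17–19-year-olds,
66.7% → 11.8% for parents of 11–16-year-olds); applying the rate to the
true-case count instead does not. Properties guaranteed by construction
and enforced in tests: cell total conserved; TP and FP — hence PPV —
invariant; sensitivity, specificity, NPV and accuracy non-increasing in
$r$. Rounding of $m$ is half-up by default with floor/ceiling exposed
for sensitivity analysis; a rate implying $m > tn$ is rejected as
infeasible. The community-sample scenario is simply $r = 0$.

A known wrinkle: the published reanalysed NPV for the parents-of-11–16
stratum prints 97.5 where recomputation from the reconstructed cells
gives 2833/2908 = 97.4 — plausibly rounding of unrounded source cells.
The package reports the recomputed value.

## Back-solving cells from published percentages

The survey microdata are access-restricted, so the integer cells behind
a published row must be recovered from its rounded percentages.
`backsolve_cells()` searches exhaustively over non-negative integer
$(tp, fp, tn, fn)$ with total within `n_tolerance` of the printed $n$
(default 3: printed stratum sizes can include subjects excluded from the
metric denominators), keeping tables whose half-up-rounded metrics equal
every supplied printed value and whose recomputed CIs match any supplied
printed bounds. The search is pruned by deriving the $tp+fp$ range from
PPV and the $tp+fn$ range from sensitivity, and capped at $n = 10^5$;
rows with $n \approx 3000$ solve in well under a second. The result is a
set — empty and multi-solution results are legitimate outcomes, and the
round-trip property (the generating table is always among the solutions
of its own rounded report) is tested on random tables.

In practice the parents-of-11–16 row is uniquely determined only when
the printed sensitivity and PPV CIs are used as filters and the total is
held exactly at $n$; the 17–19 parents row (whose printed $n=415$
exceeds its metric denominators, 413) cannot be fully pinned down — its
feasible reconstructions differ by one or two true negatives.

## Prevalence projection onto a screen-only wave

For a wave with screening data only, `project_prevalence()` estimates
prevalence as $s \times \mathrm{PPV}/100$ with a range from the PPV's
95% CI — deliberately crude: no sampling error in $s$ is propagated, no
Rogan–Gladen-style correction is attempted, and the range should be read
as indicative. `run_study2()` applies this per stratum, mapping
parent-report PPVs to the 11–16 band and self-report PPVs to 17–19
(the only strata published for the follow-up wave). The PPV *point* is
scenario-invariant, but its printed CI is not: the default takes CI
bounds from the 2.4%-false-negative analysis, which is the only source
consistent with the published 17–19 projection limits (the zero-FN
alternative is selectable via `ppv_ci_source`). The projection inputs —
published screen-positive proportions and PPV rows — ship with the
package as `mhcyp_screen_positive()` and `mhcyp_published_metrics()`.

## The synthetic generator

Because the microdata are restricted, `generate_survey()` provides a
survey-like stand-in with the structure the pipeline assumes: a latent
disorder of low prevalence; five conditionally independent Bernoulli
items per informant with status-specific endorsement probabilities
(scalars or per-item vectors — the verbatim item content is not public,
so items are anonymous indicators); informant availability drawn
independently; routing-faithful verification; and a reference standard
that misses a verified true case with probability `ref_fn_rate` (0
community / 0.024 clinical). Both classification systems are simulated
as rating the same cases, the behaviour reported for the older band.
Subjects drawn with no informant at all are dropped, since such subjects
cannot appear in a survey file.

The default configuration targets the 2017 operating point, chosen once
from the published margins: band sizes 3118 and 937 (the union sizes
implied by the published stratum counts, ~4055 subjects in all),
prevalence 0.6%/0.8%, informant availability matching 3112 parents /
2597 children / 2591 dyads in the younger band, and control endorsement
probabilities solved from the binomial tail to hit screen-positive rates
of ~6.5% (parents), ~34% (children 11–16) and ~45% (self-report 17–19).
Case endorsement probabilities are plausible round values (no item-level
case marginals are published). What the generator deliberately does
*not* emulate: informant correlation given status (a reserved
configuration slot errors if nonzero), item heterogeneity in the default
config, survey weights and clustering, and system-discordant clinical
ratings. Passing tests on synthetic data therefore validate the
*pipeline arithmetic and routing logic*, not the screen's real-world
operating characteristics.

`closed_form_metrics()` is the generator's analytic counterpart:
per-informant positivity is the Poisson-binomial tail
$P(\text{endorsed} \ge \tau \mid \text{status})$, combination uses
conditional independence, and PPV/NPV follow from Bayes' rule at the
band's prevalence. It describes accuracy against the *latent status*
under complete verification, which is why parameter-recovery tests run
the generator with `verification = "complete"` — under routing, the
verified-case subset is conditioned on the screen itself and combined
sensitivity is 1 by design (a property tested separately).

## Numerical and testing choices

* Monte-Carlo recovery tests compare estimates to the closed form within
  four binomial standard errors plus a $2/n$ discreteness allowance,
  with item probabilities drawn from interior ranges so no expected
  proportion sits against a boundary; 20 random configurations at
  $10^5$ subjects in the deepest suite, four at $2 \times 10^4$ in the
  unit suite.
* Confusion tables are verified against an independent per-subject loop
  tally on random record sets across every informant mode, threshold
  variant and classification system.
* Missing items score as "no" (conservative toward screen-negative);
  `strict = TRUE` rejects incomplete responses instead. An absent
  informant is an absent file row, never a row of blanks, keeping
  "not asked" distinct from "item skipped".
* I/O round-trips byte-identically; generation is reproducible from a
  single integer seed.

## Limitations

The projection inherits every caveat of its inputs: published
proportions rather than raw data, no uncertainty in the screen-positive
proportion, PPVs transported across waves and (for 17–19-year-olds)
across reporting informants. The back-solver recovers cells only up to
what rounding left identifiable. The generator's independence
assumptions make its data cleaner than real dyads, in which informant
agreement is notoriously partial; results on synthetic data should be
read as software verification, not as evidence about the instrument.
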