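---
title: "Component-stratified signal detection: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Component-stratified signal detection: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adcvigil)
```

This vignette is the package's account of its statistical machinery: what
each stage assumes, which tunable parameters matter, what the synthetic
generator does and does not emulate, and where the design was genuinely
open and a choice had to be made.

## The analysis in one paragraph

Spontaneous adverse-event reports are deduplicated to one record per case,
suspect drugs are annotated with the structural component classes of the
antibody–drug conjugates (ADCs) they belong to, and for every stratum
(single drug, antibody subtype, linker type, payload category, or DAR
class) and every event a 2×2 table is counted at report level. Four
disproportionality statistics — ROR, PRR, IC, and EBGM — are computed per
table, each with its canonical positivity criterion, and only pairs that
pass **all four simultaneously** are consensus signals. Consensus signals
are ranked by ROR within each stratum (top 20 = "strong"); a
Fisher-exact/Benjamini–Hochberg layer then checks that consensus signals
are not artifacts of multiple testing.

The disproportionality model treats reports as exchangeable draws from a
large reporting population: cell `a` is approximately Poisson with mean
λ·E, where E = (a+b)(a+c)/N is the count expected under independence of
exposure and event, and λ is the relative reporting rate that all four
statistics estimate on different scales. None of this is causal; a signal
is a reporting disproportion, nothing more.

## Estimators and their thresholds

The per-method defaults in `algorithm_config()` are the published
criteria in long-standing pharmacovigilance use, and every one of them is
overridable:

| method | statistic | default flag |
|--------|-----------|--------------|
| ROR | (a·d)/(b·c), Wald CI on the log scale | a ≥ 3 and CI lower bound > 1 |
| PRR | [a/(a+b)]/[c/(c+d)] with Pearson χ² | a ≥ 3, PRR ≥ 2, χ² ≥ 4 |
| IC  | log₂((a+½)/(E+½)) | IC025 > 0 |
| EBGM | posterior geometric mean of λ | EB05 > 2 |

Three choices deserve comment.

**IC variant.** The information component is implemented in its
additive-shrinkage closed form, IC = log₂((a+s)/(E+s)) with s = ½ and a
Gamma(a+s, E+s) posterior for the credible bound. The original Bayesian
confidence propagation formulation with four beta-binomial priors gives
nearly identical values at database scale but is iterative and
implementation-sensitive; the closed form is deterministic, used by
regulatory groups, and exactly testable against its own posterior (the
package cross-checks IC025 against Monte-Carlo quantiles of the stated
gamma at 10⁶ draws).

**χ² without Yates correction.** The PRR ≥ 2 / χ² ≥ 4 rule was defined on
the uncorrected Pearson statistic; Yates is available via
`algorithm_config(yates = TRUE)` but off by default.

**EBGM prior scope.** The two-component gamma mixture prior is fitted
*once* on the tables of every suspect drug in the collection (study ADCs
and background drugs alike) and reused across component strata. This
mirrors a database-wide shrinkage model: the prior describes how relative
reporting rates vary across the whole database, not within one stratum.
Per-stratum refitting is possible by passing a different `prior` to
`detect_signals()`.

The prior is fitted by direct numerical maximisation of the marginal
likelihood (each count is marginally a two-component negative-binomial
mixture) using Nelder–Mead on log/logit-transformed hyperparameters,
relative tolerance 10⁻⁸. Degenerate simplexes are restarted from the last
iterate; genuine non-convergence is an error carrying the last iterate,
never a silent fallback. With fewer than 50 usable tables the configured
default prior (0.2, 0.1, 2, 4, P = ⅓) is returned with a warning. EB05 is
found by monotone bisection on the posterior mixture CDF, bracket
[10⁻⁸, 10·max(a/E, prior mean)] with self-extension, relative tolerance
10⁻¹⁰; parameter-recovery simulations (10⁵ tables from a known
single-gamma truth) recover the prior mean within 10%.

## Counting rules

- **Unit.** One deduplicated report counts once per (stratum, event) pair
  regardless of how often a PT is listed. The "PT-level event" tally
  (distinct report × PT pairs) is reported separately by
  `descriptive_tallies()` because the two units are easy to conflate:
  a collection has both a report count and a several-fold larger PT-level
  event count, and published accounts sometimes switch between them.
- **Exposure.** Primary and secondary suspect roles count as exposure;
  concomitant and interacting drugs are background. This is the
  conservative pharmacovigilance default where sources are silent.
- **Comparator.** The default comparator is *all other reports in the
  collection*, including reports of other ADC classes — the common
  full-background convention that keeps N constant across strata. The
  alternative, restricting the background to ADC reports only
  (`comparator = "adc_only"`), sharpens class contrasts but shrinks N and
  changes E; it is a config switch, not a default.
- **Zero cells.** Tables with a = 0 are kept (they can never be signals);
  no continuity correction is applied at the counting stage — corrections
  belong to the estimators.
- **Dedup rule.** One record per case: greatest case version, ties broken
  by latest receipt date. The rule is idempotent and order-independent,
  which the tests assert by permutation.
- **DAR boundaries.** `lt3`: DAR < 3; `3to5`: 3 ≤ DAR ≤ 5 (closed
  interval); `gt5`: DAR > 5. The printed class labels are ambiguous at
  the boundaries; the closed middle interval matches the labels "<3,
  3–5, >5" while keeping the classes disjoint and exhaustive.

## The sensitivity layer

Fisher's exact p-value uses the two-sided point-probability method (the
sum of hypergeometric outcomes no more probable than the observed table),
which matches the default of standard statistical libraries and is
verified against full enumeration for every table with N ≤ 40.
Benjamini–Hochberg is applied over all pairs *within one stratification
scheme* — all antibody-stratum pairs together, say — because that is the
narrowest family consistent with testing every component-type/event
combination; a global family across schemes would mix hypotheses of
different granularity. Significance is the strict inequality q < 0.05.
The concordance report (Jaccard index between the consensus set and its
FDR-significant subset) is the robustness summary: 1 means no consensus
signal was lost to multiple-testing adjustment.

## What the generator emulates — and what it does not

`simulate_reports()` draws, per case: one suspect drug (a study ADC with
probability 0.3, uniform over the 13 included ADCs, else one of 25
background drugs), a truncated-Poisson(λ = 3, ≥ 1) number of distinct
events from a Zipf(s = 1) background frequency law, demographics from
fixed marginals (54.9% female, 79.4% serious, 76.4% healthcare-
professional reporters, country mix led by the US at 36.5%), onset times
exponential with median 26 days, 63% of onset dates blanked and 2% made
implausible (event before therapy start), and 5% of cases re-emitted as a
later case version. These defaults are the study conditions: they mirror
the marginal structure reported for ADC-related spontaneous reports,
including the high onset-date missingness that real FAERS data show.
Planted effects multiply the sampling weight of chosen (target, PT) pairs
by a relative reporting rate ≥ 1, where the target may be a drug or a
whole component class (expanded to member drugs).

Deliberately **not** modelled: reporting biases (notoriety, masking,
competition), time-varying reporting rates, multi-drug cases in the main
generator (single exposure keeps ground-truth cells analytically
computable; multi-drug handling is exercised by dedicated fixtures),
country-specific reporting cultures, and any dependence between
demographics and events. Passing tests therefore demonstrate that the
*estimators and the consensus logic* behave correctly under a clean
multiplicative-disproportionality model — they do not certify performance
under the confounding structure of real FAERS data.

One stated generator design choice is not implemented literally:
per-case counter-derived RNG streams (useful for permutation-stable
parallel generation) are unnecessary in a fully vectorised sequential
generator, so a single seed governs the whole draw; identical seed and
configuration give byte-identical output, which the tests assert at file
level.

## Numerical and formatting choices

- Undefined statistics propagate as explicit `NA` markers (ROR with a
  zero cell other than a, IC/EBGM at E = 0), never as silent zeros; an
  undefined flag always disqualifies a pair from consensus.
- Percentages use half-up rounding at two decimals, matching printed
  tables; base `round()` half-even would differ at exact halves.
- Quantiles (onset time, age) interpolate linearly between order
  statistics (type 7), the common default; the choice is config-visible
  because published tables rarely state one.
- Age bins: <18, 18–64 (18 ≤ age < 65), 65–85 (closed), >85, plus
  unspecified — chosen to make the printed bin labels disjoint and
  exhaustive at the ambiguous 65 and 85 boundaries.
- Ties in ROR ranking break by larger a, then event name, making
  strong-signal lists permutation-stable.

## Problem sizes used by the test-suite and acceptance script

The suite's calibration studies use 200 null datasets of 5,000 cases for
consensus conservatism and false-discovery control, 50 seeds of 4,000
cases with one planted effect (relative reporting rate 20, expected
exposed-event count well above 10) for sensitivity, and 10⁵ tables for
prior recovery; the acceptance script reruns the same designs at 100 null
replicates and 25 planted seeds. These sizes give Monte-Carlo error
comfortably below the asserted margins while keeping a full run in the
minutes range on one CPU.

## Known limitations

Signals are reporting disproportions in a spontaneous-report system:
no denominators, no causality. The component classes of marketed ADCs are
strongly confounded with one another (payload class tracks linker and
antibody choices), so stratified signals must be read as descriptive
contrasts, not component effects. Small strata produce unstable RORs with
very wide intervals; the consensus criterion suppresses most of these but
the `prr_unstable` marker should still be checked. Finally, baseline
tables printed in source literature occasionally contain internal
inconsistencies (an identical association statistic printed for two
different variables; a pooled median outside the range of its subgroup
medians); the package always recomputes such quantities from counts and
reports its own oracle-checked values rather than reproducing printed
ones.
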