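---
title: "Scoring the content validity of PRO measures against the ICF"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring the content validity of PRO measures against the ICF}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(covalid)
```

## The problem

Whether a patient-reported outcome (PRO) questionnaire is *content valid* for
a population is a question about coverage: do its items reflect the issues
that population actually experiences? `covalid` operationalizes this for
brain-tumor populations in three stages built on the WHO ICF framework: a
relevance survey derived from the ICF category catalog, rated by patients,
proxies and healthcare professionals (HCPs); patient–proxy agreement on those
ratings; and a coverage score for each PRO instrument whose items have been
linked (by trained human raters, upstream of this package) to ICF categories.

## Survey construction ledger

The ICF catalog is reduced to survey items by a disposition ledger. Each
examined category is marked `not_specific`, `too_difficult`, `standalone`, or
`combined` (with a group id); (sub)headings and child-only categories are
excluded before these decisions and may be supplied either as explicit catalog
rows or as a single annotation count — the ICF tree itself is not shipped, so
the package never tries to derive that exclusion structurally, and because
published ledgers report only the combined heading + child count, the
annotation stores one number. `build_survey_ledger()` enforces the identities

* eligible = examined − heading/child − not_specific − too_difficult,
* eligible = standalone + combined categories,
* survey items = standalone + combined groups,

and the default synthetic catalog reproduces the study-scale ledger: 1031
categories, 198 heading/child exclusions, 320 not specific, 5 too difficult,
63 standalone and 445 categories combined into 85 items, i.e. 833 examined,
508 eligible and 148 survey items. Combining is a partition: a category
belongs to at most one item, so the code→item map is single-valued and
duplicate ownership is a load-time error, not a warning.

## Relevance rules

Scores are 0–3; "not applicable" and score 0 are a single state, mirroring
the survey instruction to answer "not at all relevant" when an item does not
apply. Dichotomization is `main` (1–3 = issue) or `sensitivity` (2–3 =
issue); because the sensitivity issue-score set is a subset of the main one,
per-item fractions under `sensitivity` can never exceed those under `main`,
and the sensitivity relevant set is nested in the main one — both are tested
as properties.

Fractions use available-case denominators: missing scores propagate through
`dichotomize()` and are excluded per item, so each item/group pair has its own
n. An item with zero available cases in a group raises an explicit error
rather than silently producing 0/0.

The decision rule is an inclusive OR: relevant iff patient fraction ≥ 25%, or
proxy fraction ≥ 25%, or HCP fraction ≥ 50%. Two numerical choices are
deliberate:

* **Thresholds are compared on exact fractions**, not display-rounded
  percentages. Rounding first would make the decision depend on the display
  convention (e.g. 24.96% printing as "25.0" would flip an item). Percent
  columns in reports are rounded to one decimal for display only.
* **The open-ended 5% rule** divides an uncovered issue's reporter count by
  the size of the reporting group. Published counts of the form "5 (4.3%)"
  are ambiguous about the denominator (5/114 = 4.4%, 5/117 = 4.3%); the
  reporting-group size is the defensible choice and the threshold is a
  parameter of `open_ended_rule()` for anyone preferring another convention.

## Patient–proxy agreement

For each item the dyad cross-tab is built available-case: a dyad contributes
only where both members answered, so n varies by item. Kappa is

κ = (p_o − p_e) / (1 − p_e), with p_o = Σ w_ij o_ij / n and
p_e = Σ w_ij r_i c_j / n²,

computed on the raw 4-level scale with weights, or unweighted (identity
weights) on the dichotomized scale. The weighted scheme **defaults to linear**
(w_ij = 1 − |i−j|/3) with a quadratic option; published analyses of this
design rarely state their scheme, so every result carries a `scheme` label and
the two are never conflated. For 2×2 tables linear (and quadratic) weights
reduce exactly to unweighted kappa.

Inference uses the Fleiss–Cohen–Everitt large-sample variance of κ̂ under the
null hypothesis of chance agreement, giving a two-sided z-test at α = 0.05 —
the convention used when flagging non-significant kappas in published item
tables. When both raters are constant on the same category, p_e = 1 and kappa
is returned as an explicit undefined state (`undefined = TRUE`, `kappa = NA`),
never coerced to 0. Interpretation bands are left-closed: [0.41, 0.61)
moderate, [0.61, 0.81) substantial, [0.81, 1] excellent; κ = 1 is assigned to
excellent although verbal band definitions often stop at 0.99.

## Content coverage

Each instrument item decomposes into 1–4 aspects; an aspect is relevant iff it
links to an ICF code owned by a relevant survey item. Flagged aspects
(not definable / not covered / personal factor / health condition) are never
relevant, but **they stay in the denominators** of analyses B ("≥50% of
aspects relevant", inclusive, so a 1-of-2 item passes B) and C ("all aspects
relevant"). Excluding flags would inflate coverage of vaguely-worded
instruments; the relevant-set membership of a flag is unambiguous (it has no
ICF content), so it counts as a present-but-irrelevant aspect. Stringency is
then monotone by construction — item relevance under C implies B implies A —
and the sufficient-band fraction can only shrink from A to C, which the
acceptance suite verifies on 1,000 synthetic instruments.

Coverage bands are low [0, 50), moderate [50, 80), sufficient [80, 100] in
percent: the apparent gap between "79.9" and "80.0" in verbal definitions is
closed by treating the boundaries as half-open intervals on the exact
fraction, and banding precedes display rounding.

## Synthetic data: what it emulates, and what it does not

All generators hang off one root seed; `simulate_study()` splits it into
per-generator child seeds (`split_seed()`), so a single integer reproduces the
whole study byte-for-byte. Default sizes mirror the study scale: 148 items,
114 patients / 71 proxies / 65 HCPs, 67 dyads, 209 instruments — seconds-scale
to generate and analyse.

* **Responses**: per item and group, an issue probability is drawn from a
  two-point set — 0.10 / 0.40 for patients and proxies (around the 25%
  threshold), 0.35 / 0.65 for HCPs (around the 50% threshold). The 0.15
  margin keeps every planted probability well clear of its threshold: at
  n = 200 per group the binomial probability of an empirical fraction
  crossing a threshold 0.15 away is below 1e-10 per item/group, so exact
  recovery of the planted relevant set in ≥99/100 replicates is an
  achievable, meaningful bar (at a 0.10 margin the per-replicate crossing
  odds across 148 items × 3 groups are no longer negligible). Issue mass is
  split 50/30/20 over scores 1–3, so the sensitivity-rule fraction is half
  the main-rule fraction by design. Missingness is 3% completely at random.
* **Dyads**: a patient marginal and a proxy transition matrix define the
  joint p_ij = m_i T_ij, from which expected kappa follows in closed form for
  any weight scheme. The default plants κ = 0.5 on the dichotomized scale
  (marginal (½, ½), transition rows (¾, ¼)/(¼, ¾)).
* **Linkings**: aspects are flagged with probability 0.1, otherwise link to a
  relevant-item code with probability 0.6; items have 1–4 aspects with
  probabilities (0.60, 0.25, 0.10, 0.05). Expected per-instrument coverage
  under A/B/C is computed by exact binomial enumeration over the aspect
  pattern and returned with the table.

The generator does **not** emulate several features of real survey data:
item-to-item correlation within respondents (real symptom clusters
co-occur), informative missingness (sicker patients skip more items),
rater-group differences beyond marginal issue rates, clinical covariates, or
the semantic structure of real instruments (aspects are exchangeable here).
Passing tests therefore demonstrate that the *rules and estimators* are
implemented correctly and recover planted truth under clean conditions — they
say nothing about, e.g., kappa's behavior under differential missingness.

## Problem sizes and test design

The test and acceptance suites run at sizes chosen for tight feedback loops:
1,000 random 4×4 tables for the kappa oracle-equivalence check, 1,000
synthetic instruments for stringency monotonicity, 100 replicates at
n = 200/group for relevance recovery, and 200 replicates of 1,000 dyads for
kappa recovery (mean within ±0.02 of the planted 0.5). Independent oracles are
kept deliberately naive: kappa via explicit double loops over the formula (and
`e1071::classAgreement` as an external reference for the unweighted case),
item-relevance rules via literal `any`/`mean`/`all` evaluation, expected
coverage via enumeration of all 2^k aspect patterns.

## Known limitations

* The package stores and scores ICF linkings; it cannot produce them. The
  human linking step (and its reliability) is out of scope.
* Reported headline coverage splits of any particular study are reproducible
  only with that study's raw responses and linking tables; the bundled
  percentage table supports the relevance worked example, not the kappa or
  coverage results, whose raw inputs are unpublished.
* Multi-rater agreement (Fleiss kappa, ICC) is not implemented; the design is
  strictly dyadic.
* The bundled table transcribes published display-rounded percentages, so
  analyses on it inherit one-decimal precision.
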