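---
title: "Profile polling for child stunting: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profile polling for child stunting: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Linear growth faltering in children under five — stunting, a height-for-age
z-score (HAZ) more than two standard deviations below the WHO reference
median — is the standard marker of chronic undernutrition. National surveys
in the DHS family record HAZ together with household covariates and a
sampling weight per child. Beyond *how many* children are stunted, policy
targeting needs to know *which households* they live in: a compact,
interpretable description of the typical stunted child's household.

`profilepoll` answers that with "polling", a maximum-likelihood profile
analysis over empirical conditional distributions. A **profile** is a
conjunction of one category value per variable in a chosen covariate subset
(e.g. *rural residence, mother without schooling, child over one year, home
delivery*). No regression model is fit; everything is a ratio of weighted
counts, which keeps the method fully nonparametric and the output directly
readable as "X% of stunted children look like this".

## The statistics

Write $w_s$ for the sampling weight of child $s$, $g_s \in \{0,1\}$ for the
binary stunting outcome and $c_s$ for the child's profile over the chosen
variable subset. The weighted empirical joint mass of a cell is

$$ m_{gc} = \sum_{s:\, g_s = g,\, c_s = c} w_s, $$

the conditional frequency of the outcome given a profile is

$$ P(g \mid c) = \frac{m_{gc}}{\sum_{g'} m_{g'c}}, $$

and for the outcome group $g$ (the stunted children) with total mass
$m_g = \sum_c m_{gc}$:

* **coverage** of a profile is $m_{gc} / m_g$ — the share of the stunted
  group's mass accounted for by that profile;
* the **winner** $c^*$ is the top-ranked profile and the **runner-up**
  $c^{**}$ the second, under one of two conventions (below);
* the **edge** is the ratio of the winner's ranking criterion to the
  runner-up's — confidence that the winner really is first. By
  construction edge $\ge 1$, with equality exactly at a tie.

Because every reported statistic is a ratio of weighted sums, all results
are invariant to a global rescaling of the weights and to record order;
the test suite asserts both at $10^{-12}$. For the same reason the
occasionally-seen normalization of cell mass by the cell count cancels
everywhere and is not applied.

### Two ranking conventions

The literal winner of a maximum-likelihood prediction is
$c^* = \arg\max_c P(g \mid c)$ (`convention = "conditional-rank"`): the
profile whose members are most *likely* to be stunted. Narrative summaries
of this style of analysis, however, describe the winner by the share of all
stunted children it covers, which is ranking by $m_{gc}$
(`convention = "coverage-rank"`). Both are implemented behind one flag and
each result records which was used. **Coverage-rank is the default**: the
selection criteria for the best profile list coverage first, and a
coverage-ranked winner is the one a targeting policy can act on. Under
either convention the reported coverage is always $m_{gc^*}/m_g$ with the
denominator over *all* observed profiles, not only qualifying ones.

### Support threshold

Without a support floor, a profile observed on a single stunted child has
$P(g\mid c) = 1$ and trivially wins under conditional ranking. `min_cell`
(default 25 unweighted records in the winning cell, configurable) excludes
such cells from the winner/runner-up competition while leaving them in the
coverage denominator. The default is a conventional minimum-cell-size rule
for survey cross-tabulations, not an estimate from data.

### Ties and determinism

Ties on the ranking criterion are broken lexicographically on the coded
category values (codebook order), and flagged. Subsets within a search are
ranked coverage-then-edge by default (edge-then-coverage and
$\text{coverage}\times\log(\text{edge})$ are available), with the
enumeration order of subsets as the final tie-break. Two runs on the same
data and configuration therefore serialize byte-identically — asserted in
the suite.

## The pipeline

1. **Ingest** (`load_children_table`): delimited text with a column map;
   children over 59 months are excluded, non-positive weights rejected with
   a count, missing HAZ retained but flagged. Delimited text (not a binary
   survey file format) is the canonical input so fixtures stay
   human-auditable; mapping from a native survey extract is the user's
   one-line export step.
2. **Codings** (`apply_standard_codings`): child age band cut *strictly
   above* 12 months (a child of exactly 12 months is "≤ 1y", matching the
   label "older than one year"); education 0 / 1–5 / ≥ 6 completed years →
   none / primary / secondary+ (the standard DHS-style cut, since only the
   labels are conventional); WHO BMI cuts 18.5 and 25.0 kg/m²; mother's
   height at 145 cm; mother's age at birth at 20 and 35 years; both a
   national and an optional rural/urban-specific wealth quintile coding are
   supported — they are alternative codings of one construct, so only one
   should enter a given candidate set.
3. **Missing data**: per-analysis complete cases — each screening or
   polling run deletes listwise on exactly the variables it uses, so each
   of the (typically 462) subset analyses keeps its own maximal sample.
   Global listwise deletion would discard records missing variables that a
   given subset never touches.
4. **Prevalence** (`weighted_prevalence`, `district_banding`): severity
   classes use strict thresholds (HAZ exactly −2 or −3 falls in the less
   severe class, matching the "HAZ < −2 SD" definition); severe + moderate
   = total to $10^{-12}$ per stratum. District bands are
   $[0, 0.30]$, $(0.30, 0.40)$, $[0.40, 0.50)$, $[0.50, 1]$ — the outer
   bands inclusive as their labels ("≤ 30%", "≥ 50%") demand, the interior
   boundaries half-open so every value has exactly one band.
5. **Screening** (`screen_variable`): weighted prevalence per category plus
   one Pearson chi-square per variable, computed on the weighted 2×K table
   rescaled to the unweighted n. No design-based (Rao–Scott-type)
   correction is applied: the screening is a descriptive gate on candidate
   covariates, not an inferential endpoint, and with unit weights the
   statistic is exactly the textbook Pearson value (asserted against a
   brute-force oracle at $10^{-10}$). Inclusion is policy-driven on top of
   the p-threshold: variables can be forced in (e.g. a family-planning
   proxy kept for programme relevance) or out. The stratifier (division)
   is excluded from the candidate set by default because polling runs
   within strata — with eleven remaining candidates, the 5-variable search
   is exactly $\binom{11}{5} = 462$ analyses.
6. **Search** (`run_search`): exhaustive over all subsets — at this scale
   (hundreds of subsets × strata of a few thousand records, grouped by
   mixed-radix integer keys) a full enumeration takes seconds, so no greedy
   heuristic is justified. "All permutations of 5 variables" is read as
   unordered subsets: profiles are order-free conjunctions, and the
   combination count matches the printed 462 while the permutation count
   does not. Each stratum selects its own winning subset; the national row
   is computed independently on the pooled data; division labels are
   data-driven (no hard-coded list), so survey rounds with different
   division sets compare gracefully — a stratum absent in one round is
   reported "not comparable" by `compare_surveys`.

## The synthetic generator

`generate_children` emulates the *shape* of a children's-recode extract —
categorical covariates with configurable marginals (optional positive
pairwise dependence through a shared-latent-uniform mixture), mean-one
lognormal sampling weights (log-sd 0.5, the order of variability typical of
two-stage designs; or constant), clusters nested in districts nested in
divisions, MCAR missingness per covariate — with a known ground truth:
planted profiles multiply the baseline stunting *odds* (logistic model) for
records matching all their values. HAZ is drawn conditionally on the
resulting indicator (severe with probability `severe_fraction`, default
1/3 of the stunted, on $[-5,-3)$; moderate on $[-3,-2)$; not stunted on
$[-2,2]$) rather than from an anthropometric model: the pipeline only ever
thresholds HAZ, so matching the threshold semantics is the property the
generator must guarantee, and it keeps the generator transparent. The same
spec and seed always produce the identical dataset, and a spec differing
only in planted effects reuses the same underlying draws, so planted-effect
coverage is monotone in the multiplier replicate by replicate.

Default marginals are an illustrative early-survey-round Bangladesh-like
composition (three-quarters rural, ~82% home delivery, 55% of mothers with
no schooling, 16% of mothers under 145 cm, 36% baseline stunting); they are
design choices for simulation, **not** estimates from any survey, and no
attempt is made to match real joint distributions or spatial
autocorrelation beyond the cluster labels.

The default planted profile — rural residence, child over one year, home
delivery, mother without schooling, mother ≥ 145 cm, odds multiplier 3 —
places every value on the modal category of its variable. That is a
deliberate identifiability choice: under coverage ranking a winning profile
is necessarily a high-mass one, so a recoverable planted truth must
dominate in mass as well as in risk. With these marginals the planted cell
is the population-level maximum-coverage cell among stunted children
(verifiable in closed form under the independence design), which makes
"does the search recover the planted subset and values?" a well-posed
test. It also mirrors the substantive finding this method is known for:
winning profiles are conjunctions of *prevalent* risk categories, not of
the rarest/highest-relative-risk ones. A planted profile on minority
categories would be recovered by conditional ranking but not, in general,
by coverage ranking — that is a property of the estimand, not a defect of
the search.

## What the tests do and do not show

The suite validates the machinery, not any substantive claim about real
surveys: exact agreement of the polling core with an independent
brute-force dictionary oracle on randomized datasets (50 seeds, both
conventions); the normalization ($\sum_g P(g\mid c) = 1$) and partition
($\sum_c m_{gc}/m_g = 1$) identities at $10^{-12}$; recovery of the planted
5-variable profile in ≥ 90% of 20 replicates at n = 5{,}000 and multiplier
3; order/scale invariance; prevalence conservation; and byte-identical
serialization. Problem sizes in the suite (n up to 20{,}000 for the
single-poll consistency check, n = 5{,}000 × 20 seeds for full-search
recovery, 200 replicates for the screening type-I check) were chosen as the
smallest at which the binomial/sampling error bounds in the assertions are
comfortably away from their thresholds. Real survey data differ in ways
the generator does not emulate — informative weights, real joint dependence
among covariates, spatial structure, non-MCAR missingness — so green tests
certify the implementation, not robustness to those features.

## Known limitations

* No design-based variance estimation or confidence intervals: coverage and
  edge are reported as point values, and the screening chi-square ignores
  the two-stage design.
* HAZ is consumed, never recomputed from raw height/age against WHO growth
  standards.
* Coverage/edge have no smoothing; in very small strata the ranking can be
  noisy, which is why the unweighted n and the `min_cell` rule are always
  reported alongside.
* Native binary survey-file reading (e.g. Stata) is out of scope; export to
  CSV/TSV first.
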