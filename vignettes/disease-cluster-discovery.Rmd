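---
title: "Discovering disease clusters after an index diagnosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering disease clusters after an index diagnosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Patients who receive a first diagnosis of a condition such as an anxiety or
stress-related disorder often accumulate further medical conditions over the
following years, and those conditions are not scattered at random: they
co-occur in groups and tend to arrive in a preferred order.  `comorbclust`
implements a reusable pipeline that makes this structure explicit.  Starting
from person-level registry tables (one row per person, one row per dated
ICD-10 3-character diagnosis), it

1. builds a matched cohort around the index diagnosis (incidence-density
   sampling of unexposed controls, matched on sex and birth year);
2. screens every candidate condition for a positive association with the
   exposure (a PheWAS of stratified Cox models with FDR control);
3. quantifies the comorbidity strength of every pair of associated
   conditions with relative-risk and phi-correlation statistics;
4. confirms pairwise association by logistic regression, assembles the
   comorbidity network, and partitions it into modules with the Louvain
   algorithm;
5. orients pairs in time (binomial tests on first-diagnosis dates, then
   nested case-control conditional logistic regression) and assembles the
   disease trajectory with its first layer D1;
6. intersects the two views — trajectory descendants of D1 roots that lie
   in the roots' comorbidity module — into disease clusters, and scores
   every exposed patient by the number of distinct cluster members they
   accumulate (the susceptibility score).

Because the registries this design targets are access-protected, the package
also ships a synthetic registry generator with planted cluster structure, so
that every stage of the pipeline is testable against a known ground truth.

## The statistics

### Pair comorbidity strength

For a disease pair (D1, D2) a *sub-cohort* is formed from the exposed
patients with neither code on record before their follow-up start.  With
$C_i$, $C_j$ the numbers of sub-cohort patients acquiring each disease
during follow-up, $C_{ij}$ the number acquiring both and $N_{ij}$ the
sub-cohort size, the pair statistics are

$$RR_{ij} = \frac{C_{ij}\,N_{ij}}{C_i\,C_j},\qquad
\Phi_{ij} = \frac{C_{ij}N_{ij} - C_iC_j}
                 {\sqrt{C_iC_j\,(N_{ij}-C_i)(N_{ij}-C_j)}},$$

with large-sample z statistics

$$z^{RR}_{ij} = \frac{\ln RR_{ij}}
  {\sqrt{\tfrac{1}{C_{ij}} - \tfrac{1}{N_{ij}}
         + \tfrac{1}{C_iC_j/N_{ij}} - \tfrac{1}{N_{ij}}}},\qquad
z^{\Phi}_{ij} = \frac{\Phi_{ij}\sqrt{\max(C_{ij}, C_j) - 2}}
                     {\sqrt{1 - \Phi_{ij}^2}}.$$

$\Phi_{ij}$ is identically the Pearson correlation of the two per-person
binary disease indicators, and $\mathrm{sign}(\Phi_{ij}) =
\mathrm{sign}(RR_{ij}-1)$ for every defined table; both identities are
enforced by oracle tests.  Two points deserve comment:

* the $\max(C_{ij}, C_j)$ term in $z^{\Phi}$ is asymmetric in the pair
  order.  It is implemented exactly as stated, because silently
  "correcting" it to the symmetric $\max(C_i, C_j)$ would change results;
  the symmetric variant is available via `phi_max_rule = "symmetric"`.
* p-values are two-sided normal.  A pair is *retained* when $RR > 1$,
  $\Phi > 0$, and the Benjamini–Hochberg q-values of **both** z tests fall
  below `alpha`.  Requiring both is the conservative reading of a
  threshold stated without naming the test; `q_rule` offers `either`,
  `rr_only` and `phi_only`.

### Screening, confirmation, orientation

The PheWAS stage fits one Cox model per condition on the time scale of
days since follow-up start, stratified by matched-set id.  Set
stratification is sharper than stratifying by the sex-by-birth-year
cross-classification (the sets were constructed within those strata) and is
the package default; `strata_by = "sex_year"` restores the coarser choice.
Persons with the condition on record before follow-up start are excluded
from that condition's risk set.  Ties use the Breslow approximation
(`ties = "efron"` is available).  A model with zero events in either arm is
flagged non-estimable and leaves the FDR family.

Non-temporal edges are confirmed by logistic regression of "D2 during
follow-up" on "D1 during follow-up" within the pair sub-cohort of exposed
patients, adjusted for sex and birth year.  The network stage describes
comorbidity *among patients*, so controls do not enter by default.  Edge
weights are $\ln OR$ — positive for every confirmed edge — and the Louvain
search runs `n_restarts` times (default 20) at resolution 1, keeping the
partition with the highest modularity, which makes the partition a
deterministic function of (graph, seed, restarts).

Temporal orientation compares first-diagnosis dates among sub-cohort
patients with both conditions.  Same-day pairs carry no information and are
excluded as ties.  The two-sided exact binomial p-value is BH-adjusted
across pairs and an orientation is only assigned below `direction_alpha`
(default 0.05); setting it to `NULL` orients every untied majority.  Each
oriented pair is then re-estimated with a nested case-control design: each
D2 case is matched at its first D2 date to at most two sub-cohort members
of the same sex and birth year who are in follow-up and D2-free on that
date (a later case may serve as an earlier control), with D1 strictly
before the case date as the exposure, and a conditional logistic model on
the matched sets.  Edges with $OR > 1$ and $q < 0.05$ form the trajectory.

### Clusters and scores

The first layer D1 is the set of trajectory nodes with in-degree zero —
conditions with no upstream disease, i.e. those listed immediately after
the index diagnosis.  The definition is operational rather than visual;
cycles (which would make "no upstream" ambiguous) are detected and
reported, never silently broken, and by construction cannot enter D1.
Clusters are built per module: the module's D1 roots plus every trajectory
descendant of those roots carrying the same module id.  Reachability is
computed on the full directed graph — the module filters *membership*, not
*paths* — because a descendant reached through an out-of-module relay is
still a downstream disease of the root; `in_module_paths = TRUE` gives the
strict variant.  Roots sharing a module form one cluster.  In validation
mode (temporal data too incomplete for trajectories, as in the motivating
study's replication register) the clusters are the comorbidity modules
themselves.

The susceptibility score of a patient for a cluster is the number of
*distinct* cluster-member codes diagnosed during follow-up.  Counting
repeat diagnoses instead of distinct diseases was the other reading of the
definition; distinct diseases was chosen because repeat visits for one
condition measure utilisation, not breadth of morbidity.

## The synthetic generator

`simulate_registry()` runs a discrete-time competing-hazard simulation:
30-day ticks, per-tick event probability = annual hazard / 12 (capped at
1), independent death and dropout ("emigration") hazards, uniform birth
years, and sex drawn Bernoulli with a default 62.7% female share echoing
the composition of anxiety/stress cohorts.  Thirty-day resolution is
adequate for year-scale follow-up and keeps a 100,000-person simulation in
seconds; the only consequence is that same-tick events tie and are handled
as such downstream.

A planted cluster consists of root codes and an ordered list of downstream
codes.  Exposure multiplies every member's hazard by `hr_exposure`.  The
cascade is compounding: a downstream code's hazard is multiplied by
`hr_cascade` for *each* upstream member (all roots and every earlier
downstream code) present at least `lag_days` earlier.  A pure
single-predecessor chain was considered and rejected: pairs two or more
steps apart in a chain co-occur mostly by coincidence of baseline events,
so their planted order would be undetectable at any realistic size, while
the compounding cascade plants a recoverable order for every (earlier,
later) member pair — which is exactly what the ground-truth set of
directed pairs promises.  Cascade boosts are evaluated against the state
at the start of each tick, so an upstream event never influences its
downstream code within the same tick.

What the generator does *not* emulate: diagnostic coding noise, repeat
diagnoses (only first occurrences are recorded), seasonality,
healthcare-seeking behaviour, socioeconomic confounding (education and
income enter the real design as covariates; the generator emits none, so
covariate defaults are empty on synthetic data), and any realistic ICD-10
ontology beyond code strings.  Passing recovery tests therefore shows that
the pipeline's inference machinery is correct under a clean generative
model, not that the design is robust to those real-data complications.

## Defaults and problem sizes

| parameter | default | meaning |
|---|---|---|
| `match_ratio` | 10 | controls per exposed person (1:10 register design) |
| `washout_days` | 183 | ≈ 6 months between index date and follow-up start |
| `condition_prevalence` | 0.005 | 0.5% floor for the PheWAS |
| `pair_prevalence` | 0.0025 | 0.25% co-occurrence floor for pairs |
| `alpha` | 0.05 | q-value threshold at every stage |
| `nested_controls` | 2 | controls per case in the nested case-control step |
| `louvain_restarts` | 20 | restarts of the Louvain search |

Birth-year matching is exact (no caliper), and a person may serve as a
control in several matched sets — standard incidence-density practice and a
necessity in small simulated populations; both choices are logged in the
cohort attributes.  "Emigration" maps to the generator's dropout date.

The package's own statistical checks run at sizes a single CPU handles
comfortably: formula oracles on 10,000 random count configurations plus an
exhaustive sign check for all tables with $N \le 60$; null calibration on
twenty 20,000-person registries with 20 candidate codes; hazard-ratio
recovery at 20,000 persons; orientation recovery at 30,000 persons; and
end-to-end cluster recovery on a 110,000-person registry yielding roughly
30,000 exposed patients with 1:5 matching, with a 40,000-person registry
replayed in network-only mode for replication.  These sizes were chosen so
that planted effects of the magnitude used (hazard ratios 3–4) are
comfortably powered, which is the regime the method is meant for.

## Numerical and degenerate-input choices

* Events landing on the first follow-up day would give Cox time 0; they
  are shifted to 0.5 days.
* Pair statistics switch to double precision before forming
  $C_iC_j(N-C_i)(N-C_j)$, which overflows 32-bit integers at registry
  scale.
* Degenerate pair tables (any margin 0 or equal to the sub-cohort size),
  $C_{ij}=0$ for $z^{RR}$, $|\Phi| \ge 1$ or $\max(C_{ij},C_j) \le 2$ for
  $z^{\Phi}$, separated 2×2 tables in the logistic stage, and nested
  case-control analyses with no informative set are all flagged
  non-estimable, dropped from the relevant FDR family, and counted in the
  run log rather than raising errors.
* Matched sets with zero eligible controls keep their exposed member;
  follow-up windows that close before they open drop the row.  Both counts
  are recorded as attributes and in the pipeline manifest.
* The empirical p-value floor of the exact binomial test is capped at 1.

## Known limitations

* The logistic and conditional-logistic stages take covariates from the
  data actually present; the motivating design's education/income and
  deprivation adjustments are only reproduced when a registry supplies
  those columns.
* The pair-screening prevalence denominator is all exposed patients, and
  the FDR family at each stage is "everything estimable in this run";
  both are stated choices where the source design is silent.
* No competing-risk modelling: death censors follow-up rather than being
  modelled as a competing event.
* Trajectories are pairwise: paths of three or more diseases are implied
  by composition of edges, not separately tested.

## A minimal run

```{r, eval = FALSE}
library(comorbclust)

cl <- planted_cluster("C01", c("C02", "C03"), hr_exposure = 3,
                      hr_cascade = 4, lag_days = 30)
cfg <- sim_config(seed = 7, n_persons = 20000, study_start = 2001,
                  study_end = 2010, clusters = list(cl))
reg <- simulate_registry(cfg)

res <- run_pipeline(reg, pipeline_config(
  exposure_codes = "F41", match_ratio = 5,
  seeds = list(cohort = 2, louvain = 11, nested = 3)))

res$clusters
cluster_recovery_report(res$clusters, ground_truth(cfg)$membership)
```
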