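---
title: "Measuring latent collaboration from EHR audit logs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring latent collaboration from EHR audit logs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Hospital care is collaborative, but much of the coordination between health
care workers (HCWs) never appears in any explicit communication record.
When a nurse charts vital signs while a respiratory therapist documents an
oxygen adjustment and a physician reviews both on the same patient's
electronic health record (EHR), the three are coordinating *through* the
record. EHR audit logs — which register every action a user performs on a
patient's chart with a timestamp — make this *latent collaboration*
measurable at scale, without surveys or observation.

`ehrcollab` implements a complete pipeline for this measurement:

1. **Sessionization** — raw events become *intervals*, maximal runs of one
   HCW's consecutive events on one patient separated by at most a gap
   cutoff.
2. **Concurrency detection** — intervals on the same patient by different
   HCWs whose spans overlap by a positive amount are linked; connected
   groups of linked intervals form *concurrent sessions*.
3. **Concurrent intensity** — per HCW and active workday, the proportion of
   intervals (and of EHR time) spent concurrently, summarized by specialty.
4. **Collaboration networks** — HCWs weighted by shared session counts,
   k-core extraction, role-level aggregation.
5. **Temporal patterns** — hourly concurrency profiles around admission and
   discharge, compared between weekdays and weekends.
6. **Interval clustering** — concurrent intervals clustered by action
   composition to score how homogeneous each session's work is.
7. **Survey validation** — expert Likert ratings test whether
   network-derived high/low-likelihood relationships are distinguishable.

```{r, eval = FALSE}
library(ehrcollab)

events <- read_events("audit_log.csv")
pipe <- collaboration_pipeline(events)        # cutoff estimated from data
graph <- build_graph(pipe$matrices$hcw_session)
```

## Sessionization and the gap cutoff

An interval continues as long as consecutive events of the same HCW on the
same patient are at most `cutoff` seconds apart; a strictly larger gap
starts a new interval (a gap exactly equal to the cutoff stays inside).
Audit-log gaps live on two timescales: seconds to a couple of minutes
within a task, tens of minutes to hours between tasks. The cutoff should
sit between them.

`estimate_cutoff()` scans candidate cutoffs (default 10–1800 s in 10 s
steps) and evaluates the number of intervals each would produce. This
trade-off curve decreases steeply while the cutoff is absorbing within-task
gaps and flattens once only between-task gaps remain; its *knee* — the
point of maximum curvature, `K(x) = f''(x) / (1 + f'(x)^2)^{3/2}` — is the
natural operating point. `knee_point()` implements the Kneedle
construction: smooth with a centered moving average (default window 5,
symmetric shrinking at the edges so straight lines gain no spurious
curvature), min–max normalize both axes, orient the curve to its increasing
form, and return the `x` maximizing the difference from the diagonal. Ties
resolve to the smallest `x` (the conservative, finer-grained
sessionization); a flat or straight curve raises a "no knee" error rather
than fabricating a cutoff. The applied curve choice — interval count
vs. cutoff rather than a gap-distribution quantile curve — is our design
decision; the curve is attached to the result for inspection.

The *active workday* filter removes (HCW, day) pairs whose summed interval
duration is below a threshold — 15 minutes by default, a value appropriate
for intensive-care settings where engaged staff accumulate far more EHR
time than that. Intervals crossing midnight contribute to each day the part
of their duration falling in it (the day boundary choice is ours; the
convention keeps daily EHR time an exact partition of total time). The
threshold applies to an HCW's activity summed over all patients.

Timestamps are treated as naive local clock time, parsed in a fixed zone:
daylight-saving transitions are not corrected and can appear as one-hour
artifacts twice a year.

## Concurrent sessions

Two intervals are linked when they share a patient, involve different HCWs,
and overlap by strictly more than zero seconds; touching endpoints do not
count. A concurrent session is a **connected component** of this link graph
within a patient: overlap is allowed to chain (A–B and B–C place A and C in
one session even if A and C never overlap directly). We consider the
component reading the right operationalization of a group working on the
same patient during one episode; for sensitivity analyses,
`assemble_sessions(rule = "clique")` instead requires each session to share
a common instant (for intervals on a line, pairwise overlap within a group
is equivalent to a common instant — the 1-D Helly property), assigning
intervals greedily in start order. Intervals in no session are
*individual*.

Six sparse matrices connect the entities downstream: interval-by-action
counts, interval-by-session and HCW-by-session membership, HCW-by-interval
ownership, and duration-weighted variants of the last two.

## Concurrent intensity

For each active (HCW, day): the fraction of intervals that are concurrent
and the fraction of EHR time in concurrent intervals. A concurrent interval
contributes its full duration — partial overlap is not prorated, since a
10-minute interval overlapped for 2 minutes still represents ten minutes of
work in a concurrent episode. Specialty summaries average per-HCW means
first and then across HCWs (so prolific documenters do not dominate their
specialty), with 95% t-based confidence intervals across HCWs; a specialty
with one HCW reports no interval. Whether to aggregate over HCWs or
HCW-days was genuinely open; we chose HCWs. One-way ANOVA compares
specialties; Spearman rank correlation relates daily EHR time to daily
concurrent time within specialty. The statistical tests are standard R
routines (`aov`, `cor.test`, `wilcox.test`, `t.test`) — the package's
contribution is the quantities tested, not the tests.

## Networks

Edge weight between two HCWs is their shared-session count, the off-
diagonal of the HCW-by-session matrix times its transpose. The k-core
(every member connected to at least `k` others inside the subgraph, plain
degree) isolates the collaborative core. Role aggregation sums edge weights
into unordered role pairs including within-role self-pairs, conserving
total weight exactly. `rank_relationships()` labels the heaviest cross-role
pairs high-likelihood and the lightest low-likelihood (ties broken
lexicographically); within-role pairs are excluded by default — with eight
roles this yields 28 candidate pairs, matching a 6 + 6 survey design.
Graphs export to GraphML, GEXF, and edge-list CSV for external layout
tools; no layout is computed here.

## Temporal patterns

Admission windows are the 24 h after admission, discharge windows the 24 h
before discharge (stays under 24 h are excluded and counted); the
intermediate phase is the calendar day containing the stay midpoint,
optionally widened by `mid_days`. Hour slots are offsets from the window
anchor — "hours since admission" — not clock hours; an interval is counted
in the slot containing its start (set `attribute = "overlap"` to prorate by
overlap seconds instead). Patients are grouped by the day type (weekend =
Saturday/Sunday) of their anchor; per-slot counts are averaged over all the
group's patients, zeros included. The Wilcoxon rank-sum test compares the
two 24-value sequences by order; a Welch t test compares their means.

## Clustering concurrent intervals

The interval-by-action count matrix (raw counts, no reweighting) is reduced
by PCA until cumulative explained variance reaches `variance_target`
(default 0.97, capped at 10 components by default), then embedded in 2-D by
an exact t-SNE with a Student-t low-dimensional kernel, written for this
package: input similarities are calibrated per point to a target perplexity
by bisection, and the map is optimized by gradient descent with momentum
and early exaggeration. The embedding is stochastic, so a seed is mandatory
and recorded in the output; the same seed reproduces the embedding exactly.

K-means runs on the 2-D embedding coordinates by default — mirroring common
practice, though distances in a t-SNE plane are distorted, so
`cluster_space = "pca"` clusters on the retained components instead. The
cluster count comes from the knee of the within-cluster sum of squares
(WSS) curve over a candidate grid (default 5–100 in steps of 5, shrunk for
small inputs), each point the best of 10 restarts; a WSS increase along the
grid triggers extra restarts, and a remaining increase warns. The WSS curve
is not smoothed before knee detection — restart-best WSS is already close
to monotone, and smoothing would blur a sharp elbow. The knee's
`"strength"` attribute (maximum normalized difference from the diagonal)
flags weak, low-confidence elbows on structureless data.

Session complexity is the number of distinct clusters among a session's
member intervals, computed as the cluster-by-interval indicator matrix
times the interval-by-session matrix, counting positive entries per
session. The reported distribution (fractions of sessions touching 1, 2,
3+ clusters) summarizes how homogeneous concurrent work is.

## The synthetic generator

Real NICU audit logs cannot be shipped, so `generate_audit_log()` emulates
their statistical structure with known ground truth: patients with
day-resolution admission/discharge spans (midnight boundaries, as admission
*dates*); care teams of several HCWs per patient; per-HCW bursty event
streams with exponential within-burst gaps (mean 30 s) and much longer
between-burst gaps (mean 4 h — about six touches per patient-day, around
the clock, as a NICU is staffed 24/7); planted teams whose members join
shared "anchors" with a configurable propensity, producing overlapping
intervals; weekend activity thinned by a rate multiplier (default 0.25);
and per-burst action templates with disjoint core action sets, so intervals
from one template share a composition profile. All randomness flows from
one mandatory seed; the same seed reproduces the event table byte for byte.

Two structural consequences matter when interpreting tests. First,
*planted* concurrency scales linearly with the day-type rate multiplier
(anchors are thinned once), while *coincidental* overlap scales roughly
quadratically (both partners are thinned); recovering a configured
weekday/weekend ratio therefore requires a configuration in which planted
concurrency dominates, which is also the regime the framework is designed
for. Second, sessions are template-homogeneous only insofar as chance
overlap is rare; purity statements are conditional on that regime.

What the generator does **not** emulate: clinical content (actions are
abstract labels), shift structure, HCW-specific workloads, documentation
spillover after discharge, or coordinated activity *without* temporal
overlap. Passing recovery tests therefore show the pipeline correctly
measures the structures it defines — not that those structures exhaust real
collaboration.

## Validation against expert judgment

`fit_likelihood_model()` regresses Likert scores (1–5) on a 0/1 indicator
of the EHR-derived likelihood class. With a single binary predictor the
intercept is exactly the low-group mean and intercept plus slope exactly
the high-group mean, so the slope is the high-minus-low difference; the
model ANOVA F test (the square of the slope's t statistic) tests whether
experts distinguish the classes. Responses are treated as independent
observations; respondent clustering is ignored — a deliberate
simplification, as is the choice of a linear model over ordinal
regression. The package ships relationship-level mean scores from a
13-expert NICU panel over 12 role pairs (`nicu_survey_scores()`) as a
worked example; note the all-equal-response edge case reports p = 1 rather
than a spurious rejection.

## Problem sizes and numerical choices in the test suite

The shipped tests exercise the oracle equivalences at 1000 random event
streams (up to 10^4 events), 500 overlap instances (up to 2000 intervals),
200 random graphs (up to 300 nodes), and 200 synthetic-log replicates for
planted-team recovery, with smaller cohort configurations (about 12 HCWs,
5 patients, 7 days) per replicate — sizes we consider ample to expose
logic errors while keeping the suite quick on one CPU. Degenerate inputs
are part of the contract: empty logs, flat knee curves, all-tied patterns,
zero-variance groups, duplicate embedding points, and rank-deficient
action matrices all have defined behavior tested explicitly.

## Known limitations

- Concurrency is a proxy: overlapping shifts can create coincidental
  overlap that the framework cannot distinguish from coordination, and
  collaboration without temporal overlap is invisible to it.
- Interval durations ignore the duration of the final action in a run.
- The likelihood model treats Likert scores as interval-scaled and
  independent across respondents.
- The t-SNE embedding step is statistically fragile as a clustering
  substrate; the PCA-space option exists for robustness checks.
- Daylight-saving artifacts are documented, not corrected.
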