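# ehrcollab

Measure latent health care worker (HCW) collaboration from EHR audit logs.

Hospital EHR systems log every action a user performs on a patient's chart
(who, whose record, what, when). When several HCWs work on the same
patient's record at the same time, they are coordinating *through* the
record — a form of collaboration that surveys and communication logs never
capture. `ehrcollab` turns raw audit-log events into quantitative measures
of this latent collaboration, for clinical informaticians and health
services researchers.

## The method

- **Sessionization.** Events of one HCW on one patient are merged into
  *intervals* while consecutive gaps stay at or below a cutoff $c$; the
  cutoff is chosen as the knee — the point of maximum curvature
  $K(x) = f''(x) / \bigl(1 + f'(x)^2\bigr)^{3/2}$ — of the interval-count
  vs. cutoff curve. Days on which an HCW accrues less than a threshold of
  EHR time (default 15 min) are excluded as inactive workdays.
- **Concurrent sessions.** Intervals on the same patient by different HCWs
  with strictly positive span overlap are linked; each connected component
  of links is a *concurrent session*, and its member intervals are
  *concurrent intervals*.
- **Concurrent intensity.** Per HCW-day: the proportion of intervals, and
  of EHR time, in concurrent intervals; summarized per specialty with 95%
  CIs and compared by one-way ANOVA and Spearman correlation.
- **Collaboration network.** HCW nodes, edge weight = number of shared
  sessions; k-core extraction and role-level aggregation identify the
  collaborative core and its structure.
- **Temporal patterns.** Hourly counts of concurrent intervals in the 24 h
  after admission / before discharge / around the stay midpoint, compared
  weekday vs. weekend (Wilcoxon rank-sum, Welch t).
- **Session complexity.** Concurrent intervals are clustered by action
  composition (PCA → seeded 2-D embedding → K-means with elbow-selected
  K); a session's complexity is the number of distinct clusters among its
  intervals.
- **Survey validation.** A linear model $\text{Likert} = \alpha + \theta
  \beta$ ($\theta$ = 1 for network-derived high-likelihood relationships)
  tests whether experts can distinguish the classes: $\alpha$ is exactly
  the low-group mean Likert and $\alpha + \beta$ the high-group mean.

A seeded synthetic audit-log generator (`sim_config()`,
`generate_audit_log()`) produces NICU-like logs with planted collaborating
teams, two-timescale gap structure, weekday/weekend asymmetry, and action
templates, so the whole pipeline is testable end to end without protected
health information.

## Worked example

```r
library(ehrcollab)

# a bundled 12-event audit-log snippet: two HCWs, two patients
events <- read_events(system.file("extdata", "example_events.csv",
                                  package = "ehrcollab"))
build_intervals(events, cutoff = 120)
#> # A tibble: 3 x 7
#>   interval_id hcw_id patient_id start               stop                duration
#> 1           1 A      1          2020-04-05 02:14:25 2020-04-05 02:15:00       35
#> 2           2 A      1          2020-04-05 02:18:23 2020-04-05 02:22:23      240
#> 3           3 B      2          2020-12-03 06:31:27 2020-12-03 06:39:27      480
```

HCW A's six events split into two intervals because one gap (203 s) exceeds
the 2-minute cutoff; HCW B's six events, with every gap under 120 s, form a
single 480-second interval.

```r
# synthetic log with three planted 3-HCW teams, then the full pipeline
log <- generate_audit_log(sim_config(seed = 42))
pipe <- collaboration_pipeline(log$events)   # knee-point cutoff: 140 s
attr(pipe$intervals, "label_report")
#>   n_concurrent n_individual
#> 1          345         1288

g <- build_graph(pipe$matrices$hcw_session, hcw_meta = log$hcw_meta)
head(igraph::as_data_frame(g)[order(-igraph::E(g)$weight), ], 5)
#>    from   to weight
#>    h004 h006     35
#>    h004 h005     33
#>    h005 h006     32
#>    h001 h002     22
#>    h001 h003     22
```

The heaviest edges are exactly the planted team pairs (h001–h003 and
h004–h006 are two of the planted teams): shared-session counts recover the
planted collaboration structure.

```r
fit <- fit_likelihood_model(nicu_survey_scores())
fit
#> Likert ~ alpha + theta * beta: alpha = 2.648 (low-group mean), beta = 0.890
#>   F = 4.747, p = 0.05435
#>   label     n  mean ci_lo ci_hi
#> 1 high      6  3.54  2.71  4.37
#> 2 low       6  2.65  2.00  3.29
```

On the bundled 12 relationship-level mean scores, high-likelihood
relationships score 3.54 on average versus 2.65 for low-likelihood ones, a
difference of β = 0.89 Likert points. (At n = 12 relationship-level
observations the F test is underpowered; response-level data sharpen it.)

A thin command-line front end over these functions is installed at
`inst/cli/ehrcollab` (subcommands `sessionize`, `concurrency`, `intensity`,
`network`, `temporal`, `cluster`, `survey`, `simulate`).

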