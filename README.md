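# funnelbench

Continuous scientific benchmarking for stochastic molecular-modelling
software, at desk scale.

Monte-Carlo protocols (docking, loop modelling, design, refinement) cannot
be regression-tested by comparing outputs byte-for-byte: every run samples a
different decoy ensemble, and whether the software still "works" is a
statistical statement about that ensemble. funnelbench implements the whole
testing loop such protocols need:

- **Funnel-quality metrics.** The Boltzmann-weighted near-native
  probability

  P_Near = Σᵢ exp(−rᵢ²/λ²) · exp(−Eᵢ/k_BT) / Σⱼ exp(−Eⱼ/k_BT)

  over a score-vs-rmsd ensemble (rᵢ = similarity to native in Å, Eᵢ = total
  energy in REU, λ = 4.0 Å by default, k_BT = 0.62 REU by default). P_Near
  lies in [0, 1]: 1 is a perfect energy funnel, 0 means no funnel or a
  wrong global minimum. Plus Pearson/Spearman correlations, sequence
  recovery, best-n selection, and the cross-score-function aggregations
  (winner-takes-all points and column averages) used to summarise score
  functions across targets.
- **A test-directory harness.** Numbered stage scripts
  (`0.compile … 9.finalize`), a questionnaire readme, `cutoffs`,
  `observers` and `citation` files; contract validation, staged execution
  with per-stage logs and a persisted hand-off record, cutoff-based
  pass/fail, and a rerun policy that distinguishes technical, stochastic
  and scientific failures (one automatic rerun; two consecutive scientific
  failures are final).
- **Revision scheduling and bisection.** Rolling earliest-run-first
  scheduling over a revision stream; a pass-to-fail transition across an
  untested gap opens a binary search that isolates the breaking revision in
  ≤ ⌈log₂ gap⌉ low-priority probes.
- **Reporting.** Self-contained HTML results pages (verdict banner, cutoff
  table, embedded funnel plots, the test's own readme) and a dashboard with
  the five-state color semantics: green = pass, red = breakage,
  magenta = script failure, yellow = running, white = not yet run.
- **A mock Monte-Carlo protocol.** A tunable score-vs-rmsd generator
  (native-funnel occupancy, decoy cloud, optional wrong-minimum basin,
  revision-indexed regression injection) stands in for the real modelling
  software, so the whole loop runs end-to-end in seconds.

## Worked example

Inject a regression at revision 21 of a 32-revision mock history, let the
rolling scheduler test every 8th revision, and watch bisection find the
culprit:

```r
library(funnelbench)

spec <- revision_history_spec(n_revisions = 32, breakage_at = 21, seed = 17)
res <- run_rolling_campaign(spec, tested_revisions = c(4, 12, 20, 28))
res$culprit
#> [1] 21
res$n_probes
#> [1] 3
for (r in res$runs) print(r)
#> <test_run> mock_test @ r4 attempt 1: passed
#> <test_run> mock_test @ r12 attempt 1: passed
#> <test_run> mock_test @ r20 attempt 1: passed
#> <test_run> mock_test @ r28 attempt 2: failed
#> <test_run> mock_test @ r24 attempt 2: failed
#> <test_run> mock_test @ r22 attempt 2: failed
#> <test_run> mock_test @ r21 attempt 2: failed
```

The rolling runs pass up to r20 and fail at r28 (after the automatic rerun
that rules out a stochastic failure — hence `attempt 2`); probes r24, r22,
r21 then bracket the breakage to exactly r21. `render_dashboard(res$runs)`
turns the same runs into the colored state grid.

Funnel quality of one healthy mock ensemble, and a score-function
comparison summarised both ways:

```r
ens <- generate_ensemble(mock_protocol_params(n_models = 500, seed = 1))
compute_pnear(ens)            # 0.9984 — a tight funnel
plot_funnel(ens, file = "funnel.png")

m <- read_comparison_matrix(system.file("extdata", "matrix_small.tsv",
                                        package = "funnelbench"))
winner_takes_all(m)
#>     score12 talaris2014     ref2015
#>           0           0           2
column_average(m)
#>     score12 talaris2014     ref2015
#>       0.233       0.600       0.800
```

Only the two rows with complete data award winner-takes-all points (both to
ref2015); the column averages use every available cell, including the
target ref2015 was never run on.

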