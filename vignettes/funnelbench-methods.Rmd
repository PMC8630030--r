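---
title: "Benchmarking stochastic modelling protocols: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking stochastic modelling protocols: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(funnelbench)
```

## Why scientific tests are not unit tests

A Metropolis Monte-Carlo protocol produces a different decoy ensemble on
every run. The question a maintainer needs answered is not "did the output
change" but "does the protocol still produce funnel-shaped energy
landscapes of the expected quality" — a statistical property of the
ensemble, robust to seed changes by design. funnelbench treats that
property as the unit under test: metrics over ensembles, cutoffs over
metrics, a rerun policy that absorbs sampling noise, and revision-level
bookkeeping that turns a quality regression into a named commit.

## The funnel-quality metric

For an ensemble of models with energies $E_i$ (REU) and
similarities-to-native $r_i$ (Å),

$$P_{Near} \;=\; \frac{\sum_i e^{-r_i^2/\lambda^2}\, e^{-E_i/k_BT}}
                     {\sum_j e^{-E_j/k_BT}}.$$

Each model's Boltzmann weight $e^{-E_i/k_BT}$ is multiplied by a Gaussian
proximity factor; $P_{Near}$ is therefore the Boltzmann-weighted
probability mass sitting near the native structure. It is 1 exactly when
every model has $r_i = 0$, and it approaches 0 when the thermodynamically
dominant models are far from the native — including the important
pathology where a score function digs an incorrect alternative minimum
below the native basin.

Two parameters matter:

- **λ (lambda), Å — default 4.0.** The length scale of "near". The shipped
  comparison configuration fixes λ = 4.0 so that values are comparable
  across score functions and protocols; per-test overrides go through the
  test's cutoffs/configuration, never through silent code changes.
- **k_BT, REU — default 0.62.** The temperature factor converting energies
  to weights. There is no single published value tied to the metric
  itself, so the package treats it as a required, always-recorded
  configuration value; 0.62 REU (roughly physiological temperature on the
  Rosetta energy scale) is the conventional choice for this kind of
  analysis. Results quoted without their (λ, k_BT) pair are not
  comparable, which is why `funnel_params()` objects travel with every
  computation.

**Numerical choices.** The implementation subtracts the minimum energy
before exponentiating. Because $P_{Near}$ depends on energies only through
differences, this changes nothing mathematically (shift invariance is
property-tested to 1e−10 for shifts up to 1e6 REU) while guaranteeing the
largest exponent is 0, so no energy magnitude can overflow. Models whose
shifted energy exceeds roughly $745 \cdot k_BT$ underflow to weight zero;
they are thermodynamically irrelevant at that point, but it does mean
strict monotonicity in a single model's similarity only holds while the
model carries nonzero weight.

## Aggregating a score-function comparison

A comparison matrix holds one metric value per (target, score function)
cell, with missing cells allowed (a score function may never have been run
on a target). Two summaries are provided, and they deliberately answer
different questions:

- **Winner-takes-all.** For every row where *all* cells are present, one
  point is distributed: wholly to the unique best cell, split equally
  among exact ties. Rows with any missing cell award nothing — an
  incomplete row cannot name a fair winner. The tie rule keeps the
  invariant that the points distributed equal the number of complete rows
  exactly, which the tests check. (Exact numeric ties are the only ties
  recognised; with continuous metrics they essentially occur only when two
  columns contain identical data.)
- **Column averages.** The mean over each column's *present* cells. Here
  partial data still contributes, so the two summaries can legitimately
  rank score functions differently.

The orientation registry (`metric_orientation()`) records that P_Near,
recoveries and correlations are higher-is-better while rmsd-like metrics
are lower-is-better, so "best" is never ambiguous.

## The test-directory contract

A scientific test is a directory: numbered stage scripts run consecutively
as numbered (`0.compile`, `1.submit`, `2.analyze`, `3.plot`, …,
`9.finalize`), plus `citation`, `cutoffs` (one per line:
`metric direction threshold [scope min_targets]`), `observers` (who gets
notified on breakage; notification is a pluggable hook that default-logs —
no email delivery) and a questionnaire-style `readme.md` whose required
sections force real documentation; the readme is embedded verbatim into
the results page so documentation is written once and never duplicated.
Bundled inputs above 5 MB trigger a recommendation to move them to an
external data submodule. Validation only reads the directory, so it is
idempotent and order-independent.

Stage execution passes state through one persisted machine-readable record
(`handoff.json`) in the working directory rather than environment
variables: a run can be inspected mid-flight and resumed deliberately
(`resume = TRUE`); an accidental rerun into a used working directory is
refused. Each stage's stdout/stderr goes to its own log file. A nonzero
exit is a `script_failure` and later stages are skipped. The harness never
pins a random seed on the scientific payload — seed-independence of the
statistical conclusion is part of what is being tested; only the mock
simulator takes explicit seeds, for fixtures and forensic replay. A
per-test runtime budget (default cap 10 CPU-minutes in mock mode) is
recorded and warned on.

## Failure taxonomy and the rerun policy

Failures come in three kinds: **technical** (a stage crashed —
`script_failure`, or infrastructure broke — `broken`), **stochastic** (an
unlucky ensemble straddled a well-chosen cutoff) and **scientific** (the
code genuinely regressed). The policy: a scientific failure triggers
exactly one automatic rerun (configurable `max_attempts`, default 2); a
pass on the rerun is final and flagged `stochastic_pass` so it stays
visible; a second failure is final. Technical failures are never rerun —
a crash is not sampling noise. For a test with independent per-run failure
probability $p$, final failure occurs with probability $p^2$: at
$p = 0.2$ the tests verify a long-run final-failure frequency in
[0.03, 0.05] over 10⁴ simulated tests. A cutoff that needs this machinery
often is itself mis-chosen, which is why stochastic passes are surfaced
rather than hidden.

The run state machine is `queued → running → {script_failure | failed |
passed | broken}`, and a verdict is only reachable when every stage exited
0.

## Scheduling and bisection

Scientific tests are too expensive to run at every revision, so the
scheduler keeps nodes busy on a rolling earliest-run-first basis: explicit
feature requests first, then the test that has gone longest without
running, then bisect probes at the lowest priority (fault isolation must
not starve fresh testing). Ties break deterministically by (test,
revision).

When a tested revision fails after an earlier tested revision passed with
untested revisions between them, a bisect opens on the bracket
(good, bad]: probe the integer midpoint (floor — no tie rule is canonical,
so the package picks one and keeps it), move `good` or `bad`, stop when
`bad = good + 1`; `bad` is the culprit. Adjacent tested revisions skip the
search entirely. A probe that ends in `script_failure` is rescheduled
without moving the bracket — it carries no information about the breakage.
Correctness and the ⌈log₂ gap⌉ probe bound are verified exhaustively over
every breakage position for all gaps up to 256 plus all positions at gaps
511–513 and 1023–1024 (about 38,000 bisections); the sweep assumes a
single monotone breakage inside the bracket, which is exactly the
assumption binary search needs and matches the "one responsible revision"
model. Flaky verdicts inside a bisect get the same one-rerun policy before
the bracket moves. Revision ids are consecutive integers; mapping real VCS
hashes to stream order is an adapter concern, not the scheduler's.

## The mock protocol

`generate_ensemble()` samples each model independently:

- with probability `f_native`, from the **native basin**: rmsd
  $|N(0, \sigma_{native})|$, energy
  $E_{floor} + slope \cdot rmsd + N(0, \sigma_{noise})$;
- optionally from an **alternative (wrong) minimum** at a configured rmsd,
  energy and width — the fraction drawn there defaults to half the
  non-native mass, since an occupancy must be chosen and the wrong-minimum
  pathology is interesting precisely when the basin is well populated;
- otherwise from a **decoy cloud**: rmsd uniform on a range, energy
  $N(\mu_{decoy}, \sigma_{decoy})$.

Defaults (500 models, 90% native occupancy, 0.5 Å basin, 5 REU/Å slope,
decoys 20 REU above the floor at 5–30 Å) describe a healthy protocol and
yield P_Near ≈ 0.9985 (established by a 100,000-model pilot run; the
n = 500 sampling spread stays above 0.97). The regression injected by
`revision_history_spec()` collapses occupancy to 20% and drops the decoy
cloud below the native floor — a wrong global minimum — which pushes
P_Near below 0.5 and reliably trips the default `pnear ge 0.7` cutoff.
Per-run payload seeds are derived by a stable 31-multiplier hash of
(history seed, test, revision, attempt), kept below 2³¹ and logged in the
run for replay; repeated attempts therefore differ, as the rerun policy
requires.

**What the mock does and does not show.** Energy noise is Gaussian and
models are i.i.d. for analyzability; real landscapes have correlated,
heavy-tailed errors, trajectory-level correlation and no clean basin
separation, and the mock emits only (energy, rmsd) statistics — no
structures. Passing tests therefore demonstrate that the *harness
machinery* (metrics, cutoffs, reruns, scheduling, bisection, reporting) is
correct, not that any particular modelling protocol is accurate.

## Reporting

Results pages are single self-contained HTML documents: verdict banner,
cutoff table (observed vs threshold for every cutoff), metric table,
plots embedded as base64 data URIs, and the readme rendered once. The
markdown renderer is intentionally minimal (ATX headings, lists, fenced
code, inline emphasis) — exactly the constructs the readme template uses.
The dashboard colors one cell per test × revision: green = passed,
red = breakage, magenta = script failure, yellow = running, white = not
yet run, with breakage listed prominently at the top and commit metadata
per revision. `failed` (scientific) and `broken` (infrastructure) runs
share the red breakage color but keep distinct markup classes; the color
map is a bijection over the five *display* states. Funnel plots are base
graphics PNGs and byte-identical for identical input.

## Problem sizes used by the shipped tests

The test suite exercises: 1,000 random 50-model ensembles for the P_Near
range check; oracle equivalence against naive direct-summation /
enumeration references on inputs up to 500 elements at 1e−10; 10⁴
simulated flaky tests for the rerun policy; the exhaustive bisect sweep
described above; a 32-revision end-to-end campaign with a regression at
revision 21 (isolated in 3 probes); and a 5-point `f_native` grid at 2,000
models × 3 replicates for generator monotonicity. These sizes make the
whole suite run in well under two minutes on one CPU while keeping every
stochastic check at ≥ 3-standard-error separation.

## Known limitations

- Linear history per branch; no merge topology, no webhook integration.
- Winner-takes-all excludes incomplete rows; with very sparse matrices the
  two summaries can disagree strongly — that is a property of the data,
  not a bug, but worth remembering when reading dashboards.
- The k_BT default is a convention, not a measurement; changing it changes
  P_Near values and any cutoff calibrated against them.
- The mock protocol's independence assumptions make its sampling error
  *smaller* than a real protocol's at equal nstruct; cutoffs tuned on the
  mock are optimistic.
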