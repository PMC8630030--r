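#' Run the mock protocol through the full pass/fail pipeline
#'
#' Executes the mock Monte-Carlo protocol for one test at one revision,
#' computes its funnel-quality metric, evaluates the cutoffs and applies
#' the stochastic-failure rerun policy until a final verdict is reached.
#' This is the scientific payload of a harness cycle with the external
#' software replaced by the simulator.
#'
#' @param test test name.
#' @param revision revision id within `spec`.
#' @param spec a [revision_history_spec()].
#' @param cutoffs list of [cutoff_spec()]s; default: aggregate P_Near at
#'   least 0.7.
#' @param params [funnel_params()] for the metric.
#' @param max_attempts rerun-policy budget (default 2).
#' @return The final `test_run` (state `passed` or `failed`), with
#'   `metrics`, `verdict`, `attempt`, `stochastic_pass` and `payload_seed`
#'   filled in. The full attempt list is attached as attribute
#'   `"attempts"`.
#' @export
run_mock_test <- function(test, revision, spec,
                          cutoffs = list(cutoff_spec("pnear", "ge", 0.7)),
                          params = funnel_params(), max_attempts = 2L) {
  attempts <- list()
  repeat {
    attempt <- length(attempts) + 1L
    ens <- run_mock_protocol(test, revision, spec, attempt = attempt)
    run <- new_test_run(test, revision = revision, attempt = attempt)
    run <- transition_run(run, "running")
    run$payload_seed <- attr(ens, "payload_seed")
    run$metrics <- list(pnear = compute_pnear(ens, params))
    run <- finalize_run(run, evaluate_cutoffs(run$metrics, cutoffs))
    attempts[[attempt]] <- run
    decision <- apply_rerun_policy(attempts, max_attempts = max_attempts)
    if (decision$action == "final") {
      run$stochastic_pass <- decision$stochastic_pass
      attr(run, "attempts") <- attempts
      return(run)
    }
  }
}

#' Rolling campaign with automatic bisection
#'
#' Drives the scheduler over a mock revision history: the listed revisions
#' are tested in rolling order; upon the first pass-to-fail transition a
#' bisect is opened and its probes are run (at the lowest scheduling
#' priority) until the breaking revision is isolated.
#'
#' @param spec a [revision_history_spec()].
#' @param test test name.
#' @param tested_revisions revisions the rolling scheduler actually tests
#'   (scientific tests are too expensive to run at every revision; the gaps
#'   are what bisection searches).
#' @param cutoffs,params,max_attempts forwarded to [run_mock_test()].
#' @return A list: `runs` (every `test_run`, rolling and probes),
#'   `scheduler` (final `scheduler_state`), `culprit` (revision id or `NA`),
#'   `n_probes`.
#' @export
run_rolling_campaign <- function(spec, test = "mock_test",
                                 tested_revisions,
                                 cutoffs = list(cutoff_spec("pnear", "ge",
                                                            0.7)),
                                 params = funnel_params(),
                                 max_attempts = 2L) {
  stopifnot(inherits(spec, "revision_history_spec"))
  stream <- revision_stream(seq_len(spec$n_revisions))
  sched <- new_scheduler(stream)
  runs <- list()

  do_run <- function(revision) {
    run <- run_mock_test(test, revision, spec, cutoffs = cutoffs,
                         params = params, max_attempts = max_attempts)
    runs[[length(runs) + 1L]] <<- run
    run
  }

  for (rev in sort(as.integer(tested_revisions))) {
    run <- do_run(rev)
    sched <- record_result(sched, test, rev, run$state)
    bs <- sched$bisects[[test]]
    if (!is.null(bs) && !is.na(bs$culprit)) break
  }

  # service bisect probes (lowest priority; here they are all that is left)
  repeat {
    bs <- sched$bisects[[test]]
    if (is.null(bs) || !is.na(bs$culprit)) break
    entry <- next_scheduled(sched$queue)
    if (is.null(entry)) break
    sched$queue <- sched$queue[-attr(entry, "index"), , drop = FALSE]
    run <- do_run(entry$revision)
    sched <- record_result(sched, test, entry$revision, run$state)
  }

  bs <- sched$bisects[[test]]
  list(runs = runs, scheduler = sched,
       culprit = if (is.null(bs)) NA_integer_ else bs$culprit,
       n_probes = if (is.null(bs)) 0L else bs$n_probes)
}
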