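RUN_STATES <- c("queued", "running", "script_failure", "failed", "passed",
                "broken")

#' Test runs and their state machine
#'
#' A `test_run` records one execution of one test at one revision: the
#' per-stage results, the metrics the analysis produced, and a state that
#' moves only along `queued -> running -> {script_failure | failed | passed
#' | broken}`. A nonzero stage exit is a technical failure
#' (`script_failure`); `failed`/`passed` are the scientific verdicts;
#' `broken` is reserved for infrastructure-level faults injected by the
#' runner (e.g. a compile failure), mirroring the dashboard's distinction
#' between breakage and script failure. `stochastic_pass` marks a pass that
#' needed a rerun after a stochastic failure.
#'
#' @param test test name.
#' @param revision revision id the run executed (integer or `NA`).
#' @param attempt attempt number (1 for the first run, 2 for a rerun).
#' @return An object of class `test_run` in state `"queued"`.
#' @export
new_test_run <- function(test, revision = NA_integer_, attempt = 1L) {
  structure(list(
    test = test,
    revision = revision,
    attempt = as.integer(attempt),
    state = "queued",
    stages = data.frame(label = character(0), status = integer(0),
                        log = character(0), seconds = numeric(0),
                        stringsAsFactors = FALSE),
    metrics = list(),
    verdict = NULL,
    stochastic_pass = FALSE,
    payload_seed = NA_integer_,
    started = NA_real_,
    finished = NA_real_
  ), class = "test_run")
}

#' @rdname new_test_run
#' @param run a `test_run`.
#' @param state target state.
#' @return The updated run; illegal transitions are an error.
#' @export
transition_run <- function(run, state) {
  stopifnot(inherits(run, "test_run"))
  state <- match.arg(state, RUN_STATES)
  allowed <- switch(run$state,
    queued = "running",
    running = c("script_failure", "failed", "passed", "broken"),
    character(0))
  if (!state %in% allowed) {
    stop(sprintf("illegal state transition %s -> %s", run$state, state),
         call. = FALSE)
  }
  run$state <- state
  if (state == "running") run$started <- as.numeric(Sys.time())
  if (state != "running") run$finished <- as.numeric(Sys.time())
  run
}

#' @export
print.test_run <- function(x, ...) {
  cat(sprintf("<test_run> %s @ r%s attempt %d: %s%s\n", x$test,
              x$revision, x$attempt, x$state,
              if (isTRUE(x$stochastic_pass)) " (stochastic pass)" else ""))
  if (nrow(x$stages)) {
    cat(sprintf("  stages run: %s\n",
                paste(sprintf("%s(%d)", x$stages$label, x$stages$status),
                      collapse = ", ")))
  }
  invisible(x)
}

stage_interpreter <- function(path) {
  switch(tolower(tools::file_ext(path)),
         r = "Rscript",
         py = "python",
         sh = "sh",
         NULL)
}

#' Execute the numbered stages of a test
#'
#' Runs each stage script in ascending numeric order inside a fresh working
#' directory. Every stage receives the working directory as its first
#' argument and can read/update the persisted hand-off record
#' `handoff.json` there (test name, revision, attempt, completed stages,
#' payload seed) — state is passed between stages through that file, not
#' through environment variables, so a run is inspectable and resumable.
#' Stage stdout/stderr are captured to per-stage log files under
#' `logs/`. The first nonzero exit aborts the run with state
#' `script_failure`; later stages are not attempted. No random seed is
#' imposed on the scientific payload — stochastic protocols are expected to
#' be seed-free so that the statistical interpretation, not a trajectory,
#' is what is tested; only the mock simulator takes explicit seeds, for
#' fixtures.
#'
#' @param test a `test_definition` (see [read_test_definition()]).
#' @param workdir run working directory; must be empty (or `resume = TRUE`).
#' @param revision revision id under test.
#' @param attempt attempt number.
#' @param resume allow reuse of a non-empty working directory.
#' @param runtime_cap_seconds warn when the total stage wall time exceeds
#'   this cap (default 600 s, the mock-mode budget).
#' @return A `test_run`; state is `"script_failure"` on any stage failure,
#'   otherwise still `"running"` (ready for [evaluate_cutoffs()] and
#'   [finalize_run()]).
#' @export
run_stages <- function(test, workdir, revision = NA_integer_, attempt = 1L,
                       resume = FALSE, runtime_cap_seconds = 600) {
  stopifnot(inherits(test, "test_definition"))
  v <- validate_test(test)
  if (!v$ok) {
    stop("test fails contract validation: ",
         paste(v$problems, collapse = "; "), call. = FALSE)
  }
  if (dir.exists(workdir) && length(list.files(workdir, all.files = TRUE,
                                               no.. = TRUE)) > 0L && !resume) {
    stop("working directory not empty (pass resume = TRUE to reuse): ",
         workdir, call. = FALSE)
  }
  dir.create(workdir, recursive = TRUE, showWarnings = FALSE)
  logdir <- file.path(workdir, "logs")
  dir.create(logdir, showWarnings = FALSE)

  run <- new_test_run(test$name, revision = revision, attempt = attempt)
  run <- transition_run(run, "running")

  handoff <- list(test = test$name, revision = revision, attempt = attempt,
                  completed_stages = character(0))
  handoff_path <- file.path(workdir, "handoff.json")
  jsonlite::write_json(handoff, handoff_path, auto_unbox = TRUE)

  for (i in seq_len(nrow(test$stages))) {
    st <- test$stages[i, ]
    script <- file.path(test$directory, st$file)
    log <- file.path(logdir, paste0(st$file, ".log"))
    if (!file.exists(script)) {
      run$stages <- rbind(run$stages, data.frame(
        label = st$label, status = 127L, log = log, seconds = 0,
        stringsAsFactors = FALSE))
      run <- transition_run(run, "script_failure")
      attr(run, "diagnosis") <- paste("missing stage executable:", st$file)
      return(run)
    }
    interp <- stage_interpreter(script)
    t0 <- proc.time()[["elapsed"]]
    status <- if (is.null(interp)) {
      suppressWarnings(system2(script, args = shQuote(workdir),
                               stdout = log, stderr = log))
    } else {
      suppressWarnings(system2(interp, args = c(shQuote(script),
                                                shQuote(workdir)),
                               stdout = log, stderr = log))
    }
    secs <- proc.time()[["elapsed"]] - t0
    run$stages <- rbind(run$stages, data.frame(
      label = st$label, status = as.integer(status), log = log,
      seconds = secs, stringsAsFactors = FALSE))
    if (status != 0L) {
      run <- transition_run(run, "script_failure")
      attr(run, "diagnosis") <-
        sprintf("stage %s exited with status %d (see %s)", st$file, status,
                log)
      return(run)
    }
    handoff$completed_stages <- c(handoff$completed_stages, st$file)
    jsonlite::write_json(handoff, handoff_path, auto_unbox = TRUE)
  }

  total <- sum(run$stages$seconds)
  if (total > runtime_cap_seconds) {
    warning(sprintf("test %s used %.1f s, over the %.0f s runtime cap",
                    test$name, total, runtime_cap_seconds), call. = FALSE)
  }
  run
}

#' Evaluate cutoffs into a pass/fail verdict
#'
#' Compares the metrics a run produced against the test's cutoff
#' specifications. An `aggregate` cutoff compares a single summary value
#' (a vector metric is summarised by its mean); a `per_target` cutoff
#' passes when at least `min_targets_passing` targets individually satisfy
#' the threshold. The verdict is the conjunction of all cutoffs, and every
#' cutoff is reported with the observed value against its threshold.
#'
#' @param metrics named list mapping metric name to either a single summary
#'   value or a named per-target numeric vector.
#' @param cutoffs list of [cutoff_spec()] objects.
#' @return A list of class `cutoff_verdict`: logical `passed` plus a data
#'   frame `reasons` (metric, scope, observed, threshold, direction,
#'   passed).
#' @export
evaluate_cutoffs <- function(metrics, cutoffs) {
  stopifnot(is.list(metrics), is.list(cutoffs), length(cutoffs) >= 1L)
  rows <- lapply(cutoffs, function(co) {
    stopifnot(inherits(co, "cutoff_spec"))
    if (!co$metric %in% names(metrics)) {
      stop("cutoff references unknown metric: ", co$metric, call. = FALSE)
    }
    vals <- metrics[[co$metric]]
    satisfies <- if (co$direction == "ge") vals >= co$threshold
                 else vals <= co$threshold
    if (co$scope == "aggregate") {
      observed <- mean(vals)
      ok <- if (co$direction == "ge") observed >= co$threshold
            else observed <= co$threshold
      detail <- sprintf("%.6g %s %.6g", observed,
                        if (ok) c(ge = ">=", le = "<=")[[co$direction]]
                        else c(ge = "<", le = ">")[[co$direction]],
                        co$threshold)
    } else {
      if (co$min_targets_passing > length(vals)) {
        stop(sprintf("cutoff on '%s' requires %d passing targets but only %d targets present",
                     co$metric, co$min_targets_passing, length(vals)),
             call. = FALSE)
      }
      observed <- sum(satisfies)
      ok <- observed >= co$min_targets_passing
      detail <- sprintf("%d/%d targets pass (need %d)", observed,
                        length(vals), co$min_targets_passing)
    }
    data.frame(metric = co$metric, scope = co$scope, observed = observed,
               threshold = co$threshold, direction = co$direction,
               passed = ok, detail = detail, stringsAsFactors = FALSE)
  })
  reasons <- do.call(rbind, rows)
  structure(list(passed = all(reasons$passed), reasons = reasons),
            class = "cutoff_verdict")
}

#' @export
print.cutoff_verdict <- function(x, ...) {
  cat(sprintf("<cutoff_verdict> %s\n", if (x$passed) "PASSED" else "FAILED"))
  for (i in seq_len(nrow(x$reasons))) {
    r <- x$reasons[i, ]
    cat(sprintf("  [%s] %s: %s\n", if (r$passed) "ok" else "FAIL", r$metric,
                r$detail))
  }
  invisible(x)
}

#' Finalize a run with its scientific verdict
#'
#' @param run a `test_run` in state `"running"` whose stages all exited 0.
#' @param verdict a `cutoff_verdict` from [evaluate_cutoffs()].
#' @return The run in state `"passed"` or `"failed"`, with `run$verdict`
#'   set.
#' @export
finalize_run <- function(run, verdict) {
  stopifnot(inherits(run, "test_run"), inherits(verdict, "cutoff_verdict"))
  if (nrow(run$stages) > 0L && any(run$stages$status != 0L)) {
    stop("cannot finalize a run with failed stages", call. = FALSE)
  }
  run$verdict <- verdict
  transition_run(run, if (verdict$passed) "passed" else "failed")
}

#' Stochastic-failure rerun policy
#'
#' Monte-Carlo protocols occasionally fail a well-chosen cutoff purely by
#' sampling noise. A scientific failure on the first attempt therefore
#' requeues the test once; a second consecutive failure is final (the test
#' is signalling breakage, or its cutoff is mis-chosen). A pass on the
#' rerun is final and flagged `stochastic_pass`. Technical failures
#' (`script_failure`) are never rerun — a crashing script is not sampling
#' noise.
#'
#' @param attempts list of completed `test_run`s for one test at one
#'   revision, in attempt order.
#' @param max_attempts maximum number of attempts (default 2: exactly one
#'   automatic rerun).
#' @return A list: `action` (`"requeue"` or `"final"`); for final verdicts,
#'   `state` and `stochastic_pass`; for requeues, `next_attempt`.
#' @export
apply_rerun_policy <- function(attempts, max_attempts = 2L) {
  stopifnot(is.list(attempts), length(attempts) >= 1L)
  last <- attempts[[length(attempts)]]
  stopifnot(inherits(last, "test_run"))
  if (last$state %in% c("queued", "running")) {
    stop("rerun policy applies only to completed attempts (state is '",
         last$state, "')", call. = FALSE)
  }
  if (last$state %in% c("script_failure", "broken")) {
    return(list(action = "final", state = last$state,
                stochastic_pass = FALSE))
  }
  if (last$state == "passed") {
    earlier_failed <- length(attempts) > 1L &&
      any(vapply(attempts[-length(attempts)],
                 function(r) r$state == "failed", logical(1)))
    return(list(action = "final", state = "passed",
                stochastic_pass = earlier_failed))
  }
  # last$state == "failed"
  if (length(attempts) < max_attempts) {
    return(list(action = "requeue", next_attempt = length(attempts) + 1L))
  }
  list(action = "final", state = "failed", stochastic_pass = FALSE)
}
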