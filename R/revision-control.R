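#' Revision streams
#'
#' A linear, totally ordered stream of code revisions. Revision ids in the
#' mock stream are consecutive integers (an adapter from real VCS hashes to
#' stream order is the caller's concern); each revision carries commit
#' metadata used by the dashboard.
#'
#' @param ids integer revision ids, strictly increasing.
#' @param branch branch name (single string, linear history).
#' @param author,message character vectors (recycled) of commit metadata.
#' @param timestamp numeric or POSIXct vector (recycled).
#' @return A data frame of class `revision_stream` with columns `id`,
#'   `branch`, `parent`, `author`, `message`, `timestamp`.
#' @export
revision_stream <- function(ids, branch = "main", author = "dev",
                            message = "commit", timestamp = seq_along(ids)) {
  ids <- as.integer(ids)
  if (length(ids) < 1L || is.unsorted(ids, strictly = TRUE)) {
    stop("revision ids must be strictly increasing", call. = FALSE)
  }
  df <- data.frame(id = ids, branch = branch,
                   parent = c(NA_integer_, ids[-length(ids)]),
                   author = author, message = message,
                   timestamp = as.numeric(timestamp),
                   stringsAsFactors = FALSE)
  class(df) <- c("revision_stream", class(df))
  df
}

#' @rdname revision_stream
#' @param path a delimited (tab-separated) table with a header row and
#'   columns `id`, `branch`, `parent`, `author`, `message`, `timestamp`.
#' @export
read_revision_stream <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "")
  need <- c("id", "branch", "author", "message", "timestamp")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("revision table missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  revision_stream(df$id, branch = df$branch, author = df$author,
                  message = df$message, timestamp = df$timestamp)
}

queue_priority_rank <- c(feature_request = 1L, rolling = 2L,
                         bisect_probe = 3L)

#' Queue entries and rolling scheduling
#'
#' The scheduler keeps nodes continuously occupied: explicit feature
#' requests run first, then regular rolling entries (the test that has gone
#' longest without running), and bisect probes fill remaining capacity at
#' the lowest priority so that fault isolation never starves fresh testing.
#'
#' @param test test name.
#' @param revision revision id to run at.
#' @param priority `"feature_request"`, `"rolling"` or `"bisect_probe"`.
#' @param enqueue_time numeric timestamp.
#' @param last_run time this test last ran (`NA` = never, which schedules
#'   first among rolling entries).
#' @return One-row data frame usable with [next_scheduled()].
#' @export
queue_entry <- function(test, revision,
                        priority = c("rolling", "feature_request",
                                     "bisect_probe"),
                        enqueue_time = 0, last_run = NA_real_) {
  priority <- match.arg(priority)
  data.frame(test = test, revision = as.integer(revision),
             priority = priority, enqueue_time = as.numeric(enqueue_time),
             last_run = as.numeric(last_run), stringsAsFactors = FALSE)
}

#' @rdname queue_entry
#' @param queue data frame of queue entries (rbind of [queue_entry()] rows).
#' @param now current time (unused by the deterministic policy, recorded for
#'   symmetry with a live scheduler).
#' @return The chosen entry as a one-row data frame with attribute `index`
#'   (its row in `queue`), or `NULL` when the queue is empty (idle).
#' @export
next_scheduled <- function(queue, now = NA_real_) {
  if (is.null(queue) || nrow(queue) == 0L) return(NULL)
  rank <- queue_priority_rank[queue$priority]
  cand <- which(rank == min(rank))
  if (queue$priority[cand[1L]] == "rolling") {
    lr <- queue$last_run[cand]
    lr[is.na(lr)] <- -Inf  # never-run tests are the earliest-run
    cand <- cand[lr == min(lr)]
  }
  # deterministic tie-break
  ord <- order(queue$test[cand], queue$revision[cand])
  chosen <- cand[ord[1L]]
  out <- queue[chosen, , drop = FALSE]
  attr(out, "index") <- chosen
  out
}

#' Bisection state over a revision bracket
#'
#' Binary search over the untested revisions between the last passing
#' (`good`) and first known failing (`bad`) revision, to isolate the exact
#' revision responsible for a breakage. Probes are midpoints (integer
#' floor); the search ends when `bad == good + 1`, at which point `bad` is
#' the culprit.
#'
#' @param test test name the bisect is for.
#' @param good last revision known to pass.
#' @param bad first revision known to fail; must satisfy `good < bad`.
#' @return A `bisect_state`: `good`, `bad`, `pending` (next probe revision,
#'   or `NULL`), `probed` (revision -> verdict), `culprit` (revision id or
#'   `NA` while unresolved), `n_probes`.
#' @export
bisect_start <- function(test, good, bad) {
  good <- as.integer(good); bad <- as.integer(bad)
  if (!is.finite(good) || !is.finite(bad) || good >= bad) {
    stop("bisect needs a bracket with good < bad", call. = FALSE)
  }
  st <- structure(list(test = test, good = good, bad = bad,
                       pending = NULL, probed = list(),
                       culprit = NA_integer_, n_probes = 0L),
                  class = "bisect_state")
  if (bad == good + 1L) {
    st$culprit <- bad
  } else {
    st$pending <- as.integer(floor((good + bad) / 2))
  }
  st
}

#' @rdname bisect_start
#' @param state a `bisect_state` with a pending probe.
#' @param revision the revision the verdict is for; must be the pending
#'   probe.
#' @param verdict `"passed"`, `"failed"` or `"script_failure"`. A
#'   script failure is a technical fault, not evidence about the breakage:
#'   the same probe is rescheduled and the bracket does not move.
#' @return The updated `bisect_state`; when `culprit` is set the search is
#'   over.
#' @export
bisect_step <- function(state, revision, verdict) {
  stopifnot(inherits(state, "bisect_state"))
  verdict <- match.arg(verdict, c("passed", "failed", "script_failure"))
  if (!is.na(state$culprit)) {
    stop("bisect already resolved (culprit r", state$culprit, ")",
         call. = FALSE)
  }
  revision <- as.integer(revision)
  if (is.null(state$pending) || revision != state$pending) {
    stop(sprintf("verdict for r%d but pending probe is r%s", revision,
                 if (is.null(state$pending)) "<none>" else state$pending),
         call. = FALSE)
  }
  if (verdict == "script_failure") {
    # reschedule the same probe; no information about the breakage gained
    return(state)
  }
  state$n_probes <- state$n_probes + 1L
  state$probed[[as.character(revision)]] <- verdict
  if (verdict == "passed") state$good <- revision else state$bad <- revision
  if (state$bad == state$good + 1L) {
    state$culprit <- state$bad
    state$pending <- NULL
  } else {
    state$pending <- as.integer(floor((state$good + state$bad) / 2))
  }
  state
}

#' @export
print.bisect_state <- function(x, ...) {
  cat(sprintf("<bisect> %s: good r%d, bad r%d, %d probes; %s\n", x$test,
              x$good, x$bad, x$n_probes,
              if (is.na(x$culprit)) sprintf("pending probe r%d", x$pending)
              else sprintf("culprit r%d", x$culprit)))
  invisible(x)
}

#' Scheduler state over a revision stream
#'
#' Tracks per-test verdicts along the stream and opens a bisect whenever a
#' pass-to-fail transition is observed between consecutively *tested*
#' revisions with an untested gap between them (adjacent revisions need no
#' search: the failing one is the culprit). Bisect probes are enqueued at
#' the lowest priority.
#'
#' @param stream a [revision_stream()].
#' @return A `scheduler_state`: the stream, a results data frame
#'   (test, revision, verdict), a queue, and a list of `bisect_state`s (one
#'   per test, keyed by test name).
#' @export
new_scheduler <- function(stream) {
  stopifnot(inherits(stream, "revision_stream"))
  structure(list(stream = stream,
                 results = data.frame(test = character(0),
                                      revision = integer(0),
                                      verdict = character(0),
                                      stringsAsFactors = FALSE),
                 queue = NULL,
                 bisects = list()),
            class = "scheduler_state")
}

#' @rdname new_scheduler
#' @param sched a `scheduler_state`.
#' @param test test name.
#' @param revision revision id (must exist in the stream).
#' @param verdict `"passed"`, `"failed"` or `"script_failure"`.
#' @param now timestamp for enqueued probes.
#' @return The updated `scheduler_state`.
#' @export
record_result <- function(sched, test, revision, verdict, now = 0) {
  stopifnot(inherits(sched, "scheduler_state"))
  verdict <- match.arg(verdict, c("passed", "failed", "script_failure"))
  revision <- as.integer(revision)
  if (!revision %in% sched$stream$id) {
    stop("revision r", revision, " is not in the stream", call. = FALSE)
  }

  bs <- sched$bisects[[test]]
  if (!is.null(bs) && is.na(bs$culprit) && !is.null(bs$pending) &&
      revision == bs$pending) {
    bs <- bisect_step(bs, revision, verdict)
    sched$bisects[[test]] <- bs
    sched$results <- rbind(sched$results, data.frame(
      test = test, revision = revision, verdict = verdict,
      stringsAsFactors = FALSE))
    if (is.na(bs$culprit)) {
      sched$queue <- rbind(sched$queue,
                           queue_entry(test, bs$pending,
                                       priority = "bisect_probe",
                                       enqueue_time = now))
    }
    return(sched)
  }

  sched$results <- rbind(sched$results, data.frame(
    test = test, revision = revision, verdict = verdict,
    stringsAsFactors = FALSE))

  if (verdict == "failed") {
    prior <- sched$results[sched$results$test == test &
                             sched$results$revision < revision &
                             sched$results$verdict != "script_failure", ,
                           drop = FALSE]
    if (nrow(prior) > 0L) {
      last_tested <- prior[which.max(prior$revision), ]
      if (last_tested$verdict == "passed") {
        bs <- bisect_start(test, good = last_tested$revision, bad = revision)
        sched$bisects[[test]] <- bs
        if (is.na(bs$culprit)) {
          sched$queue <- rbind(sched$queue,
                               queue_entry(test, bs$pending,
                                           priority = "bisect_probe",
                                           enqueue_time = now))
        }
      }
    }
  }
  sched
}
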