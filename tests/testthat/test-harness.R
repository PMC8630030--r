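test_that("scaffolded tests satisfy the directory contract immediately", {
  dest <- withr::local_tempdir()
  td <- scaffold_test("mock_funnel", destination = dest)
  v <- validate_test(td)
  expect_true(v$ok)
  expect_length(v$problems, 0)
  # validation is idempotent
  expect_true(validate_test(file.path(dest, "mock_funnel"))$ok)
  # refuses to overwrite
  expect_error(scaffold_test("mock_funnel", destination = dest),
               "refusing")
})

test_that("oversized bundled inputs trigger the external-submodule warning", {
  dest <- withr::local_tempdir()
  td <- scaffold_test("fat_inputs", destination = dest)
  big <- file.path(dest, "fat_inputs", "input_files", "big.dat")
  writeBin(raw(6 * 1024^2), big)
  v <- validate_test(file.path(dest, "fat_inputs"))
  expect_true(v$ok)  # a warning, not a violation
  expect_match(v$warnings, "5 MB", all = FALSE)
})

test_that("a deleted readme is a contract violation naming the readme", {
  dest <- withr::local_tempdir()
  scaffold_test("no_docs", destination = dest)
  file.remove(file.path(dest, "no_docs", "readme.md"))
  v <- validate_test(file.path(dest, "no_docs"))
  expect_false(v$ok)
  expect_match(v$problems, "readme", all = FALSE)
})

test_that("stages run in numeric order and hand off through the persisted record", {
  dest <- withr::local_tempdir()
  td <- scaffold_test("ordered", destination = dest)
  dir <- file.path(dest, "ordered")
  # each stage appends its prefix to an order file in the workdir
  for (f in list.files(dir, pattern = "^[0-9]+\\.")) {
    n <- sub("\\..*$", "", f)
    writeLines(c("args <- commandArgs(trailingOnly = TRUE)",
                 sprintf("cat('%s\\n', file = file.path(args[[1]], 'order.txt'), append = TRUE)", n),
                 "quit(status = 0)"),
               file.path(dir, f))
  }
  wd <- file.path(withr::local_tempdir(), "run1")
  run <- run_stages(read_test_definition(dir), wd)
  expect_identical(run$state, "running")
  expect_equal(trimws(readLines(file.path(wd, "order.txt"))),
               c("0", "1", "2", "3", "9"))
  handoff <- jsonlite::read_json(file.path(wd, "handoff.json"))
  expect_length(handoff$completed_stages, 5)

  # same workdir without resume is refused
  expect_error(run_stages(read_test_definition(dir), wd), "resume")
})

test_that("a failing stage yields script_failure and skips later stages", {
  dest <- withr::local_tempdir()
  scaffold_test("crashy", destination = dest)
  dir <- file.path(dest, "crashy")
  writeLines("quit(status = 1)", file.path(dir, "2.analyze.R"))
  marker <- file.path(dest, "stage3_ran")
  writeLines(sprintf("file.create('%s'); quit(status = 0)", marker),
             file.path(dir, "3.plot.R"))
  run <- run_stages(read_test_definition(dir),
                    file.path(withr::local_tempdir(), "wd"))
  expect_identical(run$state, "script_failure")
  expect_false(file.exists(marker))
  expect_equal(nrow(run$stages), 3L)  # 0, 1, then the crash at 2
  expect_match(attr(run, "diagnosis"), "2.analyze")
})

test_that("cutoff lines parse into specs and round-trip through format()", {
  co <- parse_cutoff_line("pnear ge 0.7 aggregate")
  expect_identical(co$metric, "pnear")
  expect_identical(co$direction, "ge")
  expect_equal(co$threshold, 0.7)
  per <- parse_cutoff_line("rmsd le 2.0 per_target 8")
  expect_identical(per$scope, "per_target")
  expect_identical(per$min_targets_passing, 8L)
  expect_identical(parse_cutoff_line(format(per))$min_targets_passing, 8L)
  expect_error(parse_cutoff_line("pnear ge"), "malformed")
})

test_that("cutoff evaluation reports observed vs threshold per cutoff", {
  pass <- evaluate_cutoffs(list(pnear = 0.8),
                           list(cutoff_spec("pnear", "ge", 0.7)))
  expect_true(pass$passed)

  fail <- evaluate_cutoffs(list(pnear = 0.65),
                           list(cutoff_spec("pnear", "ge", 0.7)))
  expect_false(fail$passed)
  expect_match(fail$reasons$detail, "0.65 < 0.7")

  # 10 targets, 7 meet the threshold, 8 required -> fail
  per_target <- stats::setNames(c(rep(0.9, 7), rep(0.3, 3)),
                                paste0("t", 1:10))
  v <- evaluate_cutoffs(list(pnear = per_target),
                        list(cutoff_spec("pnear", "ge", 0.7,
                                         scope = "per_target",
                                         min_targets_passing = 8)))
  expect_false(v$passed)
  expect_match(v$reasons$detail, "7/10")
  # and passes once only 7 are required
  v7 <- evaluate_cutoffs(list(pnear = per_target),
                         list(cutoff_spec("pnear", "ge", 0.7,
                                          scope = "per_target",
                                          min_targets_passing = 7)))
  expect_true(v7$passed)

  expect_error(evaluate_cutoffs(list(pnear = 0.8),
                                list(cutoff_spec("rmsd", "le", 2))),
               "unknown metric")
})

test_that("the state machine only reaches a verdict through running", {
  run <- new_test_run("t", 1L)
  expect_error(transition_run(run, "passed"), "illegal")
  run <- transition_run(run, "running")
  expect_error(transition_run(run, "queued"), "illegal")
  run <- transition_run(run, "passed")
  expect_error(transition_run(run, "failed"), "illegal")
})

test_that("finalize refuses runs with failed stages", {
  run <- new_test_run("t", 1L)
  run <- transition_run(run, "running")
  run$stages <- data.frame(label = "analyze", status = 1L, log = "",
                           seconds = 0)
  v <- evaluate_cutoffs(list(pnear = 0.9),
                        list(cutoff_spec("pnear", "ge", 0.7)))
  expect_error(finalize_run(run, v), "failed stages")
})

test_that("rerun policy: one automatic rerun for scientific failures only", {
  mk <- function(state, attempt = 1L) {
    r <- new_test_run("t", 1L, attempt = attempt)
    r <- transition_run(r, "running")
    r$state <- state
    r
  }
  expect_equal(apply_rerun_policy(list(mk("failed")))$action, "requeue")

  two_fails <- apply_rerun_policy(list(mk("failed"), mk("failed", 2L)))
  expect_equal(two_fails$action, "final")
  expect_equal(two_fails$state, "failed")

  recovered <- apply_rerun_policy(list(mk("failed"), mk("passed", 2L)))
  expect_equal(recovered$action, "final")
  expect_equal(recovered$state, "passed")
  expect_true(recovered$stochastic_pass)

  first_pass <- apply_rerun_policy(list(mk("passed")))
  expect_false(first_pass$stochastic_pass)

  tech <- apply_rerun_policy(list(mk("script_failure")))
  expect_equal(tech$action, "final")
  expect_equal(tech$state, "script_failure")

  r <- new_test_run("t", 1L)
  r <- transition_run(r, "running")
  expect_error(apply_rerun_policy(list(r)), "completed")
})

test_that("long-run final-failure frequency of a flaky test is about p squared", {
  # mock test straddling its cutoff: each independent run fails w.p. p
  p <- 0.2
  n <- 10000
  set.seed(100)
  mk <- function(state, attempt) {
    r <- new_test_run("flaky", 1L, attempt = attempt)
    r <- transition_run(r, "running")
    r$state <- state
    r
  }
  final_failed <- 0L
  for (i in seq_len(n)) {
    a1 <- mk(if (runif(1) < p) "failed" else "passed", 1L)
    d <- apply_rerun_policy(list(a1))
    if (d$action == "requeue") {
      a2 <- mk(if (runif(1) < p) "failed" else "passed", 2L)
      d <- apply_rerun_policy(list(a1, a2))
    }
    if (d$state == "failed") final_failed <- final_failed + 1L
  }
  freq <- final_failed / n
  # within binomial error of p^2 = 0.04
  expect_gt(freq, 0.03)
  expect_lt(freq, 0.05)
})
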