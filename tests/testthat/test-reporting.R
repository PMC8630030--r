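finished_run <- function(state = "passed", test = "mock_funnel",
                         revision = 3L, metrics = list(pnear = 0.85)) {
  run <- new_test_run(test, revision)
  run <- transition_run(run, "running")
  run$metrics <- metrics
  if (state %in% c("passed", "failed")) {
    run <- finalize_run(run, evaluate_cutoffs(metrics,
                                              list(cutoff_spec("pnear",
                                                               "ge", 0.7))))
    run$state <- state
  } else {
    run$state <- state
  }
  run
}

template_readme <- function() {
  dest <- withr::local_tempdir(.local_envir = parent.frame())
  td <- scaffold_test("doc_test", destination = dest)
  td$readme
}

test_that("the five display states map bijectively onto the five colors", {
  states <- c("queued", "running", "script_failure", "failed", "passed")
  colors <- vapply(states, run_state_color, character(1))
  expect_length(unique(colors), 5L)
  expect_identical(colors[["passed"]], "green")
  expect_identical(colors[["failed"]], "red")
  expect_identical(run_state_color("broken"), "red")
  expect_identical(colors[["script_failure"]], "magenta")
  expect_identical(colors[["running"]], "yellow")
  expect_identical(colors[["queued"]], "white")
})

test_that("results pages embed verdict, cutoffs, metrics and the readme once", {
  readme <- template_readme()
  run <- finished_run("passed")
  html <- render_results_page(run, readme)
  expect_match(html, "PASSED")
  expect_match(html, "pnear")
  expect_match(html, "0.85")
  # every questionnaire heading present, exactly once
  for (h in c("Purpose of the test", "Quality measures and analysis",
              "Pass/fail criteria")) {
    expect_equal(lengths(regmatches(html, gregexpr(h, html, fixed = TRUE))),
                 1L)
  }
  failing <- render_results_page(finished_run("failed",
                                              metrics = list(pnear = 0.5)),
                                 readme)
  expect_match(failing, "BREAKAGE")
})

test_that("results pages refuse to render without documentation", {
  expect_error(render_results_page(finished_run(), readme = character(0)),
               "readme")
  expect_error(render_results_page(finished_run(), readme = "   "),
               "readme")
})

test_that("plots are embedded as self-contained images", {
  readme <- template_readme()
  ens <- generate_ensemble(mock_protocol_params(n_models = 50, seed = 3))
  plots <- vapply(1:3, function(i) {
    f <- tempfile(fileext = ".png")
    plot_funnel(ens, file = f)
    f
  }, character(1))
  on.exit(unlink(plots))
  html <- render_results_page(finished_run(), readme, plots = plots)
  expect_equal(lengths(regmatches(html,
                                  gregexpr("data:image/png;base64",
                                           html))),
               3L)
  expect_false(grepl("src=\"file:", html))
})

test_that("funnel plots are deterministic files with both basins in range", {
  p <- mock_protocol_params(n_models = 200, f_native = 0.5,
                            alt_basin = list(rmsd = 12, energy = -32,
                                             width = 0.5), seed = 9)
  ens <- generate_ensemble(p)
  f1 <- tempfile(fileext = ".png")
  f2 <- tempfile(fileext = ".png")
  on.exit(unlink(c(f1, f2)))
  plot_funnel(ens, file = f1)
  plot_funnel(ens, file = f2)
  expect_gt(file.size(f1), 0)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("the dashboard shows five state classes and lists breakage on top", {
  runs <- list(finished_run("passed", test = "t_pass", revision = 1L),
               finished_run("failed", test = "t_fail", revision = 1L,
                            metrics = list(pnear = 0.2)),
               finished_run("script_failure", test = "t_script",
                            revision = 1L),
               finished_run("running", test = "t_running", revision = 1L),
               finished_run("queued", test = "t_queued", revision = 1L))
  runs[[5]] <- new_test_run("t_queued", 1L)  # genuinely not-yet-run
  html <- render_dashboard(runs)
  for (cls in c("state-passed", "state-failed", "state-script_failure",
                "state-running", "state-queued")) {
    expect_match(html, cls)
  }
  broken_section <- sub(".*<div id='broken'>(.*?)</div>.*", "\\1", html)
  expect_match(broken_section, "t_fail")
  expect_false(grepl("t_pass", broken_section))
})

test_that("dashboards annotate revisions with committer metadata", {
  stream <- read_revision_stream(system.file("extdata",
                                             "revisions_small.tsv",
                                             package = "funnelbench"))
  runs <- list(finished_run("passed", test = "t", revision = 2L))
  html <- render_dashboard(runs, stream = stream)
  expect_match(html, "ben")
  expect_match(html, "tune packer weights")
  expect_match(html, "<th>r5</th>")
})

test_that("an empty run set still renders a valid dashboard", {
  html <- render_dashboard(list())
  expect_match(html, "<html>")
  expect_match(html, "none")
})

test_that("the markdown subset renders headings, lists and code", {
  md <- c("# Title", "", "## Section", "", "para with `code` and **bold**",
          "", "- item one", "- item two", "", "```", "x <- 1", "```")
  html <- markdown_to_html(md)
  expect_match(html, "<h1>Title</h1>")
  expect_match(html, "<h2>Section</h2>")
  expect_match(html, "<li>item one</li>")
  expect_match(html, "<code>code</code>")
  expect_match(html, "<strong>bold</strong>")
  expect_match(html, "<pre><code>")
  # comments are dropped
  expect_false(grepl("answer here",
                     markdown_to_html("<!-- answer here -->")))
})
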