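#' Dashboard state colors
#'
#' The dashboard colors each test-by-revision cell by its display state:
#' green for a pass, red for breakage (a scientific failure or an
#' infrastructure fault), magenta for a script failure, yellow while
#' running, white for not yet run. `failed` and `broken` runs share the
#' red breakage color but keep distinct state classes in the markup; the
#' color mapping is a bijection over the five display states.
#'
#' @param state a `test_run` state.
#' @return For `display_state`, one of `"queued"`, `"running"`,
#'   `"script_failure"`, `"breakage"`, `"passed"`; for `run_state_color`,
#'   a color name.
#' @export
display_state <- function(state) {
  state <- match.arg(state, RUN_STATES)
  if (state %in% c("failed", "broken")) "breakage" else state
}

#' @rdname display_state
#' @export
run_state_color <- function(state) {
  colors <- c(queued = "white", running = "yellow",
              script_failure = "magenta", breakage = "red",
              passed = "green")
  colors[[display_state(state)]]
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

#' Minimal markdown renderer
#'
#' Converts the questionnaire-readme subset of markdown — ATX headings,
#' unordered lists, fenced code blocks, inline code, bold/italic and
#' paragraphs — to HTML. HTML comments are dropped. This is intentionally
#' small: readmes follow the template, and the renderer covers exactly the
#' constructs the template uses.
#'
#' @param lines character vector of markdown lines (or a single string with
#'   newlines).
#' @return A single HTML string.
#' @export
markdown_to_html <- function(lines) {
  if (length(lines) == 1L && grepl("\n", lines)) {
    lines <- strsplit(lines, "\n", fixed = TRUE)[[1L]]
  }
  lines <- gsub("<!--.*?-->", "", lines)
  out <- character(0)
  in_code <- FALSE
  in_list <- FALSE
  para <- character(0)
  flush_para <- function() {
    if (length(para)) {
      txt <- paste(html_escape(para), collapse = " ")
      txt <- gsub("`([^`]+)`", "<code>\\1</code>", txt)
      txt <- gsub("\\*\\*([^*]+)\\*\\*", "<strong>\\1</strong>", txt)
      txt <- gsub("\\*([^*]+)\\*", "<em>\\1</em>", txt)
      out <<- c(out, paste0("<p>", txt, "</p>"))
      para <<- character(0)
    }
  }
  close_list <- function() {
    if (in_list) {
      out <<- c(out, "</ul>")
      in_list <<- FALSE
    }
  }
  for (line in lines) {
    if (grepl("^```", line)) {
      flush_para(); close_list()
      out <- c(out, if (in_code) "</code></pre>" else "<pre><code>")
      in_code <- !in_code
      next
    }
    if (in_code) {
      out <- c(out, html_escape(line))
      next
    }
    h <- regmatches(line, regexec("^(#{1,6})\\s+(.*)$", line))[[1L]]
    if (length(h) == 3L) {
      flush_para(); close_list()
      lvl <- nchar(h[[2L]])
      out <- c(out, sprintf("<h%d>%s</h%d>", lvl, html_escape(h[[3L]]), lvl))
      next
    }
    li <- regmatches(line, regexec("^\\s*[-*]\\s+(.*)$", line))[[1L]]
    if (length(li) == 2L) {
      flush_para()
      if (!in_list) {
        out <- c(out, "<ul>")
        in_list <- TRUE
      }
      out <- c(out, paste0("<li>", html_escape(li[[2L]]), "</li>"))
      next
    }
    if (!nzchar(trimws(line))) {
      flush_para(); close_list()
      next
    }
    para <- c(para, line)
  }
  flush_para(); close_list()
  if (in_code) out <- c(out, "</code></pre>")
  paste(out, collapse = "\n")
}

report_css <- function() {
  paste(
    "body { font-family: sans-serif; margin: 2em; }",
    ".banner { padding: 0.8em 1em; font-weight: bold; color: black; }",
    ".banner.passed { background: green; color: white; }",
    ".banner.failed, .banner.breakage, .banner.broken { background: red; color: white; }",
    ".banner.script_failure { background: magenta; color: white; }",
    "table { border-collapse: collapse; }",
    "td, th { border: 1px solid #999; padding: 0.3em 0.6em; }",
    ".cell { width: 2em; text-align: center; }",
    ".state-passed { background: green; }",
    ".state-failed, .state-broken { background: red; }",
    ".state-script_failure { background: magenta; }",
    ".state-running { background: yellow; }",
    ".state-queued { background: white; }",
    "img.plot { max-width: 640px; display: block; margin: 1em 0; }",
    sep = "\n")
}

embed_image <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  mime <- switch(tolower(tools::file_ext(path)),
                 png = "image/png", svg = "image/svg+xml",
                 jpg = , jpeg = "image/jpeg", "application/octet-stream")
  sprintf('<img class="plot" src="data:%s;base64,%s" alt="%s"/>',
          mime, jsonlite::base64_enc(bytes), html_escape(basename(path)))
}

#' Render a per-run results page
#'
#' Builds the single self-contained HTML document a maintainer examines
#' after a run: a verdict banner, the cutoff table with observed-vs-
#' threshold rows, the metric table, every plot embedded inline (base64),
#' and the test's readme rendered from markdown — embedded exactly once, so
#' the documentation lives in one place.
#'
#' @param run a `test_run`.
#' @param readme readme lines (mandatory — a run without documentation is
#'   refused).
#' @param plots character vector of image files to embed (may be empty).
#' @param metrics named list of metric values shown in the metric table;
#'   defaults to `run$metrics`.
#' @param file output path; `NULL` returns the HTML string only.
#' @return The HTML document as a single string, invisibly when written to
#'   `file`.
#' @export
render_results_page <- function(run, readme, plots = character(0),
                                metrics = NULL, file = NULL) {
  stopifnot(inherits(run, "test_run"))
  if (missing(readme) || is.null(readme) || !any(nzchar(trimws(readme)))) {
    stop("refusing to render a results page without a readme (documentation is mandatory)",
         call. = FALSE)
  }
  if (is.null(metrics)) metrics <- run$metrics

  banner_state <- display_state(run$state)
  html <- c(
    "<!DOCTYPE html>",
    "<html><head><meta charset='utf-8'/>",
    sprintf("<title>%s @ r%s</title>", html_escape(run$test), run$revision),
    "<style>", report_css(), "</style></head><body>",
    sprintf('<div class="banner %s">%s @ revision r%s &mdash; %s%s</div>',
            banner_state, html_escape(run$test), run$revision,
            toupper(banner_state),
            if (isTRUE(run$stochastic_pass)) " (stochastic pass after rerun)"
            else ""))

  if (!is.null(run$verdict)) {
    rs <- run$verdict$reasons
    rows <- vapply(seq_len(nrow(rs)), function(i) {
      sprintf("<tr><td>%s</td><td>%s</td><td>%s</td><td>%s</td></tr>",
              html_escape(rs$metric[i]), rs$scope[i],
              html_escape(rs$detail[i]),
              if (rs$passed[i]) "pass" else "fail")
    }, character(1))
    html <- c(html, "<h2>Verdict</h2>",
              "<table><tr><th>metric</th><th>scope</th><th>observed vs cutoff</th><th>verdict</th></tr>",
              rows, "</table>")
  }

  if (length(metrics)) {
    rows <- vapply(names(metrics), function(nm) {
      v <- metrics[[nm]]
      sprintf("<tr><td>%s</td><td>%s</td></tr>", html_escape(nm),
              paste(sprintf("%.4g", v), collapse = ", "))
    }, character(1))
    html <- c(html, "<h2>Metrics</h2>",
              "<table><tr><th>metric</th><th>value(s)</th></tr>", rows,
              "</table>")
  }

  if (length(plots)) {
    html <- c(html, "<h2>Plots</h2>",
              vapply(plots, embed_image, character(1)))
  }

  html <- c(html, "<h2>Documentation</h2>", markdown_to_html(readme),
            "</body></html>")
  doc <- paste(html, collapse = "\n")
  if (!is.null(file)) {
    writeLines(doc, file)
    return(invisible(doc))
  }
  doc
}

#' Render the dashboard index
#'
#' One cell per test-by-revision pair, colored by the five-state semantics
#' (see [run_state_color()]). Tests whose latest run is a breakage (failed
#' or broken) are listed prominently in a section at the top; each
#' revision column is annotated with its committer and commit message when
#' a revision stream is supplied.
#'
#' @param runs list of `test_run`s (possibly several states per test).
#' @param stream optional [revision_stream()] supplying commit metadata.
#' @param file output path; `NULL` returns the HTML string only.
#' @return The HTML document as a single string, invisibly when written to
#'   `file`.
#' @export
render_dashboard <- function(runs, stream = NULL, file = NULL) {
  stopifnot(is.list(runs))
  df <- if (length(runs)) {
    do.call(rbind, lapply(runs, function(r) {
      stopifnot(inherits(r, "test_run"))
      data.frame(test = r$test, revision = as.integer(r$revision),
                 state = r$state, stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(test = character(0), revision = integer(0),
               state = character(0), stringsAsFactors = FALSE)
  }

  tests <- sort(unique(df$test))
  revisions <- if (!is.null(stream)) stream$id else sort(unique(df$revision))

  latest_state <- vapply(tests, function(tn) {
    sub <- df[df$test == tn, ]
    sub$state[which.max(sub$revision)]
  }, character(1))
  broken_tests <- tests[latest_state %in% c("failed", "broken")]

  cell <- function(tn, rev) {
    sub <- df[df$test == tn & df$revision == rev, ]
    if (nrow(sub) == 0L) {
      return('<td class="cell state-queued" title="not yet run"></td>')
    }
    st <- sub$state[nrow(sub)]
    sprintf('<td class="cell state-%s" title="%s: %s"></td>', st,
            html_escape(tn), st)
  }

  grid_rows <- vapply(tests, function(tn) {
    paste0("<tr><th>", html_escape(tn), "</th>",
           paste(vapply(revisions, function(r) cell(tn, r), character(1)),
                 collapse = ""),
           "</tr>")
  }, character(1))

  rev_header <- paste0("<tr><th></th>",
                       paste(sprintf("<th>r%d</th>", revisions),
                             collapse = ""), "</tr>")

  html <- c("<!DOCTYPE html>",
            "<html><head><meta charset='utf-8'/><title>benchmark dashboard</title>",
            "<style>", report_css(), "</style></head><body>",
            "<h1>Benchmark dashboard</h1>",
            "<div id='broken'>",
            "<h2>Broken tests</h2>",
            if (length(broken_tests)) {
              paste0("<ul>",
                     paste(sprintf('<li class="broken-test">%s</li>',
                                   html_escape(broken_tests)),
                           collapse = ""),
                     "</ul>")
            } else "<p>none</p>",
            "</div>",
            "<h2>Test state by revision</h2>",
            "<table>", rev_header, grid_rows, "</table>")

  if (!is.null(stream)) {
    rows <- vapply(seq_len(nrow(stream)), function(i) {
      sprintf("<tr><td>r%d</td><td>%s</td><td>%s</td></tr>", stream$id[i],
              html_escape(stream$author[i]), html_escape(stream$message[i]))
    }, character(1))
    html <- c(html, "<h2>Revisions</h2>",
              "<table><tr><th>revision</th><th>committer</th><th>message</th></tr>",
              rows, "</table>")
  }

  html <- c(html, "</body></html>")
  doc <- paste(html, collapse = "\n")
  if (!is.null(file)) {
    writeLines(doc, file)
    return(invisible(doc))
  }
  doc
}

#' Plot a score-vs-rmsd funnel
#'
#' Scatter of energy against similarity-to-native with the P_Near value
#' annotated; the picture a maintainer reads to judge funnel quality at a
#' glance. Output is deterministic for fixed input.
#'
#' @param ens an [ensemble()].
#' @param pnear optional precomputed P_Near to annotate; computed with
#'   `params` when `NULL`.
#' @param cutoff optional cutoff value drawn as a reference line in the
#'   annotation.
#' @param file output PNG path; `NULL` draws on the active device.
#' @param params [funnel_params()] used when `pnear` is `NULL`.
#' @param width,height device size in pixels.
#' @return The path (invisibly) when writing to `file`.
#' @export
plot_funnel <- function(ens, pnear = NULL, cutoff = NULL, file = NULL,
                        params = funnel_params(), width = 640,
                        height = 480) {
  stopifnot(inherits(ens, "ensemble"))
  if (is.null(pnear)) pnear <- compute_pnear(ens, params)
  draw <- function() {
    m <- ens$models
    graphics::plot(m$similarity, m$energy,
                   xlab = "rmsd to native [Angstrom]",
                   ylab = "energy [REU]",
                   main = sprintf("%s (%s)", ens$target_id,
                                  ens$score_function),
                   pch = 16, cex = 0.6,
                   col = grDevices::adjustcolor("steelblue", 0.6),
                   xlim = c(0, max(m$similarity) * 1.05 + 1e-9))
    lab <- sprintf("P_Near = %.3f", pnear)
    if (!is.null(cutoff)) lab <- paste0(lab, sprintf(" (cutoff %.2f)", cutoff))
    graphics::legend("topright", legend = lab, bty = "n")
  }
  if (is.null(file)) {
    draw()
    return(invisible(NULL))
  }
  grDevices::png(file, width = width, height = height)
  on.exit(grDevices::dev.off())
  draw()
  invisible(file)
}
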