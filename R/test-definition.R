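#' @keywords internal
readme_required_sections <- function() {
  c("Purpose of the test",
    "Benchmark set",
    "Protocol",
    "Quality measures and analysis",
    "Pass/fail criteria",
    "Known limitations",
    "Maintenance")
}

# 5 MB: bundled inputs above this belong in an external data submodule
INPUT_SIZE_WARN_BYTES <- 5 * 1024^2

#' Scaffold a new scientific-test directory
#'
#' Creates a test directory from the standard template: numbered stage
#' scripts (`0.compile` ... `9.finalize`, run consecutively as numbered), a
#' `citation` file, a `cutoffs` file (one cutoff per line), an `observers`
#' file (contact addresses notified on breakage) and a questionnaire-style
#' `readme.md` whose required sections must all be answered before the test
#' validates. Stage 0 is a no-op in mock mode (there is nothing to compile).
#'
#' @param name test name; the directory `destination/name` must not already
#'   exist.
#' @param suite suite label recorded in the readme.
#' @param destination parent directory (must be writable).
#' @return A `test_definition` (see [read_test_definition()]), invisibly.
#' @export
scaffold_test <- function(name, suite = "scientific", destination = ".") {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!dir.exists(destination)) {
    stop("destination does not exist: ", destination, call. = FALSE)
  }
  if (file.access(destination, mode = 2L) != 0L) {
    stop("destination is not writable: ", destination, call. = FALSE)
  }
  dir <- file.path(destination, name)
  if (dir.exists(dir)) {
    stop("refusing to overwrite existing test directory: ", dir,
         call. = FALSE)
  }
  dir.create(dir, recursive = TRUE)
  dir.create(file.path(dir, "input_files"))

  stage_stub <- function(label) {
    c("#!/usr/bin/env Rscript",
      sprintf("# stage '%s'; receives the run working directory as argv[1]", label),
      "args <- commandArgs(trailingOnly = TRUE)",
      "workdir <- args[[1]]",
      sprintf("message('stage %s: nothing to do (template stub)')", label),
      "quit(status = 0)")
  }
  writeLines(stage_stub("compile"), file.path(dir, "0.compile.R"))
  writeLines(stage_stub("submit"), file.path(dir, "1.submit.R"))
  writeLines(stage_stub("analyze"), file.path(dir, "2.analyze.R"))
  writeLines(stage_stub("plot"), file.path(dir, "3.plot.R"))
  writeLines(stage_stub("finalize"), file.path(dir, "9.finalize.R"))
  Sys.chmod(list.files(dir, pattern = "^[0-9]+\\.", full.names = TRUE),
            mode = "0755")

  writeLines(c("# references describing the protocol, the benchmark set and",
               "# the quality measures used by this test"),
             file.path(dir, "citation"))
  writeLines(c("# one cutoff per line: metric direction threshold [scope min_targets]",
               "pnear ge 0.7 aggregate"),
             file.path(dir, "cutoffs"))
  writeLines("maintainer@example.org", file.path(dir, "observers"))

  readme <- c(sprintf("# %s", name),
              "",
              sprintf("Suite: %s", suite),
              "")
  for (s in readme_required_sections()) {
    readme <- c(readme,
                sprintf("## %s", s),
                "",
                "<!-- answer here; short free-form answers defeat the purpose -->",
                "TODO",
                "")
  }
  writeLines(readme, file.path(dir, "readme.md"))

  invisible(read_test_definition(dir, suite = suite))
}

#' Read a test directory into a test definition
#'
#' @param dir path to a scaffolded test directory.
#' @param suite suite label.
#' @return A `test_definition`: name, suite, directory, the ordered stage
#'   descriptors (integer prefix + label + path), readme text, parsed
#'   cutoffs, observers and citations.
#' @export
read_test_definition <- function(dir, suite = "scientific") {
  if (!dir.exists(dir)) stop("no such test directory: ", dir, call. = FALSE)
  stage_files <- list.files(dir, pattern = "^[0-9]+\\.")
  prefix <- as.integer(sub("^([0-9]+)\\..*$", "\\1", stage_files))
  ord <- order(prefix)
  stages <- data.frame(
    prefix = prefix[ord],
    label = sub("^[0-9]+\\.([^.]*).*$", "\\1", stage_files[ord]),
    file = stage_files[ord],
    stringsAsFactors = FALSE)

  read_or_empty <- function(f) {
    p <- file.path(dir, f)
    if (file.exists(p)) readLines(p, warn = FALSE) else character(0)
  }
  strip_comments <- function(x) {
    x <- x[!grepl("^\\s*#", x)]
    x[nzchar(trimws(x))]
  }
  cutoffs_lines <- strip_comments(read_or_empty("cutoffs"))
  cutoffs <- lapply(cutoffs_lines, parse_cutoff_line)

  structure(list(
    name = basename(normalizePath(dir, mustWork = TRUE)),
    suite = suite,
    directory = dir,
    stages = stages,
    readme = read_or_empty("readme.md"),
    cutoffs = cutoffs,
    observers = strip_comments(read_or_empty("observers")),
    citations = strip_comments(read_or_empty("citation"))
  ), class = "test_definition")
}

#' @export
print.test_definition <- function(x, ...) {
  cat(sprintf("<test_definition> %s (suite %s): %d stages, %d cutoffs, %d observers\n",
              x$name, x$suite, nrow(x$stages), length(x$cutoffs),
              length(x$observers)))
  invisible(x)
}

#' Validate the test-directory contract
#'
#' Checks the contract every scientific test must satisfy: at least one
#' numbered stage script with strictly increasing integer prefixes, a
#' non-empty questionnaire readme answering every required section, at least
#' one parseable cutoff, at least one observer, and a citation file. Bundled
#' input files above 5 MB trigger a warning entry recommending an external
#' data submodule (a warning, not a violation). Validation only reads the
#' directory, so it is idempotent and independent of the order in which
#' files were created.
#'
#' @param x a `test_definition` or a directory path.
#' @return A list of class `test_validation` with logical `ok`, character
#'   `problems`, character `warnings`.
#' @export
validate_test <- function(x) {
  if (is.character(x)) x <- read_test_definition(x)
  stopifnot(inherits(x, "test_definition"))
  problems <- character(0)
  warnings <- character(0)

  st <- x$stages
  if (nrow(st) == 0L) {
    problems <- c(problems, "no numbered stage scripts (expected 0.compile ... 9.finalize)")
  } else {
    if (any(duplicated(st$prefix)) || is.unsorted(st$prefix, strictly = TRUE)) {
      problems <- c(problems, "stage prefixes must be strictly increasing integers")
    }
  }

  if (length(x$readme) == 0L || !any(nzchar(trimws(x$readme)))) {
    problems <- c(problems, "readme.md missing or empty (documentation is mandatory)")
  } else {
    for (s in readme_required_sections()) {
      if (!any(grepl(paste0("^##\\s*", s), x$readme, fixed = FALSE))) {
        problems <- c(problems,
                      sprintf("readme.md missing required section '%s'", s))
      }
    }
  }

  if (length(x$cutoffs) == 0L) {
    problems <- c(problems, "cutoffs file defines no cutoffs")
  }
  if (length(x$observers) == 0L) {
    problems <- c(problems, "observers file lists no contact addresses")
  }
  if (!file.exists(file.path(x$directory, "citation"))) {
    problems <- c(problems, "citation file missing")
  }

  input_dir <- file.path(x$directory, "input_files")
  if (dir.exists(input_dir)) {
    sizes <- file.size(list.files(input_dir, recursive = TRUE,
                                  full.names = TRUE))
    total <- sum(sizes, na.rm = TRUE)
    if (isTRUE(total > INPUT_SIZE_WARN_BYTES)) {
      warnings <- c(warnings, sprintf(
        "bundled input files total %.1f MB (> 5 MB): move them to an external data submodule",
        total / 1024^2))
    }
  }

  structure(list(ok = length(problems) == 0L, problems = problems,
                 warnings = warnings, test = x$name),
            class = "test_validation")
}

#' @export
print.test_validation <- function(x, ...) {
  cat(sprintf("<test_validation> %s: %s\n", x$test,
              if (x$ok) "OK" else "CONTRACT VIOLATIONS"))
  for (p in x$problems) cat("  problem:", p, "\n")
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Cutoff specifications
#'
#' A cutoff compares one named metric against a threshold. `scope`
#' `"aggregate"` compares a single summary value; `"per_target"` requires at
#' least `min_targets_passing` targets to individually satisfy the
#' threshold. The on-disk format is one cutoff per line:
#' `metric direction threshold [scope min_targets]`.
#'
#' @param metric metric name, as produced by the analysis stage.
#' @param direction `"ge"` (metric must be at least the threshold) or
#'   `"le"` (at most).
#' @param threshold finite numeric threshold.
#' @param scope `"aggregate"` (default) or `"per_target"`.
#' @param min_targets_passing for `per_target` scope, how many targets must
#'   pass.
#' @return An object of class `cutoff_spec`.
#' @export
cutoff_spec <- function(metric, direction = c("ge", "le"), threshold,
                        scope = c("aggregate", "per_target"),
                        min_targets_passing = NULL) {
  direction <- match.arg(direction)
  scope <- match.arg(scope)
  stopifnot(is.character(metric), length(metric) == 1L,
            is.numeric(threshold), length(threshold) == 1L,
            is.finite(threshold))
  if (scope == "per_target") {
    if (is.null(min_targets_passing) || min_targets_passing < 1L) {
      stop("per_target cutoffs need `min_targets_passing` >= 1",
           call. = FALSE)
    }
  }
  structure(list(metric = metric, direction = direction,
                 threshold = as.numeric(threshold), scope = scope,
                 min_targets_passing =
                   if (scope == "per_target") as.integer(min_targets_passing)
                   else NA_integer_),
            class = "cutoff_spec")
}

#' @rdname cutoff_spec
#' @param line a single cutoffs-file line.
#' @export
parse_cutoff_line <- function(line) {
  parts <- strsplit(trimws(line), "[ \t]+")[[1L]]
  if (length(parts) < 3L) {
    stop("malformed cutoff line: ", line, call. = FALSE)
  }
  cutoff_spec(metric = parts[[1L]],
              direction = parts[[2L]],
              threshold = as.numeric(parts[[3L]]),
              scope = if (length(parts) >= 4L) parts[[4L]] else "aggregate",
              min_targets_passing =
                if (length(parts) >= 5L) as.integer(parts[[5L]]) else NULL)
}

#' @export
format.cutoff_spec <- function(x, ...) {
  s <- sprintf("%s %s %g %s", x$metric, x$direction, x$threshold, x$scope)
  if (x$scope == "per_target") s <- paste(s, x$min_targets_passing)
  s
}

#' @export
print.cutoff_spec <- function(x, ...) {
  cat("<cutoff>", format(x), "\n")
  invisible(x)
}
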