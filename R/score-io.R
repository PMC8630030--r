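#' Read a scored-model table into an ensemble
#'
#' Two dialects are supported. `rosetta_scorefile` is the whitespace table
#' whose data lines start with `SCORE:`; the first such line is the header
#' and the `description` column names each model. `delimited` is an ordinary
#' comma- or tab-separated table with a header row (the separator is sniffed
#' from the header line unless given). Rows whose energy or similarity field
#' is not numeric are rejected; the number of rejected rows is attached as
#' attribute `rejected_rows` and reported via a message.
#'
#' @param path path to the score table.
#' @param dialect `"rosetta_scorefile"` or `"delimited"`.
#' @param energy_col name of the energy column (default `"total_score"`).
#' @param similarity_col name of the similarity column (default `"rmsd"`).
#' @param tag_col name of the model-identifier column (default
#'   `"description"`); if absent, tags are generated.
#' @param sep field separator for the `delimited` dialect; `NULL` sniffs
#'   comma vs tab.
#' @param target_id,score_function,protocol metadata for the returned
#'   [ensemble()].
#' @return An [ensemble()]; `attr(, "rejected_rows")` counts discarded rows.
#' @export
read_score_table <- function(path,
                             dialect = c("rosetta_scorefile", "delimited"),
                             energy_col = "total_score",
                             similarity_col = "rmsd",
                             tag_col = "description",
                             sep = NULL,
                             target_id = NULL,
                             score_function = NA_character_,
                             protocol = NA_character_) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.null(target_id)) {
    target_id <- tools::file_path_sans_ext(basename(path))
  }

  if (dialect == "rosetta_scorefile") {
    lines <- readLines(path, warn = FALSE)
    score_lines <- grep("^SCORE:", lines, value = TRUE)
    if (length(score_lines) == 0L) {
      stop("no SCORE: lines found in ", path, call. = FALSE)
    }
    fields <- lapply(score_lines, function(l) {
      strsplit(trimws(sub("^SCORE:", "", l)), "[ \t]+")[[1L]]
    })
    header <- fields[[1L]]
    rows <- fields[-1L]
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) stop("empty table: ", path, call. = FALSE)
    if (is.null(sep)) {
      sep <- if (grepl("\t", lines[[1L]])) "\t" else ","
    }
    fields <- strsplit(lines, sep, fixed = TRUE)
    fields <- lapply(fields, trimws)
    header <- fields[[1L]]
    rows <- fields[-1L]
  }

  for (col in c(energy_col, similarity_col)) {
    if (!col %in% header) {
      stop(sprintf("column '%s' not found in header of %s", col, path),
           call. = FALSE)
    }
  }
  e_i <- match(energy_col, header)
  s_i <- match(similarity_col, header)
  t_i <- match(tag_col, header)

  n_rejected <- 0L
  tags <- character(0)
  energy <- numeric(0)
  similarity <- numeric(0)
  for (k in seq_along(rows)) {
    r <- rows[[k]]
    if (length(r) != length(header)) {
      n_rejected <- n_rejected + 1L
      next
    }
    e <- suppressWarnings(as.numeric(r[[e_i]]))
    s <- suppressWarnings(as.numeric(r[[s_i]]))
    if (!is.finite(e) || !is.finite(s) || s < 0) {
      n_rejected <- n_rejected + 1L
      next
    }
    energy <- c(energy, e)
    similarity <- c(similarity, s)
    tags <- c(tags, if (!is.na(t_i)) r[[t_i]] else sprintf("model_%04d", k))
  }
  if (length(energy) == 0L) {
    stop(sprintf("no valid data rows in %s (%d rejected)", path, n_rejected),
         call. = FALSE)
  }
  if (n_rejected > 0L) {
    message(sprintf("read_score_table: rejected %d malformed row(s) in %s",
                    n_rejected, basename(path)))
  }
  if (anyDuplicated(tags)) tags <- make.unique(tags, sep = "_")
  ens <- ensemble(energy = energy, similarity = similarity, tag = tags,
                  target_id = target_id, score_function = score_function,
                  protocol = protocol)
  attr(ens, "rejected_rows") <- n_rejected
  ens
}

#' Write an ensemble as a score table
#'
#' Writes either the `SCORE:`-prefixed whitespace dialect (with a
#' `description` column holding the model tags) or a plain tab-delimited
#' table.
#'
#' @param ens an [ensemble()].
#' @param path output path.
#' @param dialect `"rosetta_scorefile"` or `"delimited"`.
#' @param energy_col,similarity_col column names used in the header.
#' @return `path`, invisibly.
#' @export
write_score_table <- function(ens, path,
                              dialect = c("rosetta_scorefile", "delimited"),
                              energy_col = "total_score",
                              similarity_col = "rmsd") {
  stopifnot(inherits(ens, "ensemble"))
  dialect <- match.arg(dialect)
  m <- ens$models
  if (dialect == "rosetta_scorefile") {
    header <- paste("SCORE:", energy_col, similarity_col, "description")
    body <- sprintf("SCORE: %.3f %.3f %s", m$energy, m$similarity, m$tag)
    writeLines(c(header, body), path)
  } else {
    df <- data.frame(m$energy, m$similarity, m$tag)
    names(df) <- c(energy_col, similarity_col, "description")
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
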