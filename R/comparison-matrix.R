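#' Target-by-score-function comparison matrices
#'
#' A `comparison_matrix` holds one metric value per (target, score function)
#' cell, with `NA` marking cells for which no data are available (shown in
#' gray in summary heat maps). It is the input to [winner_takes_all()] and
#' [column_average()].
#'
#' @param values numeric matrix (or object coercible to one); `NA` marks a
#'   missing cell.
#' @param targets row labels (benchmark targets); defaults to existing
#'   rownames.
#' @param score_functions column labels; defaults to existing colnames.
#' @return An object of class `comparison_matrix` (a numeric matrix with
#'   dimnames).
#' @examples
#' m <- comparison_matrix(rbind(c(0.2, 0.9), c(0.4, NA)),
#'                        targets = c("1abc", "2xyz"),
#'                        score_functions = c("talaris2014", "ref2015"))
#' @export
comparison_matrix <- function(values, targets = NULL, score_functions = NULL) {
  m <- as.matrix(values)
  storage.mode(m) <- "double"
  if (!is.null(targets)) rownames(m) <- targets
  if (!is.null(score_functions)) colnames(m) <- score_functions
  if (is.null(rownames(m))) rownames(m) <- sprintf("target_%d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- sprintf("sfxn_%d", seq_len(ncol(m)))
  if (any(duplicated(rownames(m))) || any(duplicated(colnames(m)))) {
    stop("row and column labels must be unique", call. = FALSE)
  }
  class(m) <- c("comparison_matrix", class(m))
  m
}

#' @export
print.comparison_matrix <- function(x, ...) {
  cat(sprintf("<comparison_matrix> %d targets x %d score functions (%d missing cells)\n",
              nrow(x), ncol(x), sum(is.na(x))))
  print(unclass(x), ...)
  invisible(x)
}

#' Winner-takes-all points per score function
#'
#' For each target (row) where every score function has a value, the best
#' score function gets a point; points are then summed by column. Exact ties
#' split the point equally, so the total number of points distributed always
#' equals the number of complete rows. Rows with any missing cell are
#' excluded entirely (an incomplete row cannot name a fair winner).
#'
#' @param x a [comparison_matrix()].
#' @param orientation `"higher"` if larger metric values win (e.g. P_Near,
#'   the default), `"lower"` if smaller values win (e.g. an rmsd).
#' @return Named numeric vector of points, one per score function.
#' @examples
#' m <- comparison_matrix(rbind(c(0.2, 0.9), c(0.4, 0.8), c(0.1, 0.7)))
#' winner_takes_all(m)
#' @export
winner_takes_all <- function(x, orientation = c("higher", "lower")) {
  orientation <- match.arg(orientation)
  m <- unclass(x)
  if (length(m) == 0L || nrow(m) == 0L || ncol(m) == 0L) {
    stop("empty comparison matrix", call. = FALSE)
  }
  pts <- stats::setNames(numeric(ncol(m)), colnames(m))
  complete <- rowSums(is.na(m)) == 0L
  for (i in which(complete)) {
    row <- m[i, ]
    best <- if (orientation == "higher") row == max(row) else row == min(row)
    pts[best] <- pts[best] + 1 / sum(best)
  }
  pts
}

#' Column averages of a comparison matrix
#'
#' Arithmetic mean of each score function's metric over the targets for which
#' it has a value; missing cells are simply left out of their column's mean.
#'
#' @param x a [comparison_matrix()].
#' @return Named numeric vector of per-column means.
#' @export
column_average <- function(x) {
  m <- unclass(x)
  if (length(m) == 0L || nrow(m) == 0L || ncol(m) == 0L) {
    stop("empty comparison matrix", call. = FALSE)
  }
  all_missing <- colSums(!is.na(m)) == 0L
  if (any(all_missing)) {
    stop("column(s) with no available data: ",
         paste(colnames(m)[all_missing], collapse = ", "), call. = FALSE)
  }
  colMeans(m, na.rm = TRUE)
}

#' Read/write comparison matrices as delimited tables
#'
#' Tab-delimited table with a header row of score-function names, target
#' names in the first column, and the literal token `NA` for unavailable
#' cells.
#'
#' @param path file path.
#' @return For the reader, a [comparison_matrix()]; the writer returns
#'   `path` invisibly.
#' @export
read_comparison_matrix <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          na.strings = "NA", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("comparison-matrix table needs a target column plus at least one score function", call. = FALSE)
  comparison_matrix(as.matrix(df[, -1L, drop = FALSE]),
                    targets = as.character(df[[1L]]))
}

#' @rdname read_comparison_matrix
#' @param x a [comparison_matrix()].
#' @export
write_comparison_matrix <- function(x, path) {
  stopifnot(inherits(x, "comparison_matrix"))
  df <- data.frame(target = rownames(x), unclass(x), check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, na = "NA",
                     row.names = FALSE)
  invisible(path)
}
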