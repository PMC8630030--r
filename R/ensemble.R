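#' Scored-model ensembles
#'
#' An `ensemble` holds the scored models produced by one protocol run on one
#' benchmark target: for every model an energy (in Rosetta Energy Units, REU,
#' lower is better) and a similarity-to-native measure (an rmsd in Angstrom or
#' a protocol-specific analogue, lower is better, never negative), plus an
#' identifying tag and optional auxiliary columns such as an interface score.
#' Every quality metric in the package consumes this container.
#'
#' @param energy numeric vector of per-model total energies (REU). Must be
#'   finite.
#' @param similarity numeric vector of per-model distances to the native
#'   structure (Angstrom or analogous units). Must be finite and `>= 0`.
#' @param tag optional character vector of model identifiers; defaults to
#'   `model_0001`, `model_0002`, ...
#' @param target_id name of the benchmark target (e.g. a PDB id).
#' @param score_function label of the score function that produced the
#'   energies.
#' @param protocol label of the sampling protocol.
#' @param extras optional data frame (or named list) of auxiliary per-model
#'   columns, e.g. `I_sc`, `I_rmsd`.
#'
#' @return An object of class `ensemble`: a list with elements `target_id`,
#'   `models` (a data frame with columns `tag`, `energy`, `similarity` and any
#'   extras), `score_function` and `protocol`.
#' @examples
#' ens <- ensemble(energy = c(-12, -8, -1), similarity = c(0.4, 1.2, 9.8),
#'                 target_id = "3eo1", score_function = "ref2015")
#' n_models(ens)
#' @seealso [compute_pnear()], [read_score_table()], [generate_ensemble()]
#' @export
ensemble <- function(energy, similarity, tag = NULL, target_id = "target",
                     score_function = NA_character_, protocol = NA_character_,
                     extras = NULL) {
  if (length(energy) != length(similarity)) {
    stop("`energy` and `similarity` must have the same length", call. = FALSE)
  }
  if (length(energy) < 1L) {
    stop("an ensemble needs at least one model", call. = FALSE)
  }
  if (is.null(tag)) {
    tag <- sprintf("model_%04d", seq_along(energy))
  }
  if (anyDuplicated(tag)) {
    stop("model tags must be unique", call. = FALSE)
  }
  models <- data.frame(tag = as.character(tag),
                       energy = as.numeric(energy),
                       similarity = as.numeric(similarity),
                       stringsAsFactors = FALSE)
  if (!is.null(extras)) {
    extras <- as.data.frame(extras, stringsAsFactors = FALSE)
    if (nrow(extras) != nrow(models)) {
      stop("`extras` must have one row per model", call. = FALSE)
    }
    models <- cbind(models, extras)
  }
  out <- structure(
    list(target_id = as.character(target_id), models = models,
         score_function = as.character(score_function),
         protocol = as.character(protocol)),
    class = "ensemble")
  validate_ensemble(out)
  out
}

#' Validate an ensemble's invariants
#'
#' Checks that all energies are finite and all similarities are finite and
#' non-negative, naming the offending model tag on failure.
#'
#' @param x an [ensemble()].
#' @return `x`, invisibly, if valid; otherwise an error.
#' @export
validate_ensemble <- function(x) {
  stopifnot(inherits(x, "ensemble"))
  m <- x$models
  if (nrow(m) < 1L) stop("an ensemble needs at least one model", call. = FALSE)
  bad_e <- !is.finite(m$energy)
  bad_s <- !is.finite(m$similarity) | m$similarity < 0
  if (any(bad_e) || any(bad_s)) {
    offenders <- unique(m$tag[bad_e | bad_s])
    stop("invalid energy/similarity for model(s): ",
         paste(offenders, collapse = ", "), call. = FALSE)
  }
  invisible(x)
}

#' @rdname ensemble
#' @param x an `ensemble`.
#' @export
n_models <- function(x) {
  stopifnot(inherits(x, "ensemble"))
  nrow(x$models)
}

#' @export
print.ensemble <- function(x, ...) {
  cat(sprintf("<ensemble> target %s: %d models (score function: %s)\n",
              x$target_id, nrow(x$models), x$score_function))
  cat(sprintf("  energy   [%.3f, %.3f] REU\n",
              min(x$models$energy), max(x$models$energy)))
  cat(sprintf("  similarity [%.3f, %.3f]\n",
              min(x$models$similarity), max(x$models$similarity)))
  invisible(x)
}

#' @export
as.data.frame.ensemble <- function(x, ...) {
  x$models
}
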