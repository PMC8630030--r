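#' Parameters of the funnel-quality metric
#'
#' P_Near depends on two tunables: `lambda`, the Gaussian length scale (in
#' Angstrom) deciding how close to the native a model must be to count as
#' "near", and `kbt`, the Boltzmann temperature factor (in REU) converting
#' energies into statistical weights. The shipped comparison configuration
#' uses `lambda = 4.0`; `kbt` defaults to 0.62 REU and is always recorded
#' alongside results so comparisons are reproducible.
#'
#' @param lambda Gaussian proximity length scale, Angstrom; must be `> 0`.
#'   Larger values count more-distant models as near-native.
#' @param kbt Boltzmann factor, REU; must be `> 0`. Smaller values
#'   concentrate weight on the lowest-energy models.
#' @return An object of class `funnel_params`.
#' @examples
#' funnel_params()
#' funnel_params(lambda = 2.0)
#' @export
funnel_params <- function(lambda = 4.0, kbt = 0.62) {
  if (!is.numeric(lambda) || length(lambda) != 1L || !is.finite(lambda) ||
      lambda <= 0) {
    stop("`lambda` must be a single positive number", call. = FALSE)
  }
  if (!is.numeric(kbt) || length(kbt) != 1L || !is.finite(kbt) || kbt <= 0) {
    stop("`kbt` must be a single positive number", call. = FALSE)
  }
  structure(list(lambda = as.numeric(lambda), kbt = as.numeric(kbt)),
            class = "funnel_params")
}

#' @export
print.funnel_params <- function(x, ...) {
  cat(sprintf("<funnel_params> lambda = %g Angstrom, kbt = %g REU\n",
              x$lambda, x$kbt))
  invisible(x)
}

#' Boltzmann-weighted funnel quality (P_Near)
#'
#' Computes the funnel-quality metric of a score-vs-rmsd ensemble,
#'
#' \deqn{P_{Near} = \frac{\sum_i e^{-r_i^2/\lambda^2}\, e^{-E_i/k_B T}}
#'                      {\sum_j e^{-E_j/k_B T}}}
#'
#' where \eqn{r_i} is model i's similarity to the native and \eqn{E_i} its
#' energy. The value lies in \eqn{[0, 1]}: 1 indicates a perfect funnel
#' (all Boltzmann weight on near-native models), 0 no funnel or an incorrect
#' global minimum. Energies enter only through differences, so the result is
#' invariant under any constant shift of all energies; the implementation
#' subtracts the minimum energy before exponentiating (a log-sum-exp-style
#' stabilisation), so arbitrarily large energy magnitudes do not overflow.
#'
#' @param ens an [ensemble()].
#' @param params a [funnel_params()].
#' @return A single number in `[0, 1]`.
#' @examples
#' ens <- ensemble(energy = c(-3, -1, 0, 2, 7), similarity = rep(0, 5))
#' compute_pnear(ens)  # 1: every model is exactly native
#' @export
compute_pnear <- function(ens, params = funnel_params()) {
  stopifnot(inherits(ens, "ensemble"), inherits(params, "funnel_params"))
  validate_ensemble(ens)
  m <- ens$models
  # shift by the minimum energy: exact invariance, no overflow for large |E|
  e <- m$energy - min(m$energy)
  w <- exp(-e / params$kbt)
  prox <- exp(-(m$similarity^2) / params$lambda^2)
  sum(prox * w) / sum(w)
}

#' Correlation between predicted and experimental quantities
#'
#' Pearson or Spearman correlation plus its square, as used to compare
#' predicted against experimentally measured quantities (e.g. ddG of
#' mutation, or folding propensity against IC50). Spearman is computed on
#' ranks with average-rank ties.
#'
#' @param x,y numeric vectors of equal length `>= 3`; neither may be
#'   constant.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return A list of class `metric_correlation` with elements `coefficient`
#'   (in `[-1, 1]`), `r_squared` (`coefficient^2`), `method`, `n`.
#' @examples
#' metric_correlation(1:10, 2 * (1:10) + 1)$coefficient  # 1
#' @export
metric_correlation <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y)) {
    stop("`x` and `y` must have the same length", call. = FALSE)
  }
  if (length(x) < 3L) {
    stop("need at least 3 paired observations", call. = FALSE)
  }
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("`x` and `y` must be finite", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant vector: correlation undefined", call. = FALSE)
  }
  r <- stats::cor(x, y, method = method)
  structure(list(coefficient = r, r_squared = r^2, method = method,
                 n = length(x)),
            class = "metric_correlation")
}

#' @export
print.metric_correlation <- function(x, ...) {
  cat(sprintf("%s correlation: r = %.4f, r^2 = %.4f (n = %d)\n",
              x$method, x$coefficient, x$r_squared, x$n))
  invisible(x)
}

#' Select the n lowest-scoring (best) models
#'
#' Returns the sub-ensemble of the `n` models with the smallest energies, as
#' used e.g. for the average sequence similarity of the 10 lowest-scoring
#' models in design benchmarks. Ties in energy are broken by model tag in
#' lexicographic order, so the selection is deterministic.
#'
#' @param ens an [ensemble()].
#' @param n number of models to keep, `1 <= n <= n_models(ens)`.
#' @return An `ensemble` with `n` models, ordered by increasing energy.
#' @export
select_lowest_scoring <- function(ens, n) {
  stopifnot(inherits(ens, "ensemble"))
  if (!is.numeric(n) || length(n) != 1L || n != as.integer(n) ||
      n < 1L || n > n_models(ens)) {
    stop("`n` must be an integer between 1 and the ensemble size",
         call. = FALSE)
  }
  m <- ens$models
  ord <- order(m$energy, m$tag)
  out <- ens
  out$models <- m[ord[seq_len(n)], , drop = FALSE]
  rownames(out$models) <- NULL
  out
}

#' Sequence recovery
#'
#' Fraction of positions at which a designed sequence recovers the native
#' residue identity.
#'
#' @param native,designed residue strings (single characters per position) of
#'   equal length `>= 1`.
#' @return A number in `[0, 1]`.
#' @examples
#' sequence_recovery("ACDEFG", "ACDEYG")  # 5/6
#' @export
sequence_recovery <- function(native, designed) {
  stopifnot(is.character(native), is.character(designed),
            length(native) == 1L, length(designed) == 1L)
  a <- strsplit(native, "", fixed = TRUE)[[1L]]
  b <- strsplit(designed, "", fixed = TRUE)[[1L]]
  if (length(a) != length(b)) {
    stop("`native` and `designed` must have the same length", call. = FALSE)
  }
  if (length(a) < 1L) stop("sequences must be non-empty", call. = FALSE)
  mean(a == b)
}

#' Metric orientation registry
#'
#' Declares, for the metric names the harness knows about, whether a larger
#' or a smaller value is better, so that cutoffs and winner-takes-all
#' comparisons are unambiguous. Names are matched case-insensitively;
#' rmsd-like names (containing "rmsd") are lower-is-better, everything else
#' registered (pnear, recovery, correlations, points) is higher-is-better.
#'
#' @param metric metric name (character scalar).
#' @return `"higher"` or `"lower"`.
#' @examples
#' metric_orientation("pnear")   # "higher"
#' metric_orientation("I_rmsd")  # "lower"
#' @export
metric_orientation <- function(metric) {
  stopifnot(is.character(metric), length(metric) == 1L)
  key <- tolower(metric)
  if (grepl("rmsd", key)) return("lower")
  known_higher <- c("pnear", "p_near", "sequence_recovery", "seqrec",
                    "recovery", "pearson", "spearman", "correlation", "r2",
                    "r_squared", "points", "accuracy", "coverage",
                    "precision")
  if (key %in% known_higher) return("higher")
  "higher"
}
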