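# Independent brute-force reference implementations. These deliberately use
# naive direct summation / enumeration, not the package's code paths.

# two-pass direct summation, no stabilisation shift
pnear_oracle <- function(energy, similarity, lambda = 4.0, kbt = 0.62) {
  num <- 0
  den <- 0
  for (i in seq_along(energy)) {
    num <- num + exp(-similarity[i]^2 / lambda^2) * exp(-energy[i] / kbt)
  }
  for (j in seq_along(energy)) {
    den <- den + exp(-energy[j] / kbt)
  }
  num / den
}

# textbook product-moment formula
pearson_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}

# Spearman = Pearson on average-ranks
spearman_oracle <- function(x, y) {
  pearson_oracle(rank(x, ties.method = "average"),
                 rank(y, ties.method = "average"))
}

# per-row argmax enumeration with fractional ties; skips incomplete rows
wta_oracle <- function(m) {
  pts <- stats::setNames(numeric(ncol(m)), colnames(m))
  for (i in seq_len(nrow(m))) {
    row <- m[i, ]
    if (any(is.na(row))) next
    winners <- which(row == max(row))
    for (w in winners) pts[w] <- pts[w] + 1 / length(winners)
  }
  pts
}

# masked column mean by explicit loop
colavg_oracle <- function(m) {
  out <- stats::setNames(numeric(ncol(m)), colnames(m))
  for (j in seq_len(ncol(m))) {
    v <- m[, j]
    out[j] <- sum(v[!is.na(v)]) / sum(!is.na(v))
  }
  out
}

# oracle verdicts for a bisect with true breakage at `culprit`
bisect_oracle_verdict <- function(revision, culprit) {
  if (revision >= culprit) "failed" else "passed"
}

make_random_ensemble <- function(n = 50, seed = NULL,
                                 energy_sd = 10, sim_max = 20) {
  if (!is.null(seed)) set.seed(seed)
  ensemble(energy = rnorm(n, 0, energy_sd),
           similarity = runif(n, 0, sim_max))
}
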