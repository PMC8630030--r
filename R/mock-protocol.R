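# run code under a temporary RNG state, restoring the caller's stream
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    get(".Random.seed", envir = .GlobalEnv)
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
        rm(".Random.seed", envir = .GlobalEnv)
      }
    } else {
      assign(".Random.seed", old, envir = .GlobalEnv)
    }
  })
  set.seed(seed)
  force(code)
}

#' Mock protocol parameters
#'
#' Defines the score-vs-rmsd landscape the mock Monte-Carlo protocol
#' samples. Each model independently lands in the native basin (with
#' probability `f_native`: rmsd is `|Normal(0, native_sigma)|` and energy
#' rises linearly with rmsd from the basin floor), in a broad decoy cloud
#' (uniform rmsd, Gaussian energies), or — when configured — in an
#' alternative, incorrect minimum, emulating the pathology where a score
#' function lowers the energy of a wrong conformation. Energy noise is
#' Gaussian for analyzability; a real energy landscape is not.
#'
#' The defaults describe a healthy protocol: 500 models, 90% native
#' occupancy, a steep funnel (5 REU/A) and a decoy cloud 20 REU above the
#' native floor, which yields P_Near close to 1.
#'
#' @param n_models number of models per run.
#' @param f_native fraction of trajectories landing in the native basin,
#'   in `[0, 1]`.
#' @param native_sigma native basin width, Angstrom (`> 0`).
#' @param funnel_slope energy increase per Angstrom inside the basin,
#'   REU/A.
#' @param e_floor native-basin energy floor, REU.
#' @param e_decoy_mean,e_decoy_sigma decoy-cloud energy distribution, REU.
#' @param decoy_rmsd_range length-2 numeric `(lo, hi)` Angstrom; `lo` must
#'   exceed `3 * native_sigma` so the basins do not overlap.
#' @param alt_basin optional alternative minimum: a list with elements
#'   `rmsd` (A), `energy` (REU), `width` (A) and optionally `fraction`
#'   (share of all models drawn there; default half of the non-native
#'   mass).
#' @param noise_sigma energy noise inside the native/alternative basins,
#'   REU (`> 0`).
#' @param seed RNG seed; `NULL` leaves the caller's RNG stream in charge.
#' @return An object of class `mock_protocol_params`.
#' @export
mock_protocol_params <- function(n_models = 500L,
                                 f_native = 0.9,
                                 native_sigma = 0.5,
                                 funnel_slope = 5,
                                 e_floor = -30,
                                 e_decoy_mean = -10,
                                 e_decoy_sigma = 5,
                                 decoy_rmsd_range = c(5, 30),
                                 alt_basin = NULL,
                                 noise_sigma = 1,
                                 seed = NULL) {
  p <- structure(list(n_models = as.integer(n_models), f_native = f_native,
                      native_sigma = native_sigma,
                      funnel_slope = funnel_slope, e_floor = e_floor,
                      e_decoy_mean = e_decoy_mean,
                      e_decoy_sigma = e_decoy_sigma,
                      decoy_rmsd_range = as.numeric(decoy_rmsd_range),
                      alt_basin = alt_basin, noise_sigma = noise_sigma,
                      seed = seed),
                 class = "mock_protocol_params")
  validate_mock_params(p)
  p
}

#' @rdname mock_protocol_params
#' @param p a `mock_protocol_params`.
#' @export
validate_mock_params <- function(p) {
  stopifnot(inherits(p, "mock_protocol_params"))
  if (p$n_models < 1L) stop("n_models must be >= 1", call. = FALSE)
  if (!is.finite(p$f_native) || p$f_native < 0 || p$f_native > 1) {
    stop("f_native must lie in [0, 1]", call. = FALSE)
  }
  if (p$native_sigma <= 0 || p$e_decoy_sigma <= 0 || p$noise_sigma <= 0) {
    stop("all sigmas must be > 0", call. = FALSE)
  }
  if (length(p$decoy_rmsd_range) != 2L ||
      p$decoy_rmsd_range[1L] >= p$decoy_rmsd_range[2L]) {
    stop("decoy_rmsd_range must be (lo, hi) with lo < hi", call. = FALSE)
  }
  if (p$decoy_rmsd_range[1L] <= 3 * p$native_sigma) {
    stop("decoy_rmsd_range[1] must exceed 3 * native_sigma (basins would overlap)",
         call. = FALSE)
  }
  if (!is.null(p$alt_basin)) {
    ab <- p$alt_basin
    if (!is.list(ab) || !all(c("rmsd", "energy", "width") %in% names(ab))) {
      stop("alt_basin needs elements rmsd, energy, width", call. = FALSE)
    }
    if (ab$width <= 0) stop("alt_basin width must be > 0", call. = FALSE)
    if (!is.null(ab$fraction) &&
        (ab$fraction < 0 || ab$fraction > 1 - p$f_native)) {
      stop("alt_basin fraction must lie in [0, 1 - f_native]", call. = FALSE)
    }
  }
  invisible(p)
}

#' Generate a mock score-vs-rmsd ensemble
#'
#' Samples `n_models` independent trajectories from the landscape described
#' by `params`. Fully deterministic given `params$seed`.
#'
#' @param params a [mock_protocol_params()].
#' @param target_id,score_function,protocol metadata for the returned
#'   [ensemble()].
#' @return An [ensemble()] of `params$n_models` models.
#' @examples
#' ens <- generate_ensemble(mock_protocol_params(n_models = 100, seed = 1))
#' compute_pnear(ens)
#' @export
generate_ensemble <- function(params, target_id = "mock_target",
                              score_function = "mock",
                              protocol = "mock_monte_carlo") {
  validate_mock_params(params)
  with_seed(params$seed, {
    n <- params$n_models
    f_alt <- if (is.null(params$alt_basin)) 0
             else if (!is.null(params$alt_basin$fraction)) params$alt_basin$fraction
             else (1 - params$f_native) / 2
    u <- stats::runif(n)
    kind <- ifelse(u < params$f_native, "native",
                   ifelse(u < params$f_native + f_alt, "alt", "decoy"))

    rmsd <- numeric(n)
    energy <- numeric(n)
    i <- kind == "native"
    if (any(i)) {
      r <- abs(stats::rnorm(sum(i), 0, params$native_sigma))
      rmsd[i] <- r
      energy[i] <- params$e_floor + params$funnel_slope * r +
        stats::rnorm(sum(i), 0, params$noise_sigma)
    }
    i <- kind == "alt"
    if (any(i)) {
      ab <- params$alt_basin
      r <- abs(stats::rnorm(sum(i), ab$rmsd, ab$width))
      rmsd[i] <- r
      energy[i] <- ab$energy + stats::rnorm(sum(i), 0, params$noise_sigma)
    }
    i <- kind == "decoy"
    if (any(i)) {
      rmsd[i] <- stats::runif(sum(i), params$decoy_rmsd_range[1L],
                              params$decoy_rmsd_range[2L])
      energy[i] <- stats::rnorm(sum(i), params$e_decoy_mean,
                                params$e_decoy_sigma)
    }
    ensemble(energy = energy, similarity = rmsd,
             tag = sprintf("model_%04d", seq_len(n)),
             target_id = target_id, score_function = score_function,
             protocol = protocol)
  })
}

#' Derive a per-run payload seed
#'
#' Stable integer hash of the history seed and the (test, revision,
#' attempt) tuple, kept below 2^31. Repeated attempts of the same test at
#' the same revision get different seeds — the harness never pins the
#' scientific payload to a fixed trajectory; the derived seed exists so a
#' run can be replayed forensically, and it is logged in every `test_run`.
#'
#' @param seed base seed of the revision history.
#' @param ... components of the run identity (coerced to character).
#' @return An integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  key <- paste(vapply(list(...), as.character, character(1)), collapse = "\r")
  h <- as.double(abs(as.integer(seed)) %% 2147483647)
  for (b in utf8ToInt(key)) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

#' Revision-indexed mock history
#'
#' Describes a stream of `n_revisions` consecutive revisions of the mock
#' protocol, with an optional regression: revisions before `breakage_at`
#' sample from `baseline` parameters, revisions at or after it from
#' `degraded` parameters.
#'
#' @param n_revisions number of revisions (ids `1 ... n_revisions`).
#' @param breakage_at revision index at which the regression lands, or
#'   `NULL` for a healthy history.
#' @param baseline,degraded [mock_protocol_params()] before/after the
#'   breakage; `degraded` defaults to a collapsed funnel (low native
#'   occupancy and a decoy cloud dropped below the native floor — a wrong
#'   global minimum).
#' @param seed base seed from which each run's payload seed is derived.
#' @return An object of class `revision_history_spec`.
#' @export
revision_history_spec <- function(n_revisions, breakage_at = NULL,
                                  baseline = mock_protocol_params(),
                                  degraded = NULL, seed = 1L) {
  n_revisions <- as.integer(n_revisions)
  stopifnot(n_revisions >= 1L)
  if (!is.null(breakage_at)) {
    breakage_at <- as.integer(breakage_at)
    if (breakage_at < 1L || breakage_at > n_revisions) {
      stop("breakage_at must lie within 1..n_revisions", call. = FALSE)
    }
  }
  if (is.null(degraded)) {
    degraded <- mock_protocol_params(
      n_models = baseline$n_models, f_native = 0.2,
      native_sigma = baseline$native_sigma,
      funnel_slope = baseline$funnel_slope, e_floor = baseline$e_floor,
      e_decoy_mean = baseline$e_floor - 5,
      e_decoy_sigma = baseline$e_decoy_sigma,
      decoy_rmsd_range = baseline$decoy_rmsd_range,
      noise_sigma = baseline$noise_sigma)
  }
  if (identical(unclass(baseline)[setdiff(names(baseline), "seed")],
                unclass(degraded)[setdiff(names(degraded), "seed")])) {
    stop("degraded parameters must differ from baseline", call. = FALSE)
  }
  structure(list(n_revisions = n_revisions, breakage_at = breakage_at,
                 baseline = baseline, degraded = degraded,
                 seed = as.integer(seed)),
            class = "revision_history_spec")
}

#' Run the mock protocol at one revision
#'
#' Uses the baseline parameters before the injected breakage and the
#' degraded parameters at or after it. The payload seed is derived from
#' `(spec$seed, test, revision, attempt)` with [derive_seed()], so the same
#' run can be replayed exactly while repeated attempts still differ.
#'
#' @param test test name (enters the seed derivation).
#' @param revision revision id in `1 ... spec$n_revisions`.
#' @param spec a [revision_history_spec()].
#' @param attempt attempt number (reruns draw fresh trajectories).
#' @return An [ensemble()]; `attr(, "payload_seed")` records the derived
#'   seed.
#' @export
run_mock_protocol <- function(test, revision, spec, attempt = 1L) {
  stopifnot(inherits(spec, "revision_history_spec"))
  revision <- as.integer(revision)
  if (revision < 1L || revision > spec$n_revisions) {
    stop(sprintf("revision r%d outside history 1..%d", revision,
                 spec$n_revisions), call. = FALSE)
  }
  params <- if (!is.null(spec$breakage_at) && revision >= spec$breakage_at) {
    spec$degraded
  } else {
    spec$baseline
  }
  params$seed <- derive_seed(spec$seed, test, revision, attempt)
  ens <- generate_ensemble(params,
                           target_id = sprintf("%s_r%d", test, revision),
                           score_function = "mock")
  attr(ens, "payload_seed") <- params$seed
  ens
}
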