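# Chain-length ensembles of the fixed-(n_at, n_ch, V) simulations.
# Polydispersity is controlled by per-length relative chemical potentials
# mu*_N entering the acceptance of the connectivity-altering moves.

#' Chain-length ensemble specification
#'
#' Either a uniform distribution on the closed interval
#' `[N_av (1 - Delta), N_av (1 + Delta)]` or a most-probable (Flory)
#' distribution `P(N) ~ p^(N - N_min)` with a hard minimum length, where `p`
#' is solved so the mean equals `N_av`.  Because the total number of spheres
#' and of chains are both conserved, the mean chain length is pinned at
#' `n_at / n_ch`; `N_av` should match it.
#'
#' The relative chemical-potential profile that makes the stationary length
#' distribution match the target is available in closed form here: flat for
#' the uniform ensemble and `mu_N = (N - N_min) log(p)` for Flory (see the
#' package vignette for the derivation).
#'
#' @param distribution `"uniform"` or `"flory"`.
#' @param N_av Average chain length.
#' @param Delta Reduced half-width of the uniform distribution.
#' @param N_min Shortest allowed chain (Flory).
#' @param N_cap Hard upper bound used by the moves (defaults to the uniform
#'   upper limit, or `6 * N_av` for Flory where the tail is unbounded).
#' @return An object of class `ensemble_spec`.
#' @export
ensemble_spec <- function(distribution = c("uniform", "flory"), N_av = 12,
                          Delta = 0.5, N_min = 3, N_cap = NULL) {
  distribution <- match.arg(distribution)
  if (distribution == "uniform") {
    lo <- as.integer(ceiling(N_av * (1 - Delta) - 1e-9))
    hi <- as.integer(floor(N_av * (1 + Delta) + 1e-9))
    if (lo < 1 || hi < lo) stop("empty uniform length interval")
    spec <- list(distribution = "uniform", N_av = N_av, Delta = Delta,
                 n_min = lo, n_max = hi)
  } else {
    if (N_min >= N_av) stop("flory ensemble needs N_min < N_av")
    p <- (N_av - N_min) / (N_av - N_min + 1)
    if (is.null(N_cap)) N_cap <- as.integer(6 * N_av)
    spec <- list(distribution = "flory", N_av = N_av, N_min = N_min, p = p,
                 n_min = as.integer(N_min), n_max = as.integer(N_cap))
  }
  structure(spec, class = "ensemble_spec")
}

#' @export
print.ensemble_spec <- function(x, ...) {
  if (x$distribution == "uniform") {
    cat(sprintf("uniform chain lengths on [%d, %d] (N_av = %g, Delta = %g)\n",
                x$n_min, x$n_max, x$N_av, x$Delta))
  } else {
    cat(sprintf("Flory chain lengths, N_min = %d, N_av = %g (p = %.4f)\n",
                x$N_min, x$N_av, x$p))
  }
  invisible(x)
}

#' Draw chain lengths from an ensemble
#'
#' @param n Number of chains.
#' @param ensemble An [ensemble_spec()].
#' @return Integer vector of lengths.
#' @export
draw_chain_lengths <- function(n, ensemble) {
  if (ensemble$distribution == "uniform") {
    lv <- seq(ensemble$n_min, ensemble$n_max)
    lv[sample.int(length(lv), n, replace = TRUE)]
  } else {
    out <- ensemble$N_min + rgeom(n, 1 - ensemble$p)
    while (any(out > ensemble$n_max)) {
      k <- out > ensemble$n_max
      out[k] <- ensemble$N_min + rgeom(sum(k), 1 - ensemble$p)
    }
    as.integer(out)
  }
}

#' Target probability mass of an ensemble
#'
#' @param ensemble An [ensemble_spec()].
#' @param N Integer lengths.
#' @return Normalized probabilities over the allowed range.
#' @export
chain_length_pmf <- function(ensemble, N = seq(ensemble$n_min, ensemble$n_max)) {
  if (ensemble$distribution == "uniform") {
    p <- rep(1 / (ensemble$n_max - ensemble$n_min + 1), length(N))
  } else {
    p <- (1 - ensemble$p) * ensemble$p^(N - ensemble$N_min)
    p <- p / sum((1 - ensemble$p) * ensemble$p^(seq(ensemble$n_min, ensemble$n_max) - ensemble$N_min))
  }
  p[N < ensemble$n_min | N > ensemble$n_max] <- 0
  p
}

# relative chemical-potential profile mu*_N (length-indexed, 1..n_max)
mu_profile <- function(ensemble) {
  if (!is.null(ensemble$mu_override)) return(ensemble$mu_override)
  mu <- numeric(ensemble$n_max)
  if (ensemble$distribution == "flory") {
    N <- seq_len(ensemble$n_max)
    mu <- (N - ensemble$N_min) * log(ensemble$p)
  }
  mu
}

#' Calibrate the chemical-potential profile
#'
#' The analytic mu profile is linear in N, so it cancels in every
#' length-conserving monomer transfer and the stationary length distribution
#' equals the composition-count distribution: geometric-like for the Flory
#' target but with finite-`n_ch` corrections (both length extremes slightly
#' suppressed, the mean slightly enhanced, at order `1/n_ch`).  This routine
#' removes those corrections by short stochastic iteration: run a batch,
#' histogram the lengths, shift `mu_N` by `eta * log(target_N / observed_N)`,
#' repeat, then freeze the profile.
#'
#' @param sys A dilute `chain_system` matching the ensemble composition.
#' @param ensemble The [ensemble_spec()] to calibrate.
#' @param spec Base [run_spec()] supplying move parameters and the seed.
#' @param batches Number of calibration batches.
#' @param batch_steps MC steps per batch.
#' @param eta Damping of the log-ratio update.
#' @return The ensemble with a calibrated `mu_override` profile (and the
#'   relaxed system as attribute `state`).
#' @export
calibrate_mu <- function(sys, ensemble, spec, batches = 4, batch_steps = 1e6,
                         eta = 0.7) {
  mu <- mu_profile(ensemble)[seq_len(ensemble$n_max)]
  Ns <- seq(ensemble$n_min, ensemble$n_max)
  target <- chain_length_pmf(ensemble)
  for (b in seq_len(batches)) {
    ensemble$mu_override <- mu
    bspec <- spec
    bspec$n_steps <- batch_steps
    bspec$record_every <- 0
    bspec$length_every <- max(1, round(batch_steps / 200))
    bspec$seed <- spec$seed + b
    bspec$ensemble <- ensemble
    res <- run_mc(sys, bspec, validate = FALSE)
    sys <- res$system
    obs <- res$length_counts$count[match(Ns, res$length_counts$length)]
    obs <- (obs + 0.5) / sum(obs + 0.5)
    upd <- eta * log(target / obs)
    mu[Ns] <- mu[Ns] + upd - mean(upd)
  }
  ensemble$mu_override <- mu
  attr(ensemble, "state") <- sys
  ensemble
}
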