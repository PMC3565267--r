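# User-facing surface of the Monte Carlo engine: move mix, run specification,
# production runs, compression, and the chain-splitting generation check.

#' Monte Carlo move mix
#'
#' Attempt probabilities of the seven-move mix: reptation, end rotation,
#' configurational-bias end regrowth, inter-chain reptation, internal
#' libration, simplified end-bridging (sEB) and simplified intramolecular
#' end-bridging (sIEB).  The default percentages (10, 10, 20, 25, 34.98,
#' 0.1, 0.1) sum to 100.18 as printed in the source protocol; they are
#' normalized here so the probabilities sum to exactly 1.
#'
#' @param reptation,end_rotation,config_bias,interchain_reptation,internal_libration,sEB,sIEB
#'   Attempt weights.
#' @return Named numeric vector of class `move_mix` summing to 1.
#' @export
move_mix <- function(reptation = 0.10, end_rotation = 0.10, config_bias = 0.20,
                     interchain_reptation = 0.25, internal_libration = 0.3498,
                     sEB = 0.001, sIEB = 0.001) {
  p <- c(reptation = reptation, end_rotation = end_rotation,
         config_bias = config_bias, interchain_reptation = interchain_reptation,
         internal_libration = internal_libration, sEB = sEB, sIEB = sIEB)
  if (any(p < 0)) stop("move probabilities must be non-negative")
  if (sum(p) <= 0) stop("at least one move must have positive probability")
  structure(p / sum(p), class = "move_mix")
}

#' Configurational-bias trial schedule
#'
#' Number of trial positions per displaced site, non-decreasing in the
#' packing fraction: more trials are needed to find open volume as the
#' packing densifies.
#'
#' @param phi Packing fraction.
#' @param breaks,values Schedule: `values[i]` trials when `phi` is below
#'   `breaks[i]` (last value beyond the final break).
#' @return Integer number of trials.
#' @export
cb_schedule <- function(phi, breaks = c(0.45, 0.58), values = c(10L, 30L, 50L)) {
  stopifnot(length(values) == length(breaks) + 1, !is.unsorted(values))
  values[findInterval(phi, breaks) + 1]
}

#' Run specification
#'
#' @param n_steps Number of MC steps (one attempted move each).
#' @param record_every Frame recording interval in steps (0 = no frames).
#' @param seed Integer seed for the engine's random-number generator.
#' @param movemix A [move_mix()].
#' @param ensemble An [ensemble_spec()] governing allowed chain lengths and
#'   the chemical-potential weights of the connectivity-altering moves;
#'   `NULL` freezes all chain lengths (sEB/sIEB and inter-chain reptation
#'   are then rejected by the length constraint).
#' @param k_trials Configurational-bias trials per site (`NULL`: from
#'   [cb_schedule()] at the system's packing fraction).
#' @param max_regrow Maximum sites regrown by the configurational-bias move.
#' @param delta_libration Internal-libration amplitude, degrees.
#' @param delta_displacement Monomer displacement half-width (sigma).
#' @param r_search End-bridging acceptor search shell beyond tangency (sigma).
#' @param length_every Interval for accumulating the chain-length histogram
#'   (0 = off).
#' @param gr_every,gr_dr,gr_rmax In-run pair-correlation accumulation
#'   (`gr_every = 0` = off).
#' @return An object of class `run_spec`.
#' @export
run_spec <- function(n_steps, record_every = 2e5, seed = 1,
                     movemix = move_mix(), ensemble = NULL, k_trials = NULL,
                     max_regrow = 3, delta_libration = 20,
                     delta_displacement = 0.15, r_search = 0.01,
                     length_every = 0, gr_every = 0, gr_dr = 0.02, gr_rmax = 0) {
  stopifnot(n_steps >= 1, record_every >= 0)
  structure(list(n_steps = n_steps, record_every = record_every, seed = seed,
                 movemix = movemix, ensemble = ensemble, k_trials = k_trials,
                 max_regrow = max_regrow, delta_libration = delta_libration,
                 delta_displacement = delta_displacement, r_search = r_search,
                 length_every = length_every, gr_every = gr_every,
                 gr_dr = gr_dr, gr_rmax = gr_rmax),
            class = "run_spec")
}

engine_params <- function(sys, spec) {
  ens <- spec$ensemble
  n_at <- n_atoms(sys)
  if (is.null(ens)) {
    lens <- lengths(sys$chains)
    n_min <- min(lens); n_max <- max(lens)
    mu <- numeric(n_max)
    # without an ensemble, forbid any length change
    if (length(unique(lens)) == 1L) { n_min <- n_max <- lens[1] }
  } else {
    n_min <- ens$n_min; n_max <- min(ens$n_max, n_at)
    mu <- mu_profile(ens)[seq_len(n_max)]
  }
  k <- spec$k_trials
  if (is.null(k)) k <- cb_schedule(packing_fraction(sys))
  list(probs = as.numeric(spec$movemix), k_trials = as.integer(k),
       max_regrow = as.integer(spec$max_regrow),
       delta_lib = spec$delta_libration * pi / 180,
       delta_disp = spec$delta_displacement, r_search = spec$r_search,
       n_min = as.integer(n_min), n_max = as.integer(n_max), mu = mu)
}

state_to_system <- function(state, template_sys) {
  chain_system(state$pos, lapply(state$chains, as.integer),
               simulation_box(state$L), sigma = template_sys$sigma,
               tangency_tol = template_sys$tangency_tol)
}

#' Run the Monte Carlo engine
#'
#' Advances a chain system by `spec$n_steps` attempted moves.  Local moves
#' use the multiple-trial (Rosenbluth) configurational-bias pattern; sEB and
#' sIEB delete and re-form bonds between nearly tangent sphere pairs,
#' transferring monomer tails between (or within) chains under the
#' ensemble's chemical-potential weights.  Chains of length one are driven
#' by displacement and multi-trial reinsertion (monomer mode).
#'
#' @param sys A valid `chain_system`.
#' @param spec A [run_spec()].
#' @param validate Check the starting state (default TRUE).
#' @return A list: `system` (final state), `stats` (per-move attempt and
#'   acceptance counts), `frames` (recorded `chain_system`s),
#'   `length_counts` (chain-length histogram, if requested), `gr`
#'   (accumulated pair correlation, if requested).
#' @export
run_mc <- function(sys, spec, validate = TRUE) {
  if (validate) {
    v <- validate_system(sys)
    if (!v$valid) stop("starting configuration violates hard-sphere constraints")
  }
  par <- engine_params(sys, spec)
  res <- run_mc_cpp(sys$pos, sys$chains, sys$box$L, sys$sigma, sys$tangency_tol,
                    spec$n_steps, par, as.integer(spec$seed),
                    spec$record_every, spec$length_every,
                    spec$gr_every, spec$gr_dr, spec$gr_rmax)
  stats <- data.frame(
    move = c("reptation", "end_rotation", "config_bias", "interchain_reptation",
             "internal_libration", "sEB", "sIEB", "displacement"),
    attempted = res$stats$attempted, accepted = res$stats$accepted)
  out <- list(system = state_to_system(res$state, sys), stats = stats,
              frames = lapply(res$frames, state_to_system, template_sys = sys))
  if (spec$length_every > 0) {
    lc <- res$length_counts
    out$length_counts <- data.frame(length = seq_along(lc) - 1L, count = lc)[-1, ]
  }
  if (spec$gr_every > 0 && res$gr_samples > 0) {
    out$gr <- normalize_gr(res$gr_counts, res$gr_dr, sys$box$L, n_atoms(sys),
                           res$gr_samples)
  }
  out
}

#' Compress a system to a target packing fraction
#'
#' Alternates short MC relaxations with isotropic shrink attempts.  Each
#' accepted shrink rescales the box by a factor `f` and repositions every
#' chain rigidly: the first sphere moves affinely with the box and the rest
#' of the chain translates with it, so intra-chain geometry (bond lengths
#' and angles) is untouched.  A shrink that would create any overlap is
#' rejected and retried after further relaxation.
#'
#' @param sys A valid `chain_system`.
#' @param phi_target Target packing fraction (greater than the current one).
#' @param spec A [run_spec()]; `n_steps` is ignored, `seed` and move
#'   parameters are used for the relaxation.
#' @param shrink_factor Linear shrink factor per attempt (just below 1).
#' @param relax_steps MC steps between successive shrink attempts.
#' @param max_cycles Attempt budget; exceeding it raises a partial-result
#'   error (condition class `polypack_compression_partial`) carrying the
#'   last valid state and its packing fraction.
#' @return The compressed `chain_system`, with attributes `phi` and
#'   `compress_stats`.
#' @export
compress_system <- function(sys, phi_target, spec = run_spec(1),
                            shrink_factor = 0.999, relax_steps = NULL,
                            max_cycles = 50000) {
  phi0 <- packing_fraction(sys)
  if (phi_target <= phi0) stop("phi_target must exceed the current packing fraction")
  if (is.null(relax_steps)) relax_steps <- 5 * n_atoms(sys)
  par <- engine_params(sys, spec)
  res <- compress_cpp(sys$pos, sys$chains, sys$box$L, sys$sigma,
                      sys$tangency_tol, phi_target, shrink_factor,
                      relax_steps, max_cycles, par, as.integer(spec$seed))
  out <- state_to_system(res, sys)
  if (!isTRUE(res$reached)) {
    cond <- structure(
      class = c("polypack_compression_partial", "error", "condition"),
      list(message = sprintf(
             "compression stalled at phi = %.4f (target %.4f) after %g cycles",
             res$phi, phi_target, res$cycles),
           call = sys.call(), last_phi = res$phi, state = out))
    stop(cond)
  }
  attr(out, "phi") <- res$phi
  attr(out, "compress_stats") <- list(cycles = res$cycles,
                                      shrink_attempted = res$shrink_attempted,
                                      shrink_accepted = res$shrink_accepted)
  out
}

#' Split all chains in half
#'
#' Removes the central bond of every (even-length) chain, doubling the
#' number of chains while leaving every sphere untouched.  Used as a
#' generation-protocol check: observables of a split configuration must
#' match those of a freshly generated one at the same composition.
#'
#' @param sys A `chain_system` whose chains all have even length.
#' @return A `chain_system` with `2 * n_chains` chains and identical
#'   positions.
#' @export
split_chains <- function(sys) {
  lens <- lengths(sys$chains)
  if (any(lens %% 2 != 0)) {
    stop("chains with odd length cannot be split in half: ",
         paste(which(lens %% 2 != 0), collapse = ", "))
  }
  new_chains <- list()
  for (ch in sys$chains) {
    h <- length(ch) / 2
    new_chains <- c(new_chains, list(ch[1:h]), list(ch[(h + 1):length(ch)]))
  }
  chain_system(sys$pos, new_chains, sys$box, sys$sigma, sys$tangency_tol)
}

#' Rapidly compressed amorphous packing
#'
#' Builds a random (amorphous) monomer packing at a target density by the
#' protocol of the source methodology for monomeric reference states: a
#' freely-jointed chain system is generated dilute and rapidly compressed -
#' chain connectivity frustrates ordering during densification - after
#' which all bonds are deleted and the monomers briefly relaxed.  The
#' direct route (`route = "monomer"`) compresses bond-free spheres instead;
#' it anneals noticeably more local order on the way, illustrating the
#' connectivity effect.
#'
#' @param n_at Number of spheres (with `route = "chain"`, `n_at / N_av`
#'   chains are generated).
#' @param phi Target packing fraction.
#' @param seed Integer seed.
#' @param route `"chain"` (compress chains, then delete bonds) or
#'   `"monomer"` (compress free spheres).
#' @param N_av Mean chain length of the chain route.
#' @param relax_steps MC steps between shrink attempts (the quench rate:
#'   fewer steps = more rapid).
#' @param relax_after Monomer relaxation steps after bond deletion.
#' @param max_cycles Shrink-attempt budget.
#' @return A monomeric `chain_system` at `phi` (attribute `route` records
#'   the protocol).
#' @export
amorphous_baseline <- function(n_at = 1200, phi = 0.61, seed = 1,
                               route = c("chain", "monomer"), N_av = 12,
                               relax_steps = 400, relax_after = 5e5,
                               max_cycles = 4e5) {
  route <- match.arg(route)
  if (route == "chain") {
    ens <- ensemble_spec("uniform", N_av, 0.5)
    sys <- make_dilute_chains(round(n_at / N_av), ens, phi = 0.10, seed = seed)
    sys <- compress_system(sys, phi, run_spec(1, seed = seed + 1, k_trials = 10),
                           shrink_factor = 0.9995, relax_steps = relax_steps,
                           max_cycles = max_cycles)
    mono <- chain_system(sys$pos, as.list(seq_len(n_atoms(sys))), sys$box)
  } else {
    sys <- make_dilute_chains(n_at, ensemble_spec("uniform", 1, 0),
                              phi = 0.10, seed = seed)
    mono <- compress_system(sys, phi,
                            run_spec(1, seed = seed + 1, k_trials = 1,
                                     movemix = move_mix(0, 0, 0, 0, 1, 0, 0)),
                            shrink_factor = 0.9995, relax_steps = relax_steps,
                            max_cycles = max_cycles)
  }
  if (relax_after > 0) {
    mono <- run_mc(mono, run_spec(relax_after, record_every = 0,
                                  seed = seed + 2, k_trials = 1,
                                  movemix = move_mix(0, 0, 0, 0, 1, 0, 0)),
                   validate = FALSE)$system
  }
  attr(mono, "route") <- route
  mono
}
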