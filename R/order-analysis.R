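# Scalar structure observables along trajectories: pair correlation g(r),
# flipper mobility fractions, and the joint crystallinity / shape / mobility
# summary used to locate the disorder-order transition.

normalize_gr <- function(counts, dr, L, n_at, n_frames = 1) {
  V <- prod(L)
  r_lo <- (seq_along(counts) - 1) * dr
  r_mid <- r_lo + dr / 2
  shell <- (4 / 3) * pi * ((r_lo + dr)^3 - r_lo^3)
  ideal_pairs <- n_at * (n_at - 1) / 2 * shell / V
  data.frame(r = r_mid, g = counts / (ideal_pairs * n_frames))
}

#' Pair radial distribution function
#'
#' Ideal-gas-normalized histogram of minimum-image pair distances.  For a
#' Poisson point set `g(r) = 1` everywhere; hard spheres have `g(r) = 0`
#' below contact.
#'
#' @param sys A `chain_system`, or a list of frames to average.
#' @param dr Bin width (sigma).
#' @param r_max Histogram range; must not exceed half the shortest box edge
#'   (minimum-image validity).  Default `min(L)/2`.
#' @return Data frame with bin centres `r` and `g`.
#' @export
g_r <- function(sys, dr = 0.02, r_max = NULL) {
  frames <- if (inherits(sys, "chain_system")) list(sys) else sys
  L <- frames[[1]]$box$L
  if (is.null(r_max)) r_max <- min(L) / 2
  if (r_max > min(L) / 2 + 1e-9) {
    stop("r_max must not exceed half the shortest box edge")
  }
  counts <- 0
  for (f in frames) counts <- counts + gr_count_cpp(f$pos, f$box$L, dr, r_max)
  normalize_gr(counts, dr, L, n_atoms(frames[[1]]), length(frames))
}

#' Contact value of g(r)
#'
#' Extrapolates the pair correlation to contact, `g(sigma+)`, by a
#' quadratic fit over the bins just above the hard core.  The hard-sphere
#' compressibility factor follows as `Z = 1 + 4 phi g(sigma+)`.
#'
#' @param gr Data frame from [g_r()].
#' @param sigma Sphere diameter.
#' @param fit_width Width of the fit window above contact (sigma).
#' @return The extrapolated contact value.
#' @export
gr_contact <- function(gr, sigma = 1, fit_width = 0.05) {
  sel <- gr$r >= sigma & gr$r <= sigma + fit_width & gr$g > 0
  if (sum(sel) < 3) stop("too few bins above contact for extrapolation")
  fit <- stats::lm(g ~ poly(r, 2, raw = TRUE), data = gr[sel, ])
  unname(stats::predict(fit, newdata = data.frame(r = sigma)))
}

#' Carnahan-Starling equation of state
#'
#' Closed-form reference values for the equilibrium monodisperse hard-sphere
#' fluid: the contact value of the pair correlation and the compressibility
#' factor `Z = p V / (n kT) = 1 + 4 phi g(sigma+)`.
#'
#' @param phi Packing fraction.
#' @return Contact value, respectively compressibility factor.
#' @export
carnahan_starling_contact <- function(phi) (1 - phi / 2) / (1 - phi)^3

#' @rdname carnahan_starling_contact
#' @export
carnahan_starling_Z <- function(phi) (1 + phi + phi^2 - phi^3) / (1 - phi)^3

#' Flipper fraction
#'
#' An interior chain sphere is a flipper at amplitude `dphi` if rotating it
#' about the axis through its two bonded neighbours by `+dphi` and `-dphi`
#' (both senses) is overlap-free.  The flip is a feasibility test only - no
#' move is applied - and proxies the translational freedom of the local
#' environment.  End spheres and monomers have no two-neighbour axis and
#' are excluded from the denominator by default; `include_ends = TRUE`
#' additionally probes each end sphere about a random axis perpendicular to
#' its single bond (sensitivity analysis only).
#'
#' @param sys A `chain_system` with at least one interior sphere.
#' @param dphi Amplitudes in degrees (default 0.01, 0.10, 1.00).
#' @param include_ends Probe end spheres about a random perpendicular axis.
#' @param seed Seed for the random end-sphere axes (only with
#'   `include_ends`).
#' @return Data frame: `dphi`, `n_flippers`, `eligible`, `fraction`.
#' @export
flipper_fraction <- function(sys, dphi = c(0.01, 0.10, 1.00),
                             include_ends = FALSE, seed = 1) {
  stopifnot(all(dphi > 0))
  pn <- prev_next(sys)
  if (all(pn$prv < 0 | pn$nxt < 0) && !include_ends) {
    stop("no interior spheres: the flipper statistic needs chains of length ",
         ">= 3 (use a displacement-based probe for monomers)")
  }
  res <- flipper_cpp(sys$pos, sys$box$L, pn$prv, pn$nxt, dphi, sys$sigma)
  nf <- res$n_flippers
  el <- res$eligible
  if (include_ends) {
    add <- end_flippers(sys, dphi, seed)
    nf <- nf + add$n
    el <- el + add$eligible
  }
  data.frame(dphi = dphi, n_flippers = nf, eligible = el,
             fraction = if (el > 0) nf / el else NA_real_)
}

prev_next <- function(sys) {
  n <- n_atoms(sys)
  prv <- rep(-1L, n)
  nxt <- rep(-1L, n)
  for (ch in sys$chains) {
    if (length(ch) < 2) next
    prv[ch[-1]] <- ch[-length(ch)] - 1L
    nxt[ch[-length(ch)]] <- ch[-1] - 1L
  }
  list(prv = prv, nxt = nxt)
}

end_flippers <- function(sys, dphi, seed) {
  pn <- prev_next(sys)
  ends <- which(xor(pn$prv >= 0, pn$nxt >= 0))
  if (length(ends) == 0) return(list(n = 0L, eligible = 0L))
  n <- integer(length(dphi))
  with_seed(seed, {
    for (e in ends) {
      nb <- if (pn$prv[e] >= 0) pn$prv[e] + 1L else pn$nxt[e] + 1L
      bond <- minimum_image(sys$pos[nb, ], sys$pos[e, ], sys$box)
      ref <- rnorm(3)
      ax <- ref - bond * sum(ref * bond) / sum(bond^2)
      ax <- ax / sqrt(sum(ax^2))
      # rotate about the random perpendicular axis through the neighbour
      for (a in seq_along(dphi)) {
        ok <- all(vapply(c(1, -1), function(s) {
          R <- rotation_about(ax, s * dphi[a])
          p <- sys$pos[nb, ] + as.numeric(R %*% bond)
          free_site(sys, p, e)
        }, logical(1)))
        if (ok) n[a] <- n[a] + 1L
      }
    }
  })
  list(n = n, eligible = length(ends))
}

free_site <- function(sys, p, self) {
  d <- minimum_image(matrix(p, nrow = n_atoms(sys), ncol = 3, byrow = TRUE),
                     sys$pos, sys$box)
  d2 <- rowSums(d^2)
  d2[self] <- Inf
  all(d2 >= (sys$sigma - 1e-12)^2)
}

#' Trajectory observables and transition detection
#'
#' Computes per-frame crystallinity and order parameters, mean Voronoi
#' shape measures, and flipper fractions, then locates the disorder-order
#' transition as the sliding window of steepest crystallinity rise.  The
#' windows of steepest asphericity fall and steepest flipper-fraction rise
#' are reported alongside: during the transition all three change together.
#'
#' @param frames List of `chain_system` frames (at least 2).
#' @param steps Optional step number of each frame (defaults to the index).
#' @param dphi Flipper amplitudes; flippers are skipped for monomeric
#'   frames.
#' @param threshold CCE norm threshold.
#' @param window Detector window in frames (default 5% of the trajectory,
#'   minimum 3).
#' @param shapes,cce Logical switches for the Voronoi and CCE blocks.
#' @return List with `series` (per-frame data frame) and `transition`
#'   (window extents and the co-location flag, when computable).
#' @export
trajectory_report <- function(frames, steps = seq_along(frames),
                              dphi = c(0.01, 0.10, 1.00), threshold = 0.245,
                              window = NULL, shapes = TRUE, cce = TRUE) {
  stopifnot(length(frames) >= 2, length(steps) == length(frames))
  monomeric <- all(lengths(frames[[1]]$chains) == 1)
  rows <- lapply(seq_along(frames), function(i) {
    f <- frames[[i]]
    row <- data.frame(frame = i, step = steps[i],
                      phi = packing_fraction(f))
    if (cce) {
      cl <- classify_frame(f, threshold = threshold)
      row$tau_c <- cl$order$tau_c
      row$S_hcp <- cl$order$S_hcp
      row$S_fcc <- cl$order$S_fcc
      row$S_5f <- cl$order$S_5f
    }
    if (shapes) {
      sh <- shape_profile(list(f))
      row$mean_b <- sh$mean_b
      row$mean_c <- sh$mean_c
      row$mean_k2 <- sh$mean_k2
      row$mean_local_density <- sh$mean_local_density
    }
    if (!monomeric) {
      fl <- flipper_fraction(f, dphi)
      for (a in seq_along(dphi)) {
        row[[sprintf("flipper_%g", dphi[a])]] <- fl$fraction[a]
      }
    }
    row
  })
  series <- do.call(rbind, rows)
  nfr <- nrow(series)
  if (is.null(window)) window <- max(3, round(0.05 * nfr))
  window <- min(window, nfr - 1)
  transition <- NULL
  steepest <- function(x, sign = 1) {
    d <- sign * (x[(1 + window):nfr] - x[1:(nfr - window)])
    i <- which.max(d)
    list(from = steps[i], to = steps[i + window], change = d[i])
  }
  if (cce) {
    tr <- steepest(series$tau_c)
    transition <- list(window_frames = window, tau_c = tr,
                       detected = tr$change > 0.1)
    if (shapes) transition$asphericity <- steepest(series$mean_b, sign = -1)
    flcol <- sprintf("flipper_%g", max(dphi))
    if (flcol %in% names(series)) transition$flipper <- steepest(series[[flcol]])
    spans <- Filter(Negate(is.null),
                    transition[c("tau_c", "asphericity", "flipper")])
    if (length(spans) > 1) {
      lo <- max(vapply(spans, `[[`, numeric(1), "from"))
      hi <- min(vapply(spans, `[[`, numeric(1), "to"))
      transition$co_located <- lo <= hi
    }
  }
  list(series = series, transition = transition)
}
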