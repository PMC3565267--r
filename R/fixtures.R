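# Ground-truth generators: close-packed stackings, reference coordination
# templates, icosahedral clusters, and dilute random chain configurations.

#' Close-packed layer stacking
#'
#' Builds a monomeric (chain length 1) system of close-packed triangular
#' layers following a stacking sequence over the letters A, B, C with no two
#' consecutive letters equal.  Pure "ABAB" repetition is hcp, pure "ABCABC"
#' is fcc; random sequences give rhcp morphologies.  Layers are commensurate
#' with an orthorhombic periodic box (in-plane cell `n1 sigma x n2 sqrt(3)
#' sigma`, layer spacing `sigma sqrt(2/3)`), so interior sites have
#' mathematically perfect 12-neighbour first shells.  If the sequence does
#' not wrap (first and last letters equal) the box gains a vacuum gap along
#' z and the packing is no longer space-filling; otherwise the packing
#' fraction is exactly pi/sqrt(18).
#'
#' @param layers Character string (or vector of single letters) over A/B/C.
#' @param n1,n2 In-plane repeat counts; each layer holds `2 * n1 * n2` sites.
#' @param spacing Sphere spacing (sigma for contact packing).
#' @return A `chain_system` of monomers with attributes `layer` (per-site
#'   layer index), `layer_letters` and `commensurate`.
#' @export
make_stacking <- function(layers, n1 = 4, n2 = 3, spacing = 1) {
  letters_vec <- parse_stacking(layers)
  nl <- length(letters_vec)
  a <- spacing
  b <- spacing * sqrt(3)
  h <- spacing * sqrt(2 / 3)
  offs <- list(A = c(0, 0), B = c(a / 2, b / 6), C = c(0, b / 3))
  wraps <- letters_vec[1] != letters_vec[nl]
  Lz <- nl * h + if (wraps) 0 else spacing  # vacuum pad when not commensurate
  ix <- rep(seq_len(n1) - 1, each = n2)
  iy <- rep(seq_len(n2) - 1, times = n1)
  base <- rbind(cbind(ix * a, iy * b), cbind(ix * a + a / 2, iy * b + b / 2))
  pos <- NULL
  layer_id <- integer()
  for (k in seq_len(nl)) {
    o <- offs[[letters_vec[k]]]
    pos <- rbind(pos, cbind(base[, 1] + o[1], base[, 2] + o[2], (k - 1) * h))
    layer_id <- c(layer_id, rep(k, nrow(base)))
  }
  box <- simulation_box(c(n1 * a, n2 * b, Lz))
  sys <- chain_system(pos, as.list(seq_len(nrow(pos))), box)
  attr(sys, "layer") <- layer_id
  attr(sys, "layer_letters") <- letters_vec
  attr(sys, "commensurate") <- wraps
  sys
}

parse_stacking <- function(layers) {
  if (length(layers) == 1 && nchar(layers) > 1) {
    layers <- strsplit(layers, "")[[1]]
  }
  layers <- toupper(as.character(layers))
  if (length(layers) < 3) stop("stacking sequence needs at least 3 layers")
  if (!all(layers %in% c("A", "B", "C"))) stop("letters must be A, B or C")
  if (any(layers[-1] == layers[-length(layers)])) {
    stop("adjacent layers must carry distinct letters")
  }
  layers
}

#' Combinatorial stacking ground truth
#'
#' Layer-wise crystal labels implied by a stacking sequence: an interior
#' layer flanked by two copies of the same letter is hcp-like, by two
#' distinct letters fcc-like; terminal layers are labelled boundary.
#'
#' @param layers Stacking sequence as in [make_stacking()].
#' @return Character vector of per-layer labels (`"hcp"`, `"fcc"`,
#'   `"boundary"`).
#' @export
stacking_ground_truth <- function(layers) {
  l <- parse_stacking(layers)
  n <- length(l)
  lab <- rep("boundary", n)
  for (i in seq(2, n - 1)) {
    lab[i] <- if (l[i - 1] == l[i + 1]) "hcp" else "fcc"
  }
  lab
}

#' Reference lattices
#'
#' `make_fcc()` builds a perfect face-centred-cubic crystal from `n_cells^3`
#' conventional cubic cells (cell edge `spacing * sqrt(2)`) in a cubic box;
#' `make_hcp()` is the `ABAB` stacking; `make_sc()` a simple cubic lattice.
#' All return monomeric chain systems.
#'
#' @param n_cells Conventional cells per box edge.
#' @param spacing Nearest-neighbour distance (sigma for contact).
#' @return A `chain_system` of monomers.
#' @export
make_fcc <- function(n_cells = 3, spacing = 1) {
  a <- spacing * sqrt(2)
  basis <- rbind(c(0, 0, 0), c(0.5, 0.5, 0), c(0.5, 0, 0.5), c(0, 0.5, 0.5)) * a
  cells <- as.matrix(expand.grid(0:(n_cells - 1), 0:(n_cells - 1), 0:(n_cells - 1))) * a
  pos <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sweep(basis, 2, cells[i, ], "+")
  }))
  sys <- chain_system(pos, as.list(seq_len(nrow(pos))), simulation_box(n_cells * a))
  attr(sys, "lattice") <- "fcc"
  sys
}

#' @rdname make_fcc
#' @param n1,n2,n_layers Repeat counts passed to [make_stacking()].
#' @export
make_hcp <- function(n_layers = 6, n1 = 4, n2 = 3, spacing = 1) {
  if (n_layers %% 2 != 0) stop("hcp needs an even number of layers")
  make_stacking(rep(c("A", "B"), n_layers / 2), n1 = n1, n2 = n2, spacing = spacing)
}

#' @rdname make_fcc
#' @export
make_sc <- function(n_cells = 4, spacing = 1.2) {
  g <- (seq_len(n_cells) - 1) * spacing
  pos <- as.matrix(expand.grid(g, g, g))
  chain_system(pos, as.list(seq_len(nrow(pos))),
               simulation_box(n_cells * spacing))
}

#' Icosahedral cluster fixture
#'
#' A central sphere with 12 shell spheres at the vertices of a regular
#' icosahedron at contact distance: the canonical fivefold-symmetric local
#' environment that competes with hcp/fcc order in dense packings.
#'
#' @param box_edge Edge of the enclosing (otherwise empty) cubic box.
#' @return A `chain_system` of 13 monomers; the central site is site 1.
#' @export
make_icosahedral_cluster <- function(box_edge = 10) {
  shell <- icosahedron_vertices()
  pos <- rbind(c(0, 0, 0), shell) + box_edge / 2
  chain_system(pos, as.list(seq_len(13)), simulation_box(box_edge))
}

icosahedron_vertices <- function() {
  gold <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(0, 1, gold), c(0, 1, -gold), c(0, -1, gold), c(0, -1, -gold),
    c(1, gold, 0), c(1, -gold, 0), c(-1, gold, 0), c(-1, -gold, 0),
    c(gold, 0, 1), c(-gold, 0, 1), c(gold, 0, -1), c(-gold, 0, -1))
  v / sqrt(1 + gold^2)
}

rotation_about <- function(axis, deg) {
  a <- axis / sqrt(sum(axis^2))
  th <- deg * pi / 180
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
}

#' Ideal coordination templates
#'
#' The 12-vector first shells of the reference structures together with
#' their distinguishing point-symmetry operations, used by the
#' characteristic-crystallographic-element norm:
#' \describe{
#'   \item{hcp}{triangular orthobicupola shell; distinguishing elements the
#'     basal mirror and the six-fold rotoinversion axis.}
#'   \item{fcc}{cuboctahedral shell; distinguishing element a four-fold
#'     rotation axis.}
#'   \item{fivefold}{icosahedral shell; distinguishing elements a five-fold
#'     rotation and the ten-fold rotoreflection about the same axis.}
#' }
#' `"fivefold_bipyramid"` gives the alternative 7-vector pentagonal
#' bipyramid motif (not used by the default classifier).
#'
#' @param name One of `"hcp"`, `"fcc"`, `"fivefold"`, `"fivefold_bipyramid"`.
#' @return An object of class `coordination_template`: list with `name`,
#'   unit `vectors` (rows) and `symmetry_ops` (list of 3x3 matrices).
#' @export
make_template <- function(name = c("hcp", "fcc", "fivefold", "fivefold_bipyramid")) {
  name <- match.arg(name)
  sigma_h <- diag(c(1, 1, -1))
  if (name == "hcp" || name == "fcc") {
    hexv <- t(vapply(seq(0, 300, by = 60) * pi / 180,
                     function(a) c(cos(a), sin(a), 0), numeric(3)))
    tri <- function(azim_deg, z_sign) {
      t(vapply(azim_deg * pi / 180, function(a) {
        c(cos(a) / sqrt(3), sin(a) / sqrt(3), z_sign * sqrt(2 / 3))
      }, numeric(3)))
    }
    up <- tri(c(90, 210, 330), 1)
    if (name == "hcp") {
      vecs <- rbind(hexv, up, tri(c(90, 210, 330), -1))
      ops <- list(sigma_h, rotation_about(c(0, 0, 1), 60) %*% (-diag(3)))
    } else {
      vecs <- rbind(hexv, up, tri(c(30, 150, 270), -1))
      # express in this frame: the four-fold axis of the cuboctahedron
      ax <- vecs[7, ] + vecs[1, ]  # vertex pair subtending 90 degrees
      ops <- list(rotation_about(ax, 90))
    }
  } else if (name == "fivefold") {
    vecs <- icosahedron_vertices()
    ax <- vecs[1, ]
    refl <- diag(3) - 2 * tcrossprod(ax)
    ops <- list(rotation_about(ax, 72), rotation_about(ax, 36) %*% refl)
  } else {
    ring <- t(vapply(seq(0, 288, by = 72) * pi / 180,
                     function(a) c(cos(a), sin(a), 0), numeric(3)))
    vecs <- rbind(ring, c(0, 0, 1), c(0, 0, -1))
    ops <- list(rotation_about(c(0, 0, 1), 72), sigma_h)
  }
  structure(list(name = name, vectors = vecs, symmetry_ops = ops),
            class = "coordination_template")
}

#' Dilute random chain configurations
#'
#' Grows `n_ch` tangent random walks with overlap rejection at a low packing
#' fraction, with chain lengths drawn from the requested ensemble.  This is
#' the generation protocol for the initial states that are subsequently
#' compressed; the chain-splitting check (see [split_chains()]) verifies
#' independence from the generation protocol.
#'
#' @param n_ch Number of chains.
#' @param ensemble An [ensemble_spec()].
#' @param phi Target packing fraction (must be at most 0.10 for reliable
#'   non-reverting growth).
#' @param seed Integer seed; regeneration is bit-identical.
#' @param exact_total Condition the drawn lengths on
#'   `sum(lengths) == round(n_ch * N_av)` (default TRUE).  The simulated
#'   ensemble conserves both the sphere and the chain count, so the mean
#'   chain length is pinned at `n_at / n_ch`; conditioning the composition
#'   makes that pinned mean coincide with the ensemble's `N_av` and the
#'   stationary length distribution with its target.
#' @return A valid `chain_system`.
#' @export
make_dilute_chains <- function(n_ch, ensemble = ensemble_spec(), phi = 0.05,
                               seed = 1, exact_total = TRUE) {
  if (phi > 0.10) stop("dilute generation requires phi <= 0.10; compress afterwards")
  lengths <- with_seed(seed, {
    if (exact_total && n_ch > 1) {
      target <- round(n_ch * ensemble$N_av)
      tries <- 0
      repeat {
        l <- draw_chain_lengths(n_ch, ensemble)
        if (sum(l) == target) break
        tries <- tries + 1
        if (tries > 1e6) {
          stop("could not draw a composition with total ", target,
               "; is N_av consistent with the ensemble?")
        }
      }
      l
    } else {
      draw_chain_lengths(n_ch, ensemble)
    }
  })
  n_at <- sum(lengths)
  L <- box_edge_for_phi(n_at, phi)
  res <- grow_chains_cpp(as.integer(lengths), rep(L, 3), 1.0, 1e-8,
                         as.integer((seed + 777L) %% .Machine$integer.max))
  if (!isTRUE(res$success)) {
    stop(sprintf("chain growth failed (chain %d); lower phi and retry",
                 res$failed_chain))
  }
  ends <- cumsum(lengths)
  chains <- mapply(function(a, b) seq(a, b), ends - lengths + 1, ends,
                   SIMPLIFY = FALSE)
  chain_system(res$pos, chains, simulation_box(L))
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Random stacking sequence
#'
#' Uniform random sequence over A/B/C with no two consecutive letters equal;
#' by default also distinct across the periodic wrap so the stacking is
#' commensurate.
#'
#' @param n_layers Number of layers.
#' @param seed Integer seed.
#' @param wrap Require first and last letters to differ (default TRUE).
#' @return Character vector of layer letters.
#' @export
random_stacking <- function(n_layers, seed = 1, wrap = TRUE) {
  with_seed(seed, {
    repeat {
      l <- character(n_layers)
      l[1] <- sample(c("A", "B", "C"), 1)
      for (i in 2:n_layers) l[i] <- sample(setdiff(c("A", "B", "C"), l[i - 1]), 1)
      if (!wrap || l[1] != l[n_layers]) return(l)
    }
  })
}
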