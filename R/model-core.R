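# Domain types and validity checking for tangent hard-sphere chain systems.
# Internal length unit is the sphere diameter sigma = 1; file I/O records
# sigma explicitly so configurations in other units are rescaled on read.

#' Periodic simulation box
#'
#' Cubic periodic box used by the Monte Carlo engine and the compression
#' protocol.  Lattice fixtures may carry orthorhombic boxes (three edge
#' lengths) so that close-packed layer stackings are exactly commensurate;
#' all geometric routines accept either.
#'
#' @param edge_length Box edge in units of sigma; either a single value
#'   (cubic) or three values (orthorhombic, fixtures only).
#' @return An object of class `simulation_box` with element `L`, the three
#'   edge lengths.
#' @examples
#' box <- simulation_box(10)
#' minimum_image(c(0.1, 0, 0), c(9.9, 0, 0), box)
#' @export
simulation_box <- function(edge_length) {
  L <- as.numeric(edge_length)
  if (!length(L) %in% c(1L, 3L) || any(!is.finite(L)) || any(L <= 0)) {
    stop("edge_length must be one or three positive finite values")
  }
  if (length(L) == 1L) L <- rep(L, 3L)
  if (length(unique(L)) == 1L && L[1] <= 2) {
    stop("cubic box edge must exceed 2 sigma")
  }
  structure(list(L = L, periodic = TRUE), class = "simulation_box")
}

is_cubic <- function(box) diff(range(box$L)) < 1e-12 * max(box$L)

#' @export
print.simulation_box <- function(x, ...) {
  cat(sprintf("periodic %s box, L = (%g, %g, %g) sigma\n",
              if (is_cubic(x)) "cubic" else "orthorhombic",
              x$L[1], x$L[2], x$L[3]))
  invisible(x)
}

#' Box edge for a target packing fraction
#'
#' Inverts phi = n_at * (pi/6) * sigma^3 / L^3 for a cubic box.
#'
#' @param n_at Number of spheres.
#' @param phi Target packing fraction.
#' @param sigma Sphere diameter (default 1).
#' @return Cubic box edge length in units of sigma.
#' @export
box_edge_for_phi <- function(n_at, phi, sigma = 1) {
  stopifnot(n_at >= 1, phi > 0, phi < 1)
  (n_at * (pi / 6) * sigma^3 / phi)^(1 / 3)
}

#' Tangent hard-sphere chain system
#'
#' The simulated state: wrapped coordinates, an ordered partition of sites
#' into chains, and a periodic box.  Bonds are the consecutive pairs within
#' each chain; tangency requires every bond length in
#' `[sigma, sigma + tangency_tol]`.
#'
#' @param positions `n_at x 3` matrix of coordinates (units of sigma).
#' @param chains List of integer vectors, each the ordered site indices of
#'   one chain; together they must partition `1:n_at`.
#' @param box A [simulation_box()].
#' @param sigma Sphere diameter; coordinates are rescaled to sigma = 1 if not.
#' @param tangency_tol Bond-length tolerance (default `1e-8` sigma).
#' @return An object of class `chain_system`.
#' @export
chain_system <- function(positions, chains, box, sigma = 1, tangency_tol = 1e-8) {
  positions <- as.matrix(positions)
  storage.mode(positions) <- "double"
  if (ncol(positions) != 3) stop("positions must have 3 columns")
  if (sigma != 1) {  # internal unit is sigma = 1
    positions <- positions / sigma
    box$L <- box$L / sigma
    sigma <- 1
  }
  chains <- lapply(chains, as.integer)
  sys <- structure(
    list(pos = wrap_positions(positions, box$L), chains = chains, box = box,
         sigma = sigma, tangency_tol = tangency_tol),
    class = "chain_system")
  part <- partition_defects(sys)
  if (nrow(part) > 0) {
    stop("chains do not partition the sites: ",
         paste(utils::head(part$problem, 3), collapse = "; "))
  }
  sys
}

wrap_positions <- function(pos, L) {
  for (k in 1:3) pos[, k] <- pos[, k] %% L[k]
  pos
}

#' @export
print.chain_system <- function(x, ...) {
  lens <- lengths(x$chains)
  cat(sprintf(paste0("chain_system: %d spheres in %d chains ",
                     "(lengths %d..%d), phi = %.4f\n"),
              n_atoms(x), length(x$chains), min(lens), max(lens),
              packing_fraction(x)))
  invisible(x)
}

#' @rdname chain_system
#' @param sys A `chain_system`.
#' @export
n_atoms <- function(sys) nrow(sys$pos)

#' @rdname chain_system
#' @export
n_chains <- function(sys) length(sys$chains)

#' Bond list of a chain system
#'
#' @param sys A `chain_system`.
#' @return Two-column integer matrix of bonded site pairs (consecutive sites
#'   within each chain).
#' @export
bonds_of <- function(sys) {
  bl <- lapply(sys$chains, function(ch) {
    if (length(ch) < 2) return(NULL)
    cbind(ch[-length(ch)], ch[-1])
  })
  out <- do.call(rbind, bl)
  if (is.null(out)) out <- matrix(integer(), 0, 2)
  out
}

#' Packing fraction
#'
#' phi = n_at * (pi/6) * sigma^3 / V.
#'
#' @param sys A `chain_system`.
#' @return The volume fraction occupied by spheres.
#' @export
packing_fraction <- function(sys) {
  n_atoms(sys) * (pi / 6) * sys$sigma^3 / prod(sys$box$L)
}

#' Minimum-image displacement
#'
#' Displacement `q - p` folded into the primary image, each component in
#' `(-L/2, L/2]`.
#'
#' @param p,q Coordinates (length 3, or `n x 3` matrices).
#' @param box A [simulation_box()].
#' @return The folded displacement, same shape as the inputs.
#' @export
minimum_image <- function(p, q, box) {
  stopifnot(is.finite(p), is.finite(q))
  d <- q - p
  if (is.matrix(d)) {
    for (k in 1:3) d[, k] <- fold1(d[, k], box$L[k])
    d
  } else {
    vapply(1:3, function(k) fold1(d[k], box$L[k]), numeric(1))
  }
}

fold1 <- function(x, L) {
  x <- x - L * round(x / L)
  x[x <= -L / 2] <- x[x <= -L / 2] + L
  x
}

partition_defects <- function(sys) {
  idx <- unlist(sys$chains)
  n <- n_atoms(sys)
  problems <- character()
  dup <- unique(idx[duplicated(idx)])
  if (length(dup)) {
    problems <- c(problems, sprintf("site %d listed in more than one chain", dup))
  }
  missing <- setdiff(seq_len(n), idx)
  if (length(missing)) {
    problems <- c(problems, sprintf("site %d not assigned to any chain", missing))
  }
  bad <- idx[idx < 1 | idx > n]
  if (length(bad)) problems <- c(problems, sprintf("site index %d out of range", bad))
  data.frame(problem = problems, stringsAsFactors = FALSE)
}

#' Validate a chain system
#'
#' Report-only check of the hard-sphere chain invariants: no non-bonded pair
#' closer than sigma (minus a `1e-12` numerical slack), every bond length in
#' `[sigma, sigma + tangency_tol]`, and the chains a partition of the sites.
#'
#' @param sys A `chain_system`.
#' @return A list with data frames `overlaps`, `bad_bonds` and
#'   `partition`, plus the logical `valid`.
#' @export
validate_system <- function(sys) {
  part <- partition_defects(sys)
  bonds <- bonds_of(sys)
  rep <- validate_cpp(sys$pos, sys$box$L, bonds - 1L, sys$sigma, sys$tangency_tol)
  overlaps <- data.frame(i = rep$overlap_i, j = rep$overlap_j, dist = rep$overlap_d)
  bb <- data.frame(bond = rep$bad_bond, length = rep$bad_bond_len)
  if (nrow(bb) > 0) {
    bb$i <- bonds[bb$bond, 1]
    bb$j <- bonds[bb$bond, 2]
  }
  list(overlaps = overlaps, bad_bonds = bb, partition = part,
       valid = nrow(overlaps) == 0 && nrow(bb) == 0 && nrow(part) == 0)
}
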