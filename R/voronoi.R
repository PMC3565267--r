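# Periodic Voronoi tessellation and inertia-tensor shape analysis of the
# cells.  Each cell's vertices are treated as equivalent unit point masses;
# the eigenvalues of their inertia tensor give the asphericity,
# acylindricity and relative shape anisotropy of the local environment.

#' Voronoi tessellation of a chain system
#'
#' Computes the full Voronoi polyhedron (vertices, faces, per-face
#' neighbour) of every site under periodic boundary conditions.  Cells tile
#' the box exactly: their volumes sum to the box volume.
#'
#' @param sys A `chain_system` with at least one site.
#' @param rc Initial candidate-neighbour cutoff (sigma); `NULL` chooses one
#'   from the density and expands automatically if a cell reaches past it.
#' @param jitter Amplitude of the random perturbation applied on retry if a
#'   degenerate configuration defeats the tessellation (default `1e-10`).
#' @return A list of `voronoi_cell` objects: `site_id`, `vertices` (rows,
#'   relative to the site), `faces` (vertex index lists), `neighbor_ids`
#'   (generator site per face) and `volume`.
#' @export
tessellate <- function(sys, rc = NULL, jitter = 1e-10) {
  stopifnot(n_atoms(sys) >= 1)
  cells <- try(voronoi_cpp(sys$pos, sys$box$L, if (is.null(rc)) -1 else rc),
               silent = TRUE)
  ok <- !inherits(cells, "try-error") &&
    abs(sum(vapply(cells, `[[`, numeric(1), "volume")) - prod(sys$box$L)) <
      1e-6 * prod(sys$box$L)
  if (!ok) {  # cosphericity defence: jitter and retry once, reported
    warning("degenerate tessellation; retrying with ", jitter, " sigma jitter")
    pos <- sys$pos + matrix(runif(3 * n_atoms(sys), -jitter, jitter),
                            ncol = 3)
    cells <- voronoi_cpp(wrap_positions(pos, sys$box$L), sys$box$L,
                         if (is.null(rc)) -1 else rc)
  }
  lapply(cells, function(cl) structure(cl, class = "voronoi_cell"))
}

#' Inertia tensor of a Voronoi cell
#'
#' All vertices are treated as equivalent unit point masses measured from
#' their centroid: `I = (1/n_ver) sum_i (r_i^2 delta - r_i r_i)`.
#'
#' @param cell A `voronoi_cell` (or any object with a `vertices` matrix).
#' @return List with the symmetric `tensor`, eigenvalues `values`
#'   (`I1 >= I2 >= I3`) and orthonormal `vectors` (columns, matching order).
#' @export
inertia_tensor <- function(cell) {
  V <- cell$vertices
  if (is.null(dim(V)) || nrow(V) < 4) stop("degenerate cell: fewer than 4 vertices")
  r <- sweep(V, 2, colMeans(V))
  n <- nrow(r)
  I3 <- diag(3) * sum(r^2) / n - crossprod(r) / n
  e <- eigen(I3, symmetric = TRUE)  # eigen() sorts decreasing: I1 >= I2 >= I3
  list(tensor = I3, values = e$values, vectors = e$vectors)
}

#' Shape measures of a Voronoi cell
#'
#' From the sorted principal moments `I1 >= I2 >= I3` of the vertex inertia
#' tensor: ellipsoid semiaxes `L1 = sqrt((5/2)(I2 + I3 - I1))` (and cyclic),
#' asphericity `b = (I1 + I2)/2 - I3`, acylindricity `c = I1 - I2`, and
#' relative shape anisotropy
#' `k2 = 4 (1 - 3 (I1 I2 + I2 I3 + I3 I1) / (I1 + I2 + I3)^2)`.
#' Lower values mean shapes closer to spherical, cylindrical and isotropic
#' respectively; `k2` lies in `[0, 1]`, reaching 1 only for collinear vertex
#' sets.  The local density is the inverse cell volume.
#'
#' @param cell A `voronoi_cell`.
#' @return A one-row data frame: `I1..I3`, `L1..L3`, `b`, `c`, `k2`,
#'   `volume`, `local_density`, `n_vertices`, `n_faces`.
#' @export
shape_measures <- function(cell) {
  it <- inertia_tensor(cell)
  I <- it$values
  tr <- sum(I)
  if (tr <= 0) stop("degenerate cell: all vertices coincident")
  L <- sqrt(pmax(0, 2.5 * c(I[2] + I[3] - I[1],
                            I[3] + I[1] - I[2],
                            I[1] + I[2] - I[3])))
  data.frame(
    I1 = I[1], I2 = I[2], I3 = I[3], L1 = L[1], L2 = L[2], L3 = L[3],
    b = (I[1] + I[2]) / 2 - I[3], c = I[1] - I[2],
    k2 = 4 * (1 - 3 * (I[1] * I[2] + I[2] * I[3] + I[3] * I[1]) / tr^2),
    volume = cell$volume, local_density = 1 / cell$volume,
    n_vertices = nrow(cell$vertices), n_faces = length(cell$faces))
}

#' Per-site shape table of one frame
#'
#' @param sys A `chain_system`.
#' @param cells Optional precomputed [tessellate()] output.
#' @return Data frame with one row per site (`site_id`, `chain_id`, shape
#'   measures).
#' @export
frame_shapes <- function(sys, cells = tessellate(sys)) {
  chain_id <- integer(n_atoms(sys))
  for (c in seq_along(sys$chains)) chain_id[sys$chains[[c]]] <- c
  rows <- lapply(cells, shape_measures)
  out <- do.call(rbind, rows)
  out <- cbind(data.frame(site_id = vapply(cells, `[[`, numeric(1), "site_id"),
                          chain_id = chain_id), out)
  rownames(out) <- NULL
  out
}

#' Shape evolution along a trajectory
#'
#' Arithmetic means of asphericity, acylindricity and relative shape
#' anisotropy over all cells of each frame, plus the frame's mean local
#' density `n_at / sum(V_cell)` (the harmonic mean of the per-site inverse
#' cell volumes), which the space-filling property pins at `n_at / V` on
#' every frame.
#'
#' @param frames List of `chain_system` frames.
#' @return Data frame with one row per frame: `frame`, `mean_b`, `mean_c`,
#'   `mean_k2`, `mean_local_density`.
#' @export
shape_profile <- function(frames) {
  rows <- lapply(seq_along(frames), function(i) {
    sh <- frame_shapes(frames[[i]])
    data.frame(frame = i, mean_b = mean(sh$b), mean_c = mean(sh$c),
               mean_k2 = mean(sh$k2),
               mean_local_density = nrow(sh) / sum(sh$volume))
  })
  do.call(rbind, rows)
}
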