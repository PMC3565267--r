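# Shared test utilities: independent oracles and small generators.

# brute-force minimum image: exhaustive search over the 27 lattice images
brute_min_image <- function(p, q, L) {
  best <- NULL
  best_d <- Inf
  for (ix in -1:1) for (iy in -1:1) for (iz in -1:1) {
    d <- (q + c(ix, iy, iz) * L) - p
    dd <- sum(d^2)
    if (dd < best_d) { best_d <- dd; best <- d }
  }
  best
}

# monomeric system from raw coordinates (no overlap requirements imposed)
point_system <- function(pos, L) {
  chain_system(pos, as.list(seq_len(nrow(pos))), simulation_box(L))
}

poisson_system <- function(n, L, seed) {
  set.seed(seed)
  point_system(matrix(runif(3 * n, 0, L), ncol = 3), L)
}

random_rotation_matrix <- function(seed) {
  set.seed(seed)
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2),
         3, 3, byrow = TRUE)
}

# synthetic "cell" wrapper so shape_measures can be driven by raw vertex sets
vertex_cell <- function(V) {
  structure(list(site_id = 1L, vertices = V, faces = list(),
                 neighbor_ids = integer(), volume = 1),
            class = "voronoi_cell")
}

# direct-summation inertia oracle (independent of inertia_tensor)
inertia_eigen_oracle <- function(V) {
  r <- sweep(V, 2, colMeans(V))
  n <- nrow(r)
  I <- diag(3) * sum(r^2) / n - t(r) %*% r / n
  sort(eigen(I, symmetric = TRUE, only.values = TRUE)$values, decreasing = TRUE)
}

# ideal close-packed first shell (12 unit vectors) with optional hcp stacking
ideal_shell <- function(type = c("fcc", "hcp")) {
  type <- match.arg(type)
  make_template(type)$vectors
}
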