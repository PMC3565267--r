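# Periodic Voronoi tessellation and inertia-tensor shape measures.

test_that("simple cubic lattice tessellates into cubes", {
  sys <- make_sc(4, 1.2)
  cells <- tessellate(sys)
  vols <- vapply(cells, `[[`, numeric(1), "volume")
  expect_equal(vols, rep(1.2^3, length(vols)), tolerance = 1e-10)
  expect_true(all(vapply(cells, function(c) length(c$faces), integer(1)) == 6L))
  expect_equal(sum(vols), prod(sys$box$L), tolerance = 1e-8 * prod(sys$box$L))
})

test_that("fcc cells are rhombic dodecahedra with isotropic vertex inertia", {
  sys <- make_fcc(3)
  cells <- tessellate(sys)
  nf <- vapply(cells, function(c) length(c$faces), integer(1))
  expect_true(all(nf == 12L))
  sh <- shape_measures(cells[[1]])
  expect_lt(sh$b, 1e-10)
  expect_lt(sh$c, 1e-10)
  expect_lt(sh$k2, 1e-10)
  expect_equal(sh$volume, 1 / sqrt(2), tolerance = 1e-10)
})

test_that("hcp cells are trapezo-rhombic dodecahedra: transversely symmetric
           and, like the fcc cell, exactly isotropic in vertex inertia", {
  sys <- make_hcp(6, 3, 2)
  cells <- tessellate(sys)
  int <- which(attr(sys, "layer") %in% 3:4)
  cell <- cells[[int[1]]]
  expect_equal(length(cell$faces), 12L)
  sh <- shape_measures(cell)
  expect_lt(sh$c, 1e-10)   # threefold axis forces I1 = I2
  # The ideal trapezo-rhombic dodecahedron shares the rhombic dodecahedron's
  # vertex quadrupole: the sigma_h-mirrored lower half contributes the same
  # tensor as the inverted lower half, so b = 0 exactly as well.
  # Independent oracle: direct summation over vertices of both cells.
  expect_lt(sh$b, 1e-10)
  eig_fcc <- inertia_eigen_oracle(tessellate(make_fcc(3))[[1]]$vertices)
  eig_hcp <- inertia_eigen_oracle(cell$vertices)
  expect_equal(eig_hcp, eig_fcc, tolerance = 1e-9)
  expect_equal(max(eig_hcp) - min(eig_hcp), 0, tolerance = 1e-10)
})

test_that("cells tile the box for disordered configurations", {
  sys <- poisson_system(500, 8, seed = 3)
  cells <- tessellate(sys)
  vols <- vapply(cells, `[[`, numeric(1), "volume")
  expect_true(all(vols > 0))
  expect_equal(sum(vols), prod(sys$box$L), tolerance = 1e-8 * prod(sys$box$L))
  # neighbour relation is symmetric
  nb <- lapply(cells, `[[`, "neighbor_ids")
  for (i in c(1, 57, 211)) {
    for (j in setdiff(unique(nb[[i]]), i)) expect_true(i %in% nb[[j]])
  }
})

test_that("mean local density is pinned at n/V along a trajectory", {
  sys <- make_dilute_chains(10, ensemble_spec("uniform", 6, 0), phi = 0.05,
                            seed = 13)
  res <- run_mc(sys, run_spec(4000, record_every = 2000, seed = 2, k_trials = 5))
  prof <- shape_profile(res$frames)
  rho <- n_atoms(sys) / prod(sys$box$L)
  expect_equal(prof$mean_local_density, rep(rho, nrow(prof)), tolerance = 1e-6)
})

test_that("inertia tensor closed-form limits hold", {
  # cube of vertices: all eigenvalues equal
  cube <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
  it <- inertia_tensor(vertex_cell(cube))
  expect_equal(it$values[1], it$values[3], tolerance = 1e-12)

  # two antipodal tight clusters on the z axis: collinear limit, k2 = 1
  set.seed(4)
  cl2 <- rbind(matrix(rnorm(30, 0, 1e-8), 10, 3) + rep(c(0, 0, 3), each = 10),
               matrix(rnorm(30, 0, 1e-8), 10, 3) - rep(c(0, 0, 3), each = 10))
  itc <- inertia_tensor(vertex_cell(cl2))
  expect_lt(itc$values[3], 1e-10)
  expect_equal(itc$values[1], itc$values[2], tolerance = 1e-6)
  shc <- shape_measures(vertex_cell(cl2))
  expect_equal(shc$k2, 1, tolerance = 1e-6)

  # isotropic tensor: all shape measures vanish
  sh_cube <- shape_measures(vertex_cell(cube))
  expect_equal(sh_cube$b, 0, tolerance = 1e-12)
  expect_equal(sh_cube$c, 0, tolerance = 1e-12)
  expect_equal(sh_cube$k2, 0, tolerance = 1e-12)

  expect_error(inertia_tensor(vertex_cell(cube[1:3, ])), "degenerate")
})

test_that("k2 stays in [0, 1] under vertex-set fuzzing", {
  set.seed(8)
  for (i in 1:2000) {
    V <- matrix(rnorm(3 * sample(4:20, 1)), ncol = 3)
    k2 <- shape_measures(vertex_cell(V))$k2
    expect_gte(k2, -1e-12)
    expect_lte(k2, 1 + 1e-12)
  }
})

test_that("shape measures are invariant to rigid rotation", {
  set.seed(9)
  V <- matrix(rnorm(36), 12, 3)
  base <- shape_measures(vertex_cell(V))
  for (s in 1:5) {
    R <- random_rotation_matrix(s)
    rot <- shape_measures(vertex_cell(V %*% t(R)))
    expect_equal(rot$b, base$b, tolerance = 1e-10)
    expect_equal(rot$c, base$c, tolerance = 1e-10)
    expect_equal(rot$k2, base$k2, tolerance = 1e-10)
  }
})

test_that("identical frames give identical shape profiles", {
  sys <- make_fcc(2)
  prof <- shape_profile(list(sys, sys))
  expect_equal(prof$mean_b[1], prof$mean_b[2])
  expect_equal(prof$mean_k2[1], prof$mean_k2[2])
})

test_that("fluid frames have strictly larger shape measures than crystals", {
  fluid <- poisson_system(108, 5.2, seed = 17)  # matched site count
  crystal <- make_fcc(3)
  pf <- shape_profile(list(fluid))
  pc <- shape_profile(list(crystal))
  expect_gt(pf$mean_b, pc$mean_b)
  expect_gt(pf$mean_c, pc$mean_c)
  expect_gt(pf$mean_k2, pc$mean_k2)
})
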