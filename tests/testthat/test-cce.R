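# Characteristic-crystallographic-element norm: perfect-crystal identity,
# discrimination, invariances, order parameters.

test_that("perfect crystals have zero self-norm and high cross-norm", {
  fcc <- make_fcc(3)
  nf <- cce_norm(fcc, sites = 1:4)
  expect_true(all(nf$eps_fcc < 1e-8))
  expect_true(all(nf$eps_hcp > 0.245))

  hcp <- make_hcp(6, 3, 2)
  int <- which(attr(hcp, "layer") %in% 3:4)
  nh <- cce_norm(hcp, sites = int[1:4])
  expect_true(all(nh$eps_hcp < 1e-8))
  expect_true(all(nh$eps_fcc > 0.245))
})

test_that("norms grow monotonically with lattice distortion", {
  tm <- make_template("fcc")
  set.seed(5)
  amps <- c(0.01, 0.05, 0.12)
  means <- vapply(amps, function(a) {
    mean(vapply(1:6, function(r) {
      shell <- tm$vectors + matrix(rnorm(36, 0, a), 12, 3)
      cce_shell(shell, tm)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
  # small distortions stay classified as fcc under the printed threshold
  expect_lt(means[1], 0.245)
})

test_that("norms are invariant to rigid motion of the configuration", {
  fcc <- make_fcc(3)
  base <- cce_norm(fcc, sites = 1:3)
  shifted <- fcc
  shifted$pos <- polypack:::wrap_positions(
    sweep(fcc$pos, 2, c(0.37, -1.2, 2.03), "+"), fcc$box$L)
  tr <- cce_norm(shifted, sites = 1:3)
  expect_equal(tr$eps_fcc, base$eps_fcc, tolerance = 1e-8)
  expect_equal(tr$eps_hcp, base$eps_hcp, tolerance = 1e-8)

  # rotation probed on an isolated shell (free of the periodic lattice)
  tm <- make_template("hcp")
  set.seed(7)
  shell <- tm$vectors + matrix(rnorm(36, 0, 0.03), 12, 3)
  e0 <- cce_shell(shell, tm)
  for (s in 1:4) {
    R <- random_rotation_matrix(100 + s)
    expect_equal(cce_shell(shell %*% t(R), tm), e0, tolerance = 1e-7)
  }
})

test_that("rotation minimization agrees with exhaustive random restarts", {
  tm <- make_template("fcc")
  set.seed(31)
  for (rep in 1:3) {
    shell <- tm$vectors + matrix(rnorm(36, 0, 0.08), 12, 3)
    fast <- cce_shell(shell, tm)
    d <- sqrt(rowSums(shell^2))
    u <- shell / mean(d)
    slow <- polypack:::cce_shell_cpp(u, tm$vectors, tm$symmetry_ops,
                                     n_starts = 400, n_refine = 12,
                                     nm_maxit = 400)
    expect_equal(fast, slow, tolerance = 1e-6)
    expect_gte(fast, slow - 1e-6)  # default search must not miss the optimum
  }
})

test_that("classification saturates on perfect crystals and vanishes in fluids", {
  hcp <- make_hcp(4, 3, 2)
  cl <- classify_frame(hcp)
  expect_equal(cl$order$S_hcp, 1)
  expect_equal(cl$order$S_fcc, 0)
  expect_equal(cl$order$tau_c, 1)

  fluid <- make_dilute_chains(40, ensemble_spec("uniform", 6, 0), phi = 0.08,
                              seed = 19)
  clf <- classify_frame(fluid, sites = seq(1, n_atoms(fluid), by = 4))
  expect_lt(clf$order$tau_c, 0.02)
  expect_true(all(clf$sites$label %in% c("amorphous")))
})

test_that("order parameters recover a constructed hcp/fcc mixture", {
  hcp <- make_hcp(6, 3, 2)
  fcc <- make_fcc(3)
  nh <- cce_norm(hcp, sites = which(attr(hcp, "layer") %in% 3:4)[1:9])
  nf <- cce_norm(fcc, sites = 1:21)
  pool <- rbind(nh, nf)  # 30% hcp sites, 70% fcc sites
  S_hcp <- mean(pool$eps_hcp < 0.245)
  S_fcc <- mean(pool$eps_fcc < 0.245)
  expect_equal(S_hcp, 0.30, tolerance = 1e-12)
  expect_equal(S_fcc, 0.70, tolerance = 1e-12)
})

test_that("no site is ever below threshold for both hcp and fcc", {
  frames <- list(
    make_fcc(3), make_hcp(4, 3, 2),
    make_stacking(random_stacking(6, seed = 3), n1 = 3, n2 = 2),
    make_dilute_chains(30, ensemble_spec("uniform", 6, 0), phi = 0.08, seed = 23))
  for (f in frames) {
    n <- cce_norm(f, sites = seq(1, n_atoms(f), by = 3))
    expect_equal(sum(n$eps_hcp < 0.245 & n$eps_fcc < 0.245), 0)
  }
})

test_that("S_X is non-decreasing in the threshold", {
  sys <- make_stacking(random_stacking(6, seed = 9), n1 = 3, n2 = 2)
  norms <- cce_norm(sys)
  S <- vapply(seq(0.05, 1.0, by = 0.05),
              function(th) mean(norms$eps_fcc < th), numeric(1))
  expect_true(all(diff(S) >= 0))
})

test_that("icosahedral environments are fivefold-exclusive", {
  ico <- make_icosahedral_cluster()
  n <- cce_norm(ico, sites = 1)  # central site
  expect_lt(n$eps_5f, 0.245)
  expect_lt(n$eps_5f, 1e-8)
  expect_gt(n$eps_hcp, 0.245)
  expect_gt(n$eps_fcc, 0.245)
})

test_that("sites with too few neighbours get infinite norms, counted amorphous", {
  few <- point_system(rbind(c(1, 1, 1), c(2.2, 1, 1), c(1, 2.2, 1)), 12)
  n <- cce_norm(few)
  expect_true(all(is.infinite(n$eps_fcc)))
  cl <- classify_frame(few)
  expect_true(all(cl$sites$label == "amorphous"))
  expect_equal(cl$order$tau_c, 0)
})

test_that("norm histograms integrate to the order parameters", {
  sys <- make_stacking(random_stacking(6, seed = 11), n1 = 3, n2 = 2)
  cl <- classify_frame(sys)
  h <- norm_distribution(cl$sites, breaks = seq(0, 2, by = 0.005))
  for (st in c("hcp", "fcc")) {
    below <- sum(h$count[h$structure == st & h$mid < 0.245]) / cl$order$n_sites
    expect_equal(below, cl$order[[paste0("S_", st)]], tolerance = 0.01)
  }
  # bidisperse separation on a pure crystal: the fcc histogram splits into a
  # spike at zero (fcc sites) and mass above threshold for the hcp template
  fcc <- make_fcc(3)
  nf <- cce_norm(fcc)
  expect_true(all(nf$eps_fcc < 0.01))
  expect_true(all(nf$eps_hcp > 0.245))
})

test_that("labels map to the conventional rendering colours", {
  expect_equal(unname(label_colors(c("hcp", "fcc", "5f"))),
               c("blue", "red", "green"))
  expect_true(is.na(label_colors("amorphous")))
})
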