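# Pair correlation, flipper mobility, and trajectory-level transition
# detection.

test_that("g(r) of a Poisson point set is unity", {
  sys <- poisson_system(800, 10, seed = 2)
  gr <- g_r(sys, dr = 0.1)
  sel <- gr$r > 0.5  # skip the lowest bins (few ideal pairs, noisy)
  expect_equal(mean(gr$g[sel]), 1, tolerance = 0.02)
  expect_true(all(abs(gr$g[sel] - 1) < 0.25))
})

test_that("g(r) of a contact fcc crystal peaks at the shell distances", {
  sys <- make_fcc(4)
  gr <- g_r(sys, dr = 0.02)
  shells <- c(1, sqrt(2), sqrt(3), 2)
  for (s in shells[shells <= max(gr$r)]) {
    near <- abs(gr$r - s) < 0.03
    expect_gt(max(gr$g[near]), 1.5)
  }
  # no mass between the first two shells or below contact
  between <- gr$r > 1.1 & gr$r < 1.3
  expect_equal(max(gr$g[between]), 0)
  expect_equal(max(gr$g[gr$r < 0.97]), 0)
})

test_that("the ideal-gas normalization integrates to the pair count", {
  sys <- poisson_system(400, 8, seed = 6)
  gr <- g_r(sys, dr = 0.05)
  rho <- (n_atoms(sys) - 1) / prod(sys$box$L)
  dr <- 0.05
  neigh <- sum(4 * pi * gr$r^2 * rho * gr$g * dr)
  expected <- (n_atoms(sys) - 1) * (4 / 3) * pi * max(gr$r + dr / 2)^3 /
    prod(sys$box$L)
  expect_equal(neigh, expected, tolerance = 0.02 * expected)
})

test_that("r_max beyond half the box is rejected", {
  sys <- poisson_system(50, 8, seed = 8)
  expect_error(g_r(sys, r_max = 5), "half the shortest box edge")
})

test_that("an isolated trimer's middle sphere flips at every amplitude", {
  pos <- rbind(c(10, 10, 10), c(10.6, 10.8, 10), c(11.2, 10, 10))
  sys <- chain_system(pos, list(1:3), simulation_box(40), tangency_tol = 1e-2)
  fl <- flipper_fraction(sys)
  expect_equal(fl$eligible, rep(1, 3))
  expect_equal(fl$fraction, rep(1, 3))
})

test_that("a blocking sphere gates the flip at its analytic arc angle", {
  # Trimer ends on the x-axis; the middle sphere rotates on a circle of
  # radius h about the bond axis.  A blocker in the rotation plane at ring
  # radius rb and azimuth alpha_b overlaps the middle sphere exactly when
  # the rotation angle lies within the analytic window
  # (alpha_b - theta, alpha_b + theta), cos(theta) = (h^2+rb^2-1)/(2 h rb).
  d <- 1.2
  h <- sqrt(1 - (d / 2)^2)
  C <- c(10 + d / 2, 10, 10)
  mid <- C + c(0, h, 0)                      # rotation angle alpha = 0
  rb <- 1.75
  theta <- acos((h^2 + rb^2 - 1) / (2 * h * rb))
  a_star <- 8 * pi / 180                     # designed blocking onset
  alpha_b <- a_star + theta                  # window = (8 deg, 8 deg + 2 theta)
  blocker <- C + c(0, rb * cos(alpha_b), rb * sin(alpha_b))
  pos <- rbind(c(10, 10, 10), mid, c(10 + d, 10, 10), blocker)
  sys <- chain_system(pos, list(c(1, 2, 3), 4), simulation_box(40),
                      tangency_tol = 1e-6)
  # window upper edge 8 + 2*theta deg > 12 deg, so 8.5 and 12 are blocked
  expect_gt(2 * theta * 180 / pi, 4 + 1e-6)
  fl <- flipper_fraction(sys, dphi = c(4, 7.5, 8.5, 12))
  expect_equal(fl$fraction, c(1, 1, 0, 0))
})

test_that("flipper fractions nest with amplitude", {
  sys <- make_dilute_chains(15, ensemble_spec("uniform", 8, 0.25), phi = 0.05,
                            seed = 12)
  sys <- compress_system(sys, 0.40, run_spec(1, seed = 13, k_trials = 10),
                         relax_steps = 400, max_cycles = 20000)
  fl <- flipper_fraction(sys, dphi = c(0.01, 0.1, 1, 10))
  expect_true(all(diff(fl$fraction) <= 0))
  # denominator counts interior spheres only
  expect_equal(unique(fl$eligible), n_atoms(sys) - 2 * n_chains(sys))
})

test_that("monomer systems are rejected by the flipper statistic", {
  sys <- make_fcc(2)
  expect_error(flipper_fraction(sys), "interior")
})

test_that("trajectory reports locate a constructed fluid-to-crystal morph", {
  fcc <- make_fcc(3)
  set.seed(33)
  frames <- lapply(c(0.4, 0.35, 0.3, 0.25, 0.12, 0.04, 0.015, 0.005, 0, 0),
                   function(a) {
    f <- fcc
    f$pos <- polypack:::wrap_positions(
      fcc$pos + matrix(rnorm(3 * n_atoms(fcc), 0, a), ncol = 3), fcc$box$L)
    f
  })
  rep <- trajectory_report(frames, window = 2)
  expect_true(rep$transition$detected)
  expect_equal(rep$series$tau_c[10], 1)
  expect_lt(rep$series$tau_c[1], 0.2)
  # asphericity falls as crystallinity rises
  expect_gt(rep$series$mean_b[1], rep$series$mean_b[10])
  expect_lt(rep$transition$asphericity$change * -1, 0)  # steepest fall found
})

test_that("a constant trajectory has no detected transition", {
  sys <- make_fcc(2)
  rep <- trajectory_report(list(sys, sys, sys, sys), window = 2)
  expect_false(rep$transition$detected)
})
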