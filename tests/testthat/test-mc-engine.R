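# The Monte Carlo engine: move mix, hard-constraint safety, conservation
# laws, detailed-balance spot checks, compression.

test_that("move mix normalizes and rejects bad input", {
  mm <- move_mix()
  expect_equal(sum(mm), 1, tolerance = 1e-12)
  expect_true(all(mm >= 0))
  expect_error(move_mix(reptation = -0.1), "non-negative")
  # printed attempt percentages are preserved as relative weights
  expect_equal(unname(mm["internal_libration"] / mm["reptation"]), 3.498,
               tolerance = 1e-12)
  expect_equal(unname(mm["sEB"] / mm["reptation"]), 0.01, tolerance = 1e-12)
})

test_that("configurational-bias trials increase with volume fraction", {
  expect_equal(cb_schedule(0.10), 10L)
  expect_equal(cb_schedule(0.50), 30L)
  expect_equal(cb_schedule(0.61), 50L)
  phis <- seq(0.05, 0.63, by = 0.02)
  expect_true(!is.unsorted(vapply(phis, cb_schedule, integer(1))))
})

test_that("a lone dimer in a huge box accepts almost every move", {
  sys <- chain_system(rbind(c(25, 25, 25), c(26, 25, 25)), list(1:2),
                      simulation_box(50))
  res <- run_mc(sys, run_spec(1e4, record_every = 0, seed = 3, k_trials = 5))
  st <- res$stats
  rep_row <- st[st$move == "reptation", ]
  expect_gt(rep_row$attempted, 0)
  expect_equal(rep_row$accepted / rep_row$attempted, 1, tolerance = 1e-3)
  expect_true(validate_system(res$system)$valid)
})

test_that("hard constraints are never violated over a dense chain run", {
  sys <- make_dilute_chains(12, ensemble_spec("uniform", 8, 0.25), phi = 0.05,
                            seed = 7)
  sys <- compress_system(sys, 0.45, run_spec(1, seed = 8, k_trials = 10),
                         relax_steps = 500, max_cycles = 30000)
  spec <- run_spec(1e5, record_every = 2e4, seed = 9, k_trials = 30,
                   ensemble = ensemble_spec("uniform", 8, 0.25))
  res <- run_mc(sys, spec)
  expect_true(validate_system(res$system)$valid)
  for (f in res$frames) expect_true(validate_system(f)$valid)
  # conservation: site count, chain count, box
  expect_equal(n_atoms(res$system), n_atoms(sys))
  expect_equal(n_chains(res$system), n_chains(sys))
  expect_equal(res$system$box$L, sys$box$L)
  expect_equal(sum(lengths(res$system$chains)), n_atoms(sys))
  # lengths confined to the ensemble interval
  expect_true(all(lengths(res$system$chains) >= 6 &
                  lengths(res$system$chains) <= 10))
})

test_that("chain lengths are frozen when no ensemble is given", {
  sys <- make_dilute_chains(10, ensemble_spec("uniform", 6, 0), phi = 0.04,
                            seed = 15)
  res <- run_mc(sys, run_spec(5e4, record_every = 0, seed = 16, k_trials = 5))
  expect_true(all(lengths(res$system$chains) == 6))
})

test_that("internal libration samples the free rotor uniformly", {
  # trimer with fixed ends: the middle sphere moves on a circle; with only
  # hard-sphere acceptance in free space its angle must be uniform
  pos <- rbind(c(10, 10, 10), c(10.6, 10 + 0.8, 10), c(11.2, 10, 10))
  sys <- chain_system(pos, list(1:3), simulation_box(20), tangency_tol = 1e-2)
  spec <- run_spec(4e4, record_every = 40, seed = 21,
                   movemix = move_mix(0, 0, 0, 0, 1, 0, 0),
                   delta_libration = 60)
  res <- run_mc(sys, spec)
  ang <- vapply(res$frames, function(f) {
    v <- f$pos[2, ] - f$pos[1, ]
    atan2(v[3], v[2])  # azimuth about the x-axis through the ends
  }, numeric(1))
  expect_equal(length(ang), 1000)
  ks <- suppressWarnings(ks.test(ang[seq(1, 1000, by = 5)], "punif", -pi, pi))
  expect_gt(ks$p.value, 0.01)
  # the ends never moved
  expect_equal(res$system$pos[1, ], pos[1, ])
  expect_equal(res$system$pos[3, ], pos[3, ])
})

test_that("connectivity-altering moves fire and keep the state legal", {
  sys <- make_dilute_chains(12, ensemble_spec("uniform", 8, 0.5), phi = 0.05,
                            seed = 25)
  sys <- compress_system(sys, 0.30, run_spec(1, seed = 26, k_trials = 10),
                         relax_steps = 400, max_cycles = 20000)
  mm <- move_mix(0.1, 0.1, 0.1, 0.2, 0.3, 0.1, 0.1)  # boosted sEB/sIEB
  spec <- run_spec(5e4, record_every = 0, seed = 27, k_trials = 10,
                   movemix = mm, ensemble = ensemble_spec("uniform", 8, 0.5),
                   r_search = 0.1)
  res <- run_mc(sys, spec)
  st <- res$stats
  expect_gt(st$accepted[st$move == "sEB"] + st$accepted[st$move == "sIEB"], 0)
  expect_true(validate_system(res$system)$valid)
  expect_equal(n_chains(res$system), 12)
})

test_that("compression reaches its target with rigid chain repositioning", {
  sys <- make_dilute_chains(1, ensemble_spec("uniform", 10, 0), phi = 0.01,
                            seed = 31)
  bond_lengths <- function(s) {
    b <- bonds_of(s)
    sqrt(rowSums(minimum_image(s$pos[b[, 1], ], s$pos[b[, 2], ], s$box)^2))
  }
  bond0 <- bond_lengths(sys)
  # libration-only relaxation: bonds and chain order are untouched, so the
  # only geometry changes come from the rigid affine repositioning
  out <- compress_system(sys, 0.20,
                         run_spec(1, seed = 32, k_trials = 5,
                                  movemix = move_mix(0, 0, 0, 0, 1, 0, 0)),
                         relax_steps = 200, max_cycles = 20000)
  expect_gte(packing_fraction(out), 0.2)
  expect_lt(packing_fraction(out), 0.2 + 1e-4)
  expect_equal(bond_lengths(out), bond0, tolerance = 1e-12)
  expect_true(validate_system(out)$valid)

  # with the full move mix the chain order may change, but every bond must
  # still sit inside the tangency interval
  out2 <- compress_system(sys, 0.20, run_spec(1, seed = 32, k_trials = 5),
                          relax_steps = 200, max_cycles = 20000)
  expect_true(validate_system(out2)$valid)
  expect_true(all(abs(bond_lengths(out2) - (1 + 5e-9)) < 1e-8))
})

test_that("oversized shrink steps are rejected, then succeed adaptively", {
  sys <- make_dilute_chains(20, ensemble_spec("uniform", 6, 0), phi = 0.08,
                            seed = 35)
  out <- compress_system(sys, 0.35, run_spec(1, seed = 36, k_trials = 10),
                         shrink_factor = 0.95,  # far too aggressive at once
                         relax_steps = 300, max_cycles = 30000)
  st <- attr(out, "compress_stats")
  expect_gt(st$shrink_attempted, st$shrink_accepted)  # rejections occurred
  expect_gte(packing_fraction(out), 0.35)
  expect_true(validate_system(out)$valid)
})

test_that("an unreachable target raises a partial-result error with state", {
  sys <- make_dilute_chains(10, ensemble_spec("uniform", 6, 0), phi = 0.05,
                            seed = 41)
  err <- tryCatch(
    compress_system(sys, 0.64, run_spec(1, seed = 42, k_trials = 5),
                    relax_steps = 50, max_cycles = 30),
    polypack_compression_partial = function(e) e)
  expect_s3_class(err, "polypack_compression_partial")
  expect_true(err$last_phi > 0.05 && err$last_phi < 0.64)
  expect_true(validate_system(err$state)$valid)
})

test_that("runs are reproducible bit-exactly for a fixed seed", {
  sys <- make_dilute_chains(8, ensemble_spec("uniform", 6, 0), phi = 0.05,
                            seed = 51)
  r1 <- run_mc(sys, run_spec(2e4, record_every = 0, seed = 52, k_trials = 5))
  r2 <- run_mc(sys, run_spec(2e4, record_every = 0, seed = 52, k_trials = 5))
  expect_identical(r1$system$pos, r2$system$pos)
  expect_identical(r1$system$chains, r2$system$chains)
})
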