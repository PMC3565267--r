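# Ground-truth lattices, stacking sequences, coordination templates and
# dilute chain generation.

test_that("close-packed stackings have perfect 12-neighbour interior shells", {
  sys <- make_stacking("ABCABC", n1 = 3, n2 = 2)
  expect_true(attr(sys, "commensurate"))
  expect_equal(packing_fraction(sys), pi / sqrt(18), tolerance = 1e-6)
  layer <- attr(sys, "layer")
  site <- which(layer == 3)[1]
  d <- sqrt(rowSums(minimum_image(
    matrix(sys$pos[site, ], n_atoms(sys), 3, byrow = TRUE), sys$pos,
    sys$box)^2))
  expect_equal(sum(abs(d - 1) < 1e-9), 12)
  expect_equal(sort(d)[2], 1, tolerance = 1e-12)  # nearest shell at contact
})

test_that("stacking sequences with repeated adjacent letters are rejected", {
  expect_error(make_stacking("ABBA"), "distinct")
  expect_error(stacking_ground_truth(c("A", "A", "B")), "distinct")
  expect_error(make_stacking("AB"), "at least 3")
})

test_that("stacking ground-truth follows the flanking-layer rule", {
  expect_equal(stacking_ground_truth("ABA")[2], "hcp")
  expect_equal(stacking_ground_truth("ABC")[2], "fcc")
  expect_equal(stacking_ground_truth("ABCBCA"),
               c("boundary", "fcc", "hcp", "hcp", "fcc", "boundary"))
})

test_that("pure stackings classify as their crystal under the CCE norm", {
  hcp <- make_stacking("ABAB", n1 = 3, n2 = 2)
  layer <- attr(hcp, "layer")
  sites <- which(layer == 2)[1:4]
  cl <- classify_frame(hcp, sites = sites)
  expect_true(all(cl$sites$label == "hcp"))
})

test_that("templates close under their symmetry operations and are distinct", {
  for (nm in c("hcp", "fcc", "fivefold")) {
    tm <- make_template(nm)
    expect_equal(nrow(tm$vectors), 12)
    expect_equal(sqrt(rowSums(tm$vectors^2)), rep(1, 12), tolerance = 1e-12)
    for (g in tm$symmetry_ops) {
      mapped <- tm$vectors %*% t(g)
      worst <- max(apply(mapped, 1, function(x) {
        min(sqrt(rowSums(sweep(tm$vectors, 2, x)^2)))
      }))
      expect_lt(worst, 1e-10)
    }
    # self-norm is exactly zero for the perfect shell
    expect_lt(cce_shell(tm$vectors, tm), 1e-10)
  }
  expect_error(make_template("bcc"))

  # cross norms separate all three structures beyond the threshold
  tms <- list(make_template("hcp"), make_template("fcc"), make_template("fivefold"))
  for (a in 1:3) for (b in 1:3) {
    if (a == b) next
    expect_gt(cce_shell(tms[[a]]$vectors, tms[[b]]), 0.245)
  }
})

test_that("icosahedral shell has equal nearest-neighbour angles", {
  v <- make_template("fivefold")$vectors
  ang <- apply(v, 1, function(x) {
    cosines <- v %*% x
    max(cosines[cosines < 1 - 1e-9])
  })
  expect_equal(max(ang) - min(ang), 0, tolerance = 1e-10)
})

test_that("dilute chain generation respects the length ensemble", {
  uni <- ensemble_spec("uniform", 12, 0.5)
  sys <- make_dilute_chains(40, uni, phi = 0.05, seed = 5)
  expect_true(all(lengths(sys$chains) >= 6 & lengths(sys$chains) <= 18))
  expect_true(validate_system(sys)$valid)

  flo <- ensemble_spec("flory", 12, N_min = 3)
  sysf <- make_dilute_chains(40, flo, phi = 0.05, seed = 6)
  expect_true(all(lengths(sysf$chains) >= 3))
  expect_true(validate_system(sysf)$valid)

  # bit-identical regeneration under a fixed seed
  again <- make_dilute_chains(40, uni, phi = 0.05, seed = 5)
  expect_identical(again$pos, sys$pos)
  expect_identical(again$chains, sys$chains)
})

test_that("generation is valid across many seeds", {
  uni <- ensemble_spec("uniform", 8, 0.5)
  for (seed in 1:25) {
    sys <- make_dilute_chains(6, uni, phi = 0.08, seed = seed)
    expect_true(validate_system(sys)$valid)
  }
})

test_that("drawn chain-length histograms match the ensemble", {
  uni <- ensemble_spec("uniform", 12, 0.5)
  set.seed(11)
  l <- draw_chain_lengths(1e4, uni)
  ct <- suppressWarnings(chisq.test(table(factor(l, levels = 6:18)),
                                    p = chain_length_pmf(uni)))
  expect_gt(ct$p.value, 0.01)

  flo <- ensemble_spec("flory", 12, N_min = 3)
  lf <- draw_chain_lengths(1e4, flo)
  expect_true(all(lf >= 3))
  obs <- table(factor(lf, levels = flo$n_min:flo$n_max))
  p <- chain_length_pmf(flo)
  keep <- p * 1e4 >= 5
  ct2 <- suppressWarnings(chisq.test(c(obs[keep], sum(obs[!keep])),
                                     p = c(p[keep], sum(p[!keep]))))
  expect_gt(ct2$p.value, 0.01)
})
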