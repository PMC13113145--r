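test_that("ideal-helix construction and extraction are inverse", {
  deg <- pi / 180
  h <- make_ideal_chain("helix", 12, seed = 4)
  ex <- extract_angles(h$structure)
  ok <- ex$valid
  expect_lt(max(abs(ex$angles[ok[, "phi"], "phi"] - (-57 * deg))), 1e-6)
  expect_lt(max(abs(ex$angles[ok[, "psi"], "psi"] - (-47 * deg))), 1e-6)
  expect_lt(max(abs(abs(ex$angles[ok[, "omega"], "omega"]) - pi)), 1e-6)
})

test_that("terminal angles are masked", {
  tab <- random_angle_table(2, 1)
  st <- nerf_reconstruct(tab)
  ex <- extract_angles(st)
  expect_false(ex$valid[1, "phi"])
  expect_false(ex$valid[2, "psi"])
  expect_false(ex$valid[2, "omega"])
  expect_true(all(ex$valid[1, c("psi", "omega", "theta1", "theta2", "theta3")]))
})

test_that("angles -> NeRF -> extraction round trips over many random tables", {
  worst <- 0
  for (seed in 1:30) {
    tab <- random_angle_table(12, seed)
    ex <- extract_angles(nerf_reconstruct(tab))
    err <- abs(torsdiff:::wrap_angle(ex$angles - tab$angles))[tab$valid]
    worst <- max(worst, max(err))
  }
  expect_lt(worst, 1e-6)
})

test_that("NeRF reconstruction reproduces physical backbones up to a rigid transform", {
  for (seed in c(3, 17)) {
    tab <- random_angle_table(15, seed)
    st <- nerf_reconstruct(tab)
    st2 <- nerf_reconstruct(extract_angles(
      transform_structure(st, random_rotation(seed), c(5, -3, 2))))
    expect_lt(torsdiff:::kabsch_rmsd(flat_coords(st), flat_coords(st2)), 1e-6)
  }
})

test_that("reconstructed bond lengths match the geometry constants", {
  bl <- geometry_constants()$bond_lengths
  tab <- random_angle_table(20, 9)
  st <- nerf_reconstruct(tab)
  co <- st$coords
  L <- n_residues(st)
  n_ca <- sqrt(rowSums((co[, "CA", ] - co[, "N", ])^2))
  ca_c <- sqrt(rowSums((co[, "C", ] - co[, "CA", ])^2))
  c_n <- sqrt(rowSums((co[-1, "N", ] - co[-L, "C", ])^2))
  expect_lt(max(abs(n_ca - bl["n_ca"])), 1e-9)
  expect_lt(max(abs(ca_c - bl["ca_c"])), 1e-9)
  expect_lt(max(abs(c_n - bl["c_n"])), 1e-9)
})

test_that("backbone chirality is consistent along physically sampled chains", {
  h <- make_ideal_chain("helix", 15, seed = 2)
  co <- h$structure$coords
  L <- n_residues(h$structure)
  signs <- vapply(seq_len(L - 1), function(i) {
    v1 <- co[i, "CA", ] - co[i, "N", ]
    v2 <- co[i, "C", ] - co[i, "CA", ]
    v3 <- co[i + 1, "N", ] - co[i, "C", ]
    sign(sum(torsdiff:::vcross(v1, v2) * v3))
  }, numeric(1))
  expect_true(all(signs == signs[1]))
})

test_that("angle extraction is invariant under rigid transforms", {
  tab <- random_angle_table(10, 5)
  st <- nerf_reconstruct(tab)
  ex0 <- extract_angles(st)
  for (seed in 1:5) {
    moved <- transform_structure(st, random_rotation(seed),
                                 torsdiff:::with_seed(seed + 50, stats::rnorm(3, sd = 10)))
    expect_lt(max(abs(extract_angles(moved)$angles - ex0$angles)), 1e-9)
  }
})

test_that("nerf_place satisfies its three geometric identities", {
  torsdiff:::with_seed(8, {
    for (k in 1:25) {
      a <- stats::rnorm(3); b <- a + stats::rnorm(3); c <- b + stats::rnorm(3)
      l <- stats::runif(1, 0.5, 3)
      theta <- stats::runif(1, 0.2, pi - 0.2)
      tau <- stats::runif(1, -pi, pi)
      d <- nerf_place(a, b, c, l, theta, tau)
      expect_lt(abs(torsdiff:::vnorm(d - c) - l), 1e-9)
      expect_lt(abs(torsdiff:::planar_angle(b, c, d) - theta), 1e-9)
      expect_lt(abs(torsdiff:::wrap_angle(
        torsdiff:::dihedral_angle(a, b, c, d) - tau)), 1e-9)
    }
  })
})

test_that("nerf_place is 2*pi-periodic in tau and mirror-symmetric in +-tau", {
  a <- c(0, 0, 0); b <- c(1, 0, 0); c <- c(1, 1, 0)
  d1 <- nerf_place(a, b, c, 1, pi / 2, 0.9)
  d2 <- nerf_place(a, b, c, 1, pi / 2, 0.9 + 2 * pi)
  expect_equal(d1, d2, tolerance = 1e-12)
  dp <- nerf_place(a, b, c, 1, pi / 2, pi / 2)
  dm <- nerf_place(a, b, c, 1, pi / 2, -pi / 2)
  # mirror images across the ABC (z = 0) plane
  expect_equal(dp[1:2], dm[1:2], tolerance = 1e-12)
  expect_equal(dp[3], -dm[3], tolerance = 1e-12)
  expect_error(nerf_place(a, b, 2 * b, 1, pi / 2, 0), "collinear")
})

test_that("unit-circle embedding and its inverse behave per contract", {
  tab <- random_angle_table(25, 11)
  emb <- embed_angles(tab)
  # every (cos, sin) pair of a valid table lies on the unit circle
  norms <- sqrt(emb[, seq(1, 11, 2)]^2 + emb[, seq(2, 12, 2)]^2)
  expect_lt(max(abs(norms - 1)), 1e-12)
  # exact inverse
  back <- unembed_angles(emb)
  expect_lt(max(abs(torsdiff:::wrap_angle(back$angles - tab$angles))), 1e-12)
  # cardinal points and scale invariance (phi column pair)
  e <- matrix(0, 1, 12); e[1, 4] <- 1   # theta columns hold sentinels here
  e[1, 1] <- 1; e[1, 2] <- 0
  expect_equal(unname(unembed_angles(e)$angles[1, "phi"]), 0)
  e[1, 1] <- 0; e[1, 2] <- 1
  expect_equal(unname(unembed_angles(e)$angles[1, "phi"]), pi / 2)
  e[1, 1] <- 2; e[1, 2] <- 0
  expect_equal(unname(unembed_angles(e)$angles[1, "phi"]), 0)
  # the pi / -pi limit maps to the same embedded point
  expect_equal(cos(pi), cos(-pi + 1e-16), tolerance = 1e-12)
  # zero-norm pair falls back to the sentinel and is flagged
  z <- embed_angles(tab)
  z[3, 1:2] <- 0
  out <- unembed_angles(z)
  expect_true(attr(out, "degenerate")[3, 1])
  expect_equal(unname(out$angles[3, "phi"]), geometry_constants()$sentinels[["phi"]])
})

test_that("degenerate geometry is rejected", {
  co <- array(0, c(2, 3, 3))
  co[1, , ] <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))   # collinear residue
  co[2, , ] <- rbind(c(3, 1, 0), c(4, 1, 0), c(5, 2, 0))
  st <- backbone_structure(co, c("GLY", "GLY"))
  expect_error(extract_angles(st), "collinear backbone atoms at residue 1")
})

test_that("superposition maps a displaced copy exactly back onto its reference", {
  tab <- random_angle_table(8, 21)
  st <- nerf_reconstruct(tab)
  moved <- transform_structure(st, random_rotation(5), c(9, -2, 4))
  back <- superpose_structures(moved, st)
  expect_lt(attr(back, "rmsd"), 1e-9)
  expect_equal(back$coords, st$coords, tolerance = 1e-8, ignore_attr = TRUE)
  expect_error(superpose_structures(nerf_reconstruct(random_angle_table(5, 1)), st))
})
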