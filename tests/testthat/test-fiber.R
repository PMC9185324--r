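# Worm-like-chain stiffness calibration, energies, forces, and invariances.

test_that("stiffness calibration follows the lattice-beam discretisation", {
  sec <- beam_section(1.8e-3)
  expect_equal(sec$A, pi * (1.8e-3)^2 / 4)
  expect_equal(sec$I, pi * (1.8e-3)^4 / 64)
  expect_equal(sec$I, 5.153e-13, tolerance = 1e-3)
  expect_equal(sec$J, 2 * sec$I)

  l0 <- 10.8e-3 / 7
  st <- calibrate_stiffness(mats$acrylic, sec, l0)
  expect_equal(st$k_s, 3.4e9 * pi * (1.8e-3)^2 / 4 / l0)
  expect_equal(st$k_bend, 3.4e9 * sec$I / l0)
  expect_equal(st$k_t, mats$acrylic$shear_modulus * sec$J / l0)

  # doubling l0 halves all three stiffnesses
  st2 <- calibrate_stiffness(mats$acrylic, sec, 2 * l0)
  expect_equal(unlist(st2), unlist(st) / 2)

  expect_error(calibrate_stiffness(mats$acrylic, sec, 0), "l0")
})

test_that("stretching energy and forces follow Hooke's law per bond", {
  ch <- std_chain()
  p0 <- straight_chain_pos(ch)
  expect_equal(wlc_energy(ch, p0)$total, 0)
  expect_equal(max(abs(wlc_forces(ch, p0))), 0)

  # stretch the last bond by delta: restoring force k_s * delta on each end
  delta <- 1e-6
  p <- p0; p[ch$n, 1] <- p[ch$n, 1] + delta
  f <- wlc_forces(ch, p)
  expect_equal(f[ch$n, 1], -ch$k_s * delta, tolerance = 1e-9)
  expect_equal(f[ch$n - 1, 1], ch$k_s * delta, tolerance = 1e-9)
  expect_equal(wlc_energy(ch, p)$stretch, 0.5 * ch$k_s * delta^2)

  expect_error(wlc_forces(ch, p0 * 0), "zero-length")
})

test_that("bending energy matches k_bend (1 - cos theta) per joint", {
  ch <- std_chain(n = 4, n_clamped = 0)  # free chain: no root-joint weight
  theta <- 0.3
  p <- straight_chain_pos(ch)
  # rotate the last bond by theta in the xy plane
  p[4, ] <- p[3, ] + ch$l0 * c(cos(theta), sin(theta), 0)
  expect_equal(wlc_energy(ch, p)$bend, ch$k_bend * (1 - cos(theta)))

  # clamped chain: the root joint carries twice the stiffness
  chc <- std_chain(n = 4, n_clamped = 2)
  p2 <- straight_chain_pos(chc)
  p2[3, ] <- p2[2, ] + chc$l0 * c(cos(theta), sin(theta), 0)
  p2[4, ] <- p2[3, ] + chc$l0 * c(cos(theta), sin(theta), 0)
  expect_equal(wlc_energy(chc, p2)$bend, 2 * chc$k_bend * (1 - cos(theta)))
})

test_that("analytic WLC forces match the numerical energy gradient", {
  for (seed in c(1, 2, 3)) {
    ch <- std_chain()
    p <- bent_chain_pos(ch, seed = seed)
    f <- wlc_forces(ch, p)
    g <- numeric_wlc_grad(ch, p)
    scale <- max(abs(f))
    expect_gt(scale, 0)
    expect_lt(max(abs(f + g)) / scale, 1e-6)
  }
  # free chain too (uniform joint weights)
  ch <- std_chain(n = 6, n_clamped = 0)
  p <- bent_chain_pos(ch, seed = 9)
  expect_lt(max(abs(wlc_forces(ch, p) + numeric_wlc_grad(ch, p))) /
              max(abs(wlc_forces(ch, p))), 1e-6)
})

test_that("internal forces are translation and rotation invariant", {
  ch <- std_chain(n_clamped = 0)
  p <- bent_chain_pos(ch, seed = 5)
  f <- wlc_forces(ch, p)
  scale <- max(abs(f))
  # net force zero
  expect_lt(max(abs(colSums(f))) / scale, 1e-12)
  # net torque about the centroid zero
  pc <- sweep(p, 2, colMeans(p))
  tq <- colSums(cbind(
    pc[, 2] * f[, 3] - pc[, 3] * f[, 2],
    pc[, 3] * f[, 1] - pc[, 1] * f[, 3],
    pc[, 1] * f[, 2] - pc[, 2] * f[, 1]))
  expect_lt(max(abs(tq)) / (scale * max(abs(pc))), 1e-10)

  # rigid-body motion produces no internal forces
  ang <- 0.7
  R <- rbind(c(cos(ang), -sin(ang), 0), c(sin(ang), cos(ang), 0), c(0, 0, 1))
  p2 <- straight_chain_pos(ch) %*% t(R) + matrix(1e-2, ch$n, 3)
  expect_lt(max(abs(wlc_forces(ch, p2))), 1e-9 * ch$k_s * ch$l0)
})

test_that("torsion energy and torque are consistent", {
  ch <- std_chain()
  g0 <- rep(0, ch$n - 1)
  expect_identical(torsion_energy(ch, g0), 0)
  expect_equal(torsion_torques(ch, g0), g0)

  phi <- 0.02
  g <- g0; g[3] <- phi
  expect_equal(torsion_torques(ch, g)[3], -ch$k_t * phi)
  expect_equal(torsion_energy(ch, g), 0.5 * ch$k_t * phi^2)
  # energy-torque consistency by finite difference
  h <- 1e-8
  gp <- g; gp[3] <- gp[3] + h
  gm <- g; gm[3] <- gm[3] - h
  dH <- (torsion_energy(ch, gp) - torsion_energy(ch, gm)) / (2 * h)
  expect_equal(-dH, torsion_torques(ch, g)[3], tolerance = 1e-6)
})

test_that("a free bent chain relaxes to straight with all bonds at l0", {
  ch <- std_chain(n = 5, n_clamped = 0)
  p <- straight_chain_pos(ch)
  p[5, ] <- p[4, ] + ch$l0 * c(cos(0.6), sin(0.6), 0)
  sys <- dem_system(p, radius = r_std, mass = m_std,
                    chain_of = rep(1L, 5), chains = list(ch))
  dt <- 0.1 * 2 * sqrt(m_std / ch$k_s)
  out <- relax_static(sys, dt = dt, tol_v = 1e-8, tol_f = 1e-9,
                      damping = 2e4)
  bonds <- diff(out$pos)
  lens <- sqrt(rowSums(bonds^2))
  expect_equal(lens, rep(ch$l0, 4), tolerance = 1e-6)
  tang <- bonds / lens
  dots <- rowSums(tang[-1, , drop = FALSE] * tang[-4, , drop = FALSE])
  expect_equal(dots, rep(1, 3), tolerance = 1e-6)
})
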