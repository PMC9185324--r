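# Time integration: critical step, collisions, conservation, relaxation,
# determinism, and failure diagnostics.

test_that("critical timestep scales with mass and stiffness", {
  cfg <- brushing_config()
  brush <- build_brush(cfg)
  pf <- pair_ae()
  dt <- critical_timestep(brush, pf, depth = cfg$depth)
  expect_equal(as.numeric(dt), 0.1 * attr(dt, "dt_crit"))

  # halving particle mass scales dt_crit by 1/sqrt(2)
  b2 <- brush; b2$mass <- brush$mass / 2
  dt2 <- critical_timestep(b2, pf, depth = cfg$depth)
  expect_equal(attr(dt2, "dt_crit"), attr(dt, "dt_crit") / sqrt(2))

  # a stiffer contact gives a smaller step
  stiffer <- pf; stiffer$e_star <- pf$e_star * 10; stiffer$g_star <- pf$g_star * 10
  dt3 <- critical_timestep(brush, stiffer, depth = cfg$depth)
  expect_lt(as.numeric(dt3), as.numeric(dt))
})

test_that("a force-free particle moves uniformly", {
  sys <- dem_system(rbind(c(0, 0, 1)), radius = r_std, mass = m_std,
                    vel = rbind(c(0.3, -0.1, 0.2)))
  out <- simulate_dynamics(sys, dt = 1e-5, n_steps = 1000, record = FALSE)
  expect_equal(out$pos[1, ], c(0, 0, 1) + 1000 * 1e-5 * c(0.3, -0.1, 0.2))
  expect_equal(out$vel[1, ], c(0.3, -0.1, 0.2))
})

test_that("an elastic frictionless bounce returns the launch speed within 1%", {
  pf <- pair_ae(e = 1, mu = 0)
  v0 <- 0.3
  sys <- dem_system(rbind(c(0, 0, r_std + 1e-5)), radius = r_std,
                    mass = m_std, vel = rbind(c(0, 0, -v0)),
                    facets = list(big_facet()), pair_facet = pf)
  sn <- 2 * pf$e_star * sqrt(r_std * 0.1 * r_std)
  dt <- 2 * sqrt(m_std / sn) / 50
  out <- simulate_dynamics(sys, dt = dt,
                           n_steps = ceiling(3 * 1e-4 / v0 / dt),
                           record = FALSE)
  expect_gt(out$vel[1, 3], 0)
  expect_equal(out$vel[1, 3] / v0, 1, tolerance = 0.01)
})

test_that("an e = 1, mu = 0 binary collision conserves energy and momentum", {
  v0 <- 0.5
  out <- binary_collision(e = 1, mu = 0, v0 = v0)
  ke0 <- 2 * 0.5 * m_std * v0^2
  ke1 <- 0.5 * m_std * sum(out$vel^2)
  expect_equal(ke1 / ke0, 1, tolerance = 0.01)
  # total momentum of the isolated pair conserved to round-off
  expect_lt(max(abs(colSums(out$vel))), 1e-12 * v0)
})

test_that("damped collisions recover the coefficient of restitution", {
  # the no-tension clamp truncates dissipation near separation, so the
  # recovery degrades as e decreases; within 10% down to e = 0.5
  for (e in c(0.9, 0.7, 0.5)) {
    out <- binary_collision(e = e, v0 = 0.4)
    ratio <- abs(out$vel[1, 1]) / 0.4
    expect_equal(ratio, e, tolerance = 0.1)
  }
})

test_that("relax_static reaches equilibrium and reports non-convergence", {
  # unloaded straight cantilever: already at equilibrium
  case <- cantilever_case(0.5)
  sys <- brushwear:::cantilever_system(case, load = 0)
  dt <- 0.1 * 2 * sqrt(sys$mass[1] / sys$ks[1])
  out <- relax_static(sys, dt = dt)
  expect_true(out$converged)
  expect_equal(out$pos, sys$pos, tolerance = 1e-12)

  # small tip load: Euler-Bernoulli within 5%
  d <- dem_cantilever_deflection(case)
  expect_equal(d, case$load * case$free_length^3 / (3 * case$EI),
               tolerance = 0.05)
  # residual at exit below tolerance by construction
  sys30 <- brushwear:::cantilever_system(cantilever_case(2))
  out30 <- relax_static(sys30, dt = dt, tol_v = 1e-6, tol_f = 2e-6)
  expect_lt(out30$resid_f, 2e-6)

  expect_error(relax_static(sys30, dt = dt, max_steps = 200),
               "did not converge")
})

test_that("a blown-up integration aborts with a diagnostic", {
  pf <- pair_ae()
  sys <- dem_system(rbind(c(0, 0, r_std / 2)), radius = r_std, mass = m_std,
                    facets = list(big_facet()), pair_facet = pf)
  # a grossly over-critical step makes the contact oscillator explode
  expect_error(simulate_dynamics(sys, dt = 1e-2, n_steps = 10000,
                                 record = FALSE),
               "aborted")
})

test_that("the engine is deterministic across repeated runs", {
  mk <- function() {
    ch <- std_chain()
    p <- straight_chain_pos(ch, axis = c(0, 0, -1))
    p[, 3] <- p[, 3] + 10.8e-3 + r_std - 0.3e-3  # tip overlaps the plane
    dem_system(p, radius = r_std, mass = m_std,
               clamped = seq_len(8) <= 2, chain_of = rep(1L, 8),
               chains = list(ch), facets = list(big_facet()),
               pair_facet = pair_ae(), pair_particle = pair_aa(),
               damping = 10)
  }
  motion <- list(type = 1L, V = 0.1, L = 8e-3, d_z = 0.2e-3,
                 t_down = 4e-3, t_hold = 2e-3)
  dt <- 1.7e-7
  o1 <- simulate_dynamics(mk(), dt = dt, n_steps = 50000, stride = 100,
                          motion = motion)
  o2 <- simulate_dynamics(mk(), dt = dt, n_steps = 50000, stride = 100,
                          motion = motion)
  expect_identical(o1$pos, o2$pos)
  expect_identical(o1$vel, o2$vel)
  expect_identical(o1$rec$force, o2$rec$force)
  expect_identical(o1$wear, o2$wear)
})
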