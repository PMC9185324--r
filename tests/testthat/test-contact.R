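# Hertz-Mindlin pair properties, force laws, and contact detection.

test_that("equivalent pair properties follow the combination rules", {
  # identical materials, equal radii and masses: symmetric halving
  p <- pair_aa()
  E <- mats$acrylic$elastic_modulus; nu <- mats$acrylic$poisson_ratio
  expect_equal(p$e_star, E / (2 * (1 - nu^2)))
  expect_equal(p$r_star, r_std / 2)
  expect_equal(p$m_star, m_std / 2)

  # acrylic sphere against an enamel plane: closed form, R* = R_a, m* = m_a
  q <- pair_ae()
  expect_equal(q$e_star, 1 / ((1 - 0.09) / 3.4e9 + (1 - 0.09) / 60e9))
  expect_equal(q$r_star, r_std)
  expect_equal(q$m_star, m_std)

  # e = 1 gives zero damping ratio; e < 1 gives beta < 0
  expect_identical(pair_aa(e = 1)$beta, 0)
  expect_lt(pair_aa(e = 0.3)$beta, 0)
  expect_equal(pair_aa(e = 0.3)$beta, log(0.3) / sqrt(log(0.3)^2 + pi^2))
})

test_that("non-physical material constants are rejected", {
  expect_error(dem_material("x", -1, 0.3, 1000, 1e9), "elastic_modulus")
  expect_error(dem_material("x", 1e9, 0.6, 1000, 1e9), "poisson_ratio")
  expect_error(dem_material("x", 1e9, 0.3, 0, 1e9), "density")
  expect_error(dem_material("x", 1e9, 0.3, 1000, 1e9, restitution = 0), "restitution")
  expect_error(dem_material("x", 1e9, 0.3, 1000, 1e9, friction = -0.1), "friction")
  expect_error(effective_pair_properties(mats$acrylic, mats$enamel,
                                         radius_a = -1, mass_a = 1), "radius_a")
})

test_that("normal force law matches the Hertz-Mindlin form", {
  p <- pair_ae()
  expect_identical(hm_normal_force(p, 0), 0)
  expect_error(hm_normal_force(p, -1e-6), "delta_n")

  # unit-substitution case: E* = 1 Pa, R* = 1 m, dn = 1 m, no damping
  unit <- p; unit$e_star <- 1; unit$r_star <- 1; unit$beta <- 0
  expect_equal(hm_normal_force(unit, 1), 4 / 3)

  # e = 1: elastic term only regardless of velocity
  pe1 <- pair_ae(e = 1)
  dn <- 1e-4
  f_el <- 4 / 3 * pe1$e_star * sqrt(pe1$r_star) * dn^1.5
  expect_equal(hm_normal_force(pe1, dn, v_n = -2), f_el)
  expect_equal(hm_normal_force(pe1, dn, v_n = 2), f_el)

  # damping opposes relative motion: approach stiffens, separation softens
  expect_gt(hm_normal_force(p, dn, v_n = -0.1), hm_normal_force(p, dn, 0))
  expect_lt(hm_normal_force(p, dn, v_n = 0.1), hm_normal_force(p, dn, 0))
  # and the total is never attractive
  expect_identical(hm_normal_force(p, 1e-7, v_n = 10), 0)

  # continuity and monotonicity in overlap at zero velocity
  dns <- seq(0, 5e-4, length.out = 40)
  fs <- vapply(dns, function(d) hm_normal_force(p, d), numeric(1))
  expect_identical(fs[1], 0)
  expect_true(all(diff(fs) > 0))
})

test_that("tangential force law and Coulomb cap behave", {
  p <- pair_ae()
  z <- hm_tangential_force(p, 1e-4, c(0, 0, 0), c(0, 0, 0))
  expect_equal(z$force, c(0, 0, 0))
  expect_error(hm_tangential_force(p, 0, c(0, 0, 0)), "active contact")

  # unit substitution: G* = 1, R* dn = 1, delta_t = (1,0,0), no damping
  unit <- p; unit$g_star <- 1; unit$r_star <- 1; unit$beta <- 0; unit$mu <- 1e12
  res <- hm_tangential_force(unit, 1, c(1, 0, 0), f_n = 1e13)
  expect_equal(res$force, c(-8, 0, 0))

  # large slip saturates exactly at the Coulomb limit and rescales delta_t
  dn <- 1e-4
  fn <- hm_normal_force(p, dn)
  cap <- hm_tangential_force(p, dn, c(1, 0, 0), f_n = fn)
  expect_equal(sqrt(sum(cap$force^2)), p$mu * fn)
  st <- 8 * p$g_star * sqrt(p$r_star * dn)
  expect_equal(cap$delta_t, -cap$force / st)

  # |F_t| <= mu |F_n| over random states
  set.seed(7)
  for (i in 1:50) {
    dni <- runif(1, 1e-6, 5e-4)
    fni <- hm_normal_force(p, dni, rnorm(1, 0, 0.1))
    res <- hm_tangential_force(p, dni, rnorm(3, 0, 1e-5), rnorm(3, 0, 0.1),
                               f_n = fni)
    expect_lte(sqrt(sum(res$force^2)), p$mu * fni + 1e-12)
  }
})

test_that("sphere-facet detection handles interior, edge, and miss cases", {
  fac <- big_facet()
  r <- 1e-3

  grazing <- detect_sphere_plane(c(0, 0, r), r, fac)
  expect_equal(grazing$delta_n, 0)
  expect_true(grazing$interior)

  half <- detect_sphere_plane(c(0.01, -0.02, r / 2), r, fac)
  expect_equal(half$delta_n, r / 2)
  expect_equal(half$normal, c(0, 0, 1))
  expect_equal(half$point, c(0.01, -0.02, 0))

  # beyond the facet bounds laterally by more than a radius: no contact
  expect_null(detect_sphere_plane(c(0.05 + 1.1 * r, 0, r / 2), r, fac))

  # edge contact: normal points from the closest edge point to the centre
  edge <- detect_sphere_plane(c(0.05 + r / 2, 0, 0), r, fac)
  expect_false(edge$interior)
  expect_equal(edge$normal, c(1, 0, 0))
  expect_equal(edge$delta_n, r / 2)

  # a centre below the plane interior is still pushed out the front face
  under <- detect_sphere_plane(c(0, 0, -r / 4), r, fac)
  expect_equal(under$normal, c(0, 0, 1))
  expect_equal(under$delta_n, 1.25 * r)

  expect_error(planar_facet(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0)), "degenerate")
})

test_that("sphere-sphere detection respects overlap and bond exclusion", {
  r <- 1e-3
  mk <- function(x, chain = NA, index = NULL)
    list(center = c(x, 0, 0), radius = r, chain = chain, index = index)

  expect_equal(detect_sphere_sphere(mk(0), mk(2 * r))$delta_n, 0)
  touch <- detect_sphere_sphere(mk(0), mk(1.8 * r))
  expect_equal(touch$delta_n, 0.2 * r)
  expect_equal(touch$normal, c(-1, 0, 0))
  expect_null(detect_sphere_sphere(mk(0), mk(2.5 * r)))

  # bonded neighbours in the same chain are excluded even when overlapping
  expect_null(detect_sphere_sphere(mk(0, chain = 1, index = 3),
                                   mk(1.5 * r, chain = 1, index = 4)))
  # non-adjacent same-chain particles do contact
  expect_false(is.null(detect_sphere_sphere(mk(0, chain = 1, index = 3),
                                            mk(1.5 * r, chain = 1, index = 5))))

  expect_error(detect_sphere_sphere(mk(0), mk(0)), "coincident")
})
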