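# Archard wear: closed form, incremental accumulation, map summaries.

test_that("the closed-form Archard law evaluates correctly", {
  expect_equal(archard_total(wear_params(K = 1, H = 1), W = 1, L = 1), 1)
  expect_equal(archard_total(wear_params(), W = 0, L = 1), 0)
  expect_equal(archard_total(wear_params(K = 1e-4, H = 0.92e9), W = 2, L = 0.056),
               1e-4 * 2 * 0.056 / 0.92e9)
  expect_error(archard_total(wear_params(), W = -1, L = 1), ">= 0")
  expect_error(wear_params(K = 0), "K")
  expect_error(wear_params(H = -1), "H")
})

test_that("incremental accumulation matches the map invariants", {
  teeth <- build_teeth(brushing_config())
  map <- wear_map(teeth, cell = 0.5e-3, params = wear_params(K = 1, H = 1e9))

  # empty stream: unchanged
  empty <- data.frame(facet = character(0), a = numeric(0), b = numeric(0),
                      f_n = numeric(0), slip = numeric(0))
  expect_equal(total_wear(accumulate_wear(map, empty)), 0)

  inc <- data.frame(facet = "left_plate", a = 1e-3, b = 2e-3,
                    f_n = 1, slip = 1e-6)
  m1 <- accumulate_wear(map, inc)
  expect_equal(total_wear(m1), 1e-15)
  expect_equal(m1$grids$left_plate[3, 5], 1e-15)

  # increments on an excluded facet are dropped and counted
  drop <- data.frame(facet = "aux_plate", a = 1e-3, b = 1e-3,
                     f_n = 2, slip = 1e-6)
  m2 <- accumulate_wear(m1, drop)
  expect_equal(total_wear(m2), total_wear(m1))
  expect_equal(m2$n_dropped, 1)
  expect_equal(m2$dropped, 2e-6)

  # linearity: doubling the increments doubles every cell
  inc2 <- rbind(inc, inc)
  m3 <- accumulate_wear(map, inc2)
  expect_equal(m3$grids$left_plate, 2 * m1$grids$left_plate)

  # conservation: total Q equals (K/H) * sum(F_n * slip) exactly
  set.seed(11)
  rnd <- data.frame(facet = "right_plate", a = runif(40, 0, 1e-2),
                    b = runif(40, 0, 1e-2), f_n = runif(40, 0, 5),
                    slip = runif(40, 0, 1e-6))
  m4 <- accumulate_wear(map, rnd)
  expect_equal(total_wear(m4), sum(rnd$f_n * rnd$slip) / 1e9)
  expect_error(accumulate_wear(map, transform(inc, f_n = -1)), ">= 0")
})

test_that("a constant-load dragged tip reproduces the closed form", {
  # single kinematic particle pressed to a fixed overlap and dragged at
  # constant speed across a wear facet: total map wear = K W L / H
  pf <- pair_ae()
  overlap <- 1e-5
  W <- 4 / 3 * pf$e_star * sqrt(pf$r_star) * overlap^1.5
  params <- wear_params(K = 1, H = 0.92e9)
  fac <- big_facet(half = 0.04)
  sys <- dem_system(rbind(c(-0.03, 0, r_std - overlap)), radius = r_std,
                    mass = m_std, clamped = TRUE, facets = list(fac),
                    pair_facet = pf, wear = params, wear_cell = 0.5e-3)
  V <- 0.1; L_slide <- 0.05
  motion <- list(type = 1L, V = V, L = 2 * L_slide, d_z = 0,
                 t_down = 0, t_hold = 0)
  dt <- 2e-6
  out <- simulate_dynamics(sys, dt = dt,
                           n_steps = floor((L_slide / V) / dt),
                           motion = motion, record = FALSE)
  map <- brushwear:::make_wear_map(out$wear, list(facet = fac), 0.5e-3,
                                   params, raw = out$wear_raw)
  got <- total_wear(map)
  want <- archard_total(params, W, L_slide)
  expect_equal(got, want, tolerance = 5e-3)
  # engine-side conservation between raw F_n * slip and the map
  expect_equal(total_wear(map) * params$H / params$K, out$wear_raw)
})

test_that("wear summaries report symmetry and groove concentration", {
  teeth <- build_teeth(brushing_config())
  map <- wear_map(teeth, params = wear_params(K = 1, H = 1))

  # uniform map: symmetry score 0, densities equal
  for (nm in names(map$grids)) map$grids[[nm]][] <- 1e-12
  s <- summarize_wear(map)
  expect_equal(s$symmetry, 0)
  expect_equal(s$groove_density, s$plate_density, tolerance = 1e-9)

  # all wear on groove facets: groove fraction 1
  map2 <- wear_map(teeth, params = wear_params(K = 1, H = 1))
  map2$grids$groove_floor[] <- 1e-12
  s2 <- summarize_wear(map2)
  expect_equal(s2$groove_fraction, 1)
  expect_equal(s2$plate_q, 0)

  # an asymmetric map scores > 0
  map3 <- wear_map(teeth, params = wear_params(K = 1, H = 1))
  g <- map3$grids$left_plate
  g[, seq_len(floor(ncol(g) / 2))] <- 1e-12
  map3$grids$left_plate <- g
  expect_gt(summarize_wear(map3)$symmetry, 0.5)

  # cell records flatten consistently
  df <- as.data.frame(map)
  expect_equal(sum(df$Q), total_wear(map))
  expect_true(all(c("facet", "a", "b", "s", "y", "Q") %in% names(df)))
})
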