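# Brush assembly, tooth model, and scrub-stroke kinematics.

test_that("the default brush has 42 chains of 8 particles, 2 clamped each", {
  cfg <- brushing_config()
  brush <- build_brush(cfg)
  expect_equal(nrow(brush$pos), 336)
  expect_equal(sum(brush$clamped), 84)
  expect_equal(brush$n_chains, 42)
  expect_equal(brush$l0, 10.8e-3 / 7)
  expect_equal(brush$free_length, 6 * 10.8e-3 / 7)

  # all tip particles initially coplanar at grazing height (centre = r)
  tips <- brush$pos[seq(8, 336, by = 8), ]
  expect_true(all(abs(tips[, 3] - brush$radius) < 1e-12))

  # anchors within the head bounds
  expect_true(all(abs(brush$anchors[, 1]) <= cfg$head_length / 2))
  expect_true(all(abs(brush$anchors[, 2]) <= cfg$head_width / 2))

  # chains initially perpendicular to the head plane
  expect_true(all(abs(diff(brush$pos[1:8, 1])) < 1e-15))
  expect_true(all(abs(diff(brush$pos[1:8, 3]) + brush$l0) < 1e-12))

  # per-particle mass is the solid-segment mass of the aggregate beam
  expect_equal(brush$mass, 1185 * pi * (1.8e-3)^2 / 4 * brush$l0)
})

test_that("brush and tooth geometry are mirror symmetric about y = 0", {
  cfg <- brushing_config()
  brush <- build_brush(cfg)
  expect_equal(sort(unique(brush$pos[, 2])), -rev(sort(unique(brush$pos[, 2]))))
  teeth <- build_teeth(cfg)
  for (f in teeth$facets) {
    ys <- f$origin[2] + c(0, f$u[2], f$v[2], f$u[2] + f$v[2])
    expect_equal(min(ys), -max(ys))
  }
})

test_that("invalid configurations are rejected", {
  expect_error(brushing_config(depth = 1e-3), "depth")
  expect_error(brushing_config(depth = 0), "depth")
  expect_error(brushing_config(tuft_cols = 20), "spacing")
  expect_error(brushing_config(groove_width = 30e-3), "groove")
  expect_error(brushing_config(speed = 0), "speed")
})

test_that("the tooth model realises the two-plate + groove layout", {
  cfg <- brushing_config()
  teeth <- build_teeth(cfg)

  # measured span is half the two-stroke length: L = 2 x span
  expect_equal(teeth$span, cfg$stroke / 2)
  expect_equal(teeth$span, 28e-3)

  # head centre crosses the groove centre at stroke fractions 1/5 and 4/5
  expect_equal(teeth$groove_center, cfg$stroke / 5)
  mp <- motion_profile(cfg$speed, cfg$depth, cfg$stroke)
  expect_equal(head_position(0.2 * mp$duration, mp)$displacement,
               teeth$groove_center)
  expect_equal(head_position(0.8 * mp$duration, mp)$displacement,
               teeth$groove_center)

  # plates share the z = 0 plane; groove floor offset by the groove depth
  lp <- teeth$facets$left_plate; rp <- teeth$facets$right_plate
  expect_equal(lp$origin[3], 0)
  expect_equal(rp$origin[3], 0)
  expect_equal(teeth$facets$groove_floor$origin[3], -cfg$groove_depth)

  # plate outward normals point away from the tooth (+z); wall normals
  # point into the groove
  expect_equal(lp$normal, c(0, 0, 1))
  expect_equal(teeth$facets$groove_left_wall$normal, c(1, 0, 0))
  expect_equal(teeth$facets$groove_right_wall$normal, c(-1, 0, 0))

  # the auxiliary plate and left support are excluded from wear
  expect_false(teeth$facets$aux_plate$wear)
  expect_false(teeth$facets$left_support$wear)
  expect_equal(sqrt(sum(teeth$facets$aux_plate$u^2)), 36e-3)
  expect_true(all(vapply(teeth$facets[c("groove_left_wall", "groove_floor",
                                        "groove_right_wall")],
                         function(f) f$groove, logical(1))))
})

test_that("head position follows the scrub profile", {
  mp <- motion_profile(speed = 0.05, depth = 0.9e-3, stroke = 0.056)
  expect_equal(mp$duration, 1.12)

  expect_equal(head_position(0, mp)$displacement, 0)
  expect_equal(head_position(mp$duration / 2, mp)$displacement, 0.028)
  expect_equal(head_position(mp$duration, mp)$displacement, 0, tolerance = 1e-12)
  expect_equal(head_position(0.1, mp)$velocity, 0.05)
  expect_equal(head_position(1.0, mp)$velocity, -0.05)
  expect_error(head_position(-0.1, mp), "window")
  expect_error(head_position(2, mp), "window")

  # displacement is continuous across the reversal
  eps <- 1e-9
  expect_equal(head_position(mp$duration / 2 - eps, mp)$displacement,
               head_position(mp$duration / 2 + eps, mp)$displacement,
               tolerance = 1e-6)
})
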