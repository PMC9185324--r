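# Assembly geometry: the 42-tuft brush, the two-plate + groove tooth model,
# and the prescribed scrub-stroke kinematics.
#
# Coordinate convention: x = stroke direction, y = vertical on the tooth
# (across the brush head), z = outward normal of the tooth plane. The tooth
# surface lies at z = 0 with the tooth solid below; overlap is positive into
# the surface. The brush-head centre starts at x = 0 and translates to
# x = L/2 and back, so the measured tooth span is [0, L/2] and the head
# centre crosses the interproximal groove at stroke fractions 1/5 and 4/5.

#' Brushing simulation configuration
#'
#' Collects every parameter of a brushing run, with defaults reproducing the
#' standard setup: 42 acrylic tuft-beams of 8 particles (diameter 1.8 mm,
#' length 10.8 mm, two particles clamped) on a 27.5 x 10.2 mm head, an
#' enamel tooth model of two coplanar plates joined by a rectangular
#' interproximal groove, a 56 mm two-stroke scrub cycle, and brushing depth
#' expressed as initial tip overlap below the tooth plane.
#'
#' @param speed Brushing speed V (m/s); 0.05, 0.10 or 0.15 are the standard
#'   settings.
#' @param depth Brushing depth d_z (m): the prescribed overlap of the
#'   undeformed bristle tips below the tooth plane, in (0, r] with bristle
#'   radius r = 0.9 mm. Standard settings r, r/2, r/4.
#' @param stroke Total two-stroke path length L (m); forward L/2, then back.
#' @param tuft_rows,tuft_cols Tuft grid on the head (rows across the head
#'   width, columns along the stroke); 3 x 14 = 42 tufts.
#' @param head_length,head_width Brush head dimensions (m).
#' @param n_particles Particles per tuft chain.
#' @param beam_length Tuft beam length tip-to-root (m).
#' @param particle_diameter Particle (and beam) diameter (m).
#' @param n_clamped Leading particles of each chain clamped to the head.
#' @param groove_width,groove_depth Rectangular interproximal groove
#'   cross-section (m).
#' @param tooth_height Vertical (y) extent of the tooth plates (m). The
#'   default spans an odd number of wear cells so the horizontal mid-plane
#'   (the symmetry plane of brush and teeth) is a cell centre.
#' @param aux_plate_length Extra wear-excluded plate attached to the
#'   right-hand side, absorbing the stroke reversal (m).
#' @param left_support_length Wear-excluded coplanar support to the left of
#'   the measured region so bristles are supported at the stroke start (m).
#' @param restitution Coefficient of restitution for all contacts.
#' @param archard_k Archard wear constant K (dimensionless). The default 1
#'   reports wear volume per unit K; relative wear distributions are
#'   K-independent.
#' @param wear_cell Wear-map cell size (m).
#' @param dt_safety Time step as a fraction of the critical step.
#' @param damping Background viscous damping coefficient (1/s,
#'   mass-proportional) suppressing ringing of released bristles.
#' @param press_speed Speed at which the head is pressed in to depth `d_z`
#'   before the stroke starts (m/s).
#' @param hold_time Settling hold between press-in and stroke start (s).
#' @param torsion Enable torsional bond forces (off by default; bending
#'   dominates brushing and is the validated mode).
#' @param gravity Enable gravity (off by default: bristle weight is
#'   negligible against contact forces and the brushing orientation is
#'   unspecified).
#' @param bristle_contacts Enable bristle-bristle (particle-particle)
#'   contacts.
#' @param stroke_scale Scale factor applied to the stroke length (with the
#'   tooth span scaled consistently); 1 is the full cycle, 0.5 a
#'   desk-scale half-stroke variant.
#' @return Object of class `brushing_config`.
#' @export
brushing_config <- function(speed = 0.10,
                            depth = 0.9e-3,
                            stroke = 0.056,
                            tuft_rows = 3, tuft_cols = 14,
                            head_length = 27.5e-3, head_width = 10.2e-3,
                            n_particles = 8,
                            beam_length = 10.8e-3,
                            particle_diameter = 1.8e-3,
                            n_clamped = 2,
                            groove_width = 2.4e-3, groove_depth = 3.0e-3,
                            tooth_height = 16.5e-3,
                            aux_plate_length = 36e-3,
                            left_support_length = 30e-3,
                            restitution = 0.3,
                            archard_k = 1.0,
                            wear_cell = 0.5e-3,
                            dt_safety = 0.1,
                            damping = 10,
                            press_speed = 0.05,
                            hold_time = 0.02,
                            torsion = FALSE,
                            gravity = FALSE,
                            bristle_contacts = TRUE,
                            stroke_scale = 1.0) {
  r <- particle_diameter / 2
  if (speed <= 0) stop("speed must be > 0")
  if (depth <= 0 || depth > r) stop("depth must lie in (0, r]")
  if (stroke <= 0) stop("stroke must be > 0")
  if (stroke_scale <= 0 || stroke_scale > 1) stop("stroke_scale must lie in (0, 1]")
  if (n_particles < 3) stop("n_particles must be >= 3")
  spacing_x <- head_length / tuft_cols
  if (spacing_x < particle_diameter)
    stop("tuft spacing along the head is smaller than the tuft diameter: ",
         "initial interpenetration")
  if (tuft_rows > 1 &&
      (2 * head_width / 3) / (tuft_rows - 1) < particle_diameter)
    stop("tuft spacing across the head is smaller than the tuft diameter")
  span <- stroke * stroke_scale / 2
  if (groove_width >= span - 2 * wear_cell)
    stop("groove wider than the tooth plates")
  cfg <- structure(list(
    speed = speed, depth = depth, stroke = stroke * stroke_scale,
    stroke_scale = stroke_scale,
    tuft_rows = tuft_rows, tuft_cols = tuft_cols,
    head_length = head_length, head_width = head_width,
    n_particles = n_particles, beam_length = beam_length,
    particle_diameter = particle_diameter, n_clamped = n_clamped,
    groove_width = groove_width, groove_depth = groove_depth,
    tooth_height = tooth_height,
    aux_plate_length = aux_plate_length,
    left_support_length = left_support_length,
    restitution = restitution, archard_k = archard_k,
    wear_cell = wear_cell, dt_safety = dt_safety,
    damping = damping, press_speed = press_speed, hold_time = hold_time,
    torsion = torsion, gravity = gravity,
    bristle_contacts = bristle_contacts,
    materials = material_presets(restitution)
  ), class = "brushing_config")
  cfg
}

#' @export
print.brushing_config <- function(x, ...) {
  cat("<brushing_config>\n")
  cat(sprintf("  V = %.3g m/s, d_z = %.3g mm, stroke L = %.3g mm (scale %.2g)\n",
              x$speed, x$depth * 1e3, x$stroke * 1e3, x$stroke_scale))
  cat(sprintf("  brush: %d x %d tufts, %d particles each (%d clamped), d = %.2g mm\n",
              x$tuft_rows, x$tuft_cols, x$n_particles, x$n_clamped,
              x$particle_diameter * 1e3))
  cat(sprintf("  groove: %.2g x %.2g mm; wear cell %.2g mm; e = %.2g; K = %.3g\n",
              x$groove_width * 1e3, x$groove_depth * 1e3, x$wear_cell * 1e3,
              x$restitution, x$archard_k))
  invisible(x)
}

#' Build the brush assembly
#'
#' Places the tuft chains on a rectangular grid over the head, initially
#' perpendicular to the head plane with all tips coplanar at grazing height
#' (tip spheres touching the tooth plane, zero overlap). The head centre
#' starts at x = 0. The first `n_clamped` particles of every chain are
#' kinematic: slaved to the head frame and excluded from integration.
#'
#' @param config A `brushing_config`.
#' @return Object of class `brush_assembly` with particle positions, masses,
#'   clamp mask, chain bookkeeping and calibrated chain stiffnesses.
#' @export
build_brush <- function(config) {
  stopifnot(inherits(config, "brushing_config"))
  r <- config$particle_diameter / 2
  n <- config$n_particles
  l0 <- config$beam_length / (n - 1)
  sec <- beam_section(config$particle_diameter)
  stiff <- calibrate_stiffness(config$materials$acrylic, sec, l0)
  mass <- config$materials$acrylic$density * sec$A * l0

  # anchor grid, centred on the head
  xs <- (seq_len(config$tuft_cols) - (config$tuft_cols + 1) / 2) *
    (config$head_length / config$tuft_cols)
  ys <- if (config$tuft_rows == 1) 0 else
    seq(-config$head_width / 3, config$head_width / 3,
        length.out = config$tuft_rows)

  n_chain <- config$tuft_rows * config$tuft_cols
  npart <- n_chain * n
  pos <- matrix(0, npart, 3)
  clamped <- logical(npart)
  chain_of <- integer(npart)
  k <- 0L
  for (iy in seq_along(ys)) {
    for (ix in seq_along(xs)) {
      k <- k + 1L
      rows <- ((k - 1L) * n + 1L):(k * n)
      # particle i (1 = root, n = tip); tips graze the tooth plane: tip
      # centre at z = r
      pos[rows, 1] <- xs[ix]
      pos[rows, 2] <- ys[iy]
      pos[rows, 3] <- r + (n - seq_len(n)) * l0
      clamped[rows[seq_len(config$n_clamped)]] <- TRUE
      chain_of[rows] <- k
    }
  }
  structure(list(
    pos = pos, clamped = clamped, chain_of = chain_of,
    n_chains = n_chain, n_per_chain = n, l0 = l0,
    radius = r, mass = mass, stiffness = stiff, section = sec,
    free_length = (n - config$n_clamped) * l0,
    anchors = cbind(rep(xs, times = length(ys)), rep(ys, each = length(xs)))
  ), class = "brush_assembly")
}

#' @export
print.brush_assembly <- function(x, ...) {
  cat(sprintf("<brush_assembly> %d chains x %d particles = %d (clamped %d)\n",
              x$n_chains, x$n_per_chain, nrow(x$pos), sum(x$clamped)))
  cat(sprintf("  l0 = %.4g mm, free length = %.4g mm, particle mass = %.4g kg\n",
              x$l0 * 1e3, x$free_length * 1e3, x$mass))
  invisible(x)
}

#' Build the simplified tooth model
#'
#' Two coplanar enamel plates at z = 0 joined by a rectangular interproximal
#' groove (two side walls and a floor). The measured span equals half the
#' stroke length, and the groove is centred so that the head centre crosses
#' it at stroke fractions 1/5 (forward) and 4/5 (backward). A wear-excluded
#' auxiliary plate extends the right-hand side (absorbing the stroke
#' reversal) and a wear-excluded support extends the left of the measured
#' region.
#'
#' @param config A `brushing_config`.
#' @return Object of class `tooth_model`: a list of `dem_facet`s plus groove
#'   geometry bookkeeping.
#' @export
build_teeth <- function(config) {
  stopifnot(inherits(config, "brushing_config"))
  L <- config$stroke
  span <- L / 2
  gxc <- L / 5                      # head centre displacement at fraction 1/5
  gw <- config$groove_width
  gd <- config$groove_depth
  gx0 <- gxc - gw / 2
  gx1 <- gxc + gw / 2
  if (gx0 <= 0 || gx1 >= span) stop("groove does not fit inside the plates")
  hh <- config$tooth_height / 2
  hy <- config$tooth_height

  facets <- list(
    left_plate = planar_facet(c(0, -hh, 0), c(gx0, 0, 0), c(0, hy, 0),
                              wear = TRUE, name = "left_plate"),
    groove_left_wall = planar_facet(c(gx0, -hh, -gd), c(0, hy, 0), c(0, 0, gd),
                                    wear = TRUE, groove = TRUE,
                                    name = "groove_left_wall"),
    groove_floor = planar_facet(c(gx0, -hh, -gd), c(gw, 0, 0), c(0, hy, 0),
                                wear = TRUE, groove = TRUE,
                                name = "groove_floor"),
    groove_right_wall = planar_facet(c(gx1, -hh, -gd), c(0, 0, gd), c(0, hy, 0),
                                     wear = TRUE, groove = TRUE,
                                     name = "groove_right_wall"),
    right_plate = planar_facet(c(gx1, -hh, 0), c(span - gx1, 0, 0), c(0, hy, 0),
                               wear = TRUE, name = "right_plate"),
    aux_plate = planar_facet(c(span, -hh, 0), c(config$aux_plate_length, 0, 0),
                             c(0, hy, 0), wear = FALSE, name = "aux_plate"),
    left_support = planar_facet(c(-config$left_support_length, -hh, 0),
                                c(config$left_support_length, 0, 0),
                                c(0, hy, 0), wear = FALSE,
                                name = "left_support")
  )
  structure(list(
    facets = facets, span = span, groove_x = c(gx0, gx1),
    groove_center = gxc, groove_depth = gd,
    tooth_height = config$tooth_height,
    material = config$materials$enamel
  ), class = "tooth_model")
}

#' @export
print.tooth_model <- function(x, ...) {
  cat(sprintf("<tooth_model> measured span %.3g mm, groove x in [%.3g, %.3g] mm, depth %.3g mm\n",
              x$span * 1e3, x$groove_x[1] * 1e3, x$groove_x[2] * 1e3,
              x$groove_depth * 1e3))
  cat(sprintf("  %d facets (%d wear-measured)\n", length(x$facets),
              sum(vapply(x$facets, function(f) f$wear, logical(1)))))
  invisible(x)
}

#' Scrub-stroke motion profile
#'
#' Constant-speed forward translation over L/2 followed by an instantaneous
#' reversal and a backward translation of L/2, parallel to the gingiva. The
#' head's vertical position is fixed during the stroke so that the
#' undeformed tip overlap equals the brushing depth d_z.
#'
#' @param speed Brushing speed V (m/s).
#' @param depth Brushing depth d_z (m).
#' @param stroke Total two-stroke path length L (m).
#' @return Object of class `motion_profile`.
#' @export
motion_profile <- function(speed = 0.10, depth = 0.9e-3, stroke = 0.056) {
  if (speed <= 0 || depth <= 0 || stroke <= 0)
    stop("speed, depth and stroke must be > 0")
  structure(list(V = speed, d_z = depth, L = stroke,
                 duration = stroke / speed),
            class = "motion_profile")
}

#' Head position along the stroke
#'
#' @param t Time since stroke start (s), in [0, L/V].
#' @param motion A `motion_profile`.
#' @return List with the head-centre `displacement` (m) along the stroke
#'   axis, the signed `velocity` (m/s), the `phase` ("forward"/"backward")
#'   and the path `fraction` travelled in [0, 1].
#' @export
head_position <- function(t, motion) {
  stopifnot(inherits(motion, "motion_profile"))
  if (any(t < 0) || any(t > motion$duration + 1e-12))
    stop("t outside the run window [0, L/V]")
  half <- motion$duration / 2
  disp <- ifelse(t <= half, motion$V * t, motion$L - motion$V * t)
  vel <- ifelse(t <= half, motion$V, -motion$V)
  list(displacement = disp, velocity = vel,
       phase = ifelse(t <= half, "forward", "backward"),
       fraction = motion$V * t / motion$L)
}
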