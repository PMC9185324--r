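# Explicit dynamics driver: assembles the flat arrays the C++ engine
# consumes, chooses the time step, and wraps single runs / quasi-static
# relaxation with diagnostics.

#' Assemble a DEM system
#'
#' Low-level constructor for the particle system handed to the time
#' integrator: free spheres, worm-like chains, bounded facets, and the two
#' Hertz-Mindlin parameter sets (particle-facet and particle-particle).
#' Chains must occupy contiguous particle rows ordered root to tip.
#'
#' @param pos n x 3 matrix of particle centres (m).
#' @param radius Particle radius, scalar or length-n (m).
#' @param mass Particle mass, scalar or length-n (kg).
#' @param vel Optional n x 3 initial velocities (m/s); zero by default.
#' @param clamped Logical length-n: kinematic particles (moved with the head
#'   frame, infinite effective mass in contacts, not integrated).
#' @param chain_of Integer length-n: chain id (1-based) or NA for free
#'   particles.
#' @param chains List of `fiber_chain` objects, one per chain id.
#' @param facets List of `dem_facet` objects.
#' @param pair_facet `contact_pair` for particle-facet contacts.
#' @param pair_particle `contact_pair` for particle-particle contacts;
#'   `NULL` disables them.
#' @param groove_x Length-2 x-interval classifying contacts as interproximal
#'   (for force tagging); defaults to an empty interval.
#' @param wear `wear_params` for Archard accumulation on wear-flagged
#'   facets.
#' @param wear_cell Wear-map cell size (m).
#' @param gravity Gravity vector (m/s^2).
#' @param damping Background mass-proportional viscous damping (1/s).
#' @param fext Optional n x 3 constant external force (N).
#' @param torsion Enable torsional bond dynamics.
#' @return Object of class `dem_sys` (a list in engine layout).
#' @export
dem_system <- function(pos, radius, mass, vel = NULL, clamped = NULL,
                       chain_of = NULL, chains = list(), facets = list(),
                       pair_facet = NULL, pair_particle = NULL,
                       groove_x = c(Inf, -Inf),
                       wear = wear_params(), wear_cell = 0.5e-3,
                       gravity = c(0, 0, 0), damping = 0, fext = NULL,
                       torsion = FALSE) {
  pos <- as.matrix(pos)
  n <- nrow(pos)
  stopifnot(ncol(pos) == 3)
  if (is.null(vel)) vel <- matrix(0, n, 3)
  vel <- as.matrix(vel)
  radius <- rep_len(radius, n)
  mass <- rep_len(mass, n)
  if (is.null(clamped)) clamped <- rep(FALSE, n)
  if (is.null(chain_of)) chain_of <- rep(NA_integer_, n)
  nC <- length(chains)

  chain_start <- integer(nC); chain_len <- integer(nC)
  ks <- kb <- kt <- l0 <- numeric(nC); tip <- integer(nC)
  broot <- integer(nC)
  for (c in seq_len(nC)) {
    rows <- which(!is.na(chain_of) & chain_of == c)
    if (length(rows) == 0) stop("chain ", c, " has no particles")
    if (any(diff(rows) != 1L)) stop("chain ", c, " is not contiguous")
    ch <- chains[[c]]
    if (length(rows) != ch$n) stop("chain ", c, " length mismatch")
    chain_start[c] <- rows[1] - 1L
    chain_len[c] <- length(rows)
    ks[c] <- ch$k_s; kb[c] <- ch$k_bend; kt[c] <- ch$k_t; l0[c] <- ch$l0
    tip[c] <- length(rows) - 1L
    broot[c] <- ch$root_joint
  }

  nF <- length(facets)
  fm <- matrix(0, nF, 9)
  fwear <- integer(nF); fgroove <- integer(nF)
  for (f in seq_len(nF)) {
    fc <- facets[[f]]
    stopifnot(inherits(fc, "dem_facet"))
    fm[f, ] <- c(fc$origin, fc$u, fc$v)
    fwear[f] <- as.integer(fc$wear)
    fgroove[f] <- as.integer(fc$groove)
  }

  pair4 <- function(p) if (is.null(p)) c(0, 0, 0, 0) else
    c(p$e_star, p$g_star, p$beta, p$mu)

  structure(list(
    pos = pos, vel = vel, radius = radius, mass = mass,
    clamped = as.integer(clamped),
    chain_start = chain_start, chain_len = chain_len,
    ks = ks, kb = kb, kt = kt, l0 = l0,
    bend_root = broot,
    torsion = isTRUE(torsion),
    facets = fm, facet_wear = fwear, facet_groove = fgroove,
    pf = pair4(pair_facet), pp = pair4(pair_particle),
    pp_on = !is.null(pair_particle) && n > 1,
    groove_x = as.numeric(groove_x),
    wear_K = wear$K, wear_H = wear$H, wear_cell = wear_cell,
    gravity = as.numeric(gravity), gamma = damping,
    fext = fext,
    tip_idx = tip,
    chain_of = as.integer(ifelse(is.na(chain_of), 0L, chain_of)) - 1L,
    facet_meta = facets
  ), class = "dem_sys")
}

default_ctrl <- function(dt, n_steps, stride = 1L, snap_times = numeric(0),
                         motion = list(type = 0L), relax = FALSE,
                         tol_v = 1e-6, tol_f = 1e-6, check_every = 100L,
                         record = TRUE, ke_abort = 100) {
  list(dt = dt, n_steps = as.numeric(n_steps), stride = as.integer(stride),
       snap_times = snap_times, motion = motion, relax = relax,
       tol_v = tol_v, tol_f = tol_f, check_every = as.integer(check_every),
       record = record, ke_abort = ke_abort)
}

run_engine <- function(sys, ctrl) {
  out <- dem_run_cpp(unclass(sys), ctrl)
  if (isTRUE(out$aborted)) {
    stop(sprintf(
      "integration aborted at step %.0f (t = %.4g s): %s [particle %d]",
      out$steps, out$t_end, out$abort_msg, out$bad_particle), call. = FALSE)
  }
  out
}

#' Step a particle system forward in time
#'
#' Semi-implicit (symplectic) Euler: velocities are updated from the
#' assembled forces, then positions from the new velocities. Clamped
#' particles follow the prescribed head motion. The engine is deterministic:
#' identical inputs give identical trajectories.
#'
#' @param sys A `dem_sys`.
#' @param dt Time step (s).
#' @param n_steps Number of steps.
#' @param stride Recording stride (steps between force-log rows).
#' @param motion Kinematic head-motion description (internal layout); the default
#'   keeps clamped particles fixed.
#' @param snap_times Times at which per-chain contact forces are snapshot.
#' @param record Keep the per-stride force log.
#' @return Engine output list: final `pos`/`vel`, force log `rec`, wear
#'   grids, diagnostics.
#' @export
simulate_dynamics <- function(sys, dt, n_steps, stride = 1L,
                              motion = list(type = 0L),
                              snap_times = numeric(0), record = TRUE) {
  stopifnot(inherits(sys, "dem_sys"))
  if (dt <= 0) stop("dt must be > 0")
  ctrl <- default_ctrl(dt, n_steps, stride = stride, snap_times = snap_times,
                       motion = motion, record = record)
  run_engine(sys, ctrl)
}

#' Relax a system to static equilibrium
#'
#' Integrates with strong mass-proportional viscous damping until both the
#' maximum particle speed and the maximum net-force residual fall below
#' tolerance. Used by the cantilever validation bench.
#'
#' @param sys A `dem_sys` (external loads fixed via `sys$fext`).
#' @param dt Time step (s); pick from [critical_timestep()].
#' @param tol_v Speed tolerance (m/s).
#' @param tol_f Net-force residual tolerance (N).
#' @param damping Viscous damping coefficient (1/s) used during relaxation.
#'   Equilibrium does not depend on it; it only sets the convergence rate.
#' @param max_steps Abort (with a residual report) if not converged.
#' @return Engine output list with `converged = TRUE`, final positions and
#'   residuals.
#' @export
relax_static <- function(sys, dt, tol_v = 1e-7, tol_f = 1e-6,
                         damping = 5e4, max_steps = 5e6) {
  stopifnot(inherits(sys, "dem_sys"))
  sys$gamma <- damping
  ctrl <- default_ctrl(dt, max_steps, stride = 1000L, relax = TRUE,
                       tol_v = tol_v, tol_f = tol_f, record = FALSE,
                       ke_abort = 1e8)
  out <- run_engine(sys, ctrl)
  if (!isTRUE(out$converged)) {
    stop(sprintf(
      "relax_static did not converge in %.0f steps (residual speed %.3g m/s, force %.3g N)",
      out$steps, out$resid_v, out$resid_f), call. = FALSE)
  }
  out
}

#' Critical time step of the assembled system
#'
#' \eqn{\Delta t_{crit} = 2\sqrt{m/k_{max}}} over the particles, where
#' \eqn{k_{max}} bounds the stiffest interaction: the chain stretching
#' stiffness and the Hertz-Mindlin normal/tangential contact stiffnesses
#' evaluated at the prescribed brushing-depth overlap.
#'
#' @param assembly A `brush_assembly`.
#' @param pair `contact_pair` for the bristle-tooth contact.
#' @param depth Overlap at which the contact stiffness is bounded (m);
#'   typically the brushing depth d_z.
#' @param safety Returned step is `safety * dt_crit`.
#' @return Recommended time step (s), with attributes `dt_crit` and
#'   `k_max`.
#' @export
critical_timestep <- function(assembly, pair, depth, safety = 0.1) {
  stopifnot(inherits(assembly, "brush_assembly"), inherits(pair, "contact_pair"))
  sn <- 2 * pair$e_star * sqrt(assembly$radius * depth)
  st <- 8 * pair$g_star * sqrt(assembly$radius * depth)
  k_max <- max(assembly$stiffness$k_s, sn, st)
  dt_crit <- 2 * sqrt(assembly$mass / k_max)
  structure(safety * dt_crit, dt_crit = dt_crit, k_max = k_max)
}

# Full brushing system: brush assembly + tooth model + contact pairs.
assemble_brushing_system <- function(config) {
  brush <- build_brush(config)
  teeth <- build_teeth(config)
  sec <- brush$section
  chain <- fiber_chain(config$n_particles, brush$l0, brush$stiffness,
                       n_clamped = config$n_clamped,
                       diameter = config$particle_diameter)
  pf <- effective_pair_properties(config$materials$acrylic,
                                  config$materials$enamel,
                                  radius_a = brush$radius, mass_a = brush$mass)
  pp <- if (config$bristle_contacts)
    effective_pair_properties(config$materials$acrylic,
                              config$materials$acrylic,
                              radius_a = brush$radius, radius_b = brush$radius,
                              mass_a = brush$mass, mass_b = brush$mass)
  else NULL
  sys <- dem_system(
    pos = brush$pos, radius = brush$radius, mass = brush$mass,
    clamped = brush$clamped, chain_of = brush$chain_of,
    chains = rep(list(chain), brush$n_chains),
    facets = teeth$facets,
    pair_facet = pf, pair_particle = pp,
    groove_x = teeth$groove_x + c(-1, 1) * brush$radius,
    wear = wear_params(K = config$archard_k,
                       H = config$materials$enamel$hardness),
    wear_cell = config$wear_cell,
    gravity = if (config$gravity) c(0, 0, -9.81) else c(0, 0, 0),
    damping = config$damping,
    torsion = config$torsion
  )
  list(sys = sys, brush = brush, teeth = teeth, pair_facet = pf,
       pair_particle = pp, chain = chain)
}
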