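# Worm-like-chain fiber model: one bristle tuft (a bundle of ~40 filaments
# treated as a single beam) is a chain of connected particles carrying
# stretching, bending and torsion energies:
#
#   H_S = 1/2 k_s sum_i (l_i - l_0)^2
#   H_B = k_bend sum_joints (1 - t_i . t_{i+1})         (unit bond tangents)
#   H_T = 1/2 k_T sum_i (gamma_i - gamma_0)^2           (scalar bond twist)
#
# Forces are the exact analytic gradients of these energies.

#' Circular beam cross-section properties
#'
#' @param diameter Beam diameter (m). Default 1.8 mm, the aggregate tuft-beam
#'   diameter.
#' @return Object of class `beam_section` with area `A`, area moment `I`
#'   (\eqn{\pi d^4/64}) and polar moment `J` (\eqn{\pi d^4/32}).
#' @export
beam_section <- function(diameter = 1.8e-3) {
  if (!is.numeric(diameter) || diameter <= 0) stop("diameter must be > 0")
  structure(list(
    diameter = diameter,
    A = pi * diameter^2 / 4,
    I = pi * diameter^4 / 64,
    J = pi * diameter^4 / 32
  ), class = "beam_section")
}

#' Calibrate chain stiffnesses from continuum beam properties
#'
#' Standard lattice-beam discretisation of an elastic rod of modulus E and
#' shear modulus G into segments of rest length `l0`:
#' \deqn{k_s = E A / l_0, \quad k_{bend} = E I / l_0, \quad k_T = G J / l_0.}
#' This mapping is what makes the cantilever validation against the elastica
#' meaningful: the chain's aggregate bending response converges to that of
#' the continuum beam.
#'
#' @param material A `dem_material` (the beam material).
#' @param section A `beam_section`.
#' @param l0 Equilibrium particle spacing (m), > 0.
#' @return List with `k_s` (N/m), `k_bend` (N m), `k_t` (N m/rad).
#' @export
calibrate_stiffness <- function(material, section, l0) {
  stopifnot(inherits(material, "dem_material"), inherits(section, "beam_section"))
  if (!is.numeric(l0) || l0 <= 0) stop("l0 must be > 0")
  list(
    k_s = material$elastic_modulus * section$A / l0,
    k_bend = material$elastic_modulus * section$I / l0,
    k_t = material$shear_modulus * section$J / l0
  )
}

#' Construct a fiber chain (one tuft)
#'
#' @param n_particles Number of particles (>= 3); 8 for the standard tuft.
#' @param l0 Equilibrium bond length (m).
#' @param stiffness List with `k_s`, `k_bend`, `k_t` as returned by
#'   [calibrate_stiffness()].
#' @param n_clamped Number of leading particles clamped to the brush head
#'   (kinematic, not integrated); 2 for the standard tuft, 0 for a free
#'   chain.
#' @param diameter Particle diameter (m).
#' @param twist0 Equilibrium twist per bond (rad).
#' @return Object of class `fiber_chain`.
#' @export
fiber_chain <- function(n_particles = 8, l0, stiffness, n_clamped = 2,
                        diameter = 1.8e-3, twist0 = 0) {
  if (n_particles < 3) stop("a fiber chain needs at least 3 particles")
  if (!is.numeric(l0) || l0 <= 0) stop("l0 must be > 0")
  ks <- stiffness$k_s; kb <- stiffness$k_bend; kt <- stiffness$k_t
  if (any(c(ks, kb, kt) <= 0)) stop("stiffnesses must be > 0")
  if (n_clamped < 0 || n_clamped > n_particles - 1)
    stop("n_clamped must leave at least one free particle")
  structure(list(
    n = as.integer(n_particles), l0 = l0,
    k_s = ks, k_bend = kb, k_t = kt,
    n_clamped = as.integer(n_clamped), diameter = diameter, twist0 = twist0,
    # joint at a built-in end: the clamp fixes the tangent, so curvature
    # there is carried over half a segment and the joint stiffness doubles
    root_joint = if (n_clamped >= 2) as.integer(n_clamped - 1) else -1L
  ), class = "fiber_chain")
}

check_positions <- function(chain, positions) {
  positions <- as.matrix(positions)
  if (nrow(positions) != chain$n || ncol(positions) != 3)
    stop("positions must be an n x 3 matrix matching the chain")
  if (!all(is.finite(positions))) stop("chain positions must be finite")
  positions
}

#' Worm-like-chain elastic energies
#'
#' @param chain A `fiber_chain`.
#' @param positions n x 3 matrix of particle positions (m).
#' @return List with `stretch`, `bend` and `total` energies (J). Torsion
#'   energy depends on the twist state and is computed by
#'   [torsion_energy()].
#' @export
wlc_energy <- function(chain, positions) {
  stopifnot(inherits(chain, "fiber_chain"))
  positions <- check_positions(chain, positions)
  wlc_energy_cpp(positions, chain$k_s, chain$k_bend, chain$l0,
                 chain$root_joint)
}

#' Worm-like-chain forces (stretching + bending)
#'
#' Analytic gradient \eqn{-\partial H / \partial x} of the stretching and
#' bending energies, including the gradient through the unit-vector
#' normalisation of the bond tangents. Each bond contributes equal and
#' opposite forces on its two particles; internal forces over a chain sum to
#' zero.
#'
#' @inheritParams wlc_energy
#' @return n x 3 matrix of forces (N).
#' @export
wlc_forces <- function(chain, positions) {
  stopifnot(inherits(chain, "fiber_chain"))
  positions <- check_positions(chain, positions)
  wlc_forces_cpp(positions, chain$k_s, chain$k_bend, chain$l0,
                 chain$root_joint)
}

#' Torsional energy of a twist state
#'
#' @param chain A `fiber_chain`.
#' @param twist Numeric vector of per-bond twist angles gamma_i (rad),
#'   length n - 1.
#' @return Energy \eqn{H_T = \tfrac12 k_T \sum (\gamma_i - \gamma_0)^2} (J).
#' @export
torsion_energy <- function(chain, twist) {
  stopifnot(inherits(chain, "fiber_chain"))
  twist <- as.numeric(twist)
  if (length(twist) != chain$n - 1L) stop("twist must have one entry per bond")
  0.5 * chain$k_t * sum((twist - chain$twist0)^2)
}

#' Restoring torsional torques
#'
#' The torque about each bond axis is \eqn{-k_T(\gamma_i - \gamma_0)};
#' magnitude \eqn{k_T \phi} for a twist offset \eqn{\phi}.
#'
#' @inheritParams torsion_energy
#' @return Numeric vector of signed torques (N m) per bond.
#' @export
torsion_torques <- function(chain, twist) {
  stopifnot(inherits(chain, "fiber_chain"))
  twist <- as.numeric(twist)
  if (length(twist) != chain$n - 1L) stop("twist must have one entry per bond")
  -chain$k_t * (twist - chain$twist0)
}

#' @export
print.fiber_chain <- function(x, ...) {
  cat(sprintf("<fiber_chain> %d particles (%d clamped), l0 = %.4g mm\n",
              x$n, x$n_clamped, x$l0 * 1e3))
  cat(sprintf("  k_s = %.4g N/m, k_bend = %.4g N m, k_t = %.4g N m/rad\n",
              x$k_s, x$k_bend, x$k_t))
  invisible(x)
}
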