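# Pairwise Hertz-Mindlin force evaluation and contact detection. The same
# C++ kernels back the time-stepping engine; these wrappers add validation
# and are the unit-testable module surface.

#' Hertz-Mindlin normal contact force
#'
#' \deqn{F_n = \frac{4}{3} E^* \sqrt{R^*}\, \delta_n^{3/2}
#'       - 2\sqrt{5/6}\, |\beta| \sqrt{S_n m^*}\, v_n^{rel}}
#' with normal contact stiffness \eqn{S_n = 2 E^* \sqrt{R^* \delta_n}}. The
#' relative normal velocity is positive when the bodies separate, so the
#' damping term always opposes relative normal motion. The total force is
#' clamped at zero: contacts are non-cohesive and never attract.
#'
#' @param pair A `contact_pair` from [effective_pair_properties()].
#' @param delta_n Normal overlap (m), must be >= 0.
#' @param v_n Relative normal velocity (m/s), positive when separating.
#' @return Signed force magnitude along the contact normal (N, >= 0).
#' @export
hm_normal_force <- function(pair, delta_n, v_n = 0) {
  stopifnot(inherits(pair, "contact_pair"))
  if (!is.numeric(delta_n) || delta_n < 0) stop("delta_n must be >= 0")
  hm_normal_cpp(pair$e_star, pair$r_star, pair$m_star, pair$beta, delta_n, v_n)
}

#' Hertz-Mindlin tangential contact force with Coulomb cap
#'
#' \deqn{F_t = -8 G^* \sqrt{R^* \delta_n}\, \delta_t
#'       - 2\sqrt{5/6}\, |\beta| \sqrt{S_t m^*}\, v_t^{rel}}
#' with \eqn{S_t = 8 G^* \sqrt{R^* \delta_n}}. The magnitude is capped at the
#' Coulomb limit \eqn{\mu |F_n|}; on capping the accumulated slip vector is
#' rescaled so the tangential spring alone carries the capped force
#' (tangential-spring truncation).
#'
#' @param pair A `contact_pair`.
#' @param delta_n Normal overlap (m), must be > 0 (an active contact).
#' @param delta_t Accumulated tangential slip vector (m), length 3.
#' @param v_t Relative tangential velocity vector (m/s), length 3.
#' @param f_n Normal force used for the Coulomb cap; defaults to the elastic
#'   normal force at `delta_n`.
#' @return List with `force` (N, length 3) and the possibly rescaled
#'   `delta_t`.
#' @export
hm_tangential_force <- function(pair, delta_n, delta_t, v_t = c(0, 0, 0),
                                f_n = NULL) {
  stopifnot(inherits(pair, "contact_pair"))
  if (!is.numeric(delta_n) || delta_n <= 0)
    stop("tangential force requires an active contact (delta_n > 0)")
  delta_t <- as.numeric(delta_t); v_t <- as.numeric(v_t)
  stopifnot(length(delta_t) == 3, length(v_t) == 3)
  if (is.null(f_n)) f_n <- hm_normal_force(pair, delta_n, 0)
  hm_tangential_cpp(pair$g_star, pair$r_star, pair$m_star, pair$beta,
                    pair$mu, delta_n, delta_t, v_t, f_n)
}

#' Define a bounded planar facet
#'
#' A one-sided rectangle given by an origin corner and two in-plane edge
#' vectors; the outward normal is `u x v` (normalised).
#'
#' @param origin Corner point (m), length 3.
#' @param u,v Edge vectors spanning the rectangle (m), length 3 each.
#' @param wear Does this facet accumulate wear? (Auxiliary support plates are
#'   excluded from wear measurement.)
#' @param groove Is this facet part of the interproximal groove?
#' @param name Optional label.
#' @return An object of class `dem_facet`.
#' @export
planar_facet <- function(origin, u, v, wear = TRUE, groove = FALSE,
                         name = "facet") {
  origin <- as.numeric(origin); u <- as.numeric(u); v <- as.numeric(v)
  stopifnot(length(origin) == 3, length(u) == 3, length(v) == 3)
  nrm <- c(u[2] * v[3] - u[3] * v[2],
           u[3] * v[1] - u[1] * v[3],
           u[1] * v[2] - u[2] * v[1])
  area <- sqrt(sum(nrm^2))
  if (area <= 1e-18) stop("degenerate facet: zero area")
  structure(list(origin = origin, u = u, v = v, normal = nrm / area,
                 area = area, wear = isTRUE(wear), groove = isTRUE(groove),
                 name = name),
            class = "dem_facet")
}

#' Sphere vs bounded-facet contact detection
#'
#' A contact is active when the distance from the sphere centre to the
#' closest point of the facet is less than the radius. For centres whose
#' in-plane projection falls inside the rectangle the signed plane distance
#' is used (so a centre that has crossed the plane is still expelled through
#' the front face) and the contact normal is the facet's outward normal; for
#' edge and corner contacts the normal points from the closest boundary point
#' to the centre.
#'
#' @param center Sphere centre (m), length 3.
#' @param radius Sphere radius (m), > 0.
#' @param facet A `dem_facet`.
#' @return `NULL` when there is no contact, otherwise a list with `point`,
#'   `normal`, `delta_n`, `interior` and in-plane `coords` of the contact
#'   point.
#' @export
detect_sphere_plane <- function(center, radius, facet) {
  stopifnot(inherits(facet, "dem_facet"))
  center <- as.numeric(center)
  stopifnot(length(center) == 3)
  if (!is.numeric(radius) || radius <= 0) stop("radius must be > 0")
  res <- sphere_facet_cpp(center, radius, facet$origin, facet$u, facet$v)
  if (!isTRUE(res$active)) return(NULL)
  res$active <- NULL
  res
}

#' Sphere vs sphere contact detection
#'
#' Centre-distance overlap test. Particles adjacent in the same chain are
#' never in contact: their interaction is the worm-like-chain bond.
#' Coincident centres are rejected (the contact normal is undefined).
#'
#' @param a,b Particle states: lists with `center` (length-3), `radius`, and
#'   optionally `chain` and `index` for the bonded-neighbour exclusion.
#' @return `NULL` when there is no contact (or the pair is a bonded
#'   neighbour), otherwise a list with `point`, `normal` (pointing from b to
#'   a) and `delta_n`.
#' @export
detect_sphere_sphere <- function(a, b) {
  ca <- as.numeric(a$center); cb <- as.numeric(b$center)
  stopifnot(length(ca) == 3, length(cb) == 3)
  if (!is.null(a$chain) && !is.null(b$chain) && !is.na(a$chain) &&
      identical(a$chain, b$chain) &&
      !is.null(a$index) && !is.null(b$index) &&
      identical(a$index, b$index))
    stop("detect_sphere_sphere() requires two distinct particles")
  if (!is.null(a$chain) && !is.null(b$chain) && !is.na(a$chain) &&
      identical(a$chain, b$chain) &&
      !is.null(a$index) && !is.null(b$index) &&
      abs(a$index - b$index) == 1L)
    return(NULL)
  res <- sphere_sphere_cpp(ca, a$radius, cb, b$radius)
  if (!isTRUE(res$active)) return(NULL)
  res$active <- NULL
  res
}
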