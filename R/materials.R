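#' Define a contact material
#'
#' Bundles the continuum constants of one material as used by the contact and
#' wear models: Young's modulus, Poisson ratio, density, indentation hardness,
#' a coefficient of restitution for the contact damping, and friction
#' coefficients against partner materials. The shear modulus is derived as
#' \eqn{G = E / (2(1+\nu))}.
#'
#' @param name Material label, used to resolve pairwise friction.
#' @param elastic_modulus Young's modulus (Pa).
#' @param poisson_ratio Poisson ratio, in (0, 0.5).
#' @param density Mass density (kg/m^3).
#' @param hardness Indentation hardness (Pa), used by the Archard wear law.
#' @param restitution Coefficient of restitution e in (0, 1]. The contact
#'   damping ratio follows \eqn{\beta = \ln e / \sqrt{\ln^2 e + \pi^2}}.
#' @param friction Friction coefficient: either a single number used against
#'   all partners, or a named numeric vector keyed by partner material name.
#' @return An object of class `dem_material`.
#' @examples
#' mat <- dem_material("acrylic", 3.4e9, 0.3, 1185, 0.22e9)
#' mat$shear_modulus   # E / 2.6
#' @export
dem_material <- function(name, elastic_modulus, poisson_ratio, density,
                         hardness, restitution = 0.3, friction = 0.18) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(elastic_modulus) || elastic_modulus <= 0)
    stop("elastic_modulus must be > 0")
  if (!is.numeric(poisson_ratio) || poisson_ratio <= 0 || poisson_ratio >= 0.5)
    stop("poisson_ratio must lie in (0, 0.5)")
  if (!is.numeric(density) || density <= 0) stop("density must be > 0")
  if (!is.numeric(hardness) || hardness <= 0) stop("hardness must be > 0")
  if (!is.numeric(restitution) || restitution <= 0 || restitution > 1)
    stop("restitution must lie in (0, 1]")
  if (!is.numeric(friction) || any(friction < 0))
    stop("friction coefficients must be >= 0")
  structure(list(
    name = name,
    elastic_modulus = elastic_modulus,
    poisson_ratio = poisson_ratio,
    density = density,
    hardness = hardness,
    shear_modulus = elastic_modulus / (2 * (1 + poisson_ratio)),
    restitution = restitution,
    friction = friction
  ), class = "dem_material")
}

#' Built-in material presets
#'
#' Bulk acrylic (the tuft-beam material) and tooth enamel, with a flat
#' friction coefficient of 0.18 for all pairings. The coefficient of
#' restitution is not a tabulated property of either material; the default
#' e = 0.3 is a configuration choice (see the methods vignette for its
#' sensitivity).
#'
#' @param restitution Coefficient of restitution applied to both presets.
#' @return Named list with elements `acrylic` and `enamel`.
#' @export
material_presets <- function(restitution = 0.3) {
  list(
    acrylic = dem_material("acrylic", 3.4e9, 0.3, 1185, 0.22e9,
                           restitution = restitution, friction = 0.18),
    enamel = dem_material("enamel", 60.0e9, 0.3, 3000, 0.92e9,
                          restitution = restitution, friction = 0.18)
  )
}

#' @export
print.dem_material <- function(x, ...) {
  cat(sprintf("<dem_material> %s\n", x$name))
  cat(sprintf("  E = %.3g Pa, nu = %.2f, rho = %.4g kg/m^3, H = %.3g Pa\n",
              x$elastic_modulus, x$poisson_ratio, x$density, x$hardness))
  cat(sprintf("  G = %.3g Pa, e = %.2f, mu = %s\n", x$shear_modulus,
              x$restitution, paste(format(x$friction), collapse = ", ")))
  invisible(x)
}

resolve_friction <- function(mat_a, mat_b) {
  fa <- mat_a$friction
  if (!is.null(names(fa)) && mat_b$name %in% names(fa)) return(unname(fa[[mat_b$name]]))
  unname(fa[[1]])
}

#' Equivalent (effective) contact-pair properties
#'
#' Combines two materials and two body geometries into the equivalent
#' quantities used by the Hertz-Mindlin force law:
#' \deqn{1/E^* = (1-\nu_a^2)/E_a + (1-\nu_b^2)/E_b}
#' \deqn{1/G^* = (2-\nu_a)/G_a + (2-\nu_b)/G_b}
#' \deqn{1/R^* = 1/R_a + 1/R_b, \quad 1/m^* = 1/m_a + 1/m_b}
#' A plane (or any immobile body) contributes `radius_b = Inf` and
#' `mass_b = Inf`, so that \eqn{R^* = R_a} and \eqn{m^* = m_a}.
#'
#' The damping ratio \eqn{\beta = \ln e / \sqrt{\ln^2 e + \pi^2}} is stored
#' signed (\eqn{\beta \le 0} for e < 1, \eqn{\beta = 0} at e = 1); force
#' routines apply its magnitude so damping always opposes relative motion.
#'
#' @param mat_a,mat_b `dem_material` objects.
#' @param radius_a Radius of body a (m), > 0.
#' @param radius_b Radius of body b (m); `Inf` for a plane.
#' @param mass_a Mass of body a (kg), > 0.
#' @param mass_b Mass of body b (kg); `Inf` for a plane or clamped body.
#' @param restitution Optional pair restitution override; by default the
#'   geometric mean of the two materials' coefficients.
#' @return An object of class `contact_pair` with fields `e_star`, `g_star`,
#'   `r_star`, `m_star`, `beta`, `mu`, `restitution`.
#' @export
effective_pair_properties <- function(mat_a, mat_b, radius_a, radius_b = Inf,
                                      mass_a, mass_b = Inf, restitution = NULL) {
  stopifnot(inherits(mat_a, "dem_material"), inherits(mat_b, "dem_material"))
  if (!is.numeric(radius_a) || radius_a <= 0) stop("radius_a must be > 0")
  if (!is.numeric(radius_b) || radius_b <= 0) stop("radius_b must be > 0 (Inf for a plane)")
  if (!is.numeric(mass_a) || mass_a <= 0) stop("mass_a must be > 0")
  if (!is.numeric(mass_b) || mass_b <= 0) stop("mass_b must be > 0 (Inf for a plane)")
  e_star <- 1 / ((1 - mat_a$poisson_ratio^2) / mat_a$elastic_modulus +
                 (1 - mat_b$poisson_ratio^2) / mat_b$elastic_modulus)
  g_star <- 1 / ((2 - mat_a$poisson_ratio) / mat_a$shear_modulus +
                 (2 - mat_b$poisson_ratio) / mat_b$shear_modulus)
  r_star <- 1 / (1 / radius_a + 1 / radius_b)
  m_star <- 1 / (1 / mass_a + 1 / mass_b)
  e <- if (is.null(restitution)) sqrt(mat_a$restitution * mat_b$restitution) else restitution
  if (e <= 0 || e > 1) stop("restitution must lie in (0, 1]")
  beta <- if (e == 1) 0 else log(e) / sqrt(log(e)^2 + pi^2)
  structure(list(
    e_star = e_star, g_star = g_star, r_star = r_star, m_star = m_star,
    beta = beta, restitution = e, mu = resolve_friction(mat_a, mat_b),
    materials = c(mat_a$name, mat_b$name)
  ), class = "contact_pair")
}

#' @export
print.contact_pair <- function(x, ...) {
  cat(sprintf("<contact_pair> %s vs %s\n", x$materials[1], x$materials[2]))
  cat(sprintf("  E* = %.4g Pa, G* = %.4g Pa, R* = %.4g m, m* = %.4g kg\n",
              x$e_star, x$g_star, x$r_star, x$m_star))
  cat(sprintf("  e = %.2f (beta = %.4f), mu = %.2f\n", x$restitution, x$beta, x$mu))
  invisible(x)
}
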