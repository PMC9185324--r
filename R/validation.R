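# Cantilever validation bench: the quasi-static tip-loaded deflection of one
# tuft chain against the inextensible large-deflection elastica.
#
# Elastica: with arc length s, section rotation theta(s), flexural rigidity
# EI and a dead tip load P perpendicular to the undeformed axis,
#   EI theta''(s) = -P cos(theta),  theta(0) = 0,  theta'(L) = 0,
# solved by shooting on theta'(0); the tip deflection is w(L) = int sin(theta) ds.

#' Define a cantilever validation case
#'
#' One tuft-beam discretised exactly as in the brushing assembly: `n`
#' particles with the first `n_clamped` clamped, acrylic properties, beam
#' diameter 1.8 mm and total length 10.8 mm. The free length is the
#' anchor-to-tip distance of the unclamped segment,
#' `(n - n_clamped) * l0`.
#'
#' @param load Tip load F (N), >= 0; applied as a constant-direction (dead)
#'   force at the tip particle.
#' @param material Beam material (`dem_material`); acrylic by default.
#' @param diameter Beam diameter (m).
#' @param length Total beam length (m).
#' @param n_particles Particles in the chain.
#' @param n_clamped Clamped leading particles.
#' @return Object of class `cantilever_case`.
#' @export
cantilever_case <- function(load, material = material_presets()$acrylic,
                            diameter = 1.8e-3, length = 10.8e-3,
                            n_particles = 8, n_clamped = 2) {
  if (!is.numeric(load) || load < 0) stop("load must be >= 0")
  sec <- beam_section(diameter)
  l0 <- length / (n_particles - 1)
  structure(list(
    load = load, material = material, section = sec,
    diameter = diameter, length = length,
    n_particles = n_particles, n_clamped = n_clamped,
    l0 = l0, free_length = (n_particles - n_clamped) * l0,
    EI = material$elastic_modulus * sec$I
  ), class = "cantilever_case")
}

#' Elastica tip deflection (nonlinear reference)
#'
#' Large-deflection tip displacement of an inextensible cantilever under a
#' dead tip load, from the elastica boundary-value problem solved by
#' shooting on the root curvature with a high-accuracy ODE integration.
#'
#' @param case A `cantilever_case`.
#' @param rtol Relative tolerance of the shooting solve.
#' @return Tip transverse deflection (m).
#' @export
elastica_deflection <- function(case, rtol = 1e-8) {
  stopifnot(inherits(case, "cantilever_case"))
  F <- case$load
  if (F == 0) return(0)
  L <- case$free_length
  EI <- case$EI
  rhs <- function(s, y, parms) {
    list(c(y[2], -(F / EI) * cos(y[1]), sin(y[1])))
  }
  shoot <- function(c0) {
    out <- deSolve::ode(y = c(theta = 0, thetap = c0, w = 0),
                        times = c(0, L), func = rhs, parms = NULL,
                        method = "lsoda", rtol = 1e-11, atol = 1e-13)
    out[nrow(out), ]
  }
  g <- function(c0) shoot(c0)[["thetap"]]
  hi <- 1.5 * F * L / EI + 1e-9
  root <- uniroot(g, lower = 0, upper = hi, tol = rtol * hi,
                  extendInt = "upX")
  fin <- shoot(root$root)
  if (abs(fin[["thetap"]]) > 1e-4 * root$root + 1e-12)
    stop(sprintf("elastica shooting did not converge (residual %.3g)",
                 fin[["thetap"]]))
  unname(fin[["w"]])
}

# Build the single-chain cantilever system along +x with a dead tip load in
# +y, and relax it to equilibrium.
cantilever_system <- function(case, load = case$load) {
  mat <- case$material
  sec <- case$section
  stiff <- calibrate_stiffness(mat, sec, case$l0)
  chain <- fiber_chain(case$n_particles, case$l0, stiff,
                       n_clamped = case$n_clamped,
                       diameter = case$diameter)
  n <- case$n_particles
  mass <- mat$density * sec$A * case$l0
  pos <- cbind((seq_len(n) - 1) * case$l0, 0, 0)
  fext <- matrix(0, n, 3)
  fext[n, 2] <- load
  pp <- effective_pair_properties(mat, mat,
                                  radius_a = case$diameter / 2,
                                  radius_b = case$diameter / 2,
                                  mass_a = mass, mass_b = mass)
  dem_system(pos, radius = case$diameter / 2, mass = mass,
             clamped = seq_len(n) <= case$n_clamped,
             chain_of = rep(1L, n), chains = list(chain),
             pair_particle = pp, fext = fext)
}

#' Quasi-static DEM cantilever deflection
#'
#' Builds the particle chain, applies the tip load, relaxes to static
#' equilibrium with strong viscous damping, and returns the tip displacement
#' along the load direction.
#'
#' @param case A `cantilever_case`.
#' @param safety Time-step safety factor against the stretching-stiffness
#'   critical step.
#' @param ... Passed to [relax_static()].
#' @return Tip deflection (m).
#' @export
dem_cantilever_deflection <- function(case, safety = 0.1, ...) {
  stopifnot(inherits(case, "cantilever_case"))
  if (case$load == 0) return(0)
  sys <- cantilever_system(case)
  mass <- sys$mass[1]
  dt <- safety * 2 * sqrt(mass / sys$ks[1])
  tol_f <- max(1e-8, 1e-6 * case$load)
  out <- relax_static(sys, dt = dt, tol_v = 1e-6, tol_f = tol_f, ...)
  out$pos[case$n_particles, 2] - sys$pos[case$n_particles, 2]
}

#' Cantilever deflection error curve
#'
#' Sweeps tip loads, computing the DEM and elastica deflections and the
#' percent error \eqn{100 |\delta_{DEM} - \delta_{th}| / \delta_{th}} per
#' load (zero loads are kept in the table but excluded from the error).
#'
#' @param loads Numeric vector of tip loads (N), >= 0.
#' @param ... Passed to [cantilever_case()].
#' @return Object of class `cantilever_bench`: a data frame with columns
#'   `load`, `delta_dem`, `delta_theory`, `pct_error`.
#' @export
deflection_error_curve <- function(loads, ...) {
  if (any(loads < 0)) stop("loads must be >= 0")
  rows <- lapply(loads, function(F) {
    case <- cantilever_case(F, ...)
    dd <- dem_cantilever_deflection(case)
    dth <- elastica_deflection(case)
    data.frame(load = F, delta_dem = dd, delta_theory = dth,
               pct_error = if (F > 0) 100 * abs(dd - dth) / dth else NA_real_)
  })
  structure(do.call(rbind, rows), class = c("cantilever_bench", "data.frame"))
}

#' Run the cantilever validation bench
#'
#' Full 0-30 N sweep with pass/fail gates on the error at the maximum load:
#' target 3.3%, hard gate 5%.
#'
#' @param loads Load sweep (N); defaults to 0 to 30 N.
#' @param target,hard Error gates (%) evaluated at the maximum load.
#' @param ... Passed to [cantilever_case()].
#' @return List of class `validation_report`: the `bench` table, error at
#'   the maximum load, and gate outcomes.
#' @export
run_validation <- function(loads = c(0, seq(2.5, 30, by = 2.5)),
                           target = 3.3, hard = 5, ...) {
  bench <- deflection_error_curve(loads, ...)
  at_max <- bench$pct_error[which.max(bench$load)]
  structure(list(
    bench = bench, max_load = max(bench$load), error_at_max = at_max,
    target = target, hard = hard,
    pass_target = at_max <= target, pass_hard = at_max <= hard
  ), class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat("<validation_report> WLC cantilever vs elastica\n")
  cat(sprintf("  error at %.3g N: %.3g%% (target <= %.2g%%: %s; hard gate <= %.2g%%: %s)\n",
              x$max_load, x$error_at_max,
              x$target, if (x$pass_target) "pass" else "FAIL",
              x$hard, if (x$pass_hard) "pass" else "FAIL"))
  print(utils::head(x$bench, 13))
  invisible(x)
}

#' @export
plot.cantilever_bench <- function(x, ...) {
  op <- par(mfrow = c(1, 2))
  on.exit(par(op))
  plot(x$load, x$delta_theory * 1e3, type = "l", xlab = "tip load (N)",
       ylab = "tip deflection (mm)", ...)
  points(x$load, x$delta_dem * 1e3, pch = 1)
  legend("topleft", c("elastica", "DEM chain"), lty = c(1, NA),
         pch = c(NA, 1), bty = "n")
  plot(x$load, x$pct_error, type = "b", xlab = "tip load (N)",
       ylab = "percent error (%)")
  invisible(x)
}
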