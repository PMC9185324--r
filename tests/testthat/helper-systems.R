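# Shared fixtures: materials, small particle systems and chains built in
# code at test time.

mats <- material_presets()
r_std <- 0.9e-3          # standard bristle-particle radius (m)
m_std <- 4.65e-6         # approximate tuft-segment particle mass (kg)

pair_aa <- function(e = 0.3, mu = 0.18) {
  p <- effective_pair_properties(mats$acrylic, mats$acrylic,
                                 radius_a = r_std, radius_b = r_std,
                                 mass_a = m_std, mass_b = m_std,
                                 restitution = e)
  p$mu <- mu
  p
}

pair_ae <- function(e = 0.3, mu = 0.18) {
  p <- effective_pair_properties(mats$acrylic, mats$enamel,
                                 radius_a = r_std, mass_a = m_std,
                                 restitution = e)
  p$mu <- mu
  p
}

# a wide horizontal facet at z = 0 (outward normal +z)
big_facet <- function(half = 0.05, wear = TRUE) {
  planar_facet(c(-half, -half, 0), c(2 * half, 0, 0), c(0, 2 * half, 0),
               wear = wear)
}

# head-on binary collision of two equal spheres; returns final engine state
binary_collision <- function(e, mu = 0, v0 = 0.5, dt_div = 50) {
  pp <- pair_aa(e = e, mu = mu)
  gap <- 0.2 * r_std
  pos <- rbind(c(-(r_std + gap / 2), 0, 0), c(r_std + gap / 2, 0, 0))
  vel <- rbind(c(v0, 0, 0), c(-v0, 0, 0))
  sn <- 2 * pp$e_star * sqrt(pp$r_star * 0.1 * r_std)
  dt <- 2 * sqrt(m_std / sn) / dt_div
  sys <- dem_system(pos, radius = r_std, mass = m_std, vel = vel,
                    pair_particle = pp)
  n_steps <- ceiling(2.5 * (gap / v0) / dt)
  simulate_dynamics(sys, dt = dt, n_steps = n_steps, stride = 1e6,
                    record = FALSE)
}

# standard 8-particle tuft chain (2 clamped) used across fiber tests
std_chain <- function(n = 8, n_clamped = 2) {
  l0 <- 10.8e-3 / (n - 1)
  stiff <- calibrate_stiffness(mats$acrylic, beam_section(), l0)
  fiber_chain(n, l0, stiff, n_clamped = n_clamped)
}

straight_chain_pos <- function(chain, axis = c(1, 0, 0)) {
  outer((seq_len(chain$n) - 1) * chain$l0, axis)
}

# randomly bent chain positions around the straight configuration
bent_chain_pos <- function(chain, scale = 0.15, seed = 42) {
  set.seed(seed)
  p <- straight_chain_pos(chain)
  p + matrix(rnorm(3 * chain$n, sd = scale * chain$l0), chain$n, 3)
}

# central-difference gradient of the WLC energy
numeric_wlc_grad <- function(chain, pos, h = 1e-9) {
  g <- matrix(0, nrow(pos), 3)
  for (i in seq_len(nrow(pos))) {
    for (k in 1:3) {
      pp <- pos; pp[i, k] <- pp[i, k] + h
      pm <- pos; pm[i, k] <- pm[i, k] - h
      g[i, k] <- (wlc_energy(chain, pp)$total - wlc_energy(chain, pm)$total) /
        (2 * h)
    }
  }
  g
}

# a cheap brushing configuration (2 tufts, quarter stroke) for smoke and
# determinism tests
tiny_config <- function(...) {
  brushing_config(tuft_rows = 1, tuft_cols = 2, head_length = 5.5e-3,
                  head_width = 10.2e-3, depth = 0.45e-3,
                  stroke_scale = 0.25, ...)
}
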