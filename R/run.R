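# Orchestration: full scrub-cycle brushing runs, the speed x depth sweep,
# and the result containers.

# small rolling checksum over a serialized object, for run manifests
fnv_hash <- function(x) {
  raw <- serialize(x, NULL, version = 2)
  h <- 0
  for (b in as.integer(raw)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run one full brushing cycle
#'
#' Executes the complete simulation for one configuration: the head is
#' pressed in to the brushing depth, held briefly, then translated through
#' one forward and one backward stroke at constant speed. Tip contact
#' forces are logged at every recording stride, wear accumulates
#' continuously during the stroke, and per-tip force snapshots are taken
#' when the head centre crosses the interproximal groove (stroke fractions
#' 1/5 and 4/5).
#'
#' @param config A `brushing_config`.
#' @param record_stride Steps between force-log rows; `NULL` picks a stride
#'   giving roughly 4000 rows.
#' @param verbose Print progress.
#' @return Object of class `brush_run`: the force log, wear map, summary,
#'   snapshots, and a run manifest.
#' @export
run_brushing <- function(config, record_stride = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "brushing_config"))
  asm <- assemble_brushing_system(config)
  dt <- critical_timestep(asm$brush, asm$pair_facet, config$depth,
                          safety = config$dt_safety)
  t_down <- config$depth / config$press_speed
  t0 <- t_down + config$hold_time
  stroke_t <- config$stroke / config$speed
  t_total <- t0 + stroke_t
  n_steps <- ceiling(t_total / dt)
  if (is.null(record_stride))
    record_stride <- max(1L, as.integer(n_steps / 4000))
  snap_times <- t0 + c(0.2, 0.8) * stroke_t
  motion <- list(type = 1L, V = config$speed, L = config$stroke,
                 d_z = config$depth, t_down = t_down, t_hold = config$hold_time)
  if (verbose)
    message(sprintf("brushing run: V = %.3g m/s, d_z = %.3g mm, %d steps (dt = %.3g s)",
                    config$speed, config$depth * 1e3, n_steps, as.numeric(dt)))
  t_wall <- system.time(
    out <- simulate_dynamics(asm$sys, dt = as.numeric(dt), n_steps = n_steps,
                             stride = record_stride, motion = motion,
                             snap_times = snap_times)
  )

  params <- wear_params(K = config$archard_k,
                        H = config$materials$enamel$hardness)
  map <- make_wear_map(out$wear, asm$teeth$facets, config$wear_cell, params,
                       raw = out$wear_raw, dropped = out$wear_dropped,
                       n_dropped = out$n_dropped)

  nrec <- as.integer(out$rec$n)
  keep <- seq_len(nrec)
  tm <- out$rec$time[keep]
  frac <- ifelse(tm >= t0, (tm - t0) * config$speed / config$stroke, NA)
  nC <- asm$brush$n_chains
  forces <- data.frame(
    time = rep(tm, nC),
    chain = rep(seq_len(nC), each = nrec),
    force = as.vector(out$rec$force[keep, , drop = FALSE]),
    f_normal = as.vector(out$rec$fnorm[keep, , drop = FALSE]),
    f_tangential = as.vector(out$rec$ftan[keep, , drop = FALSE]),
    tip_x = as.vector(out$rec$tipx[keep, , drop = FALSE]),
    tip_y = as.vector(out$rec$tipy[keep, , drop = FALSE]),
    in_groove = as.vector(out$rec$groove[keep, , drop = FALSE]) > 0,
    n_contacts = as.vector(out$rec$ncontact[keep, , drop = FALSE]),
    stroke_fraction = rep(frac, nC)
  )
  # tag rows at the interproximal crossings (stroke fractions 1/5 and 4/5)
  forces$crossing <- !is.na(forces$stroke_fraction) &
    (abs(forces$stroke_fraction - 0.2) < 0.01 |
     abs(forces$stroke_fraction - 0.8) < 0.01)

  snaps <- list(
    time = out$snaps$time, fraction = c(0.2, 0.8),
    force = out$snaps$force, f_normal = out$snaps$fnorm,
    f_tangential = out$snaps$ftan,
    contact = out$snaps$contact > 0
  )
  snap_forces <- as.vector(snaps$force)[as.vector(snaps$contact)]
  summary <- list(
    wear = summarize_wear(map),
    groove_max_force = out$groove_max,
    groove_max_time = out$groove_max_t,
    max_force = out$all_max,
    mean_snap_force = if (length(snap_forces)) mean(snap_forces) else NA_real_,
    n_snap_contacts = sum(snaps$contact),
    kinetic_energy_final = out$rec$ke[nrec]
  )

  cfg_manifest <- unclass(config)
  cfg_manifest$materials <- lapply(cfg_manifest$materials, unclass)
  manifest <- list(
    config = cfg_manifest,
    dt = as.numeric(dt), n_steps = n_steps, record_stride = record_stride,
    t_press = t_down, t_hold = config$hold_time, t_stroke = stroke_t,
    package_version = as.character(utils::packageVersion("brushwear"))
  )
  manifest$hash <- fnv_hash(manifest)

  structure(list(
    config = config, forces = forces, wear = map, snaps = snaps,
    summary = summary, manifest = manifest,
    diagnostics = list(ke = out$rec$ke[keep], time = tm,
                       wall_time = unname(t_wall["elapsed"]),
                       steps = out$steps)
  ), class = "brush_run")
}

#' @export
print.brush_run <- function(x, ...) {
  cat("<brush_run>\n")
  cat(sprintf("  V = %.3g m/s, d_z = %.3g mm, L = %.3g mm (%.0f steps, %.1f s wall)\n",
              x$config$speed, x$config$depth * 1e3, x$config$stroke * 1e3,
              x$diagnostics$steps, x$diagnostics$wall_time))
  cat(sprintf("  total wear: %.4g m^3 (per unit K); groove share %.1f%%\n",
              x$summary$wear$total, 100 * x$summary$wear$groove_fraction))
  cat(sprintf("  max tip force in groove: %.4g N; mean tip force at crossings: %.4g N\n",
              x$summary$groove_max_force, x$summary$mean_snap_force))
  invisible(x)
}

#' @export
summary.brush_run <- function(object, ...) {
  s <- object$summary
  out <- data.frame(
    speed = object$config$speed, depth = object$config$depth,
    total_wear = s$wear$total, groove_fraction = s$wear$groove_fraction,
    groove_density = s$wear$groove_density, plate_density = s$wear$plate_density,
    symmetry = s$wear$symmetry,
    groove_max_force = s$groove_max_force, max_force = s$max_force,
    mean_snap_force = s$mean_snap_force
  )
  class(out) <- c("brush_run_summary", "data.frame")
  out
}

#' @export
plot.brush_run <- function(x, which = c("wear", "forces"), ...) {
  which <- match.arg(which)
  if (which == "wear") return(plot(x$wear, ...))
  f <- x$forces
  agg_max <- tapply(f$force, f$time, max)
  tms <- as.numeric(names(agg_max))
  plot(tms, agg_max, type = "l", xlab = "time (s)",
       ylab = "max per-tip contact force (N)", ...)
  abline(v = x$snaps$time, lty = 3)
  invisible(x)
}

#' Run a speed x depth sweep
#'
#' The standard comparison slices: brushing depth varied at fixed speed
#' V = 0.1 m/s (d_z = r/4, r/2, r) and brushing speed varied at fixed depth
#' d_z = r (V = 0.05, 0.10, 0.15 m/s), each condition a full brushing run.
#' Set `full_grid = TRUE` for all 9 combinations.
#'
#' @param config Base `brushing_config`; each condition overrides `speed`
#'   and `depth`.
#' @param speeds,depths Condition values.
#' @param full_grid Run the full cartesian grid instead of the two slices.
#' @param verbose Print per-run progress.
#' @return Object of class `brush_sweep`: the per-condition runs and a
#'   comparison table of total wear.
#' @export
run_sweep <- function(config = brushing_config(),
                      speeds = c(0.05, 0.10, 0.15),
                      depths = config$particle_diameter / 2 * c(1 / 4, 1 / 2, 1),
                      full_grid = FALSE, verbose = FALSE) {
  stopifnot(inherits(config, "brushing_config"))
  conds <- if (full_grid) {
    expand.grid(speed = speeds, depth = depths)
  } else {
    unique(rbind(
      data.frame(speed = 0.10, depth = depths),
      data.frame(speed = speeds, depth = max(depths))
    ))
  }
  runs <- vector("list", nrow(conds))
  rows <- vector("list", nrow(conds))
  for (i in seq_len(nrow(conds))) {
    cfg <- config
    cfg$speed <- conds$speed[i]
    cfg$depth <- conds$depth[i]
    res <- tryCatch(run_brushing(cfg, verbose = verbose),
                    error = function(e) e)
    if (inherits(res, "error")) {
      warning(sprintf("condition (V = %.3g, d_z = %.3g) failed: %s",
                      conds$speed[i], conds$depth[i], conditionMessage(res)))
      rows[[i]] <- data.frame(speed = conds$speed[i], depth = conds$depth[i],
                              total_wear = NA, groove_fraction = NA,
                              groove_density = NA, plate_density = NA,
                              symmetry = NA, groove_max_force = NA,
                              max_force = NA, mean_snap_force = NA)
    } else {
      runs[[i]] <- res
      rows[[i]] <- summary(res)
    }
  }
  table <- do.call(rbind, rows)
  structure(list(runs = runs, table = table, config = config),
            class = "brush_sweep")
}

#' @export
print.brush_sweep <- function(x, ...) {
  cat("<brush_sweep>\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}
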