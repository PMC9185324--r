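# Archard wear model. Closed form Q = K W L / H for a constant load sliding
# over a distance, and the incremental DEM form Q = (K/H) sum F_n * delta_t
# accumulated per contact increment onto a discretised map of the tooth
# surface.

#' Archard wear parameters
#'
#' @param K Archard wear constant (dimensionless), > 0. The default 1
#'   reports wear volume per unit K: the constant for acrylic on enamel is
#'   not tabulated, and every relative wear comparison (speed vs depth,
#'   spatial concentration) is K-independent.
#' @param H Hardness of the worn material (Pa); enamel 0.92 GPa.
#' @return Object of class `wear_params`.
#' @export
wear_params <- function(K = 1.0, H = 0.92e9) {
  if (!is.numeric(K) || K <= 0) stop("K must be > 0")
  if (!is.numeric(H) || H <= 0) stop("H must be > 0")
  structure(list(K = K, H = H), class = "wear_params")
}

#' Closed-form Archard wear volume
#'
#' \deqn{Q = K W L / H} for total normal load `W` sliding a distance `L`
#' over a material of hardness `H`.
#'
#' @param params `wear_params`.
#' @param W Total normal load (N), >= 0.
#' @param L Sliding distance (m), >= 0.
#' @return Wear volume (m^3).
#' @export
archard_total <- function(params, W, L) {
  stopifnot(inherits(params, "wear_params"))
  if (any(W < 0) || any(L < 0)) stop("W and L must be >= 0")
  params$K * W * L / params$H
}

# Build a wear_map object from the engine's per-facet grids.
make_wear_map <- function(grids, facets, cell, params, raw = NA_real_,
                          dropped = 0, n_dropped = 0) {
  names(grids) <- names(facets)
  keep <- !vapply(grids, is.null, logical(1))
  structure(list(
    grids = grids[keep], facets = facets[keep], cell = cell,
    params = params, raw = raw, dropped = dropped, n_dropped = n_dropped
  ), class = "wear_map")
}

#' Create an empty wear map over a tooth model
#'
#' One grid per wear-measured facet, cell size `cell`, indexed by the
#' facet's in-plane coordinates.
#'
#' @param teeth A `tooth_model`.
#' @param cell Cell size (m).
#' @param params `wear_params`.
#' @return Object of class `wear_map`.
#' @export
wear_map <- function(teeth, cell = 0.5e-3, params = wear_params()) {
  stopifnot(inherits(teeth, "tooth_model"))
  grids <- lapply(teeth$facets, function(f) {
    if (!f$wear) return(NULL)
    nu <- max(1, ceiling(sqrt(sum(f$u^2)) / cell - 1e-9))
    nv <- max(1, ceiling(sqrt(sum(f$v^2)) / cell - 1e-9))
    matrix(0, nu, nv)
  })
  make_wear_map(grids, teeth$facets, cell, params, raw = 0)
}

#' Accumulate sliding increments onto a wear map
#'
#' Each increment deposits \eqn{(K/H) F_n \delta_t} into the cell containing
#' its contact point; increments on wear-excluded facets are dropped and
#' counted.
#'
#' @param map A `wear_map`.
#' @param increments Data frame with columns `facet` (name), `a`, `b`
#'   (in-plane contact coordinates, m), `f_n` (N, >= 0) and `slip` (m, >= 0).
#' @param params Optional `wear_params` override.
#' @return The updated `wear_map`.
#' @export
accumulate_wear <- function(map, increments, params = NULL) {
  stopifnot(inherits(map, "wear_map"))
  if (is.null(params)) params <- map$params
  if (nrow(increments) == 0) return(map)
  if (any(increments$f_n < 0) || any(increments$slip < 0))
    stop("increments require f_n >= 0 and slip >= 0")
  for (i in seq_len(nrow(increments))) {
    nm <- increments$facet[i]
    dq <- params$K / params$H * increments$f_n[i] * increments$slip[i]
    if (!nm %in% names(map$grids)) {
      map$dropped <- map$dropped + increments$f_n[i] * increments$slip[i]
      map$n_dropped <- map$n_dropped + 1
      next
    }
    g <- map$grids[[nm]]
    iu <- min(nrow(g), max(1, 1 + floor(increments$a[i] / map$cell)))
    iv <- min(ncol(g), max(1, 1 + floor(increments$b[i] / map$cell)))
    g[iu, iv] <- g[iu, iv] + dq
    map$grids[[nm]] <- g
    map$raw <- map$raw + increments$f_n[i] * increments$slip[i]
  }
  map
}

#' Total accumulated wear volume
#'
#' @param map A `wear_map`.
#' @return Total wear volume over all measured cells (m^3, per unit K when
#'   K = 1).
#' @export
total_wear <- function(map) {
  stopifnot(inherits(map, "wear_map"))
  sum(vapply(map$grids, sum, numeric(1)))
}

facet_v_is_vertical <- function(f) {
  # is the facet's v axis the vertical (y) axis of the tooth?
  abs(f$v[2]) > abs(f$v[1]) && abs(f$v[2]) > abs(f$v[3])
}

mirror_grid <- function(g, f) {
  # mirror a facet grid about the horizontal (y = 0) mid-plane
  if (facet_v_is_vertical(f)) g[, rev(seq_len(ncol(g))), drop = FALSE]
  else g[rev(seq_len(nrow(g))), , drop = FALSE]
}

#' Summarise a wear map
#'
#' Totals, the split between the interproximal groove band and the plate
#' interiors (as per-area wear densities), and a top-bottom symmetry score:
#' the relative L1 difference between the map and its mirror image about the
#' horizontal mid-plane (0 for a perfectly symmetric map).
#'
#' @param map A `wear_map`.
#' @param band Width of the groove-adjacent band on the plates included in
#'   the groove region (m).
#' @param groove_x Optional x-interval of the groove (m); taken from the
#'   facet flags plus `band` on adjacent plates.
#' @return Object of class `wear_summary`.
#' @export
summarize_wear <- function(map, band = 1e-3, groove_x = NULL) {
  stopifnot(inherits(map, "wear_map"))
  total <- total_wear(map)
  groove_q <- 0; groove_area <- 0
  plate_q <- 0; plate_area <- 0
  l1 <- 0
  for (nm in names(map$grids)) {
    f <- map$facets[[nm]]
    g <- map$grids[[nm]]
    cellA <- map$cell^2
    l1 <- l1 + sum(abs(g - mirror_grid(g, f)))
    if (f$groove) {
      groove_q <- groove_q + sum(g)
      groove_area <- groove_area + length(g) * cellA
    } else {
      # groove-adjacent band on the plates: cells whose u-coordinate lies
      # within `band` of the facet edge that borders the groove
      ulen <- sqrt(sum(f$u^2))
      uc <- (seq_len(nrow(g)) - 0.5) * map$cell
      near <- if (!is.null(groove_x)) {
        x0 <- f$origin[1] + uc * f$u[1] / ulen
        x0 > groove_x[1] - band & x0 < groove_x[2] + band
      } else if (grepl("left", nm)) uc > ulen - band else uc < band
      groove_q <- groove_q + sum(g[near, , drop = FALSE])
      groove_area <- groove_area + sum(near) * ncol(g) * cellA
      plate_q <- plate_q + sum(g[!near, , drop = FALSE])
      plate_area <- plate_area + sum(!near) * ncol(g) * cellA
    }
  }
  structure(list(
    total = total,
    groove_q = groove_q, groove_area = groove_area,
    plate_q = plate_q, plate_area = plate_area,
    groove_density = if (groove_area > 0) groove_q / groove_area else 0,
    plate_density = if (plate_area > 0) plate_q / plate_area else 0,
    groove_fraction = if (total > 0) groove_q / total else 0,
    symmetry = if (total > 0) l1 / total else 0,
    raw = map$raw, dropped = map$dropped, n_dropped = map$n_dropped
  ), class = "wear_summary")
}

#' @export
print.wear_summary <- function(x, ...) {
  cat("<wear_summary>\n")
  cat(sprintf("  total wear: %.4g m^3 (per unit K)\n", x$total))
  cat(sprintf("  groove band: %.3g%% of wear (density %.3g vs plate %.3g m^3/m^2)\n",
              100 * x$groove_fraction, x$groove_density, x$plate_density))
  cat(sprintf("  top-bottom symmetry score: %.4g\n", x$symmetry))
  invisible(x)
}

#' @export
print.wear_map <- function(x, ...) {
  cat(sprintf("<wear_map> %d facets, cell %.2g mm, total %.4g m^3\n",
              length(x$grids), x$cell * 1e3, total_wear(x)))
  invisible(x)
}

#' Flatten a wear map to cell records
#'
#' @param x A `wear_map`.
#' @param ... Unused.
#' @return Data frame with one row per cell: facet name, in-plane cell-centre
#'   coordinates `a`, `b` (m), unfolded coordinate `s` along the tooth
#'   cross-section (m), vertical coordinate `y` (m), and wear volume `Q`.
#' @export
as.data.frame.wear_map <- function(x, ...) {
  offs <- unfold_offsets(x)
  out <- lapply(names(x$grids), function(nm) {
    f <- x$facets[[nm]]
    g <- x$grids[[nm]]
    a <- (seq_len(nrow(g)) - 0.5) * x$cell
    b <- (seq_len(ncol(g)) - 0.5) * x$cell
    dd <- expand.grid(a = a, b = b)
    vvert <- facet_v_is_vertical(f)
    data.frame(
      facet = nm, a = dd$a, b = dd$b,
      s = offs[[nm]]$off + offs[[nm]]$sign *
        (if (offs[[nm]]$along == "u") dd$a else dd$b),
      y = f$origin[2] + if (vvert) dd$b else dd$a,
      Q = as.vector(g)
    )
  })
  do.call(rbind, out)
}

# Unfolded arc-length coordinate along the tooth cross-section (left plate,
# down the left wall, across the floor, up the right wall, right plate).
unfold_offsets <- function(map) {
  offs <- list()
  s <- 0
  order <- intersect(c("left_plate", "groove_left_wall", "groove_floor",
                       "groove_right_wall", "right_plate"), names(map$grids))
  for (nm in order) {
    f <- map$facets[[nm]]
    ulen <- sqrt(sum(f$u^2)); vlen <- sqrt(sum(f$v^2))
    vvert <- facet_v_is_vertical(f)
    along <- if (vvert) "u" else "v"  # walk along the non-vertical axis
    len <- if (along == "u") ulen else vlen
    sgn <- 1
    if (nm == "groove_left_wall") sgn <- -1  # wall v runs bottom-up; walk down
    offs[[nm]] <- list(off = if (sgn > 0) s else s + len, sign = sgn,
                       along = along)
    s <- s + len
  }
  # facets not on the walk (none by construction) start past the end
  for (nm in setdiff(names(map$grids), order))
    offs[[nm]] <- list(off = s, sign = 1, along = "u")
  offs
}

#' Plot a wear map
#'
#' Image of the unfolded tooth cross-section (left plate, groove walls and
#' floor, right plate) against the vertical tooth coordinate, coloured by
#' accumulated wear volume per cell.
#'
#' @param x A `wear_map`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.wear_map <- function(x, ...) {
  df <- as.data.frame(x)
  su <- sort(unique(round(df$s, 9)))
  yu <- sort(unique(round(df$y, 9)))
  z <- matrix(0, length(su), length(yu))
  iu <- match(round(df$s, 9), su)
  iv <- match(round(df$y, 9), yu)
  for (k in seq_len(nrow(df))) z[iu[k], iv[k]] <- z[iu[k], iv[k]] + df$Q[k]
  image(su * 1e3, yu * 1e3, z, col = hcl.colors(64, "YlOrRd", rev = TRUE),
        xlab = "unfolded tooth coordinate (mm)", ylab = "y (mm)", ...)
  invisible(x)
}
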