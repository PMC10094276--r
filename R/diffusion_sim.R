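#' Slab geometry and simulation configuration
#'
#' The reference geometry is the 30 x 30 x 10 mm experimental slab; the
#' third axis (`Lz`, the 10 mm height) is the diffusion/depth axis in
#' one-face mode, with depth 0 at the brine-exposed face.
#'
#' @param lengths slab edge lengths in metres, `c(Lx, Ly, Lz)`.
#' @param spacing grid spacing per axis, metres (recycled to length 3).
#'   Must divide each length to within rounding.
#' @return an object of class `"slab_geometry"`.
#' @export
slab_geometry <- function(lengths = c(0.03, 0.03, 0.01), spacing = 5e-4) {
  stopifnot(length(lengths) == 3, all(lengths > 0), all(spacing > 0))
  spacing <- rep_len(spacing, 3)
  n <- lengths / spacing
  if (any(abs(n - round(n)) > 1e-8))
    stop_brinesim("grid spacing must divide each slab length", "invalid_geometry")
  structure(list(lengths = lengths, spacing = spacing,
                 n_nodes = as.integer(round(n)) + 1L), class = "slab_geometry")
}

#' @param de effective diffusion coefficient, m^2 s^-1.
#' @param boundary_mode `"one_face"` (Dirichlet on the depth-0 face, no-flux
#'   elsewhere; the paraffin-sealed configuration), `"all_faces"` (Dirichlet
#'   on every face; full immersion), or `"sealed"` (no-flux everywhere; used
#'   for conservation checks).
#' @param boundary_value fixed concentration at Dirichlet faces. The default
#'   1350 mol m^-3 is the brine-side NaCl concentration used for the
#'   visualisation fields; pass a mass fraction (e.g. 0.08) to work on the
#'   fraction scale instead.
#' @param initial_value uniform initial concentration, same units.
#' @param duration total simulated time, seconds.
#' @param time_step time step, seconds.
#' @param output_times times (seconds) at which fields are returned;
#'   snapped to the nearest whole step. Defaults to `duration`.
#' @rdname slab_geometry
#' @export
sim_config <- function(de, boundary_mode = c("one_face", "all_faces", "sealed"),
                       boundary_value = 1350, initial_value = 0,
                       duration, time_step = 60, output_times = NULL) {
  boundary_mode <- match.arg(boundary_mode)
  if (!is.finite(de) || de <= 0) stop_brinesim("de must be positive", "invalid_config")
  if (time_step <= 0 || duration <= 0)
    stop_brinesim("duration and time_step must be positive", "invalid_config")
  if (is.null(output_times)) output_times <- duration
  if (any(output_times < 0 | output_times > duration + 1e-9))
    stop_brinesim("output_times must lie within [0, duration]", "invalid_config")
  structure(list(de = de, boundary_mode = boundary_mode,
                 boundary_value = boundary_value, initial_value = initial_value,
                 duration = duration, time_step = time_step,
                 output_times = sort(output_times)), class = "sim_config")
}

#' Gridded concentration field
#'
#' @param coords list of node coordinate vectors, one per axis (length 1
#'   list for 1D depth profiles).
#' @param values concentration array (vector in 1D) on the node grid.
#' @param time field time, seconds.
#' @param c0,cs initial and boundary concentrations (for normalisation in
#'   [penetration_depth()]).
#' @return an object of class `"concentration_field"`.
#' @export
concentration_field <- function(coords, values, time, c0, cs) {
  structure(list(coords = coords, values = values, time = time,
                 c0 = c0, cs = cs), class = "concentration_field")
}

#' Analytic semi-infinite erf profile
#'
#' Closed-form solution of Fick's second law for a semi-infinite medium
#' with a fixed surface concentration:
#' \deqn{C(x,t) = C_s - (C_s - C_0)\,\mathrm{erf}\!\left(\frac{x}{2\sqrt{D_e t}}\right).}
#'
#' @param x depth from the exposed face, metres (>= 0).
#' @param t time, seconds (>= 0; at t = 0 the initial condition is
#'   returned, with the surface value at x = 0).
#' @param de effective diffusivity, m^2 s^-1.
#' @param cs surface (brine) concentration.
#' @param c0 initial concentration.
#' @return concentration at (x, t), vectorised over `x`.
#' @export
analytic_profile <- function(x, t, de, cs, c0 = 0) {
  if (t < 0) stop_brinesim("time must be non-negative", "invalid_config")
  stopifnot(all(x >= 0), de > 0)
  if (t == 0) return(ifelse(x == 0, cs, c0))
  cs - (cs - c0) * pracma::erf(x / (2 * sqrt(de * t)))
}

# constant-coefficient tridiagonal solve (Thomas); a sub-, b main, cc super-
# diagonal. Matrices allowed: each column an independent system.
thomas_solve <- function(a, b, cc, d) {
  n <- nrow(d); m <- ncol(d)
  cp <- matrix(0, n, m); dp <- matrix(0, n, m)
  cp[1, ] <- cc[1, ] / b[1, ]
  dp[1, ] <- d[1, ] / b[1, ]
  for (i in 2:n) {
    denom <- b[i, ] - a[i, ] * cp[i - 1, ]
    cp[i, ] <- cc[i, ] / denom
    dp[i, ] <- (d[i, ] - a[i, ] * dp[i - 1, ]) / denom
  }
  x <- dp
  for (i in (n - 1):1) x[i, ] <- dp[i, ] - cp[i, ] * x[i + 1, ]
  x
}

# second-difference operator along a 1D line with mixed BCs.
# dirichlet: logical mask of pinned nodes (operator returns 0 there);
# un-pinned endpoints get the mirror (no-flux) stencil.
apply_lap_1d <- function(u, dirichlet) {
  n <- length(u)
  out <- numeric(n)
  out[2:(n - 1)] <- u[1:(n - 2)] - 2 * u[2:(n - 1)] + u[3:n]
  out[1] <- 2 * (u[2] - u[1])
  out[n] <- 2 * (u[n - 1] - u[n])
  out[dirichlet] <- 0
  out
}

#' One-dimensional transient diffusion in a slab
#'
#' Solves dC/dt = De d2C/dx2 on the depth axis with second-order central
#' differences in space and Crank-Nicolson time stepping (unconditionally
#' stable). The first two steps are taken as four implicit-Euler half-steps
#' (Rannacher start-up) to damp the oscillations Crank-Nicolson otherwise
#' produces from the discontinuous initial boundary jump. Boundary modes:
#' `one_face` fixes C = Cs at depth 0 and seals the far face (zero flux);
#' `all_faces` fixes both ends; `sealed` seals both.
#'
#' @param cfg a [sim_config()].
#' @param geom a [slab_geometry()]; the third axis length is the depth.
#' @param dx grid spacing, metres (default 0.25 mm); must divide the depth.
#' @param init optional non-uniform initial condition: a vector of nodal
#'   values replacing the uniform `initial_value`.
#' @return a list of [concentration_field()]s, one per output time.
#' @export
solve_slab_1d <- function(cfg, geom = slab_geometry(), dx = 2.5e-4,
                          init = NULL) {
  stopifnot(inherits(cfg, "sim_config"), inherits(geom, "slab_geometry"))
  L <- geom$lengths[3]
  n <- L / dx
  if (abs(n - round(n)) > 1e-8)
    stop_brinesim("dx must divide the slab depth", "invalid_geometry")
  n <- as.integer(round(n)) + 1L
  x <- seq(0, L, length.out = n)
  cs <- cfg$boundary_value; c0 <- cfg$initial_value
  if (!all(is.finite(c(cs, c0, cfg$de))))
    stop_brinesim("non-finite simulation inputs", "invalid_config")
  dirichlet <- rep(FALSE, n)
  if (cfg$boundary_mode == "one_face") dirichlet[1] <- TRUE
  if (cfg$boundary_mode == "all_faces") dirichlet[c(1, n)] <- TRUE

  u <- if (is.null(init)) rep(c0, n) else {
    stopifnot(length(init) == n, all(is.finite(init)))
    as.numeric(init)
  }
  u[dirichlet] <- cs

  r <- cfg$de * cfg$time_step / dx^2
  nsteps <- ceiling(cfg$duration / cfg$time_step - 1e-9)
  out_steps <- round(cfg$output_times / cfg$time_step)
  fields <- list()
  emit <- function(u, step) {
    concentration_field(list(x), u, time = step * cfg$time_step, c0 = c0, cs = cs)
  }
  if (0 %in% out_steps) fields[[length(fields) + 1]] <- emit(u, 0)

  # implicit solve of (I - theta*r*A) u = rhs with the BC-aware stencil
  solve_step <- function(rhs, theta) {
    a <- matrix(-theta * r, n, 1); b <- matrix(1 + 2 * theta * r, n, 1)
    cc <- matrix(-theta * r, n, 1)
    cc[1, 1] <- -2 * theta * r; a[n, 1] <- -2 * theta * r
    a[dirichlet, 1] <- 0; cc[dirichlet, 1] <- 0; b[dirichlet, 1] <- 1
    rhs[dirichlet] <- cs
    thomas_solve(a, b, cc, matrix(rhs, n, 1))[, 1]
  }

  n_rannacher <- if (any(dirichlet)) 2L else 0L
  for (step in seq_len(nsteps)) {
    if (step <= n_rannacher) {
      for (half in 1:2) u <- solve_step(u, theta = 0.5)  # backward Euler, dt/2
    } else {
      rhs <- u + 0.5 * r * apply_lap_1d(u, dirichlet)
      u <- solve_step(rhs, theta = 0.5)
    }
    if (step %in% out_steps) fields[[length(fields) + 1]] <- emit(u, step)
  }
  fields
}

# --- 3D Douglas ADI ---------------------------------------------------------

# implicit sweep along one axis of a 3D array: solves (I - theta*r*A_d)u = rhs
# for every grid line along axis `ax`. `dmask` marks Dirichlet nodes (identity
# rows with rhs = cs); un-pinned line endpoints use the no-flux mirror stencil.
sweep_axis <- function(rhs, dmask, ax, theta_r, cs) {
  perm <- c(ax, setdiff(1:3, ax))
  r2 <- aperm(rhs, perm); m2 <- aperm(dmask, perm)
  pd <- dim(r2)
  n <- pd[1]; nl <- prod(pd[2:3])
  dim(r2) <- c(n, nl); dim(m2) <- c(n, nl)
  a <- matrix(-theta_r, n, nl); b <- matrix(1 + 2 * theta_r, n, nl)
  cc <- matrix(-theta_r, n, nl)
  cc[1, ] <- -2 * theta_r; a[n, ] <- -2 * theta_r
  a[m2] <- 0; cc[m2] <- 0; b[m2] <- 1
  r2[m2] <- cs
  x <- thomas_solve(a, b, cc, r2)
  dim(x) <- pd
  aperm(x, order(perm))
}

# explicit second-difference operator along one axis with the same BCs
lap_axis <- function(u, dmask, ax) {
  dd <- dim(u)
  perm <- c(ax, setdiff(1:3, ax))
  u2 <- aperm(u, perm); m2 <- aperm(dmask, perm)
  n <- dim(u2)[1]
  out <- u2
  out[2:(n - 1), , ] <- u2[1:(n - 2), , ] - 2 * u2[2:(n - 1), , ] + u2[3:n, , ]
  out[1, , ] <- 2 * (u2[2, , ] - u2[1, , ])
  out[n, , ] <- 2 * (u2[n - 1, , ] - u2[n, , ])
  out[m2] <- 0
  aperm(out, order(perm))
}

#' Three-dimensional transient diffusion in a slab
#'
#' Solves the constant-De Fickian diffusion equation on the structured
#' rectangular grid with Douglas alternating-direction-implicit (ADI) time
#' stepping, Crank-Nicolson consistent (second order) with one tridiagonal
#' sweep per axis per step. `all_faces` mode fixes every boundary face at
#' the boundary value (immersion); `one_face` fixes only the depth-0 face
#' of the third axis and seals the rest; `sealed` seals everything.
#' Start-up uses damped (implicit Euler) Douglas-Rachford steps, as in the
#' 1D solver.
#'
#' @param cfg a [sim_config()].
#' @param geom a [slab_geometry()]; its `spacing` sets the grid (default
#'   0.5 mm per axis).
#' @param init optional non-uniform initial condition: an array of nodal
#'   values replacing the uniform `initial_value`.
#' @return a list of [concentration_field()]s (3D arrays), one per output
#'   time.
#' @export
solve_slab_3d <- function(cfg, geom = slab_geometry(), init = NULL) {
  stopifnot(inherits(cfg, "sim_config"), inherits(geom, "slab_geometry"))
  nn <- geom$n_nodes
  if (prod(nn) > 1e7)
    stop_brinesim("grid exceeds 10^7 nodes; refine the spacing less", "grid_too_large")
  coords <- lapply(1:3, function(d) seq(0, geom$lengths[d], length.out = nn[d]))
  cs <- cfg$boundary_value; c0 <- cfg$initial_value
  dmask <- array(FALSE, nn)
  if (cfg$boundary_mode == "all_faces") {
    dmask[1, , ] <- TRUE; dmask[nn[1], , ] <- TRUE
    dmask[, 1, ] <- TRUE; dmask[, nn[2], ] <- TRUE
    dmask[, , 1] <- TRUE; dmask[, , nn[3]] <- TRUE
  } else if (cfg$boundary_mode == "one_face") {
    dmask[, , 1] <- TRUE
  }
  u <- if (is.null(init)) array(c0, nn) else {
    stopifnot(all(dim(init) == nn), all(is.finite(init)))
    array(as.numeric(init), nn)
  }
  u[dmask] <- cs
  r <- cfg$de * cfg$time_step / geom$spacing^2  # per-axis ratios
  nsteps <- ceiling(cfg$duration / cfg$time_step - 1e-9)
  out_steps <- round(cfg$output_times / cfg$time_step)
  fields <- list()
  emit <- function(u, step)
    concentration_field(coords, u, time = step * cfg$time_step, c0 = c0, cs = cs)
  if (0 %in% out_steps) fields[[length(fields) + 1]] <- emit(u, 0)

  # one Douglas ADI step of length rfac*dt with implicit weight theta:
  # theta = 1/2, rfac = 1 is the Crank-Nicolson-consistent scheme;
  # theta = 1 gives the damped (implicit Euler) Douglas-Rachford variant.
  douglas_step <- function(u, theta, rfac = 1) {
    rr <- r * rfac
    lx <- lap_axis(u, dmask, 1); ly <- lap_axis(u, dmask, 2)
    lz <- lap_axis(u, dmask, 3)
    rhs <- u + (1 - theta) * rr[1] * lx + rr[2] * ly + rr[3] * lz
    us <- sweep_axis(rhs, dmask, 1, theta * rr[1], cs)
    us <- sweep_axis(us - theta * rr[2] * ly, dmask, 2, theta * rr[2], cs)
    sweep_axis(us - theta * rr[3] * lz, dmask, 3, theta * rr[3], cs)
  }

  n_rannacher <- if (any(dmask)) 2L else 0L
  for (step in seq_len(nsteps)) {
    u <- if (step <= n_rannacher) {
      # two damped half-steps (Rannacher start-up), advancing one full dt
      douglas_step(douglas_step(u, theta = 1, rfac = 0.5), theta = 1, rfac = 0.5)
    } else {
      douglas_step(u, theta = 0.5)
    }
    if (step %in% out_steps) fields[[length(fields) + 1]] <- emit(u, step)
  }
  fields
}

#' Penetration depth of the solute front
#'
#' The greatest depth at which the concentration has reached at least
#' `threshold_frac` of the way from the initial value to the boundary
#' value, capped at the slab depth.
#'
#' @param field a 1D [concentration_field()] along the depth axis (or a 3D
#'   field, in which case the centreline along the third axis is used).
#' @param threshold_frac fraction of the boundary step, in (0, 1).
#' @return depth in metres (0 if the front is nowhere past the threshold).
#' @export
penetration_depth <- function(field, threshold_frac = 0.01) {
  stopifnot(inherits(field, "concentration_field"),
            threshold_frac > 0, threshold_frac < 1)
  prof <- depth_profile(field)
  thr <- field$c0 + threshold_frac * (field$cs - field$c0)
  hit <- if (field$cs >= field$c0) prof$values >= thr else prof$values <= thr
  if (!any(hit)) return(0)
  max(prof$x[hit])
}

# centreline depth profile of a field (identity for 1D fields)
depth_profile <- function(field) {
  if (length(field$coords) == 1)
    return(list(x = field$coords[[1]], values = field$values))
  nn <- dim(field$values)
  i <- ceiling(nn[1] / 2); j <- ceiling(nn[2] / 2)
  list(x = field$coords[[3]], values = field$values[i, j, ])
}

#' Average a depth field over slices
#'
#' Emulates sectioning the one-way sample into slices orthogonal to the
#' transfer direction: each slice value is the volume (here depth) average
#' of the concentration over the slice, computed by trapezoidal
#' integration on the grid; slice centres sit at the midpoints.
#'
#' @param field a 1D [concentration_field()] (or 3D; centreline used).
#' @param slice_thickness slice thickness, metres; must be a whole number
#'   of grid cells and divide the depth.
#' @return a [slice_profile()].
#' @export
field_to_slices <- function(field, slice_thickness = 0.002) {
  prof <- depth_profile(field)
  x <- prof$x; v <- prof$values
  dx <- x[2] - x[1]
  per <- slice_thickness / dx
  if (abs(per - round(per)) > 1e-8)
    stop_brinesim("slice thickness must be a whole number of grid cells",
                  "invalid_geometry")
  per <- as.integer(round(per))
  L <- max(x)
  nsl <- L / slice_thickness
  if (abs(nsl - round(nsl)) > 1e-8)
    stop_brinesim("slice thickness must divide the slab depth", "invalid_geometry")
  nsl <- as.integer(round(nsl))
  centers <- (seq_len(nsl) - 0.5) * slice_thickness
  means <- vapply(seq_len(nsl), function(k) {
    idx <- ((k - 1) * per + 1):(k * per + 1)
    vv <- v[idx]
    (sum(vv) - 0.5 * (vv[1] + vv[length(vv)])) * dx / slice_thickness
  }, numeric(1))
  unit <- if (max(abs(c(field$c0, field$cs))) <= 1) "fraction" else "molar"
  slice_profile(time = field$time / 3600, slice_centers = centers,
                salt_frac = means, slice_thickness = slice_thickness,
                unit = unit)
}

#' Mean absolute relative error between two slice profiles
#'
#' The validation metric for simulated versus observed depth profiles:
#' mean over slices of 100 |sim - obs| / obs.
#'
#' @param simulated,observed [slice_profile()]s on the same slice grid.
#' @return mean absolute relative error, percent.
#' @export
profile_relative_error <- function(simulated, observed) {
  stopifnot(inherits(simulated, "slice_profile"), inherits(observed, "slice_profile"))
  if (length(simulated$slice_centers) != length(observed$slice_centers) ||
      any(abs(simulated$slice_centers - observed$slice_centers) > 1e-9))
    stop_brinesim("slice grids do not match", "grid_mismatch")
  if (any(observed$salt_frac == 0))
    stop_brinesim("observed profile contains zero values; relative error undefined",
                  "invalid_profile")
  mean(100 * abs(simulated$salt_frac - observed$salt_frac) / observed$salt_frac)
}

#' Total solute in a field
#'
#' Trapezoidal volume integral of the concentration; with the field in
#' mol m^-3 the result is in mol. For 1D fields the depth integral is
#' multiplied by the slab cross-section from `geom`.
#'
#' @param field a [concentration_field()].
#' @param geom a [slab_geometry()] (cross-section for 1D fields).
#' @return total solute amount.
#' @export
total_solute <- function(field, geom = slab_geometry()) {
  tw <- function(x) {  # trapezoidal weights
    n <- length(x); h <- x[2] - x[1]
    w <- rep(h, n); w[c(1, n)] <- h / 2; w
  }
  if (length(field$coords) == 1) {
    w <- tw(field$coords[[1]])
    sum(w * field$values) * geom$lengths[1] * geom$lengths[2]
  } else {
    wx <- tw(field$coords[[1]]); wy <- tw(field$coords[[2]])
    wz <- tw(field$coords[[3]])
    W <- outer(outer(wx, wy), wz)
    sum(W * field$values)
  }
}

#' Export a concentration field
#'
#' `write_field_csv()` writes long-format `x,y,z,c,t` rows;
#' `write_field_vtk()` writes a legacy ASCII VTK structured-points file for
#' visualisation.
#'
#' @param field a [concentration_field()].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_field_csv <- function(field, path) {
  if (length(field$coords) == 1) {
    df <- data.frame(x = 0, y = 0, z = field$coords[[1]],
                     c = field$values, t = field$time)
  } else {
    g <- expand.grid(x = field$coords[[1]], y = field$coords[[2]],
                     z = field$coords[[3]])
    df <- data.frame(g, c = as.vector(field$values), t = field$time)
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_field_csv
#' @export
write_field_vtk <- function(field, path) {
  if (length(field$coords) != 3)
    stop_brinesim("VTK export requires a 3D field", "invalid_field")
  nn <- dim(field$values)
  sp <- vapply(field$coords, function(x) x[2] - x[1], numeric(1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               sprintf("solute concentration at t=%g s", field$time),
               "ASCII", "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", nn[1], nn[2], nn[3]),
               "ORIGIN 0 0 0",
               sprintf("SPACING %g %g %g", sp[1], sp[2], sp[3]),
               sprintf("POINT_DATA %d", prod(nn)),
               "SCALARS concentration double 1",
               "LOOKUP_TABLE default"), con)
  writeLines(format(as.vector(field$values), scientific = TRUE, digits = 8), con)
  invisible(path)
}
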