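#' Tissue parameters of the diffusion-form bioheat model
#'
#' The Pennes bioheat equation is reduced to a diffusion process
#' `dT/dt = D lap(T) + P(x, t, T)` with `D = k / (rho c)` the thermal
#' diffusivity and `P` collecting local sources and sinks. For perfused
#' regions `P = w_b c_b (T_a - T) / (rho c)`; metabolic heat is zero in
#' phantoms. Only `D` is optimized; `rho_c` sets the scale of the
#' perfusion term.
#'
#' @param D thermal diffusivity, mm^2/s (> 0).
#' @param rho_c volumetric heat capacity rho*c, J/(m^3 K); water-like
#'   default 4e6.
#' @param c_b blood (coolant) specific heat, J/(kg K); default 4182.
#' @param w_b perfusion rate, kg/(m^3 s); 0 disables the sink term.
#' @param T_a arterial / coolant temperature, degrees C; default 25.
#' @param Q_m metabolic heat, W/m^3; default 0 (no metabolic activity).
#' @return An object of class `tissue_params`.
#' @export
tissue_params <- function(D = 1, rho_c = 4e6, c_b = 4182, w_b = 0,
                          T_a = 25, Q_m = 0) {
  stopifnot(D > 0, rho_c > 0, c_b > 0, w_b >= 0)
  structure(list(D = D, rho_c = rho_c, c_b = c_b, w_b = w_b, T_a = T_a,
                 Q_m = Q_m), class = "tissue_params")
}

#' Perfusion rate of a pump-driven coolant tube
#'
#' `w_b = flow_rate * rho_water / (r^2 pi * l)` in kg/(m^3 s): the pumped
#' water mass per second distributed over the tube volume.
#'
#' @param flow_rate pump flow, m^3/s.
#' @param tube_radius tube radius, m.
#' @param tube_length tube length, m.
#' @param water_density kg/m^3; default 1000.
#' @return Perfusion rate w_b, kg/(m^3 s).
#' @export
perfusion_rate <- function(flow_rate, tube_radius, tube_length,
                           water_density = 1000) {
  if (tube_radius <= 0 || tube_length <= 0)
    stop("tube radius and length must be positive", call. = FALSE)
  flow_rate * water_density / (tube_radius^2 * pi * tube_length)
}

#' Relative axial source profile from extracted isotherms
#'
#' For each point r_i on the applicator axis (one per image row), the
#' orthogonal distances to all M extracted isotherms t_m are summed; the
#' totals are divided by the maximum total q_max, giving relative source
#' strengths q_i in `[0, 1]`. The axial position where the isotherms bulge
#' widest gets q = 1. Distances from the left and right half-image
#' isotherms both enter the sum, preserving asymmetry information.
#'
#' @param isotherm_sets one [extract_isotherm_set()] or a list of them
#'   (e.g. the latest set per orientation).
#' @param min_radius radius of the unmeasurable applicator core, mm,
#'   subtracted from every vertex radius before summing. The masked
#'   artifact band keeps every extracted path at least that far from the
#'   axis, so without the correction axial positions with no heating
#'   would inherit a constant spurious strength; subtracting it lets the
#'   profile decay to zero where the isotherms collapse onto the band.
#'   `NULL` (default) uses the smallest observed vertex radius; 0
#'   disables the correction.
#' @return An object of class `source_profile`: `rows` (0-based axial row
#'   index), `z_mm` (axial position), `q`, `q_max` (mm), and `T_abs`
#'   (filled by [absolute_source()]).
#' @export
source_profile <- function(isotherm_sets, min_radius = NULL) {
  if (inherits(isotherm_sets, "isotherm_set"))
    isotherm_sets <- list(isotherm_sets)
  if (length(isotherm_sets) == 0L)
    stop("no isotherm data to build a source profile from", call. = FALSE)
  frame <- isotherm_sets[[1L]]$frame
  nr <- frame$matrix[1L]
  dists <- vector("list", 0L)
  rows <- vector("list", 0L)
  for (set in isotherm_sets) {
    stopifnot(inherits(set, "isotherm_set"))
    for (it in set$isotherms) {
      dists[[length(dists) + 1L]] <-
        abs(it$vertices$col - set$frame$axis_column) *
        set$frame$pixel_spacing
      rows[[length(rows) + 1L]] <- it$vertices$row
    }
  }
  if (length(dists) == 0L) stop("empty isotherm input", call. = FALSE)
  d <- unlist(dists)
  if (is.null(min_radius)) min_radius <- min(d)
  total <- numeric(nr)
  for (m in seq_along(dists)) {
    contrib <- pmax(0, dists[[m]] - min_radius)
    total[rows[[m]] + 1L] <- total[rows[[m]] + 1L] + contrib
  }
  q_max <- max(total)
  # all radii at the band edge means no evidence of heating anywhere:
  # emit a zero profile (inert clamp) rather than a uniform one
  q <- if (q_max > 0) relative_strengths(total) else numeric(nr)
  structure(list(rows = seq_len(nr) - 1L,
                 z_mm = frame$axis_origin[3L] +
                   (seq_len(nr) - 1L) * frame$pixel_spacing,
                 q = q, q_max = q_max, min_radius = min_radius,
                 T_abs = NULL),
            class = "source_profile")
}

#' Normalize summed isotherm distances to relative source strengths
#'
#' The elementary normalization step of the axial source model: the total
#' isotherm distance of each axis point is divided by the maximum total,
#' giving strengths in `[0, 1]` (all 1 when every total is equal,
#' including the degenerate all-zero case).
#'
#' @param total_distances summed isotherm distances per axis point, mm.
#' @return Relative strengths q in `[0, 1]`, with `max(q) = 1`.
#' @export
relative_strengths <- function(total_distances) {
  stopifnot(all(total_distances >= 0))
  q_max <- max(total_distances)
  if (q_max > 0) total_distances / q_max
  else rep(1, length(total_distances))
}

#' Scale a relative source profile to absolute temperatures
#'
#' Assigns `T_i = q_i * T_max` to every axis point. `T_max` is the
#' ablation parameter limiting the heat input; values below the current
#' local temperature are inert because the profile is applied as a clamp
#' `max(T_i, T_current)` (see [adi_step()]), which also floors sub-baseline
#' values.
#'
#' @param profile a [source_profile()].
#' @param T_max peak source temperature, degrees C.
#' @return The profile with `T_abs` filled.
#' @export
absolute_source <- function(profile, T_max) {
  stopifnot(inherits(profile, "source_profile"))
  profile$T_abs <- profile$q * T_max
  profile
}

#' Solver state of the 3D bioheat simulation
#'
#' Bundles the temperature volume, time, step size, Dirichlet boundary
#' temperature, axial source profile, tissue parameters and the optional
#' perfused-region mask. The initial condition is the uniform baseline
#' temperature before ablation.
#'
#' @param grid a [volume_grid()].
#' @param field initial 3D temperature array; default uniform
#'   `boundary_T`.
#' @param time simulation time, s.
#' @param dt time step, s; the scheme is unconditionally stable so dt is
#'   limited by accuracy, not stability.
#' @param boundary_T Dirichlet face temperature T_Gamma, degrees C.
#' @param source optional [source_profile()] with `T_abs` filled.
#' @param params a [tissue_params()].
#' @param sink_mask optional 3D logical array marking perfused voxels;
#'   required when `params$w_b > 0`.
#' @param src_radius applicator radius, mm: the source profile clamps
#'   every voxel whose center lies within this radius of the axis, so
#'   the injected heat corresponds to a physical applicator dimension
#'   independent of the grid resolution.
#' @param max_r largest diffusion number `D dt / dx^2` per internal
#'   substep: steps exceeding it are sub-cycled, which keeps the
#'   Crank-Nicolson solution monotone near the clamped source (the
#'   scheme is stable for any dt, but its discrete maximum principle
#'   degrades at large diffusion numbers).
#' @return An object of class `solver_state`.
#' @export
solver_state <- function(grid, field = NULL, time = 0, dt = 0.5,
                         boundary_T = 21, source = NULL,
                         params = tissue_params(), sink_mask = NULL,
                         src_radius = 1.5, max_r = 1) {
  stopifnot(inherits(grid, "volume_grid"), dt > 0, max_r > 0,
            src_radius > 0)
  if (is.null(field)) field <- array(boundary_T, grid$shape)
  stopifnot(all(dim(field) == grid$shape))
  if (params$w_b > 0 && is.null(sink_mask))
    stop("w_b > 0 requires a sink_mask marking the perfused region",
         call. = FALSE)
  if (!is.null(sink_mask)) stopifnot(all(dim(sink_mask) == grid$shape))
  structure(list(grid = grid, field = field, time = time, dt = dt,
                 boundary_T = boundary_T, source = source, params = params,
                 sink_mask = sink_mask, src_radius = src_radius,
                 src_xs = source_cross_section(grid, src_radius),
                 max_r = max_r),
            class = "solver_state")
}

#' Local source/sink field of the bioheat equation
#'
#' `P(x, t, T) = w_b c_b (T_a - T) / (rho c)` inside the perfused mask and
#' zero elsewhere; negative wherever the tissue is hotter than the
#' coolant, i.e. a heat sink.
#'
#' @param state a [solver_state()].
#' @return 3D array of temperature rates, K/s.
#' @export
sink_term <- function(state) {
  stopifnot(inherits(state, "solver_state"))
  P <- array(0, state$grid$shape)
  if (state$params$w_b > 0) {
    b <- state$params$w_b * state$params$c_b / state$params$rho_c
    P[state$sink_mask] <- b * (state$params$T_a -
                                 state$field[state$sink_mask])
  }
  P
}

#' Solve a tridiagonal linear system (Thomas algorithm)
#'
#' Direct O(n) solve; the Crank-Nicolson sweep matrices are diagonally
#' dominant, so no pivoting is needed.
#'
#' @param lower subdiagonal (length n-1).
#' @param diag main diagonal (length n).
#' @param upper superdiagonal (length n-1).
#' @param rhs right-hand side (length n).
#' @return Solution vector of length n.
#' @export
thomas_solve <- function(lower, diag, upper, rhs) {
  thomas_solve_cpp(as.numeric(lower), as.numeric(diag), as.numeric(upper),
                   as.numeric(rhs))
}

# Voxel indices (0-based linear) of the applicator source cylinder and
# the per-z clamp temperatures from a source profile. The applicator is
# a physical cylinder of radius src_radius (mm) around the axis x = y =
# 0, so the set of clamped voxels — and with it the injected heat — is
# tied to a physical dimension, not to the grid resolution. On even
# grids, where the axis lies between voxel centers, the clamped
# cross-section stays symmetric.
# In-plane cross-section of the applicator cylinder: 0-based linear xy
# indices of voxels it touches and the fraction of each voxel cell
# covered by the disc (8x8 subsampling). The disc is inflated by 0.55
# grid cells: a discretely clamped region has an effective thermal
# radius about half a cell smaller than its nominal one (the flux leaves
# through the cell faces, analogous to the equivalent-radius correction
# of well models), and the inflation makes the simulated far field
# grid-resolution independent (calibrated by matching runs of the same
# solver at 1 mm and 0.5 mm spacing). Cached per solver state.
source_cross_section <- function(grid, src_radius = 1.5) {
  sh <- grid$shape
  src_radius <- src_radius + 0.55 * grid$spacing
  x <- grid_coords(grid, 1L)
  y <- grid_coords(grid, 2L)
  off <- (seq_len(8L) - 4.5) / 8 * grid$spacing
  cov <- matrix(0, sh[1L], sh[2L])
  for (ox in off) {
    xs2 <- (x + ox)^2
    for (oy in off) cov <- cov + (outer(xs2, (y + oy)^2, `+`) <=
                                    src_radius^2)
  }
  cov <- cov / 64
  xy <- which(cov > 0) - 1L                                  # 0-based
  if (length(xy) == 0L) {
    xy <- which.min(outer(x^2, y^2, `+`)) - 1L
    return(list(xy_lin = (xy %% sh[1L]) + sh[1L] * (xy %/% sh[1L]),
                w = 1))
  }
  list(xy_lin = (xy %% sh[1L]) + sh[1L] * (xy %/% sh[1L]),
       w = cov[xy + 1L])
}

source_voxels <- function(grid, source, xs) {
  if (is.null(source) || is.null(source$T_abs))
    return(list(idx = integer(0), T = numeric(0), w = numeric(0)))
  sh <- grid$shape
  kz <- round((source$z_mm - grid$origin[3L]) / grid$spacing)
  ok <- kz >= 0 & kz <= sh[3L] - 1 & is.finite(source$T_abs)
  kz <- as.integer(kz[ok]); Tz <- source$T_abs[ok]
  Tk <- tapply(Tz, kz, max)                 # several rows may share a voxel
  kz <- as.integer(names(Tk)); Tz <- as.numeric(Tk)
  idx <- outer(xs$xy_lin, sh[1L] * sh[2L] * kz, `+`)
  list(idx = as.integer(idx), T = rep(Tz, each = length(xs$xy_lin)),
       w = rep(xs$w, times = length(kz)))
}

#' Advance the bioheat simulation by one time step
#'
#' One Crank-Nicolson step of the diffusion + sink equation, split into
#' three directional sweeps (Douglas alternating-direction-implicit
#' scheme), each solving tridiagonal systems with the Thomas algorithm.
#' The perfusion sink is averaged half-explicit / half-implicit. Dirichlet
#' faces are reset to `boundary_T` and axis voxels are clamped to
#' `max(T_i, T_current)` — the observed axial profile drives the
#' simulation instead of an explicit treatment-specific heat-source term.
#'
#' @param state a [solver_state()].
#' @return The state advanced by `dt`.
#' @export
adi_step <- function(state) {
  stopifnot(inherits(state, "solver_state"))
  if (is.null(state$src_xs))
    state$src_xs <- source_cross_section(state$grid,
                                         if (is.null(state$src_radius))
                                           1.5 else state$src_radius)
  sv <- source_voxels(state$grid, state$source, state$src_xs)
  sink_b <- numeric(0)
  if (state$params$w_b > 0) {
    b <- state$params$w_b * state$params$c_b / state$params$rho_c
    sink_b <- as.numeric(state$sink_mask) * b
  }
  state$field <- adi_step_cpp(state$field, state$grid$shape,
                              state$grid$spacing, state$dt,
                              state$params$D, state$boundary_T,
                              sv$idx, sv$T, sv$w, sink_b, state$params$T_a,
                              if (is.null(state$max_r)) 1 else state$max_r)
  state$time <- state$time + state$dt
  state
}

#' Run the simulation for a duration
#'
#' Repeats [adi_step()] `ceiling(duration / dt)` times; the advanced time
#' is the step count times `dt` (durations are normally multiples of the
#' step size).
#'
#' @param state a [solver_state()].
#' @param duration simulated seconds (>= 0).
#' @return The advanced state.
#' @export
simulate_bioheat <- function(state, duration) {
  stopifnot(inherits(state, "solver_state"), duration >= 0)
  n <- ceiling(duration / state$dt - 1e-9)
  for (i in seq_len(n)) state <- adi_step(state)
  state
}
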