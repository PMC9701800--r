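#' Parameter set of the adaptive fit
#'
#' The two global parameters re-estimated per image: thermal diffusivity
#' `D` (optimization range `[0.1, 5]` mm^2/s, covering reported tissue
#' diffusivities 0.142-3.68 mm^2/s with headroom for their increase at
#' ablation temperatures) and the ablation parameter `T_max`
#' (range `[80, 300]` degrees C). The initial `T_max` is the known ambient
#' baseline temperature; starting values outside the bounds are projected
#' onto them before the first fit.
#'
#' @param D thermal diffusivity, mm^2/s.
#' @param T_max peak source temperature, degrees C.
#' @param bounds_D,bounds_Tmax length-2 optimization ranges.
#' @return An object of class `parameter_set`.
#' @export
parameter_set <- function(D = 1, T_max = 21, bounds_D = c(0.1, 5),
                          bounds_Tmax = c(80, 300)) {
  stopifnot(length(bounds_D) == 2L, length(bounds_Tmax) == 2L,
            bounds_D[1L] < bounds_D[2L], bounds_Tmax[1L] < bounds_Tmax[2L])
  structure(list(D = D, T_max = T_max, bounds_D = as.numeric(bounds_D),
                 bounds_Tmax = as.numeric(bounds_Tmax)),
            class = "parameter_set")
}

clamp_params <- function(P) {
  P$D <- min(max(P$D, P$bounds_D[1L]), P$bounds_D[2L])
  P$T_max <- min(max(P$T_max, P$bounds_Tmax[1L]), P$bounds_Tmax[2L])
  P
}

#' Residuals between simulation and extracted isotherms
#'
#' Simulates forward from the accepted previous state under a candidate
#' parameter set, then samples the 3D volume at every isotherm vertex of
#' the current map (via the frame geometry) and returns the difference
#' between the simulated and the measured temperature at that vertex
#' (the vertex isovalue is used where no measured value is attached,
#' e.g. for synthetic isotherm sets). The sum of squares of this vector
#' is the objective the per-image fit minimizes; candidate forward
#' simulations are discarded, only the accepted state advances.
#'
#' @param P a [parameter_set()].
#' @param prev_state the accepted [solver_state()] at the previous
#'   acquisition time.
#' @param iso_set the [extract_isotherm_set()] of the current map.
#' @param q_profile the relative [source_profile()] in effect.
#' @param dt_to_acquisition seconds between the previous state and the
#'   current acquisition.
#' @return Numeric residual vector (degrees C), one entry per vertex.
#' @export
residuals_thermo <- function(P, prev_state, iso_set, q_profile,
                             dt_to_acquisition) {
  stopifnot(inherits(iso_set, "isotherm_set"))
  if (length(iso_set$isotherms) == 0L)
    stop("empty isotherm set", call. = FALSE)
  st <- prev_state
  st$params$D <- P$D
  st$source <- absolute_source(q_profile, P$T_max)
  st <- simulate_bioheat(st, dt_to_acquisition)
  res <- numeric(0)
  for (it in iso_set$isotherms) {
    pts <- slice_to_world(iso_set$frame,
                          cbind(it$vertices$row, it$vertices$col))
    Tsim <- sample_volume(st$field, st$grid, pts,
                          outside_value = st$boundary_T)
    target <- if (is.null(it$vertices$value)) it$isovalue else
      it$vertices$value
    res <- c(res, Tsim - target)
  }
  res
}

#' Bounded Levenberg-Marquardt least-squares fit
#'
#' Minimizes the sum of squared residuals over the two parameters with
#' hard box bounds (projection-based trust-region Levenberg-Marquardt as
#' implemented in \pkg{minpack.lm}); the blend of steepest descent and
#' Gauss-Newton steps makes the ill-conditioned inverse heat problem
#' robust to poor starting values. Deterministic given identical inputs.
#'
#' @param residual_fn function of a [parameter_set()] returning the
#'   residual vector.
#' @param P_init starting [parameter_set()]; projected into its bounds.
#' @param maxiter,ftol,ptol convergence controls (iteration cap, relative
#'   sum-of-squares tolerance, relative step tolerance).
#' @return List with the fitted `parameter_set` and a `fit_record`
#'   (sse_before, sse_after, n_residuals, n_iterations, converged).
#' @export
lm_fit <- function(residual_fn, P_init, maxiter = 25L, ftol = 1e-4,
                   ptol = 1e-4) {
  P0 <- clamp_params(P_init)
  # a start exactly on a bound freezes the bounded MINPACK iteration;
  # nudge projected starts strictly into the interior
  nudge <- function(x, b) min(max(x, b[1L] + 1e-3 * diff(b)),
                              b[2L] - 1e-3 * diff(b))
  P0$D <- nudge(P0$D, P0$bounds_D)
  P0$T_max <- nudge(P0$T_max, P0$bounds_Tmax)
  wrap <- function(par) {
    P <- P0; P$D <- par[1L]; P$T_max <- par[2L]
    r <- residual_fn(P)
    if (any(!is.finite(r)))
      stop("non-finite residuals during fit", call. = FALSE)
    r
  }
  r0 <- wrap(c(P0$D, P0$T_max))
  fit <- minpack.lm::nls.lm(
    par = c(P0$D, P0$T_max),
    lower = c(P0$bounds_D[1L], P0$bounds_Tmax[1L]),
    upper = c(P0$bounds_D[2L], P0$bounds_Tmax[2L]),
    fn = wrap,
    control = minpack.lm::nls.lm.control(maxiter = maxiter, ftol = ftol,
                                         ptol = ptol, factor = 10))
  P1 <- P0; P1$D <- fit$par[1L]; P1$T_max <- fit$par[2L]
  P1 <- clamp_params(P1)
  sse_before <- sum(r0^2)
  sse_after <- min(fit$deviance, sse_before)
  record <- list(sse_before = sse_before, sse_after = sse_after,
                 n_residuals = length(r0), n_iterations = fit$niter,
                 converged = fit$info %in% 1:4)
  list(params = P1, record = record)
}

#' One adaptive update of the simulation from a new temperature map
#'
#' The sequential loop body: extract the isotherm set of the incoming
#' map, rebuild the relative axial source profile from the accumulated
#' latest isotherm set of every orientation, refit `{D, T_max}` against
#' the new map's isotherms by bounded Levenberg-Marquardt, and advance the
#' accepted state to the acquisition time under the fitted parameters.
#' When isotherm extraction fails the update is skipped: the state
#' advances under the previous parameters and the record is flagged.
#'
#' @param state accepted [solver_state()] at the previous acquisition.
#' @param P current [parameter_set()].
#' @param new_map the incoming [temperature_map()].
#' @param iso_store named list holding the latest [extract_isotherm_set()]
#'   per orientation angle (accumulated across the series).
#' @param opts list of options: `isovalues` (vector or NULL for the
#'   default ladder), `span`, `n_isovalues`, `anchor_offset` (degrees C
#'   the ladder starts above baseline; the lowest isovalue must exceed
#'   the baseline by more than the noise scale to be localizable, default
#'   3), `interval` (s between acquisitions), `connectivity`,
#'   `accumulate` (use all stored orientations' isotherms in the residual
#'   instead of only the newest map's), `maxiter`, `ftol`, `ptol`,
#'   `restart_P` (a [parameter_set()] to retry from when a fit ends
#'   pinned at a parameter bound, the signature of capture in a wrong
#'   basin; [run_reconstruction()] sets it to the initial parameters).
#' @return List `state`, `params`, `record`, `iso_store`.
#' @export
adaptive_update <- function(state, P, new_map, iso_store = list(),
                            opts = list()) {
  o <- modifyList(list(isovalues = NULL, span = 24, n_isovalues = 8L,
                       anchor_offset = 3, interval = 2, connectivity = 1L,
                       accumulate = FALSE, maxiter = 25L, ftol = 1e-4,
                       ptol = 1e-4, restart_P = NULL), opts)
  isovals <- o$isovalues
  if (is.null(isovals))
    isovals <- default_isovalues(new_map$baseline_T0, o$span, o$n_isovalues,
                                 anchor = new_map$baseline_T0 +
                                   o$anchor_offset)
  # advance to the map's acquisition time (maps arrive every `interval`
  # seconds; filtered series, e.g. orientation subsets, leave larger gaps)
  gap <- (new_map$time_index + 1) * o$interval - state$time
  if (gap <= 0) gap <- o$interval
  iso_set <- tryCatch(
    extract_isotherm_set(new_map, isovals, connectivity = o$connectivity),
    error = function(e) NULL)
  if (is.null(iso_set)) {                     # skip update, keep old P
    state$source <- if (!is.null(state$source)) state$source else NULL
    state <- simulate_bioheat(state, gap)
    rec <- list(time_index = new_map$time_index, D = P$D, T_max = P$T_max,
                sse_before = NA_real_, sse_after = NA_real_,
                n_residuals = 0L, n_iterations = 0L, converged = FALSE,
                skipped = TRUE)
    return(list(state = state, params = P, record = rec,
                iso_store = iso_store))
  }
  key <- sprintf("%.3f", new_map$frame$angle)
  iso_store[[key]] <- iso_set
  q_prof <- source_profile(unname(iso_store))
  fit_sets <- if (isTRUE(o$accumulate)) unname(iso_store) else list(iso_set)
  prev <- state
  resid_fn <- function(Pc) {
    unlist(lapply(fit_sets, function(s)
      residuals_thermo(Pc, prev, s, q_prof, gap)))
  }
  fit <- lm_fit(resid_fn, P, o$maxiter, o$ftol, o$ptol)
  # A solution pinned at a parameter bound, or one whose clamp is fully
  # inert (T_max so low that no axis voxel is ever raised — a
  # zero-gradient plateau), signals capture in a wrong basin, typical
  # while the ablation is still powering up or after an unrealistic
  # initialization. Retry from the configured restart values with T_max
  # at least above the hottest measured vertex temperature (the source
  # cannot be cooler than anything it heated) and keep the better fit.
  at_bound <- fit$params$D %in% fit$params$bounds_D ||
    fit$params$T_max %in% fit$params$bounds_Tmax
  inert <- q_prof$q_max > 0 &&
    fit$params$T_max * max(q_prof$q) <= new_map$baseline_T0
  if ((at_bound || inert) && q_prof$q_max > 0 &&
      !is.null(o$restart_P)) {
    retry <- o$restart_P
    retry$bounds_D <- P$bounds_D
    retry$bounds_Tmax <- P$bounds_Tmax
    max_meas <- max(vapply(iso_set$isotherms, function(it)
      max(it$vertices$value, new_map$baseline_T0), numeric(1L)))
    retry$T_max <- max(retry$T_max,
                       2 * max_meas - new_map$baseline_T0)
    fit2 <- lm_fit(resid_fn, retry, o$maxiter, o$ftol, o$ptol)
    if (fit2$record$sse_after < fit$record$sse_after) fit <- fit2
  }
  state$params$D <- fit$params$D
  state$source <- absolute_source(q_prof, fit$params$T_max)
  state <- simulate_bioheat(state, gap)
  rec <- c(list(time_index = new_map$time_index, D = fit$params$D,
                T_max = fit$params$T_max), fit$record, list(skipped = FALSE))
  list(state = state, params = fit$params, record = rec,
       iso_store = iso_store)
}

#' Run the full sequential reconstruction over a series
#'
#' Initializes the volume at the uniform baseline temperature with
#' Dirichlet faces and applies [adaptive_update()] for every acquired
#' map in time order.
#'
#' @param series list of [temperature_map()] objects (time ordered).
#' @param grid a [volume_grid()]; default 60^3 at 1 mm.
#' @param P_init initial [parameter_set()]; default D = 1 mm^2/s and
#'   `T_max` at the baseline temperature (projected into bounds).
#' @param dt solver time step, s.
#' @param params a [tissue_params()] (perfusion configuration).
#' @param sink_mask optional perfused-region mask on `grid`.
#' @param opts options passed to [adaptive_update()].
#' @return List: final `state`, final `params`, `fits` (one row per
#'   image), `iso_store`.
#' @export
run_reconstruction <- function(series, grid = volume_grid(),
                               P_init = NULL, dt = 0.5,
                               params = tissue_params(),
                               sink_mask = NULL, opts = list()) {
  if (length(series) == 0L) stop("empty series", call. = FALSE)
  baseline <- series[[1L]]$baseline_T0
  if (is.null(P_init)) P_init <- parameter_set(D = 1, T_max = baseline)
  params$D <- clamp_params(P_init)$D
  state <- solver_state(grid, time = 0, dt = dt, boundary_T = baseline,
                        params = params, sink_mask = sink_mask)
  if (is.null(opts$restart_P))
    opts$restart_P <- parameter_set(D = 1, T_max = baseline,
                                    bounds_D = P_init$bounds_D,
                                    bounds_Tmax = P_init$bounds_Tmax)
  P <- P_init
  iso_store <- list()
  fits <- vector("list", length(series))
  for (i in seq_along(series)) {
    up <- adaptive_update(state, P, series[[i]], iso_store, opts)
    state <- up$state; P <- up$params; iso_store <- up$iso_store
    fits[[i]] <- as.data.frame(up$record)
  }
  list(state = state, params = P, fits = do.call(rbind, fits),
       iso_store = iso_store)
}
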