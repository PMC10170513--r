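#' Deposition schedule
#'
#' @param stride time between hill depositions, ps (default 1 ps).
#' @param max_time maximum simulation time, ps.
#' @param stop_on_unbound stop the run at the first deposition instant at
#'   which the unbound predicate holds.
#' @return object of class `deposition_schedule`.
#' @export
deposition_schedule <- function(stride = 1, max_time, stop_on_unbound = TRUE) {
  stopifnot(stride > 0, max_time >= 0)
  structure(list(stride = stride, max_time = max_time,
                 stop_on_unbound = isTRUE(stop_on_unbound)),
            class = "deposition_schedule")
}

#' 1-D Langevin system for metadynamics
#'
#' Wraps an analytic potential and Langevin parameters into a dynamical
#' system whose single collective variable is the coordinate itself (the
#' CV chain rule is the identity). The optional `unbound_at` threshold
#' defines the unbound predicate `x >= unbound_at`.
#'
#' @param potential an [analytic_potential()].
#' @param params a [langevin_params()].
#' @param x0 initial position, Angstrom.
#' @param unbound_at unbound threshold (NA: no unbound state).
#' @return object of class `langevin_system`.
#' @export
langevin_system <- function(potential, params = langevin_params(), x0,
                            unbound_at = NA_real_) {
  stopifnot(inherits(potential, "analytic_potential"),
            inherits(params, "langevin_params"))
  structure(list(potential = potential, params = params, x0 = x0,
                 unbound_at = unbound_at),
            class = "langevin_system")
}

new_metad_trajectory <- function(records, status, widths, periodic, period,
                                 wt, stride, temperature) {
  structure(list(records = records, status = status, widths = widths,
                 periodic = periodic, period = period, wt = wt,
                 stride = stride, temperature = temperature),
            class = "metad_trajectory")
}

#' Assemble a metadynamics trajectory from deposition records
#'
#' Builds the trajectory container from externally produced records
#' (e.g. a COLVAR-style file read with [read_colvar()]), so that the
#' recovery estimators can post-process runs made elsewhere. The record
#' table needs columns `time`, `cv_1` (... `cv_n`), `bias` (the
#' accumulated bias just before each deposition, hills only), `height`
#' (deposited height) and logical `unbound`.
#'
#' @param records data frame of deposition records, times strictly
#'   increasing.
#' @param status terminal status, `"unbound"` or `"max_time_reached"`;
#'   by default inferred from the `unbound` flags.
#' @param widths per-CV hill widths used in the run.
#' @param temperature simulation temperature, K.
#' @param wt a [wt_params()] describing the schedule that produced the
#'   run.
#' @param periodic,period per-CV periodicity (defaults: aperiodic).
#' @return a `metad_trajectory`.
#' @export
metad_trajectory <- function(records, status = NULL, widths = 0.2,
                             temperature = 300, wt = wt_params(),
                             periodic = NULL, period = NULL) {
  records <- as.data.frame(records)
  ncv <- length(grep("^cv_", names(records)))
  need <- c("time", "bias", "height", "unbound")
  if (ncv < 1 || !all(need %in% names(records)))
    stop("records need columns time, cv_*, bias, height, unbound",
         call. = FALSE)
  if (nrow(records) > 1 && any(diff(records$time) <= 0))
    stop("record times must be strictly increasing", call. = FALSE)
  records$unbound <- as.logical(records$unbound)
  if (is.null(status))
    status <- if (any(records$unbound)) "unbound" else "max_time_reached"
  if (is.null(periodic)) periodic <- rep(FALSE, ncv)
  if (is.null(period)) period <- ifelse(periodic, 360, NA_real_)
  stride <- if (nrow(records) > 1) records$time[2] - records$time[1] else 1
  new_metad_trajectory(records, status, rep_len(widths, ncv), periodic,
                       period, wt, stride, temperature)
}

#' @export
print.metad_trajectory <- function(x, ...) {
  cat(sprintf("<metad_trajectory> %d depositions, status: %s\n",
              nrow(x$records), x$status))
  invisible(x)
}

#' Number of CVs in a trajectory
#' @param traj a `metad_trajectory`.
#' @export
traj_ncv <- function(traj) length(traj$widths)

#' Deposited hills of a trajectory
#'
#' Rebuilds the [hills()] list from the deposition records (records with
#' zero height, i.e. the terminal unbound record, deposit nothing).
#'
#' @param traj a `metad_trajectory`.
#' @return a [hills()] object.
#' @export
traj_hills <- function(traj) {
  r <- traj$records
  keep <- r$height > 0
  ncv <- traj_ncv(traj)
  centers <- as.matrix(r[keep, paste0("cv_", seq_len(ncv)), drop = FALSE])
  biasf <- if (traj$wt$enabled)
    1 + traj$wt$kb_deltaT / (KB_KCAL * traj$temperature) else NA_real_
  hills(centers, matrix(traj$widths, sum(keep), ncv, byrow = TRUE),
        r$height[keep], r$time[keep],
        periodic = traj$periodic, period = traj$period, biasf = biasf)
}

#' Run a metadynamics simulation
#'
#' Propagates the system, and every `stride` ps records the current CV
#' point, the accumulated bias V(s,t) at that point (hills only, walls
#' excluded), evaluates the unbound predicate, and deposits a Gaussian
#' hill whose height follows the well-tempered rescaling when enabled.
#' The run terminates at the first unbound deposition instant (recorded
#' with zero deposited height) or at `max_time`. With identical seed and
#' configuration the trajectory is bit-identical across runs.
#'
#' @param system a [langevin_system()] or [generate_pseudo_complex()]
#'   system.
#' @param ... method arguments: `params` ([wt_params()]), `walls` (list of
#'   [wall_spec()]), `schedule` ([deposition_schedule()]), `widths`
#'   (per-CV hill sigma), `seed`.
#' @return a `metad_trajectory`.
#' @export
run_metad <- function(system, ...) UseMethod("run_metad")

#' @rdname run_metad
#' @param params a [wt_params()].
#' @param walls list of [wall_spec()]s.
#' @param schedule a [deposition_schedule()].
#' @param widths hill width sigma (CV units); scalar for 1-D systems.
#' @param seed integer seed.
#' @export
run_metad.langevin_system <- function(system, params = wt_params(),
                                      walls = list(), schedule,
                                      widths = 0.2, seed = 1, ...) {
  stopifnot(inherits(params, "wt_params"),
            inherits(schedule, "deposition_schedule"),
            length(widths) == 1, widths > 0)
  lp <- system$params
  steps_per_stride <- as.integer(round(schedule$stride / lp$timestep))
  if (steps_per_stride < 1)
    stop("configuration error: stride shorter than the timestep", call. = FALSE)
  max_deposits <- as.integer(floor(schedule$max_time / schedule$stride))
  floor_loc <- NA_real_; floor_k <- 0; wall_loc <- NA_real_; wall_k <- 0
  for (w in walls) {
    stopifnot(inherits(w, "wall_spec"))
    if (w$cv_index != 1L)
      stop("configuration error: 1-D system has a single CV", call. = FALSE)
    if (w$kind == "lower_floor") { floor_loc <- w$location; floor_k <- w$force_constant }
    else { wall_loc <- w$location; wall_k <- w$force_constant }
  }
  set.seed(seed)
  res <- cpp_metad_1d(system$x0, system$potential$code,
                      system$potential$params, lp$timestep,
                      lp$friction * lp$mass, lp$kT,
                      steps_per_stride, max_deposits,
                      params$omega0, params$kb_deltaT, params$enabled,
                      widths, floor_loc, floor_k, wall_loc, wall_k,
                      if (schedule$stop_on_unbound) system$unbound_at else NA_real_,
                      schedule$stop_on_unbound)
  n <- length(res$cv)
  records <- data.frame(time = schedule$stride * seq_len(n),
                        cv_1 = res$cv, bias = res$bias,
                        height = res$height,
                        unbound = as.logical(res$unbound))
  new_metad_trajectory(records, res$status, widths, FALSE, NA_real_,
                       params, schedule$stride, lp$temperature)
}
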