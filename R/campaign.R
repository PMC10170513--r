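#' Standard double-well benchmark system
#'
#' The 1-D benchmark used throughout the package's validation: an
#' overdamped particle in a quartic double well with the "bound" minimum
#' at x = -1.5 A, the barrier top at x = 0 and the "unbound" threshold at
#' x = +1.0 A (past the barrier, committed to the far basin, which is
#' also the absorbing boundary of the unbiased reference oracle). At
#' 300 K the thermal width of the bound basin is about 0.2 A for an
#' 8 kBT barrier, so the standard 0.2 A hill width is about one third
#' of the basin's full width. The default friction (2 ps^-1) makes the
#' bound-basin relaxation time (gamma m / V'' of about 0.1 ps) much
#' shorter than the 1 ps deposition stride, the infrequent-deposition
#' regime the flooding estimator assumes.
#'
#' @param barrier_kT barrier height in units of kB T.
#' @param temperature temperature, K.
#' @param friction gamma, ps^-1.
#' @param timestep dt, ps.
#' @param x_min half-separation of the minima, Angstrom.
#' @return a [langevin_system()].
#' @export
double_well_fixture <- function(barrier_kT = 8, temperature = 300,
                                friction = 2, timestep = 0.001,
                                x_min = 1.5) {
  lp <- langevin_params(temperature = temperature, friction = friction,
                        timestep = timestep, mass = 1)
  pot <- analytic_potential("double_well", barrier = barrier_kT * lp$kT,
                            x_min = x_min)
  langevin_system(pot, lp, x0 = -x_min, unbound_at = 1.0)
}

#' Replica campaign configuration
#'
#' A campaign runs `n_replicas` independent metadynamics simulations of
#' one system, differing only in the seed (replica i uses
#' `base_seed + i`), and aggregates the per-replica kinetic estimates.
#' Mode `"flooding"` runs well-tempered metadynamics and recovers
#' RT_calcd = alpha_max x t via the acceleration factor (default hill
#' height 0.40 kcal/mol, bias factor 10 kcal/mol); mode `"tmetad"` runs
#' constant-height metadynamics (default height 0.25 kcal/mol) and
#' records the time to the unbound state.
#'
#' @param system a system accepted by [run_metad()].
#' @param mode `"flooding"` or `"tmetad"`.
#' @param n_replicas number of replicas (>= 1; 10 is the conventional
#'   campaign size).
#' @param base_seed integer base seed.
#' @param params a [wt_params()]; defaults depend on `mode`.
#' @param walls list of [wall_spec()]s.
#' @param schedule a [deposition_schedule()].
#' @param widths per-CV hill width(s), CV units.
#' @param out_dir optional directory for per-replica HILLS/COLVAR files
#'   and the summary CSV/JSON.
#' @return object of class `campaign_config`.
#' @export
campaign_config <- function(system, mode = c("flooding", "tmetad"),
                            n_replicas = 10, base_seed = 1, params = NULL,
                            walls = list(), schedule, widths = 0.2,
                            out_dir = NULL) {
  mode <- match.arg(mode)
  stopifnot(n_replicas >= 1)
  if (is.null(params)) {
    params <- if (mode == "flooding") wt_params(omega0 = 0.40, kb_deltaT = 10)
              else wt_params(omega0 = 0.25, enabled = FALSE)
  }
  if (mode == "tmetad" && params$enabled)
    stop("configuration error: t_META-D runs use constant-height hills",
         call. = FALSE)
  structure(list(system = system, mode = mode,
                 n_replicas = as.integer(n_replicas),
                 base_seed = as.integer(base_seed), params = params,
                 walls = walls, schedule = schedule, widths = widths,
                 out_dir = out_dir),
            class = "campaign_config")
}

#' Run a replica campaign
#'
#' Runs every replica, extracts the per-replica estimate (RT_calcd in
#' minutes for `"flooding"`, t_META-D in ns for `"tmetad"`), and
#' aggregates: geometric-mean tau with SEM of log10 values for RT,
#' arithmetic mean with SEM for t_META-D, plus the ECD of the estimates
#' and (n >= 5) the exponentiality check. Replicas that fail numerically
#' or never reach the unbound state are logged and excluded; the
#' summary reports `n_effective`.
#'
#' @param config a [campaign_config()].
#' @return object of class `campaign`: list with `replicas` (per-replica
#'   data frame), `values`, `summary` ([aggregate_replicas()] result),
#'   `ecd`, `exponentiality`, `n_effective`, `log`, `config`.
#' @export
run_campaign <- function(config) {
  stopifnot(inherits(config, "campaign_config"))
  logs <- character()
  say <- function(...) logs <<- c(logs, sprintf(...))
  rows <- list()
  values <- numeric()
  trajs <- list()
  for (i in seq_len(config$n_replicas)) {
    seed <- config$base_seed + i
    traj <- tryCatch(
      run_metad(config$system, params = config$params, walls = config$walls,
                schedule = config$schedule, widths = config$widths,
                seed = seed),
      error = function(e) e)
    if (inherits(traj, "error")) {
      say("replica %d (seed %d): numerical failure: %s", i, seed,
          conditionMessage(traj))
      rows[[i]] <- data.frame(replica = i, seed = seed, status = "failed",
                              n_hills = NA_real_, estimate = NA_real_)
      next
    }
    n_hills <- sum(traj$records$height > 0)
    say("replica %d (seed %d): %d hills deposited, stop reason: %s",
        i, seed, n_hills, traj$status)
    if (traj$status != "unbound") {
      say("replica %d (seed %d): censored (no unbinding within max_time)",
          i, seed)
      rows[[i]] <- data.frame(replica = i, seed = seed, status = "censored",
                              n_hills = n_hills, estimate = NA_real_)
      next
    }
    est <- if (config$mode == "flooding") {
      rt_estimate(traj)$rt_min
    } else {
      t_metad(traj)$t_metad_ns
    }
    rows[[i]] <- data.frame(replica = i, seed = seed, status = "unbound",
                            n_hills = n_hills, estimate = est)
    values <- c(values, est)
    trajs[[length(trajs) + 1L]] <- traj
  }
  replicas <- do.call(rbind, rows)
  n_eff <- length(values)
  summary <- if (n_eff >= 1) {
    aggregate_replicas(values, kind = if (config$mode == "flooding")
      "geometric" else "arithmetic")
  } else NULL
  out <- structure(list(
    replicas = replicas, values = values, summary = summary,
    ecd = if (n_eff >= 1) ecd(values) else NULL,
    exponentiality = if (n_eff >= 5) exponentiality_check(values) else NULL,
    n_effective = n_eff, log = logs, config = config, trajectories = trajs),
    class = "campaign")
  if (!is.null(config$out_dir)) write_campaign(out, config$out_dir)
  out
}

#' @export
print.campaign <- function(x, ...) {
  cat(sprintf("<campaign> mode %s, %d/%d effective replicas\n",
              x$config$mode, x$n_effective, x$config$n_replicas))
  if (!is.null(x$summary)) print(x$summary)
  invisible(x)
}

write_campaign <- function(campaign, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (j in seq_along(campaign$trajectories)) {
    traj <- campaign$trajectories[[j]]
    write_colvar(traj, file.path(out_dir, sprintf("COLVAR.%d", j)))
    write_hills(traj_hills(traj), file.path(out_dir, sprintf("HILLS.%d", j)))
  }
  write.table(campaign$replicas, file.path(out_dir, "replicas.csv"),
              sep = ",", row.names = FALSE, quote = FALSE)
  writeLines(campaign$log, file.path(out_dir, "campaign.log"))
  jsonlite::write_json(campaign_report_list(campaign),
                       file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

campaign_report_list <- function(campaign, fit = NULL) {
  s <- campaign$summary
  rep <- list(
    mode = campaign$config$mode,
    n_replicas = campaign$config$n_replicas,
    n_effective = campaign$n_effective,
    base_seed = campaign$config$base_seed,
    units = if (campaign$config$mode == "flooding")
      "RT_calcd in minutes; mean on log10 scale" else "t_META-D in ns")
  if (!is.null(s)) {
    rep$mean <- s$mean
    rep$sem <- s$sem
    rep$tau <- s$tau
    rep$values <- campaign$values
  }
  if (!is.null(campaign$exponentiality)) {
    rep$exponentiality <- campaign$exponentiality[c("statistic", "p_value")]
  }
  if (!is.null(campaign$ecd)) {
    rep$ecd <- list(value = campaign$ecd$value, prob = campaign$ecd$prob)
  }
  if (!is.null(fit)) {
    stopifnot(inherits(fit, "skr_fit"))
    x_new <- s$mean   # log10 tau (flooding) or mean t_META-D (tmetad)
    pred <- predict(fit, x_new)
    rep$skr_prediction <- list(descriptor = x_new,
                               log_rt_pred = pred$y_pred,
                               slope = fit$slope, intercept = fit$intercept)
  }
  rep
}

#' Campaign report
#'
#' Human-readable and JSON-serializable summary of a campaign; when an
#' SKR fit is supplied, the campaign's descriptor is pushed through it
#' to give a predicted experimental log RT for the simulated "compound".
#'
#' @param campaign a [run_campaign()] result.
#' @param skr_fit optional [fit_skr()] model.
#' @param path optional path for a JSON copy.
#' @return the report, as a list (class `campaign_report`).
#' @export
report <- function(campaign, skr_fit = NULL, path = NULL) {
  stopifnot(inherits(campaign, "campaign"))
  rep <- campaign_report_list(campaign, fit = skr_fit)
  if (!is.null(path)) {
    jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  structure(rep, class = "campaign_report")
}

#' @export
print.campaign_report <- function(x, ...) {
  cat(sprintf("Campaign (%s): n = %d effective of %d\n", x$mode,
              x$n_effective, x$n_replicas))
  if (!is.null(x$mean))
    cat(sprintf("  mean = %.4g +- %.3g; tau = %.4g (%s)\n",
                x$mean, x$sem, x$tau, x$units))
  if (!is.null(x$exponentiality))
    cat(sprintf("  exponentiality: D = %.3f, p = %.3f\n",
                x$exponentiality$statistic, x$exponentiality$p_value))
  if (!is.null(x$skr_prediction))
    cat(sprintf("  SKR prediction: log RT = %.3f\n",
                x$skr_prediction$log_rt_pred))
  invisible(x)
}
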