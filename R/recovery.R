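#' Acceleration factor alpha
#'
#' Running average over deposition records of `exp(beta V(s(t), t))`,
#' the conformational-flooding acceleration factor: `alpha(t_k)` is the
#' mean of the boosted Boltzmann weights of the bias experienced up to
#' time `t_k`. Accumulation is done in log space (shifted-exponential
#' running mean) so the series stays finite even when `beta V` is large.
#' `beta` uses the physical simulation temperature, not the boosted one.
#'
#' @param traj a `metad_trajectory` (non-empty).
#' @param beta inverse temperature in mol/kcal; defaults to the
#'   trajectory's own simulation temperature.
#' @return object of class `alpha_series`: a data frame with columns
#'   `time` (ps), `log_alpha` (natural log), `alpha`, `bound`.
#' @export
acceleration_factor <- function(traj, beta = NULL) {
  stopifnot(inherits(traj, "metad_trajectory"))
  r <- traj$records
  if (nrow(r) == 0L)
    stop("invalid input: empty trajectory", call. = FALSE)
  if (is.null(beta)) beta <- beta_from_temperature(traj$temperature)
  v <- r$bias
  if (any(!is.finite(v)) || any(v < 0))
    stop("invalid input: bias values must be finite and >= 0", call. = FALSE)
  la <- cumulative_logmeanexp(beta * v)
  out <- data.frame(time = r$time, log_alpha = la, alpha = exp(la),
                    bound = !r$unbound)
  class(out) <- c("alpha_series", "data.frame")
  out
}

## log of the running mean of exp(x), computed stably:
## m_k = max(x_1..x_k); log mean = m_k + log(sum exp(x_i - m_k)) - log k
cumulative_logmeanexp <- function(x) {
  n <- length(x)
  out <- numeric(n)
  m <- -Inf; s <- 0      # s = sum exp(x_i - m)
  for (k in seq_len(n)) {
    if (x[k] > m) {
      s <- s * exp(m - x[k]) + 1
      m <- x[k]
    } else {
      s <- s + exp(x[k] - m)
    }
    out[k] <- m + log(s) - log(k)
  }
  out
}

#' Transition time from an alpha series
#'
#' The transition out of the bound basin is read off the alpha series as
#' the time of its global maximum (for a unimodal series this is where
#' the sign of d(alpha)/dt flips). Ties take the earliest time. When the
#' maximum sits at the final record the series is still rising and no
#' transition was observed: `converged = FALSE`.
#'
#' @param series an [acceleration_factor()] result (length >= 2).
#' @return list with `t_star` (ps), `alpha_max`, `log_alpha_max` and
#'   `converged`.
#' @export
transition_time <- function(series) {
  stopifnot(inherits(series, "alpha_series"), nrow(series) >= 2)
  k <- which.max(series$log_alpha)   # earliest on ties
  list(t_star = series$time[k],
       alpha_max = series$alpha[k],
       log_alpha_max = series$log_alpha[k],
       converged = k < nrow(series))
}

#' Calculated residence time RT = alpha x t
#'
#' @param alpha_max peak acceleration factor (>= 1 for non-negative
#'   bias).
#' @param t_star transition time, ps (> 0).
#' @param log_alpha_max optional natural log of `alpha_max`, used for the
#'   log-scale outputs when `alpha_max` overflows.
#' @param converged logical convergence flag, carried through.
#' @return object of class `rt_estimate`: list with `rt_ps`, `rt_min`,
#'   `log10_rt_min`, `alpha_max`, `t_star`, `converged`.
#' @export
rt_calcd <- function(alpha_max, t_star, log_alpha_max = NULL,
                     converged = TRUE) {
  if (is.null(log_alpha_max)) log_alpha_max <- log(alpha_max)
  if (!is.finite(log_alpha_max) || alpha_max < 1 || t_star <= 0)
    stop("invalid input: need alpha_max >= 1 and t_star > 0", call. = FALSE)
  log10_rt_ps <- log_alpha_max / log(10) + log10(t_star)
  structure(list(rt_ps = alpha_max * t_star,
                 rt_min = 10^(log10_rt_ps - log10(PS_PER_MIN)),
                 log10_rt_min = log10_rt_ps - log10(PS_PER_MIN),
                 alpha_max = alpha_max, t_star = t_star,
                 converged = converged),
            class = "rt_estimate")
}

#' Full conformational-flooding estimate for one trajectory
#'
#' Convenience wrapper: alpha series, transition detection and
#' RT = alpha_max x t_star in one call.
#'
#' @inheritParams acceleration_factor
#' @return an `rt_estimate` (see [rt_calcd()]).
#' @export
rt_estimate <- function(traj, beta = NULL) {
  a <- acceleration_factor(traj, beta)
  tt <- transition_time(a)
  rt_calcd(tt$alpha_max, tt$t_star, log_alpha_max = tt$log_alpha_max,
           converged = tt$converged)
}

#' t_META-D descriptor
#'
#' Simulation time at which the ligand first satisfies the unbound
#' criterion in a constant-height metadynamics run. Runs that never
#' reach the unbound state are flagged as censored.
#'
#' @param traj a `metad_trajectory` from a plain (non-well-tempered)
#'   run.
#' @return list with `t_metad_ns`, `time_ps`, `censored`, `status`.
#' @export
t_metad <- function(traj) {
  stopifnot(inherits(traj, "metad_trajectory"))
  r <- traj$records
  k <- which(r$unbound)[1]
  if (is.na(k)) {
    return(list(t_metad_ns = NA_real_, time_ps = NA_real_,
                censored = TRUE, status = traj$status))
  }
  list(t_metad_ns = r$time[k] / PS_PER_NS, time_ps = r$time[k],
       censored = FALSE, status = traj$status)
}
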