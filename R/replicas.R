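#' Replica aggregation
#'
#' Summarizes per-replica kinetic estimates. For residence times the
#' representative parameter is the geometric mean tau, computed as the
#' mean of log10 values, with the SEM of the log10 values (sample
#' standard deviation over sqrt(n)); for the t_META-D descriptor the
#' plain arithmetic mean +- SEM is conventional.
#'
#' @param values positive per-replica values (minutes for RT, ns for
#'   t_META-D).
#' @param kind `"geometric"` (default; RT aggregation) or
#'   `"arithmetic"`.
#' @return object of class `replica_summary`: list with `n`, `values`,
#'   `mean` (log10 minutes for geometric, linear for arithmetic),
#'   `sem`, `tau` (geometric mean on the linear scale; equals `mean`
#'   for arithmetic), `kind`.
#' @export
aggregate_replicas <- function(values, kind = c("geometric", "arithmetic")) {
  kind <- match.arg(kind)
  values <- as.numeric(values)
  if (length(values) == 0L || any(!is.finite(values)) || any(values <= 0))
    stop("invalid input: replica values must be finite and positive",
         call. = FALSE)
  n <- length(values)
  if (kind == "geometric") {
    lv <- log10(values)
    m <- mean(lv)
    sem <- if (n > 1) sd(lv) / sqrt(n) else NA_real_
    tau <- 10^m
  } else {
    m <- mean(values)
    sem <- if (n > 1) sd(values) / sqrt(n) else NA_real_
    tau <- m
  }
  structure(list(n = n, values = values, mean = m, sem = sem, tau = tau,
                 kind = kind),
            class = "replica_summary")
}

#' @export
print.replica_summary <- function(x, ...) {
  unit <- if (x$kind == "geometric") "log10 units" else "linear units"
  cat(sprintf("<replica_summary> n = %d, mean = %.3g +- %.3g (%s), tau = %.4g\n",
              x$n, x$mean, x$sem, unit, x$tau))
  invisible(x)
}

#' Empirical cumulative distribution
#'
#' @param values non-empty numeric vector.
#' @return data frame with sorted `value` and probabilities
#'   `prob = i/n`; duplicated values appear as repeated rows (a vertical
#'   step of height k/n).
#' @export
ecd <- function(values) {
  stopifnot(length(values) >= 1)
  v <- sort(as.numeric(values))
  data.frame(value = v, prob = seq_along(v) / length(v))
}

#' Poisson (exponential) cumulative curve
#'
#' Theoretical rare-event CDF `P(x) = 1 - exp(-x / theta)`. Two
#' application modes are provided because published comparisons divide
#' by log tau: `"standard"` treats `x` and `theta` on the linear scale
#' (the exponential CDF of the rare-event law); `"as_printed"` applies
#' the same formula with `x = log10 RT` and `theta = log10 tau`. The
#' mode is recorded on the result.
#'
#' @param x evaluation points (>= 0).
#' @param theta characteristic parameter (> 0).
#' @param mode `"standard"` or `"as_printed"`.
#' @return numeric probabilities with attribute `mode`.
#' @export
poisson_cdf <- function(x, theta, mode = c("standard", "as_printed")) {
  mode <- match.arg(mode)
  stopifnot(theta > 0, all(x >= 0))
  structure(1 - exp(-x / theta), mode = mode)
}

#' Exponentiality check of replica transition times
#'
#' One-sample Kolmogorov-Smirnov statistic of the values against the
#' exponential CDF with the rate fitted by the sample mean, with the
#' asymptotic p-value. Because the rate is estimated from the same
#' sample the p-value is conservative (biased upward relative to a
#' Lilliefors-corrected test); this is the documented approximation.
#'
#' @param values positive sample, n >= 5.
#' @return list with `statistic`, `p_value`, `n`, `rate`.
#' @export
exponentiality_check <- function(values) {
  values <- as.numeric(values)
  stopifnot(length(values) >= 5, all(values > 0))
  rate <- 1 / mean(values)
  ks <- suppressWarnings(ks.test(values, "pexp", rate = rate, exact = FALSE))
  list(statistic = unname(ks$statistic), p_value = ks$p.value,
       n = length(values), rate = rate)
}

#' Unpaired two-sample Student's t-test
#'
#' Classic pooled-variance t-test with significance stars
#' (`***` p < 0.001, `**` p < 0.01, `*` p < 0.05). Degenerate samples
#' with zero pooled variance give t = 0 (equal means) or an infinite
#' t (unequal means) rather than an error.
#'
#' @param a,b numeric samples, each of length >= 2.
#' @return list with `t`, `dof`, `p_value`, `stars`.
#' @export
unpaired_t_test <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  stopifnot(length(a) >= 2, length(b) >= 2)
  na <- length(a); nb <- length(b)
  dof <- na + nb - 2
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / dof
  dm <- mean(a) - mean(b)
  if (sp2 == 0) {
    t <- if (dm == 0) 0 else sign(dm) * Inf
    p <- if (dm == 0) 1 else 0
  } else {
    t <- dm / sqrt(sp2 * (1 / na + 1 / nb))
    p <- 2 * pt(-abs(t), dof)
  }
  list(t = t, dof = dof, p_value = p, stars = stars_for_p(p))
}

stars_for_p <- function(p) {
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else "ns"
}
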