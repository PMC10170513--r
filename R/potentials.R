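#' Analytic toy potentials
#'
#' Reduced free-energy surfaces with known kinetics, used as stand-ins
#' for the protein-ligand unbinding landscape. The 1-D double well
#' `V(x) = h ((x/xm)^2 - 1)^2` has minima at x = -xm (the "bound" basin)
#' and x = +xm (the "unbound" basin, V = 0) separated by a barrier of
#' height `h` at x = 0; equivalently `a x^4 - b x^2 + c` with
#' `a = h/xm^4`, `b = 2h/xm^2`, `c = h`.
#'
#' @param family `"double_well"`, `"harmonic"` or `"flat"`.
#' @param barrier barrier height h in kcal/mol (double well).
#' @param x_min half-separation xm of the minima, Angstrom (double well).
#' @param k force constant, kcal mol^-1 A^-2 (harmonic).
#' @param x0 center of the harmonic well, Angstrom.
#' @return object of class `analytic_potential`.
#' @examples
#' pot <- analytic_potential("double_well", barrier = 4, x_min = 1.5)
#' potential_energy(pot, 0)$energy  # the barrier top
#' @export
analytic_potential <- function(family = c("double_well", "harmonic", "flat"),
                               barrier = 4, x_min = 1.5, k = 1, x0 = 0) {
  family <- match.arg(family)
  p <- switch(family,
    flat = list(code = 0L, params = c(0, 0)),
    harmonic = {
      stopifnot(k > 0)
      list(code = 1L, params = c(k, x0))
    },
    double_well = {
      stopifnot(barrier > 0, x_min > 0)
      list(code = 2L, params = c(barrier, x_min))
    })
  structure(list(family = family, code = p$code, params = p$params,
                 barrier = if (family == "double_well") barrier else NA_real_,
                 x_min = if (family == "double_well") x_min else NA_real_),
            class = "analytic_potential")
}

#' Potential energy and analytic force
#'
#' @param potential an [analytic_potential()].
#' @param x position(s), Angstrom.
#' @return list with numeric `energy` (kcal/mol) and `force`
#'   (kcal mol^-1 A^-1, the negative gradient), vectorized over `x`.
#' @export
potential_energy <- function(potential, x) {
  stopifnot(inherits(potential, "analytic_potential"))
  p <- potential$params
  switch(potential$family,
    flat = list(energy = rep(0, length(x)), force = rep(0, length(x))),
    harmonic = list(energy = 0.5 * p[1] * (x - p[2])^2,
                    force = -p[1] * (x - p[2])),
    double_well = {
      u <- x / p[2]
      q <- u^2 - 1
      list(energy = p[1] * q^2, force = -4 * p[1] * q * u / p[2])
    })
}

#' Langevin dynamics parameters
#'
#' Overdamped (Brownian) dynamics: the propagator is the Euler-Maruyama
#' update `x <- x + F dt / (gamma m) + sqrt(2 kB T dt / (gamma m)) eta`
#' with standard-normal `eta`, so the diffusion coefficient is
#' `D = kB T / (gamma m)`.
#'
#' @param temperature physical temperature, K.
#' @param friction gamma, ps^-1.
#' @param timestep dt, ps.
#' @param mass particle mass, amu.
#' @return object of class `langevin_params`.
#' @export
langevin_params <- function(temperature = 300, friction = 10,
                            timestep = 0.002, mass = 1) {
  stopifnot(temperature > 0, friction > 0, timestep > 0, mass > 0)
  structure(list(temperature = temperature, friction = friction,
                 timestep = timestep, mass = mass,
                 kT = KB_KCAL * temperature,
                 beta = 1 / (KB_KCAL * temperature)),
            class = "langevin_params")
}

#' Simulate overdamped Langevin dynamics
#'
#' Propagates a particle on an analytic potential, optionally under an
#' external bias. With no bias (or a [hills()] bias on the coordinate
#' itself) the inner loop runs in compiled code; an arbitrary
#' `bias_provider` closure falls back to an R loop.
#'
#' @param potential an [analytic_potential()].
#' @param params a [langevin_params()].
#' @param n_steps number of steps.
#' @param x0 initial position.
#' @param seed integer seed (randomness is drawn from R's RNG).
#' @param bias_provider `NULL`, or a function `f(x)` returning the bias
#'   force at `x` (kcal mol^-1 A^-1).
#' @param sample_every keep every k-th position.
#' @return numeric vector of sampled positions (the position after steps
#'   `sample_every, 2*sample_every, ...`).
#' @export
simulate_langevin <- function(potential, params, n_steps, x0 = 0,
                              seed = NULL, bias_provider = NULL,
                              sample_every = 1L) {
  stopifnot(inherits(potential, "analytic_potential"),
            inherits(params, "langevin_params"), n_steps >= 1)
  if (!is.null(seed)) set.seed(seed)
  fric <- params$friction * params$mass
  if (is.null(bias_provider)) {
    return(cpp_langevin_1d(x0, potential$code, potential$params,
                           params$timestep, fric, params$kT,
                           as.integer(n_steps), as.integer(sample_every)))
  }
  ## generic R path for closure-valued bias forces
  mob <- params$timestep / fric
  noise <- sqrt(2 * params$kT * params$timestep / fric)
  x <- x0
  out <- numeric(floor(n_steps / sample_every))
  j <- 0L
  for (i in seq_len(n_steps)) {
    f <- potential_energy(potential, x)$force + bias_provider(x)
    x <- x + f * mob + noise * rnorm(1)
    if (!is.finite(x)) stop("numerical failure: non-finite position", call. = FALSE)
    if (i %% sample_every == 0L) { j <- j + 1L; out[j] <- x }
  }
  out
}

#' Unbiased mean first-passage time (reference oracle)
#'
#' Brute-force estimate of the mean first-passage time from `x0` to an
#' absorbing boundary over independent unbiased Langevin replicas. This
#' is the unbiased control against which biased residence-time estimates
#' are validated; it is only feasible when the barrier is low enough for
#' spontaneous escapes within the per-replica cap.
#'
#' @inheritParams simulate_langevin
#' @param n_replicas number of independent first-passage runs.
#' @param absorbing_boundary escape is recorded at the first step with
#'   `x >= absorbing_boundary`.
#' @param max_steps per-replica step cap; replicas that never escape
#'   raise a censoring error.
#' @return list with `mfpt` (ps), `stderr` (ps), `times` (per-replica
#'   first-passage times, ps) and `n`.
#' @export
reference_mfpt <- function(potential, params, n_replicas = 10,
                           absorbing_boundary, x0, seed = 1,
                           max_steps = 5e8) {
  stopifnot(inherits(potential, "analytic_potential"),
            inherits(params, "langevin_params"), n_replicas >= 1)
  set.seed(seed)
  fric <- params$friction * params$mass
  steps <- vapply(seq_len(n_replicas), function(i) {
    cpp_fpt_1d(x0, potential$code, potential$params, params$timestep,
               fric, params$kT, absorbing_boundary, max_steps)
  }, numeric(1))
  censored <- sum(steps < 0)
  if (censored > 0) {
    stop(sprintf("censoring: %d of %d replicas did not escape within the cap",
                 censored, n_replicas), call. = FALSE)
  }
  times <- steps * params$timestep
  list(mfpt = mean(times),
       stderr = if (n_replicas > 1) sd(times) / sqrt(n_replicas) else NA_real_,
       times = times, n = n_replicas)
}

#' Kramers high-friction escape-time estimate
#'
#' Closed-form overdamped escape time over a parabolic barrier,
#' `tau = 2 pi gamma m / sqrt(V''_min |V''_barrier|) * exp(barrier / kT)`,
#' used as an independent order-of-magnitude oracle for the double well.
#'
#' @param potential a double-well [analytic_potential()].
#' @param params a [langevin_params()].
#' @return escape time in ps.
#' @export
kramers_time <- function(potential, params) {
  stopifnot(potential$family == "double_well")
  h <- potential$barrier; xm <- potential$x_min
  curv_min <- 8 * h / xm^2      # V'' at x = +-xm
  curv_top <- 4 * h / xm^2      # |V''| at x = 0
  fric <- params$friction * params$mass
  2 * pi * fric / sqrt(curv_min * curv_top) * exp(h / params$kT)
}
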