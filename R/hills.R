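#' Gaussian hill list
#'
#' Container for deposited metadynamics hills: one row per hill with the
#' deposit time (ps), the center in CV space, per-CV widths sigma and the
#' deposited height (kcal/mol). Stored as a plain data frame with columns
#' `time`, `center_1..n`, `sigma_1..n`, `height` plus attributes carrying
#' CV periodicity, so it maps one-to-one onto HILLS-style columnar files.
#'
#' @param centers numeric matrix (hills x n_cv) of hill centers, or a
#'   vector for 1-D.
#' @param sigmas numeric matrix like `centers` (or vector, recycled) of
#'   strictly positive widths.
#' @param heights numeric vector of hill heights (>= 0), kcal/mol.
#' @param times numeric vector of deposit times, ps.
#' @param periodic logical per-CV periodicity flags.
#' @param period numeric per-CV periods (NA for aperiodic CVs).
#' @param biasf bias factor (1 + DeltaT/T0) recorded for HILLS output;
#'   NA when not well-tempered.
#' @return object of class `hills` (a data frame).
#' @export
hills <- function(centers, sigmas, heights, times,
                  periodic = NULL, period = NULL, biasf = NA_real_) {
  if (is.null(dim(centers))) centers <- matrix(centers, ncol = 1)
  ncv <- ncol(centers)
  n <- nrow(centers)
  if (is.null(dim(sigmas))) {
    sigmas <- matrix(rep_len(sigmas, ncv), n, ncv, byrow = TRUE)
  }
  stopifnot(ncol(sigmas) == ncv, nrow(sigmas) == n,
            length(heights) == n, length(times) == n)
  if (any(sigmas <= 0)) stop("hill widths must be strictly positive", call. = FALSE)
  if (any(heights < 0)) stop("hill heights must be >= 0", call. = FALSE)
  if (is.null(periodic)) periodic <- rep(FALSE, ncv)
  if (is.null(period)) period <- ifelse(periodic, 360, NA_real_)
  df <- data.frame(time = as.numeric(times))
  for (i in seq_len(ncv)) df[[paste0("center_", i)]] <- centers[, i]
  for (i in seq_len(ncv)) df[[paste0("sigma_", i)]] <- sigmas[, i]
  df$height <- as.numeric(heights)
  structure(df, class = c("hills", "data.frame"),
            ncv = ncv, periodic = periodic, period = period,
            biasf = as.numeric(biasf))
}

#' Empty hill list
#' @param ncv number of collective variables.
#' @inheritParams hills
#' @export
empty_hills <- function(ncv = 1, periodic = NULL, period = NULL,
                        biasf = NA_real_) {
  hills(matrix(numeric(0), 0, ncv), matrix(numeric(0), 0, ncv),
        numeric(0), numeric(0), periodic = periodic, period = period,
        biasf = biasf)
}

hills_centers <- function(h) {
  as.matrix(h[paste0("center_", seq_len(attr(h, "ncv")))])
}
hills_sigmas <- function(h) {
  as.matrix(h[paste0("sigma_", seq_len(attr(h, "ncv")))])
}

## displacement s - c, wrapped into (-period/2, period/2] on periodic CVs
wrap_delta <- function(delta, periodic, period) {
  if (!any(periodic)) return(delta)
  for (i in which(periodic)) {
    p <- period[i]
    delta[, i] <- delta[, i] - p * round(delta[, i] / p)
  }
  delta
}

#' Accumulated bias potential V(s)
#'
#' Sum over deposited hills of multidimensional product Gaussians,
#' `V(s) = sum_j h_j prod_i exp(-d_ij^2 / (2 sigma_ij^2))`, with the
#' displacement `d` wrapped on periodic CVs.
#'
#' @param h a [hills()] object.
#' @param s numeric CV vector (length = n_cv).
#' @param deriv logical; also return the gradient dV/ds as attribute
#'   `"gradient"`.
#' @return bias in kcal/mol (>= 0).
#' @export
bias_value <- function(h, s, deriv = FALSE) {
  stopifnot(inherits(h, "hills"))
  ncv <- attr(h, "ncv")
  if (length(s) != ncv)
    stop("configuration error: CV dimensionality mismatch", call. = FALSE)
  if (nrow(h) == 0L) {
    v <- 0
    if (deriv) attr(v, "gradient") <- numeric(ncv)
    return(v)
  }
  centers <- hills_centers(h)
  sigmas <- hills_sigmas(h)
  delta <- matrix(s, nrow(h), ncv, byrow = TRUE) - centers
  delta <- wrap_delta(delta, attr(h, "periodic"), attr(h, "period"))
  z <- delta / sigmas
  g <- h$height * exp(-rowSums(z^2) / 2)   # per-hill contribution
  v <- sum(g)
  if (deriv) {
    grad <- colSums(g * (-delta / sigmas^2))
    attr(v, "gradient") <- as.numeric(grad)
  }
  v
}

#' Well-tempered metadynamics parameters
#'
#' @param omega0 initial hill height, kcal/mol.
#' @param kb_deltaT bias factor k_B * DeltaT in kcal/mol (the "kT"
#'   parameter; 10 kcal/mol corresponds to DeltaT of about 5000 K).
#' @param enabled logical; `FALSE` gives plain constant-height
#'   metadynamics.
#' @return object of class `wt_params`.
#' @export
wt_params <- function(omega0 = 0.40, kb_deltaT = 10, enabled = TRUE) {
  stopifnot(omega0 > 0)
  if (enabled) stopifnot(kb_deltaT > 0)
  structure(list(omega0 = omega0, kb_deltaT = kb_deltaT, enabled = enabled),
            class = "wt_params")
}

#' Well-tempered hill height
#'
#' Height of the next hill given the accumulated bias at the deposition
#' point: `omega0 * exp(-V / (kB DeltaT))` under well-tempering, a
#' constant `omega0` otherwise.
#'
#' @param v_at_center accumulated bias V at the hill center, kcal/mol.
#' @param params a [wt_params()].
#' @return height in kcal/mol, in (0, omega0].
#' @export
next_hill_height <- function(v_at_center, params) {
  stopifnot(inherits(params, "wt_params"))
  if (!is.finite(v_at_center) || v_at_center < 0)
    stop("invariant violation: accumulated bias must be finite and >= 0",
         call. = FALSE)
  if (!params$enabled) return(params$omega0)
  params$omega0 * exp(-v_at_center / params$kb_deltaT)
}

#' One-sided harmonic restraint on a CV
#'
#' A `lower_floor` penalizes excursions below `location` (e.g. the 15 A
#' floor on the pulling distance that keeps the ligand from an erratic
#' intracellular exit); an `upper_wall` penalizes excursions above it
#' (e.g. the 3 A cap on a binding-site RMSD).
#'
#' @param cv_index 1-based index of the restrained CV.
#' @param kind `"lower_floor"` or `"upper_wall"`.
#' @param location restraint location in CV units.
#' @param force_constant k in kcal mol^-1 unit^-2 (> 0).
#' @return object of class `wall_spec`.
#' @export
wall_spec <- function(cv_index, kind = c("lower_floor", "upper_wall"),
                      location, force_constant = 10) {
  kind <- match.arg(kind)
  stopifnot(cv_index >= 1, force_constant > 0)
  structure(list(cv_index = as.integer(cv_index), kind = kind,
                 location = location, force_constant = force_constant),
            class = "wall_spec")
}

#' Wall restraint energy
#'
#' Half-harmonic: `k (x - loc)^2` on the forbidden side of each wall,
#' zero elsewhere.
#'
#' @param s CV vector.
#' @param walls list of [wall_spec()]s.
#' @param deriv logical; attach gradient dE/ds as attribute `"gradient"`.
#' @return energy in kcal/mol.
#' @export
wall_energy <- function(s, walls, deriv = FALSE) {
  e <- 0
  grad <- numeric(length(s))
  for (w in walls) {
    stopifnot(inherits(w, "wall_spec"))
    if (w$cv_index > length(s))
      stop("configuration error: wall cv_index beyond CV set", call. = FALSE)
    x <- s[w$cv_index]
    d <- x - w$location
    viol <- if (w$kind == "lower_floor") d < 0 else d > 0
    if (viol) {
      e <- e + w$force_constant * d^2
      grad[w$cv_index] <- grad[w$cv_index] + 2 * w$force_constant * d
    }
  }
  if (deriv) attr(e, "gradient") <- grad
  e
}
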