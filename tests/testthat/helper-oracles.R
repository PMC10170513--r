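## Independent oracles kept deliberately separate from the package
## implementations they check.

## Torsion by the acos-of-plane-normals formula with the sign taken from
## the triple product (different formulation from the package's atan2).
torsion_oracle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  xp <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  n1 <- xp(b1, b2); n2 <- xp(b2, b3)
  ct <- sum(n1 * n2) / sqrt(sum(n1^2) * sum(n2^2))
  ang <- acos(min(1, max(-1, ct))) * 180 / pi
  if (sum(xp(n1, n2) * b2) < 0) ang <- -ang
  ang
}

## Exhaustive pair scan for the minimum inter-group distance.
min_dist_oracle <- function(fr, ia, ib) {
  best <- Inf
  for (i in ia) for (j in ib) {
    d <- sqrt(sum((fr$coords[i, ] - fr$coords[j, ])^2))
    if (d < best) best <- d
  }
  best
}

## Exact 1-D overdamped mean first-passage time by double quadrature:
## MFPT(x0 -> b) = (1/D) int_x0^b dy e^{V(y)/kT} int_{-inf}^y e^{-V(z)/kT} dz
mfpt_quadrature <- function(system, boundary, lower = -6) {
  kT <- system$params$kT
  D <- kT / (system$params$friction * system$params$mass)
  V <- function(x) potential_energy(system$potential, x)$energy
  inner <- function(y) {
    integrate(function(z) exp(-V(z) / kT), lower, y, rel.tol = 1e-9)$value
  }
  f <- Vectorize(function(y) exp(V(y) / kT) * inner(y))
  integrate(f, system$x0, boundary, rel.tol = 1e-8)$value / D
}

## random rotation matrix (QR of a Gaussian matrix, det +1)
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

## a fake metadynamics trajectory carrying prescribed bias records, for
## exercising the recovery layer in isolation
fake_traj <- function(bias, times = seq_along(bias), unbound = NULL,
                      temperature = 300, status = "unbound") {
  if (is.null(unbound)) unbound <- rep(FALSE, length(bias))
  n <- length(bias)
  structure(list(
    records = data.frame(time = times, cv_1 = rep(0, n), bias = bias,
                         height = rep(0.4, n), unbound = unbound),
    status = status, widths = 0.2, periodic = FALSE, period = NA_real_,
    wt = wt_params(), stride = if (length(times) > 1)
      times[2] - times[1] else 1, temperature = temperature),
    class = "metad_trajectory")
}
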