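#' Collective-variable calculators
#'
#' Center-of-mass (COM) based collective variables: distance, angle,
#' dihedral and RMSD, matching the CV families commonly used to drive
#' ligand unbinding in metadynamics (a pulling COM distance, two angular
#' CVs orthogonal to it, and RMSDs of the binding-site side chains and of
#' the ligand heavy atoms).
#'
#' Angles are reported in degrees: plain angles in [0, 180], dihedrals as
#' signed torsions in (-180, 180] with the IUPAC sign convention
#' (clockwise positive looking from the second to the third COM).
#'
#' @name cv_geometry
NULL

#' Mass-weighted center of mass of a selection
#'
#' @param frame a [frame()].
#' @param group an [atom_group()] (or bare index vector).
#' @return length-3 numeric vector, Angstrom.
#' @export
center_of_mass <- function(frame, group) {
  stopifnot(inherits(frame, "frame"))
  group <- check_group(frame, group)
  idx <- group$indices
  m <- frame$masses[idx]
  colSums(frame$coords[idx, , drop = FALSE] * m) / sum(m)
}

#' COM-COM distance collective variable
#'
#' @inheritParams center_of_mass
#' @param gA,gB the two selections.
#' @return distance in Angstrom (>= 0).
#' @export
cv_distance <- function(frame, gA, gB) {
  d <- center_of_mass(frame, gA) - center_of_mass(frame, gB)
  sqrt(sum(d * d))
}

#' COM angle collective variable
#'
#' Angle at the COM of `g2` formed by the COMs of `g1` and `g3`.
#'
#' @inheritParams center_of_mass
#' @param g1,g2,g3 selections; the vertex is `g2`.
#' @return angle in degrees, in [0, 180].
#' @export
cv_angle <- function(frame, g1, g2, g3) {
  a <- center_of_mass(frame, g1)
  b <- center_of_mass(frame, g2)
  c3 <- center_of_mass(frame, g3)
  u <- a - b
  v <- c3 - b
  nu <- sqrt(sum(u * u)); nv <- sqrt(sum(v * v))
  if (nu == 0 || nv == 0)
    stop("degenerate geometry: coincident COMs in angle CV", call. = FALSE)
  ct <- sum(u * v) / (nu * nv)
  ct <- min(1, max(-1, ct))
  acos(ct) * 180 / pi
}

#' COM dihedral collective variable
#'
#' Signed torsion defined by four COMs, computed with the atan2
#' formulation (numerically stable near 0 and 180 degrees). Sign follows
#' the IUPAC convention: positive for a clockwise rotation of the
#' g1-g2 bond projection when looking from g2 towards g3.
#'
#' @inheritParams center_of_mass
#' @param g1,g2,g3,g4 selections defining the torsion.
#' @return dihedral in degrees, in (-180, 180].
#' @export
cv_dihedral <- function(frame, g1, g2, g3, g4) {
  p1 <- center_of_mass(frame, g1)
  p2 <- center_of_mass(frame, g2)
  p3 <- center_of_mass(frame, g3)
  p4 <- center_of_mass(frame, g4)
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  nb2 <- sqrt(sum(b2 * b2))
  if (nb2 == 0 || sum(n1 * n1) == 0 || sum(n2 * n2) == 0)
    stop("degenerate geometry: collinear COMs in dihedral CV", call. = FALSE)
  x <- sum(n1 * n2)
  y <- sum(cross3(n1, n2) * b2) / nb2
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' RMSD collective variable
#'
#' Root-mean-square deviation of a selection from a reference frame. By
#' default no superposition is performed: when the receptor backbone is
#' held by harmonic positional restraints the lab frame is the natural
#' reference, and the biased RMSD must reflect absolute displacement.
#' Optimal rigid-body superposition (Kabsch) is available via
#' `superpose = TRUE`.
#'
#' @inheritParams center_of_mass
#' @param reference a [frame()] providing coordinates for every index in
#'   `group`.
#' @param superpose logical; superpose `frame` onto `reference` over the
#'   selection before computing the deviation.
#' @return RMSD in Angstrom (>= 0).
#' @export
cv_rmsd <- function(frame, reference, group, superpose = FALSE) {
  stopifnot(inherits(reference, "frame"))
  group <- check_group(frame, group)
  if (max(group$indices) > nrow(reference$coords))
    stop("invalid selection: reference lacks coordinates for group", call. = FALSE)
  x <- frame$coords[group$indices, , drop = FALSE]
  y <- reference$coords[group$indices, , drop = FALSE]
  if (superpose) {
    xc <- sweep(x, 2, colMeans(x))
    yc <- sweep(y, 2, colMeans(y))
    s <- svd(crossprod(xc, yc))
    d <- sign(det(s$v %*% t(s$u)))
    R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
    x <- xc %*% t(R)
    y <- yc
  }
  sqrt(mean(rowSums((x - y)^2)))
}

#' Collective-variable specification
#'
#' Declares one CV so that sets of CVs can be evaluated, biased and
#' serialized uniformly. Distance and RMSD CVs are aperiodic (Angstrom);
#' dihedral CVs are periodic with period 360 degrees.
#'
#' @param kind one of `"distance"`, `"angle"`, `"dihedral"`, `"rmsd"`.
#' @param groups list of [atom_group()]s: 2 for distance, 3 for angle,
#'   4 for dihedral, 1 for rmsd.
#' @param reference reference [frame()], required for `kind = "rmsd"`.
#' @param label optional name used in COLVAR headers.
#' @param superpose passed to [cv_rmsd()].
#' @return an object of class `cv_spec`.
#' @export
cv_spec <- function(kind = c("distance", "angle", "dihedral", "rmsd"),
                    groups, reference = NULL, label = NULL,
                    superpose = FALSE) {
  kind <- match.arg(kind)
  if (inherits(groups, "atom_group")) groups <- list(groups)
  groups <- lapply(groups, as_atom_group)
  need <- c(distance = 2L, angle = 3L, dihedral = 4L, rmsd = 1L)[[kind]]
  if (length(groups) != need)
    stop(sprintf("cv_spec: kind '%s' needs %d group(s), got %d",
                 kind, need, length(groups)), call. = FALSE)
  if (kind == "rmsd") {
    if (is.null(reference) || !inherits(reference, "frame"))
      stop("cv_spec: rmsd needs a reference frame", call. = FALSE)
    if (max(groups[[1L]]$indices) > nrow(reference$coords))
      stop("cv_spec: rmsd reference lacks coordinates for the group",
           call. = FALSE)
  }
  periodic <- kind == "dihedral"
  structure(list(kind = kind, groups = groups, reference = reference,
                 label = if (is.null(label)) kind else label,
                 periodic = periodic, period = if (periodic) 360 else NA_real_,
                 superpose = superpose),
            class = "cv_spec")
}

#' Evaluate one CV spec on a frame
#' @param spec a [cv_spec()].
#' @param frame a [frame()].
#' @return scalar CV value.
#' @export
evaluate_cv <- function(spec, frame) {
  stopifnot(inherits(spec, "cv_spec"))
  g <- spec$groups
  switch(spec$kind,
    distance = cv_distance(frame, g[[1]], g[[2]]),
    angle    = cv_angle(frame, g[[1]], g[[2]], g[[3]]),
    dihedral = cv_dihedral(frame, g[[1]], g[[2]], g[[3]], g[[4]]),
    rmsd     = cv_rmsd(frame, spec$reference, g[[1]], spec$superpose))
}

#' Evaluate an ordered set of CV specs
#'
#' @param frame a [frame()].
#' @param specs list of [cv_spec()]s (possibly empty).
#' @return named numeric vector in spec order, with attributes `periodic`
#'   (logical vector) and `period` (numeric vector, NA when aperiodic).
#' @export
evaluate_cvs <- function(frame, specs) {
  if (inherits(specs, "cv_spec")) specs <- list(specs)
  vals <- vapply(specs, evaluate_cv, numeric(1), frame = frame)
  names(vals) <- vapply(specs, function(s) s$label, character(1))
  attr(vals, "periodic") <- vapply(specs, function(s) s$periodic, logical(1))
  attr(vals, "period") <- vapply(specs, function(s) s$period, numeric(1))
  vals
}

#' Minimum inter-group atomic distance
#'
#' @inheritParams center_of_mass
#' @param gA,gB disjoint selections.
#' @return smallest pairwise distance between members of the two groups.
#' @export
min_intergroup_distance <- function(frame, gA, gB) {
  gA <- check_group(frame, gA); gB <- check_group(frame, gB)
  if (length(intersect(gA$indices, gB$indices)) > 0L)
    stop("invalid selection: groups overlap", call. = FALSE)
  a <- frame$coords[gA$indices, , drop = FALSE]
  b <- frame$coords[gB$indices, , drop = FALSE]
  ## squared distances via the expansion |a-b|^2 = |a|^2 + |b|^2 - 2 a.b
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(max(0, min(d2)))
}

#' Unbound-state detector
#'
#' A ligand is unbound when no receptor atom lies within `cutoff` of any
#' ligand atom, i.e. the minimum ligand-receptor inter-atomic distance
#' exceeds the cutoff (default 5 Angstrom, the fully-solvated criterion).
#'
#' @inheritParams center_of_mass
#' @param ligand,receptor disjoint [atom_group()]s.
#' @param cutoff contact cutoff in Angstrom.
#' @return logical flag.
#' @export
is_unbound <- function(frame, ligand, receptor, cutoff = 5) {
  min_intergroup_distance(frame, ligand, receptor) > cutoff
}
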