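#' Coordinate frame
#'
#' A frame holds particle coordinates (Angstrom) and per-particle masses
#' (amu); it is the substrate on which all collective variables are
#' evaluated.
#'
#' @param coords numeric matrix with one row per particle and 3 columns
#'   (x, y, z), or a numeric length-3 vector for a single particle.
#' @param masses numeric vector of strictly positive masses, recycled to
#'   the number of particles; defaults to unit masses.
#' @param time time stamp in ps.
#' @return an object of class `frame`.
#' @examples
#' fr <- frame(rbind(c(0, 0, 0), c(2, 0, 0)))
#' center_of_mass(fr, atom_group(1:2))
#' @export
frame <- function(coords, masses = NULL, time = 0) {
  if (is.null(dim(coords))) coords <- matrix(coords, ncol = 3, byrow = TRUE)
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 3L || nrow(coords) < 1L)
    stop("coords must be an n x 3 matrix with n >= 1", call. = FALSE)
  if (any(!is.finite(coords)))
    stop("coords must be finite", call. = FALSE)
  n <- nrow(coords)
  if (is.null(masses)) masses <- rep(1, n)
  masses <- rep_len(as.numeric(masses), n)
  if (any(!is.finite(masses)) || any(masses <= 0))
    stop("masses must be finite and strictly positive", call. = FALSE)
  structure(list(coords = coords, masses = masses, time = as.numeric(time)),
            class = "frame")
}

#' @export
print.frame <- function(x, ...) {
  cat(sprintf("<frame> %d particles, t = %g ps\n", nrow(x$coords), x$time))
  invisible(x)
}

#' Particle selection
#'
#' @param indices integer vector of particle indices (1-based, unique).
#' @return an object of class `atom_group`.
#' @export
atom_group <- function(indices) {
  indices <- as.integer(indices)
  if (length(indices) == 0L)
    stop("invalid selection: empty atom group", call. = FALSE)
  if (anyNA(indices) || any(indices < 1L))
    stop("invalid selection: indices must be positive integers", call. = FALSE)
  if (anyDuplicated(indices))
    stop("invalid selection: duplicate indices", call. = FALSE)
  structure(list(indices = indices), class = "atom_group")
}

as_atom_group <- function(x) {
  if (inherits(x, "atom_group")) x else atom_group(x)
}

check_group <- function(frame, group) {
  group <- as_atom_group(group)
  if (max(group$indices) > nrow(frame$coords))
    stop("invalid selection: index beyond frame bounds", call. = FALSE)
  group
}

#' Apply a rigid-body transform to a frame
#'
#' Utility used mainly in invariance tests: rotates by matrix `R` about the
#' origin then translates by `shift`.
#'
#' @param fr a [frame()].
#' @param R 3x3 rotation matrix (default identity).
#' @param shift length-3 translation vector.
#' @return the transformed frame.
#' @export
transform_frame <- function(fr, R = diag(3), shift = c(0, 0, 0)) {
  stopifnot(inherits(fr, "frame"))
  fr$coords <- fr$coords %*% t(R) + matrix(shift, nrow(fr$coords), 3, byrow = TRUE)
  fr
}
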