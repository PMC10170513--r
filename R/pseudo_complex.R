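#' Pseudo-molecular cage-ligand complex
#'
#' A desk-scale stand-in for a receptor-antagonist complex used to
#' exercise the geometric CVs end to end: a fixed "receptor" made of a
#' binding cage (two particle rings stacked around the exit axis) plus
#' three distal anchor triads about 15 A below it, a rigid "ligand"
#' cluster bound at the cage center, and a binding-funnel potential
#' acting on the ligand center of mass (a double well along the exit
#' axis z, minima at the bound pose and at a dissociated pose, plus a
#' harmonic transverse restraint). The ligand moves as a rigid body
#' (translation only); the receptor is held fixed, mimicking a
#' positionally restrained protein.
#'
#' The returned object carries a 5-CV set structured like a GPCR
#' unbinding protocol: a pulling COM distance to a distal anchor
#' (about 15 A in the bound pose, so the standard 15 A floor applies
#' as-is), a COM angle and dihedral built on the distal triads (far
#' enough away that thermal fluctuations stay within a few degrees),
#' and two RMSDs (binding-site particles, ligand). The first three CVs
#' form the translational set used for t_META-D style runs.
#'
#' @param seed integer seed controlling the small coordinate jitter.
#' @param barrier funnel barrier height, kcal/mol.
#' @param z_out axial position of the dissociated minimum, Angstrom.
#' @param k_perp transverse force constant, kcal mol^-1 A^-2.
#' @param params a [langevin_params()] for the ligand COM dynamics.
#' @return object of class `pseudo_complex` with elements `frame0`,
#'   `cage`, `ligand`, `specs` (list of 5 [cv_spec()]s), and the funnel
#'   parameters.
#' @export
generate_pseudo_complex <- function(seed = 1, barrier = 3, z_out = 10,
                                    k_perp = 2,
                                    params = langevin_params(
                                      friction = 2, timestep = 0.05)) {
  set.seed(seed)
  ang <- seq(0, 2 * pi, length.out = 7)[-7]
  ring <- function(z) cbind(4 * cos(ang), 4 * sin(ang), z)
  cage_xyz <- rbind(ring(-1.5), ring(1.5))
  ## distal anchor triads (the analogue of helix anchors near the far
  ## membrane edge): one below the cage on the exit axis, two off-axis
  triad <- function(center) {
    matrix(center, 3, 3, byrow = TRUE) +
      rbind(c(0.8, 0, 0), c(-0.4, 0.7, 0), c(-0.4, -0.7, 0))
  }
  anchor_xyz <- rbind(triad(c(0, 0, -15)), triad(c(10, 0, -12)),
                      triad(c(0, 10, -12)))
  recept_xyz <- rbind(cage_xyz, anchor_xyz)
  recept_xyz <- recept_xyz + matrix(rnorm(length(recept_xyz), sd = 0.05),
                                    nrow(recept_xyz), 3)
  ## rigid 5-particle ligand: center plus four tetrahedral arms
  arms <- rbind(c(1, 1, 1), c(-1, -1, 1), c(-1, 1, -1), c(1, -1, -1)) / sqrt(3)
  lig_xyz <- rbind(c(0, 0, 0), arms)
  coords <- rbind(recept_xyz, lig_xyz)
  masses <- c(rep(12, nrow(recept_xyz)), rep(12, nrow(lig_xyz)))
  frame0 <- frame(coords, masses)
  n_rec <- nrow(recept_xyz)
  cage <- atom_group(1:12)
  receptor <- atom_group(seq_len(n_rec))
  ligand <- atom_group(n_rec + seq_len(nrow(lig_xyz)))
  g_pull <- atom_group(13:15)            # axial distal triad
  g_side1 <- atom_group(16:18)
  g_side2 <- atom_group(19:21)
  specs <- list(
    cv_spec("distance", list(ligand, g_pull), label = "d_pull"),
    cv_spec("angle", list(ligand, g_pull, g_side1), label = "ang"),
    cv_spec("dihedral", list(ligand, g_pull, g_side1, g_side2),
            label = "dih"),
    cv_spec("rmsd", list(cage), reference = frame0, label = "rmsd_site"),
    cv_spec("rmsd", list(ligand), reference = frame0, label = "rmsd_lig"))
  structure(list(frame0 = frame0, cage = cage, receptor = receptor,
                 ligand = ligand, specs = specs, barrier = barrier,
                 z_out = z_out, k_perp = k_perp, params = params,
                 seed = seed),
            class = "pseudo_complex")
}

#' Frame of a pseudo-complex with the ligand rigidly displaced
#'
#' @param system a [generate_pseudo_complex()] object.
#' @param offset length-3 displacement of the ligand from its bound pose.
#' @param time frame time stamp, ps.
#' @return a [frame()].
#' @export
pseudo_complex_frame <- function(system, offset = c(0, 0, 0), time = 0) {
  fr <- system$frame0
  idx <- system$ligand$indices
  fr$coords[idx, ] <- fr$coords[idx, ] +
    matrix(offset, length(idx), 3, byrow = TRUE)
  fr$time <- time
  fr
}

## funnel energy/force on the ligand COM offset r = (x, y, z)
funnel_force <- function(system, r) {
  zm <- system$z_out / 2
  u <- (r[3] - zm) / zm
  q <- u^2 - 1
  e <- system$barrier * q^2 + 0.5 * system$k_perp * (r[1]^2 + r[2]^2)
  f <- c(-system$k_perp * r[1], -system$k_perp * r[2],
         -4 * system$barrier * q * u / zm)
  list(energy = e, force = f)
}

#' @rdname run_metad
#' @param specs CV set to bias (defaults to the system's 5-CV set).
#' @param unbound_test predicate `f(frame)`; defaults to [is_unbound()]
#'   of the ligand against the whole receptor at a 5 Angstrom cutoff.
#' @export
run_metad.pseudo_complex <- function(system, specs = system$specs,
                                     params = wt_params(), walls = list(),
                                     schedule, widths, seed = 1,
                                     unbound_test = NULL, ...) {
  stopifnot(inherits(params, "wt_params"),
            inherits(schedule, "deposition_schedule"))
  ncv <- length(specs)
  widths <- rep_len(widths, ncv)
  stopifnot(all(widths > 0))
  if (is.null(unbound_test))
    unbound_test <- function(fr) is_unbound(fr, system$ligand,
                                            system$receptor, 5)
  lp <- system$params
  steps_per_stride <- as.integer(round(schedule$stride / lp$timestep))
  if (steps_per_stride < 1)
    stop("configuration error: stride shorter than the timestep", call. = FALSE)
  max_deposits <- as.integer(floor(schedule$max_time / schedule$stride))
  periodic <- vapply(specs, function(s) s$periodic, logical(1))
  period <- vapply(specs, function(s) s$period, numeric(1))
  h <- empty_hills(ncv, periodic = periodic, period = period)
  cvs_at <- function(r) evaluate_cvs(pseudo_complex_frame(system, r), specs)
  ## composite bias + wall energy as a function of the ligand offset;
  ## its numeric gradient supplies the bias force (chain rule through
  ## the CV geometry done by finite differences)
  bias_e <- function(r) {
    s <- cvs_at(r)
    bias_value(h, s) + wall_energy(s, walls)
  }
  bias_f <- function(r, dh = 1e-4) {
    g <- numeric(3)
    for (i in 1:3) {
      rp <- r; rp[i] <- r[i] + dh
      rm <- r; rm[i] <- r[i] - dh
      g[i] <- (bias_e(rp) - bias_e(rm)) / (2 * dh)
    }
    -g
  }
  set.seed(seed)
  fric <- lp$friction * lp$mass
  mob <- lp$timestep / fric
  noise <- sqrt(2 * lp$kT * lp$timestep / fric)
  r <- c(0, 0, 0)
  rec <- vector("list", max_deposits)
  status <- "max_time_reached"
  n_rec <- 0L
  for (k in seq_len(max_deposits)) {
    have_bias <- nrow(h) > 0 || length(walls) > 0
    for (i in seq_len(steps_per_stride)) {
      f <- funnel_force(system, r)$force
      if (have_bias) f <- f + bias_f(r)
      r <- r + f * mob + noise * rnorm(3)
      if (any(!is.finite(r)))
        stop("numerical failure: non-finite position", call. = FALSE)
    }
    t_k <- schedule$stride * k
    s <- cvs_at(r)
    v_here <- bias_value(h, s)
    unb <- unbound_test(pseudo_complex_frame(system, r, t_k))
    n_rec <- k
    if (unb && schedule$stop_on_unbound) {
      rec[[k]] <- c(t_k, s, v_here, 0, 1)
      status <- "unbound"
      break
    }
    hk <- next_hill_height(v_here, params)
    rec[[k]] <- c(t_k, s, v_here, hk, as.numeric(unb))
    h <- rbind_hill(h, s, widths, hk, t_k)
  }
  if (n_rec == 0L) {
    records <- empty_records(ncv)
  } else {
    records <- as.data.frame(do.call(rbind, rec[seq_len(n_rec)]))
    names(records) <- c("time", paste0("cv_", seq_len(ncv)), "bias",
                        "height", "unbound")
    records$unbound <- as.logical(records$unbound)
  }
  new_metad_trajectory(records, status, widths, periodic, period, params,
                       schedule$stride, lp$temperature)
}

empty_records <- function(ncv) {
  df <- data.frame(time = numeric(0))
  for (i in seq_len(ncv)) df[[paste0("cv_", i)]] <- numeric(0)
  df$bias <- numeric(0); df$height <- numeric(0); df$unbound <- logical(0)
  df
}

rbind_hill <- function(h, center, widths, height, time) {
  ncv <- attr(h, "ncv")
  row <- data.frame(time = time)
  for (i in seq_len(ncv)) row[[paste0("center_", i)]] <- center[i]
  for (i in seq_len(ncv)) row[[paste0("sigma_", i)]] <- widths[i]
  row$height <- height
  out <- rbind(as.data.frame(h), row)
  structure(out, class = c("hills", "data.frame"), ncv = ncv,
            periodic = attr(h, "periodic"), period = attr(h, "period"),
            biasf = attr(h, "biasf"))
}

#' Export a pseudo-complex frame as minimal PDB text
#'
#' @param fr a [frame()].
#' @param path output file.
#' @param elements per-particle element symbols (recycled).
#' @return `path`, invisibly.
#' @export
write_pdb <- function(fr, path, elements = "C") {
  stopifnot(inherits(fr, "frame"))
  n <- nrow(fr$coords)
  el <- rep_len(elements, n)
  lines <- sprintf(
    "ATOM  %5d %-4s%-4sA%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
    seq_len(n), substr(el, 1, 4), "UNK", 1L,
    fr$coords[, 1], fr$coords[, 2], fr$coords[, 3], el)
  writeLines(c(lines, "END"), path)
  invisible(path)
}
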