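test_that("bias_value matches Gaussian closed forms", {
  h0 <- empty_hills(1)
  expect_equal(bias_value(h0, 0.3), 0)

  h1 <- hills(0.5, 0.2, 0.40, 1)
  expect_equal(bias_value(h1, 0.5), 0.40)
  expect_equal(bias_value(h1, 0.7), 0.40 * exp(-0.5))

  expect_error(bias_value(h1, c(1, 2)), "dimensionality")

  ## multidimensional product kernel
  h2 <- hills(matrix(c(1, 90), 1, 2), matrix(c(0.2, 1.5), 1, 2), 0.25, 1)
  expect_equal(bias_value(h2, c(1.2, 91.5)),
               0.25 * exp(-0.5) * exp(-0.5))
})

test_that("bias_value is invariant to hill insertion order", {
  set.seed(31)
  n <- 40
  centers <- cbind(rnorm(n), runif(n, -180, 180))
  sig <- matrix(c(0.2, 1.5), n, 2, byrow = TRUE)
  hts <- runif(n, 0.05, 0.4)
  h_fwd <- hills(centers, sig, hts, seq_len(n),
                 periodic = c(FALSE, TRUE), period = c(NA, 360))
  perm <- sample(n)
  h_perm <- hills(centers[perm, ], sig, hts[perm], seq_len(n),
                  periodic = c(FALSE, TRUE), period = c(NA, 360))
  for (s in list(c(0, 0), c(1, 179), c(-2, -179))) {
    expect_equal(bias_value(h_fwd, s), bias_value(h_perm, s),
                 tolerance = 1e-10)
  }
})

test_that("periodic CVs use wrapped displacements", {
  h <- hills(matrix(179, 1, 1), matrix(2, 1, 1), 1, 1,
             periodic = TRUE, period = 360)
  ## -179 deg is 2 deg away from 179 deg across the seam
  expect_equal(bias_value(h, -179), exp(-0.5 * (2 / 2)^2))
  expect_equal(bias_value(h, -1), exp(-0.5 * (180 / 2)^2))
})

test_that("well-tempered height follows the exponential rescaling", {
  wt <- wt_params(omega0 = 0.40, kb_deltaT = 10)
  expect_equal(next_hill_height(0, wt), 0.40)
  expect_equal(next_hill_height(10, wt), 0.40 / exp(1))
  plain <- wt_params(omega0 = 0.25, enabled = FALSE)
  expect_equal(next_hill_height(57.3, plain), 0.25)
  expect_error(next_hill_height(-1, wt), "invariant violation")
  set.seed(1)
  v <- runif(20, 0, 50)
  hts <- vapply(v, next_hill_height, numeric(1), params = wt)
  expect_true(all(hts > 0 & hts <= 0.40))
})

test_that("wall energy is half-harmonic with a consistent gradient", {
  floor15 <- wall_spec(1, "lower_floor", 15, force_constant = 10)
  wall3 <- wall_spec(2, "upper_wall", 3, force_constant = 10)
  walls <- list(floor15, wall3)
  expect_equal(wall_energy(c(16, 0), walls), 0)
  expect_equal(wall_energy(c(14, 0), walls), 10)
  expect_equal(wall_energy(c(16, 3), walls), 0)
  expect_equal(wall_energy(c(14.5, 3.5), walls), 10 * 0.25 + 10 * 0.25)
  ## central finite differences vs analytic gradient
  for (s1 in c(13.7, 15.2)) for (s2 in c(2.2, 3.9)) {
    s <- c(s1, s2)
    g <- attr(wall_energy(s, walls, deriv = TRUE), "gradient")
    for (i in 1:2) {
      hstep <- 1e-6
      sp <- s; sp[i] <- s[i] + hstep
      sm <- s; sm[i] <- s[i] - hstep
      fd <- (wall_energy(sp, walls) - wall_energy(sm, walls)) / (2 * hstep)
      expect_equal(g[i], fd, tolerance = 1e-6)
    }
  }
})

test_that("bias + wall forces agree with finite differences of the energy", {
  set.seed(13)
  n <- 25
  h <- hills(cbind(rnorm(n), rnorm(n, 90, 20)),
             matrix(c(0.2, 1.5), n, 2, byrow = TRUE),
             runif(n, 0.1, 0.4), seq_len(n))
  walls <- list(wall_spec(1, "lower_floor", 0.5, 7),
                wall_spec(2, "upper_wall", 95, 3))
  energy <- function(s) bias_value(h, s) + wall_energy(s, walls)
  for (rep in 1:10) {
    s <- c(rnorm(1), rnorm(1, 90, 25))
    gb <- attr(bias_value(h, s, deriv = TRUE), "gradient")
    gw <- attr(wall_energy(s, walls, deriv = TRUE), "gradient")
    g <- gb + gw
    for (i in 1:2) {
      hstep <- 1e-5
      sp <- s; sp[i] <- s[i] + hstep
      sm <- s; sm[i] <- s[i] - hstep
      fd <- (energy(sp) - energy(sm)) / (2 * hstep)
      denom <- max(abs(fd), 1)   # guard the gradient's zero crossings
      expect_lt(abs(g[i] - fd) / denom, 1e-5)
    }
  }
})

test_that("run_metad honors the schedule and is deterministic", {
  sys <- double_well_fixture(6)
  empty <- run_metad(sys, schedule = deposition_schedule(1, 0), seed = 1)
  expect_equal(nrow(empty$records), 0)
  expect_equal(empty$status, "max_time_reached")

  sch <- deposition_schedule(1, 60)
  t1 <- run_metad(sys, schedule = sch, widths = 0.2, seed = 42)
  t2 <- run_metad(sys, schedule = sch, widths = 0.2, seed = 42)
  expect_identical(t1$records, t2$records)
  t3 <- run_metad(sys, schedule = sch, widths = 0.2, seed = 43)
  expect_false(identical(t1$records, t3$records))
  expect_equal(t1$records$time, seq_len(nrow(t1$records)) * 1)
})

test_that("a confined run never unbinds and its bias grows monotonically", {
  ## barrier too high for the short schedule and unbound test disabled
  pot <- analytic_potential("double_well", barrier = 20, x_min = 1.5)
  sys <- langevin_system(pot, langevin_params(friction = 2,
                                              timestep = 0.001), x0 = -1.5)
  traj <- run_metad(sys, params = wt_params(0.40, 10),
                    schedule = deposition_schedule(1, 150), widths = 0.2,
                    seed = 9)
  expect_equal(traj$status, "max_time_reached")
  expect_false(any(traj$records$unbound))
  total_bias <- cumsum(traj$records$height)
  expect_true(all(diff(total_bias) > 0))
  expect_true(all(traj$records$height <= 0.40))
})

test_that("well-tempered heights decay at a pinned CV point", {
  ## stiff harmonic well pins the particle so every hill lands on the
  ## same spot; with a small bias factor the decay is fast
  pot <- analytic_potential("harmonic", k = 100)
  sys <- langevin_system(pot, langevin_params(friction = 2,
                                              timestep = 0.001), x0 = 0)
  traj <- run_metad(sys, params = wt_params(0.40, kb_deltaT = 1),
                    schedule = deposition_schedule(1, 400), widths = 0.2,
                    seed = 4)
  hts <- traj$records$height
  expect_lt(mean(tail(hts, 20)), 0.1 * mean(head(hts, 20)))
  expect_lt(tail(hts, 1), 0.1 * 0.40)
  ## with well-tempering off the heights stay constant and the deposited
  ## total grows linearly
  plain <- run_metad(sys, params = wt_params(0.25, enabled = FALSE),
                     schedule = deposition_schedule(1, 50), widths = 0.2,
                     seed = 4)
  expect_true(all(plain$records$height == 0.25))
  v_end <- bias_value(traj_hills(plain), 0)
  n <- nrow(plain$records)
  expect_gt(v_end, 0.6 * n * 0.25)   # pinned: strong overlap at the center
  expect_lte(v_end, n * 0.25)
})

test_that("HILLS and COLVAR files round-trip exactly", {
  sys <- double_well_fixture(6)
  traj <- run_metad(sys, schedule = deposition_schedule(1, 40),
                    widths = 0.2, seed = 17)
  h <- traj_hills(traj)
  fh <- tempfile(fileext = ".hills")
  write_hills(h, fh)
  h2 <- read_hills(fh)
  expect_equal(h2, h)
  expect_identical(readLines(fh)[1],
                   "#! FIELDS time center_1 sigma_1 height biasf")

  fc <- tempfile(fileext = ".colvar")
  write_colvar(traj, fc)
  r2 <- read_colvar(fc)
  expect_equal(as.data.frame(r2), as.data.frame(traj$records))

  ## periodic multi-CV hills round-trip with attributes
  hp <- hills(cbind(c(1, 2), c(170, -170)),
              matrix(c(0.2, 1.5), 2, 2, byrow = TRUE), c(0.4, 0.3), 1:2,
              periodic = c(FALSE, TRUE), period = c(NA, 360), biasf = 17.8)
  fp <- tempfile()
  write_hills(hp, fp)
  expect_equal(read_hills(fp), hp)
})

test_that("external COLVAR records can be rebuilt into a trajectory", {
  sys <- double_well_fixture(8)
  traj <- run_metad(sys, schedule = deposition_schedule(1, 2000),
                    widths = 0.2, seed = 23)
  f <- tempfile()
  write_colvar(traj, f)
  rebuilt <- metad_trajectory(read_colvar(f), widths = 0.2,
                              temperature = 300)
  expect_equal(rebuilt$status, traj$status)
  e1 <- rt_estimate(traj)
  e2 <- rt_estimate(rebuilt)
  expect_equal(e2$rt_min, e1$rt_min)
  expect_equal(e2$t_star, e1$t_star)

  bad <- data.frame(time = c(2, 1), cv_1 = 0, bias = 0, height = 0.4,
                    unbound = FALSE)
  expect_error(metad_trajectory(bad), "strictly increasing")
  expect_error(metad_trajectory(data.frame(time = 1)), "records need")
})
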