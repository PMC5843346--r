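# Membrane-binding observables: plane position, z_L-P, dipole tilt, RMSD,
# bound-state histograms, percent eluted

make_flat_frame <- function(p_z_nm, extra = NULL) {
  n <- length(p_z_nm)
  atoms <- data.frame(serial = seq_len(n), name = "P", resname = "LIP",
                      chain = " ", resseq = seq_len(n),
                      x = seq_len(n), y = 0, z = p_z_nm * 10,
                      element = "P", hetero = FALSE)
  if (!is.null(extra)) {
    extra$serial <- n + seq_len(nrow(extra))
    atoms <- rbind(atoms, extra)
  }
  protein_structure(atoms, "flat")
}

test_that("membrane plane is the mean phosphorus z in nm", {
  fr <- make_flat_frame(rep(3, 8))
  expect_equal(membrane_plane_z(fr, 1:8), 3)
  fr2 <- make_flat_frame(c(2.9, 3.1))
  expect_equal(membrane_plane_z(fr2, 1:2), 3)
  set.seed(41)
  zs <- stats::rnorm(128, 3, 0.2)
  fr3 <- make_flat_frame(zs)
  expect_equal(membrane_plane_z(fr3, 1:128), mean(zs), tolerance = 1e-9)
  expect_error(membrane_plane_z(fr, integer(0)), "empty")
})

test_that("z_L-P is signed and recovers scripted trajectories", {
  mem <- make_membrane_frames(32, plane_z = 3, jitter = 0,
                              z_script = seq(4.5, 2, length.out = 20),
                              theta_script = rep(10, 20), seed = 8)
  obs <- trajectory_observables(mem$traj, mem$protein_indices, mem$p_indices)
  expect_equal(obs$z_lp, mem$truth$z, tolerance = 1e-6)
  # protein below the plane gives a negative distance
  mem2 <- make_membrane_frames(8, plane_z = 3, jitter = 0, z_script = -1,
                               theta_script = 0, seed = 9)
  expect_lt(z_protein_membrane(mem2$traj$frames[[1]], mem2$protein_indices,
                               mem2$p_indices), 0)
})

test_that("scripted dipole elevations are recovered through the macrodipole", {
  th <- seq(-90, 90, length.out = 19)
  mem <- make_membrane_frames(16, jitter = 0, z_script = rep(2.5, 19),
                              theta_script = th, seed = 10)
  cs <- charge_state_from_vector(mem$traj$frames[[1]], mem$charges)
  got <- vapply(mem$traj$frames, function(fr)
    dipole_plane_angle(macrodipole(cs, fr)), numeric(1))
  expect_equal(got, th, tolerance = 1e-3)
})

test_that("dipole plane angle covers poles, plane and sign symmetry", {
  d <- function(v) structure(list(vector = v), class = "dipole_result")
  expect_equal(dipole_plane_angle(d(c(0, 0, 2))), 90)
  expect_equal(dipole_plane_angle(d(c(1, 1, 0))), 0)
  expect_equal(dipole_plane_angle(d(c(1, 0, -1))), -45)
  set.seed(42)
  for (i in 1:10) {
    v <- stats::rnorm(3)
    expect_equal(dipole_plane_angle(d(v)), -dipole_plane_angle(d(-v)))
  }
  expect_error(dipole_plane_angle(d(c(0, 0, 0))), "zero dipole")
  expect_equal(dipole_plane_angle(d(c(0, 0, 2)), flip = TRUE), -90)
})

test_that("Kabsch RMSD removes rigid motion and matches the quaternion oracle", {
  set.seed(17)
  X <- matrix(stats::rnorm(60, sd = 5), ncol = 3)
  expect_equal(kabsch_rmsd(X, X), 0, tolerance = 1e-12)
  R <- random_rotation()
  Y <- X %*% t(R) + matrix(c(3, -2, 7), nrow(X), 3, byrow = TRUE)
  expect_lt(kabsch_rmsd(Y, X), 1e-7)
  # perturbed copy against the independent Horn eigen-oracle
  Yp <- Y + matrix(stats::rnorm(60, sd = 1), ncol = 3)
  expect_equal(kabsch_rmsd(Yp, X), quat_superpose_rmsd_A(Yp, X) / 10,
               tolerance = 1e-6)
  # invariance under further rigid transforms and symmetry
  for (i in 1:5) {
    R2 <- random_rotation()
    Yp2 <- Yp %*% t(R2) + matrix(stats::rnorm(3, sd = 10), nrow(Yp), 3,
                                 byrow = TRUE)
    expect_equal(kabsch_rmsd(Yp2, X), kabsch_rmsd(Yp, X), tolerance = 1e-6)
  }
  expect_equal(kabsch_rmsd(Yp, X), kabsch_rmsd(X, Yp), tolerance = 1e-9)
  expect_error(kabsch_rmsd(X[1:5, ], X), "differ in size")
})

test_that("bound-state histograms window, count and normalize correctly", {
  times <- seq(0, 100, length.out = 1001)
  vals <- rep(2.5, 1001)
  h <- bound_window_histogram(times, vals, bins = 10)
  expect_equal(sum(h$counts > 0), 1)
  expect_equal(h$window, c(30, 100))
  h2 <- bound_window_histogram(times, seq_along(times),
                               window = c(30, 100), bins = 5,
                               normalize = FALSE)
  expect_equal(h2$n, sum(times >= 30))
  expect_equal(sum(h2$counts), h2$n)
  set.seed(2023)
  u <- stats::runif(1e4)
  hu <- bound_window_histogram(seq_len(1e4), u, window = c(1, 1e4), bins = 20)
  p <- suppressWarnings(stats::chisq.test(hu$counts)$p.value)
  expect_gt(p, 0.01)
  expect_equal(sum(hu$density * diff(hu$bin_edges)), 1, tolerance = 1e-9)
  expect_error(bound_window_histogram(times, vals, window = c(200, 300)),
               "window")
})

test_that("simulator heights are reproduced by the geometric observable", {
  b <- two_pole_body(175, 2)
  fld <- field_model(200, salt_mM = 100, plane_z = 3)
  sim <- simulate_bd(b, fld, 200, 0.01, seed = 31, z0 = 4.5)
  idx <- c(1, 50, 100, 200)
  mem <- make_membrane_frames(16, plane_z = 3, jitter = 0,
                              z_script = sim$z[idx] - 3,
                              theta_script = rep(0, 4), seed = 1)
  obs <- trajectory_observables(mem$traj, mem$protein_indices, mem$p_indices)
  expect_equal(obs$z_lp, sim$z[idx] - 3, tolerance = 1e-9)
})

test_that("percent eluted is the A280 ratio against the no-vesicle reference", {
  expect_equal(percent_eluted(0.42, 0.42), 100)
  expect_equal(percent_eluted(0, 0.42), 0)
  expect_equal(percent_eluted(0.186 * 0.73, 0.73), 18.6, tolerance = 1e-9)
  expect_error(percent_eluted(0.1, 0), "positive")
})
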