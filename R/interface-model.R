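# Screened interfacial field of a charged membrane and an overdamped
# rigid-body Brownian-dynamics simulator of a charged/dipolar protein in it.
#
# Units: lengths nm (body-frame site coordinates are stored in Angstrom and
# converted on use), potentials mV, charges e, energies kJ/mol, times ns.

# 1 e * mV in kJ/mol (Faraday constant * 1e-3 V / 1000)
E_MV_TO_KJMOL <- 0.0964853
# Boltzmann/gas constant, kJ/mol/K
KB_KJMOL <- 0.0083144626

#' Debye screening length of a 1:1 electrolyte
#'
#' `kappa^-1 = 0.304 / sqrt(I[M])` nm at 298 K, with the standard
#' `sqrt(eps_r(T) * T)` scaling at other temperatures (water permittivity
#' from the Malmberg-Maryott fit).
#'
#' @param ionic_strength_mM ionic strength in mM (> 0).
#' @param temperature temperature in K.
#' @return Debye length in nm.
#' @export
debye_length <- function(ionic_strength_mM, temperature = 298) {
  if (ionic_strength_mM <= 0) stop("ionic strength must be positive")
  eps <- function(tK) {
    t <- tK - 273.15
    87.740 - 0.40008 * t + 9.398e-4 * t^2 - 1.410e-6 * t^3
  }
  0.304 / sqrt(ionic_strength_mM / 1000) *
    sqrt(eps(temperature) * temperature / (eps(298) * 298))
}

#' Screened interfacial field model
#'
#' Linearized Gouy-Chapman form: `psi(z) = psi0 * exp(-kappa (z - plane_z))`
#' above the membrane plane. A uniform-field variant (the `kappa -> 0`
#' limit, used for closed-form orientation checks) is selected with
#' `uniform_E`, giving `psi(z) = psi0 - E0 (z - plane_z)`.
#'
#' @param psi0 surface potential, mV (sign = membrane polarity).
#' @param kappa inverse Debye length, nm^-1; alternatively give `salt_mM`.
#' @param salt_mM 1:1 salt concentration in mM used to derive `kappa`.
#' @param plane_z membrane surface position, nm.
#' @param temperature temperature, K (default 320, the simulation bath).
#' @param uniform_E if non-NULL, uniform field strength E0 in mV/nm.
#' @return object of class `field_model`.
#' @export
field_model <- function(psi0, kappa = NULL, salt_mM = NULL, plane_z = 0,
                        temperature = 320, uniform_E = NULL) {
  if (is.null(kappa)) {
    if (is.null(uniform_E)) {
      if (is.null(salt_mM)) stop("give kappa or salt_mM")
      kappa <- 1 / debye_length(salt_mM, temperature)
    } else kappa <- 0
  }
  if (is.null(uniform_E) && kappa <= 0) stop("kappa must be positive")
  if (temperature <= 0) stop("temperature must be positive")
  structure(list(psi0 = psi0, kappa = kappa, plane_z = plane_z,
                 temperature = temperature, uniform_E = uniform_E),
            class = "field_model")
}

#' Interfacial potential at height z
#'
#' @param field a `field_model`.
#' @param z height(s), nm; must satisfy `z >= plane_z`.
#' @return potential in mV.
#' @export
gc_potential <- function(field, z) {
  if (any(z < field$plane_z - 1e-12))
    stop("z below the membrane plane (inside membrane)")
  dz <- z - field$plane_z
  if (!is.null(field$uniform_E)) return(field$psi0 - field$uniform_E * dz)
  field$psi0 * exp(-field$kappa * dz)
}

# field strength E_z = -dpsi/dz, mV/nm
gc_field_strength <- function(field, z) {
  if (!is.null(field$uniform_E)) return(rep(field$uniform_E, length(z)))
  field$kappa * field$psi0 * exp(-field$kappa * (z - field$plane_z))
}

#' Rigid charged body for Brownian dynamics
#'
#' Body-frame site coordinates are recentred so the mass-weighted center of
#' mass sits at the body origin (equal site masses by default).
#'
#' @param sites n x 3 matrix of body-frame coordinates, Angstrom.
#' @param charges per-site charges, e.
#' @param D_t translational diffusion coefficient, nm^2/ns.
#' @param D_r rotational diffusion coefficient, rad^2/ns.
#' @param contact_radius hard contact radius, nm (>= body extent to keep
#'   sites above the membrane plane at contact).
#' @param masses optional site masses (u), default equal.
#' @return object of class `rigid_body`.
#' @export
rigid_body <- function(sites, charges, D_t = 0.1, D_r = 0.05,
                       contact_radius = NULL, masses = NULL) {
  sites <- as.matrix(sites)
  if (ncol(sites) != 3) stop("sites must be n x 3 (Angstrom)")
  if (length(charges) != nrow(sites)) stop("one charge per site required")
  if (is.null(masses)) masses <- rep(1, nrow(sites))
  com <- colSums(sites * masses) / sum(masses)
  sites <- sweep(sites, 2, com)
  extent_nm <- if (nrow(sites) > 0) max(sqrt(rowSums(sites^2))) / 10 else 0
  if (is.null(contact_radius)) contact_radius <- max(extent_nm, 0.1)
  if (contact_radius <= 0) stop("contact_radius must be positive")
  structure(list(sites = sites, charges = as.numeric(charges),
                 masses = masses, D_t = D_t, D_r = D_r,
                 contact_radius = contact_radius, extent_nm = extent_nm),
            class = "rigid_body")
}

#' Axially charge-separated rigid body with prescribed dipole and net charge
#'
#' A compact body with two charged caps on the z axis, mimicking the polar
#' charge asymmetry of a beta-barrel protein: the cap charges are
#' `(Q + mu/h)/2` on top and `(Q - mu/h)/2` on the bottom (each spread over
#' four sites), which gives exactly the requested body-frame dipole
#' `mu_D` (along +z, about the COM) and net charge. Deterministic geometry.
#'
#' @param mu_D dipole magnitude, Debye.
#' @param net_charge net charge, e.
#' @param half_height_nm cap distance from the body center, nm.
#' @param pole_radius_nm lateral spread of each cap's sites, nm.
#' @param ... diffusion coefficients and contact radius for [rigid_body()].
#' @return a `rigid_body`.
#' @export
two_pole_body <- function(mu_D, net_charge = 0, half_height_nm = 0.45,
                          pole_radius_nm = 0.3, ...) {
  mu_enm <- mu_D / E_ANGSTROM_TO_DEBYE / 10
  q_top <- (net_charge + mu_enm / half_height_nm) / 2
  q_bot <- (net_charge - mu_enm / half_height_nm) / 2
  h <- half_height_nm * 10
  r <- pole_radius_nm * 10
  ring <- rbind(c(r, 0), c(-r, 0), c(0, r), c(0, -r))
  sites <- rbind(cbind(ring, h), cbind(ring, -h))
  rigid_body(sites, c(rep(q_top / 4, 4), rep(q_bot / 4, 4)), ...)
}

#' Body-frame dipole of a rigid body
#' @param body a `rigid_body`.
#' @return length-3 dipole vector in Debye (about the body COM).
#' @export
body_dipole <- function(body) {
  colSums(body$sites * body$charges) * E_ANGSTROM_TO_DEBYE
}

# --- quaternions (w, x, y, z) ---------------------------------------------

quat_normalize <- function(q) q / sqrt(sum(q^2))

quat_multiply <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

quat_from_rotvec <- function(v) {
  th <- sqrt(sum(v^2))
  if (th < 1e-12) return(c(1, 0, 0, 0))
  c(cos(th / 2), sin(th / 2) * v / th)
}

quat_to_matrix <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

# lab-frame site positions (nm) for a pose
pose_sites_nm <- function(body, com_nm, q) {
  R <- quat_to_matrix(q)
  sweep((body$sites / 10) %*% t(R), 2, com_nm, "+")
}

#' Electrostatic energy of a posed rigid body in the interfacial field
#'
#' `U = sum_i q_i psi(z_i)`, converted with 1 e*mV = 0.0964853 kJ/mol. Any
#' site below the membrane plane is an overlap error (the simulator treats
#' it as a rejected move).
#'
#' @param body a `rigid_body`.
#' @param com_nm body COM position, nm (length 3 or a single z).
#' @param q orientation quaternion (w, x, y, z).
#' @param field a `field_model`.
#' @return energy in kJ/mol.
#' @export
body_energy <- function(body, com_nm, q = c(1, 0, 0, 0), field) {
  if (length(com_nm) == 1) com_nm <- c(0, 0, com_nm)
  r <- pose_sites_nm(body, com_nm, quat_normalize(q))
  if (any(r[, 3] < field$plane_z - 1e-12))
    stop("overlap: site below the membrane plane")
  sum(body$charges * gc_potential(field, r[, 3])) * E_MV_TO_KJMOL
}

# analytic force (on COM) and torque about COM, kJ/mol/nm and kJ/mol/rad
body_force_torque <- function(body, com_nm, q, field) {
  R <- quat_to_matrix(q)
  rel <- (body$sites / 10) %*% t(R)
  z <- rel[, 3] + com_nm[3]
  fz <- body$charges * gc_field_strength(field, z) * E_MV_TO_KJMOL
  force <- c(0, 0, sum(fz))
  torque <- c(sum(rel[, 2] * fz), -sum(rel[, 1] * fz), 0)
  list(force = force, torque = torque)
}

#' Overdamped rigid-body Brownian dynamics in the interfacial field
#'
#' Euler-Maruyama updates of position and orientation:
#' `dr = (D_t/kBT) F dt + sqrt(2 D_t dt) xi` and a rotation by
#' `(D_r/kBT) tau dt + sqrt(2 D_r dt) xi_rot` applied as a quaternion
#' increment (renormalized every step). The COM z is confined between a
#' reflecting wall at `plane_z + contact_radius` and a reflecting ceiling at
#' `z_max`; a move that would put a site below the membrane plane is
#' rejected. Reproducible per `seed`.
#'
#' @param body a `rigid_body`.
#' @param field a `field_model`.
#' @param steps number of integration steps.
#' @param dt time step, ns.
#' @param seed RNG seed (recorded in the output).
#' @param z0 initial COM height, nm (default mid-box).
#' @param q0 initial orientation quaternion.
#' @param z_max reflecting ceiling, nm (default 10, bounding the box).
#' @param record_every store every k-th step (default 1).
#' @param rotation_only freeze translation (closed-form orientation checks).
#' @return data.frame of class `sim_trajectory` with columns `time`, `x`,
#'   `y`, `z`, `qw`, `qx`, `qy`, `qz`, `energy`; attributes `seed`, `params`.
#' @export
simulate_bd <- function(body, field, steps, dt, seed, z0 = NULL,
                        q0 = c(1, 0, 0, 0), z_max = 10, record_every = 1,
                        rotation_only = FALSE) {
  set.seed(seed)
  kBT <- KB_KJMOL * field$temperature
  lo <- field$plane_z + body$contact_radius
  if (is.null(z0)) z0 <- (lo + z_max) / 2
  if (z0 < lo || z0 > z_max) stop("z0 outside [wall, ceiling]")
  if (field$kappa > 0) {
    rms <- sqrt(6 * body$D_t * dt)
    if (rms >= 0.1 / field$kappa)
      warning(sprintf(
        "dt too coarse: per-step RMS displacement %.3g nm >= 0.1 Debye lengths",
        rms))
  }
  com <- c(0, 0, z0)
  q <- quat_normalize(q0)
  nrec <- floor(steps / record_every)
  out <- matrix(NA_real_, nrow = nrec, ncol = 9)
  st <- sqrt(2 * body$D_t * dt)
  sr <- sqrt(2 * body$D_r * dt)
  ct <- body$D_t / kBT * dt
  cr <- body$D_r / kBT * dt
  rec <- 0L
  for (s in seq_len(steps)) {
    ft <- body_force_torque(body, com, q, field)
    if (rotation_only) {
      new_com <- com
    } else {
      new_com <- com + ct * ft$force + st * stats::rnorm(3)
      # reflecting wall and ceiling on COM z
      if (new_com[3] < lo) new_com[3] <- 2 * lo - new_com[3]
      if (new_com[3] > z_max) new_com[3] <- 2 * z_max - new_com[3]
      if (new_com[3] < lo) new_com[3] <- lo  # pathological double bounce
    }
    dphi <- cr * ft$torque + sr * stats::rnorm(3)
    new_q <- quat_normalize(quat_multiply(quat_from_rotvec(dphi), q))
    # reject moves that sink a site below the membrane plane
    r <- pose_sites_nm(body, new_com, new_q)
    if (all(r[, 3] >= field$plane_z)) {
      com <- new_com; q <- new_q
    }
    if (s %% record_every == 0) {
      rec <- rec + 1L
      u <- sum(body$charges * gc_potential(field,
              pose_sites_nm(body, com, q)[, 3])) * E_MV_TO_KJMOL
      if (!is.finite(u))
        stop("integration failure: non-finite energy at step ", s)
      out[rec, ] <- c(s * dt, com, q, u)
    }
  }
  df <- as.data.frame(out)
  names(df) <- c("time", "x", "y", "z", "qw", "qx", "qy", "qz", "energy")
  attr(df, "seed") <- seed
  attr(df, "params") <- list(field = field, dt = dt, steps = steps,
                             z_max = z_max, contact_radius = body$contact_radius)
  class(df) <- c("sim_trajectory", "data.frame")
  df
}

# lab-frame unit dipole direction per recorded step (n x 3), vectorized
# over the quaternion columns
sim_dipole_dirs <- function(body, sim) {
  m <- body_dipole(body)
  # apolar bodies are probed along their body z axis instead
  if (sqrt(sum(m^2)) < 1e-9) m <- c(0, 0, 1) else m <- m / sqrt(sum(m^2))
  w <- sim$qw; x <- sim$qx; y <- sim$qy; z <- sim$qz
  cbind(
    (1 - 2 * (y^2 + z^2)) * m[1] + 2 * (x * y - w * z) * m[2] + 2 * (x * z + w * y) * m[3],
    2 * (x * y + w * z) * m[1] + (1 - 2 * (x^2 + z^2)) * m[2] + 2 * (y * z - w * x) * m[3],
    2 * (x * z - w * y) * m[1] + 2 * (y * z + w * x) * m[2] + (1 - 2 * (x^2 + y^2)) * m[3])
}

# cos(angle between the lab-frame body dipole and +z) per recorded step
sim_dipole_cosz <- function(body, sim) {
  sim_dipole_dirs(body, sim)[, 3]
}

#' Paired-polarity orientation experiment
#'
#' Runs Brownian-dynamics simulations at surface potentials `+psi0` and
#' `-psi0` over several seeds and summarises the final-window orientation of
#' the body dipole: the circular mean (mean unit-vector) angle between the
#' dipole and the membrane normal for each polarity, and their difference.
#' A dipolar body should flip by about 180 degrees when the membrane
#' polarity is inverted.
#'
#' @param body a `rigid_body` with nonzero dipole (checked unless
#'   `allow_apolar`).
#' @param psi0 magnitude of the surface potential, mV.
#' @param salt_mM electrolyte concentration, mM.
#' @param steps,dt integration steps and time step (ns).
#' @param seeds vector of RNG seeds (one pair of runs per seed).
#' @param window_frac final fraction of each run used (default 0.7, the
#'   bound-state window convention).
#' @param z0 starting height, nm.
#' @param allow_apolar skip the nonzero-dipole check (control experiments).
#' @return list with `theta_plus`, `theta_minus` (degrees from +z),
#'   `difference` (degrees), and the per-seed mean-direction table.
#' @export
orientation_flip_experiment <- function(body, psi0, salt_mM, steps, dt,
                                        seeds, window_frac = 0.7, z0 = 4,
                                        allow_apolar = FALSE) {
  mu <- body_dipole(body)
  if (!allow_apolar && sqrt(sum(mu^2)) < 1e-6)
    stop("body has zero dipole; use allow_apolar = TRUE for controls")
  run_mean_dir <- function(psi, seed) {
    fld <- field_model(psi, salt_mM = salt_mM)
    sim <- simulate_bd(body, fld, steps, dt, seed, z0 = z0)
    keep <- sim$time >= (1 - window_frac) * max(sim$time)
    colMeans(sim_dipole_dirs(body, sim[keep, , drop = FALSE]))
  }
  per_seed <- t(vapply(seeds, function(s) {
    c(run_mean_dir(abs(psi0), s), run_mean_dir(-abs(psi0), s))
  }, numeric(6)))
  colnames(per_seed) <- c("px", "py", "pz", "mx", "my", "mz")
  # circular mean: polar angle of the seed-averaged mean direction
  polar <- function(v) {
    v <- v / sqrt(sum(v^2))
    acos(max(-1, min(1, v[3]))) * 180 / pi
  }
  theta_plus <- polar(colMeans(per_seed[, 1:3, drop = FALSE]))
  theta_minus <- polar(colMeans(per_seed[, 4:6, drop = FALSE]))
  list(theta_plus = theta_plus, theta_minus = theta_minus,
       difference = abs(theta_plus - theta_minus),
       per_seed = as.data.frame(per_seed))
}

#' Mean height of a body with and without the interfacial field
#'
#' Compares the time-averaged COM height over the bound-state window of a
#' simulation in the field against a zero-field control with the same seed;
#' used to demonstrate like-charge binding through the dipole term.
#'
#' @param body a `rigid_body`.
#' @param field a `field_model`.
#' @param steps,dt,seed as in [simulate_bd()].
#' @param window_frac final fraction of the run averaged.
#' @param z0 starting height, nm.
#' @return list with `mean_z_field`, `mean_z_control` (nm).
#' @export
binding_height_experiment <- function(body, field, steps, dt, seed,
                                      window_frac = 0.7, z0 = 4) {
  null_field <- field_model(0, kappa = field$kappa, plane_z = field$plane_z,
                            temperature = field$temperature)
  mz <- function(fld) {
    sim <- simulate_bd(body, fld, steps, dt, seed, z0 = z0)
    keep <- sim$time >= (1 - window_frac) * max(sim$time)
    mean(sim$z[keep])
  }
  list(mean_z_field = mz(field), mean_z_control = mz(null_field))
}
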