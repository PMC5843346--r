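# Geometric observables of membrane-binding trajectories: phosphorus plane,
# COM-to-plane distance, dipole tilt relative to the membrane plane, Kabsch
# RMSD and bound-state histograms. Reporting unit for distances is nm.

#' Membrane plane position from phosphorus atoms
#'
#' Mean z of the selected phosphorus atoms of one leaflet, in nm.
#'
#' @param frame a `protein_structure`.
#' @param p_indices atom indices of the leaflet phosphorus atoms.
#' @return plane position, nm.
#' @export
membrane_plane_z <- function(frame, p_indices) {
  if (length(p_indices) == 0) stop("empty phosphorus selection")
  mean(frame$atoms$z[p_indices]) / 10
}

#' Signed protein-membrane distance z_L-P
#'
#' Distance between the protein center of mass and the cis-leaflet
#' phosphorus plane, positive when the protein sits above the leaflet.
#'
#' @param frame a `protein_structure`.
#' @param protein_indices atom indices of the protein.
#' @param p_indices atom indices of the leaflet phosphorus atoms.
#' @return signed distance, nm.
#' @export
z_protein_membrane <- function(frame, protein_indices, p_indices) {
  if (length(protein_indices) == 0) stop("empty protein selection")
  com_z <- center_of_mass(frame, protein_indices)[3] / 10
  unname(com_z - membrane_plane_z(frame, p_indices))
}

#' Elevation of the macrodipole above the membrane plane
#'
#' `theta = 90 - angle(mu, +z)`: the elevation of the dipole above the x-y
#' (membrane) plane in degrees, in `[-90, +90]`; negative when the dipole
#' points toward a membrane located at lower z. `flip = TRUE` inverts the
#' sign convention.
#'
#' @param dipole a `dipole_result` or length-3 vector.
#' @param flip invert the sign convention.
#' @return angle in degrees.
#' @export
dipole_plane_angle <- function(dipole, flip = FALSE) {
  v <- if (inherits(dipole, "dipole_result")) dipole$vector else dipole
  if (sqrt(sum(v^2)) == 0) stop("undefined angle: zero dipole")
  th <- 90 - dipole_axis_angle(v, c(0, 0, 1))
  if (flip) -th else th
}

#' Optimal-superposition RMSD (Kabsch)
#'
#' Least-squares rigid superposition of `frame` onto `reference` over paired
#' selections (identical atom order), with the determinant guard against
#' improper rotations; the residual RMSD is reported in nm.
#'
#' @param frame,reference `protein_structure` objects (or n x 3 coordinate
#'   matrices in Angstrom).
#' @param indices atom indices used for the superposition (applied to both).
#' @return RMSD, nm.
#' @export
kabsch_rmsd <- function(frame, reference, indices = NULL) {
  X <- if (inherits(frame, "protein_structure")) coords(frame) else as.matrix(frame)
  Y <- if (inherits(reference, "protein_structure")) coords(reference) else as.matrix(reference)
  if (!is.null(indices)) {
    X <- X[indices, , drop = FALSE]
    Y <- Y[indices, , drop = FALSE]
  }
  if (nrow(X) != nrow(Y)) stop("alignment error: selections differ in size")
  if (nrow(X) < 3) stop("alignment error: need at least 3 atoms")
  Xc <- sweep(X, 2, colMeans(X))
  Yc <- sweep(Y, 2, colMeans(Y))
  H <- t(Xc) %*% Yc
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  diffs <- Yc - Xc %*% t(R)
  sqrt(mean(rowSums(diffs^2))) / 10
}

#' Observable series over a trajectory
#'
#' Convenience driver computing `z_L-P`, the dipole-plane angle and the
#' Kabsch RMSD for every frame of a trajectory.
#'
#' @param traj an `md_trajectory`.
#' @param protein_indices,p_indices atom index sets (protein; leaflet P).
#' @param reference reference `protein_structure` for RMSD (default frame 1).
#' @param charge_state optional `charge_state` (aligned to the frame atom
#'   table) enabling the dipole angle series.
#' @return data.frame of class `observable_series`: `time` (ns), `z_lp`
#'   (nm), `rmsd` (nm) and, when charges are given, `theta` (degrees).
#' @export
trajectory_observables <- function(traj, protein_indices, p_indices,
                                   reference = NULL, charge_state = NULL) {
  if (is.null(reference)) reference <- traj$frames[[1]]
  n <- length(traj$frames)
  z <- numeric(n); r <- rep(NA_real_, n); th <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    f <- traj$frames[[i]]
    z[i] <- z_protein_membrane(f, protein_indices, p_indices)
    if (length(protein_indices) >= 3)
      r[i] <- kabsch_rmsd(f, reference, protein_indices)
    if (!is.null(charge_state)) {
      dip <- macrodipole(charge_state, f)
      th[i] <- dipole_plane_angle(dip)
    }
  }
  out <- data.frame(time = traj$times, z_lp = z, rmsd = r, theta = th)
  class(out) <- c("observable_series", "data.frame")
  out
}

#' Bound-state histogram of an observable series
#'
#' Histogram of the values inside a time window; the default window is the
#' final 70% of the series, the bound-state convention for 100-ns adsorption
#' runs analysed over their last 70 ns.
#'
#' @param times time stamps, ns.
#' @param values observable values.
#' @param window explicit `c(t_start, t_end)` in ns, or NULL.
#' @param window_frac final fraction of the series used when `window` is
#'   NULL (default 0.7).
#' @param bins number of bins over the in-window range (default 50).
#' @param normalize scale counts to unit area.
#' @return list of class `bound_histogram`: `bin_edges`, `counts`,
#'   `density`, `window`, `n`.
#' @export
bound_window_histogram <- function(times, values, window = NULL,
                                   window_frac = 0.7, bins = 50,
                                   normalize = TRUE) {
  if (length(times) != length(values)) stop("times and values differ in length")
  if (is.null(window)) {
    t0 <- max(times) - window_frac * (max(times) - min(times))
    window <- c(t0, max(times))
  }
  if (window[1] > max(times) || window[2] < min(times) ||
      window[2] <= window[1])
    stop("window outside the series time range")
  keep <- times >= window[1] & times <= window[2]
  if (!any(keep)) stop("empty window")
  v <- values[keep]
  rng <- range(v)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  edges <- seq(rng[1], rng[2], length.out = bins + 1)
  counts <- as.numeric(table(cut(v, edges, include.lowest = TRUE)))
  dens <- counts / (sum(counts) * diff(edges))
  structure(list(bin_edges = edges, counts = counts,
                 density = if (normalize) dens else NULL,
                 window = window, n = sum(counts)),
            class = "bound_histogram")
}

#' Percent of protein eluted in a filtration binding assay
#'
#' Eluted fraction quantified by A280, relative to a no-vesicle reference
#' taken as 100% elution; low percentages indicate strong membrane binding.
#'
#' @param a280_sample absorbance of the eluate with vesicles present.
#' @param a280_reference absorbance of the no-vesicle reference (> 0).
#' @return percent eluted.
#' @export
percent_eluted <- function(a280_sample, a280_reference) {
  if (any(a280_reference <= 0)) stop("reference absorbance must be positive")
  if (any(a280_sample < 0)) stop("sample absorbance must be non-negative")
  100 * a280_sample / a280_reference
}
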