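# Synthetic fixtures with analytically known ground truth: point-charge
# "proteins" with prescribed dipole and net charge, membrane frames with a
# scripted protein, amide-I spectra built from Gaussian band tables, pKa
# tables, and residue-level ionizable inventories emulating the titration
# landmarks of the two studied FABPs. Every generator records its ground
# truth so recovery tests never recompute it from the fixture itself.

#' Wrap an explicit per-atom charge vector as a charge state
#'
#' @param structure a `protein_structure`.
#' @param q per-atom charges, e (aligned to the atom table).
#' @param ph pH label to record (default NA).
#' @return a `charge_state`.
#' @export
charge_state_from_vector <- function(structure, q, ph = NA_real_) {
  if (length(q) != nrow(structure$atoms))
    stop("charge vector does not align with structure atoms")
  structure(list(per_atom_charge = as.numeric(q), net_charge = sum(q),
                 ph = ph, protonation = NULL, library = "explicit"),
            class = "charge_state")
}

#' Point-charge protein with prescribed macrodipole and net charge
#'
#' Places `n_sites` sites uniformly in a sphere of radius `radius_A` and
#' solves for the least-norm charge vector satisfying `sum(q) = net_charge`
#' and `sum(q * (r - COM))` equal to the requested dipole vector (magnitude
#' `target_dipole_D` along `direction`). Sites have equal masses, so the
#' center of mass is the centroid.
#'
#' @param n_sites number of charge sites (>= 4 for a full constraint set).
#' @param target_dipole_D requested dipole magnitude, Debye.
#' @param net_charge requested net charge, e.
#' @param seed RNG seed.
#' @param radius_A sphere radius, Angstrom (default 20 = 2 nm).
#' @param direction dipole direction (default +z).
#' @param write_dir if non-NULL, writes `<label>.pdb`, `<label>_charges.tsv`
#'   and `<label>_truth.json` there.
#' @param label file stem used with `write_dir`.
#' @return list: `structure`, `charges` (e), `charge_state`, `truth`
#'   (requested dipole vector in Debye, net charge, seed), and file paths
#'   when written.
#' @export
make_point_protein <- function(n_sites, target_dipole_D, net_charge, seed,
                               radius_A = 20, direction = c(0, 0, 1),
                               write_dir = NULL, label = "point_protein") {
  if (n_sites < 4)
    stop("infeasible: need >= 4 sites to satisfy charge + dipole constraints")
  set.seed(seed)
  # uniform in sphere
  u <- matrix(stats::rnorm(3 * n_sites), ncol = 3)
  u <- u / sqrt(rowSums(u^2))
  r <- radius_A * stats::runif(n_sites)^(1 / 3)
  xyz <- u * r
  cen <- colMeans(xyz)
  rel <- sweep(xyz, 2, cen)
  dirn <- direction / sqrt(sum(direction^2))
  mu_eA <- (target_dipole_D / E_ANGSTROM_TO_DEBYE) * dirn
  A <- rbind(rep(1, n_sites), t(rel))
  b <- c(net_charge, mu_eA)
  M <- A %*% t(A)
  if (abs(det(M)) < 1e-10)
    stop("infeasible: degenerate site geometry for the constraint set")
  q <- as.numeric(t(A) %*% solve(M, b))
  atoms <- data.frame(serial = seq_len(n_sites),
                      name = paste0("Q", seq_len(n_sites)),
                      resname = "STE", chain = "A", resseq = 1,
                      x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                      element = "C", hetero = FALSE,
                      stringsAsFactors = FALSE)
  st <- protein_structure(atoms, source_id = label)
  truth <- list(dipole_D = unname(target_dipole_D),
                dipole_vector_D = unname(mu_eA * E_ANGSTROM_TO_DEBYE),
                net_charge = unname(net_charge), seed = seed)
  out <- list(structure = st, charges = q,
              charge_state = charge_state_from_vector(st, q), truth = truth)
  if (!is.null(write_dir)) {
    pdb <- file.path(write_dir, paste0(label, ".pdb"))
    chg <- file.path(write_dir, paste0(label, "_charges.tsv"))
    tr <- file.path(write_dir, paste0(label, "_truth.json"))
    write_pdb_frames(st, pdb)
    utils::write.table(data.frame("STE", paste0("Q", seq_len(n_sites)), 0,
                                  formatC(q, digits = 10, format = "g")),
                       chg, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    jsonlite::write_json(truth, tr, auto_unbox = TRUE, digits = NA)
    out$paths <- list(pdb = pdb, charges = chg, truth = tr)
  }
  out
}

#' Rigid Brownian-dynamics body from a point-charge protein
#'
#' @param pp output of [make_point_protein()] (or a list with `structure`
#'   and `charges`).
#' @param ... diffusion coefficients and contact radius passed to
#'   [rigid_body()].
#' @return a `rigid_body`.
#' @export
as_rigid_body <- function(pp, ...) {
  rigid_body(coords(pp$structure), pp$charges, ...)
}

#' Membrane frames with a scripted rigid protein
#'
#' Builds a trajectory of `n_frames` frames: `n_lipids` phosphorus atoms
#' jittered around the plane `plane_z`, plus a two-site unit-dipole protein
#' whose center follows `z_script` (nm above the plane) and whose dipole
#' elevation above the membrane plane follows `theta_script` (degrees).
#' The ground truth (scripted series) is recorded alongside.
#'
#' @param n_lipids phosphorus atoms per frame.
#' @param plane_z membrane plane, nm.
#' @param jitter Gaussian jitter of the P atoms about the plane, nm.
#' @param z_script,theta_script numeric vectors of length `n_frames`.
#' @param seed RNG seed.
#' @param separation_A protein site separation, Angstrom.
#' @param write_gro if non-NULL, writes the trajectory in GRO dialect there
#'   plus a `_truth.json` sidecar.
#' @return list: `traj` (`md_trajectory`), `protein_indices`, `p_indices`,
#'   `charges` (per-atom, e), `truth` (times ns, z nm, theta deg).
#' @export
make_membrane_frames <- function(n_lipids, plane_z = 3, jitter = 0.05,
                                 z_script, theta_script, seed,
                                 separation_A = 10, write_gro = NULL) {
  if (length(z_script) != length(theta_script))
    stop("z_script and theta_script differ in length")
  n_frames <- length(z_script)
  set.seed(seed)
  side <- ceiling(sqrt(n_lipids))
  gx <- (seq_len(side) - 0.5) * 70 / side  # Angstrom, 7 nm box
  grid <- expand.grid(x = gx, y = gx)[seq_len(n_lipids), ]
  half <- separation_A / 2
  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    pz <- (plane_z + stats::rnorm(n_lipids, 0, jitter)) * 10
    th <- theta_script[f] * pi / 180
    d <- c(cos(th), 0, sin(th))
    cen <- c(35, 35, (plane_z + z_script[f]) * 10)
    pro_xyz <- rbind(cen - half * d, cen + half * d)  # -q then +q site
    atoms <- data.frame(
      serial = seq_len(n_lipids + 2),
      name = c(rep("P", n_lipids), "QN", "QP"),
      resname = c(rep("LIP", n_lipids), "PRO", "PRO"),
      chain = " ",
      resseq = c(seq_len(n_lipids), n_lipids + 1, n_lipids + 1),
      x = c(grid$x, pro_xyz[, 1]), y = c(grid$y, pro_xyz[, 2]),
      z = c(pz, pro_xyz[, 3]),
      element = c(rep("P", n_lipids), "C", "C"), hetero = FALSE,
      stringsAsFactors = FALSE)
    frames[[f]] <- protein_structure(atoms, source_id = "membrane_fixture",
                                     model_index = f)
  }
  times <- seq_len(n_frames) - 1
  traj <- md_trajectory(times, frames, source = "membrane_fixture")
  charges <- c(rep(0, n_lipids), -1, 1)
  truth <- list(times = times, z = z_script, theta = theta_script,
                plane_z = plane_z, jitter = jitter, seed = seed)
  out <- list(traj = traj, protein_indices = n_lipids + (1:2),
              p_indices = seq_len(n_lipids), charges = charges,
              truth = truth)
  if (!is.null(write_gro)) {
    write_gro_frames(traj, write_gro)
    tr <- sub("\\.gro$", "_truth.json", write_gro)
    jsonlite::write_json(truth, tr, auto_unbox = TRUE, digits = NA)
    out$paths <- list(gro = write_gro, truth = tr)
  }
  out
}

#' Synthetic amide-I spectrum from a band table
#'
#' Sum of Gaussian components with the requested relative areas and unit
#' total area, plus white noise at the requested signal-to-noise ratio
#' (`snr = Inf` for noiseless).
#'
#' @param bands data.frame with `center` (cm^-1), `area_frac` (percent) and
#'   optionally `fwhm` (cm^-1). The default width of 9 cm^-1 keeps purely
#'   Gaussian components as resolvable under FSD(18, k = 2) as the measured
#'   amide-I components are: synthetic Gaussians lack the Lorentzian wings
#'   that the deconvolution removes, so wider Gaussian components would
#'   merge where the experimental bands were resolved.
#' @param step grid step, cm^-1.
#' @param range wavenumber range, cm^-1.
#' @param snr peak-signal-to-noise ratio.
#' @param seed RNG seed.
#' @param write_path if non-NULL, writes a two-column ASCII spectrum there
#'   plus a `_truth.json` sidecar.
#' @return list: `spectrum` (`ir_spectrum`), `truth` (band table incl. fwhm
#'   and amplitudes, snr, seed).
#' @export
make_amideI_spectrum <- function(bands, step = 1, range = c(1550, 1750),
                                 snr = Inf, seed = 1, write_path = NULL) {
  if (any(bands$center < 1600 | bands$center > 1700))
    stop("band centers must lie in [1600, 1700]")
  if (anyDuplicated(bands$center) > 0)
    warning("duplicate band centers in generator table")
  if (is.null(bands$fwhm)) bands$fwhm <- 9
  set.seed(seed)
  nu <- seq(range[1], range[2], by = step)
  amp <- (bands$area_frac / 100) / (bands$fwhm * GAUSS_AREA_FACTOR)
  ab <- gaussian_sum(nu, bands$center, bands$fwhm, amp)
  if (is.finite(snr)) ab <- ab + stats::rnorm(length(ab), 0, max(ab) / snr)
  sp <- new_spectrum(nu, ab, metadata = list(label = "synthetic_amideI",
                                             seed = seed))
  truth <- list(bands = data.frame(center = bands$center, fwhm = bands$fwhm,
                                   area_frac = bands$area_frac,
                                   amplitude = amp),
                snr = snr, seed = seed)
  out <- list(spectrum = sp, truth = truth)
  if (!is.null(write_path)) {
    writeLines(c("# synthetic amide-I spectrum",
                 sprintf("%.4f\t%.8e", nu, ab)), write_path)
    tr <- sub("\\.[^.]*$", "", write_path)
    tr <- paste0(tr, "_truth.json")
    jsonlite::write_json(truth, tr, auto_unbox = TRUE, digits = NA)
    out$paths <- list(spectrum = write_path, truth = tr)
  }
  out
}

#' Write a pKa table file
#'
#' @param entries data.frame: `chain`, `resseq`, `resname`, `pka`, `type`.
#' @param path output file (tab-separated, '#' header comment).
#' @return `path`, invisibly.
#' @export
make_pka_file <- function(entries, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# chain\tres_seq\tres_name\tpKa\ttype", con)
  writeLines(sprintf("%s\t%d\t%s\t%.3f\t%s", entries$chain,
                     as.integer(entries$resseq), entries$resname,
                     entries$pka, entries$type), con)
  invisible(path)
}

# Residue templates: backbone heavy atoms plus the charged-group atoms the
# formal library places charges on.
RESIDUE_TEMPLATES <- list(
  GLY = c("N", "CA", "C", "O"),
  ASP = c("N", "CA", "C", "O", "CB", "CG", "OD1", "OD2"),
  GLU = c("N", "CA", "C", "O", "CB", "CG", "CD", "OE1", "OE2"),
  HIS = c("N", "CA", "C", "O", "CB", "CG", "ND1", "NE2"),
  CYS = c("N", "CA", "C", "O", "CB", "SG"),
  TYR = c("N", "CA", "C", "O", "CB", "OH"),
  LYS = c("N", "CA", "C", "O", "CB", "CG", "CD", "CE", "NZ"),
  ARG = c("N", "CA", "C", "O", "CB", "CG", "CD", "NE", "CZ", "NH1", "NH2"))

#' Residue-level synthetic protein with a prescribed ionizable inventory
#'
#' Builds a single-chain structure from a vector of 3-letter residue codes:
#' each residue gets its backbone and charged-group heavy atoms at jittered
#' positions along a coarse random walk (no realistic stereochemistry — the
#' fixture exists for protonation/charge arithmetic, not geometry). The last
#' residue carries an OXT.
#'
#' @param resnames character vector of codes among GLY, ASP, GLU, HIS, CYS,
#'   TYR, LYS, ARG.
#' @param seed RNG seed.
#' @param chain chain identifier.
#' @return a `protein_structure`.
#' @export
make_ionizable_protein <- function(resnames, seed, chain = "A") {
  unknown <- setdiff(unique(resnames), names(RESIDUE_TEMPLATES))
  if (length(unknown) > 0) stop("no template for residue(s): ",
                                paste(unknown, collapse = ", "))
  set.seed(seed)
  rows <- list()
  serial <- 0L
  pos <- c(0, 0, 0)
  for (i in seq_along(resnames)) {
    rn <- resnames[i]
    names_i <- RESIDUE_TEMPLATES[[rn]]
    if (i == length(resnames)) names_i <- c(names_i, "OXT")
    pos <- pos + stats::rnorm(3, 0, 1.2) + c(3.5, 0, 0)  # coarse walk, Angstrom
    for (nm in names_i) {
      serial <- serial + 1L
      at <- pos + stats::rnorm(3, 0, 1.0)
      el <- substr(nm, 1, 1)
      rows[[serial]] <- data.frame(serial = serial, name = nm, resname = rn,
                                   chain = chain, resseq = i,
                                   x = at[1], y = at[2], z = at[3],
                                   element = el, hetero = FALSE,
                                   stringsAsFactors = FALSE)
    }
  }
  protein_structure(do.call(rbind, rows),
                    source_id = sprintf("synthetic_%d_residues", length(resnames)))
}

#' Synthetic stand-in for the L-BABP ionizable inventory
#'
#' A residue-level fixture (structure + pKa table) emulating the titration
#' landmarks of chicken liver bile acid-binding protein: net charge +2 at
#' pH 6.8 rising to +7 at pH 5.0 through the protonation of exactly Glu25,
#' Glu94, Glu101, His83 and His98 (the glutamate/histidine pKa values of
#' those five sites sit between 5 and 6.8; all other sites keep intrinsic
#' values). The structure geometry is synthetic; only the ionizable
#' inventory is meaningful.
#'
#' @param seed RNG seed for the fixture geometry.
#' @param pka_path optional path; when given the pKa table is also written
#'   as a file via [make_pka_file()].
#' @return list: `structure`, `pka` (a `pka_table`), `truth` (expected
#'   charges and flip set).
#' @export
lbabp_like_fixture <- function(seed = 401, pka_path = NULL) {
  n <- 110
  resnames <- rep("GLY", n)
  resnames[c(25, 94, 101, 40, 55, 70)] <- "GLU"
  resnames[c(83, 98)] <- "HIS"
  resnames[c(5, 12, 22, 33, 44, 52, 61, 73, 88, 104, 108)] <- "LYS"
  resnames[c(17, 66)] <- "ARG"
  resnames[c(9, 29, 48, 78, 91)] <- "ASP"
  st <- make_ionizable_protein(resnames, seed = seed)
  pka <- load_pka(st, "builtin")
  shift <- pka$resname == "GLU" & pka$resseq %in% c(25, 94, 101)
  pka$pka[shift] <- 5.9
  shift_h <- pka$resname == "HIS" & pka$resseq %in% c(83, 98)
  pka$pka[shift_h] <- 5.8
  if (!is.null(pka_path))
    make_pka_file(data.frame(chain = pka$chain, resseq = pka$resseq,
                             resname = pka$resname, pka = pka$pka,
                             type = pka$type), pka_path)
  list(structure = st, pka = pka,
       truth = list(z_ph6.8 = 2, z_ph5 = 7,
                    flips = c("GLU25", "GLU94", "GLU101", "HIS83", "HIS98")))
}

#' Synthetic stand-in for the ReP1-NCXSQ ionizable inventory
#'
#' Emulates the titration landmarks of the squid Na/Ca-exchanger regulatory
#' protein: net charge -1 at pH 7, +1 at pH 5.0 (after the protonation of
#' Glu72 and His113), and an isoelectric point of 5.85. The Glu72 and
#' His113 pKa values are the two free parameters of the table and are set
#' so that the fractional net charge crosses zero at pH 5.85; all other
#' sites keep intrinsic values.
#'
#' @inheritParams lbabp_like_fixture
#' @return list: `structure`, `pka`, `truth`.
#' @export
rep1_like_fixture <- function(seed = 402, pka_path = NULL) {
  n <- 115
  resnames <- rep("GLY", n)
  resnames[c(72, 8, 20, 35, 50, 90)] <- "GLU"
  resnames[113] <- "HIS"
  resnames[c(4, 15, 27, 41, 58, 69, 84, 97, 109)] <- "LYS"
  resnames[c(31, 63, 102)] <- "ARG"
  resnames[c(11, 24, 38, 46, 77, 88, 105)] <- "ASP"
  st <- make_ionizable_protein(resnames, seed = seed)
  pka <- load_pka(st, "builtin")
  pka$pka[pka$resname == "HIS" & pka$resseq == 113] <- 5.30
  pka$pka[pka$resname == "GLU" & pka$resseq == 72] <- 6.05
  if (!is.null(pka_path))
    make_pka_file(data.frame(chain = pka$chain, resseq = pka$resseq,
                             resname = pka$resname, pka = pka$pka,
                             type = pka$type), pka_path)
  list(structure = st, pka = pka,
       truth = list(z_ph7 = -1, z_ph5 = 1, pI = 5.85,
                    flips = c("GLU72", "HIS113")))
}
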