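# Protonation equilibria, net charge, isoelectric point, formal partial
# charges on canonical heavy atoms, and the protein macrodipole in Debye.

# 1 e * Angstrom in Debye
E_ANGSTROM_TO_DEBYE <- 4.80321

# Built-in intrinsic pKa values of the ionizable groups (model-compound
# values; used when no external pKa-predictor table is supplied).
INTRINSIC_PKA <- data.frame(
  resname = c("ASP", "GLU", "HIS", "CYS", "TYR", "LYS", "ARG", "NT", "CT"),
  pka     = c(3.65,  4.25,  6.0,   8.3,   10.3,  10.5,  12.5,  8.0,  3.6),
  type    = c("acid", "acid", "base", "acid", "acid", "base", "base",
              "base", "acid"),
  stringsAsFactors = FALSE)

ACID_RES <- c("ASP", "GLU", "CYS", "TYR")
BASE_RES <- c("HIS", "LYS", "ARG")

# Ionizable sites of a structure: side chains plus one N-/C-terminus per
# chain (protein atoms only). Returns a data.frame keyed by (chain, resseq,
# resname) with pseudo-residues NT/CT for the termini.
ionizable_sites <- function(structure) {
  a <- structure$atoms[!structure$atoms$hetero, , drop = FALSE]
  res <- unique(a[, c("chain", "resseq", "resname")])
  side <- res[res$resname %in% c(ACID_RES, BASE_RES), , drop = FALSE]
  term <- do.call(rbind, lapply(split(res, res$chain), function(r) {
    data.frame(chain = r$chain[c(1, nrow(r))],
               resseq = r$resseq[c(1, nrow(r))],
               resname = c("NT", "CT"), stringsAsFactors = FALSE)
  }))
  out <- rbind(side, term)
  rownames(out) <- NULL
  out[order(out$chain, out$resseq, out$resname), , drop = FALSE]
}

site_key <- function(df) paste(df$chain, df$resseq, df$resname, sep = "|")

#' Load a pKa table for the ionizable residues of a structure
#'
#' Either the built-in intrinsic (model-compound) pKa set, or a tab-separated
#' file in the format written by external pKa predictors: columns `chain`,
#' `res_seq`, `res_name`, `pKa`, `type` (`acid`|`base`), '#' comments
#' allowed. Termini are the pseudo-residues `NT`/`CT`. Residues present in
#' the structure but missing from the file fall back to intrinsic values with
#' a warning; file rows that reference residues absent from the structure are
#' a consistency error.
#'
#' @param structure a `protein_structure`.
#' @param source `"builtin"` or a file path.
#' @return data.frame of class `pka_table`: `chain`, `resseq`, `resname`,
#'   `pka`, `type`.
#' @export
load_pka <- function(structure, source = "builtin") {
  sites <- ionizable_sites(structure)
  intr <- INTRINSIC_PKA
  base <- merge(sites, intr, by = "resname", sort = FALSE)
  base <- base[, c("chain", "resseq", "resname", "pka", "type")]
  if (!identical(source, "builtin")) {
    if (!file.exists(source)) stop("pKa file not found: ", source)
    raw <- utils::read.table(source, sep = "\t", header = FALSE,
                             comment.char = "#", stringsAsFactors = FALSE,
                             col.names = c("chain", "resseq", "resname",
                                           "pka", "type"))
    raw$chain <- as.character(raw$chain)
    if (any(raw$pka < 0 | raw$pka > 14))
      stop("pKa out of [0, 14] in ", source)
    if (!all(raw$type %in% c("acid", "base")))
      stop("pKa table type column must be acid|base")
    unknown <- !(site_key(raw) %in% site_key(sites))
    if (any(unknown))
      stop("pKa record(s) reference residues absent from the structure: ",
           paste(site_key(raw)[unknown], collapse = ", "))
    hit <- match(site_key(base), site_key(raw))
    missed <- is.na(hit)
    if (any(missed))
      warning(sum(missed), " ionizable residue(s) missing from pKa file; ",
              "using intrinsic values: ",
              paste(site_key(base)[missed], collapse = ", "))
    base$pka[!missed] <- raw$pka[hit[!missed]]
    base$type[!missed] <- raw$type[hit[!missed]]
  }
  class(base) <- c("pka_table", "data.frame")
  base
}

#' Protonation states at a given pH
#'
#' Discrete mode: a site is protonated iff `pH <= pKa` (tie protonated).
#' Fractional mode: Henderson-Hasselbalch occupancy
#' `1 / (1 + 10^(pH - pKa))`.
#'
#' @param pka a `pka_table`.
#' @param ph pH in `[0, 14]`.
#' @param mode `"discrete"` or `"fractional"`.
#' @return data.frame: the pKa table plus column `protonated` (logical or
#'   fraction in `[0, 1]`).
#' @export
protonation_states <- function(pka, ph, mode = c("discrete", "fractional")) {
  mode <- match.arg(mode)
  if (ph < 0 || ph > 14) stop("pH outside [0, 14]")
  out <- as.data.frame(pka)
  frac <- 1 / (1 + 10^(ph - out$pka))
  out$protonated <- if (mode == "discrete") ph <= out$pka else frac
  attr(out, "ph") <- ph
  attr(out, "mode") <- mode
  out
}

#' Net charge from a protonation map
#'
#' Bases (His, Lys, Arg, N-terminus) contribute +1 when protonated; acids
#' (Asp, Glu, Cys, Tyr, C-terminus) contribute -1 when deprotonated. With a
#' fractional map the contributions are occupancy-weighted.
#'
#' @param prot protonation map from [protonation_states()].
#' @return net charge in elementary charges.
#' @export
net_charge <- function(prot) {
  p <- as.numeric(prot$protonated)
  sum(ifelse(prot$type == "base", p, p - 1))
}

#' Isoelectric point of a pKa table
#'
#' pH at which the fractional net charge crosses zero; the fractional charge
#' is strictly decreasing in pH, so the root (found by bisection to 1e-4) is
#' unique.
#'
#' @param pka a `pka_table`.
#' @param tol bisection tolerance in pH units.
#' @return pI in pH units.
#' @export
isoelectric_point <- function(pka, tol = 1e-4) {
  if (!any(pka$type == "acid") || !any(pka$type == "base"))
    stop("no isoelectric point: table needs at least one acid and one base")
  f <- function(ph) net_charge(protonation_states(pka, ph, "fractional"))
  lo <- 0; hi <- 14
  if (f(lo) < 0 || f(hi) > 0)
    stop("no isoelectric point: fractional charge does not change sign on [0, 14]")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Canonical heavy atoms carrying the formal charge of each ionizable group.
# value = charge per listed atom, state = protonation flag it applies to.
FORMAL_PLACEMENT <- list(
  ASP = list(atoms = c("OD1", "OD2"), q = -0.5, when = FALSE),
  GLU = list(atoms = c("OE1", "OE2"), q = -0.5, when = FALSE),
  CYS = list(atoms = "SG", q = -1, when = FALSE),
  TYR = list(atoms = "OH", q = -1, when = FALSE),
  LYS = list(atoms = "NZ", q = 1, when = TRUE),
  ARG = list(atoms = c("NE", "NH1", "NH2"), q = 1 / 3, when = TRUE),
  HIS = list(atoms = c("ND1", "NE2"), q = 0.5, when = TRUE))

#' Assign partial charges from a protonation map
#'
#' The built-in `"formal"` library places integer group charges on the
#' canonical charged-group heavy atoms (e.g. Asp: -0.5 on each of OD1/OD2
#' when deprotonated; Lys: +1 on NZ when protonated; N-terminus: +1 on the
#' backbone N; C-terminus: -0.5 on O and OXT, or -1 on O when OXT is
#' absent). A charge-library file (`library = path`) assigns every mapped
#' atom: tab-separated columns `resname`, `atom`, `protonated` (0/1),
#' `charge_e`; atoms of a residue absent from the file get zero, and more
#' than 5% unmapped atoms is a coverage error.
#'
#' Fractional protonation maps scale the group charges by occupancy, e.g. a
#' half-protonated His carries +0.25 on each of ND1/NE2.
#'
#' @param structure a `protein_structure`.
#' @param prot protonation map from [protonation_states()].
#' @param library `"formal"` or a charge-library file path.
#' @return object of class `charge_state`: list with `per_atom_charge`
#'   (e, aligned to the atom table), `net_charge`, `ph`, `protonation`.
#' @export
assign_partial_charges <- function(structure, prot, library = "formal") {
  a <- structure$atoms
  q <- numeric(nrow(a))
  prot_rows <- !a$hetero
  if (identical(library, "formal")) {
    pnum <- as.numeric(prot$protonated)
    for (i in seq_len(nrow(prot))) {
      ch <- prot$chain[i]; rs <- prot$resseq[i]; rn <- prot$resname[i]
      if (rn == "NT") {
        idx <- which(prot_rows & a$chain == ch & a$resseq == rs & a$name == "N")
        q[idx] <- q[idx] + pnum[i] * 1
      } else if (rn == "CT") {
        oxt <- which(prot_rows & a$chain == ch & a$resseq == rs & a$name == "OXT")
        o <- which(prot_rows & a$chain == ch & a$resseq == rs & a$name == "O")
        dep <- 1 - pnum[i]  # acid: charge -1 when deprotonated
        if (length(oxt) == 1) {
          q[c(o, oxt)] <- q[c(o, oxt)] - 0.5 * dep
        } else {
          q[o] <- q[o] - 1 * dep
        }
      } else {
        pl <- FORMAL_PLACEMENT[[rn]]
        if (is.null(pl)) next
        idx <- which(prot_rows & a$chain == ch & a$resseq == rs &
                       a$name %in% pl$atoms)
        if (length(idx) == 0) {
          warning("no chargeable atoms found for ", rn, " ", ch, rs)
          next
        }
        occ <- if (pl$when) pnum[i] else 1 - pnum[i]
        # spread the group charge over the atoms actually present
        total <- pl$q * length(pl$atoms) * occ
        q[idx] <- q[idx] + total / length(idx)
      }
    }
  } else {
    if (!file.exists(library)) stop("charge library not found: ", library)
    lib <- utils::read.table(library, sep = "\t", header = FALSE,
                             comment.char = "#", stringsAsFactors = FALSE,
                             col.names = c("resname", "atom", "protonated",
                                           "charge"))
    # protonation flag per residue (discrete; fractional maps are rounded);
    # terminus pseudo-residues do not set the flag of their host residue
    pr <- prot[!(prot$resname %in% c("NT", "CT")), , drop = FALSE]
    pr$flag <- as.integer(round(as.numeric(pr$protonated)))
    key_res <- paste(a$chain, a$resseq, sep = "|")
    pk <- paste(pr$chain, pr$resseq, sep = "|")
    flag <- pr$flag[match(key_res, pk)]
    flag[is.na(flag)] <- 0L
    lk <- paste(lib$resname, lib$atom, lib$protonated)
    ak <- paste(a$resname, a$name, flag)
    hit <- match(ak, lk)
    unmapped <- is.na(hit) & !a$hetero
    if (mean(unmapped[!a$hetero]) > 0.05)
      stop("charge library covers too few atoms; unmapped residues: ",
           paste(unique(a$resname[unmapped]), collapse = ", "))
    q[!is.na(hit)] <- lib$charge[hit[!is.na(hit)]]
  }
  q[a$hetero] <- 0
  structure(list(per_atom_charge = q, net_charge = sum(q),
                 ph = attr(prot, "ph"), protonation = prot,
                 library = if (identical(library, "formal")) "formal" else "file"),
            class = "charge_state")
}

#' Center of mass of selected atoms (Angstrom)
#'
#' @param structure a `protein_structure`.
#' @param indices atom indices (default: all non-hetero atoms).
#' @return length-3 numeric vector.
#' @export
center_of_mass <- function(structure, indices = NULL) {
  a <- structure$atoms
  if (is.null(indices)) indices <- which(!a$hetero)
  if (length(indices) == 0) stop("empty selection for center of mass")
  m <- atomic_mass(a$element[indices])
  xyz <- as.matrix(a[indices, c("x", "y", "z")])
  colSums(xyz * m) / sum(m)
}

#' Protein macrodipole
#'
#' `mu = sum q_i (r_i - r_0)` over the assigned per-atom charges, reported in
#' Debye (1 e*Angstrom = 4.80321 D). For a neutral charge set the result is
#' origin-independent; for a net-charged protein the origin matters and is
#' recorded in the result. HETATM sites carry zero charge and do not
#' contribute.
#'
#' @param charge_state a `charge_state` from [assign_partial_charges()].
#' @param structure the matching `protein_structure`.
#' @param origin_rule `"com"` (mass-weighted, default), `"cog"` (geometric
#'   center of non-hetero atoms) or a length-3 numeric vector (Angstrom).
#' @return object of class `dipole_result`: list with `vector` (D),
#'   `magnitude` (D), `origin` (Angstrom), `origin_rule`.
#' @export
macrodipole <- function(charge_state, structure, origin_rule = "com") {
  q <- charge_state$per_atom_charge
  if (length(q) != nrow(structure$atoms))
    stop("charge state does not align with structure atoms")
  if (all(q == 0))
    warning("all charges zero; returning zero dipole")
  if (is.numeric(origin_rule) && length(origin_rule) == 3) {
    r0 <- origin_rule; rule <- "custom"
  } else if (identical(origin_rule, "com")) {
    r0 <- center_of_mass(structure); rule <- "center-of-mass"
  } else if (identical(origin_rule, "cog")) {
    idx <- which(!structure$atoms$hetero)
    r0 <- colMeans(coords(structure)[idx, , drop = FALSE])
    rule <- "center-of-geometry"
  } else stop("unknown origin rule: ", origin_rule)
  xyz <- coords(structure)
  mu_eA <- colSums(xyz * q) - sum(q) * r0
  vec <- mu_eA * E_ANGSTROM_TO_DEBYE
  structure(list(vector = unname(vec), magnitude = sqrt(sum(vec^2)),
                 origin = unname(r0), origin_rule = rule),
            class = "dipole_result")
}

#' @export
print.dipole_result <- function(x, ...) {
  cat(sprintf("macrodipole: |mu| = %.2f D, vector (%.2f, %.2f, %.2f) D, origin %s\n",
              x$magnitude, x$vector[1], x$vector[2], x$vector[3], x$origin_rule))
  invisible(x)
}

#' Angle between a dipole and a reference axis
#'
#' @param dipole a `dipole_result` (or length-3 vector in any units).
#' @param axis length-3 reference vector.
#' @return angle in degrees, in `[0, 180]`.
#' @export
dipole_axis_angle <- function(dipole, axis) {
  v <- if (inherits(dipole, "dipole_result")) dipole$vector else dipole
  nv <- sqrt(sum(v^2)); na <- sqrt(sum(axis^2))
  if (nv == 0 || na == 0) stop("undefined angle: zero vector")
  acos(max(-1, min(1, sum(v * axis) / (nv * na)))) * 180 / pi
}
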