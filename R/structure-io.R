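# Structure and trajectory input: PDB (via bio3d), a GRO-dialect reader,
# atom selection, element inference and atomic masses.
# Internal length unit is Angstrom; trajectory times are ns.

#' Construct a protein structure object
#'
#' A light container for an atom table parsed from a coordinate file. All
#' downstream electrostatics and trajectory observables operate on this class.
#'
#' @param atoms data.frame with columns `serial`, `name`, `resname`, `chain`,
#'   `resseq`, `x`, `y`, `z` (Angstrom), `element`, `hetero` (logical).
#' @param source_id free-text identifier (e.g. a PDB ID or fixture label).
#' @param model_index integer model number the atoms came from.
#' @return object of class `protein_structure`.
#' @export
protein_structure <- function(atoms, source_id = "", model_index = 1L) {
  required <- c("serial", "name", "resname", "chain", "resseq",
                "x", "y", "z", "element", "hetero")
  missing <- setdiff(required, names(atoms))
  if (length(missing) > 0)
    stop("atom table lacks columns: ", paste(missing, collapse = ", "))
  if (nrow(atoms) < 1) stop("empty structure: no atoms")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite coordinates in atom table")
  if (any(!nzchar(atoms$resname))) stop("empty residue name in atom table")
  if (anyDuplicated(atoms$serial)) stop("duplicate atom serials within model")
  structure(list(atoms = as.data.frame(atoms, stringsAsFactors = FALSE),
                 source_id = source_id,
                 model_index = as.integer(model_index)),
            class = "protein_structure")
}

#' @export
print.protein_structure <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("protein_structure '%s': %d atoms, %d residues, chains %s\n",
              x$source_id, nrow(a),
              length(unique(paste(a$chain, a$resseq))),
              paste(unique(a$chain), collapse = ",")))
  invisible(x)
}

#' Coordinates of a structure as an n x 3 matrix (Angstrom)
#' @param structure a `protein_structure`.
#' @return numeric matrix with columns x, y, z.
#' @export
coords <- function(structure) {
  as.matrix(structure$atoms[, c("x", "y", "z")])
}

#' Construct a trajectory object
#'
#' @param times numeric vector of frame times in ns, strictly increasing.
#' @param frames list of `protein_structure`, identical atom count and order.
#' @param box optional list of per-frame box vectors (nm) or NULL.
#' @param source free-text origin.
#' @return object of class `md_trajectory`.
#' @export
md_trajectory <- function(times, frames, box = NULL, source = "") {
  if (length(times) != length(frames))
    stop("times and frames differ in length")
  if (length(frames) < 1) stop("empty trajectory")
  if (any(diff(times) <= 0)) stop("frame times must be strictly increasing")
  n <- vapply(frames, function(f) nrow(f$atoms), integer(1))
  if (length(unique(n)) != 1)
    stop("frames have inconsistent atom counts: ",
         paste(unique(n), collapse = ", "))
  nm0 <- frames[[1]]$atoms$name
  for (f in frames) if (!identical(f$atoms$name, nm0))
    stop("frames have inconsistent atom ordering")
  structure(list(times = as.numeric(times), frames = frames,
                 box = box, source = source),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat(sprintf("md_trajectory '%s': %d frames x %d atoms, t = %.3g..%.3g ns\n",
              x$source, length(x$frames), nrow(x$frames[[1]]$atoms),
              x$times[1], x$times[length(x$times)]))
  invisible(x)
}

# Element inference from a PDB atom name when columns 77-78 are absent.
# Digits are stripped; two-letter elements are only trusted when the name
# starts in column 13 (handled upstream); here we use the first alphabetic
# character, with a special case for common two-letter ions.
infer_element <- function(name) {
  two <- c("CL", "NA", "MG", "ZN", "FE", "CA", "MN", "BR")
  nm <- toupper(trimws(name))
  out <- character(length(nm))
  for (i in seq_along(nm)) {
    s <- gsub("[^A-Z]", "", nm[i])
    if (s %in% two) out[i] <- substr(s, 1, 2)
    else out[i] <- substr(s, 1, 1)
  }
  out
}

#' Standard atomic masses (u) by element symbol
#'
#' Unknown elements fall back to the mass of carbon with a warning; this keeps
#' center-of-mass calculations defined for coarse or synthetic sites.
#' @param element character vector of element symbols.
#' @return numeric vector of masses in unified atomic mass units.
#' @export
atomic_mass <- function(element) {
  tab <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
           P = 30.974, CL = 35.45, NA_ = 22.990, MG = 24.305, ZN = 65.38,
           FE = 55.845, CA = 40.078, MN = 54.938, BR = 79.904, K = 39.098)
  key <- toupper(element)
  key[key == "NA"] <- "NA_"
  m <- tab[key]
  if (any(is.na(m))) {
    warning("unknown element(s) ", paste(unique(element[is.na(m)]), collapse = ","),
            "; assigning carbon mass")
    m[is.na(m)] <- tab[["C"]]
  }
  unname(m)
}

# Pre-scan of a PDB file: coordinate fields of every ATOM/HETATM line must
# parse; reports the 1-based line number of the first malformed record.
validate_pdb_lines <- function(lines) {
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  if (!any(is_atom)) stop("empty structure: file contains no ATOM records")
  for (i in which(is_atom)) {
    xyz <- suppressWarnings(as.numeric(c(substr(lines[i], 31, 38),
                                         substr(lines[i], 39, 46),
                                         substr(lines[i], 47, 54))))
    if (any(is.na(xyz)))
      stop(sprintf("malformed coordinate field at line %d: '%s'", i, lines[i]))
  }
  invisible(TRUE)
}

#' Read a PDB file
#'
#' Parses ATOM (and optionally HETATM) records through bio3d. Multi-MODEL
#' files become trajectories with one frame per MODEL block. Alternate
#' locations other than ' ' or 'A' are dropped. Elements are taken from
#' columns 77-78 when present, otherwise inferred from the atom name.
#'
#' @param path file path.
#' @param model integer model number or `"all"` (default). With `"all"` a
#'   single-model file returns a `protein_structure`, a multi-model file an
#'   `md_trajectory` (frame times are the 0-based model index in ns).
#' @param include_hetero keep HETATM records (default TRUE; they are excluded
#'   from charge and dipole calculations downstream via the `hetero` flag).
#' @return `protein_structure` or `md_trajectory`.
#' @export
read_pdb <- function(path, model = "all", include_hetero = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  validate_pdb_lines(lines)
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- pdb$atom
  keep <- is.na(at$alt) | at$alt %in% c("", " ", "A")
  if (!include_hetero) keep <- keep & at$type == "ATOM"
  at <- at[keep, , drop = FALSE]
  if (nrow(at) == 0) stop("empty structure: no atoms after filtering")
  elesy <- at$elesy
  bad <- is.na(elesy) | !nzchar(trimws(elesy))
  elesy[bad] <- infer_element(at$elety[bad])
  chain <- at$chain
  chain[is.na(chain)] <- " "
  mk_atoms <- function(xyz_row) {
    data.frame(serial = at$eleno, name = at$elety, resname = at$resid,
               chain = chain, resseq = at$resno,
               x = xyz_row[seq(1, length(xyz_row), 3)][keep_idx],
               y = xyz_row[seq(2, length(xyz_row), 3)][keep_idx],
               z = xyz_row[seq(3, length(xyz_row), 3)][keep_idx],
               element = trimws(elesy), hetero = at$type == "HETATM",
               stringsAsFactors = FALSE)
  }
  keep_idx <- which(keep)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nmod <- nrow(xyz)
  src <- sub("\\.pdb$", "", basename(path), ignore.case = TRUE)
  if (identical(model, "all") && nmod > 1) {
    frames <- lapply(seq_len(nmod), function(m)
      protein_structure(mk_atoms(xyz[m, ]), source_id = src, model_index = m))
    return(md_trajectory(times = seq_len(nmod) - 1, frames = frames,
                         source = src))
  }
  m <- if (identical(model, "all")) 1L else as.integer(model)
  if (m < 1 || m > nmod) stop("model index out of range: ", m)
  protein_structure(mk_atoms(xyz[m, ]), source_id = src, model_index = m)
}

#' Select atoms of a structure by named predicates
#'
#' Predicates combine with AND; each accepts a vector of admissible values.
#' Unknown predicate names are a configuration error.
#'
#' @param structure a `protein_structure`.
#' @param ... named predicates among `name`, `resname`, `chain`, `resseq`,
#'   `element`, `hetero` (logical scalar).
#' @return integer vector of atom indices in original order (possibly empty).
#' @export
select_atoms <- function(structure, ...) {
  sel <- list(...)
  known <- c("name", "resname", "chain", "resseq", "element", "hetero")
  bad <- setdiff(names(sel), known)
  if (length(bad) > 0 || (length(sel) > 0 && any(!nzchar(names(sel)))))
    stop("unknown selector key(s): ", paste(bad, collapse = ", "))
  a <- structure$atoms
  keep <- rep(TRUE, nrow(a))
  for (k in names(sel)) keep <- keep & (a[[k]] %in% sel[[k]])
  which(keep)
}

#' Read a GRO-dialect multi-frame coordinate file
#'
#' Fixed-width records (title, atom count, atom lines, box line) repeated per
#' frame. Coordinates are nm in the file and converted to Angstrom
#' internally; the box line is kept in nm. A `t=` field in the title line is
#' parsed as the frame time in ps (converted to ns), otherwise frame indices
#' are used.
#'
#' @param path file path.
#' @return an `md_trajectory` (single-frame files give a 1-frame trajectory).
#' @export
read_gro_frames <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- sub("\r$", "", readLines(path, warn = FALSE))
  i <- 1L
  frames <- list(); times <- numeric(0); boxes <- list()
  natoms_ref <- NA_integer_
  nf <- 0L
  while (i <= length(lines) && nzchar(trimws(lines[i]))) {
    title <- lines[i]
    n <- suppressWarnings(as.integer(trimws(lines[i + 1])))
    if (is.na(n)) stop("format error: bad atom count at line ", i + 1)
    if (is.na(natoms_ref)) natoms_ref <- n
    if (n != natoms_ref)
      stop("format error: inconsistent atom counts between frames (",
           natoms_ref, " vs ", n, ")")
    if (i + 1 + n + 1 > length(lines))
      stop("format error: truncated frame starting at line ", i)
    rec <- lines[(i + 2):(i + 1 + n)]
    resseq <- as.integer(substr(rec, 1, 5))
    resname <- trimws(substr(rec, 6, 10))
    name <- trimws(substr(rec, 11, 15))
    serial <- suppressWarnings(as.integer(substr(rec, 16, 20)))
    x <- as.numeric(substr(rec, 21, 28))
    y <- as.numeric(substr(rec, 29, 36))
    z <- as.numeric(substr(rec, 37, 44))
    if (any(is.na(x) | is.na(y) | is.na(z)))
      stop("format error: malformed coordinate in frame starting at line ", i)
    serial[is.na(serial)] <- seq_len(n)[is.na(serial)]
    # GRO serials wrap at 99999; re-serialize to keep them unique
    atoms <- data.frame(serial = seq_len(n), name = name, resname = resname,
                        chain = " ", resseq = resseq,
                        x = x * 10, y = y * 10, z = z * 10,
                        element = infer_element(name), hetero = FALSE,
                        stringsAsFactors = FALSE)
    box <- suppressWarnings(as.numeric(strsplit(trimws(lines[i + n + 2]),
                                                "\\s+")[[1]]))
    nf <- nf + 1L
    t_ps <- NA_real_
    tm <- regmatches(title, regexpr("t=\\s*[-0-9.eE+]+", title))
    if (length(tm) == 1)
      t_ps <- suppressWarnings(as.numeric(sub("t=\\s*", "", tm)))
    times <- c(times, if (is.finite(t_ps)) t_ps / 1000 else nf - 1)
    frames[[nf]] <- protein_structure(atoms, source_id = basename(path),
                                      model_index = nf)
    boxes[[nf]] <- box[seq_len(min(3, length(box)))]
    i <- i + n + 3L
  }
  if (nf == 0) stop("format error: no frames in ", path)
  md_trajectory(times, frames, box = boxes, source = basename(path))
}

# --- fixture writers -------------------------------------------------------

# Fixed-column PDB ATOM line for our own generated fixtures
# (name 13-16, altLoc 17, resName 18-20, chainID 22, resSeq 23-26).
format_pdb_atom <- function(a) {
  sprintf("ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          a$serial %% 100000,
          ifelse(nchar(a$name) < 4, paste0(" ", a$name), a$name),
          a$resname, a$chain, a$resseq %% 10000, a$x, a$y, a$z, a$element)
}

#' Write a structure (or list of frames) to a PDB file
#'
#' Minimal fixed-column writer used by the synthetic-data generators; frames
#' are wrapped in MODEL/ENDMDL blocks. Coordinates keep PDB precision
#' (3 decimals, Angstrom).
#'
#' @param x a `protein_structure` or a list of them.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pdb_frames <- function(x, path) {
  if (inherits(x, "protein_structure")) x <- list(x)
  con <- file(path, "w")
  on.exit(close(con))
  multi <- length(x) > 1
  for (m in seq_along(x)) {
    if (multi) writeLines(sprintf("MODEL     %4d", m), con)
    a <- x[[m]]$atoms
    for (i in seq_len(nrow(a))) writeLines(format_pdb_atom(a[i, ]), con)
    writeLines(if (multi) "ENDMDL" else "TER", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Write a trajectory to a GRO-dialect file
#'
#' @param traj an `md_trajectory` (coordinates Angstrom, written as nm).
#' @param path output file.
#' @param box box vector in nm written on each frame's box line.
#' @return `path`, invisibly.
#' @export
write_gro_frames <- function(traj, path, box = c(7, 7, 10)) {
  con <- file(path, "w")
  on.exit(close(con))
  for (m in seq_along(traj$frames)) {
    a <- traj$frames[[m]]$atoms
    writeLines(sprintf("synthetic frame t= %.4f", traj$times[m] * 1000), con)
    writeLines(sprintf("%5d", nrow(a)), con)
    writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       a$resseq %% 100000, substr(a$resname, 1, 5),
                       substr(a$name, 1, 5), a$serial %% 100000,
                       a$x / 10, a$y / 10, a$z / 10), con)
    writeLines(sprintf("%10.5f%10.5f%10.5f", box[1], box[2], box[3]), con)
  }
  invisible(path)
}
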