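## trajectory_io: topology + multi-frame coordinates in a uniform nm/ps
## representation.  PDB parsing/writing is delegated to bio3d; the plain
## frames format is a documented package-native text format.

#' Build a topology object
#'
#' A topology holds per-atom metadata (name, element, residue, chain) for a
#' structure whose coordinates live in a separate trajectory.  Atom indices
#' are the row numbers of `atoms` (contiguous from 1); every atom belongs to
#' exactly one residue and every residue to exactly one chain.
#'
#' @param atoms data.frame with columns `elety` (atom name), `elesy`
#'   (element symbol), `resid` (residue name), `resno` (residue number,
#'   as deposited), `chain` (chain label).
#' @return An object of class `hj_topology`.
#' @export
topology <- function(atoms) {
  stopifnot(is.data.frame(atoms))
  need <- c("elety", "elesy", "resid", "resno", "chain")
  miss <- setdiff(need, names(atoms))
  if (length(miss))
    stop("topology metadata error: missing column(s) ", paste(miss, collapse = ", "))
  if (any(is.na(atoms$chain) | atoms$chain == ""))
    stop("topology metadata error: atoms without chain labels")
  atoms <- as.data.frame(atoms[, need], stringsAsFactors = FALSE)
  rownames(atoms) <- NULL
  # residue -> chain uniqueness
  rkey <- paste(atoms$chain, atoms$resno, atoms$resid, sep = "|")
  chains <- sort(unique(atoms$chain))
  strands <- lapply(chains, function(ch) {
    sub <- atoms[atoms$chain == ch, , drop = FALSE]
    unique(sub$resno)
  })
  names(strands) <- chains
  out <- list(atoms = atoms, natoms = nrow(atoms), strands = strands,
              masses = atom_masses(atoms$elesy, atoms$elety))
  class(out) <- "hj_topology"
  out
}

#' @export
print.hj_topology <- function(x, ...) {
  cat("hj_topology:", x$natoms, "atoms,",
      length(unique(paste(x$atoms$chain, x$atoms$resno))), "residues, chains",
      paste(names(x$strands), collapse = ""), "\n")
  invisible(x)
}

#' Read a structure file into a topology and a single coordinate frame
#'
#' Coordinates are converted to nanometres at the boundary (PDB is Angstrom
#' native).  Residue numbering and chain labels are preserved verbatim.
#'
#' @param path path to a PDB file.
#' @param format file format; only `"pdb"` is supported.
#' @return list with elements `topology` (class `hj_topology`) and `coords`
#'   (natoms x 3 matrix, nm).
#' @export
read_structure <- function(path, format = c("pdb")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("format error: file not found: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)),
    error = function(e) stop("format error: cannot parse PDB file ", path,
                             " (", conditionMessage(e), ")", call. = FALSE))
  atm <- pdb$atom
  if (nrow(atm) == 0L) stop("format error: no ATOM records in ", path)
  if (all(is.na(atm$chain) | atm$chain == ""))
    stop("metadata error: missing chain labels in ", path)
  topo <- topology(data.frame(elety = atm$elety, elesy = atm$elesy,
                              resid = atm$resid, resno = atm$resno,
                              chain = atm$chain, stringsAsFactors = FALSE))
  coords <- cbind(atm$x, atm$y, atm$z) / 10  # Angstrom -> nm
  colnames(coords) <- c("x", "y", "z")
  list(topology = topo, coords = coords)
}

#' Construct a trajectory from a topology and a list of coordinate frames
#'
#' @param topology an `hj_topology`.
#' @param frames list of natoms x 3 coordinate matrices (nm), or a
#'   3-D array `[frame, atom, xyz]`.
#' @param dt frame spacing, ps.
#' @param t0 time of the first frame, ps.
#' @return An object of class `hj_trajectory` with fields `topology`,
#'   `xyz` (n_frames x 3*natoms matrix, frame-major, nm), `times` (ps), `dt`.
#' @export
as_trajectory <- function(topology, frames, dt, t0 = 0) {
  stopifnot(inherits(topology, "hj_topology"), dt > 0)
  if (is.array(frames) && length(dim(frames)) == 3L) {
    frames <- lapply(seq_len(dim(frames)[1]), function(i) frames[i, , , drop = TRUE])
  }
  n <- length(frames)
  xyz <- matrix(NA_real_, nrow = n, ncol = 3L * topology$natoms)
  for (i in seq_len(n)) {
    fr <- frames[[i]]
    if (!is.matrix(fr) || nrow(fr) != topology$natoms || ncol(fr) != 3L)
      stop("frame-consistency error: frame ", i, " has wrong dimensions")
    xyz[i, ] <- as.numeric(t(fr))
  }
  out <- list(topology = topology, xyz = xyz,
              times = t0 + dt * (seq_len(n) - 1), dt = dt)
  class(out) <- "hj_trajectory"
  out
}

#' @export
print.hj_trajectory <- function(x, ...) {
  cat("hj_trajectory:", n_frames(x), "frames x", x$topology$natoms,
      "atoms, dt =", x$dt, "ps\n")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj an `hj_trajectory`.
#' @export
n_frames <- function(traj) nrow(traj$xyz)

#' Extract one frame's coordinates
#' @param traj an `hj_trajectory`.
#' @param i frame index (1-based).
#' @return natoms x 3 matrix, nm.
#' @export
frame_coords <- function(traj, i) {
  stopifnot(i >= 1L, i <= n_frames(traj))
  m <- matrix(traj$xyz[i, ], ncol = 3L, byrow = TRUE)
  colnames(m) <- c("x", "y", "z")
  m
}

#' Read a multi-frame coordinate file against a known topology
#'
#' Supports multi-model PDB (`format = "pdb"`) and the package's plain
#' frames text format (`format = "frames"`): a header line
#' `"natoms dt_ps"` followed, per frame, by one `"x y z"` line per atom in
#' nm.  Every frame must match the topology's atom count.
#'
#' @param topology an `hj_topology` the frames must conform to.
#' @param path input file.
#' @param format `"pdb"` or `"frames"`.
#' @param dt frame spacing in ps; required for PDB input, read from the
#'   header for frames input (a supplied value overrides the header).
#' @param t0 time of the first frame, ps.
#' @return An `hj_trajectory`.
#' @export
read_trajectory <- function(topology, path, format = c("pdb", "frames"),
                            dt = NULL, t0 = 0) {
  format <- match.arg(format)
  stopifnot(inherits(topology, "hj_topology"))
  if (!file.exists(path)) stop("format error: file not found: ", path)
  if (format == "pdb") {
    if (is.null(dt)) stop("configuration error: dt (ps) required for PDB input")
    pdb <- tryCatch(
      suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)),
      error = function(e) stop("format error: cannot parse PDB file ", path,
                               " (", conditionMessage(e), ")", call. = FALSE))
    if (nrow(pdb$atom) != topology$natoms)
      stop("frame-consistency error: file has ", nrow(pdb$atom),
           " atoms per frame, topology has ", topology$natoms)
    xyz <- as.matrix(pdb$xyz) / 10  # Angstrom -> nm
  } else {
    lines <- readLines(path)
    lines <- lines[!grepl("^\\s*(#|$)", lines)]
    if (!length(lines)) stop("format error: empty frames file ", path)
    hdr <- scan(text = lines[1], quiet = TRUE)
    if (length(hdr) != 2L) stop("format error: frames header must be 'natoms dt_ps'")
    natoms <- as.integer(hdr[1])
    if (is.null(dt)) dt <- hdr[2]
    if (natoms != topology$natoms)
      stop("frame-consistency error: header natoms ", natoms,
           " != topology atoms ", topology$natoms)
    body <- lines[-1]
    if (length(body) %% natoms != 0L) {
      bad <- length(body) %/% natoms + 1L
      stop("frame-consistency error: frame ", bad, " is incomplete in ", path)
    }
    vals <- scan(text = body, quiet = TRUE)
    if (length(vals) != 3L * length(body))
      stop("format error: non-numeric coordinate line in ", path)
    nfr <- length(body) %/% natoms
    xyz <- matrix(vals, nrow = nfr, ncol = 3L * natoms, byrow = TRUE)
  }
  if (is.null(dt) || dt <= 0) stop("configuration error: invalid dt")
  frames <- lapply(seq_len(nrow(xyz)),
                   function(i) matrix(xyz[i, ], ncol = 3L, byrow = TRUE))
  as_trajectory(topology, frames, dt = dt, t0 = t0)
}

#' Write a trajectory to disk
#'
#' PDB output writes one MODEL per frame (coordinates nm -> Angstrom);
#' frames output writes the plain text format read by [read_trajectory()].
#'
#' @param traj an `hj_trajectory`.
#' @param path output file.
#' @param format `"pdb"` or `"frames"`.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path, format = c("pdb", "frames")) {
  format <- match.arg(format)
  stopifnot(inherits(traj, "hj_trajectory"))
  a <- traj$topology$atoms
  if (format == "pdb") {
    bio3d::write.pdb(file = path, xyz = traj$xyz * 10,
                     resno = a$resno, resid = a$resid, chain = a$chain,
                     elety = a$elety, elesy = a$elesy,
                     eleno = seq_len(nrow(a)))
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("%d %.6f", traj$topology$natoms, traj$dt), con)
    for (i in seq_len(n_frames(traj))) {
      fr <- frame_coords(traj, i)
      writeLines(sprintf("%.6f %.6f %.6f", fr[, 1], fr[, 2], fr[, 3]), con)
    }
  }
  invisible(path)
}

#' Discard burn-in and subsample a trajectory
#'
#' Retains frames with time >= `burn_in`, then every `stride` ps starting
#' from the earliest retained frame.  `stride` must be a positive integer
#' multiple of the trajectory's dt.  An empty selection is legal and yields
#' a 0-frame trajectory that downstream analyses refuse.
#'
#' @param traj an `hj_trajectory`.
#' @param burn_in initial time span to drop, ps (default 0).
#' @param stride sampling interval, ps (default `traj$dt`).
#' @return An `hj_trajectory` with the retained frames; `dt` becomes `stride`.
#' @export
select_frames <- function(traj, burn_in = 0, stride = NULL) {
  stopifnot(inherits(traj, "hj_trajectory"), burn_in >= 0)
  stride <- stride %||% traj$dt
  ratio <- stride / traj$dt
  if (stride <= 0 || abs(ratio - round(ratio)) > 1e-9 || round(ratio) < 1)
    stop("configuration error: stride (", stride,
         " ps) must be a positive multiple of dt (", traj$dt, " ps)")
  keep <- which(traj$times >= burn_in - 1e-9)
  if (length(keep)) {
    t0 <- traj$times[keep[1]]
    k <- (traj$times[keep] - t0) / stride
    keep <- keep[abs(k - round(k)) < 1e-6]
  }
  out <- traj
  out$xyz <- traj$xyz[keep, , drop = FALSE]
  out$times <- traj$times[keep]
  out$dt <- stride
  out
}
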