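## dipole_geometry: per-frame transition-dipole vectors for each dye, the
## pairwise orientation factor kappa and the centre-to-centre distance R.

#' Define a dye: residue selection, dipole end atoms, dipole magnitude
#'
#' The transition dipole of a cyanine runs along the polymethine long
#' axis; its geometric stand-in is the segment between the centroids of
#' two end-atom selections.  When the end selections are omitted they
#' default to the two indolenine-ring nitrogens: at extraction time the
#' residue must then contain exactly two nitrogen atoms, one per end.
#'
#' @param label short label, e.g. `"Cy5_A"`.
#' @param chain chain the dye residue sits on.
#' @param resno residue number of the dye residue.
#' @param resname optional residue name to match (e.g. `"CY5"`).
#' @param end_r,end_s character vectors of atom names whose centroids are
#'   the dipole head (`r`) and tail (`s`); must be disjoint and non-empty
#'   when given.
#' @param mu_debye transition dipole magnitude, Debye (>= 0).
#' @return An object of class `dye_definition`.
#' @export
dye_definition <- function(label, chain, resno, resname = NULL,
                           end_r = NULL, end_s = NULL, mu_debye = 0) {
  if (xor(is.null(end_r), is.null(end_s)))
    stop("configuration error: give both end_r and end_s, or neither")
  if (!is.null(end_r)) {
    if (!length(end_r) || !length(end_s))
      stop("configuration error: empty end-atom selection for dye ", label)
    if (length(intersect(end_r, end_s)))
      stop("configuration error: end_r and end_s overlap for dye ", label)
  }
  if (!is.numeric(mu_debye) || mu_debye < 0)
    stop("configuration error: mu_debye must be >= 0")
  out <- list(label = label, chain = chain, resno = as.integer(resno),
              resname = resname, end_r = end_r, end_s = end_s,
              mu_debye = mu_debye)
  class(out) <- "dye_definition"
  out
}

# atom row indices of the dye residue in a topology
dye_atom_indices <- function(topology, dye) {
  a <- topology$atoms
  idx <- which(a$chain == dye$chain & a$resno == dye$resno)
  if (!is.null(dye$resname)) idx <- idx[a$resid[idx] == dye$resname]
  if (!length(idx))
    stop("selection error: no atoms for dye ", dye$label, " (chain ",
         dye$chain, ", residue ", dye$resno, ")")
  idx
}

# resolve the two end-atom index sets for a dye within a topology
dye_end_indices <- function(topology, dye) {
  idx <- dye_atom_indices(topology, dye)
  a <- topology$atoms
  if (is.null(dye$end_r)) {
    nit <- idx[toupper(trimws(a$elesy[idx])) == "N"]
    if (length(nit) != 2L)
      stop("selection error: dye ", dye$label, " has ", length(nit),
           " nitrogen atoms; explicit end_r/end_s selections are required")
    return(list(r = nit[1], s = nit[2], all = idx))
  }
  pick <- function(names, which_end) {
    sel <- idx[a$elety[idx] %in% names]
    missing <- setdiff(names, a$elety[idx])
    if (length(missing))
      stop("selection error: atom(s) ", paste(missing, collapse = ", "),
           " of ", which_end, " not found in dye ", dye$label)
    sel
  }
  list(r = pick(dye$end_r, "end_r"), s = pick(dye$end_s, "end_s"), all = idx)
}

#' Extract a dye's transition-dipole geometry from one frame
#'
#' The dipole head `r` is the centroid of the `end_r` atoms, the tail `s`
#' the centroid of the `end_s` atoms; the unit vector points from tail to
#' head, `u = (r - s)/|r - s|`, and the centre is the midpoint `(r + s)/2`.
#'
#' @param coords natoms x 3 frame coordinates, nm.
#' @param topology the matching `hj_topology`.
#' @param dye a [dye_definition()].
#' @return An object of class `dipole_geometry`: list with `r`, `s`,
#'   `center` (nm), unit vector `u`, and `length` (nm).
#' @export
dipole_from_frame <- function(coords, topology, dye) {
  ends <- dye_end_indices(topology, dye)
  r <- colMeans(coords[ends$r, , drop = FALSE])
  s <- colMeans(coords[ends$s, , drop = FALSE])
  l <- vnorm(r - s)
  if (l < 1e-9)
    stop("degenerate-geometry error: coincident dipole ends for dye ", dye$label)
  out <- list(r = unname(r), s = unname(s), center = unname((r + s) / 2),
              u = unname((r - s) / l), length = l)
  class(out) <- "dipole_geometry"
  out
}

#' Build a dipole geometry from explicit end points
#'
#' Convenience constructor used by the synthetic generator and in tests.
#'
#' @param r,s dipole head and tail positions, nm.
#' @return A `dipole_geometry`.
#' @export
dipole_geometry <- function(r, s) {
  l <- vnorm(r - s)
  if (l < 1e-9) stop("degenerate-geometry error: coincident dipole ends")
  out <- list(r = r, s = s, center = (r + s) / 2, u = (r - s) / l, length = l)
  class(out) <- "dipole_geometry"
  out
}

#' Orientation factor kappa of two transition dipoles
#'
#' \deqn{\kappa_{m,n} = \hat\mu_m\cdot\hat\mu_n
#'   - 3(\hat R_{m,n}\cdot\hat\mu_m)(\hat R_{m,n}\cdot\hat\mu_n)}
#' where \eqn{\hat R_{m,n}} is the unit vector between the dipole centres.
#' The signed value is returned; \eqn{|\kappa| \le 2}, with 2 attained only
#' for collinear dipoles.  \eqn{|\kappa|} below 1 indicates predominantly
#' stacked (H-like) dyes, above 1 predominantly end-to-end (J-like).
#'
#' @param m,n `dipole_geometry` objects.
#' @return Signed scalar kappa.
#' @export
orientation_factor <- function(m, n) {
  Rv <- n$center - m$center
  R <- vnorm(Rv)
  if (R < 1e-9) stop("degenerate-geometry error: coincident dipole centers")
  Rhat <- Rv / R
  sum(m$u * n$u) - 3 * sum(Rhat * m$u) * sum(Rhat * n$u)
}

#' Centre-to-centre distance of two dipoles
#'
#' @param m,n `dipole_geometry` objects.
#' @return Euclidean distance of the dipole centres, nm.
#' @export
center_distance <- function(m, n) vnorm(m$center - n$center)

#' Per-frame dimer observations over a trajectory
#'
#' Applies burn-in and stride via [select_frames()], then computes one
#' record per retained frame: time (ps), centre distance `R_nm`, signed
#' `kappa` and `abs_kappa`, and -- when a [coupling_config()] is supplied
#' and both dyes carry a dipole magnitude -- the signed extended-dipole
#' coupling `J_meV` and `abs_J`.
#'
#' @param traj an `hj_trajectory`.
#' @param dye_m,dye_n [dye_definition()]s.
#' @param stride sampling interval, ps (default: every frame).
#' @param burn_in initial span to drop, ps.
#' @param coupling optional [coupling_config()]; enables the J columns.
#' @return data.frame of observations in time order.
#' @export
observe_dimer <- function(traj, dye_m, dye_n, stride = NULL, burn_in = 0,
                          coupling = NULL) {
  sub <- select_frames(traj, burn_in = burn_in, stride = stride)
  nf <- n_frames(sub)
  if (nf == 0L) stop("analysis error: no frames retained after burn-in/stride")
  with_J <- !is.null(coupling) && dye_m$mu_debye > 0 && dye_n$mu_debye > 0
  R <- kap <- J <- numeric(nf)
  topo <- sub$topology
  for (i in seq_len(nf)) {
    fr <- frame_coords(sub, i)
    gm <- dipole_from_frame(fr, topo, dye_m)
    gn <- dipole_from_frame(fr, topo, dye_n)
    R[i] <- center_distance(gm, gn)
    kap[i] <- orientation_factor(gm, gn)
    if (with_J)
      J[i] <- extended_dipole_J(gm, gn, dye_m$mu_debye, dye_n$mu_debye, coupling)
  }
  out <- data.frame(time = sub$times, R_nm = R, kappa = kap,
                    abs_kappa = abs(kap))
  if (with_J) {
    out$J_meV <- J
    out$abs_J <- abs(J)
  }
  out
}
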