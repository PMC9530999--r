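## junction_geometry: Holliday-junction arm descriptors.  The axis of a
## duplex arm is the first principal direction of its ordered base-pair
## centroids -- an explicit package convention, validated on constructed
## geometries with known angles.

#' Define a duplex arm by its two strand spans
#'
#' The two spans list, in pairing order, the residues of the two strands
#' that form the arm; the i-th residue of `span1` pairs with the i-th of
#' `span2`, so their mid-point is a base-pair centroid.
#'
#' @param label arm label.
#' @param chain1,resnos1 chain and ordered residue numbers of one strand.
#' @param chain2,resnos2 chain and ordered residue numbers of the partner
#'   strand, in pairing order (same length as `resnos1`).
#' @return An object of class `arm_definition`.
#' @export
arm_definition <- function(label, chain1, resnos1, chain2, resnos2) {
  if (!length(resnos1) || length(resnos1) != length(resnos2))
    stop("configuration error: arm spans must be non-empty and equal length")
  out <- list(label = label, chain1 = chain1, resnos1 = as.integer(resnos1),
              chain2 = chain2, resnos2 = as.integer(resnos2))
  class(out) <- "arm_definition"
  out
}

residue_com <- function(coords, topology, chain, resno) {
  idx <- which(topology$atoms$chain == chain & topology$atoms$resno == resno)
  if (!length(idx))
    stop("topology error: no atoms in chain ", chain, " residue ", resno)
  m <- topology$masses[idx]
  colSums(coords[idx, , drop = FALSE] * m) / sum(m)
}

# ordered base-pair centroids of an arm in one frame
arm_centroids <- function(coords, topology, arm) {
  t(vapply(seq_along(arm$resnos1), function(i) {
    (residue_com(coords, topology, arm$chain1, arm$resnos1[i]) +
       residue_com(coords, topology, arm$chain2, arm$resnos2[i])) / 2
  }, numeric(3)))
}

principal_axis <- function(pts) {
  if (nrow(pts) < 2L) stop("geometry error: need >= 2 points for an axis")
  ctr <- colMeans(pts)
  sv <- svd(sweep(pts, 2, ctr))
  if (sv$d[1] < 1e-9)
    stop("geometry error: degenerate (coincident) point set")
  list(axis = sv$v[, 1], anchor = ctr, spread = sv$d)
}

#' Principal axis of a duplex arm
#'
#' Fits the first principal direction of the arm's ordered base-pair
#' centroids.  The axis is oriented away from the junction: away from
#' `center` when given, otherwise from the first (innermost) centroid
#' toward the last.
#'
#' @param coords natoms x 3 frame coordinates, nm.
#' @param topology the matching `hj_topology`.
#' @param arm an [arm_definition()]; needs at least 4 base pairs.
#' @param center optional junction-centre position used to orient the
#'   axis outward.
#' @return list with unit `axis` and `anchor` (centroid mean, nm).
#' @export
arm_axis <- function(coords, topology, arm, center = NULL) {
  pts <- arm_centroids(coords, topology, arm)
  if (nrow(pts) < 4L)
    stop("geometry error: arm ", arm$label, " has fewer than 4 base pairs")
  pa <- principal_axis(pts)
  ref <- if (is.null(center)) pts[nrow(pts), ] - pts[1, ] else pa$anchor - center
  if (sum(pa$axis * ref) < 0) pa$axis <- -pa$axis
  list(axis = pa$axis, anchor = pa$anchor)
}

fold_180 <- function(deg) {
  deg <- deg %% 360
  ifelse(deg > 180, 360 - deg, deg)
}

angle_deg <- function(u, v) {
  c <- sum(u * v) / (vnorm(u) * vnorm(v))
  acos(max(-1, min(1, c))) * 180 / pi
}

# axis of a composite (stacked) duplex: principal direction of the pooled
# centroids of both arms, oriented from arm 1 toward arm 2
duplex_axis <- function(coords, topology, arm_pair) {
  stopifnot(length(arm_pair) == 2L)
  p1 <- arm_centroids(coords, topology, arm_pair[[1]])
  p2 <- arm_centroids(coords, topology, arm_pair[[2]])
  pa <- principal_axis(rbind(p1, p2))
  if (sum(pa$axis * (colMeans(p2) - colMeans(p1))) < 0) pa$axis <- -pa$axis
  list(axis = pa$axis, anchor = pa$anchor)
}

#' Junction inter-duplex angle (IDA) and twist angle for one frame
#'
#' The junction's two quasi-continuous duplexes are each described by two
#' stacked arms.  The IDA is the angle between the two duplex axes
#' (oriented from the first arm of each pair toward the second), in
#' [0, 180] degrees.  The twist is the angle between the projections of
#' the two axes onto the plane perpendicular to the inter-duplex vector
#' (anchor of duplex 2 minus anchor of duplex 1), folded into [0, 90] so
#' coplanar duplexes give exactly 0; this is a package convention.
#'
#' @param coords natoms x 3 frame coordinates, nm.
#' @param topology the matching `hj_topology`.
#' @param duplex1,duplex2 each a list of two [arm_definition()]s forming
#'   one stacked duplex.
#' @param time optional time stamp, ps.
#' @return data.frame with `time`, `ida_deg`, `twist_deg`.
#' @export
junction_angles <- function(coords, topology, duplex1, duplex2, time = NA) {
  d1 <- duplex_axis(coords, topology, duplex1)
  d2 <- duplex_axis(coords, topology, duplex2)
  ida <- fold_180(angle_deg(d1$axis, d2$axis))
  cvec <- d2$anchor - d1$anchor
  if (vnorm(cvec) < 1e-6)
    stop("geometry error: coincident duplex anchors; twist undefined")
  chat <- cvec / vnorm(cvec)
  proj <- function(u) u - sum(u * chat) * chat
  p1 <- proj(d1$axis); p2 <- proj(d2$axis)
  if (vnorm(p1) < 1e-9 || vnorm(p2) < 1e-9)
    stop("geometry error: duplex axis parallel to inter-duplex vector")
  tw <- angle_deg(p1, p2)
  if (tw > 90) tw <- 180 - tw
  data.frame(time = time, ida_deg = ida, twist_deg = tw)
}

#' IDA and twist time series over a trajectory
#'
#' @param traj an `hj_trajectory`.
#' @param duplex1,duplex2 as in [junction_angles()].
#' @param stride sampling interval, ps (default: every frame).
#' @param burn_in initial span to drop, ps.
#' @return data.frame with one row per retained frame.
#' @export
junction_angle_series <- function(traj, duplex1, duplex2, stride = NULL,
                                  burn_in = 0) {
  sub <- select_frames(traj, burn_in = burn_in, stride = stride)
  if (n_frames(sub) == 0L)
    stop("analysis error: no frames retained for junction angles")
  do.call(rbind, lapply(seq_len(n_frames(sub)), function(i)
    junction_angles(frame_coords(sub, i), sub$topology, duplex1, duplex2,
                    time = sub$times[i])))
}
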