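## contacts: 26-group residue partition (6 central bases per strand + the
## dyes) and frame-averaged contact-probability matrices with the mixed
## centre-of-mass / dye-end criterion.

#' Build residue groups for contact analysis
#'
#' One group per central base of each strand (default window 11--16, label
#' `"<resno><chain>"`, e.g. `"13A"`) plus one group per dye (labelled by
#' the dye's label).  With four 26-residue strands and two dyes this gives
#' the canonical 26 groups.  A dye residue that happens to fall inside the
#' window is excluded from the base groups (dyes are their own group).
#'
#' @param topology an `hj_topology`.
#' @param dyes list of [dye_definition()]s.
#' @param center_window integer residue numbers forming the central window
#'   (default `11:16`).
#' @param heavy_only if TRUE, centre-of-mass calculations skip hydrogens.
#' @return list of `residue_group` objects, ordered strand-by-strand then
#'   dyes.
#' @export
build_groups <- function(topology, dyes = list(), center_window = 11:16,
                         heavy_only = FALSE) {
  a <- topology$atoms
  dye_key <- vapply(dyes, function(d) paste(d$chain, d$resno), "")
  groups <- list()
  for (ch in names(topology$strands)) {
    for (rn in center_window) {
      if (paste(ch, rn) %in% dye_key) next  # dye residues are their own group
      idx <- which(a$chain == ch & a$resno == rn)
      if (!length(idx))
        stop("topology error: strand ", ch, " has no residue ", rn,
             " in the centre window")
      groups[[length(groups) + 1L]] <- structure(
        list(label = paste0(rn, ch), kind = "base", atom_idx = idx, dye = NULL),
        class = "residue_group")
    }
  }
  for (d in dyes) {
    idx <- dye_atom_indices(topology, d)
    groups[[length(groups) + 1L]] <- structure(
      list(label = d$label, kind = "dye", atom_idx = idx, dye = d),
      class = "residue_group")
  }
  labels <- vapply(groups, `[[`, "", "label")
  if (anyDuplicated(labels))
    stop("topology error: duplicated group labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  attr(groups, "heavy_only") <- heavy_only
  groups
}

# representative points of a group in one frame: base -> its centre of
# mass; dye -> whole-residue centre of mass plus the two dipole ends
group_points <- function(coords, topology, group, heavy_only = FALSE) {
  idx <- group$atom_idx
  m <- topology$masses[idx]
  if (heavy_only) {
    keep <- toupper(trimws(topology$atoms$elesy[idx])) != "H"
    idx <- idx[keep]; m <- m[keep]
  }
  com <- colSums(coords[idx, , drop = FALSE] * m) / sum(m)
  if (group$kind == "base") return(matrix(com, nrow = 1L))
  ends <- dye_end_indices(topology, group$dye)
  rbind(com,
        colMeans(coords[ends$r, , drop = FALSE]),
        colMeans(coords[ends$s, , drop = FALSE]))
}

#' Are two residue groups in contact in a frame?
#'
#' Contact means the shortest distance between the groups' representative
#' points is within (<=) the cutoff.  Base groups contribute their centre
#' of mass; dye groups contribute the whole-dye centre of mass and both
#' dipole ends, accounting for the anisotropic dye shape.
#'
#' @param coords natoms x 3 frame coordinates, nm.
#' @param topology the matching `hj_topology`.
#' @param g1,g2 `residue_group` objects from [build_groups()].
#' @param cutoff contact cutoff, nm (default 1.2, the short-range
#'   interaction cutoff of the simulations these maps describe).
#' @param heavy_only skip hydrogens in centres of mass.
#' @return logical.
#' @export
in_contact <- function(coords, topology, g1, g2, cutoff = 1.2,
                       heavy_only = FALSE) {
  p1 <- group_points(coords, topology, g1, heavy_only)
  p2 <- group_points(coords, topology, g2, heavy_only)
  for (i in seq_len(nrow(p1)))
    for (j in seq_len(nrow(p2)))
      if (vnorm(p1[i, ] - p2[j, ]) <= cutoff) return(TRUE)
  FALSE
}

#' Frame-averaged contact-probability map
#'
#' Entry (i, j) is the fraction of retained frames in which groups i and j
#' are in contact; the diagonal is 1 by definition (a residue is always in
#' contact with itself).  The result is symmetric with entries in [0, 1].
#'
#' @param traj an `hj_trajectory`.
#' @param groups list from [build_groups()].
#' @param cutoff contact cutoff, nm.
#' @param stride sampling interval, ps (default 500).
#' @param burn_in initial span to drop, ps.
#' @return An object of class `contact_map`: list with `labels`,
#'   probability matrix `P`, `cutoff`, `n_frames_used`, `stride`.
#' @export
contact_map <- function(traj, groups, cutoff = 1.2, stride = 500,
                        burn_in = 0) {
  sub <- select_frames(traj, burn_in = burn_in, stride = stride)
  nf <- n_frames(sub)
  if (nf == 0L) stop("analysis error: no frames retained for contact map")
  heavy_only <- isTRUE(attr(groups, "heavy_only"))
  ng <- length(groups)
  labels <- vapply(groups, `[[`, "", "label")
  counts <- matrix(0, ng, ng, dimnames = list(labels, labels))
  topo <- sub$topology
  for (f in seq_len(nf)) {
    fr <- frame_coords(sub, f)
    pts <- lapply(groups, group_points, coords = fr, topology = topo,
                  heavy_only = heavy_only)
    for (i in seq_len(ng - 1L)) {
      for (j in seq.int(i + 1L, ng)) {
        p1 <- pts[[i]]; p2 <- pts[[j]]
        hit <- FALSE
        for (k in seq_len(nrow(p1))) {
          d2 <- (p2[, 1] - p1[k, 1])^2 + (p2[, 2] - p1[k, 2])^2 +
            (p2[, 3] - p1[k, 3])^2
          if (any(d2 <= cutoff^2)) { hit <- TRUE; break }
        }
        if (hit) counts[i, j] <- counts[i, j] + 1
      }
    }
  }
  P <- counts / nf
  P <- P + t(P)
  diag(P) <- 1
  out <- list(labels = labels, P = P, cutoff = cutoff,
              n_frames_used = nf, stride = sub$dt)
  class(out) <- "contact_map"
  validate_contact_map(out)
  out
}

validate_contact_map <- function(cm) {
  stopifnot(isTRUE(all.equal(cm$P, t(cm$P))),
            all(abs(diag(cm$P) - 1) < 1e-12),
            all(cm$P >= 0 & cm$P <= 1 + 1e-12))
  invisible(cm)
}

#' Pool contact maps from several trajectories
#'
#' Frame-count-weighted average of per-trajectory maps computed with the
#' same groups and cutoff.
#'
#' @param maps list of `contact_map` objects.
#' @return A pooled `contact_map`.
#' @export
pool_contact_maps <- function(maps) {
  stopifnot(length(maps) >= 1L)
  lab <- maps[[1]]$labels
  cut <- maps[[1]]$cutoff
  for (m in maps)
    if (!identical(m$labels, lab) || m$cutoff != cut)
      stop("analysis error: contact maps have incompatible groups or cutoff")
  w <- vapply(maps, `[[`, 0, "n_frames_used")
  P <- Reduce(`+`, Map(function(m, wi) m$P * wi, maps, w)) / sum(w)
  diag(P) <- 1
  out <- list(labels = lab, P = P, cutoff = cut, n_frames_used = sum(w),
              stride = maps[[1]]$stride)
  class(out) <- "contact_map"
  validate_contact_map(out)
  out
}

#' @export
print.contact_map <- function(x, ...) {
  cat("contact_map:", length(x$labels), "groups, cutoff", x$cutoff,
      "nm,", x$n_frames_used, "frames\n")
  invisible(x)
}

#' Write a contact map as TSV
#'
#' Writes the square matrix with group labels as header row/column, plus a
#' long-format companion (`<path>` with suffix `.long.tsv`) of
#' `group_i  group_j  probability` rows.  A commented header records the
#' cutoff, stride and frame count.
#'
#' @param cm a `contact_map`.
#' @param path output TSV path.
#' @param meta optional named character vector of extra `# key: value`
#'   header lines.
#' @return `path`, invisibly.
#' @export
write_contact_map <- function(cm, path, meta = NULL) {
  hdr <- c(sprintf("# cutoff_nm: %g", cm$cutoff),
           sprintf("# stride_ps: %g", cm$stride),
           sprintf("# n_frames_used: %d", cm$n_frames_used),
           if (!is.null(meta)) sprintf("# %s: %s", names(meta), meta))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(hdr, con)
  writeLines(paste(c("group", cm$labels), collapse = "\t"), con)
  for (i in seq_along(cm$labels))
    writeLines(paste(c(cm$labels[i], sprintf("%.6f", cm$P[i, ])),
                     collapse = "\t"), con)
  close(con); on.exit()
  longp <- sub("\\.tsv$", "", path)
  longp <- paste0(longp, ".long.tsv")
  con2 <- file(longp, "w"); on.exit(close(con2))
  writeLines(c(hdr, "group_i\tgroup_j\tprobability"), con2)
  for (i in seq_along(cm$labels))
    for (j in seq_along(cm$labels))
      writeLines(sprintf("%s\t%s\t%.6f", cm$labels[i], cm$labels[j],
                         cm$P[i, j]), con2)
  invisible(path)
}
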