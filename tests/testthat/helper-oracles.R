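# Independent oracles and small fixture builders used across the suite.
# Oracles are written against first principles (SI constants, explicit
# loops) so they never share code paths with the package implementation.

`%||%` <- function(a, b) if (is.null(a)) b else a

# four-charge Coulomb oracle for the extended-dipole coupling, fully in SI
oracle_J_charges <- function(rm, sm, rn, sn, mu_m, mu_n, nref = 1.33) {
  D <- 3.33564095198152e-30; eps0 <- 8.8541878128e-12
  meV <- 1.602176634e-22
  lm <- sqrt(sum((rm - sm)^2)) * 1e-9
  ln <- sqrt(sum((rn - sn)^2)) * 1e-9
  qm <- mu_m * D / lm; qn <- mu_n * D / ln
  total <- 0
  for (m_end in list(list(p = rm, q = qm), list(p = sm, q = -qm)))
    for (n_end in list(list(p = rn, q = qn), list(p = sn, q = -qn))) {
      d <- sqrt(sum((m_end$p - n_end$p)^2)) * 1e-9
      total <- total + m_end$q * n_end$q / d
    }
  total / (4 * pi * eps0 * nref^2) / meV
}

# uniformly random unit vector
rand_unit <- function() {
  z <- runif(1, -1, 1); phi <- runif(1, 0, 2 * pi)
  c(sqrt(1 - z^2) * cos(phi), sqrt(1 - z^2) * sin(phi), z)
}

# random well-separated dipole pair (no near-coincident end points).
# well_conditioned = TRUE additionally rejects geometries whose four-term
# reciprocal sum is catastrophically cancelled (|sum| < 2% of the largest
# term): a relative comparison at 1e-12 is only meaningful when the
# result is not dominated by rounding of the cancelled terms.
rand_dipole_pair <- function(min_gap = 0.3, well_conditioned = FALSE) {
  repeat {
    lm <- runif(1, 0.8, 2); ln <- runif(1, 0.8, 2)
    cm <- runif(3, -1, 1)
    cn <- cm + runif(1, 1.5, 6) * rand_unit()
    um <- rand_unit(); un <- rand_unit()
    m <- dipole_geometry(cm + lm / 2 * um, cm - lm / 2 * um)
    n <- dipole_geometry(cn + ln / 2 * un, cn - ln / 2 * un)
    gaps <- c(sqrt(sum((m$r - n$r)^2)), sqrt(sum((m$s - n$s)^2)),
              sqrt(sum((m$r - n$s)^2)), sqrt(sum((m$s - n$r)^2)))
    if (min(gaps) <= min_gap) next
    if (well_conditioned) {
      terms <- c(1 / gaps[1], 1 / gaps[2], -1 / gaps[3], -1 / gaps[4])
      if (abs(sum(terms)) < 0.02 * max(abs(terms))) next
    }
    return(list(m = m, n = n))
  }
}

# random proper rotation matrix (QR of a Gaussian matrix)
rand_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  Q <- qr.Q(qr_)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

apply_rigid <- function(geom, Q, shift) {
  dipole_geometry(drop(Q %*% geom$r) + shift, drop(Q %*% geom$s) + shift)
}

# topology of single-atom bead residues from a data.frame with columns
# chain, resno (positions supplied separately per frame)
bead_topology <- function(beads) {
  topology(data.frame(elety = "CA", elesy = "C", resid = "DN",
                      resno = beads$resno, chain = beads$chain,
                      stringsAsFactors = FALSE))
}

# naive all-pairs/all-frames contact-map oracle (base COM = bead or
# mass-weighted mean; dye adds residue COM and both end centroids)
oracle_contact_map <- function(traj, groups, cutoff) {
  topo <- traj$topology
  ng <- length(groups)
  P <- matrix(0, ng, ng)
  nf <- n_frames(traj)
  for (f in seq_len(nf)) {
    fr <- frame_coords(traj, f)
    reps <- lapply(groups, function(g) {
      idx <- g$atom_idx
      w <- topo$masses[idx]
      com <- colSums(fr[idx, , drop = FALSE] * w) / sum(w)
      if (g$kind == "base") return(list(com))
      a <- topo$atoms
      ridx <- idx[a$elety[idx] %in% g$dye$end_r]
      sidx <- idx[a$elety[idx] %in% g$dye$end_s]
      list(com, colMeans(fr[ridx, , drop = FALSE]),
           colMeans(fr[sidx, , drop = FALSE]))
    })
    for (i in seq_len(ng))
      for (j in seq_len(ng)) {
        hit <- FALSE
        for (p in reps[[i]]) {
          for (q in reps[[j]])
            if (sqrt(sum((p - q)^2)) <= cutoff) { hit <- TRUE; break }
          if (hit) break
        }
        if (hit) P[i, j] <- P[i, j] + 1
      }
  }
  P <- P / nf
  diag(P) <- 1
  P
}

# minimal multi-model PDB text for tiny hand-built fixtures
pdb_lines <- function(frames, elety, resid, chain, resno) {
  out <- character(0)
  for (k in seq_along(frames)) {
    fr <- frames[[k]]
    out <- c(out, sprintf("MODEL     %d", k))
    for (i in seq_len(nrow(fr)))
      out <- c(out, sprintf(
        "ATOM  %5d %-4s %-3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           %s",
        i, elety[i], resid[i], chain[i], resno[i],
        fr[i, 1], fr[i, 2], fr[i, 3], substr(elety[i], 1, 1)))
    out <- c(out, "ENDMDL")
  }
  c(out, "END")
}
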