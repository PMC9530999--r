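# straight pseudo-duplex builder: two bead strands flanking the line
# origin + t * u, base pairs at t = t0 + (i - 1) * rise
straight_duplex <- function(chains, n_bp = 8, u = c(0, 0, 1),
                            origin = c(0, 0, 0), t0 = 0.34, rise = 0.34,
                            perp = c(0.1, 0, 0)) {
  resno <- rep(seq_len(n_bp), 2)
  chain <- rep(chains, each = n_bp)
  topo <- bead_topology(data.frame(chain = chain, resno = resno))
  pos <- matrix(NA_real_, 2 * n_bp, 3)
  for (i in seq_len(n_bp)) {
    ctr <- origin + (t0 + (i - 1) * rise) * u
    pos[i, ] <- ctr + perp
    pos[n_bp + i, ] <- ctr - perp
  }
  list(topology = topo, coords = pos,
       arm = arm_definition(paste(chains, collapse = ""), chains[1],
                            seq_len(n_bp), chains[2], seq_len(n_bp)))
}

merge_duplexes <- function(d1, d2) {
  topo <- topology(rbind(d1$topology$atoms, d2$topology$atoms))
  list(topology = topo, coords = rbind(d1$coords, d2$coords))
}

test_that("arm axis recovers a straight arm's direction", {
  d <- straight_duplex(c("A", "B"))
  ax <- arm_axis(d$coords, d$topology, d$arm, center = c(0, 0, 0))
  expect_equal(ax$axis, c(0, 0, 1), tolerance = 1e-9)
  # reversing residue order still re-orients away from the given centre
  arm_rev <- arm_definition("rev", "A", 8:1, "B", 8:1)
  ax_rev <- arm_axis(d$coords, d$topology, arm_rev, center = c(0, 0, 0))
  expect_equal(ax_rev$axis, c(0, 0, 1), tolerance = 1e-9)
  # without a centre, orientation follows first -> last centroid
  ax2 <- arm_axis(d$coords, d$topology, arm_rev)
  expect_equal(ax2$axis, c(0, 0, -1), tolerance = 1e-9)
})

test_that("arm axis tolerates helical perturbation and flags degeneracy", {
  set.seed(23)
  d <- straight_duplex(c("A", "B"), n_bp = 12)
  # helical wobble of the pair centroids around the construction axis
  theta <- seq(0, 4 * pi, length.out = 12)
  wob <- 0.05 * cbind(cos(theta), sin(theta), 0)
  coords <- d$coords + rbind(wob, wob)
  ax <- arm_axis(coords, d$topology, d$arm, center = c(0, 0, 0))
  ang <- acos(min(1, abs(sum(ax$axis * c(0, 0, 1))))) * 180 / pi
  expect_lt(ang, 1)
  # fewer than 4 base pairs is a geometry error
  small <- straight_duplex(c("A", "B"), n_bp = 3)
  expect_error(arm_axis(small$coords, small$topology, small$arm),
               "geometry error")
})

# build a full mock junction frame from two straight duplexes at a given
# crossing angle, each duplex split into two arms
crossed_junction <- function(angle_deg, offset = c(0, 0, 0.8)) {
  u1 <- c(1, 0, 0)
  u2 <- c(cos(angle_deg * pi / 180), sin(angle_deg * pi / 180), 0)
  arm <- function(chains, u, origin, perp) {
    straight_duplex(chains, n_bp = 6, u = u, origin = origin, perp = perp)
  }
  a1 <- arm(c("A", "B"), u1, c(0, 0, 0), c(0, 0.1, 0))
  a2 <- arm(c("C", "D"), -u1, c(0, 0, 0), c(0, 0.1, 0))
  a3 <- arm(c("E", "F"), u2, offset, c(0, 0, 0.1))
  a4 <- arm(c("G", "H"), -u2, offset, c(0, 0, 0.1))
  m12 <- merge_duplexes(a1, a2)
  m34 <- merge_duplexes(a3, a4)
  all <- merge_duplexes(m12, m34)
  list(topology = all$topology, coords = all$coords,
       duplex1 = list(a2$arm, a1$arm),  # oriented -u1 -> +u1
       duplex2 = list(a4$arm, a3$arm))
}

test_that("constructed crossing angles are recovered as the IDA", {
  j60 <- crossed_junction(60)
  ang <- junction_angles(j60$coords, j60$topology, j60$duplex1, j60$duplex2)
  expect_lt(abs(ang$ida_deg - 60), 1)
  j135 <- crossed_junction(135)
  ang135 <- junction_angles(j135$coords, j135$topology, j135$duplex1,
                            j135$duplex2)
  expect_lt(abs(ang135$ida_deg - 135), 1)
})

test_that("parallel duplexes give IDA 0 and coplanar duplexes twist 0", {
  u1 <- c(1, 0, 0)
  a1 <- straight_duplex(c("A", "B"), n_bp = 6, u = u1, perp = c(0, 0.1, 0))
  a2 <- straight_duplex(c("C", "D"), n_bp = 6, u = -u1, perp = c(0, 0.1, 0))
  # second duplex parallel to the first, offset in z
  a3 <- straight_duplex(c("E", "F"), n_bp = 6, u = u1,
                        origin = c(0, 0, 1.5), perp = c(0, 0.1, 0))
  a4 <- straight_duplex(c("G", "H"), n_bp = 6, u = -u1,
                        origin = c(0, 0, 1.5), perp = c(0, 0.1, 0))
  all <- merge_duplexes(merge_duplexes(a1, a2), merge_duplexes(a3, a4))
  ang <- junction_angles(all$coords, all$topology, list(a2$arm, a1$arm),
                         list(a4$arm, a3$arm))
  expect_lt(ang$ida_deg, 1e-6)
  # coplanar crossed duplexes (offset within the junction plane): twist 0
  j <- crossed_junction(60, offset = c(0, 1.5, 0))
  # flatten the perpendicular offsets into the plane to stay exactly coplanar
  ang2 <- junction_angles(j$coords, j$topology, j$duplex1, j$duplex2)
  expect_lt(ang2$twist_deg, 6)  # near-coplanar by construction
})

test_that("junction angles are rigid-motion invariant and continuous", {
  set.seed(77)
  j <- crossed_junction(60)
  ref <- junction_angles(j$coords, j$topology, j$duplex1, j$duplex2)
  Q <- rand_rotation(); shift <- runif(3, -5, 5)
  rot <- t(Q %*% t(j$coords)) + matrix(shift, nrow(j$coords), 3, byrow = TRUE)
  moved <- junction_angles(rot, j$topology, j$duplex1, j$duplex2)
  expect_equal(moved$ida_deg, ref$ida_deg, tolerance = 1e-8)
  expect_equal(moved$twist_deg, ref$twist_deg, tolerance = 1e-8)
  # small coordinate perturbations move the angles only slightly
  pert <- junction_angles(j$coords + matrix(rnorm(length(j$coords), 0, 1e-4),
                                            nrow(j$coords), 3),
                          j$topology, j$duplex1, j$duplex2)
  expect_lt(abs(pert$ida_deg - ref$ida_deg), 0.5)
  expect_lt(abs(pert$twist_deg - ref$twist_deg), 0.5)
})

test_that("angle time series run over trajectories with stride", {
  mock <- generate_mock_junction("IsoI", "transverse", n_frames = 6,
                                 ida_deg = 60)
  ser <- junction_angle_series(mock$trajectory, mock$arms$duplex1,
                               mock$arms$duplex2)
  expect_equal(nrow(ser), 6)
  expect_true(all(abs(ser$ida_deg - 60) < 1))
  expect_true(all(ser$ida_deg >= 0 & ser$ida_deg <= 180))
  expect_true(all(ser$twist_deg >= 0 & ser$twist_deg <= 180))
})
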