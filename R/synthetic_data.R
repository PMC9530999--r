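## synthetic_data: seed-controlled generators with known ground truth --
## rigid-rod dimer ensembles emulating the observed orientation/distance
## modes, and a pseudo-atom mock four-strand junction.

.mode_defaults <- list(
  # per-mode centre-distance distributions (nm) chosen to emulate the
  # reported heatmap peaks: closely spaced H dimer ~0.5 nm, J dimer
  # ~1.4 nm, separated H ~2.2-2.9 nm, effectively-monomer ~4.2 nm
  H_dimer     = list(r_mean = 0.5, r_sd = 0.04),
  J_dimer     = list(r_mean = 1.4, r_sd = 0.04),
  separated_H = list(r_mean = 2.5, r_sd = 0.30),
  monomer     = list(r_mean = 4.2, r_sd = 0.50)
)

#' Specification for a synthetic dimer ensemble
#'
#' Two rigid rods of lengths `l_m`, `l_n`; per frame the centre
#' separation is drawn from a normal distribution along the mode's
#' canonical axis (perpendicular to the rods for the H modes,
#' longitudinal for the J mode) and each rod is perturbed by independent
#' small rotations about two axes orthogonal to its director with angles
#' ~ Normal(0, `angle_sd_deg`).  The monomer mode draws the second rod's
#' orientation uniformly on the sphere.  `mixture` samples a mode per
#' frame by `weights`, each mode using its default distance distribution.
#'
#' @param mode one of `"H_dimer"`, `"J_dimer"`, `"separated_H"`,
#'   `"monomer"`, `"mixture"`.
#' @param n_frames number of frames (>= 1).
#' @param dt frame spacing, ps.
#' @param seed RNG seed; identical (spec, seed) gives bit-identical
#'   output.
#' @param r_mean,r_sd centre-distance distribution, nm; defaults are the
#'   mode's canonical values.
#' @param angle_sd_deg angular noise SD, degrees.
#' @param l_m,l_n rod lengths, nm (defaults 1.4, the Cy5 scale).
#' @param weights named non-negative weights over modes (mixture mode
#'   only); normalized to sum to 1.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(mode = c("H_dimer", "J_dimer", "separated_H",
                                    "monomer", "mixture"),
                           n_frames = 3000, dt = 100, seed = 1,
                           r_mean = NULL, r_sd = NULL, angle_sd_deg = 10,
                           l_m = 1.4, l_n = 1.4, weights = NULL) {
  mode <- match.arg(mode)
  stopifnot(n_frames >= 1, dt > 0, angle_sd_deg >= 0, l_m > 0, l_n > 0)
  if (mode == "mixture") {
    if (is.null(weights) || is.null(names(weights)) ||
        !all(names(weights) %in% names(.mode_defaults)) || any(weights < 0) ||
        sum(weights) <= 0)
      stop("configuration error: mixture mode needs named non-negative weights")
    weights <- weights / sum(weights)
  } else {
    def <- .mode_defaults[[mode]]
    r_mean <- r_mean %||% def$r_mean
    r_sd <- r_sd %||% def$r_sd
    if (r_sd < 0) stop("configuration error: r_sd must be >= 0")
  }
  out <- list(mode = mode, n_frames = as.integer(n_frames), dt = dt,
              seed = as.integer(seed), r_mean = r_mean, r_sd = r_sd,
              angle_sd_deg = angle_sd_deg, l_m = l_m, l_n = l_n,
              weights = weights)
  class(out) <- "synthetic_spec"
  out
}

rot_axis <- function(axis, theta) {
  # Rodrigues rotation matrix about a unit axis
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

random_unit_vector <- function() {
  z <- runif(1, -1, 1); phi <- runif(1, 0, 2 * pi)
  r <- sqrt(1 - z^2)
  c(r * cos(phi), r * sin(phi), z)
}

# 6-atom topology for a rod pair: each dye residue has end atoms C1
# (dipole head), C2 (tail) and a centre atom C3, all carbon so the
# centre of mass is exact
rod_pair_topology <- function() {
  topology(data.frame(
    elety = rep(c("C1", "C2", "C3"), 2),
    elesy = "C", resid = "CY5",
    resno = 1L, chain = rep(c("A", "C"), each = 3),
    stringsAsFactors = FALSE))
}

#' Dye definitions matching the synthetic rod-pair topology
#'
#' @param mu_m,mu_n transition dipole magnitudes, Debye (default: the
#'   Cy5 value 15.35 D for both).
#' @return list of two [dye_definition()]s (chains A and C).
#' @export
rod_pair_dyes <- function(mu_m = 15.35, mu_n = 15.35) {
  list(dye_definition("dye_A", chain = "A", resno = 1, resname = "CY5",
                      end_r = "C1", end_s = "C2", mu_debye = mu_m),
       dye_definition("dye_C", chain = "C", resno = 1, resname = "CY5",
                      end_r = "C1", end_s = "C2", mu_debye = mu_n))
}

#' Generate a synthetic rigid-rod dimer trajectory with ground truth
#'
#' @param spec a [synthetic_spec()].
#' @return list with `trajectory` (an `hj_trajectory` of the 6-atom rod
#'   pair), `ground_truth` (data.frame: `time`, `R_true`, `kappa_true`,
#'   `mode`), `dyes` (matching [rod_pair_dyes()]) and `spec`.
#' @export
generate_dimer_trajectory <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  topo <- rod_pair_topology()
  n <- spec$n_frames
  sd_rad <- spec$angle_sd_deg * pi / 180
  ex <- c(1, 0, 0); ey <- c(0, 1, 0); ez <- c(0, 0, 1)
  frames <- vector("list", n)
  R_true <- kappa_true <- numeric(n)
  mode_lab <- character(n)
  for (i in seq_len(n)) {
    mode <- spec$mode
    if (mode == "mixture")
      mode <- sample(names(spec$weights), 1L, prob = spec$weights)
    mode_lab[i] <- mode
    if (spec$mode == "mixture") {
      def <- .mode_defaults[[mode]]
      r_mean <- def$r_mean; r_sd <- def$r_sd
    } else {
      r_mean <- spec$r_mean; r_sd <- spec$r_sd
    }
    R <- max(rnorm(1, r_mean, r_sd), 0.05)
    sep_axis <- if (mode == "J_dimer") ex else ez
    # independent small rotations about the two axes orthogonal to the
    # unperturbed director (x)
    u_m <- drop(rot_axis(ez, rnorm(1, 0, sd_rad)) %*%
                  (rot_axis(ey, rnorm(1, 0, sd_rad)) %*% ex))
    u_n <- if (mode == "monomer") random_unit_vector() else
      drop(rot_axis(ez, rnorm(1, 0, sd_rad)) %*%
             (rot_axis(ey, rnorm(1, 0, sd_rad)) %*% ex))
    c_m <- c(0, 0, 0); c_n <- R * sep_axis
    fr <- rbind(c_m + spec$l_m / 2 * u_m, c_m - spec$l_m / 2 * u_m, c_m,
                c_n + spec$l_n / 2 * u_n, c_n - spec$l_n / 2 * u_n, c_n)
    frames[[i]] <- fr
    R_true[i] <- R
    kappa_true[i] <- sum(u_m * u_n) -
      3 * sum(sep_axis * u_m) * sum(sep_axis * u_n)
  }
  traj <- as_trajectory(topo, frames, dt = spec$dt)
  list(trajectory = traj,
       ground_truth = data.frame(time = traj$times, R_true = R_true,
                                 kappa_true = kappa_true, mode = mode_lab,
                                 stringsAsFactors = FALSE),
       dyes = rod_pair_dyes(), spec = spec)
}

# mock-junction dye placements (centres, director x, dye length 1.0 nm):
# transverse Iso I stacks the A/C dyes 0.5 nm apart; transverse Iso II
# puts them on opposite sides ~4 nm apart; adjacent Iso I is end-to-end
# at 1.4 nm; adjacent Iso II is a separated H arrangement at 2.2 nm
.mock_dye_placements <- list(
  IsoI_transverse  = list(c1 = c(0, 0, 1.2), c2 = c(0, 0, 1.7),
                          u1 = c(1, 0, 0), u2 = c(1, 0, 0)),
  IsoII_transverse = list(c1 = c(0, 0, 2.0), c2 = c(0, 0, -2.0),
                          u1 = c(1, 0, 0), u2 = c(1, 0, 0)),
  IsoI_adjacent    = list(c1 = c(-0.7, 0, 1.0), c2 = c(0.7, 0, 1.0),
                          u1 = c(1, 0, 0), u2 = c(1, 0, 0)),
  IsoII_adjacent   = list(c1 = c(0, 0, 1.0), c2 = c(0, 2.2, 1.0),
                          u1 = c(1, 0, 0), u2 = c(1, 0, 0))
)

#' Generate a mock four-strand junction with tethered pseudo-dyes
#'
#' Four 26-residue pseudo-strands (one carbon pseudo-atom per base,
#' 0.34 nm rise) arranged as two straight duplex arms crossing at
#' `ida_deg`; each strand runs in along one arm (residues 1--13) and out
#' along its stacking partner (14--26), with the arm pairing switched
#' between the Iso I and Iso II conformers.  Two three-atom pseudo-dye
#' residues (ends C1/C2 plus centre C3, length 1 nm) are placed per the
#' isomer/attachment geometry; frames are static replicates unless
#' `jitter_sd` > 0 adds seeded Gaussian coordinate noise.
#'
#' @param isomer `"IsoI"` or `"IsoII"`.
#' @param attachment `"adjacent"` (dyes on strands A and B) or
#'   `"transverse"` (strands A and C).
#' @param n_frames number of frames.
#' @param seed RNG seed (used when `jitter_sd > 0`).
#' @param ida_deg crossing angle of the two duplex axes, degrees.
#' @param dt frame spacing, ps (default 500, the contact stride).
#' @param jitter_sd per-coordinate Gaussian noise SD, nm (default 0).
#' @return list with `topology`, `trajectory`, `ground_truth` (constant
#'   construction values `R_true`, `kappa_true`), `dyes` (two
#'   [dye_definition()]s) and `arms` (four [arm_definition()]s grouped
#'   into the two stacked duplexes).
#' @export
generate_mock_junction <- function(isomer = c("IsoI", "IsoII"),
                                   attachment = c("adjacent", "transverse"),
                                   n_frames = 100, seed = 1, ida_deg = 60,
                                   dt = 500, jitter_sd = 0) {
  isomer <- match.arg(isomer)
  attachment <- match.arg(attachment)
  stopifnot(n_frames >= 1, dt > 0, jitter_sd >= 0)
  rise <- 0.34
  e1 <- c(1, 0, 0)
  e2 <- c(cos(ida_deg * pi / 180), sin(ida_deg * pi / 180), 0)
  arms <- list(a1 = e1, a2 = -e1, a3 = e2, a4 = -e2)
  # strand traversal: in-arm (residues 1-13) -> out-arm (14-26)
  trav <- if (isomer == "IsoI")
    list(A = c("a2", "a3"), B = c("a4", "a1"), C = c("a1", "a4"),
         D = c("a3", "a2"))
  else
    list(A = c("a2", "a4"), B = c("a3", "a1"), C = c("a1", "a3"),
         D = c("a4", "a2"))
  zoff <- c(A = 0.05, B = -0.05, C = 0.10, D = -0.10)
  # the two stacked duplexes sit side by side: arms a3/a4 (second duplex)
  # are displaced perpendicular to the junction plane
  arm_z <- c(a1 = 0, a2 = 0, a3 = -0.8, a4 = -0.8)
  atoms <- list(); xyz <- list()
  for (ch in c("A", "B", "C", "D")) {
    ain <- trav[[ch]][1]; aout <- trav[[ch]][2]
    u_in <- arms[[ain]]; u_out <- arms[[aout]]
    for (j in 1:26) {
      pos <- if (j <= 13)
        (14 - j) * rise * u_in + c(0, 0, arm_z[[ain]])
      else (j - 13) * rise * u_out + c(0, 0, arm_z[[aout]])
      pos <- pos + c(0, 0, zoff[[ch]])
      atoms[[length(atoms) + 1L]] <- data.frame(
        elety = "CA", elesy = "C", resid = "DN", resno = j, chain = ch,
        stringsAsFactors = FALSE)
      xyz[[length(xyz) + 1L]] <- pos
    }
  }
  place <- .mock_dye_placements[[paste(isomer, attachment, sep = "_")]]
  dye_chain2 <- if (attachment == "transverse") "C" else "B"
  l_dye <- 1.0
  dye_pos <- list(list(chain = "A", c = place$c1, u = place$u1),
                  list(chain = dye_chain2, c = place$c2, u = place$u2))
  for (d in dye_pos) {
    for (k in 1:3) atoms[[length(atoms) + 1L]] <- data.frame(
      elety = paste0("C", k), elesy = "C", resid = "CY5", resno = 27L,
      chain = d$chain, stringsAsFactors = FALSE)
    xyz[[length(xyz) + 1L]] <- d$c + l_dye / 2 * d$u
    xyz[[length(xyz) + 1L]] <- d$c - l_dye / 2 * d$u
    xyz[[length(xyz) + 1L]] <- d$c
  }
  topo <- topology(do.call(rbind, atoms))
  base <- do.call(rbind, xyz)
  set.seed(seed)
  frames <- lapply(seq_len(n_frames), function(i) {
    if (jitter_sd > 0)
      base + matrix(rnorm(length(base), 0, jitter_sd), nrow(base), 3)
    else base
  })
  traj <- as_trajectory(topo, frames, dt = dt)
  R_true <- vnorm(place$c2 - place$c1)
  Rhat <- (place$c2 - place$c1) / R_true
  kappa_true <- sum(place$u1 * place$u2) -
    3 * sum(Rhat * place$u1) * sum(Rhat * place$u2)
  dyes <- list(
    dye_definition(paste0("Cy5_A"), chain = "A", resno = 27,
                   resname = "CY5", end_r = "C1", end_s = "C2",
                   mu_debye = 15.35),
    dye_definition(paste0("Cy5_", dye_chain2), chain = dye_chain2,
                   resno = 27, resname = "CY5", end_r = "C1",
                   end_s = "C2", mu_debye = 15.35))
  # arm definitions: arm ak pairs its incoming and outgoing strands
  arm_def <- list()
  for (ak in names(arms)) {
    inc <- names(trav)[vapply(trav, function(x) x[1] == ak, TRUE)]
    out <- names(trav)[vapply(trav, function(x) x[2] == ak, TRUE)]
    arm_def[[ak]] <- arm_definition(ak, chain1 = out, resnos1 = 14:26,
                                    chain2 = inc, resnos2 = 13:1)
  }
  list(topology = topo, trajectory = traj,
       ground_truth = data.frame(time = traj$times, R_true = R_true,
                                 kappa_true = kappa_true,
                                 mode = paste(isomer, attachment),
                                 stringsAsFactors = FALSE),
       dyes = dyes,
       arms = list(duplex1 = list(arm_def$a1, arm_def$a2),
                   duplex2 = list(arm_def$a3, arm_def$a4)))
}

#' Write / read a ground-truth sidecar (JSON lines)
#'
#' One JSON object per frame with the per-frame true values.
#'
#' @param ground_truth data.frame as returned by the generators.
#' @param path output path.
#' @return `path` (write) or the data.frame (read).
#' @export
write_ground_truth <- function(ground_truth, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_len(nrow(ground_truth)))
    writeLines(jsonlite::toJSON(as.list(ground_truth[i, ]),
                                auto_unbox = TRUE, digits = NA), con)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  lines <- readLines(path)
  do.call(rbind, lapply(lines, function(l)
    as.data.frame(jsonlite::fromJSON(l), stringsAsFactors = FALSE)))
}
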