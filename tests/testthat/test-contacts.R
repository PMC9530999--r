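test_that("group builder yields the canonical 26-group partition", {
  mock <- generate_mock_junction("IsoI", "transverse", n_frames = 1)
  groups <- build_groups(mock$topology, mock$dyes)
  expect_length(groups, 26)  # 4 strands x 6 central bases + 2 dyes
  labels <- vapply(groups, `[[`, "", "label")
  expect_true(all(paste0(11:16, "A") %in% labels))
  expect_true(all(c("Cy5_A", "Cy5_C") %in% labels))
  # a narrower window counts accordingly
  expect_length(build_groups(mock$topology, mock$dyes,
                             center_window = 12:13), 10)
  # missing residues are a topology error naming the strand
  expect_error(build_groups(mock$topology, mock$dyes, center_window = 30:31),
               "topology error")
})

test_that("a dye residue inside the window stays out of the base groups", {
  topo <- topology(data.frame(
    elety = c("CA", "CA", "CA", "C1", "C2", "C3"),
    elesy = "C", resid = c("DN", "DN", "DN", "CY5", "CY5", "CY5"),
    resno = c(11L, 12L, 11L, 12L, 12L, 12L),
    chain = c("A", "A", "B", "B", "B", "B")))
  dye <- dye_definition("dyeB", "B", 12, end_r = "C1", end_s = "C2")
  groups <- build_groups(topo, list(dye), center_window = 11:12)
  labels <- vapply(groups, `[[`, "", "label")
  # strand B residue 12 is the dye, so no base group "12B"
  expect_false("12B" %in% labels)
  expect_true("dyeB" %in% labels)
  expect_true(all(c("11A", "12A", "11B") %in% labels))
  kinds <- vapply(groups, `[[`, "", "kind")
  expect_equal(sum(kinds == "dye"), 1L)
})

test_that("contact criterion: COM for bases, COM + both ends for dyes", {
  topo <- topology(data.frame(
    elety = c("CA", "C1", "C2", "C3"), elesy = "C",
    resid = c("DN", "CY5", "CY5", "CY5"),
    resno = c(11L, 27L, 27L, 27L), chain = c("A", "A", "A", "A")))
  dye <- dye_definition("dye", "A", 27, end_r = "C1", end_s = "C2")
  groups <- build_groups(topo, list(dye), center_window = 11)
  base <- groups[[1]]; dyeg <- groups[[2]]
  mk <- function(base_pos, r, s, c3) rbind(base_pos, r, s, c3)
  # two base COMs 1.0 nm apart: contact; 1.3 nm apart: not
  fr <- mk(c(0, 0, 0), c(1.0, 0, 0), c(3.0, 0, 0), c(2.0, 0, 0))
  expect_true(in_contact(fr, topo, base, dyeg, cutoff = 1.2))
  # dye end within cutoff while the dye COM is far: still a contact
  fr2 <- mk(c(0, 0, 0), c(1.1, 0, 0), c(2.9, 0, 0), c(2.0, 0, 0))
  expect_true(in_contact(fr2, topo, base, dyeg, cutoff = 1.2))
  # everything beyond cutoff: no contact
  fr3 <- mk(c(0, 0, 0), c(1.3, 0, 0), c(3.0, 0, 0), c(2.15, 0, 0))
  expect_false(in_contact(fr3, topo, base, dyeg, cutoff = 1.2))
  # the boundary itself counts as within
  beads <- bead_topology(data.frame(chain = c("A", "B"), resno = c(1L, 1L)))
  b <- build_groups(beads, center_window = 1)
  frb <- rbind(c(0, 0, 0), c(1.2, 0, 0))
  expect_true(in_contact(frb, beads, b[[1]], b[[2]], cutoff = 1.2))
})

test_that("contact probabilities equal per-frame fractions by construction", {
  beads <- bead_topology(data.frame(chain = c("A", "B"), resno = c(1L, 1L)))
  groups <- build_groups(beads, center_window = 1)
  # 40 of 100 frames within cutoff
  frames <- c(lapply(1:40, function(i) rbind(c(0, 0, 0), c(1.0, 0, 0))),
              lapply(1:60, function(i) rbind(c(0, 0, 0), c(1.5, 0, 0))))
  traj <- as_trajectory(beads, frames, dt = 500)
  cm <- contact_map(traj, groups, cutoff = 1.2, stride = 500)
  expect_equal(cm$P[1, 2], 0.40)
  expect_equal(cm$P, t(cm$P))
  expect_equal(unname(diag(cm$P)), rep(1, 2))
})

test_that("contact maps match a brute-force oracle and are cutoff-monotone", {
  mock <- generate_mock_junction("IsoI", "adjacent", n_frames = 100,
                                 seed = 9, jitter_sd = 0.15)
  groups <- build_groups(mock$topology, mock$dyes)
  cm <- contact_map(mock$trajectory, groups, cutoff = 1.2, stride = 500)
  expect_equal(unname(cm$P), oracle_contact_map(mock$trajectory, groups, 1.2),
               tolerance = 1e-12)
  expect_true(all(cm$P >= 0 & cm$P <= 1))
  # raising the cutoff never decreases any entry
  cm_lo <- contact_map(mock$trajectory, groups, cutoff = 0.8, stride = 500)
  expect_true(all(cm$P - cm_lo$P >= -1e-12))
  # probabilities strictly between 0 and 1 exist (jitter makes it nontrivial)
  off_diag <- cm$P[upper.tri(cm$P)]
  expect_true(any(off_diag > 0 & off_diag < 1))
})

test_that("pooling contact maps is a frame-count-weighted average", {
  mock1 <- generate_mock_junction("IsoI", "transverse", n_frames = 30,
                                  seed = 1, jitter_sd = 0.2)
  mock2 <- generate_mock_junction("IsoI", "transverse", n_frames = 60,
                                  seed = 2, jitter_sd = 0.2)
  groups <- build_groups(mock1$topology, mock1$dyes)
  cm1 <- contact_map(mock1$trajectory, groups, stride = 500)
  cm2 <- contact_map(mock2$trajectory, groups, stride = 500)
  pooled <- pool_contact_maps(list(cm1, cm2))
  expected <- (cm1$P * 30 + cm2$P * 60) / 90
  diag(expected) <- 1
  expect_equal(pooled$P, expected, tolerance = 1e-12)
  expect_equal(pooled$n_frames_used, 90)
  expect_error(pool_contact_maps(list(cm1, contact_map(
    mock2$trajectory, groups, cutoff = 0.9, stride = 500))),
    "analysis error")
})

test_that("contact map TSV output round-trips labels and probabilities", {
  mock <- generate_mock_junction("IsoI", "transverse", n_frames = 10)
  groups <- build_groups(mock$topology, mock$dyes)
  cm <- contact_map(mock$trajectory, groups, stride = 500)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_contact_map(cm, f)
  tab <- utils::read.delim(f, comment.char = "#", check.names = FALSE)
  expect_equal(tab$group, cm$labels)
  expect_equal(as.numeric(tab[tab$group == "Cy5_A", "Cy5_C"]),
               cm$P["Cy5_A", "Cy5_C"], tolerance = 1e-6)
  expect_true(file.exists(sub("\\.tsv$", ".long.tsv", f)))
})
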