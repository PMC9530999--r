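test_that("dipole extraction: ends, centre, unit vector, length", {
  topo <- topology(data.frame(elety = c("C1", "C2"), elesy = "C",
                              resid = "CY5", resno = 1L, chain = "A"))
  dye <- dye_definition("d", "A", 1, end_r = "C1", end_s = "C2",
                        mu_debye = 15.35)
  fr <- rbind(c(1.4, 0, 0), c(0, 0, 0))
  g <- dipole_from_frame(fr, topo, dye)
  expect_equal(g$u, c(1, 0, 0))
  expect_equal(g$center, c(0.7, 0, 0))
  expect_equal(g$length, 1.4)
  # swapped ends: u negated, centre and length unchanged
  dye_sw <- dye_definition("d", "A", 1, end_r = "C2", end_s = "C1")
  g2 <- dipole_from_frame(fr, topo, dye_sw)
  expect_equal(g2$u, -g$u)
  expect_equal(g2$center, g$center)
  expect_equal(g2$length, g$length)
})

test_that("multi-atom end selections use the plain centroid", {
  topo <- topology(data.frame(elety = c("N1", "N2", "N3", "N4"),
                              elesy = "N", resid = "CY5", resno = 1L,
                              chain = "A"))
  dye <- dye_definition("d", "A", 1, end_r = c("N1", "N2"),
                        end_s = c("N3", "N4"))
  set.seed(11)
  fr <- matrix(runif(12), 4, 3)
  g <- dipole_from_frame(fr, topo, dye)
  expect_equal(g$r, unname((fr[1, ] + fr[2, ]) / 2))  # hand sum
  expect_equal(g$s, unname((fr[3, ] + fr[4, ]) / 2))
})

test_that("default dipole ends are the two ring nitrogens", {
  topo <- topology(data.frame(elety = c("N1", "C5", "N2"),
                              elesy = c("N", "C", "N"), resid = "CY5",
                              resno = 1L, chain = "A"))
  dye <- dye_definition("d", "A", 1)
  fr <- rbind(c(0, 0, 0), c(0.7, 0, 0), c(1.4, 0, 0))
  g <- dipole_from_frame(fr, topo, dye)
  expect_equal(g$length, 1.4)
  # too many nitrogens without explicit selections is an error
  topo2 <- topology(data.frame(elety = c("N1", "N2", "N3"), elesy = "N",
                               resid = "CY5", resno = 1L, chain = "A"))
  expect_error(dipole_from_frame(fr, topo2, dye), "selection error")
})

test_that("selection and degeneracy errors name the problem", {
  topo <- topology(data.frame(elety = c("C1", "C2"), elesy = "C",
                              resid = "CY5", resno = 1L, chain = "A"))
  fr <- rbind(c(0, 0, 0), c(0, 0, 0))
  dye_bad <- dye_definition("d", "A", 1, end_r = "C9", end_s = "C2")
  expect_error(dipole_from_frame(fr, topo, dye_bad), "C9")
  dye <- dye_definition("d", "A", 1, end_r = "C1", end_s = "C2")
  expect_error(dipole_from_frame(fr, topo, dye), "degenerate-geometry")
  expect_error(dye_definition("d", "A", 1, end_r = "C1", end_s = "C1"),
               "configuration error")
})

test_that("kappa takes its canonical values on canonical geometries", {
  along <- function(u, c0) dipole_geometry(c0 + u / 2, c0 - u / 2)
  ex <- c(1, 0, 0); ey <- c(0, 1, 0); ez <- c(0, 0, 1)
  # parallel dipoles, perpendicular separation: stacked limit
  expect_equal(orientation_factor(along(ex, c(0, 0, 0)),
                                  along(ex, c(0, 0, 1))), 1, tolerance = 1e-12)
  # collinear parallel dipoles: end-to-end limit
  expect_equal(orientation_factor(along(ex, c(0, 0, 0)),
                                  along(ex, c(3, 0, 0))), -2, tolerance = 1e-12)
  # orthogonal dipoles, separation along the third axis
  expect_equal(orientation_factor(along(ex, c(0, 0, 0)),
                                  along(ey, c(0, 0, 1))), 0, tolerance = 1e-12)
  expect_error(orientation_factor(along(ex, c(0, 0, 0)),
                                  along(ey, c(0, 0, 0))),
               "degenerate-geometry")
})

test_that("kappa symmetries and bound hold on random geometries", {
  set.seed(101)
  for (i in 1:200) {
    p <- rand_dipole_pair()
    k <- orientation_factor(p$m, p$n)
    expect_lte(abs(k), 2 + 1e-9)
    # argument order (Rhat -> -Rhat) leaves kappa unchanged
    expect_equal(orientation_factor(p$n, p$m), k, tolerance = 1e-12)
    # negating both dipoles leaves kappa; negating one flips the sign
    flip <- function(g) dipole_geometry(g$s, g$r)
    expect_equal(orientation_factor(flip(p$m), flip(p$n)), k,
                 tolerance = 1e-12)
    expect_equal(orientation_factor(flip(p$m), p$n), -k, tolerance = 1e-12)
  }
})

test_that("kappa and R are invariant under rigid motions", {
  set.seed(7)
  for (i in 1:25) {
    p <- rand_dipole_pair()
    Q <- rand_rotation(); shift <- runif(3, -5, 5)
    m2 <- apply_rigid(p$m, Q, shift); n2 <- apply_rigid(p$n, Q, shift)
    expect_equal(orientation_factor(m2, n2), orientation_factor(p$m, p$n),
                 tolerance = 1e-10)
    expect_equal(center_distance(m2, n2), center_distance(p$m, p$n),
                 tolerance = 1e-10)
  }
})

test_that("centre distance matches the direct formula", {
  a <- dipole_geometry(c(0.5, 0, 0), c(-0.5, 0, 0))
  b <- dipole_geometry(c(0.5, 0, 0.57), c(-0.5, 0, 0.57))
  expect_equal(center_distance(a, b), 0.57)
  expect_equal(center_distance(a, a), 0)
  set.seed(3)
  p <- rand_dipole_pair()
  expect_equal(center_distance(p$m, p$n),
               sqrt(sum((p$m$center - p$n$center)^2)), tolerance = 1e-12)
})

test_that("observe_dimer yields one time-ordered record per retained frame", {
  sp <- synthetic_spec("H_dimer", n_frames = 50, seed = 5, r_sd = 0,
                       angle_sd_deg = 0)
  g <- generate_dimer_trajectory(sp)
  obs <- observe_dimer(g$trajectory, g$dyes[[1]], g$dyes[[2]])
  expect_equal(nrow(obs), 50)
  expect_true(all(diff(obs$time) > 0))
  # frozen geometry: constant kappa and R series
  expect_true(all(abs(obs$kappa - 1) < 1e-12))
  expect_true(all(abs(obs$R_nm - 0.5) < 1e-12))
  # stacked noisy ensemble stays below the H/J boundary on average
  gn <- generate_dimer_trajectory(synthetic_spec("H_dimer", n_frames = 500,
                                                 seed = 6))
  on <- observe_dimer(gn$trajectory, gn$dyes[[1]], gn$dyes[[2]])
  expect_lt(mean(on$abs_kappa), 1)
})
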