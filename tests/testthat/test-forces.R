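# Two free beads along x at separation r, optionally with velocities.
pair_system <- function(r, types = c("H", "T"), box = 10, vel = NULL) {
  top <- free_topology(2)
  top$type <- types
  fr <- dpd_frame(rbind(c(1, 1, 1), c(1 + r, 1, 1)), box = box, velocities = vel)
  list(top = top, fr = fr)
}

test_that("conservative force is a * (1 - r/rc) inside the cutoff, zero outside", {
  ff <- dpd_forcefield()
  s <- pair_system(0.5, c("H", "H"))
  f <- compute_forces(s$fr, s$top, ff, include = "conservative")
  expect_equal(f$forces[1, 1], -12.5)           # 25 * 0.5, pushing bead 1 to -x
  expect_equal(f$forces[2, 1], 12.5)
  expect_vec_equal(f$forces[, 2:3], 0)

  s <- pair_system(1.2)
  f <- compute_forces(s$fr, s$top, ff, include = "conservative")
  expect_vec_equal(f$forces, 0)

  # soft core: magnitude tends to a as r -> 0+
  s <- pair_system(1e-6, c("H", "T"))
  f <- compute_forces(s$fr, s$top, ff, include = "conservative")
  expect_equal(abs(f$forces[1, 1]), 100, tolerance = 1e-4)

  # exactly coincident beads: zero force with a warning, not NaN
  top <- free_topology(2)
  fr <- dpd_frame(rbind(c(1, 1, 1), c(1, 1, 1)), box = 10)
  expect_warning(f <- compute_forces(fr, top, ff, include = "conservative"),
                 "coincident")
  expect_vec_equal(f$forces, 0)
})

test_that("dissipative drag is -gamma w^2 (e.v) e and kills transverse motion", {
  ff <- dpd_forcefield(sigma = 0, gamma = 4.5, kT = 0)
  u <- 0.8
  # relative velocity along the pair axis: drag gamma * w^2 * u on top of conservative
  s <- pair_system(0.5, c("H", "H"), vel = rbind(c(u, 0, 0), c(0, 0, 0)))
  f <- compute_forces(s$fr, s$top, ff, include = "all")
  fc <- compute_forces(s$fr, s$top, ff, include = "conservative")
  drag <- f$forces[1, 1] - fc$forces[1, 1]
  expect_equal(drag, -4.5 * 0.25 * u, tolerance = 1e-12)

  # transverse relative velocity: projection along r-hat is zero
  s <- pair_system(0.5, c("H", "H"), vel = rbind(c(0, u, 0), c(0, 0, 0)))
  f <- compute_forces(s$fr, s$top, ff, include = "all")
  expect_vec_equal(f$forces - fc$forces, 0, tol = 1e-12)
})

test_that("random force has zero mean and variance sigma^2 w^2 / dt", {
  ff <- dpd_forcefield()                     # sigma = 3
  s <- pair_system(0.5, c("H", "H"))
  set.seed(42)
  n <- 4000
  fx <- vapply(seq_len(n), function(i)
    compute_forces(s$fr, s$top, ff, dt = 0.01)$forces[1, 1], 0)
  fc <- compute_forces(s$fr, s$top, ff, include = "conservative")$forces[1, 1]
  rnd <- fx - fc
  sd_theory <- 3 * 0.5 / sqrt(0.01)          # sigma w / sqrt(dt) = 15
  expect_lt(abs(mean(rnd)), 4 * sd_theory / sqrt(n))
  expect_equal(sd(rnd), sd_theory, tolerance = 0.05)
  # uniform-noise option has the same two moments
  ffu <- dpd_forcefield(noise = "uniform")
  set.seed(43)
  fxu <- vapply(seq_len(n), function(i)
    compute_forces(s$fr, s$top, ffu, dt = 0.01)$forces[1, 1], 0)
  expect_equal(sd(fxu - fc), sd_theory, tolerance = 0.05)
})

test_that("bond force restores toward rs and obeys Newton's third law", {
  ff <- dpd_forcefield(a = matrix(0, 2, 2, dimnames = list(c("H", "T"), c("H", "T"))))
  top <- build_lipid_topology(1, 1, 1)
  # at r = rs the bond force vanishes
  fr <- dpd_frame(rbind(c(1, 1, 1), c(1.7, 1, 1)), box = 10)
  f <- compute_forces(fr, top, ff, include = "conservative")
  expect_vec_equal(f$forces, 0, tol = 1e-12)
  # stretched to 2 rs: magnitude ks |1 - r/rs| = 120, pulling inward
  fr <- dpd_frame(rbind(c(1, 1, 1), c(2.4, 1, 1)), box = 10)
  f <- compute_forces(fr, top, ff, include = "conservative")
  expect_equal(f$forces[1, 1], 120)           # bead 1 pulled toward +x
  expect_vec_equal(colSums(f$forces), c(0, 0, 0), tol = 1e-12)
})

test_that("angle force vanishes at theta0, sums to zero, and matches finite differences", {
  # pure angle system: beads farther apart than rc, bonds stripped, one
  # triple on the head block
  ff <- dpd_forcefield()
  top <- build_lipid_topology(3, 1, 1, angles = "head")
  top <- within_top_strip(top)
  p0 <- rbind(c(5, 5, 5), c(5, 5, 7), c(5, 5, 9), c(20, 20, 20))
  fr <- dpd_frame(p0, box = 30)
  f <- compute_forces(fr, top, ff, include = "conservative")
  expect_vec_equal(f$forces, 0, tol = 1e-10)   # straight triple at theta0 = pi

  # bent to theta = pi/2: energy k (pi/2)^2, force = -grad E
  p1 <- rbind(c(5, 5, 5), c(5, 5, 7), c(5, 7, 7), c(20, 20, 20))
  fr1 <- dpd_frame(p1, box = 30)
  f1 <- compute_forces(fr1, top, ff, include = "conservative")
  expect_equal(f1$epot, 6 * (pi / 2)^2, tolerance = 1e-10)
  expect_vec_equal(colSums(f1$forces), c(0, 0, 0), tol = 1e-10)
  # central-difference oracle bead by bead
  h <- 1e-6
  for (b in 1:3) {
    for (a in 1:3) {
      pp <- p1; pp[b, a] <- pp[b, a] + h
      pm <- p1; pm[b, a] <- pm[b, a] - h
      ep <- compute_forces(dpd_frame(pp, box = 30), top, ff,
                           include = "conservative")$epot
      em <- compute_forces(dpd_frame(pm, box = 30), top, ff,
                           include = "conservative")$epot
      expect_equal(f1$forces[b, a], -(ep - em) / (2 * h), tolerance = 1e-5)
    }
  }
})

test_that("pair forces respect the minimum image convention", {
  ff <- dpd_forcefield()
  top <- free_topology(2)
  # beads on opposite faces are images 0.4 apart
  fr <- dpd_frame(rbind(c(0.2, 1, 1), c(9.8, 1, 1)), box = 10)
  f <- compute_forces(fr, top, ff, include = "conservative")
  # unwrapped replica at true separation 0.4
  fr2 <- dpd_frame(rbind(c(3.0, 1, 1), c(2.6, 1, 1)), box = 10)
  f2 <- compute_forces(fr2, top, ff, include = "conservative")
  expect_equal(f$forces[1, 1], f2$forces[1, 1], tolerance = 1e-12)
  expect_equal(f$forces[1, 1], 25 * 0.6)      # pushed toward +x, away from image
})

test_that("fluctuation-dissipation and interaction-matrix invariants are enforced", {
  expect_error(dpd_forcefield(sigma = 3, gamma = 2), "fluctuation-dissipation")
  bad <- default_interactions(); bad[1, 2] <- 50
  expect_error(dpd_forcefield(a = bad), "symmetric")
  expect_error(dpd_forcefield(bond_r0 = 1.5), "bond_r0")
  expect_silent(dpd_forcefield())
})
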