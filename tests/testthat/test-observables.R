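test_that("axial density is flat for a uniform gas and conserves counts", {
  gas <- make_ideal_gas(rho = 3, D = 10, kT = 1, seed = 6)
  prof <- axial_density(gas$frame, gas$topology, bin_width = 1)
  expect_equal(unname(prof$density[, "N"]), rep(3, 10), tolerance = 0.15)
  # exact count conservation
  vol <- prof$box^2 * prof$bin_width
  expect_equal(sum(prof$density[, "N"]) * vol, nrow(gas$frame$positions))
  expect_error(axial_density(gas$frame, gas$topology, bin_width = -1), "positive")
})

test_that("axial density matches a naive per-bead oracle and locates lamellar slabs", {
  fx <- make_perfect_lamella(period = 15, D = 30, chains_per_leaflet = 20, seed = 2)
  prof <- axial_density(fx$frame, fx$topology, bin_width = 0.5)
  nb <- length(prof$bin_mid)
  for (ty in c("H", "T")) {
    ref <- oracle_axial_counts(fx$frame$positions[fx$topology$type == ty, 3], 30, nb)
    expect_equal(unname(prof$counts[, ty]), ref)
  }
  # head density vanishes inside tail slabs and peaks near period boundaries
  h <- prof$density[, "H"]
  mid_tail <- which(abs(prof$bin_mid - 7.5) < 2 | abs(prof$bin_mid - 22.5) < 2)
  expect_vec_equal(h[mid_tail], 0)
  expect_gt(max(h), 0)
})

test_that("radial density sees a filled cylinder and is flat for a gas", {
  # single ideal cylinder of H beads, radius 2, axis along z
  set.seed(3)
  n <- 4000; D <- 20
  r <- 2 * sqrt(runif(n)); th <- runif(n, 0, 2 * pi)
  pos <- cbind(10 + r * cos(th), 10 + r * sin(th), runif(n, 0, D))
  top <- free_topology(n, "H")
  fr <- dpd_frame(pos, box = D)
  prof <- radial_density(fr, top, axis_point = c(10, 10, 0), bin_width = 0.5, r_max = 5)
  expect_vec_equal(prof$density[prof$bin_mid > 2.1, "H"], 0)
  expect_gt(min(prof$density[prof$bin_mid < 1.9, "H"]), 0)
  # annulus normalisation conserves the count inside the sampled cylinder
  vol <- pi * diff(prof$bin_edges^2) * D
  expect_equal(sum(prof$density[, "H"] * vol), n)

  gas <- make_ideal_gas(rho = 3, D = 10, kT = 0, seed = 4)
  pg <- radial_density(gas$frame, gas$topology, axis_point = c(5, 5, 0),
                       bin_width = 0.5, r_max = 4)
  expect_equal(unname(pg$density[, "N"]), rep(3, 8), tolerance = 0.2)
  expect_error(radial_density(gas$frame, gas$topology, c(5, 5, 0), axis_dir = c(0, 0, 0)),
               "degenerate")
})

test_that("chain direction is the unwrapped head-to-tail unit vector", {
  # straight chain along +z
  fx <- make_oriented_chains(1, polar_angle = 0, D = 30, seed = 1)
  expect_vec_equal(chain_direction(fx$frame, fx$topology), c(0, 0, 1), tol = 1e-12)
  # chain along +x
  fx <- make_oriented_chains(1, polar_angle = pi / 2, D = 30, seed = 1)
  d <- chain_direction(fx$frame, fx$topology)
  expect_equal(abs(d[1, 3]), 0, tolerance = 1e-12)
  expect_equal(sqrt(sum(d^2)), 1, tolerance = 1e-12)

  # a chain crossing the periodic boundary has the same direction as its
  # unwrapped copy
  top <- build_lipid_topology(1, 2, 1)
  p_unwrapped <- rbind(c(5, 5, 9.4), c(5, 5, 10.1), c(5, 5, 10.8))
  fr_wrapped <- dpd_frame(p_unwrapped, box = 10)   # constructor wraps
  expect_vec_equal(chain_direction(fr_wrapped, top), c(0, 0, 1), tol = 1e-12)
})

test_that("order parameter hits its analytic limits and stays within bounds", {
  fx <- make_oriented_chains(200, polar_angle = 0, D = 30, seed = 2)
  expect_equal(order_parameter_mean(fx$frame, fx$topology), 1, tolerance = 1e-12)
  fx <- make_oriented_chains(200, polar_angle = pi / 2, D = 30, seed = 2)
  expect_equal(order_parameter_mean(fx$frame, fx$topology), -0.5, tolerance = 1e-12)
  # random orientations stay within [-0.5, 1] bin by bin and empty bins are NA
  fx <- make_oriented_chains(500, polar_angle = "isotropic", D = 30, seed = 3)
  prof <- order_parameter(fx$frame, fx$topology, bin_width = 0.5)
  pop <- prof$n_chains > 0
  expect_true(all(prof$p2[pop] >= -0.5 - 1e-12 & prof$p2[pop] <= 1 + 1e-12))
  expect_true(all(is.na(prof$p2[!pop])))
})

test_that("gyration components obey the collinear closed form and rigid motions", {
  # 13 beads at 0.7 rc spacing along z
  fx <- make_perfect_lamella(period = 30, n_head = 3, n_tail = 10, D = 30,
                             chains_per_leaflet = 5, spacing = 0.7, seed = 5)
  g <- gyration_components(fx$frame, fx$topology)
  expect_equal(g$rg_zz, 0.7 * sqrt((13^2 - 1) / 12), tolerance = 1e-12)
  expect_equal(g$rg_zz, 2.619, tolerance = 1e-3)
  expect_equal(g$rg_xx, 0, tolerance = 1e-12)
  expect_equal(g$rg_yy, 0, tolerance = 1e-12)

  # single-bead "chain" has zero extent
  top1 <- build_lipid_topology(1, 1, 1)
  top1$n_tail <- 0L; top1$type <- "H"; top1$chain_id <- 1L
  top1$bonds <- matrix(integer(0), 0, 2)
  fr1 <- dpd_frame(matrix(c(1, 2, 3), 1, 3), box = 10)
  g1 <- gyration_components(fr1, top1)
  expect_equal(unlist(g1[, 2:4]), c(rg_xx = 0, rg_yy = 0, rg_zz = 0))

  # translation invariance and 90-degree rotation equivariance
  set.seed(8)
  top <- build_lipid_topology(3, 10, 4)
  pos <- matrix(runif(52 * 3, 10, 12), 52, 3)   # compact: no wrap ambiguity
  fr <- dpd_frame(pos, box = 30)
  g0 <- gyration_components(fr, top)
  frt <- dpd_frame(pos + rep(c(3, -2, 5), each = 52), box = 30)
  gt <- gyration_components(frt, top)
  expect_vec_equal(unlist(g0[, 2:4]), unlist(gt[, 2:4]), tol = 1e-10)
  # rotate +90 about x: (y, z) -> (z, -y); swaps the yy and zz components
  rot <- cbind(pos[, 1], pos[, 3], -pos[, 2] + 25)
  gr <- gyration_components(dpd_frame(rot, box = 30), top)
  expect_equal(gr$rg_yy, g0$rg_zz, tolerance = 1e-10)
  expect_equal(gr$rg_zz, g0$rg_yy, tolerance = 1e-10)
})

test_that("nanoparticle layering is flat at t = 0, localises on planes, and conserves count", {
  box <- box_spec(12, 3)
  top <- lipid_mixture_topology(3, 10, 0.1, box)
  fr <- place_preassembled(top, box, "lamellar", seed = 9)
  traj <- structure(list(frames = list(fr), times = 0), class = "dpd_trajectory")
  lay <- nanoparticle_layering(traj, top, bin_width = 1)
  expect_length(lay, 1)
  prof <- lay[[1]]
  vol <- prof$box^2 * prof$bin_width
  expect_equal(sum(prof$density[, "N"]) * vol, top$n_nanoparticles)
  # random placement: roughly flat
  expect_lt(diff(range(prof$density[, "N"])) / mean(prof$density[, "N"]), 1)

  # two-plane fixture shows two sharp peaks
  n_np <- 200
  posn <- cbind(runif(n_np, 0, 12), runif(n_np, 0, 12),
                rep(c(3.5, 9.5), each = n_np / 2))
  topn <- free_topology(n_np, "N")
  topn$n_nanoparticles <- as.integer(n_np)
  trj <- structure(list(frames = list(dpd_frame(posn, box = 12)), times = 0),
                   class = "dpd_trajectory")
  layn <- nanoparticle_layering(trj, topn, bin_width = 1)[[1]]
  dn <- layn$density[, "N"]
  expect_equal(sort(layn$bin_mid[order(-dn)[1:2]]), c(3.5, 9.5))
  expect_equal(sum(dn > 0), 2)

  # no nanoparticles: empty result with a warning
  top0 <- lipid_mixture_topology(3, 10, 0, box)
  fr0 <- place_random_melt(top0, box, seed = 1)
  trj0 <- structure(list(frames = list(fr0), times = 0), class = "dpd_trajectory")
  expect_warning(res <- nanoparticle_layering(trj0, top0), "no nanoparticles")
  expect_length(res, 0)
})
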