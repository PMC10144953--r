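# Independent reference implementations used as oracles: plain-R all-pairs
# loops, deliberately ignorant of the cell-list engine.

# unbonded topology of one species, for free-bead systems
free_topology <- function(n, type = "H") {
  structure(list(type = rep(type, n), chain_id = rep(NA_integer_, n),
                 bonds = matrix(integer(0), 0, 2),
                 angles = matrix(integer(0), 0, 3),
                 n_head = 0L, n_tail = 0L, n_lipids = 0L,
                 n_nanoparticles = 0L, angle_scheme = "head"),
            class = "dpd_topology")
}

# all-pairs conservative (+ optional dissipative) forces and virial
oracle_pair_forces <- function(pos, vel, type, aMat, box, rc = 1,
                               gamma = 0) {
  n <- nrow(pos)
  f <- matrix(0, n, 3)
  vir <- matrix(0, 3, 3)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- pos[i, ] - pos[j, ]
      d <- d - box * round(d / box)
      r <- sqrt(sum(d^2))
      if (r >= rc || r < 1e-10) next
      a <- aMat[type[i], type[j]]
      w <- 1 - r / rc
      e <- d / r
      fm <- a * w
      if (gamma > 0) fm <- fm - gamma * w^2 * sum(e * (vel[i, ] - vel[j, ]))
      fv <- fm * e
      f[i, ] <- f[i, ] + fv
      f[j, ] <- f[j, ] - fv
      vir <- vir + outer(fv, d)
    }
  }
  list(forces = f, virial = vir)
}

# naive per-bead histogram for density profiles
oracle_axial_counts <- function(z, box, nbins) {
  w <- box / nbins
  counts <- numeric(nbins)
  for (zz in z) {
    zz <- zz - box * floor(zz / box)
    k <- min(floor(zz / w) + 1, nbins)
    counts[k] <- counts[k] + 1
  }
  counts
}

# brute-force listing of consecutive-head angle triples for one architecture
oracle_head_triples <- function(n_head, n_tail, n_lipids) {
  nb <- n_head + n_tail
  out <- NULL
  for (c in seq_len(n_lipids)) {
    off <- (c - 1) * nb
    heads <- off + seq_len(n_head)
    if (n_head >= 3) {
      for (s in 1:(n_head - 2)) out <- rbind(out, heads[s:(s + 2)])
    }
  }
  if (is.null(out)) matrix(integer(0), 0, 3) else out
}

# reference 1-D integration of a single bonded pair at fine time step
# (plain velocity-Verlet; the bond force F = ks (1 - r/rs) is linear in r)
oracle_bond_pair <- function(r0, ks, rs, dt, n_steps, refine = 100) {
  h <- dt / refine
  x <- r0 / 2            # symmetric pair on the x axis: positions +/- x
  v <- 0
  acc <- function(x) ks * (1 - 2 * x / rs)   # force on +x bead
  a <- acc(x)
  out <- numeric(n_steps + 1)
  out[1] <- 2 * x
  for (s in seq_len(n_steps * refine)) {
    x <- x + h * v + 0.5 * h^2 * a
    anew <- acc(x)
    v <- v + 0.5 * h * (a + anew)
    a <- anew
    if (s %% refine == 0) out[s / refine + 1] <- 2 * x
  }
  out
}

# drop the bonds of a topology (isolates angle terms in force tests)
within_top_strip <- function(top) {
  top$bonds <- matrix(integer(0), 0, 2)
  top
}

expect_vec_equal <- function(a, b, tol = 1e-12) {
  expect_lt(max(abs(a - b)), tol)
}
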