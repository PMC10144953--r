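#' Random-melt initial configuration
#'
#' Lays every lipid down as a random walk with step length `bond_r0` starting
#' from a uniformly random point, places nanoparticles uniformly at random,
#' and wraps everything into the box.  The topology bead count must match the
#' box density within one chain of rounding.
#'
#' @param topology a [build_lipid_topology()] result.
#' @param box a [box_spec()].
#' @param seed integer RNG seed; identical inputs give bit-identical frames.
#' @param bond_r0 bond step length used for the walks (rc).
#' @return a [dpd_frame()] (zero velocities).
#' @export
place_random_melt <- function(topology, box, seed = 1, bond_r0 = 0.7) {
  stopifnot(inherits(topology, "dpd_topology"), inherits(box, "dpd_box"))
  check_bead_count(topology, box)
  set.seed(seed)
  D <- box$length
  nb <- topology$n_head + topology$n_tail
  nl <- topology$n_lipids
  pos <- matrix(0, n_beads(topology), 3)
  if (nl > 0) {
    # random-walk chains: cumulative sum of unit steps scaled to bond_r0
    steps <- matrix(rnorm(3 * nl * nb), ncol = 3)
    steps <- steps / sqrt(rowSums(steps^2)) * bond_r0
    starts <- matrix(runif(3 * nl, 0, D), ncol = 3)
    for (c in seq_len(nl)) {
      idx <- ((c - 1) * nb + 1):(c * nb)
      walk <- apply(steps[idx[-1], , drop = FALSE], 2, cumsum)
      pos[idx, ] <- rbind(starts[c, ],
                          sweep(matrix(walk, ncol = 3), 2, starts[c, ], "+"))
    }
  }
  if (topology$n_nanoparticles > 0) {
    np_idx <- (nl * nb + 1):n_beads(topology)
    pos[np_idx, ] <- matrix(runif(3 * topology$n_nanoparticles, 0, D), ncol = 3)
  }
  dpd_frame(pos, box = D)
}

#' Preassembled lamellar or hexagonal initial configuration
#'
#' Lamellar: chains are extended along z in leaflet pairs, giving alternating
#' head/tail slabs with an integer number of repeats per box; the repeat
#' period is the divisor of D closest to twice the extended chain length
#' 2 (NH+NT) rs, and the intra-chain spacing is clamped to within 15% of the
#' equilibrium bond length so the starting bonds carry little strain.
#' Hexagonal: head beads seed cylinder cores on a (commensurate) triangular
#' lattice with axes along z, and each chain performs an outward-biased
#' random walk with step rs so heads stay near the core and tails fill the
#' matrix.  Nanoparticles are placed uniformly at random in either phase.
#'
#' The returned frame carries the construction geometry as attributes:
#' `period` (lamellar repeat, rc) or `cylinders` (matrix of xy axis
#' positions).
#'
#' @inheritParams place_random_melt
#' @param phase `"lamellar"` or `"hexagonal"`.
#' @return a [dpd_frame()] (zero velocities).
#' @export
place_preassembled <- function(topology, box, phase = c("lamellar", "hexagonal"),
                               seed = 1, bond_r0 = 0.7) {
  stopifnot(inherits(topology, "dpd_topology"), inherits(box, "dpd_box"))
  phase <- match.arg(phase)
  check_bead_count(topology, box)
  set.seed(seed)
  D <- box$length
  nb <- topology$n_head + topology$n_tail
  nl <- topology$n_lipids
  pos <- matrix(0, n_beads(topology), 3)

  if (phase == "lamellar") {
    target <- 2 * nb * bond_r0            # extended bilayer thickness
    n_rep <- max(1L, which.min(abs(D / seq_len(max(1L, floor(D / 2))) - target)))
    period <- D / n_rep
    sz <- bond_r0
    # chains round-robin over the 2*n_rep leaflets; within a leaflet the
    # chains sit on a jittered square grid so the local density is near rho
    # everywhere (random xy would stack chains and quench in a huge overlap
    # energy that destroys the mesophase before it can relax)
    leaflet <- (seq_len(nl) - 1L) %% (2L * n_rep)
    n_leaf <- 2L * n_rep
    slot <- integer(nl)                      # index within the leaflet
    for (l in seq_len(n_leaf) - 1L) slot[leaflet == l] <- seq_len(sum(leaflet == l))
    per_leaf <- max(tabulate(leaflet + 1L, n_leaf))
    ngrid <- ceiling(sqrt(per_leaf))
    sp <- D / ngrid
    for (c in seq_len(nl)) {
      idx <- ((c - 1) * nb + 1):(c * nb)
      rep_i <- leaflet[c] %/% 2L
      z0 <- rep_i * period
      m <- seq_len(nb) - 0.5
      z <- if (leaflet[c] %% 2L == 0L) z0 + m * sz else z0 + period - m * sz
      gx <- (slot[c] - 1L) %% ngrid
      gy <- (slot[c] - 1L) %/% ngrid
      pos[idx, 1] <- (gx + 0.5 + runif(1, -0.25, 0.25)) * sp
      pos[idx, 2] <- (gy + 0.5 + runif(1, -0.25, 0.25)) * sp
      pos[idx, 3] <- z
    }
    geom <- list(period = period)
  } else {
    nx <- max(2L, as.integer(round(D / 10)))   # columns of cylinders
    ax <- D / nx
    ny <- max(2L, as.integer(round(D / (ax * sqrt(3) / 2))))
    ay <- D / ny
    cyl <- expand.grid(i = seq_len(nx) - 1L, j = seq_len(ny) - 1L)
    centers <- cbind((cyl$i + 0.5 + 0.5 * (cyl$j %% 2)) %% nx * ax,
                     (cyl$j + 0.5) * ay)
    ncyl <- nrow(centers)
    assign_cyl <- ((seq_len(nl) - 1L) %% ncyl) + 1L
    for (c in seq_len(nl)) {
      idx <- ((c - 1) * nb + 1):(c * nb)
      ctr <- centers[assign_cyl[c], ]
      phi <- runif(1, 0, 2 * pi)
      r0 <- 0.5 * sqrt(runif(1))
      p <- c(ctr[1] + r0 * cos(phi), ctr[2] + r0 * sin(phi), runif(1, 0, D))
      pos[idx[1], ] <- p
      for (m in 2:nb) {
        rad <- c(p[1] - ctr[1], p[2] - ctr[2], 0)
        nr <- sqrt(sum(rad^2))
        rad <- if (nr > 1e-8) rad / nr else c(cos(phi), sin(phi), 0)
        dir <- rad + 0.8 * rnorm(3)
        dir <- dir / sqrt(sum(dir^2))
        p <- p + dir * bond_r0
        pos[idx[m], ] <- p
      }
    }
    geom <- list(cylinders = centers)
  }

  if (topology$n_nanoparticles > 0) {
    np_idx <- (nl * nb + 1):n_beads(topology)
    pos[np_idx, ] <- matrix(runif(3 * topology$n_nanoparticles, 0, D), ncol = 3)
  }
  fr <- dpd_frame(pos, box = D)
  for (nm in names(geom)) attr(fr, nm) <- geom[[nm]]
  fr
}

check_bead_count <- function(topology, box) {
  target <- round(box$density * box$length^3)
  nb <- topology$n_head + topology$n_tail
  if (abs(n_beads(topology) - target) > nb)
    stop("bead count ", n_beads(topology), " inconsistent with density ",
         box$density, " in box ", box$length,
         " (target ", target, ")", call. = FALSE)
  invisible(TRUE)
}
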