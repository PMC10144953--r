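#' Ideal-gas fixture with known kinetic pressure
#'
#' Unbonded beads placed uniformly at random with Maxwell-Boltzmann
#' velocities at `kT`.  Analytic expectations: flat axial density rho,
#' kinetic pressure rho*kT on each diagonal component, sigma_z = 0.
#'
#' @param rho bead number density (beads/rc^3).
#' @param D box side (rc).
#' @param kT temperature.
#' @param seed RNG seed.
#' @return list with `frame`, `topology` and `expected` (list of analytic
#'   values: `density`, `kinetic_pressure`, `sigma_z`).
#' @export
make_ideal_gas <- function(rho = 3, D = 10, kT = 1, seed = 1) {
  stopifnot(rho > 0, D > 0, kT >= 0)
  set.seed(seed)
  n <- round(rho * D^3)
  top <- structure(list(type = rep("N", n), chain_id = rep(NA_integer_, n),
                        bonds = matrix(integer(0), 0, 2),
                        angles = matrix(integer(0), 0, 3),
                        n_head = 0L, n_tail = 0L, n_lipids = 0L,
                        n_nanoparticles = as.integer(n), angle_scheme = "head"),
                   class = "dpd_topology")
  fr <- dpd_frame(matrix(runif(3 * n, 0, D), ncol = 3), box = D)
  fr <- init_velocities(fr, kT = kT)
  list(frame = fr, topology = top,
       expected = list(density = n / D^3, kinetic_pressure = n / D^3 * kT,
                       sigma_z = 0))
}

#' Rigid straight chains with a prescribed orientation distribution
#'
#' Each chain is a straight rod of `n_beads` beads spaced `spacing` apart
#' whose polar angle theta (from the z axis) is drawn by `polar_angle`;
#' azimuths are uniform.  Used to test the P2 order parameter against its
#' analytic limits: all chains at theta = 0 give P2 = 1, theta = pi/2 gives
#' -0.5, and an isotropic distribution gives 0.
#'
#' @param n_chains number of chains.
#' @param polar_angle either a single angle (radians), or a function
#'   `function(n)` returning n angles; `"isotropic"` draws theta with the
#'   sin(theta) weight of the uniform sphere measure.
#' @param D box side.
#' @param n_beads beads per chain (first bead is the head end).
#' @param n_head head beads per chain (for species labels).
#' @param spacing bead spacing along the rod (rc).
#' @param seed RNG seed.
#' @return list with `frame`, `topology`, `expected` (list with `p2` when
#'   the distribution has a closed form, else NULL).
#' @export
make_oriented_chains <- function(n_chains, polar_angle = 0, D = 30,
                                 n_beads = 13, n_head = 3, spacing = 0.7,
                                 seed = 1) {
  stopifnot(n_chains >= 1, n_beads >= 2)
  set.seed(seed)
  expected <- NULL
  if (identical(polar_angle, "isotropic")) {
    theta <- acos(runif(n_chains, -1, 1))
    expected <- list(p2 = 0)
  } else if (is.function(polar_angle)) {
    theta <- polar_angle(n_chains)
  } else {
    theta <- rep(polar_angle, n_chains)
    expected <- list(p2 = 1.5 * cos(polar_angle)^2 - 0.5)
  }
  phi <- runif(n_chains, 0, 2 * pi)
  dirs <- cbind(sin(theta) * cos(phi), sin(theta) * sin(phi), cos(theta))
  starts <- matrix(runif(3 * n_chains, 0, D), ncol = 3)
  s <- (seq_len(n_beads) - 1) * spacing
  bead_chain <- rep(seq_len(n_chains), each = n_beads)
  pos <- starts[bead_chain, , drop = FALSE] +
    rep(s, n_chains) * dirs[bead_chain, , drop = FALSE]
  top <- build_lipid_topology(n_head, n_beads - n_head, n_chains)
  list(frame = dpd_frame(pos, box = D), topology = top, expected = expected)
}

#' Perfect lamellar stack with analytic density and gyration
#'
#' Chains fully extended along z at fixed spacing, arranged in leaflet pairs
#' so head and tail slabs alternate with the given period.  Analytic
#' expectations: a square-wave head density, order parameter exactly 1 in
#' every populated bin, and the collinear-chain gyration components
#' rg_zz = spacing * sqrt((n^2 - 1)/12), rg_xx = rg_yy = 0.
#'
#' @param period lamellar repeat distance; must divide D.
#' @param n_head,n_tail beads per block.
#' @param D box side.
#' @param chains_per_leaflet chains in each leaflet.
#' @param spacing bead spacing along z.
#' @param seed RNG seed (xy placement).
#' @return list with `frame`, `topology`, `expected` (list with `rg_zz`,
#'   `rg_xy`, `head_fraction`, `p2`).
#' @export
make_perfect_lamella <- function(period, n_head = 3, n_tail = 10, D = 30,
                                 chains_per_leaflet = 40, spacing = 0.7,
                                 seed = 1) {
  n_rep <- D / period
  if (abs(n_rep - round(n_rep)) > 1e-9)
    stop("period must divide the box length", call. = FALSE)
  n_rep <- as.integer(round(n_rep))
  set.seed(seed)
  nb <- n_head + n_tail
  nl <- 2L * n_rep * chains_per_leaflet
  top <- build_lipid_topology(n_head, n_tail, nl)
  pos <- matrix(0, nl * nb, 3)
  c <- 0L
  for (rep_i in seq_len(n_rep) - 1L) {
    for (leaf in 0:1) {
      for (k in seq_len(chains_per_leaflet)) {
        c <- c + 1L
        idx <- ((c - 1) * nb + 1):(c * nb)
        m <- (seq_len(nb) - 0.5) * spacing
        z0 <- rep_i * period
        z <- if (leaf == 0) z0 + m else z0 + period - m
        pos[idx, 1] <- runif(1, 0, D)
        pos[idx, 2] <- runif(1, 0, D)
        pos[idx, 3] <- z
      }
    }
  }
  n <- nb
  list(frame = dpd_frame(pos, box = D), topology = top,
       expected = list(rg_zz = spacing * sqrt((n^2 - 1) / 12), rg_xy = 0,
                       head_fraction = n_head / nb, p2 = 1))
}

#' Two-phase slab fixture for interfacial-tension checks
#'
#' Two unbonded bead species filling opposite half-boxes along z, with
#' like-species repulsion `a_like` and unlike repulsion `a_unlike`.  With
#' `a_unlike > a_like` the two planar interfaces carry positive tension
#' localised at z = 0 and z = D/2; with equal repulsions the system is one
#' effective species and sigma_z averages to zero.  The effective
#' Flory-Huggins parameter is chi = 0.286 (a_unlike - a_like).
#'
#' @param a_like,a_unlike repulsion parameters (kBT/rc).
#' @param D box side.
#' @param rho bead density.
#' @param kT temperature.
#' @param seed RNG seed.
#' @return list with `frame`, `topology`, `ff` (a [dpd_forcefield()] over
#'   species H and T) and `expected` (list with `chi`,
#'   `interface_positions`).
#' @export
make_two_phase_slab <- function(a_like = 25, a_unlike = 100, D = 10, rho = 3,
                                kT = 1, seed = 1) {
  set.seed(seed)
  n_half <- round(rho * D^3 / 2)
  n <- 2L * n_half
  pos <- cbind(runif(n, 0, D), runif(n, 0, D),
               c(runif(n_half, 0, D / 2), runif(n_half, D / 2, D)))
  type <- rep(c("H", "T"), each = n_half)
  top <- structure(list(type = type, chain_id = rep(NA_integer_, n),
                        bonds = matrix(integer(0), 0, 2),
                        angles = matrix(integer(0), 0, 3),
                        n_head = 0L, n_tail = 0L, n_lipids = 0L,
                        n_nanoparticles = 0L, angle_scheme = "head"),
                   class = "dpd_topology")
  ff <- dpd_forcefield(a = default_interactions(a_like, a_unlike, c("H", "T")),
                       kT = kT)
  fr <- init_velocities(dpd_frame(pos, box = D), kT = kT)
  list(frame = fr, topology = top, ff = ff,
       expected = list(chi = 0.286 * (a_unlike - a_like),
                       interface_positions = c(0, D / 2)))
}

#' Flory-Huggins chi from DPD repulsion parameters
#'
#' chi = 0.286 (a_ij - a_ii), the standard mapping between the unlike-bead
#' repulsion excess and the effective immiscibility at melt density rho = 3.
#'
#' @param a_unlike unlike-species repulsion.
#' @param a_like like-species repulsion.
#' @return scalar chi.
#' @export
flory_huggins_chi <- function(a_unlike, a_like = 25) 0.286 * (a_unlike - a_like)
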