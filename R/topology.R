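#' Build the bonded topology of a lipid melt
#'
#' Each lipid is one linear chain of `n_head` hydrophilic H beads followed by
#' `n_tail` hydrophobic T beads, connected by harmonic bonds between
#' consecutive beads.  By default harmonic angles sit on every window of
#' three consecutive beads, making the whole chain a weakly stiff rod: this
#' is what stabilises the lamellar mesophase and yields the rod-like chain
#' extents seen in equilibrium (with `angles = "head"` only the head block
#' is stiffened and the melt loses long-range orientational order).
#' Chainless single-bead nanoparticles (species N) can be appended; they
#' carry no bonds or angles.
#'
#' @param n_head number of head beads per lipid (NH >= 1).
#' @param n_tail number of tail beads per lipid (NT >= 1).
#' @param n_lipids number of lipid chains (>= 1).
#' @param n_nanoparticles number of single-bead nanoparticles appended after
#'   the lipid beads (default 0).
#' @param angles which consecutive-bead triples receive the harmonic angle:
#'   `"all"` (default, every triple: a uniformly stiff rod-like chain) or
#'   `"head"` (head-bead windows only, flexible tails).
#' @return object of class `dpd_topology`: list with `type` (character per
#'   bead), `chain_id` (integer, `NA` for nanoparticles), `bonds` (2-column
#'   integer matrix), `angles` (3-column integer matrix), and the counts
#'   `n_head`, `n_tail`, `n_lipids`, `n_nanoparticles`.
#' @examples
#' top <- build_lipid_topology(3, 10, 1)
#' n_beads(top)          # 13
#' nrow(top$bonds)       # 12
#' nrow(top$angles)      # 11 consecutive triples
#' @export
build_lipid_topology <- function(n_head, n_tail, n_lipids,
                                 n_nanoparticles = 0,
                                 angles = c("all", "head")) {
  angles <- match.arg(angles)
  for (v in list(n_head, n_tail, n_lipids)) {
    if (length(v) != 1 || !is.finite(v) || v < 1 || v != round(v))
      stop("n_head, n_tail and n_lipids must be positive integers", call. = FALSE)
  }
  if (n_nanoparticles < 0 || n_nanoparticles != round(n_nanoparticles))
    stop("n_nanoparticles must be a non-negative integer", call. = FALSE)
  nb <- n_head + n_tail
  chain_type <- c(rep("H", n_head), rep("T", n_tail))
  type <- c(rep(chain_type, n_lipids), rep("N", n_nanoparticles))
  chain_id <- c(rep(seq_len(n_lipids), each = nb), rep(NA_integer_, n_nanoparticles))

  # bonds between consecutive beads of each chain
  first <- (seq_len(n_lipids) - 1L) * nb
  i1 <- rep(first, each = nb - 1L) + seq_len(nb - 1L)
  bonds <- cbind(i1, i1 + 1L)
  dimnames(bonds) <- NULL

  # angle triples: consecutive windows, whole-chain by default
  win_start <- if (angles == "head") {
    if (n_head >= 3) seq_len(n_head - 2L) else integer(0)
  } else {
    if (nb >= 3) seq_len(nb - 2L) else integer(0)
  }
  if (length(win_start) > 0) {
    a1 <- rep(first, each = length(win_start)) + rep(win_start, n_lipids)
    atrip <- cbind(a1, a1 + 1L, a1 + 2L)
  } else {
    atrip <- matrix(integer(0), 0, 3)
  }
  dimnames(atrip) <- NULL

  structure(list(type = type, chain_id = chain_id,
                 bonds = bonds, angles = atrip,
                 n_head = as.integer(n_head), n_tail = as.integer(n_tail),
                 n_lipids = as.integer(n_lipids),
                 n_nanoparticles = as.integer(n_nanoparticles),
                 angle_scheme = angles),
            class = "dpd_topology")
}

#' Number of beads in a topology
#' @param topology a `dpd_topology`.
#' @return integer bead count.
#' @export
n_beads <- function(topology) length(topology$type)

#' @export
print.dpd_topology <- function(x, ...) {
  cat(sprintf("DPD topology: %d lipids (NH = %d, NT = %d), %d nanoparticles\n",
              x$n_lipids, x$n_head, x$n_tail, x$n_nanoparticles))
  cat(sprintf("  %d beads, %d bonds, %d angle triples (%s scheme)\n",
              n_beads(x), nrow(x$bonds), nrow(x$angles), x$angle_scheme))
  invisible(x)
}

#' Nanoparticle count at a prescribed volume concentration
#'
#' The nanoparticle concentration is defined as the number of nanoparticles
#' per box volume in reduced units, phi_NP = N_NP / D^3, so the count for a
#' cubic box of side `box_length` is `round(phi_np * box_length^3)`.
#'
#' @param phi_np nanoparticle concentration (>= 0, beads per rc^3).
#' @param box_length box side D in rc.
#' @return integer nanoparticle count.
#' @examples
#' nanoparticle_count(0.15, 30)  # 4050
#' @export
nanoparticle_count <- function(phi_np, box_length) {
  if (phi_np < 0) stop("phi_np must be non-negative", call. = FALSE)
  if (box_length <= 0) stop("box_length must be positive", call. = FALSE)
  as.integer(round(phi_np * box_length^3))
}

#' Cubic simulation box specification
#'
#' @param length box side D in rc (> 0).
#' @param density target total bead number density rho in beads/rc^3
#'   (default 3, the conventional DPD melt density for a_ii = 25).
#' @return object of class `dpd_box`.
#' @export
box_spec <- function(length, density = 3) {
  if (length <= 0) stop("box length must be positive", call. = FALSE)
  if (density <= 0) stop("density must be positive", call. = FALSE)
  structure(list(length = length, density = density), class = "dpd_box")
}

#' Lipid + nanoparticle topology filling a box at fixed total density
#'
#' Nanoparticles displace lipid beads at fixed total bead density: with
#' N_NP = round(phi_np D^3) nanoparticles, the number of lipids is
#' round((rho D^3 - N_NP) / (NH + NT)), so the total bead count stays within
#' one chain of rho D^3.
#'
#' @inheritParams build_lipid_topology
#' @param phi_np nanoparticle concentration (beads/rc^3).
#' @param box a [box_spec()].
#' @return a `dpd_topology`.
#' @export
lipid_mixture_topology <- function(n_head, n_tail, phi_np, box,
                                   angles = c("all", "head")) {
  stopifnot(inherits(box, "dpd_box"))
  n_np <- nanoparticle_count(phi_np, box$length)
  target <- round(box$density * box$length^3)
  n_lip <- round((target - n_np) / (n_head + n_tail))
  if (n_lip < 1)
    stop("box too small or concentration too high: no room for lipids", call. = FALSE)
  top <- build_lipid_topology(n_head, n_tail, n_lip, n_np, angles = match.arg(angles))
  if (abs(n_beads(top) - target) > n_head + n_tail)
    stop("bead-count bookkeeping failed: ", n_beads(top), " vs target ", target,
         call. = FALSE)
  top
}
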