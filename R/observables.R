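#' Unwrap lipid chains across periodic boundaries
#'
#' Follows each chain bead-by-bead, replacing every bond vector by its
#' minimum image, so that centre-of-mass, end-to-end and gyration
#' computations see contiguous chains.  Assumes bond lengths < D/2 (true for
#' any sane bonded model).  Nanoparticle rows are returned untouched.
#'
#' @param frame a [dpd_frame()].
#' @param topology a `dpd_topology` (beads ordered chain-major).
#' @return N x 3 matrix of unwrapped coordinates.
#' @export
unwrap_chains <- function(frame, topology) {
  pos <- frame$positions
  box <- frame$box
  lip <- which(!is.na(topology$chain_id))
  if (length(lip) == 0) return(pos)
  cid <- topology$chain_id[lip]
  p <- pos[lip, , drop = FALSE]
  n <- nrow(p)
  if (n > 1) {
    d <- p[-1, , drop = FALSE] - p[-n, , drop = FALSE]
    kstep <- -round(d / box)         # image shifts that minimise each bond
    same <- cid[-1] == cid[-n]
    kstep[!same, ] <- 0
    K <- rbind(0, apply(kstep, 2, cumsum))
    firsts <- c(1L, which(!same) + 1L)
    chain_len <- diff(c(firsts, n + 1L))
    base <- K[firsts, , drop = FALSE]
    K <- K - base[rep(seq_along(firsts), chain_len), , drop = FALSE]
    p <- p + K * box
  }
  out <- pos
  out[lip, ] <- p
  out
}

as_frame_list <- function(frames) {
  if (inherits(frames, "dpd_frame")) return(list(frames))
  if (inherits(frames, "dpd_trajectory")) return(frames$frames)
  if (is.list(frames) && all(vapply(frames, inherits, TRUE, "dpd_frame")))
    return(frames)
  stop("expected a dpd_frame, a list of frames, or a dpd_trajectory", call. = FALSE)
}

profile_types <- function(topology) {
  intersect(c("H", "T", "N"), unique(topology$type))
}

#' Axial (z) density profile per bead species
#'
#' Histograms bead z coordinates into bins of width `bin_width` and
#' normalises by the bin volume D * D * dz, giving absolute bead densities in
#' beads/rc^3.  The bin count is round(D / bin_width), so the effective bin
#' width divides D exactly.  Multiple frames are averaged.
#'
#' @param frames a frame, list of frames, or `dpd_trajectory`.
#' @param topology matching `dpd_topology`.
#' @param bin_width nominal bin width (rc); default 0.25.
#' @return object of class `axial_profile`: list with `bin_edges`, `bin_mid`,
#'   `density` (bins x species matrix), `counts` (mean counts per bin),
#'   `bin_width`, `box`, `n_frames`.
#' @export
axial_density <- function(frames, topology, bin_width = 0.25) {
  if (bin_width <= 0) stop("bin_width must be positive", call. = FALSE)
  fl <- as_frame_list(frames)
  box <- fl[[1]]$box
  nbins <- max(1L, as.integer(round(box / bin_width)))
  w <- box / nbins
  types <- profile_types(topology)
  counts <- matrix(0, nbins, length(types), dimnames = list(NULL, types))
  for (fr in fl) {
    z <- wrap_positions(fr$positions[, 3], box)
    bin <- pmin(as.integer(z / w) + 1L, nbins)
    for (ty in types) {
      sel <- topology$type == ty
      counts[, ty] <- counts[, ty] + tabulate(bin[sel], nbins)
    }
  }
  counts <- counts / length(fl)
  structure(list(bin_edges = seq(0, box, by = w), bin_mid = (seq_len(nbins) - 0.5) * w,
                 density = counts / (box * box * w), counts = counts,
                 bin_width = w, box = box, n_frames = length(fl)),
            class = "axial_profile")
}

#' Radial density profile about a cylinder axis
#'
#' Bins minimum-image distances from an axis (a point plus a direction,
#' normally a box axis) into cylindrical annuli and normalises by the
#' annulus volume pi (r2^2 - r1^2) * D, giving absolute densities within the
#' sampled cylinder r < `r_max`.
#'
#' @inheritParams axial_density
#' @param axis_point 3-vector on the cylinder axis.
#' @param axis_dir 3-vector along the axis (nonzero; typically c(0,0,1)).
#' @param r_max maximum sampled radius (default D/2).
#' @return object of class `radial_profile` with `bin_edges`, `bin_mid`,
#'   `density`, `counts`, `bin_width`.
#' @export
radial_density <- function(frames, topology, axis_point, axis_dir = c(0, 0, 1),
                           bin_width = 0.25, r_max = NULL) {
  if (bin_width <= 0) stop("bin_width must be positive", call. = FALSE)
  nrm <- sqrt(sum(axis_dir^2))
  if (nrm < 1e-12) stop("degenerate axis direction", call. = FALSE)
  u <- axis_dir / nrm
  fl <- as_frame_list(frames)
  box <- fl[[1]]$box
  if (is.null(r_max)) r_max <- box / 2
  nbins <- max(1L, as.integer(ceiling(r_max / bin_width)))
  types <- profile_types(topology)
  counts <- matrix(0, nbins, length(types), dimnames = list(NULL, types))
  for (fr in fl) {
    d <- sweep(fr$positions, 2, axis_point)
    d <- min_image(d, box)
    along <- drop(d %*% u)
    perp <- d - outer(along, u)
    r <- sqrt(rowSums(perp^2))
    bin <- as.integer(r / bin_width) + 1L
    ok <- bin <= nbins
    for (ty in types) {
      sel <- ok & topology$type == ty
      counts[, ty] <- counts[, ty] + tabulate(bin[sel], nbins)
    }
  }
  counts <- counts / length(fl)
  edges <- seq(0, nbins * bin_width, by = bin_width)
  vol <- pi * diff(edges^2) * box
  structure(list(bin_edges = edges, bin_mid = (edges[-1] + edges[-length(edges)]) / 2,
                 density = counts / vol, counts = counts,
                 bin_width = bin_width, box = box, n_frames = length(fl)),
            class = "radial_profile")
}

#' End-to-end chain directions
#'
#' The direction of a lipid is the unit vector from its first (head-end)
#' bead to its last (tail-end) bead after unwrapping the chain across
#' periodic boundaries.  With `direction = "head"` only the head block
#' (first to last H bead) defines the direction.
#'
#' @param frame a [dpd_frame()].
#' @param topology a `dpd_topology`.
#' @param direction `"whole"` (default) or `"head"`.
#' @return n_lipids x 3 matrix of unit vectors; chains with coincident
#'   endpoints give NA rows (with a warning).
#' @export
chain_direction <- function(frame, topology, direction = c("whole", "head")) {
  direction <- match.arg(direction)
  if (topology$n_lipids == 0) return(matrix(numeric(0), 0, 3))
  u <- unwrap_chains(frame, topology)
  nb <- topology$n_head + topology$n_tail
  first <- (seq_len(topology$n_lipids) - 1L) * nb + 1L
  last <- if (direction == "head" && topology$n_head >= 2)
    first + topology$n_head - 1L else first + nb - 1L
  d <- u[last, , drop = FALSE] - u[first, , drop = FALSE]
  nrm <- sqrt(rowSums(d^2))
  bad <- nrm < 1e-12
  if (any(bad)) {
    warning(sum(bad), " chain(s) with coincident endpoints skipped")
    nrm[bad] <- NA_real_
  }
  d / nrm
}

chain_p2 <- function(frame, topology, direction = "whole") {
  dirs <- chain_direction(frame, topology, direction)
  1.5 * dirs[, 3]^2 - 0.5
}

#' Orientational order parameter P2 profile along z
#'
#' For every lipid the angle theta between its chain direction and the z
#' axis enters P2 = (3 cos^2 theta - 1)/2: 1 for chains parallel to z, -0.5
#' for perpendicular chains, 0 for an isotropic ensemble.  Chains are
#' assigned to z bins by their first head bead, and the per-bin ensemble
#' average runs over chains and frames.  Empty bins are reported as NA, not
#' zero (zero means isotropic, which an empty bin cannot claim).
#'
#' @inheritParams axial_density
#' @param direction passed to [chain_direction()].
#' @return object of class `order_profile`: data.frame with `bin_mid`, `p2`,
#'   `n_chains`.
#' @export
order_parameter <- function(frames, topology, bin_width = 0.25,
                            direction = c("whole", "head")) {
  direction <- match.arg(direction)
  fl <- as_frame_list(frames)
  box <- fl[[1]]$box
  nbins <- max(1L, as.integer(round(box / bin_width)))
  w <- box / nbins
  nb <- topology$n_head + topology$n_tail
  first <- (seq_len(topology$n_lipids) - 1L) * nb + 1L
  sums <- numeric(nbins)
  ns <- numeric(nbins)
  for (fr in fl) {
    p2 <- chain_p2(fr, topology, direction)
    z <- wrap_positions(fr$positions[first, 3], box)
    bin <- pmin(as.integer(z / w) + 1L, nbins)
    ok <- !is.na(p2)
    if (any(ok)) {
      rs <- rowsum(p2[ok], bin[ok])
      add <- numeric(nbins)
      add[as.integer(rownames(rs))] <- rs[, 1]
      sums <- sums + add
      ns <- ns + tabulate(bin[ok], nbins)
    }
  }
  p2bar <- ifelse(ns > 0, sums / ns, NA_real_)
  out <- data.frame(bin_mid = (seq_len(nbins) - 0.5) * w, p2 = p2bar, n_chains = ns)
  class(out) <- c("order_profile", "data.frame")
  attr(out, "bin_width") <- w
  attr(out, "box") <- box
  out
}

#' Mean orientational order parameter of a frame
#'
#' Ensemble average of P2 = (3 cos^2 theta - 1)/2 over all chains (and
#' frames), without spatial binning.
#'
#' @inheritParams order_parameter
#' @return scalar between -0.5 and 1.
#' @export
order_parameter_mean <- function(frames, topology,
                                 direction = c("whole", "head")) {
  direction <- match.arg(direction)
  fl <- as_frame_list(frames)
  vals <- unlist(lapply(fl, chain_p2, topology = topology, direction = direction))
  mean(vals, na.rm = TRUE)
}

#' Chain-averaged gyration-tensor components over time
#'
#' Per frame and per chain, the diagonal gyration-tensor components are the
#' bead-averaged squared deviations from the chain centre of mass (chains
#' unwrapped first); the per-chain tensors are then averaged over chains and
#' the square roots reported, so `rg_zz` is the rms z-extent of a chain.
#'
#' @inheritParams axial_density
#' @return object of class `gyration_series`: data.frame with `time`,
#'   `rg_xx`, `rg_yy`, `rg_zz`.
#' @export
gyration_components <- function(frames, topology) {
  fl <- as_frame_list(frames)
  nb <- topology$n_head + topology$n_tail
  nl <- topology$n_lipids
  rows <- lapply(fl, function(fr) {
    if (nl == 0) return(data.frame(time = fr$time, rg_xx = NA, rg_yy = NA, rg_zz = NA))
    u <- unwrap_chains(fr, topology)[seq_len(nl * nb), , drop = FALSE]
    g <- rep(seq_len(nl), each = nb)
    com <- rowsum(u, g) / nb
    dev <- u - com[g, , drop = FALSE]
    g2 <- rowsum(dev^2, g) / nb            # per-chain diagonal components
    m <- colMeans(g2)                      # chain average, then sqrt
    data.frame(time = fr$time, rg_xx = sqrt(m[1]), rg_yy = sqrt(m[2]),
               rg_zz = sqrt(m[3]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("gyration_series", "data.frame")
  out
}

#' Nanoparticle axial layering over time
#'
#' The nanoparticle (species N) axial density profile at each requested
#' time, taken from the nearest sampled frame, tracking how an initially
#' uniform nanoparticle distribution develops layers as the lipid matrix
#' orders.
#'
#' @param trajectory a `dpd_trajectory` (or list of frames).
#' @param topology matching `dpd_topology`.
#' @param bin_width axial bin width (rc).
#' @param times times (tau) at which to report; default every sampled frame.
#' @return named list of `axial_profile` objects (names = times); empty list
#'   with a warning when the system has no nanoparticles.
#' @export
nanoparticle_layering <- function(trajectory, topology, bin_width = 0.25,
                                  times = NULL) {
  fl <- as_frame_list(trajectory)
  if (topology$n_nanoparticles == 0) {
    warning("no nanoparticles in the topology; empty result")
    return(list())
  }
  ft <- vapply(fl, function(f) f$time, 0)
  if (is.null(times)) times <- ft
  idx <- vapply(times, function(t) which.min(abs(ft - t)), 0L)
  out <- lapply(idx, function(i) axial_density(fl[[i]], topology, bin_width))
  names(out) <- signif(ft[idx], 8)
  out
}
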