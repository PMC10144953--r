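#' Instantaneous pressure tensor of a frame
#'
#' p_ab = (1/V) ( sum_i m v_ia v_ib + sum over pairs of F_ij,a r_ij,b ): the kinetic
#' term plus the pair virial over every interaction.  By default the virial
#' sums all pair forces (conservative, dissipative, random, bond) plus the
#' torque-free decomposition of the angle force over its two bond vectors;
#' `include = "conservative"` restricts it to the deterministic part
#' (conservative + bond + angle), which is the conventional choice for
#' time-averaged pressures and is deterministic given the frame.
#'
#' @inheritParams compute_forces
#' @return object of class `pressure_tensor`: list with `components`
#'   (3 x 3, kBT/rc^3), `kinetic_part`, `virial_part`.
#' @export
pressure_tensor <- function(frame, topology, ff, dt = 0.01,
                            include = c("all", "conservative")) {
  include <- match.arg(include)
  if (isFALSE(attr(frame, "has_velocities")))
    stop("frame carries no velocities: kinetic pressure undefined", call. = FALSE)
  pp <- pressure_parts(frame, topology, ff, dt, include, nbins = 0L)
  structure(list(components = pp$kinetic + pp$virial,
                 kinetic_part = pp$kinetic, virial_part = pp$virial),
            class = "pressure_tensor")
}

#' @export
print.pressure_tensor <- function(x, ...) {
  cat("Pressure tensor (kBT/rc^3):\n")
  print(x$components)
  invisible(x)
}

# one force evaluation -> kinetic/virial tensors (and slab diagonals)
pressure_parts <- function(frame, topology, ff, dt, include, nbins) {
  ti <- type_index(topology, ff)
  V <- frame$box^3
  res <- cpp_eval(frame$positions, frame$velocities, ti,
                  topology$bonds, topology$angles, unclass(ff),
                  frame$box, dt,
                  if (include == "all") noise_mode(ff) else 0L,
                  include == "all", as.integer(nbins))
  v <- frame$velocities
  kin <- ff$mass * crossprod(v) / V          # sum m v_a v_b / V
  vir <- (res$virial + t(res$virial)) / 2 / V  # symmetrise fp noise
  dimnames(kin) <- dimnames(vir) <- list(c("x", "y", "z"), c("x", "y", "z"))
  out <- list(kinetic = kin, virial = vir)
  if (nbins > 0) {
    box <- frame$box
    w <- box / nbins
    z <- wrap_positions(frame$positions[, 3], box)
    bin <- pmin(as.integer(z / w) + 1L, nbins)
    slab_kin <- matrix(0, nbins, 3)
    for (a in 1:3) {
      rs <- rowsum(ff$mass * v[, a]^2, bin)
      slab_kin[as.integer(rownames(rs)), a] <- rs[, 1]
    }
    out$slab_kinetic <- slab_kin               # raw sums, not yet / volume
    out$slab_virial <- res$slab_virial
  }
  out
}

#' Interfacial tension from a pressure tensor or frame
#'
#' sigma_z = p_zz - (p_xx + p_yy)/2, the excess normal stress along z.  For
#' an isotropic fluid it vanishes; for a lamellar stack normal to z it
#' measures the net interfacial tension per unit area times the number of
#' interfaces divided by D.
#'
#' @param x a `pressure_tensor`, a plain 3 x 3 matrix, or a [dpd_frame()]
#'   (then `topology` and `ff` are required and the tensor is computed).
#' @param ... passed to [pressure_tensor()] when `x` is a frame.
#' @return scalar tension (kBT/rc^3).
#' @export
tension_global <- function(x, ...) {
  p <- if (inherits(x, "pressure_tensor")) x$components
       else if (is.matrix(x)) x
       else pressure_tensor(x, ...)$components
  unname(p[3, 3] - (p[1, 1] + p[2, 2]) / 2)
}

#' Slab-resolved Irving-Kirkwood tension profile along z
#'
#' The box is cut into slabs of width ~`slab_width`; the kinetic part of the
#' local pressure is binned by bead position, and each pair-virial
#' contribution is distributed over the slabs crossed by the ij segment in
#' proportion to the segment length inside each slab (the Irving-Kirkwood
#' partition).  The slab-width-weighted mean of the per-slab tension equals
#' the global sigma_z by construction, to rounding error.  Multiple frames
#' are time-averaged; both the profile and the matching global tension come
#' from the same force evaluations, so the identity holds even when the
#' stochastic forces are included.
#'
#' @inheritParams axial_density
#' @param ff a [dpd_forcefield()].
#' @param slab_width nominal slab width (rc); the bin count is
#'   round(D / slab_width).
#' @param dt time step used to scale the random force.
#' @param include `"all"` or `"conservative"` (see [pressure_tensor()]).
#' @return object of class `tension_profile`: list with `slab_centers`,
#'   `sigma_z` (per slab, kBT/rc^3), `slab_width`, `global` (matching global
#'   tension), `n_frames`.
#' @export
tension_profile <- function(frames, topology, ff, slab_width = 0.5, dt = 0.01,
                            include = c("all", "conservative")) {
  include <- match.arg(include)
  if (slab_width <= 0) stop("slab_width must be positive", call. = FALSE)
  fl <- as_frame_list(frames)
  box <- fl[[1]]$box
  nbins <- max(1L, as.integer(round(box / slab_width)))
  if (box / nbins < 1e-6) stop("slab thinner than numerical resolution", call. = FALSE)
  w <- box / nbins
  slab_sum <- matrix(0, nbins, 3)
  glob <- matrix(0, 3, 3)
  for (fr in fl) {
    pp <- pressure_parts(fr, topology, ff, dt, include, nbins)
    slab_sum <- slab_sum + pp$slab_kinetic + pp$slab_virial
    glob <- glob + pp$kinetic + pp$virial
  }
  vslab <- box * box * w
  p_slab <- slab_sum / length(fl) / vslab      # per-slab diagonal pressure
  sigma <- p_slab[, 3] - (p_slab[, 1] + p_slab[, 2]) / 2
  glob <- glob / length(fl)
  structure(list(slab_centers = (seq_len(nbins) - 0.5) * w, sigma_z = sigma,
                 slab_width = w, box = box,
                 global = unname(glob[3, 3] - (glob[1, 1] + glob[2, 2]) / 2),
                 n_frames = length(fl)),
            class = "tension_profile")
}

#' @export
print.tension_profile <- function(x, ...) {
  cat(sprintf("Tension profile: %d slabs of %.3g rc, global sigma_z = %.4g kBT/rc^3\n",
              length(x$sigma_z), x$slab_width, x$global))
  invisible(x)
}

#' Interfacial tension as a function of time
#'
#' Global sigma_z for every sampled frame of a trajectory, with a centred
#' running mean over `window` samples.  During self-assembly from a random
#' start the series decays from large positive values to a plateau whose
#' mean is the equilibrium interfacial tension.
#'
#' @param trajectory a `dpd_trajectory` (frames must carry velocities).
#' @param topology,ff matching topology and force field.
#' @param dt time step used to scale the random force.
#' @param include `"all"` or `"conservative"`.
#' @param window running-mean window in samples (odd; default 11).
#' @return object of class `tension_series`: data.frame with `time`,
#'   `sigma_z`, `running_mean`.
#' @export
tension_series <- function(trajectory, topology, ff, dt = 0.01,
                           include = c("all", "conservative"), window = 11) {
  include <- match.arg(include)
  fl <- as_frame_list(trajectory)
  sig <- vapply(fl, function(fr)
    tension_global(pressure_tensor(fr, topology, ff, dt, include)), 0)
  times <- vapply(fl, function(f) f$time, 0)
  k <- max(1L, as.integer(window))
  half <- k %/% 2L
  rm <- vapply(seq_along(sig), function(i) {
    lo <- max(1L, i - half); hi <- min(length(sig), i + half)
    mean(sig[lo:hi])
  }, 0)
  out <- data.frame(time = times, sigma_z = sig, running_mean = rm)
  class(out) <- c("tension_series", "data.frame")
  out
}

#' Plateau mean of a tension series
#'
#' Mean of sigma_z over the final fraction of the series (default the last
#' third), the window used to quote equilibrium tensions.
#'
#' @param series a `tension_series`.
#' @param fraction final fraction of samples to average (0, 1].
#' @return scalar mean tension.
#' @export
plateau_mean <- function(series, fraction = 1 / 3) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]", call. = FALSE)
  n <- nrow(series)
  keep <- seq.int(max(1L, n - ceiling(fraction * n) + 1L), n)
  mean(series$sigma_z[keep])
}

#' Locate tension peaks and measure lamellar domain sizes
#'
#' Local maxima of the tension profile mark the H/T interfaces of a lamellar
#' stack (large peaks) and the chain-end junctions inside domains (small
#' peaks).  Peaks are classified large/small by thresholding at the midpoint
#' between the means of the two height clusters (1-D 2-means); the spacing
#' between consecutive large peaks (cyclically, across the periodic
#' boundary) is one domain, assigned to head or tail by whichever species
#' dominates the density between the two peaks.
#'
#' @param profile a `tension_profile` (or list with `slab_centers` and
#'   `sigma_z`).
#' @param density an `axial_profile` of the same system with H and T
#'   columns.
#' @param min_height discard maxima below this absolute height before
#'   classification (default: 5% of the tallest peak).
#' @return object of class `peak_summary`: list with
#'   `large_peak_positions`, `large_peak_mean`, `small_peak_positions`,
#'   `small_peak_mean`, `head_domain_size`, `tail_domain_size`,
#'   `head_domain_sizes`, `tail_domain_sizes`.
#' @export
peak_and_domain_summary <- function(profile, density, min_height = NULL) {
  z <- profile$slab_centers
  y <- profile$sigma_z
  n <- length(y)
  if (n < 3) stop("profile too short for peak detection", call. = FALSE)
  # local maxima on the periodic profile
  yl <- y[c(n, seq_len(n - 1))]
  yr <- y[c(seq_len(n - 1) + 1, 1)]
  pk <- which(y > yl & y >= yr)
  if (is.null(min_height)) min_height <- 0.05 * max(y)
  pk <- pk[y[pk] >= min_height]
  if (length(pk) < 2)
    stop("fewer than two peaks: cannot compute domain sizes", call. = FALSE)
  h <- y[pk]
  if (length(pk) == 2 || diff(range(h)) < 1e-12) {
    large <- pk
    small <- integer(0)
  } else {
    km <- kmeans(matrix(h, ncol = 1), matrix(c(min(h), max(h)), 2, 1))
    thr <- mean(km$centers)
    large <- pk[h >= thr]
    small <- pk[h < thr]
  }
  if (length(large) < 2)
    stop("fewer than two large peaks: cannot compute domain sizes", call. = FALSE)
  zp <- sort(z[large])
  box <- if (!is.null(profile$box)) profile$box else max(z) + profile$slab_width / 2
  gaps <- diff(c(zp, zp[1] + box))
  # dominant species between consecutive large peaks decides head vs tail
  mids <- zp + gaps / 2
  mids <- mids - box * floor(mids / box)
  dom <- vapply(seq_along(gaps), function(i) {
    lo <- zp[i]; hi <- zp[i] + gaps[i]
    zm <- density$bin_mid
    zs <- zm - box * floor((zm - lo) / box)   # shift into [lo, lo+box)
    sel <- zs > lo & zs < hi
    if (!any(sel)) return(NA_character_)
    if (sum(density$density[sel, "H"]) >= sum(density$density[sel, "T"])) "H" else "T"
  }, "")
  head_sizes <- gaps[dom == "H" & !is.na(dom)]
  tail_sizes <- gaps[dom == "T" & !is.na(dom)]
  structure(list(
    large_peak_positions = zp,
    large_peak_mean = mean(y[large]),
    small_peak_positions = sort(z[small]),
    small_peak_mean = if (length(small)) mean(y[small]) else NA_real_,
    head_domain_sizes = head_sizes,
    tail_domain_sizes = tail_sizes,
    head_domain_size = if (length(head_sizes)) mean(head_sizes) else NA_real_,
    tail_domain_size = if (length(tail_sizes)) mean(tail_sizes) else NA_real_),
    class = "peak_summary")
}

#' @export
print.peak_summary <- function(x, ...) {
  cat("Lamellar peak summary\n")
  cat("  large peaks at z =", paste(signif(x$large_peak_positions, 4), collapse = ", "),
      "(mean height", signif(x$large_peak_mean, 3), ")\n")
  if (length(x$small_peak_positions))
    cat("  small peaks at z =", paste(signif(x$small_peak_positions, 4), collapse = ", "),
        "(mean height", signif(x$small_peak_mean, 3), ")\n")
  cat(sprintf("  head domain %.3g rc, tail domain %.3g rc\n",
              x$head_domain_size, x$tail_domain_size))
  invisible(x)
}
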