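#' Simulation frame (positions, velocities, forces, box, time)
#'
#' @param positions N x 3 numeric matrix of bead coordinates (rc); wrapped
#'   into `[0, box)` on construction.
#' @param box cubic box side D (rc).
#' @param velocities optional N x 3 matrix (rc/tau); zeros if omitted.
#' @param forces optional N x 3 matrix; zeros if omitted.
#' @param time simulation time (tau).
#' @return object of class `dpd_frame`.
#' @export
dpd_frame <- function(positions, box, velocities = NULL, forces = NULL, time = 0) {
  positions <- as.matrix(positions)
  if (ncol(positions) != 3) stop("positions must have 3 columns", call. = FALSE)
  if (box <= 0) stop("box length must be positive", call. = FALSE)
  if (!all(is.finite(positions))) stop("non-finite positions", call. = FALSE)
  n <- nrow(positions)
  if (is.null(velocities)) velocities <- matrix(0, n, 3)
  if (is.null(forces)) forces <- matrix(0, n, 3)
  velocities <- as.matrix(velocities); forces <- as.matrix(forces)
  if (nrow(velocities) != n || nrow(forces) != n)
    stop("positions, velocities and forces must have equal lengths", call. = FALSE)
  if (!all(is.finite(velocities)) || !all(is.finite(forces)))
    stop("non-finite velocities or forces", call. = FALSE)
  structure(list(positions = wrap_positions(positions, box),
                 velocities = velocities, forces = forces,
                 box = box, time = time),
            class = "dpd_frame")
}

#' @export
print.dpd_frame <- function(x, ...) {
  cat(sprintf("DPD frame: %d beads, box %g rc, t = %g tau\n",
              nrow(x$positions), x$box, x$time))
  invisible(x)
}

#' Wrap coordinates into the periodic box [0, D)
#' @param x numeric matrix or vector of coordinates.
#' @param box box side D.
#' @return wrapped coordinates of the same shape.
#' @export
wrap_positions <- function(x, box) {
  w <- x - box * floor(x / box)
  w[w >= box] <- 0  # fp edge: floor(x/box)*box can round to x
  w
}

#' Minimum-image displacement
#' @param d displacement(s) between two wrapped coordinates.
#' @param box box side D.
#' @return displacement folded into `[-D/2, D/2]`.
#' @export
min_image <- function(d, box) d - box * round(d / box)

#' Draw Maxwell-Boltzmann velocities at temperature kT
#'
#' Each velocity component is drawn from a zero-mean Gaussian with variance
#' kT/m, then the centre-of-mass velocity is subtracted so the net momentum
#' is exactly zero (the DPD thermostat conserves momentum, so any drift set
#' here would persist).
#'
#' @param frame a [dpd_frame()].
#' @param kT thermal energy (>= 0); `kT = 0` gives all-zero velocities.
#' @param seed optional integer seed for reproducibility.
#' @param mass bead mass.
#' @return the frame with velocities replaced.
#' @export
init_velocities <- function(frame, kT = 1, seed = NULL, mass = 1) {
  stopifnot(inherits(frame, "dpd_frame"))
  if (kT < 0) stop("kT must be non-negative", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(frame$positions)
  if (kT == 0) {
    frame$velocities <- matrix(0, n, 3)
    return(frame)
  }
  v <- matrix(rnorm(3 * n, sd = sqrt(kT / mass)), n, 3)
  v <- sweep(v, 2, colMeans(v))  # remove net momentum
  frame$velocities <- v
  frame
}

#' Instantaneous kinetic temperature of a frame
#'
#' kT_kin = m <v^2> / 3, the equipartition estimate over all beads.
#'
#' @param frame a `dpd_frame`.
#' @param mass bead mass.
#' @return scalar kinetic temperature in reduced units.
#' @export
kinetic_temperature <- function(frame, mass = 1) {
  v <- frame$velocities
  mass * mean(rowSums(v^2)) / 3
}
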