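#' Run configuration for the DPD integrator
#'
#' @param dt time step (tau); 0.01 is the standard choice for soft DPD
#'   potentials at sigma = 3.
#' @param n_steps number of integration steps (>= 0).
#' @param lambda_vv the lambda factor of the modified velocity-Verlet
#'   predictor; 0.65 is the empirical optimum for sigma = 3.
#' @param seed RNG seed applied before the run.
#' @param sample_every trajectory sampling stride in steps (0 = only the
#'   initial frame is kept).
#' @param thermo_every energy-trace stride in steps.
#' @return object of class `dpd_runconfig`.
#' @export
run_config <- function(dt = 0.01, n_steps = 1000, lambda_vv = 0.65, seed = 1,
                       sample_every = 100, thermo_every = 100) {
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  if (lambda_vv <= 0 || lambda_vv > 1) stop("lambda_vv must lie in (0, 1]", call. = FALSE)
  if (n_steps < 0) stop("n_steps must be >= 0", call. = FALSE)
  structure(list(dt = dt, n_steps = as.integer(n_steps), lambda_vv = lambda_vv,
                 seed = as.integer(seed), sample_every = as.integer(sample_every),
                 thermo_every = as.integer(thermo_every)),
            class = "dpd_runconfig")
}

#' Evaluate all DPD forces on a frame
#'
#' One full force evaluation: soft conservative repulsion, pairwise
#' dissipative drag and random kicks (the DPD thermostat), harmonic bonds and
#' harmonic angles, using a cell-list neighbour search under the minimum
#' image convention.  Random kicks are antisymmetric per pair (one noise
#' draw shared by ij and ji), which is what makes the thermostat conserve
#' momentum exactly.
#'
#' @param frame a [dpd_frame()].
#' @param topology a `dpd_topology`.
#' @param ff a [dpd_forcefield()].
#' @param dt time step used to scale the random force (it enters as
#'   dt^-1/2).
#' @param include `"all"` for conservative + dissipative + random, or
#'   `"conservative"` for the deterministic part only (conservative + bond +
#'   angle).
#' @return list with `forces` (N x 3), `epot` (potential energy, kBT),
#'   `virial` (3 x 3 pair-virial tensor, sum over F_a d_b) and `n_overlap`
#'   (count of exactly coincident pairs, whose force direction is undefined
#'   and which therefore contribute zero force).
#' @export
compute_forces <- function(frame, topology, ff, dt = 0.01,
                           include = c("all", "conservative")) {
  include <- match.arg(include)
  ti <- type_index(topology, ff)
  res <- cpp_eval(frame$positions, frame$velocities, ti,
                  topology$bonds, topology$angles, unclass(ff),
                  frame$box, dt,
                  if (include == "all") noise_mode(ff) else 0L,
                  include == "all", 0L)
  if (res$n_overlap > 0)
    warning(res$n_overlap, " coincident bead pair(s): overlap force set to zero")
  res
}

#' Advance the system by one modified velocity-Verlet step
#'
#' The Groot-Warren scheme: positions advance with the current force,
#' velocities are predicted with lambda*dt*f, forces are recomputed at the
#' new positions and predicted velocities (the dissipative force depends on
#' velocities), and the final velocity uses the mean of old and new forces.
#'
#' @inheritParams compute_forces
#' @param cfg a [run_config()]; only `dt` and `lambda_vv` are used.
#' @return the updated `dpd_frame` (positions rewrapped, forces stored).
#' @export
dpd_step <- function(frame, topology, ff, cfg = run_config()) {
  res <- dpd_run(frame, topology, ff,
                 run_config(dt = cfg$dt, n_steps = 1, lambda_vv = cfg$lambda_vv,
                            seed = cfg$seed, sample_every = 0, thermo_every = 0),
                 set_seed = FALSE)
  res$frame
}

#' Integrate a DPD trajectory
#'
#' Runs `cfg$n_steps` steps of the modified velocity-Verlet integrator in
#' the NVT ensemble (the pairwise dissipative + random forces are the
#' thermostat), sampling frames every `sample_every` steps and recording the
#' energy trace (potential, kinetic and total energy per bead-set, in kBT)
#' every `thermo_every` steps.  The initial frame is always the first
#' trajectory sample.
#'
#' @inheritParams compute_forces
#' @param cfg a [run_config()].
#' @param set_seed set the RNG seed from `cfg$seed` before integrating
#'   (default TRUE); disable to continue a run under the current RNG state.
#' @return list with `frame` (final state), `trajectory` (class
#'   `dpd_trajectory`: list of sampled frames + `times`), and `energy`
#'   (data.frame: step, epot, ekin, etotal).
#' @export
dpd_run <- function(frame, topology, ff, cfg = run_config(), set_seed = TRUE) {
  stopifnot(inherits(frame, "dpd_frame"), inherits(topology, "dpd_topology"),
            inherits(ff, "dpd_forcefield"), inherits(cfg, "dpd_runconfig"))
  if (n_beads(topology) != nrow(frame$positions))
    stop("frame and topology bead counts differ", call. = FALSE)
  if (set_seed) set.seed(cfg$seed)
  ti <- type_index(topology, ff)
  res <- cpp_run(frame$positions, frame$velocities, ti,
                 topology$bonds, topology$angles, unclass(ff),
                 frame$box, cfg$dt, cfg$n_steps, cfg$lambda_vv,
                 cfg$sample_every, cfg$thermo_every, noise_mode(ff),
                 frame$time)
  frames <- lapply(res$samples, function(s)
    dpd_frame(s$pos, box = frame$box, velocities = s$vel, time = s$time))
  traj <- structure(list(frames = frames,
                         times = vapply(frames, function(f) f$time, 0)),
                    class = "dpd_trajectory")
  en <- data.frame(step = res$energy$step, epot = res$energy$epot,
                   ekin = res$energy$ekin)
  en$etotal <- en$epot + en$ekin
  final <- dpd_frame(res$pos, box = frame$box, velocities = res$vel,
                     forces = res$forces, time = res$time)
  list(frame = final, trajectory = traj, energy = en)
}

#' @export
print.dpd_trajectory <- function(x, ...) {
  cat(sprintf("DPD trajectory: %d frames, t = %g .. %g tau\n",
              length(x$frames), min(x$times), max(x$times)))
  invisible(x)
}
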