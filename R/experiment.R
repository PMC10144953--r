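config_defaults <- function() {
  list(n_head = 3L, n_tail = 10L, phi_np = 0, box_length = 30, density = 3,
       phase = "lamellar", dt = 0.01, n_steps = 10000L, lambda = 0.65,
       seeds = 1L, sample_every = 500L, thermo_every = 500L,
       bin_width = 0.25, slab_width = 0.5, plateau_fraction = 1 / 3,
       kT = 1, gamma = 4.5, sigma = 3, a_like = 25, a_unlike = 100,
       bond_k = 120, bond_r0 = 0.7, angle_k = 6, noise = "gaussian",
       angle_scheme = "all", output_dir = "dpd_output")
}

#' Read and validate an experiment configuration (YAML)
#'
#' A config names the chain architecture (NH, NT), the nanoparticle
#' concentrations, the box, the force-field constants, the run protocol and
#' the analysis bin widths; anything omitted takes the documented default
#' (D = 30, rho = 3, dt = 0.01, sigma = 3, gamma = 4.5, lambda = 0.65, ...).
#' Unknown keys and out-of-range values are rejected with a descriptive
#' error.
#'
#' @param path YAML file path.
#' @return object of class `dpd_config` (a named list).
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  validate_config(raw)
}

#' @rdname read_config
#' @param config a named list of config values (partial; defaults fill in).
#' @export
validate_config <- function(config) {
  defs <- config_defaults()
  unknown <- setdiff(names(config), names(defs))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "), call. = FALSE)
  cfg <- defs
  cfg[names(config)] <- config
  if (cfg$dt <= 0) stop("dt must be positive", call. = FALSE)
  if (cfg$n_head < 1 || cfg$n_tail < 1)
    stop("n_head and n_tail must be >= 1", call. = FALSE)
  if (any(cfg$phi_np < 0)) stop("phi_np must be non-negative", call. = FALSE)
  if (cfg$box_length <= 0 || cfg$density <= 0)
    stop("box_length and density must be positive", call. = FALSE)
  if (length(cfg$seeds) < 1) stop("seeds must be non-empty", call. = FALSE)
  if (!cfg$phase %in% c("random", "lamellar", "hexagonal"))
    stop("phase must be one of random, lamellar, hexagonal", call. = FALSE)
  if (cfg$lambda <= 0 || cfg$lambda > 1) stop("lambda must be in (0, 1]", call. = FALSE)
  if (cfg$n_steps < 0) stop("n_steps must be >= 0", call. = FALSE)
  structure(cfg, class = "dpd_config")
}

#' Write a config back to YAML
#' @param config a `dpd_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 12)
  invisible(path)
}

forcefield_from_config <- function(cfg) {
  dpd_forcefield(a = default_interactions(cfg$a_like, cfg$a_unlike),
                 gamma = cfg$gamma, sigma = cfg$sigma, kT = cfg$kT,
                 bond_k = cfg$bond_k, bond_r0 = cfg$bond_r0,
                 angle_k = cfg$angle_k, noise = cfg$noise)
}

write_units_csv <- function(df, path, units) {
  con <- file(path, "w")
  writeLines(paste0("# ", units), con)
  write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  close(con)
  invisible(path)
}

#' Run a full build-simulate-analyse experiment
#'
#' For every (phi_np, seed) pair: builds the topology and starting
#' configuration, integrates the DPD trajectory, and writes the standard
#' analysis artifacts under `output_dir/phi_<phi>/seed_<seed>/`: the energy
#' trace, axial density and order-parameter profiles (averaged over the
#' plateau window), the gyration-series, the nanoparticle layering, and the
#' tension profile and series.  Per-seed plateau observables are pooled
#' into a mean +/- sd summary per concentration.
#'
#' @param config a `dpd_config` from [read_config()]/[validate_config()].
#' @param quiet suppress progress messages.
#' @return data.frame summary (one row per phi_np: pooled mean and sd of
#'   the plateau tension and gyration components), invisibly; the artifact
#'   tree is written as a side effect, including `summary.csv` and a JSON
#'   run manifest.
#' @export
run_experiment <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "dpd_config"))
  cfg <- config
  ff <- forcefield_from_config(cfg)
  box <- box_spec(cfg$box_length, cfg$density)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  per_seed <- list()
  for (phi in cfg$phi_np) {
    for (seed in cfg$seeds) {
      tag <- sprintf("phi_%g/seed_%d", phi, seed)
      if (!quiet) message("running ", tag)
      outdir <- file.path(cfg$output_dir, tag)
      dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
      top <- lipid_mixture_topology(cfg$n_head, cfg$n_tail, phi, box,
                                    angles = cfg$angle_scheme)
      fr <- switch(cfg$phase,
                   random = place_random_melt(top, box, seed, cfg$bond_r0),
                   place_preassembled(top, box, cfg$phase, seed, cfg$bond_r0))
      fr <- init_velocities(fr, kT = cfg$kT)
      rc <- run_config(dt = cfg$dt, n_steps = cfg$n_steps, lambda_vv = cfg$lambda,
                       seed = seed, sample_every = cfg$sample_every,
                       thermo_every = cfg$thermo_every)
      run <- dpd_run(fr, top, ff, rc, set_seed = FALSE)
      traj <- run$trajectory

      write_units_csv(run$energy, file.path(outdir, "energy.csv"),
                      "step [1], energies [kBT]")
      nfr <- length(traj$frames)
      plateau <- traj$frames[seq.int(max(1L, nfr - ceiling(cfg$plateau_fraction * nfr) + 1L), nfr)]
      dens <- axial_density(plateau, top, cfg$bin_width)
      ddf <- data.frame(z = dens$bin_mid, dens$density, check.names = FALSE)
      write_units_csv(ddf, file.path(outdir, "density_axial.csv"),
                      "z [rc], densities [beads/rc^3]")
      op <- order_parameter(plateau, top, cfg$bin_width)
      write_units_csv(as.data.frame(op), file.path(outdir, "order_profile.csv"),
                      "bin_mid [rc], p2 [1], n_chains [1]")
      rg <- gyration_components(traj, top)
      write_units_csv(as.data.frame(rg), file.path(outdir, "gyration_series.csv"),
                      "time [tau], rg components [rc]")
      if (top$n_nanoparticles > 0) {
        lay <- nanoparticle_layering(traj, top, cfg$bin_width)
        ldf <- do.call(rbind, lapply(names(lay), function(tm)
          data.frame(time = as.numeric(tm), z = lay[[tm]]$bin_mid,
                     density_np = lay[[tm]]$density[, "N"])))
        write_units_csv(ldf, file.path(outdir, "np_layering.csv"),
                        "time [tau], z [rc], density [beads/rc^3]")
      } else {
        writeLines("no nanoparticles at this concentration; layering not applicable",
                   file.path(outdir, "np_layering_NOTE.txt"))
      }
      tp <- tension_profile(plateau, top, ff, cfg$slab_width, cfg$dt)
      write_units_csv(data.frame(z = tp$slab_centers, sigma_z = tp$sigma_z),
                      file.path(outdir, "tension_profile.csv"),
                      "z [rc], sigma_z [kBT/rc^3]")
      ts <- tension_series(traj, top, ff, cfg$dt)
      write_units_csv(as.data.frame(ts), file.path(outdir, "tension_series.csv"),
                      "time [tau], sigma_z [kBT/rc^3]")

      np <- max(1L, nrow(rg) - ceiling(cfg$plateau_fraction * nrow(rg)) + 1L)
      per_seed[[tag]] <- data.frame(
        phi_np = phi, seed = seed,
        tension = plateau_mean(ts, cfg$plateau_fraction),
        rg_xx = mean(rg$rg_xx[np:nrow(rg)]),
        rg_yy = mean(rg$rg_yy[np:nrow(rg)]),
        rg_zz = mean(rg$rg_zz[np:nrow(rg)]))
    }
  }
  seed_df <- do.call(rbind, per_seed)
  rownames(seed_df) <- NULL
  pooled <- do.call(rbind, lapply(split(seed_df, seed_df$phi_np), function(d) {
    data.frame(phi_np = d$phi_np[1], n_seeds = nrow(d),
               tension_mean = mean(d$tension), tension_sd = sd_or_zero(d$tension),
               rg_xx_mean = mean(d$rg_xx), rg_xx_sd = sd_or_zero(d$rg_xx),
               rg_yy_mean = mean(d$rg_yy), rg_yy_sd = sd_or_zero(d$rg_yy),
               rg_zz_mean = mean(d$rg_zz), rg_zz_sd = sd_or_zero(d$rg_zz))
  }))
  rownames(pooled) <- NULL
  write_units_csv(seed_df, file.path(cfg$output_dir, "per_seed.csv"),
                  "tension [kBT/rc^3], rg [rc]")
  write_units_csv(pooled, file.path(cfg$output_dir, "summary.csv"),
                  "tension [kBT/rc^3], rg [rc]")
  manifest <- list(config = unclass(cfg),
                   package_version = as.character(utils::packageVersion("dpdlipid")),
                   generated = "dpdlipid::run_experiment")
  jsonlite::write_json(manifest, file.path(cfg$output_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(pooled)
}

sd_or_zero <- function(x) if (length(x) > 1) sd(x) else 0
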