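#' Default bead-bead repulsion matrix
#'
#' Maximum-repulsion parameters for the three bead species: hydrophilic head
#' (H), hydrophobic tail (T) and nanoparticle (N).  Like species repel with
#' `a_like` and unlike species with `a_unlike`; the large unlike repulsion is
#' what drives microphase separation (Flory-Huggins chi = 0.286 (aij - aii)).
#'
#' @param a_like repulsion between beads of the same species (kBT/rc).
#' @param a_unlike repulsion between beads of different species (kBT/rc).
#' @param types character vector of bead species names.
#' @return symmetric numeric matrix with `types` as dimnames.
#' @export
default_interactions <- function(a_like = 25, a_unlike = 100,
                                 types = c("H", "T", "N")) {
  n <- length(types)
  a <- matrix(a_unlike, n, n, dimnames = list(types, types))
  diag(a) <- a_like
  a
}

#' DPD force-field parameters
#'
#' Bundles every interaction constant of the coarse-grained model: the soft
#' pairwise repulsion matrix, the dissipative/random thermostat pair
#' (`gamma`, `sigma`), the harmonic bond (`bond_k`, `bond_r0`) and the
#' harmonic angle (`angle_k`, `angle_theta0`) of the lipid chains.  The
#' thermostat pair must satisfy the fluctuation-dissipation relation
#' sigma^2 = 2 gamma kT, which ties the random-force amplitude to the drag so
#' that the pair thermostat samples the canonical ensemble at `kT`.
#'
#' Defaults are the standard melt parametrisation: a_ii = 25, a_ij = 100,
#' sigma = 3, gamma = 4.5, ks = 120 with rs = 0.7 rc, k_theta = 6 with
#' theta0 = pi, and reduced units kT = rc = m = 1.
#'
#' @param a symmetric repulsion matrix with bead-species dimnames
#'   (default [default_interactions()]).
#' @param gamma friction coefficient of the dissipative force.
#' @param sigma amplitude of the random force; must satisfy
#'   sigma^2 = 2 gamma kT.
#' @param kT thermal energy (reduced; 1).
#' @param cutoff pair cutoff rc (reduced length unit; 1).
#' @param bond_k harmonic bond spring constant ks.
#' @param bond_r0 equilibrium bond length rs, in units of rc; must be < rc.
#' @param angle_k angle stiffness k_theta.
#' @param angle_theta0 equilibrium angle theta0 in radians (pi = straight).
#' @param mass bead mass (reduced; 1).
#' @param noise distribution of the pair noise zeta: zero-mean unit-variance
#'   Gaussian (default) or uniform.
#' @return object of class `dpd_forcefield`.
#' @examples
#' ff <- dpd_forcefield()
#' ff$a["H", "T"]   # 100
#' @export
dpd_forcefield <- function(a = default_interactions(), gamma = 4.5, sigma = 3.0,
                           kT = 1, cutoff = 1, bond_k = 120, bond_r0 = 0.7,
                           angle_k = 6, angle_theta0 = pi, mass = 1,
                           noise = c("gaussian", "uniform")) {
  noise <- match.arg(noise)
  if (!is.matrix(a) || nrow(a) != ncol(a))
    stop("'a' must be a square matrix", call. = FALSE)
  if (is.null(rownames(a)) || !identical(rownames(a), colnames(a)))
    stop("'a' must carry identical row and column bead-species names", call. = FALSE)
  if (any(a < 0)) stop("repulsion parameters must be non-negative", call. = FALSE)
  if (max(abs(a - t(a))) > 1e-12)
    stop("interaction matrix must be symmetric", call. = FALSE)
  if (cutoff <= 0) stop("cutoff must be positive", call. = FALSE)
  if (kT < 0) stop("kT must be non-negative", call. = FALSE)
  if (abs(sigma^2 - 2 * gamma * kT) > 1e-8)
    stop("fluctuation-dissipation violated: need sigma^2 = 2*gamma*kT ",
         "(got sigma^2 = ", sigma^2, ", 2*gamma*kT = ", 2 * gamma * kT, ")",
         call. = FALSE)
  if (bond_r0 <= 0 || bond_r0 >= cutoff)
    stop("bond_r0 must lie in (0, cutoff)", call. = FALSE)
  if (bond_k < 0 || angle_k < 0) stop("spring constants must be >= 0", call. = FALSE)
  structure(list(a = a, gamma = gamma, sigma = sigma, kT = kT, cutoff = cutoff,
                 bond_k = bond_k, bond_r0 = bond_r0, angle_k = angle_k,
                 angle_theta0 = angle_theta0, mass = mass, noise = noise),
            class = "dpd_forcefield")
}

#' @export
print.dpd_forcefield <- function(x, ...) {
  cat("DPD force field (reduced units)\n")
  cat("  species:", paste(rownames(x$a), collapse = ", "), "\n")
  cat("  repulsion a_ij:\n")
  print(x$a)
  cat(sprintf("  thermostat: gamma = %g, sigma = %g (kT = %g, noise %s)\n",
              x$gamma, x$sigma, x$kT, x$noise))
  cat(sprintf("  bond: ks = %g, rs = %g rc; angle: k = %g, theta0 = %g rad\n",
              x$bond_k, x$bond_r0, x$angle_k, x$angle_theta0))
  invisible(x)
}

noise_mode <- function(ff) if (identical(ff$noise, "uniform")) 2L else 1L

type_index <- function(topology, ff) {
  idx <- match(topology$type, rownames(ff$a))
  if (anyNA(idx))
    stop("bead species ", paste(unique(topology$type[is.na(idx)]), collapse = ", "),
         " missing from the interaction matrix", call. = FALSE)
  idx
}
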