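#' @useDynLib rodbend, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# all pairs of rows of `coords` closer than `cutoff` (two-column matrix)
close_pairs <- function(coords, cutoff) {
  close_pairs_cpp(coords_matrix(coords), cutoff)
}

#' Species-specific protein affinity model for lipid dynamics
#'
#' Square-well attraction between lipid headgroups and protein anchor
#' sites: a lipid of species s within `range` of any site has energy
#' `-epsilon[s]` (in kT), otherwise 0. The defaults give cardiolipin a
#' well depth of ln 2 and DPPG ln 1.5, so in the non-interacting limit the
#' shell concentrations relative to DPPE double and rise 1.5-fold
#' respectively.
#'
#' @param epsilon named per-species well depths in kT.
#' @param range interaction range in nm (1.0 nm shell).
#' @param step_length Gaussian tangent-step length per proposal, nm.
#' @param n_sweeps number of Monte Carlo sweeps (one attempted move per
#'   lipid per sweep).
#' @param stride record a frame every `stride` sweeps.
#' @param seed RNG seed.
#' @return An `affinity_model` list.
#' @export
affinity_model <- function(epsilon = c(CL = log(2), DPPG = log(1.5), DPPE = 0),
                           range = 1.0, step_length = 0.2,
                           n_sweeps = 20000, stride = NULL, seed = 1L) {
  if (range <= 0) abort("interaction range must be > 0")
  if (any(!is.finite(epsilon))) abort("epsilon must be finite")
  if (step_length <= 0) abort("step_length must be > 0")
  if (is.null(stride)) stride <- max(1L, as.integer(n_sweeps / 200))
  structure(
    list(epsilon = epsilon, range = range, step_length = step_length,
         n_sweeps = as.integer(n_sweeps), stride = as.integer(stride),
         seed = as.integer(seed)),
    class = "affinity_model"
  )
}

#' Metropolis Monte Carlo lipid lateral dynamics on the vesicle
#'
#' Each sweep proposes, for every lipid in turn, a Gaussian tangent-plane
#' displacement re-projected onto its leaflet sphere. The move is rejected
#' outright if it brings two same-leaflet headgroups closer than the spec's
#' minimum separation (hard core) and otherwise accepted with probability
#' `min(1, exp(-dE/kT))`, where the energy is the square-well protein
#' affinity of [affinity_model()]. Frames are recorded every
#' `model$stride` sweeps (plus the initial configuration).
#'
#' @param config a `vesicle` from [place_lipids()] /
#'   [place_proteins_evenly()].
#' @param model an [affinity_model()].
#' @return A `lipid_trajectory`: `frames` (list of n x 3 matrices),
#'   `sweeps`, `lipids` (species/leaflet tibble), `protein_sites`,
#'   `outer_radius`, `inner_radius`, `model`.
#' @export
run_lipid_dynamics <- function(config, model = affinity_model()) {
  stopifnot(inherits(config, "vesicle"), inherits(model, "affinity_model"))
  if (nrow(config$protein_sites) == 0 && any(model$epsilon != 0)) {
    abort("affinity model has non-zero well depths but the vesicle has no protein sites")
  }
  species <- unique(config$lipids$species)
  missing_eps <- setdiff(species, names(model$epsilon))
  eps_by_species <- c(model$epsilon,
                      setNames(rep(0, length(missing_eps)), missing_eps))
  lipids <- config$lipids
  m <- as.matrix(lipids[, c("x", "y", "z")])
  radius <- ifelse(lipids$leaflet == "outer", config$outer_radius,
                   config$inner_radius)
  leaflet <- as.integer(lipids$leaflet == "outer")
  eps <- as.numeric(eps_by_species[lipids$species])
  sites <- as.matrix(config$protein_sites[, c("x", "y", "z")])
  if (nrow(sites) == 0) sites <- matrix(0, 0, 3)
  set.seed(model$seed)
  res <- mc_lipid_dynamics_cpp(m, radius, leaflet, eps, sites,
                               model$range, model$step_length,
                               model$n_sweeps, model$stride,
                               config$spec$min_separation)
  structure(
    list(frames = res$frames, sweeps = res$sweeps,
         lipids = lipids[, c("species", "leaflet")],
         protein_sites = config$protein_sites,
         outer_radius = config$outer_radius,
         inner_radius = config$inner_radius,
         model = model, spec = config$spec),
    class = "lipid_trajectory"
  )
}

#' @export
print.lipid_trajectory <- function(x, ...) {
  cat(sprintf("<lipid_trajectory> %d lipids, %d frames (every %d of %d sweeps)\n",
              nrow(x$lipids), length(x$frames), x$model$stride,
              x$model$n_sweeps))
  invisible(x)
}

#' Convert one trajectory frame to a vesicle configuration
#'
#' @param traj a [run_lipid_dynamics()] result.
#' @param frame 1-based frame index.
#' @return A `vesicle` object with that frame's coordinates.
#' @export
trajectory_frame <- function(traj, frame) {
  stopifnot(inherits(traj, "lipid_trajectory"))
  m <- traj$frames[[frame]]
  lipids <- traj$lipids
  lipids$x <- m[, 1]; lipids$y <- m[, 2]; lipids$z <- m[, 3]
  structure(
    list(lipids = lipids, outer_radius = traj$outer_radius,
         inner_radius = traj$inner_radius,
         protein_sites = traj$protein_sites, spec = traj$spec),
    class = "vesicle"
  )
}
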