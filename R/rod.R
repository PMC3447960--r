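#' Specification of a synthetic rod-like receptor
#'
#' Describes an idealised multi-chain receptor rod at one backbone particle
#' per residue: each chain is a straight line of particles along +z spaced
#' `rise_per_residue` apart, with chains placed symmetrically around the rod
#' axis at a nearest-neighbour chain separation of 1.0 nm. Defaults follow
#' Tsr numbering: 500 residues per chain, two chains (a homodimer), and a
#' bending hinge at residue 268 between the HAMP and coiled-coil domains.
#'
#' @param n_residues_per_chain residues (= particles) per chain.
#' @param n_chains number of chains (2 for a dimer).
#' @param rise_per_residue axial spacing between consecutive residues, nm.
#' @param hinge_residue 1-based residue index of the bending hinge.
#' @param domain_map named list of integer residue ranges, ordered and
#'   disjoint; `NULL` gives a Tsr-like three-domain split (ligand-binding,
#'   HAMP, coiled-coil) around the hinge.
#' @param noise_sd isotropic Gaussian positional noise per coordinate, nm.
#' @param seed RNG seed used when building noisy rods.
#' @return A `rod_spec` list.
#' @examples
#' spec <- rod_spec(n_residues_per_chain = 100, hinge_residue = 50)
#' rod <- build_rod(spec)
#' @export
rod_spec <- function(n_residues_per_chain = 500,
                     n_chains = 2,
                     rise_per_residue = 0.15,
                     hinge_residue = 268,
                     domain_map = NULL,
                     noise_sd = 0,
                     seed = 1L) {
  if (n_residues_per_chain < 1) abort("n_residues_per_chain must be positive")
  if (n_chains < 1) abort("n_chains must be positive")
  if (rise_per_residue <= 0) abort("rise_per_residue must be positive")
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  if (hinge_residue < 1 || hinge_residue > n_residues_per_chain) {
    abort("hinge_residue must lie within 1..n_residues_per_chain")
  }
  n <- as.integer(n_residues_per_chain)
  h <- as.integer(hinge_residue)
  if (is.null(domain_map)) {
    domain_map <- default_domain_map(n, h)
  }
  check_domain_map(domain_map, n)
  structure(
    list(n_residues_per_chain = n, n_chains = as.integer(n_chains),
         rise_per_residue = rise_per_residue, hinge_residue = h,
         domain_map = domain_map, noise_sd = noise_sd, seed = as.integer(seed)),
    class = "rod_spec"
  )
}

# Tsr-like partition: ligand-binding | HAMP (~50 residues ending at the
# hinge) | coiled-coil from the hinge onwards.
default_domain_map <- function(n, h) {
  hamp_start <- max(2L, h - 49L)
  dm <- list()
  if (hamp_start > 1L) dm$ligand_binding <- 1:(hamp_start - 1L)
  if (h > hamp_start) dm$HAMP <- hamp_start:(h - 1L)
  dm$coiled_coil <- h:n
  dm
}

check_domain_map <- function(domain_map, n) {
  if (!is.list(domain_map) || is.null(names(domain_map))) {
    abort("domain_map must be a named list of residue ranges")
  }
  all_res <- unlist(domain_map, use.names = FALSE)
  if (any(all_res < 1 | all_res > n)) abort("domain ranges outside 1..n")
  if (anyDuplicated(all_res)) abort("domain ranges must be disjoint")
  starts <- vapply(domain_map, min, numeric(1))
  if (is.unsorted(starts, strictly = TRUE)) abort("domain ranges must be ordered")
  invisible(TRUE)
}

domain_labels <- function(domain_map, resid) {
  lab <- rep(NA_character_, length(resid))
  for (nm in names(domain_map)) lab[resid %in% domain_map[[nm]]] <- nm
  lab[is.na(lab)] <- "unassigned"
  lab
}

#' Build an idealised straight receptor rod
#'
#' Each chain is a line of particles along +z with spacing
#' `rise_per_residue`; chains sit on a circle around the z axis with
#' nearest-neighbour chain separation 1.0 nm (a single chain sits on the
#' axis). Isotropic Gaussian noise of sd `noise_sd` is added per coordinate
#' using the spec seed; `noise_sd = 0` gives exactly collinear chains.
#'
#' @param spec a [rod_spec()].
#' @return A `particle_model` tibble (chain, resid, domain, x, y, z in nm).
#' @export
build_rod <- function(spec) {
  stopifnot(inherits(spec, "rod_spec"))
  n <- spec$n_residues_per_chain
  nc <- spec$n_chains
  z <- (seq_len(n) - 1) * spec$rise_per_residue
  offsets <- chain_offsets(nc)
  chains <- LETTERS[seq_len(nc)]
  df <- purrr::map_dfr(seq_len(nc), function(j) {
    tibble::tibble(
      chain = chains[j], resid = seq_len(n),
      domain = domain_labels(spec$domain_map, seq_len(n)),
      x = offsets[j, 1], y = offsets[j, 2], z = z
    )
  })
  if (spec$noise_sd > 0) {
    set.seed(spec$seed)
    df$x <- df$x + rnorm(nrow(df), 0, spec$noise_sd)
    df$y <- df$y + rnorm(nrow(df), 0, spec$noise_sd)
    df$z <- df$z + rnorm(nrow(df), 0, spec$noise_sd)
  }
  as_particle_model(df)
}

# chains on a circle around the z axis, adjacent chains 1.0 nm apart
chain_offsets <- function(n_chains, separation = 1.0) {
  if (n_chains == 1) return(matrix(0, 1, 2))
  ang <- 2 * pi * (seq_len(n_chains) - 1) / n_chains
  radius <- separation / (2 * sin(pi / n_chains))
  cbind(radius * cos(ang), radius * sin(ang))
}

#' Bend a rod rigidly about its hinge
#'
#' All particles with residue index strictly greater than `hinge` (in every
#' chain) are rotated by `angle` degrees about an axis perpendicular to the
#' rod axis passing through the centroid of the hinge-residue particles;
#' particles at or below the hinge are unchanged.
#'
#' @param model a `particle_model` of a straight or near-straight rod.
#' @param hinge 1-based hinge residue, strictly inside every chain.
#' @param angle bending angle in degrees.
#' @param axis optional explicit unit rotation axis (length-3). When `NULL`
#'   a random axis perpendicular to the rod axis is drawn from the current
#'   RNG stream (or from `axis_seed` if given).
#' @param axis_seed optional seed for the random axis draw.
#' @return The bent `particle_model`, with the rotation axis in attribute
#'   `"bend_axis"`.
#' @export
bend_at_hinge <- function(model, hinge, angle, axis = NULL, axis_seed = NULL) {
  stopifnot(inherits(model, "particle_model"))
  rng <- range(model$resid)
  if (hinge <= rng[1] || hinge >= rng[2]) {
    abort("hinge must be strictly inside the chain: no segment to rotate")
  }
  m <- model_coords(model)
  rod_axis <- fit_axis(m)$direction
  if (is.null(axis)) {
    if (!is.null(axis_seed)) set.seed(axis_seed)
    basis <- perpendicular_basis(rod_axis)
    phi <- runif(1, 0, 2 * pi)
    axis <- basis[, 1] * cos(phi) + basis[, 2] * sin(phi)
  }
  axis <- unit_vector(axis)
  pivot <- colMeans(m[model$resid == hinge, , drop = FALSE])
  move <- model$resid > hinge
  R <- rotation_matrix(axis, angle)
  m[move, ] <- sweep(sweep(m[move, , drop = FALSE], 2, pivot) %*% t(R), 2, pivot, "+")
  out <- set_model_coords(model, m)
  attr(out, "bend_axis") <- axis
  out
}

#' Bending-angle distribution for ensemble generation
#'
#' Unimodal distribution over bending angles truncated to `[0, max_deg]`.
#' The default family is a truncated gamma parameterised by its mode and an
#' (untruncated) standard deviation: strictly non-negative, unimodal and
#' right-skewed, with defaults matching the dimer behaviour used throughout
#' (mode 30 degrees, hard cap 60 degrees). A wrapped-normal family is
#' available as an alternative.
#'
#' @param mode_deg modal angle, degrees.
#' @param spread_deg spread (sd-like) parameter, degrees; must be > 0.
#' @param max_deg truncation cap, degrees.
#' @param family `"truncated-gamma"` (default) or `"wrapped-normal"`.
#' @return A `bending_distribution` list.
#' @export
bending_distribution <- function(mode_deg = 30, spread_deg = 15, max_deg = 60,
                                 family = c("truncated-gamma", "wrapped-normal")) {
  family <- match.arg(family)
  if (!(mode_deg >= 0 && mode_deg <= max_deg && max_deg <= 180)) {
    abort("need 0 <= mode_deg <= max_deg <= 180")
  }
  if (spread_deg <= 0) abort("spread_deg must be > 0")
  structure(list(mode_deg = mode_deg, spread_deg = spread_deg,
                 max_deg = max_deg, family = family),
            class = "bending_distribution")
}

#' Draw bending angles from a bending distribution
#'
#' @param dist a [bending_distribution()].
#' @param n number of draws.
#' @return Numeric vector of angles in `[0, max_deg]` degrees.
#' @export
draw_bending_angles <- function(dist, n) {
  stopifnot(inherits(dist, "bending_distribution"), n >= 0)
  if (dist$max_deg <= 0) abort("distribution support is empty")
  if (dist$spread_deg < 1e-8) return(rep(dist$mode_deg, n))
  if (dist$family == "truncated-gamma") {
    # scale s from mode m and sd sigma: sd^2 = m*s + s^2
    m <- dist$mode_deg; sig <- dist$spread_deg
    s <- (-m + sqrt(m^2 + 4 * sig^2)) / 2
    k <- m / s + 1
    hi <- stats::pgamma(dist$max_deg, shape = k, scale = s)
    if (hi <= 0) abort("distribution support is empty after truncation")
    u <- runif(n, 0, hi)
    stats::qgamma(u, shape = k, scale = s)
  } else {
    out <- numeric(0)
    while (length(out) < n) {
      x <- rnorm(n, dist$mode_deg, dist$spread_deg)
      x <- abs(((x + 180) %% 360) - 180)  # wrap, fold to [0, 180]
      out <- c(out, x[x <= dist$max_deg])
    }
    out[seq_len(n)]
  }
}

#' Generate a bending ensemble with known ground truth
#'
#' Draws `n_frames` bending angles from `dist`, bends a noise-free straight
#' rod at the spec hinge about a fresh random perpendicular axis per frame,
#' and adds per-frame isotropic Gaussian noise of sd `spec$noise_sd`. The
#' ground-truth angles (and axes) are returned in the `truth` element so
#' recovery by the analysis pipeline can be tested.
#'
#' @param spec a [rod_spec()]; `spec$noise_sd` is the per-frame noise.
#' @param dist a [bending_distribution()].
#' @param n_frames number of frames (>= 1).
#' @param seed RNG seed for angles, axes and noise.
#' @return An `ensemble` with an extra `truth` tibble
#'   (frame, angle, axis columns).
#' @export
sample_bending_ensemble <- function(spec, dist = bending_distribution(),
                                    n_frames, seed = 1L) {
  stopifnot(inherits(spec, "rod_spec"), n_frames >= 1)
  set.seed(seed)
  base_spec <- spec
  base_spec$noise_sd <- 0
  base <- build_rod(base_spec)
  angles <- draw_bending_angles(dist, n_frames)
  basis <- perpendicular_basis(c(0, 0, 1))
  np <- nrow(base)
  coords <- vector("list", n_frames)
  axes <- matrix(NA_real_, n_frames, 3)
  for (i in seq_len(n_frames)) {
    phi <- runif(1, 0, 2 * pi)
    ax <- basis[, 1] * cos(phi) + basis[, 2] * sin(phi)
    axes[i, ] <- ax
    bent <- bend_at_hinge(base, spec$hinge_residue, angles[i], axis = ax)
    m <- model_coords(bent)
    if (spec$noise_sd > 0) {
      m <- m + matrix(rnorm(np * 3, 0, spec$noise_sd), np, 3)
    }
    coords[[i]] <- m
  }
  ens <- new_ensemble(base[, c("chain", "resid", "domain")], coords,
                      times = seq_len(n_frames) - 1)
  ens$truth <- tibble::tibble(frame = seq_len(n_frames), angle = angles,
                              axis_x = axes[, 1], axis_y = axes[, 2],
                              axis_z = axes[, 3])
  ens$hinge <- spec$hinge_residue
  ens
}
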