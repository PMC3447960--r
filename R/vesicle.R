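#' Specification of a two-leaflet mixed-lipid vesicle
#'
#' Defaults reproduce the reference construction: 35,000 lipids at a
#' 70/20/10 DPPE/DPPG/CL composition by count, a 4 nm bilayer, and an
#' area per lipid of 0.78 nm^2 at the headgroup spheres — the one free
#' parameter, calibrated once so that the default lipid count closes to an
#' outer diameter of ~70 nm.
#'
#' @param n_lipids_total total lipid count over both leaflets.
#' @param composition named fractions per species summing to 1.
#' @param area_per_lipid headgroup area per lipid, nm^2.
#' @param bilayer_thickness distance between the leaflet spheres, nm.
#' @param min_separation minimum same-leaflet headgroup distance, nm.
#' @param jitter_sd tangent-plane jitter applied to lattice positions, nm.
#' @param seed RNG seed for placement.
#' @return A `vesicle_spec` list.
#' @export
vesicle_spec <- function(n_lipids_total = 35000,
                         composition = c(DPPE = 0.70, DPPG = 0.20, CL = 0.10),
                         area_per_lipid = 0.78,
                         bilayer_thickness = 4.0,
                         min_separation = 0.45,
                         jitter_sd = 0.05,
                         seed = 1L) {
  if (n_lipids_total <= 0) abort("n_lipids_total must be positive")
  if (is.null(names(composition)) || any(!nzchar(names(composition)))) {
    abort("composition must be a named vector of species fractions")
  }
  if (abs(sum(composition) - 1) > 1e-9) abort("composition must sum to 1")
  if (any(composition < 0)) abort("composition fractions must be >= 0")
  if (area_per_lipid <= 0) abort("area_per_lipid must be positive")
  structure(
    list(n_lipids_total = as.integer(n_lipids_total),
         composition = composition, area_per_lipid = area_per_lipid,
         bilayer_thickness = bilayer_thickness,
         min_separation = min_separation, jitter_sd = jitter_sd,
         seed = as.integer(seed)),
    class = "vesicle_spec"
  )
}

#' Leaflet radii of the vesicle
#'
#' Solves `4 * pi * (R^2 + (R - t)^2) = n * APL` for the unique positive
#' outer radius R (closed-form quadratic); the inner radius is `R - t`.
#'
#' @param spec a [vesicle_spec()].
#' @return list with `outer_radius` and `inner_radius` in nm.
#' @export
solve_radius <- function(spec) {
  stopifnot(inherits(spec, "vesicle_spec"))
  n <- spec$n_lipids_total
  t <- spec$bilayer_thickness
  apl <- spec$area_per_lipid
  if (n <= 0) abort("need a positive lipid count")
  a <- 8 * pi
  b <- -8 * pi * t
  cc <- 4 * pi * t^2 - n * apl
  disc <- b^2 - 4 * a * cc
  if (disc <= 0) abort("no real radius for these parameters")
  R <- (-b + sqrt(disc)) / (2 * a)
  if (R - t <= 0) abort("parameters give a non-positive inner radius")
  list(outer_radius = R, inner_radius = R - t)
}

#' Per-species, per-leaflet lipid counts
#'
#' Species counts are `round(fraction * total)` with largest-remainder
#' correction so the total is exact; each species is then split between the
#' leaflets proportionally to the leaflet sphere areas (again with
#' largest-remainder rounding), so both leaflets carry the same species
#' fractions.
#'
#' @param spec a [vesicle_spec()].
#' @return Tibble (species, outer, inner, total).
#' @export
allocate_counts <- function(spec) {
  stopifnot(inherits(spec, "vesicle_spec"))
  totals <- largest_remainder(spec$n_lipids_total, spec$composition)
  radii <- solve_radius(spec)
  a_out <- radii$outer_radius^2
  a_in <- radii$inner_radius^2
  f_out <- a_out / (a_out + a_in)
  outer <- vapply(totals, function(ct) {
    largest_remainder(ct, c(f_out, 1 - f_out))[1]
  }, integer(1))
  tibble::tibble(species = names(spec$composition),
                 outer = outer, inner = totals - outer, total = totals)
}

#' Build the vesicle: place lipid headgroups on both leaflet spheres
#'
#' Headgroup positions come from a spherical Fibonacci lattice per leaflet
#' (randomly rotated under the spec seed) with small tangent-plane jitter;
#' species labels are assigned by random permutation. Placements violating
#' the minimum same-leaflet separation are re-jittered; configurations whose
#' density cannot satisfy the separation constraint error out. When protein
#' `sites` are given, lipids inside any footprint are re-placed elsewhere
#' (species counts preserved).
#'
#' @param spec a [vesicle_spec()].
#' @param sites optional protein site tibble from an existing vesicle
#'   (columns x, y, z, footprint_radius).
#' @return A `vesicle` object: `lipids` tibble (species, leaflet, x, y, z),
#'   `outer_radius`, `inner_radius`, `protein_sites`, `spec`.
#' @export
place_lipids <- function(spec, sites = NULL) {
  stopifnot(inherits(spec, "vesicle_spec"))
  set.seed(spec$seed)
  counts <- allocate_counts(spec)
  radii <- solve_radius(spec)
  leaf <- list(outer = radii$outer_radius, inner = radii$inner_radius)
  lipids <- purrr::map_dfr(c("outer", "inner"), function(lf) {
    n <- sum(counts[[lf]])
    R <- leaf[[lf]]
    hex_area <- sqrt(3) / 2 * spec$min_separation^2
    if (n * hex_area > 4 * pi * R^2) {
      abort(sprintf("%s leaflet cannot hold %d lipids at min_separation %g nm",
                    lf, n, spec$min_separation))
    }
    pts <- fibonacci_sphere(n) %*% t(random_rotation())
    pts <- jitter_on_sphere(pts, spec$jitter_sd, R, spec$min_separation, sites)
    species <- sample(rep(counts$species, counts[[lf]]))
    tibble::tibble(species = species, leaflet = lf,
                   x = pts[, 1], y = pts[, 2], z = pts[, 3])
  })
  structure(
    list(lipids = lipids, outer_radius = radii$outer_radius,
         inner_radius = radii$inner_radius,
         protein_sites = sites %||%
           tibble::tibble(x = numeric(), y = numeric(), z = numeric(),
                          footprint_radius = numeric()),
         spec = spec),
    class = "vesicle"
  )
}

# scale unit points to radius R, jitter tangentially, re-project, and
# resolve min-separation / footprint violations by re-drawing
jitter_on_sphere <- function(pts, jitter_sd, R, min_sep, sites,
                             max_iter = 60) {
  n <- nrow(pts)
  cur <- pts * R
  if (jitter_sd > 0) {
    cur <- reproject(cur + matrix(rnorm(3 * n, 0, jitter_sd), n, 3), R)
  }
  for (it in seq_len(max_iter)) {
    bad <- placement_violations(cur, min_sep, sites)
    if (length(bad) == 0) return(cur)
    # re-draw offenders: jitter them from their lattice position again,
    # with shrinking amplitude, or (late iterations) anywhere on the sphere
    amp <- jitter_sd * 0.8^it
    if (it <= max_iter / 2) {
      cur[bad, ] <- reproject(
        pts[bad, , drop = FALSE] * R +
          matrix(rnorm(3 * length(bad), 0, amp), length(bad), 3), R)
    } else {
      cur[bad, ] <- random_sphere_points(length(bad)) * R
    }
  }
  abort("could not satisfy min_separation/footprint constraints while placing lipids")
}

reproject <- function(m, R) m * (R / sqrt(rowSums(m^2)))

random_sphere_points <- function(n) {
  m <- matrix(rnorm(3 * n), n, 3)
  m / sqrt(rowSums(m^2))
}

# indices of points violating min separation (pairwise) or protein footprints
placement_violations <- function(cur, min_sep, sites) {
  bad <- close_pair_indices(cur, min_sep)
  if (!is.null(sites) && nrow(sites) > 0) {
    sm <- as.matrix(sites[, c("x", "y", "z")])
    for (s in seq_len(nrow(sm))) {
      d2 <- (cur[, 1] - sm[s, 1])^2 + (cur[, 2] - sm[s, 2])^2 +
        (cur[, 3] - sm[s, 3])^2
      bad <- union(bad, which(d2 < sites$footprint_radius[s]^2))
    }
  }
  bad
}

# of each violating pair keep the first, flag the second for re-draw
close_pair_indices <- function(cur, min_sep) {
  pr <- close_pairs(cur, min_sep)   # Rcpp cell list, two-column matrix
  if (nrow(pr) == 0) return(integer())
  unique(pmax(pr[, 1], pr[, 2]))
}

#' Distribute protein anchor sites evenly on the outer sphere
#'
#' Anchor sites are placed at a spherical Fibonacci lattice on the outer
#' leaflet sphere (antipodal for two sites); lipids within any footprint
#' are removed and re-placed elsewhere on their leaflet, preserving species
#' counts exactly.
#'
#' @param config a `vesicle` from [place_lipids()].
#' @param n_sites number of protein anchors (>= 1).
#' @param footprint_radius protein footprint radius in nm; lipids closer
#'   than this (3-D distance) to an anchor are displaced.
#' @return The updated `vesicle` with `protein_sites` filled in.
#' @export
place_proteins_evenly <- function(config, n_sites, footprint_radius = 0.5) {
  stopifnot(inherits(config, "vesicle"), n_sites >= 1)
  R <- config$outer_radius
  cap_area <- pi * footprint_radius^2
  if (n_sites * cap_area > 0.5 * 4 * pi * R^2) {
    abort("protein footprints would cover more than half the sphere")
  }
  pts <- fibonacci_sphere(n_sites) * R
  sites <- tibble::tibble(x = pts[, 1], y = pts[, 2], z = pts[, 3],
                          footprint_radius = footprint_radius)
  config$protein_sites <- sites
  set.seed(config$spec$seed + 1L)
  for (lf in c("outer", "inner")) {
    in_leaf <- which(config$lipids$leaflet == lf)
    if (length(in_leaf) == 0) next
    m <- as.matrix(config$lipids[in_leaf, c("x", "y", "z")])
    Rl <- if (lf == "outer") config$outer_radius else config$inner_radius
    m <- relocate_footprint_lipids(m, sites, Rl, config$spec$min_separation)
    config$lipids[in_leaf, c("x", "y", "z")] <- as.data.frame(m)
  }
  config
}

relocate_footprint_lipids <- function(m, sites, R, min_sep, max_tries = 500) {
  sm <- as.matrix(sites[, c("x", "y", "z")])
  in_fp <- function(pts) {
    bad <- rep(FALSE, nrow(pts))
    for (s in seq_len(nrow(sm))) {
      d2 <- (pts[, 1] - sm[s, 1])^2 + (pts[, 2] - sm[s, 2])^2 +
        (pts[, 3] - sm[s, 3])^2
      bad <- bad | d2 < sites$footprint_radius[s]^2
    }
    bad
  }
  moved <- which(in_fp(m))
  for (i in moved) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      cand <- as.numeric(random_sphere_points(1)) * R
      if (any(in_fp(matrix(cand, 1, 3)))) next
      d2 <- (m[, 1] - cand[1])^2 + (m[, 2] - cand[2])^2 + (m[, 3] - cand[3])^2
      d2[i] <- Inf
      if (min(d2) >= min_sep^2) {
        m[i, ] <- cand
        placed <- TRUE
        break
      }
    }
    if (!placed) abort("could not relocate a lipid outside the protein footprints")
  }
  m
}

#' @export
print.vesicle <- function(x, ...) {
  comp <- dplyr::count(x$lipids, .data$species)
  cat(sprintf("<vesicle> %d lipids (%s), outer R %.2f nm, inner R %.2f nm, %d protein sites\n",
              nrow(x$lipids),
              paste(sprintf("%s %d", comp$species, comp$n), collapse = ", "),
              x$outer_radius, x$inner_radius, nrow(x$protein_sites)))
  invisible(x)
}
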