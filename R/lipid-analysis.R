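#' Shell enrichment of lipid species around protein sites
#'
#' A lipid is in-shell at a frame when its headgroup lies within `shell`
#' of any protein anchor. Distances are 3-D Euclidean to the anchor points
#' by default (the shell is defined relative to the protein, not along the
#' membrane); `metric = "geodesic"` instead combines the arc length on the
#' lipid's own leaflet sphere with the radial gap to the site in
#' quadrature. Two normalisations are reported per species s:
#'
#' * `enrich_bulk`  = (shell fraction of s) / (global fraction of s)
#' * `enrich_dppe`  = `[n_s / n_ref]_shell / [n_s / n_ref]_global`
#'   with reference species `ref` (DPPE), so `enrich_dppe` is identically 1
#'   for the reference itself.
#'
#' Frames with an empty shell are flagged (`undefined`) and get `NA`
#' enrichments.
#'
#' @param traj a `lipid_trajectory` (or a `vesicle` for a single frame).
#' @param shell shell distance in nm.
#' @param reference_species reference species for the relative convention.
#' @param metric `"euclidean"` or `"geodesic"`.
#' @return An `enrichment_series` tibble (frame, sweep, species, n_shell,
#'   enrich_bulk, enrich_dppe, undefined).
#' @export
shell_enrichment <- function(traj, shell = 1.0, reference_species = "DPPE",
                             metric = c("euclidean", "geodesic")) {
  metric <- match.arg(metric)
  if (shell <= 0) abort("shell must be > 0")
  if (inherits(traj, "vesicle")) {
    traj <- list(frames = list(as.matrix(traj$lipids[, c("x", "y", "z")])),
                 sweeps = 0L, lipids = traj$lipids,
                 protein_sites = traj$protein_sites,
                 outer_radius = traj$outer_radius)
  }
  sites <- as.matrix(traj$protein_sites[, c("x", "y", "z")])
  if (nrow(sites) == 0) abort("no protein sites: shell is undefined")
  species <- sort(unique(traj$lipids$species))
  totals <- table(factor(traj$lipids$species, levels = species))
  out <- purrr::map_dfr(seq_along(traj$frames), function(f) {
    m <- traj$frames[[f]]
    in_shell <- shell_membership(m, sites, shell, metric, traj$outer_radius)
    counts <- table(factor(traj$lipids$species[in_shell], levels = species))
    tibble::tibble(frame = f, sweep = traj$sweeps[f], species = species,
                   n_shell = as.integer(counts))
  })
  n_tot <- sum(totals)
  glob_frac <- as.numeric(totals) / n_tot
  names(glob_frac) <- species
  if (!reference_species %in% species) {
    abort(sprintf("reference species '%s' not present", reference_species))
  }
  out <- out |>
    dplyr::group_by(.data$frame) |>
    dplyr::mutate(shell_total = sum(.data$n_shell),
                  ref_shell = .data$n_shell[.data$species == reference_species]) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      undefined = .data$shell_total == 0,
      enrich_bulk = ifelse(.data$undefined, NA_real_,
                           (.data$n_shell / .data$shell_total) /
                             glob_frac[.data$species]),
      enrich_dppe = ifelse(.data$undefined | .data$ref_shell == 0, NA_real_,
                           (.data$n_shell / .data$ref_shell) /
                             (glob_frac[.data$species] /
                                glob_frac[reference_species]))
    ) |>
    dplyr::select(-"shell_total", -"ref_shell")
  attr(out, "shell") <- shell
  attr(out, "reference_species") <- reference_species
  attr(out, "species_totals") <- as.integer(totals)
  class(out) <- c("enrichment_series", class(tibble::tibble()))
  out
}

shell_membership <- function(m, sites, shell, metric, outer_radius) {
  hit <- rep(FALSE, nrow(m))
  if (metric == "euclidean") {
    for (s in seq_len(nrow(sites))) {
      d2 <- (m[, 1] - sites[s, 1])^2 + (m[, 2] - sites[s, 2])^2 +
        (m[, 3] - sites[s, 3])^2
      hit <- hit | d2 <= shell^2
    }
  } else {
    # arc length on the lipid's own leaflet sphere to the site's radial
    # projection, combined in quadrature with the leaflet-to-site radial
    # gap (so inner-leaflet lipids are not counted through the bilayer)
    rl <- sqrt(rowSums(m^2))
    mu <- m / rl
    rs <- sqrt(rowSums(sites^2))
    su <- sites / rs
    for (s in seq_len(nrow(su))) {
      ang <- acos(pmin(1, pmax(-1, mu %*% su[s, ])))
      d <- sqrt((rl * ang)^2 + (rs[s] - rl)^2)
      hit <- hit | d <= shell
    }
  }
  hit
}

#' Steady-state enrichment summary
#'
#' Pools the shell counts over the steady-state window (the last
#' `window` fraction of frames) and recomputes both enrichment conventions
#' from the pooled counts, which is more stable than averaging noisy
#' per-frame ratios.
#'
#' @param es an [shell_enrichment()] series.
#' @param window fraction of trailing frames to pool (default last half).
#' @return Tibble (species, n_shell, enrich_bulk, enrich_dppe).
#' @export
enrichment_summary <- function(es, window = 0.5) {
  stopifnot(inherits(es, "enrichment_series"))
  frames <- sort(unique(es$frame))
  keep <- frames[frames > max(frames) - window * length(frames)]
  ref <- attr(es, "reference_species")
  totals <- attr(es, "species_totals")
  pooled <- es |>
    dplyr::filter(.data$frame %in% keep) |>
    dplyr::group_by(.data$species) |>
    dplyr::summarise(n_shell = sum(.data$n_shell), .groups = "drop")
  glob <- totals / sum(totals)
  shell_tot <- sum(pooled$n_shell)
  ref_shell <- pooled$n_shell[pooled$species == ref]
  ref_glob <- glob[pooled$species == ref]
  pooled |>
    dplyr::mutate(
      enrich_bulk = (.data$n_shell / shell_tot) / glob,
      enrich_dppe = (.data$n_shell / ref_shell) / (glob / ref_glob)
    )
}

#' Lateral mixing statistic (phase-separation detector)
#'
#' For every lipid, the fraction of its k nearest same-leaflet neighbours
#' (surface distances; chord and geodesic orderings coincide on a sphere)
#' that share its species. Per species the observed mean fraction is
#' compared with the well-mixed expectation — the fraction of that species
#' among the *other* lipids of the same leaflet — giving a demixing index
#' `observed - expected` that is ~0 for a well-mixed vesicle and grows
#' towards `1 - expected` under full phase separation.
#'
#' @param config a `vesicle`, `lipid_trajectory` frame
#'   ([trajectory_frame()]), or tibble with species/leaflet/x/y/z.
#' @param k number of nearest neighbours.
#' @return A `mixing_statistic` tibble (species, n, observed, expected,
#'   demixing_index).
#' @export
mixing_statistic <- function(config, k = 6) {
  lipids <- if (inherits(config, "vesicle")) config$lipids else config
  n <- nrow(lipids)
  if (k >= n) abort("k must be smaller than the number of lipids")
  m <- as.matrix(lipids[, c("x", "y", "z")])
  leaflet <- as.integer(factor(lipids$leaflet))
  # cell size ~ twice the typical spacing keeps ring searches short
  area <- sum(vapply(split(seq_len(n), leaflet), function(i) {
    r <- sqrt(max(rowSums(m[i, , drop = FALSE]^2)))
    4 * pi * r^2
  }, numeric(1)))
  cell <- 2 * sqrt(area / n)
  nn <- knn_same_group_cpp(m, leaflet, as.integer(k), cell)
  same <- matrix(lipids$species[nn], nrow = n) == lipids$species
  frac <- rowMeans(same)
  # well-mixed expectation per (species, leaflet): (N_sl - 1) / (N_l - 1)
  leaf_tot <- table(leaflet)
  out <- purrr::map_dfr(split(seq_len(n), lipids$species), function(idx) {
    sp <- lipids$species[idx[1]]
    sl <- table(factor(leaflet[idx], levels = names(leaf_tot)))
    expected <- sum(as.numeric(sl) / length(idx) *
                      (as.numeric(sl) - 1) / (as.numeric(leaf_tot) - 1))
    tibble::tibble(species = sp, n = length(idx),
                   observed = mean(frac[idx]), expected = expected,
                   demixing_index = mean(frac[idx]) - expected)
  })
  class(out) <- c("mixing_statistic", class(tibble::tibble()))
  out
}
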