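#' Total-least-squares line fit through a point cloud
#'
#' Fits the principal axis of the centred points: the line through the
#' centroid along the largest-eigenvalue direction of the scatter matrix.
#' The residual MSD is the mean squared perpendicular distance to that
#' line (the sum of the two smaller covariance eigenvalues). The direction
#' sign is fixed to point from the first half of the point list to the
#' second, i.e. from low to high residue index when points are given in
#' residue order.
#'
#' @param points n x 3 matrix (or data frame with x/y/z), n >= 2, in nm.
#' @return list with `centroid` (nm), `direction` (unit vector) and
#'   `msd` (nm^2).
#' @export
fit_axis <- function(points) {
  m <- coords_matrix(points)
  n <- nrow(m)
  if (n < 2) abort("need at least 2 points to fit an axis")
  centroid <- colMeans(m)
  mc <- sweep(m, 2, centroid)
  C <- crossprod(mc) / n
  if (sum(diag(C)) < 1e-24) abort("all points coincident: no axis defined")
  e <- eigen(C, symmetric = TRUE)
  dir <- e$vectors[, 1]
  # orient low -> high index
  half <- colMeans(m[seq(ceiling(n / 2) + 1, n), , drop = FALSE]) -
    colMeans(m[seq_len(floor(n / 2)), , drop = FALSE])
  if (sum(dir * half) < 0) dir <- -dir
  list(centroid = centroid,
       direction = dir,
       msd = max(0, sum(e$values[2:3])))
}

# per-residue aggregated moments (pooled across chains), in residue order:
# counts, coordinate sums and upper-triangle second moments
residue_moments <- function(resid, m) {
  o <- order(resid)
  resid <- resid[o]; m <- m[o, , drop = FALSE]
  f <- factor(resid, levels = sort(unique(resid)))
  agg <- function(v) as.numeric(rowsum(v, f))
  list(
    resid = sort(unique(resid)),
    n = as.numeric(table(f)),
    sx = agg(m[, 1]), sy = agg(m[, 2]), sz = agg(m[, 3]),
    sxx = agg(m[, 1]^2), syy = agg(m[, 2]^2), szz = agg(m[, 3]^2),
    sxy = agg(m[, 1] * m[, 2]), sxz = agg(m[, 1] * m[, 3]),
    syz = agg(m[, 2] * m[, 3])
  )
}

# residual MSD of a TLS line fit from aggregate moments
msd_from_moments <- function(n, s1, s2) {
  mu <- s1 / n
  C <- s2 / n - tcrossprod(mu)
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  max(0, sum(ev[2:3]))
}

#' Bisection mean-square-deviation profile for hinge location
#'
#' For every candidate split residue i (at least `min_segment` residues
#' from each end), fits one total-least-squares line to the residues with
#' index <= i and one to those with index >= i (the split residue is the
#' joint and belongs to both arms), and records the count-weighted mean of
#' the two residual MSDs. The profile minimum locates the bending hinge.
#'
#' Multi-chain models are reduced to their per-residue chain-centroid trace
#' before fitting (`pool = "centroid"`, the default): the dimer bends as
#' one body and its axis is the centroid trace. Fitting the raw pooled
#' particles instead (`pool = "particles"`) adds a constant lateral-offset
#' baseline to every split MSD whose interaction with the fit direction
#' biases the argmin by a few residues on idealised parallel-chain rods, so
#' it is kept only as an option (for single chains the two are identical).
#'
#' A flat profile (max - min < 1e-6 nm^2, e.g. a perfectly straight rod) is
#' reported via the `flat` attribute instead of a spurious argmin.
#'
#' @param model a `particle_model`, or one frame of an ensemble.
#' @param selection optional selection (see [select_particles()]).
#' @param min_segment minimum residues on each side of a split.
#' @param pool `"centroid"` (fit chain-centroid trace) or `"particles"`
#'   (fit all particles pooled).
#' @return A `hinge_profile` tibble (resid, msd, nm^2) with attributes
#'   `hinge` (argmin residue, `NA` when flat) and `flat`.
#' @export
bisection_msd_profile <- function(model, selection = NULL, min_segment = 10,
                                  pool = c("centroid", "particles")) {
  pool <- match.arg(pool)
  df <- select_particles(model, selection)
  prof <- msd_profile_impl(df$resid, coords_matrix(df), min_segment, pool)
  new_hinge_profile(prof)
}

new_hinge_profile <- function(prof) {
  out <- tibble::tibble(resid = prof$resid, msd = prof$msd)
  flat <- (max(prof$msd) - min(prof$msd)) < 1e-6
  attr(out, "hinge") <- if (flat) NA_integer_ else prof$resid[which.min(prof$msd)]
  attr(out, "flat") <- flat
  class(out) <- c("hinge_profile", class(tibble::tibble()))
  out
}

msd_profile_impl <- function(resid, m, min_segment, pool = "centroid") {
  if (pool == "centroid") {
    cm <- residue_centroids(resid, m)
    resid <- cm$resid
    m <- cm$coords
  }
  mom <- residue_moments(resid, m)
  r <- mom$resid
  nr <- length(r)
  if (min_segment < 2) abort("min_segment must be at least 2")
  if (nr < 2 * min_segment) abort("selection too short for the requested min_segment")
  cum <- lapply(mom[c("n", "sx", "sy", "sz", "sxx", "syy", "szz",
                      "sxy", "sxz", "syz")], cumsum)
  tot <- lapply(cum, function(v) v[nr])
  # split residue k belongs to both arms (it is the joint)
  cand <- seq(min_segment, nr - min_segment + 1)
  msd <- vapply(cand, function(k) {
    n1 <- cum$n[k]
    s1 <- c(cum$sx[k], cum$sy[k], cum$sz[k])
    S1 <- matrix(c(cum$sxx[k], cum$sxy[k], cum$sxz[k],
                   cum$sxy[k], cum$syy[k], cum$syz[k],
                   cum$sxz[k], cum$syz[k], cum$szz[k]), 3, 3)
    # upper arm: residues k..nr (inclusive of the joint)
    p <- k - 1
    n2 <- tot$n - cum$n[p]
    s2 <- c(tot$sx - cum$sx[p], tot$sy - cum$sy[p], tot$sz - cum$sz[p])
    S2 <- matrix(c(tot$sxx - cum$sxx[p], tot$sxy - cum$sxy[p], tot$sxz - cum$sxz[p],
                   tot$sxy - cum$sxy[p], tot$syy - cum$syy[p], tot$syz - cum$syz[p],
                   tot$sxz - cum$sxz[p], tot$syz - cum$syz[p], tot$szz - cum$szz[p]),
                 3, 3)
    (n1 * msd_from_moments(n1, s1, S1) + n2 * msd_from_moments(n2, s2, S2)) /
      (n1 + n2)
  }, numeric(1))
  list(resid = r[cand], msd = msd)
}

# mean particle position per residue across chains, in residue order
residue_centroids <- function(resid, m) {
  f <- factor(resid, levels = sort(unique(resid)))
  cnt <- as.numeric(table(f))
  list(resid = sort(unique(resid)),
       coords = rowsum(m, f) / cnt)
}

#' Bending angle of a rod about a hinge
#'
#' The unsigned angle (degrees, in `[0, 180]`) between the two
#' total-least-squares axes fitted to the particles below/at and above the
#' hinge residue, pooled across chains; 0 means straight.
#'
#' @param model a `particle_model`.
#' @param hinge 1-based hinge residue, with at least `min_segment` residues
#'   on each side.
#' @param min_segment minimum residues per segment.
#' @param selection optional selection.
#' @return Angle in degrees.
#' @export
bending_angle <- function(model, hinge, min_segment = 10, selection = NULL) {
  df <- select_particles(model, selection)
  segment_angle(df$resid, coords_matrix(df), hinge, min_segment)
}

segment_angle <- function(resid, m, hinge, min_segment) {
  low <- resid <= hinge
  r <- sort(unique(resid))
  if (sum(r <= hinge) < min_segment || sum(r > hinge) < min_segment) {
    abort("hinge too close to a terminus for the requested min_segment")
  }
  d1 <- fit_axis_ordered(resid[low], m[low, , drop = FALSE])
  d2 <- fit_axis_ordered(resid[!low], m[!low, , drop = FALSE])
  rad2deg(acos(pmin(1, pmax(-1, sum(d1 * d2)))))
}

# TLS direction with sign fixed along increasing residue index
fit_axis_ordered <- function(resid, m) {
  o <- order(resid)
  fit_axis(m[o, , drop = FALSE])$direction
}

#' Per-frame bending angles and histogram statistics for an ensemble
#'
#' Computes the bending angle of every frame about `hinge`, plus a
#' fixed-origin histogram (bins `[0, bin_width)`, ...), the modal angle
#' (midpoint of the highest-count bin; ties resolved to the lower bin and
#' flagged) and the maximum angle.
#'
#' @param ensemble an `ensemble`.
#' @param hinge hinge residue; defaults to the ensemble's generator hinge
#'   when present.
#' @param bin_width histogram bin width in degrees.
#' @param min_segment minimum residues per fitted segment.
#' @param selection optional selection applied to the topology.
#' @return A `bending_series` tibble (frame, time, angle) with attributes
#'   `hinge`, `histogram` (tibble: bin_lo, bin_hi, mid, count), `modal`,
#'   `max` and `modal_tie`.
#' @export
bending_series <- function(ensemble, hinge = NULL, bin_width = 5,
                           min_segment = 10, selection = NULL) {
  stopifnot(inherits(ensemble, "ensemble"))
  if (length(ensemble$coords) == 0) abort("empty ensemble")
  if (is.null(hinge)) hinge <- ensemble$hinge
  if (is.null(hinge)) abort("no hinge given and none stored in the ensemble")
  keep <- selection_index(ensemble$topology, selection)
  resid <- ensemble$topology$resid[keep]
  angles <- vapply(ensemble$coords, function(m) {
    segment_angle(resid, m[keep, , drop = FALSE], hinge, min_segment)
  }, numeric(1))
  out <- tibble::tibble(frame = seq_along(angles), time = ensemble$times,
                        angle = angles)
  n_bins <- max(1, ceiling(max(angles) / bin_width + 1e-12))
  lo <- (seq_len(n_bins) - 1) * bin_width
  counts <- vapply(seq_len(n_bins), function(b) {
    sum(angles >= lo[b] & angles < lo[b] + bin_width)
  }, integer(1))
  # right-closed top edge so the maximum lands in the last bin
  counts[n_bins] <- counts[n_bins] + sum(angles == lo[n_bins] + bin_width)
  hist <- tibble::tibble(bin_lo = lo, bin_hi = lo + bin_width,
                         mid = lo + bin_width / 2, count = counts)
  top <- which(counts == max(counts))
  attr(out, "hinge") <- hinge
  attr(out, "histogram") <- hist
  attr(out, "modal") <- hist$mid[top[1]]
  attr(out, "modal_tie") <- length(top) > 1
  attr(out, "max") <- max(angles)
  class(out) <- c("bending_series", class(tibble::tibble()))
  out
}
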