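#' Least-squares rigid superposition (Kabsch)
#'
#' Optimal rotation via the SVD of the cross-covariance with reflection
#' correction, after centring both point sets. Returns the rotation R and
#' translation t such that `mobile %*% R + t` best matches `reference` in
#' the least-squares sense, plus the post-fit RMSD.
#'
#' @param mobile n x 3 matrix (nm).
#' @param reference n x 3 matrix (nm), same n >= 3.
#' @return list with `rotation` (3 x 3), `translation` (length 3),
#'   `rmsd` (nm).
#' @export
superpose <- function(mobile, reference) {
  P <- coords_matrix(mobile); Q <- coords_matrix(reference)
  if (nrow(P) != nrow(Q)) abort("point sets must have equal size")
  if (nrow(P) < 3) abort("need at least 3 points to superpose")
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  if (sum(Pc^2) < 1e-24 || sum(Qc^2) < 1e-24) {
    abort("degenerate point set: all points coincident")
  }
  C <- crossprod(Pc, Qc)
  s <- svd(C)
  if (s$d[2] < 1e-12 * max(s$d[1], 1e-300)) {
    abort("rank-deficient scatter: superposition rotation is not unique")
  }
  d <- sign(det(s$u) * det(s$v))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  rmsd <- sqrt(mean(rowSums((Pc %*% R - Qc)^2)))
  list(rotation = R, translation = cq - as.numeric(cp %*% R), rmsd = rmsd)
}

pairwise_rmsd_matrix <- function(coord_list) {
  nf <- length(coord_list)
  D <- matrix(0, nf, nf)
  if (nf < 2) return(D)
  for (i in seq_len(nf - 1)) {
    for (j in (i + 1):nf) {
      r <- superpose(coord_list[[j]], coord_list[[i]])$rmsd
      D[i, j] <- r; D[j, i] <- r
    }
  }
  D
}

#' Per-frame RMSD series after selection-local superposition
#'
#' Each frame's selected particles are superposed onto the reference
#' frame's before the RMSD is taken, so the series reports internal
#' deformation of the selection only (a rigidly bent domain superposed on
#' itself shows no extra RMSD). The modal RMSD is the midpoint of the
#' highest-count fixed-origin histogram bin.
#'
#' @param ensemble an `ensemble`.
#' @param selection selection over the topology (see [select_particles()]).
#' @param reference 1-based reference frame id.
#' @param bin_width histogram bin width in nm.
#' @return An `rmsd_series` tibble (frame, time, rmsd) with attributes
#'   `modal`, `histogram`, `reference`, `selection`.
#' @export
rmsd_series <- function(ensemble, selection = NULL, reference = 1,
                        bin_width = 0.02) {
  stopifnot(inherits(ensemble, "ensemble"))
  if (reference < 1 || reference > length(ensemble$coords)) {
    abort(sprintf("reference frame %s not in the ensemble", reference))
  }
  keep <- selection_index(ensemble$topology, selection)
  ref <- ensemble$coords[[reference]][keep, , drop = FALSE]
  vals <- vapply(ensemble$coords, function(m) {
    superpose(m[keep, , drop = FALSE], ref)$rmsd
  }, numeric(1))
  out <- tibble::tibble(frame = seq_along(vals), time = ensemble$times,
                        rmsd = vals)
  n_bins <- max(1, ceiling(max(vals) / bin_width + 1e-12))
  lo <- (seq_len(n_bins) - 1) * bin_width
  counts <- vapply(seq_len(n_bins), function(b) {
    sum(vals >= lo[b] & vals < lo[b] + bin_width) +
      if (b == n_bins) sum(vals == lo[b] + bin_width) else 0L
  }, numeric(1))
  hist <- tibble::tibble(bin_lo = lo, bin_hi = lo + bin_width,
                         mid = lo + bin_width / 2, count = counts)
  attr(out, "modal") <- hist$mid[which.max(counts)]
  attr(out, "histogram") <- hist
  attr(out, "reference") <- reference
  attr(out, "selection") <- selection
  class(out) <- c("rmsd_series", class(tibble::tibble()))
  out
}

#' GROMOS conformational clustering
#'
#' The g_cluster/GROMOS procedure: compute all pairwise post-superposition
#' RMSDs; repeatedly take the unassigned frame with the most unassigned
#' neighbours within `cutoff` as the next cluster centroid, assign it plus
#' its neighbours, remove them, and recount. Ties are broken towards the
#' lowest frame id. An optional time `window` restricts clustering to
#' frames with `window[1] <= time <= window[2]` (e.g. the last 100 ns of a
#' run); frame ids in the output always refer to the full ensemble.
#'
#' @param ensemble an `ensemble`.
#' @param selection optional particle selection used for the RMSDs.
#' @param cutoff RMSD neighbour cutoff in nm (> 0).
#' @param window optional numeric `c(t0, t1)` time window in ns.
#' @return A `gromos_clustering` list: `clusters` tibble (cluster,
#'   centroid, representative, size), `membership` tibble (frame, cluster),
#'   `rmsd` matrix over the clustered frames, `frames` (their ids),
#'   `cutoff`.
#' @export
gromos_cluster <- function(ensemble, selection = NULL, cutoff, window = NULL) {
  stopifnot(inherits(ensemble, "ensemble"))
  if (cutoff <= 0) abort("cutoff must be > 0")
  frames <- seq_along(ensemble$coords)
  if (!is.null(window)) {
    frames <- frames[ensemble$times >= window[1] & ensemble$times <= window[2]]
    if (length(frames) == 0) abort("time window contains no frames")
  }
  keep <- selection_index(ensemble$topology, selection)
  coord_list <- lapply(frames, function(f) {
    ensemble$coords[[f]][keep, , drop = FALSE]
  })
  D <- pairwise_rmsd_matrix(coord_list)
  nf <- length(frames)
  neigh <- D <= cutoff          # includes self
  active <- rep(TRUE, nf)
  assignment <- rep(NA_integer_, nf)
  clusters <- list()
  k <- 0
  while (any(active)) {
    counts <- colSums(neigh[active, , drop = FALSE]) * active
    centroid <- which.max(counts)          # ties -> lowest index
    members <- which(active & neigh[, centroid])
    k <- k + 1
    assignment[members] <- k
    rep_id <- cluster_medoid(D, members)
    clusters[[k]] <- tibble::tibble(
      cluster = k, centroid = frames[centroid],
      representative = frames[rep_id], size = length(members)
    )
    active[members] <- FALSE
  }
  structure(
    list(
      clusters = dplyr::bind_rows(clusters),
      membership = tibble::tibble(frame = frames, cluster = assignment),
      rmsd = D, frames = frames, cutoff = cutoff
    ),
    class = "gromos_clustering"
  )
}

# medoid: member minimising the summed RMSD to all other members
cluster_medoid <- function(D, members) {
  if (length(members) == 1) return(members)
  sums <- rowSums(D[members, members, drop = FALSE])
  members[which.min(sums)]     # ties -> lowest frame id
}

#' @export
print.gromos_clustering <- function(x, ...) {
  cat(sprintf("<gromos_clustering> %d frames -> %d clusters (cutoff %g nm)\n",
              length(x$frames), nrow(x$clusters), x$cutoff))
  print(x$clusters, n = 5)
  invisible(x)
}

#' Representative ("middle") structure of a cluster
#'
#' The member frame minimising the sum of pairwise RMSDs to all other
#' members — the RMSD medoid, which is what the GROMACS `g_cluster`
#' "middle structure" denotes. Ties go to the lowest frame id.
#'
#' @param clustering a [gromos_cluster()] result.
#' @param cluster 1-based cluster index (1 = dominant cluster).
#' @return The representative frame id.
#' @export
cluster_representative <- function(clustering, cluster = 1) {
  stopifnot(inherits(clustering, "gromos_clustering"))
  row <- clustering$clusters[clustering$clusters$cluster == cluster, ]
  if (nrow(row) == 0) abort(sprintf("no cluster %s", cluster))
  row$representative
}
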