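#' Kirchhoff (GNM connectivity) matrix
#'
#' Builds the N x N Laplacian of the elastic network in which every pair of
#' particles within `cutoff` is joined by a spring of unit strength:
#' off-diagonal entries are -1 for connected pairs, the diagonal holds the
#' particle degree, and every row sums to zero.
#'
#' @param model `particle_model` or n x 3 coordinate matrix (nm).
#' @param cutoff connection cutoff in nm (0.7 nm is the GNM default used
#'   for one-particle-per-residue receptor models).
#' @return Symmetric N x N matrix.
#' @export
build_kirchhoff <- function(model, cutoff = 0.7) {
  m <- coords_matrix(model)
  n <- nrow(m)
  if (n < 2) abort("need at least 2 particles")
  d <- as.matrix(stats::dist(m))
  if (any(d[upper.tri(d)] == 0)) {
    warn("coincident particles: zero-distance pair counted as connected")
  }
  A <- (d <= cutoff)
  diag(A) <- FALSE
  K <- -1 * A
  diag(K) <- rowSums(A)
  dimnames(K) <- NULL
  K
}

#' Anisotropic network model Hessian
#'
#' Standard ANM super-element assembly with unit spring constants: for each
#' connected pair (i, j) within `cutoff` the off-diagonal 3 x 3 block is
#' `-(r_ij r_ij^T) / |r_ij|^2` and diagonal blocks are minus the sum of the
#' off-diagonal blocks of their row.
#'
#' @param model `particle_model` or n x 3 coordinate matrix (nm).
#' @param cutoff connection cutoff in nm (1.3 nm default for ANM).
#' @return Symmetric 3N x 3N matrix.
#' @export
build_hessian <- function(model, cutoff = 1.3) {
  m <- coords_matrix(model)
  n <- nrow(m)
  if (n < 2) abort("need at least 2 particles")
  d <- as.matrix(stats::dist(m))
  pairs <- which(d <= cutoff & upper.tri(d), arr.ind = TRUE)
  if (nrow(pairs) > 0 && any(d[pairs] == 0)) {
    abort("coincident connected particles: spring direction undefined")
  }
  H <- matrix(0, 3 * n, 3 * n)
  for (p in seq_len(nrow(pairs))) {
    i <- pairs[p, 1]; j <- pairs[p, 2]
    r <- m[j, ] - m[i, ]
    blk <- -tcrossprod(r) / sum(r^2)
    ii <- (3 * i - 2):(3 * i); jj <- (3 * j - 2):(3 * j)
    H[ii, jj] <- blk
    H[jj, ii] <- blk
    H[ii, ii] <- H[ii, ii] - blk
    H[jj, jj] <- H[jj, jj] - blk
  }
  H
}

#' Eigendecomposition of an elastic-network matrix
#'
#' Full symmetric eigendecomposition with eigenvalues in ascending order.
#' Zero modes are identified by `|lambda| < 1e-8 * max(lambda)`; the
#' "dominant" mode of a network is its lowest non-zero mode. Spring
#' constants are unitless, so eigenvalues are in arbitrary units and only
#' ratios and mode shapes are meaningful.
#'
#' @param matrix symmetric matrix from [build_kirchhoff()] or
#'   [build_hessian()].
#' @param kind `"gnm"` or `"anm"`, stored as metadata.
#' @param cutoff cutoff metadata in nm.
#' @return A `network_modes` list: `values` (ascending), `vectors`
#'   (orthonormal columns), `n_zero`, `kind`, `cutoff`.
#' @export
decompose_modes <- function(matrix, kind = c("gnm", "anm"), cutoff = NA_real_) {
  kind <- match.arg(kind)
  if (max(abs(matrix - t(matrix))) > 1e-8 * max(1, max(abs(matrix)))) {
    abort("matrix must be symmetric")
  }
  e <- eigen((matrix + t(matrix)) / 2, symmetric = TRUE)
  ord <- order(e$values)
  values <- e$values[ord]
  vectors <- e$vectors[, ord, drop = FALSE]
  tol <- 1e-8 * max(abs(values))
  structure(
    list(kind = kind, cutoff = cutoff, values = values, vectors = vectors,
         n_zero = sum(abs(values) < tol), tol = tol),
    class = "network_modes"
  )
}

#' @export
print.network_modes <- function(x, ...) {
  cat(sprintf("<network_modes> %s, cutoff %g nm, %d modes, %d zero\n",
              toupper(x$kind), x$cutoff, length(x$values), x$n_zero))
  invisible(x)
}

#' Gaussian network model of a particle model
#'
#' Convenience wrapper: Kirchhoff matrix at `cutoff`, decomposed, with the
#' topology attached for residue-level mode analysis.
#'
#' @inheritParams build_kirchhoff
#' @return A `network_modes` object with `topology` attached.
#' @export
gnm <- function(model, cutoff = 0.7) {
  stopifnot(inherits(model, "particle_model"))
  K <- build_kirchhoff(model, cutoff)
  modes <- decompose_modes(K, "gnm", cutoff)
  modes$topology <- model[, c("chain", "resid", "domain")]
  modes$components <- graph_components(K)
  modes$matrix <- K
  modes
}

#' Anisotropic network model of a particle model
#'
#' @inheritParams build_hessian
#' @return A `network_modes` object with `topology` attached.
#' @export
anm <- function(model, cutoff = 1.3) {
  stopifnot(inherits(model, "particle_model"))
  H <- build_hessian(model, cutoff)
  modes <- decompose_modes(H, "anm", cutoff)
  modes$topology <- model[, c("chain", "resid", "domain")]
  modes
}

# connected-component labels from a Kirchhoff/adjacency matrix
graph_components <- function(K) {
  A <- K != 0
  diag(A) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  igraph::components(g)$membership
}

#' Hinge regions from the dominant slow GNM mode
#'
#' Following the slow-mode hinge criterion for GNMs: residues whose
#' dominant-mode component magnitude falls strictly below the
#' `threshold_quantile` quantile of all per-residue magnitudes are merged
#' into contiguous runs; each run is reported with its minimum-magnitude
#' residue and the number of sign crossings of the mode inside it.
#'
#' The dominant mode is computed per connected component of the network
#' (for a dimer whose chains are farther apart than the GNM cutoff, each
#' chain is its own component and gets its own slow mode). A near-degenerate
#' dominant eigenvalue within a component (relative gap < 1e-6) triggers a
#' warning and the magnitudes are combined as the RMS over the degenerate
#' cluster, which is invariant to rotations within the eigenspace.
#' Per-residue magnitudes are averaged over chains.
#'
#' @param modes a `network_modes` from [gnm()].
#' @param threshold_quantile quantile in `[0, 1]`; 0 selects nothing.
#' @return A `hinge_runs` tibble (run, resid_start, resid_end, resid_min,
#'   n_sign_crossings) with attribute `residues` (the full hinge residue
#'   set) and `magnitudes` (per-residue tibble).
#' @export
slow_mode_hinges <- function(modes, threshold_quantile = 0.1) {
  stopifnot(inherits(modes, "network_modes"))
  if (modes$kind != "gnm") abort("slow-mode hinge analysis expects GNM modes")
  if (is.null(modes$topology)) abort("modes carry no topology; use gnm()")
  topo <- modes$topology
  comp <- modes$components
  n <- nrow(topo)
  mag <- numeric(n)
  signed <- numeric(n)
  for (cc in unique(comp)) {
    in_cc <- comp == cc
    if (sum(in_cc) < 3) next
    sub <- decompose_modes(
      build_kirchhoff_sub(modes, in_cc), "gnm", modes$cutoff)
    vals <- sub$values
    nz <- which(abs(vals) >= sub$tol)
    if (length(nz) == 0) next
    dom <- nz[1]
    cluster <- dom
    if (length(nz) > 1) {
      gap <- (vals[nz[2]] - vals[dom]) / max(abs(vals[dom]), 1e-300)
      if (gap < 1e-6) {
        warn("near-degenerate dominant eigenvalue: combining the degenerate modes")
        k <- 2
        while (k < length(nz) &&
               (vals[nz[k + 1]] - vals[dom]) / vals[dom] < 1e-6) k <- k + 1
        cluster <- nz[seq_len(k)]
      }
    }
    V <- sub$vectors[, cluster, drop = FALSE]
    mag[in_cc] <- sqrt(rowSums(V^2))
    signed[in_cc] <- V[, 1]
  }
  per_res <- tibble::tibble(resid = topo$resid, mag = mag, signed = signed) |>
    dplyr::group_by(.data$resid) |>
    dplyr::summarise(mag = mean(.data$mag), signed = .data$signed[1],
                     .groups = "drop") |>
    dplyr::arrange(.data$resid)
  thr <- quantile(per_res$mag, threshold_quantile, names = FALSE)
  low <- per_res$mag < thr
  runs <- run_table(per_res, low)
  attr(runs, "residues") <- per_res$resid[low]
  attr(runs, "magnitudes") <- per_res
  class(runs) <- c("hinge_runs", class(tibble::tibble()))
  runs
}

build_kirchhoff_sub <- function(modes, keep) {
  K <- modes$matrix
  if (is.null(K)) {
    # reconstruct from the stored spectrum
    K <- modes$vectors %*% (modes$values * t(modes$vectors))
  }
  K[keep, keep, drop = FALSE]
}

run_table <- function(per_res, low) {
  if (!any(low)) {
    return(tibble::tibble(run = integer(), resid_start = integer(),
                          resid_end = integer(), resid_min = integer(),
                          n_sign_crossings = integer()))
  }
  r <- rle(low)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  sel <- which(r$values)
  purrr::map_dfr(seq_along(sel), function(k) {
    i0 <- starts[sel[k]]; i1 <- ends[sel[k]]
    seg <- per_res[i0:i1, ]
    tibble::tibble(
      run = k,
      resid_start = seg$resid[1],
      resid_end = seg$resid[nrow(seg)],
      resid_min = seg$resid[which.min(seg$mag)],
      n_sign_crossings = sum(diff(sign(seg$signed)) != 0)
    )
  })
}

#' Mean-square fluctuation profile from GNM modes
#'
#' Diagonal of the Moore-Penrose pseudo-inverse of the Kirchhoff matrix
#' (zero modes excluded), the standard GNM fluctuation profile up to a
#' global scale.
#'
#' @param modes a `network_modes` from [gnm()] or [decompose_modes()].
#' @return Numeric vector of per-particle mean-square fluctuations.
#' @export
gnm_msf <- function(modes) {
  stopifnot(inherits(modes, "network_modes"))
  nz <- which(abs(modes$values) >= modes$tol)
  V <- modes$vectors[, nz, drop = FALSE]
  rowSums(sweep(V^2, 2, modes$values[nz], "/"))
}
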