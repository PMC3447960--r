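#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @export
tidy.hinge_profile <- function(x, ...) {
  tibble::tibble(resid = x$resid, msd = x$msd)
}

#' @export
glance.hinge_profile <- function(x, ...) {
  tibble::tibble(hinge = attr(x, "hinge"), flat = attr(x, "flat"),
                 min_msd = min(x$msd), max_msd = max(x$msd),
                 n_candidates = nrow(x))
}

#' @export
tidy.bending_series <- function(x, ...) {
  tibble::tibble(frame = x$frame, time = x$time, angle = x$angle)
}

#' @export
glance.bending_series <- function(x, ...) {
  tibble::tibble(hinge = attr(x, "hinge"), modal_angle = attr(x, "modal"),
                 max_angle = attr(x, "max"), modal_tie = attr(x, "modal_tie"),
                 n_frames = nrow(x))
}

#' @export
tidy.network_modes <- function(x, ...) {
  tibble::tibble(mode = seq_along(x$values), eigenvalue = x$values,
                 zero = abs(x$values) < x$tol)
}

#' @export
glance.network_modes <- function(x, ...) {
  nz <- x$values[abs(x$values) >= x$tol]
  tibble::tibble(kind = x$kind, cutoff = x$cutoff, n_modes = length(x$values),
                 n_zero = x$n_zero,
                 dominant_eigenvalue = if (length(nz)) nz[1] else NA_real_)
}

#' @export
tidy.gromos_clustering <- function(x, ...) x$membership

#' @export
glance.gromos_clustering <- function(x, ...) {
  tibble::tibble(n_frames = length(x$frames), n_clusters = nrow(x$clusters),
                 cutoff = x$cutoff,
                 dominant_size = max(x$clusters$size),
                 dominant_representative = x$clusters$representative[1])
}

#' @export
tidy.rmsd_series <- function(x, ...) {
  tibble::tibble(frame = x$frame, time = x$time, rmsd = x$rmsd)
}

#' @export
glance.rmsd_series <- function(x, ...) {
  tibble::tibble(modal_rmsd = attr(x, "modal"), mean_rmsd = mean(x$rmsd),
                 max_rmsd = max(x$rmsd), reference = attr(x, "reference"),
                 n_frames = nrow(x))
}

#' @export
tidy.fingerprint <- function(x, ...) {
  tibble::tibble(
    resid = rep(x$resid, times = ncol(x$D)),
    frame = rep(seq_len(ncol(x$D)), each = nrow(x$D)),
    time = rep(x$times, each = nrow(x$D)),
    distance = as.numeric(x$D)
  )
}

#' @export
glance.enrichment_series <- function(x, ...) {
  s <- enrichment_summary(x)
  tidyr::pivot_wider(
    dplyr::select(s, "species", "enrich_bulk"),
    names_from = "species", values_from = "enrich_bulk",
    names_prefix = "enrich_bulk_"
  )
}
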