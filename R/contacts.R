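#' Residue-level interaction fingerprint
#'
#' For every residue i of the query selection and every frame t,
#' `D[i, t]` is the shortest distance from any particle of that residue to
#' any particle of the partner selection — the per-residue minimum-distance
#' fingerprint used to characterise dimer-dimer interfaces.
#'
#' @param ensemble an `ensemble`.
#' @param query selection for the query copy (see [select_particles()]).
#' @param partner selection for the binding partner; must not overlap the
#'   query.
#' @return A `fingerprint` object: matrix `D` (residues x frames, nm),
#'   `resid` (query residue ids), `times`.
#' @export
contact_fingerprint <- function(ensemble, query, partner) {
  stopifnot(inherits(ensemble, "ensemble"))
  qi <- selection_index(ensemble$topology, query)
  pi_ <- selection_index(ensemble$topology, partner)
  if (length(intersect(qi, pi_)) > 0) {
    abort("query and partner selections overlap")
  }
  qres <- ensemble$topology$resid[qi]
  resid <- sort(unique(qres))
  grp <- match(qres, resid)
  D <- vapply(ensemble$coords, function(m) {
    qm <- m[qi, , drop = FALSE]
    pm <- m[pi_, , drop = FALSE]
    # squared cross distances query x partner
    cross <- outer(rowSums(qm^2), rowSums(pm^2), "+") - 2 * tcrossprod(qm, pm)
    dmin <- sqrt(pmax(0, apply(cross, 1, min)))
    as.numeric(tapply(dmin, grp, min))
  }, numeric(length(resid)))
  D <- matrix(D, nrow = length(resid))
  structure(list(D = D, resid = resid, times = ensemble$times),
            class = "fingerprint")
}

#' @export
print.fingerprint <- function(x, ...) {
  cat(sprintf("<fingerprint> %d residues x %d frames, min distance %.3g nm\n",
              nrow(x$D), ncol(x$D), min(x$D)))
  invisible(x)
}

#' Contact residue set from a fingerprint
#'
#' Residues with fingerprint distance below `threshold` in a given frame,
#' or — for a window of frames — in at least half of the window's frames.
#'
#' @param fp a [contact_fingerprint()] result.
#' @param threshold contact distance threshold in nm (> 0).
#' @param frame single frame index, or `NULL` to use `window`.
#' @param window integer vector of frame indices (defaults to all frames
#'   when both `frame` and `window` are `NULL`).
#' @return Integer vector of residue ids in contact.
#' @export
contact_set <- function(fp, threshold = 0.8, frame = NULL, window = NULL) {
  stopifnot(inherits(fp, "fingerprint"))
  if (threshold <= 0) abort("threshold must be > 0")
  if (!is.null(frame)) {
    hit <- fp$D[, frame] < threshold
  } else {
    if (is.null(window)) window <- seq_len(ncol(fp$D))
    if (length(window) == 0) abort("empty frame window")
    hit <- rowMeans(fp$D[, window, drop = FALSE] < threshold) >= 0.5
  }
  fp$resid[hit]
}

#' Interface similarity between a fingerprint and a reference interface
#'
#' Per-frame Jaccard index between the query's contact set in that frame
#' and the reference fingerprint's time-averaged contact set (residues in
#' contact in at least half of the reference frames). Frames where both
#' sets are empty get `NA` and are flagged — an empty-vs-empty comparison
#' carries no interface information.
#'
#' @param query_fp query [contact_fingerprint()].
#' @param reference_fp reference fingerprint over the same residue set.
#' @param threshold contact threshold in nm.
#' @return An `interface_similarity` tibble (frame, time, similarity,
#'   undefined) with attribute `reference_set`.
#' @export
interface_similarity <- function(query_fp, reference_fp, threshold = 0.8) {
  stopifnot(inherits(query_fp, "fingerprint"),
            inherits(reference_fp, "fingerprint"))
  if (!identical(query_fp$resid, reference_fp$resid)) {
    abort("fingerprints must index the same residues")
  }
  ref_set <- contact_set(reference_fp, threshold)
  sim <- vapply(seq_len(ncol(query_fp$D)), function(t) {
    qs <- query_fp$resid[query_fp$D[, t] < threshold]
    u <- length(union(qs, ref_set))
    if (u == 0) return(NA_real_)
    length(intersect(qs, ref_set)) / u
  }, numeric(1))
  out <- tibble::tibble(frame = seq_along(sim), time = query_fp$times,
                        similarity = sim, undefined = is.na(sim))
  attr(out, "reference_set") <- ref_set
  class(out) <- c("interface_similarity", class(tibble::tibble()))
  out
}
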