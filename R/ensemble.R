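#' Conformational ensemble container
#'
#' An `ensemble` bundles a shared topology (one row per particle: chain,
#' 1-based residue index, domain label) with an ordered list of coordinate
#' matrices (one n x 3 matrix per frame, nm) and strictly increasing frame
#' times in ns.
#'
#' @param topology tibble with columns `chain`, `resid`, `domain`.
#' @param coords list of n x 3 numeric matrices, one per frame.
#' @param times numeric vector of frame times (ns), strictly increasing.
#' @return An object of class `ensemble`.
#' @export
new_ensemble <- function(topology, coords, times = seq_along(coords) - 1) {
  stopifnot(is.data.frame(topology), is.list(coords), length(coords) >= 1)
  n <- nrow(topology)
  ok <- vapply(coords, function(m) is.matrix(m) && nrow(m) == n && ncol(m) == 3,
               logical(1))
  if (!all(ok)) {
    abort(sprintf("frame %d does not match the topology (%d particles expected)",
                  which(!ok)[1], n))
  }
  if (length(times) != length(coords) || any(diff(times) <= 0)) {
    abort("frame times must be strictly increasing, one per frame")
  }
  structure(
    list(topology = tibble::as_tibble(topology), coords = coords,
         times = as.numeric(times)),
    class = "ensemble"
  )
}

#' @export
length.ensemble <- function(x) length(x$coords)

#' @export
print.ensemble <- function(x, ...) {
  cat(sprintf("<ensemble> %d frames x %d particles (%d chains), t = %g..%g ns\n",
              length(x$coords), nrow(x$topology),
              length(unique(x$topology$chain)),
              min(x$times), max(x$times)))
  invisible(x)
}

#' Extract one frame of an ensemble as a particle model
#'
#' @param ensemble an [new_ensemble()] object.
#' @param frame 1-based frame index.
#' @return A `particle_model` tibble.
#' @export
ensemble_frame <- function(ensemble, frame) {
  stopifnot(inherits(ensemble, "ensemble"))
  if (frame < 1 || frame > length(ensemble$coords)) {
    abort(sprintf("frame %s out of range 1..%d", frame, length(ensemble$coords)))
  }
  m <- ensemble$coords[[frame]]
  out <- ensemble$topology
  out$x <- m[, 1]; out$y <- m[, 2]; out$z <- m[, 3]
  as_particle_model(out, model_id = frame)
}

#' @export
as_tibble.ensemble <- function(x, ...) {
  purrr::map2_dfr(seq_along(x$coords), x$times, function(i, t) {
    m <- x$coords[[i]]
    dplyr::mutate(x$topology, frame = i, time = t,
                  x = m[, 1], y = m[, 2], z = m[, 3])
  })
}

#' Construct a particle model tibble
#'
#' A `particle_model` is a tibble with one row per particle and columns
#' `chain`, `resid` (1-based), `domain`, and coordinates `x`, `y`, `z` in nm.
#'
#' @param df data frame with the required columns.
#' @param model_id identifier stored as an attribute.
#' @return A tibble of class `particle_model`.
#' @export
as_particle_model <- function(df, model_id = 1L) {
  need <- c("chain", "resid", "domain", "x", "y", "z")
  if (!all(need %in% names(df))) {
    abort(paste("particle model needs columns:", paste(need, collapse = ", ")))
  }
  dup <- df |>
    dplyr::count(.data$chain, .data$resid) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf("duplicate residue index %d in chain %s",
                  dup$resid[1], dup$chain[1]))
  }
  if (!all(is.finite(c(df$x, df$y, df$z)))) abort("coordinates must be finite")
  out <- tibble::as_tibble(df)
  attr(out, "model_id") <- model_id
  class(out) <- c("particle_model", class(tibble::tibble()))
  out
}

model_coords <- function(model) coords_matrix(model)

set_model_coords <- function(model, m) {
  model$x <- m[, 1]; model$y <- m[, 2]; model$z <- m[, 3]
  model
}
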