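#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_col geom_point
#'   geom_vline geom_hline geom_tile labs scale_fill_viridis_c theme_minimal
#' @export
ggplot2::autoplot

#' @export
autoplot.hinge_profile <- function(object, ...) {
  p <- ggplot(tidy(object), aes(x = .data$resid, y = .data$msd)) +
    geom_line() +
    labs(x = "split residue", y = expression(MSD ~ (nm^2)),
         title = "Bisection line-fit MSD profile") +
    theme_minimal()
  if (!attr(object, "flat")) {
    p <- p + geom_vline(xintercept = attr(object, "hinge"),
                        linetype = "dashed", colour = "red")
  }
  p
}

#' @export
autoplot.bending_series <- function(object, ...) {
  hist <- attr(object, "histogram")
  ggplot(hist, aes(x = .data$mid, y = .data$count)) +
    geom_col(width = hist$bin_hi[1] - hist$bin_lo[1], fill = "steelblue") +
    geom_vline(xintercept = attr(object, "modal"), linetype = "dashed") +
    labs(x = "bending angle (degrees)", y = "frames",
         title = sprintf("Bending angles (modal %.1f deg, max %.1f deg)",
                         attr(object, "modal"), attr(object, "max"))) +
    theme_minimal()
}

#' @export
autoplot.rmsd_series <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$time, y = .data$rmsd)) +
    geom_line() +
    geom_hline(yintercept = attr(object, "modal"), linetype = "dashed") +
    labs(x = "time (ns)", y = "RMSD (nm)") +
    theme_minimal()
}

#' @export
autoplot.network_modes <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$mode, y = .data$eigenvalue,
                           colour = .data$zero)) +
    geom_point() +
    labs(x = "mode", y = "eigenvalue (arbitrary units)",
         title = sprintf("%s spectrum (cutoff %g nm)",
                         toupper(object$kind), object$cutoff)) +
    theme_minimal()
}

#' @export
autoplot.fingerprint <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$frame, y = .data$resid,
                           fill = .data$distance)) +
    geom_tile() +
    scale_fill_viridis_c(name = "min distance (nm)", direction = -1) +
    labs(x = "frame", y = "residue", title = "Interaction fingerprint") +
    theme_minimal()
}

#' @export
autoplot.enrichment_series <- function(object, ...) {
  ggplot(object, aes(x = .data$frame, y = .data$enrich_bulk,
                     colour = .data$species)) +
    geom_line() +
    geom_hline(yintercept = 1, linetype = "dashed") +
    labs(x = "frame", y = "shell enrichment (vs bulk)",
         title = sprintf("Lipid shell enrichment (%g nm shell)",
                         attr(object, "shell"))) +
    theme_minimal()
}
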