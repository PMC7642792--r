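# ggplot2 figures for curves, resolution results and local maps.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an FSC/mFSC curve
#'
#' Curve value against shell index, with the resolution threshold drawn as
#' a horizontal reference.
#'
#' @param object an `fsc_curve`.
#' @param t threshold line to draw (default 0.143).
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot fsc_curve
#' @export
autoplot.fsc_curve <- function(object, t = 0.143, ...) {
  df <- as.data.frame(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$value)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_hline(yintercept = t, linetype = "dashed", colour = "grey40") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "shell index k (Fourier pixels)",
                  y = attr(object, "method"),
                  title = sprintf("%s curve (sigma_g = %s)",
                                  attr(object, "method"),
                                  format(attr(object, "sigma_g")))) +
    ggplot2::ylim(-0.2, 1)
}

#' Plot a resolution result
#'
#' Curve plus the per-shell CI cutoff; the determined resolution shell is
#' marked with a vertical line.
#'
#' @param object a `resolution_result`.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot resolution_result
#' @export
autoplot.resolution_result <- function(object, ...) {
  df <- as.data.frame(object$curve)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$k)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_hline(yintercept = object$params$t, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_line(ggplot2::aes(y = .data$value)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$ci_cutoff), colour = "steelblue",
                       linetype = "dotdash") +
    ggplot2::labs(x = "shell index k (Fourier pixels)", y = "correlation",
                  title = if (object$resolvable)
                    sprintf("resolution k* = %d (%.2f A)", object$k_star,
                            object$resolution_angstrom)
                  else "no resolvable signal") +
    ggplot2::ylim(-0.2, 1)
  if (object$resolvable)
    p <- p + ggplot2::geom_vline(xintercept = object$k_star,
                                 colour = "firebrick", linetype = "dotted")
  p
}

#' Plot a central section of a local resolution map
#'
#' Heat map of the z = n/2 section; sentinel (0) voxels are blank.
#'
#' @param object a `local_resolution_map`.
#' @param z section index (default the central section).
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot local_resolution_map
#' @export
autoplot.local_resolution_map <- function(object, z = NULL, ...) {
  d <- object$data$data
  n <- object$data$n
  if (is.null(z)) z <- n / 2 + 1
  sl <- d[, , z]
  df <- expand.grid(x = seq_len(n), y = seq_len(n))
  df$resolution <- as.vector(sl)
  df$resolution[df$resolution == 0] <- NA
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$resolution)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "white", direction = -1,
                                  name = "resolution (A)") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("local resolution, section z = %d", z))
}

#' @importFrom ggplot2 .data
NULL
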