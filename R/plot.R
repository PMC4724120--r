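# ggplot2 views of scan grids. These are data displays, not publication
# figures: composition on the x axis (two-species), growth rate or second
# species fraction on the y axis where present.

#' Plot a composition scan
#'
#' Two-species scans in maximum-growth mode become a line plot of the
#' chosen metric against the first species' biomass fraction; fixed-rate
#' scans and three-species scans become a filled raster over
#' (fraction, growth rate) or (fraction, fraction).
#'
#' @param object A [scan_compositions()] result.
#' @param metric Column to display (default `"optdeg"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot commfba_scan
#' @export
autoplot.commfba_scan <- function(object, metric = "optdeg", ...) {
  sp <- attr(object, "species")
  df <- tibble::as_tibble(object)
  f1 <- paste0("F_", sp[1])
  multi_mu <- length(sp) == 2 &&
    any(duplicated(df[[f1]]))
  if (length(sp) == 2 && !multi_mu) {
    return(
      ggplot2::ggplot(df, ggplot2::aes(x = .data[[f1]],
                                       y = .data[[metric]])) +
        ggplot2::geom_line(na.rm = TRUE) +
        ggplot2::geom_point(size = 0.6, na.rm = TRUE) +
        ggplot2::labs(x = paste("biomass fraction", sp[1]), y = metric) +
        ggplot2::theme_minimal()
    )
  }
  yvar <- if (length(sp) >= 3) paste0("F_", sp[2]) else "mu_c"
  ylab <- if (length(sp) >= 3) paste("biomass fraction", sp[2]) else
    "community growth rate (1/h)"
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[f1]], y = .data[[yvar]],
                                   fill = .data[[metric]])) +
    ggplot2::geom_raster(na.rm = TRUE) +
    ggplot2::scale_fill_viridis_c(na.value = "grey85") +
    ggplot2::labs(x = paste("biomass fraction", sp[1]), y = ylab,
                  fill = metric) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
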