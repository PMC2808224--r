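#' Plot a dose-response scan
#'
#' Steady-state values of the watched places against the scanned
#' concentration.
#'
#' @param object A `pn_scan`.
#' @param places Which watched places to draw (default: all).
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.pn_scan <- function(object, places = object$watch_places, ...) {
  v <- object$values
  df <- do.call(rbind, lapply(places, function(p) {
    data.frame(x = v[[object$scan_place]], place = p, ssv = v[[p]],
               stringsAsFactors = FALSE)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$ssv,
                                   colour = .data$place)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = paste(object$scan_place, "concentration"),
                  y = "steady-state value", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
plot.pn_scan <- function(x, ...) print(autoplot.pn_scan(x, ...))

#' Plot a trajectory
#'
#' Concentration time courses on a logarithmic time axis.
#'
#' @param object A `pn_trajectory`.
#' @param places Which species to draw (default: all).
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.pn_trajectory <- function(object, places = rownames(object$states), ...) {
  df <- as.data.frame(object)
  df <- df[df$place %in% places, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value,
                                   colour = .data$place)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "time", y = "concentration", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
plot.pn_trajectory <- function(x, ...) print(autoplot.pn_trajectory(x, ...))

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
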