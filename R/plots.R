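# ggplot2 quick-look methods for the result types.

#' Plot methods
#'
#' `autoplot()` methods give quick-look figures: the density profile for an
#' `nnlif_density`, the firing-rate trace for an `nnlif_result`, the scan of
#' `N I(N)` against 1 with roots marked for an `nnlif_rootset`, and the
#' relative-entropy decay on a log scale (with the fitted exponential) for
#' an `nnlif_entropy`.
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @return A ggplot object.
#' @name nnlifpd-autoplot
NULL

#' @rdname nnlifpd-autoplot
#' @export
autoplot.nnlif_density <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$v, y = .data$p)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$grid$params$VR, linetype = 3) +
    ggplot2::labs(x = "membrane voltage v", y = "density p(v)",
                  title = sprintf("t = %.3g, N = %.4g", object$t, object$N))
}

#' @rdname nnlifpd-autoplot
#' @export
autoplot.nnlif_result <- function(object, ...) {
  ggplot2::ggplot(object$trace, ggplot2::aes(x = .data$time, y = .data$N)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time", y = "firing rate N(t)",
                  title = sprintf("status: %s", object$status))
}

#' @rdname nnlifpd-autoplot
#' @export
autoplot.nnlif_rootset <- function(object, ...) {
  sc <- object$scan
  sc$NI <- sc$F + 1
  gg <- ggplot2::ggplot(sc, ggplot2::aes(x = .data$N, y = .data$NI)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "firing rate N", y = "N I(N)")
  if (nrow(object$roots))
    gg <- gg + ggplot2::geom_point(
      data = data.frame(N = object$roots$N, NI = 1),
      ggplot2::aes(x = .data$N, y = .data$NI), shape = 21, size = 2)
  gg
}

#' @rdname nnlifpd-autoplot
#' @export
autoplot.nnlif_entropy <- function(object, ...) {
  tr <- object$trace[object$trace$H > 0, ]
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$time, y = .data$H)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time", y = "relative entropy H(t)",
                  title = sprintf("fitted decay rate %.4g", object$fitted_rate))
}

#' @importFrom ggplot2 .data
NULL
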