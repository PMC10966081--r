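# ggplot2 views of the result tables. Cosmetic companions to the numeric
# output, never part of the acceptance surface.

#' Plot index or entropy series over the diagonal grid
#'
#' Line-and-point plots of [ben4_index()] / [ben4_entropy()] output, one
#' coloured series per index (and linetype per mode when both modes are
#' present).
#'
#' @param data A tibble as returned by [ben4_index()] or [ben4_entropy()].
#'
#' @return A ggplot object.
#' @examples
#' ben4_index(1:10, names = c("GA", "ABC"), mode = "published") |>
#'   plot_index_series()
#' @export
plot_index_series <- function(data) {
  stopifnot(all(c("index", "m", "value") %in% names(data)))
  p <- ggplot2::ggplot(data, ggplot2::aes(
    x = .data$m, y = .data$value, colour = .data$index))
  if ("mode" %in% names(data) && length(unique(data$mode)) > 1L) {
    p <- p + ggplot2::aes(linetype = .data$mode)
  }
  p + ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "m (= n, unit cells)", y = "index value",
                  colour = "index")
}

#' @rdname plot_index_series
#' @export
plot_entropy_series <- function(data) {
  stopifnot(all(c("index", "m", "entropy") %in% names(data)))
  ggplot2::ggplot(data, ggplot2::aes(
    x = .data$m, y = .data$entropy, colour = .data$index)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "m (= n, unit cells)", y = "entropy (nats)",
                  colour = "index")
}

#' Plot a fitted entropy-index regression
#'
#' Observed points with the fitted logarithmic (or power) curve overlaid.
#'
#' @param object A `ti_fit` from [fit_log()] or [fit_power()].
#' @param ... Ignored.
#'
#' @return A ggplot object.
#' @examples
#' d <- synthetic_log_data(2, 3, sigma = 0.05, n = 20, seed = 1)
#' autoplot(fit_log(d, x, y))
#' @method autoplot ti_fit
#' @export
autoplot.ti_fit <- function(object, ...) {
  d <- object$data
  xs <- seq(min(d$x), max(d$x), length.out = 200)
  curve <- tibble(
    x = xs,
    y = if (object$type == "log") {
      object$beta0 + object$beta1 * log(xs)
    } else {
      object$a * xs^object$b
    }
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curve, colour = "steelblue") +
    ggplot2::labs(
      x = "index value",
      y = if (object$type == "log") "entropy (nats)" else "y",
      title = sprintf("%s model: R2 = %.4f, SE = %.4f",
                      object$type, object$R2, object$SE))
}
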