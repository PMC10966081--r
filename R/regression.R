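# Logarithmic and power regressions of entropy on index.
#
# The logarithmic model is y = b0 + b1*ln(x) + e, fit by OLS; the power
# model y = a*x^b is fit as OLS of ln(y) on ln(x). Goodness statistics
# follow the usual curve-estimation output: R (correlation, carrying the
# slope's sign), R^2, residual standard error SE = sqrt(RSS/(n-2)),
# F = ESS/(RSS/(n-2)) on (1, n-2) df, and the F upper-tail p-value.

# noise-free synthetic input legitimately yields an exact fit; the stock
# lm warning about it is expected, not actionable
lm_summary_quiet <- function(model) {
  withCallingHandlers(
    summary(model),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
}

new_ti_fit <- function(model, type, data) {
  s <- lm_summary_quiet(model)
  b <- coef(model)
  n <- length(model$residuals)
  r2 <- s$r.squared
  fstat <- unname(s$fstatistic[1])
  out <- list(
    model = model, type = type, data = data,
    beta0 = unname(b[1]), beta1 = unname(b[2]),
    R = sign(b[2]) * sqrt(r2), R2 = r2,
    SE = s$sigma, F = fstat,
    p = pf(fstat, 1, n - 2, lower.tail = FALSE),
    n_points = n
  )
  if (type == "power") {
    out$a <- exp(out$beta0)
    out$b <- out$beta1
  }
  structure(out, class = "ti_fit")
}

check_fit_input <- function(x, y, require_pos_y = FALSE) {
  if (length(x) != length(y) || length(x) < 3L) {
    abort("Need at least 3 (x, y) pairs of equal length.",
          class = "topoent_bad_fit")
  }
  if (anyNA(x) || anyNA(y)) {
    abort("Missing values are not allowed.", class = "topoent_bad_fit")
  }
  if (any(x <= 0)) {
    abort("All x must be positive (the model takes ln(x)).",
          class = "topoent_bad_fit")
  }
  if (require_pos_y && any(y <= 0)) {
    abort("All y must be positive for the power model.",
          class = "topoent_bad_fit")
  }
  if (length(unique(x)) < 2L) {
    abort("x is constant; the slope is unidentifiable.",
          class = "topoent_bad_fit")
  }
  invisible(NULL)
}

#' Fit the logarithmic model entropy = b0 + b1 ln(index)
#'
#' Ordinary least squares of `y` on `ln(x)`. `fit_power()` fits the power
#' model `y = a * x^b` as OLS of `ln(y)` on `ln(x)`, with goodness
#' statistics reported on the log-log scale.
#'
#' Both take a data frame first so they chain with the pipe; `x` and `y`
#' are data-masked column expressions.
#'
#' @param data A data frame.
#' @param x,y Column expressions for the predictor (positive) and response
#'   (positive too for `fit_power()`).
#'
#' @return An object of class `ti_fit` with elements `beta0`, `beta1`, `R`,
#'   `R2`, `SE`, `F`, `p`, `n_points` (and `a`, `b` for the power model);
#'   see [tidy.ti_fit()] and [glance.ti_fit()].
#' @examples
#' d <- tibble::tibble(x = 1:10, y = 2 + 3 * log(1:10))
#' fit_log(d, x, y)
#' @export
fit_log <- function(data, x, y) {
  x <- eval_tidy(enquo(x), data)
  y <- eval_tidy(enquo(y), data)
  check_fit_input(x, y)
  d <- tibble(x = x, y = y)
  new_ti_fit(lm(y ~ log(x), data = d), "log", d)
}

#' @rdname fit_log
#' @export
fit_power <- function(data, x, y) {
  x <- eval_tidy(enquo(x), data)
  y <- eval_tidy(enquo(y), data)
  check_fit_input(x, y, require_pos_y = TRUE)
  d <- tibble(x = x, y = y)
  new_ti_fit(lm(log(y) ~ log(x), data = d), "power", d)
}

#' @export
print.ti_fit <- function(x, ...) {
  eq <- if (x$type == "log") {
    sprintf("y = %.3f + %.3f * ln(x)", x$beta0, x$beta1)
  } else {
    sprintf("y = %.4g * x^%.3f  (fit on the log-log scale)", x$a, x$b)
  }
  cat(sprintf("<ti_fit: %s model, n = %d>\n  %s\n", x$type, x$n_points, eq))
  cat(sprintf("  R = %.3f  R2 = %.3f  SE = %.3f  F = %.3f  p = %.3g\n",
              x$R, x$R2, x$SE, x$F, x$p))
  invisible(x)
}

#' Broom-style accessors for `ti_fit` objects
#'
#' `tidy()` returns one row per model term; `glance()` returns the
#' one-row goodness summary (R, R2, SE, F, p, n).
#'
#' @param x,... A `ti_fit` object; further arguments are ignored.
#'
#' @return A tibble.
#' @examples
#' d <- tibble::tibble(x = 1:10, y = 2 + 3 * log(1:10))
#' fit_log(d, x, y) |> glance()
#' @method tidy ti_fit
#' @export
tidy.ti_fit <- function(x, ...) {
  s <- lm_summary_quiet(x$model)$coefficients
  term <- if (x$type == "log") c("(Intercept)", "ln(x)") else c("ln(a)", "b")
  tibble(
    term = term,
    estimate = unname(s[, 1]),
    std.error = unname(s[, 2]),
    statistic = unname(s[, 3]),
    p.value = unname(s[, 4])
  )
}

#' @rdname tidy.ti_fit
#' @method glance ti_fit
#' @export
glance.ti_fit <- function(x, ...) {
  tibble(
    r = x$R, r.squared = x$R2, sigma = x$SE,
    statistic = x$F, p.value = x$p, nobs = x$n_points
  )
}

#' Goodness-of-fit table of the logarithmic model across all indices
#'
#' For each index, fits entropy on `ln(index)` over the given grid (both
#' series recomputed at full precision in the requested mode) and reports
#' the curve-estimation statistics, one row per index.
#'
#' @inheritParams ben4_entropy
#' @param digits If not `NULL`, round the reported statistics to this many
#'   decimals (the reference layout uses 3).
#'
#' @return A tibble with columns `index`, `beta1`, `beta0`, `R`, `R2`,
#'   `SE`, `F`, `p`.
#' @examples
#' goodness_table(1:10, names = c("GA", "ABC"))
#' @export
goodness_table <- function(grid = 1:10, names = index_names(),
                           mode = "published", freq33 = NULL,
                           digits = NULL) {
  grid <- as_grid(grid)
  idx <- ben4_index(grid, names, mode = mode, freq33 = freq33)
  ent <- ben4_entropy(grid, names, mode = mode, freq33 = freq33)
  out <- purrr::map_dfr(names, function(nm) {
    d <- tibble(
      x = idx$value[idx$index == nm],
      y = ent$entropy[ent$index == nm]
    )
    fit <- fit_log(d, x, y)
    tibble(index = nm, beta1 = fit$beta1, beta0 = fit$beta0,
           R = fit$R, R2 = fit$R2, SE = fit$SE, F = fit$F, p = fit$p)
  })
  if (!is.null(digits)) {
    out <- dplyr::mutate(out, dplyr::across(
      c("beta1", "beta0", "R", "R2", "SE", "p"), ~ round(.x, digits)))
  }
  out
}
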