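# Seeded fixtures and independent oracles: classic graphs with closed-form
# index values, Erdos-Renyi random graphs for oracle-equivalence checks,
# and synthetic regression data with known coefficients.

#' Generate classic and random graphs as edge lists
#'
#' `kind` is one of `"path"`, `"cycle"`, `"star"`, `"complete"`,
#' `"random"`. `size` is the number of vertices (a star on `size` vertices
#' has `size - 1` leaves). Random graphs are Erdos-Renyi G(n, p); with a
#' `seed` the construction is reproducible and the caller's RNG state is
#' left untouched.
#'
#' @param kind Graph family.
#' @param size Number of vertices (>= 2; >= 3 for a cycle).
#' @param p Edge probability in (0, 1], random graphs only.
#' @param seed Optional integer seed, random graphs only.
#'
#' @return An edge-list tibble with columns `from`, `to`.
#' @examples
#' make_graph("cycle", 6)
#' make_graph("random", 20, p = 0.3, seed = 7)
#' @export
make_graph <- function(kind = c("path", "cycle", "star", "complete", "random"),
                       size, p = 0.3, seed = NULL) {
  kind <- match.arg(kind)
  if (length(size) != 1L || !is.numeric(size) || size != trunc(size) ||
      size < 2L || (kind == "cycle" && size < 3L)) {
    abort("`size` must be an integer >= 2 (>= 3 for a cycle).",
          class = "topoent_bad_fixture")
  }
  g <- switch(kind,
    path     = igraph::make_ring(size, circular = FALSE),
    cycle    = igraph::make_ring(size, circular = TRUE),
    star     = igraph::make_star(size, mode = "undirected"),
    complete = igraph::make_full_graph(size),
    random   = {
      if (p <= 0 || p > 1) {
        abort("`p` must be in (0, 1].", class = "topoent_bad_fixture")
      }
      sample_g <- function() igraph::sample_gnp(size, p)
      if (is.null(seed)) sample_g() else withr::with_seed(seed, sample_g())
    }
  )
  el <- igraph::as_edgelist(g, names = FALSE)
  if (nrow(el) == 0L) {
    # degree-based indices need at least one edge; retry densification is
    # not appropriate for a seeded fixture, so fail loudly
    abort("Generated graph has no edges; increase `size` or `p`.",
          class = "topoent_bad_fixture")
  }
  as_edge_list(tibble(from = el[, 1], to = el[, 2]))
}

#' Brute-force edge-by-edge index oracle
#'
#' Sums the index weight edge by edge over an explicit graph, with no
#' partition shortcut. This is the reference against which the
#' partition-based [compute_index()] route is verified.
#'
#' @inheritParams as_edge_list
#' @inheritParams index_entropy
#'
#' @return A single numeric value.
#' @examples
#' brute_force_index(make_graph("cycle", 6), "M1")
#' @export
brute_force_index <- function(edges, name) {
  edges <- as_edge_list(edges)
  check_index_name(name)
  deg <- graph_degrees(edges)
  total <- 0
  for (i in seq_len(nrow(edges))) {
    a <- deg[[as.character(edges$from[i])]]
    b <- deg[[as.character(edges$to[i])]]
    total <- total + edge_weight(name, a, b)
  }
  total
}

#' Synthetic data for the logarithmic regression model
#'
#' Draws `y = beta0 + beta1 * ln(x) + e`, with `e` Gaussian with standard
#' deviation `sigma` and `x` the strictly increasing positive sequence
#' `1..n`. Gaussian noise is the OLS-consistent choice for exercising
#' [fit_log()]; with `sigma = 0` the fit recovers the coefficients
#' exactly.
#'
#' @param beta0,beta1 True intercept and slope.
#' @param sigma Noise standard deviation (>= 0).
#' @param n Number of points (>= 3).
#' @param seed Optional integer seed; the caller's RNG state is preserved.
#'
#' @return A tibble with columns `x` and `y`.
#' @examples
#' synthetic_log_data(2, 3, sigma = 0.1, n = 10, seed = 1)
#' @export
synthetic_log_data <- function(beta0, beta1, sigma, n, seed = NULL) {
  if (length(n) != 1L || n != trunc(n) || n < 3L) {
    abort("`n` must be an integer >= 3.", class = "topoent_bad_fixture")
  }
  if (length(sigma) != 1L || !is.numeric(sigma) || sigma < 0) {
    abort("`sigma` must be a single non-negative number.",
          class = "topoent_bad_fixture")
  }
  x <- seq_len(n)
  draw <- function() stats::rnorm(n, 0, sigma)
  e <- if (sigma == 0) {
    rep(0, n)
  } else if (is.null(seed)) {
    draw()
  } else {
    withr::with_seed(seed, draw())
  }
  tibble(x = as.numeric(x), y = beta0 + beta1 * log(x) + e)
}
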