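# Degree-level description of the beryllonitrene BeN4(m, n) lattice.
#
# The lattice is characterised entirely by its vertex- and edge-degree
# partitions: every index computed downstream is degree-based, so the
# partitions *are* the structure. m and n count unit cells along the two
# lattice directions.

check_grid <- function(m, n) {
  for (v in list(m = m, n = n)) {
    if (length(v) != 1L || !is.numeric(v) || is.na(v) || v < 1 || v != trunc(v)) {
      abort("`m` and `n` must be single integers >= 1.", class = "topoent_bad_grid")
    }
  }
  invisible(list(m = as.integer(m), n = as.integer(n)))
}

#' Vertex and edge counts of the BeN4(m, n) lattice
#'
#' The lattice on `m` by `n` unit cells has `5mn + m + n + 1` vertices and
#' `8mn - n` edges.
#'
#' @param m,n Unit-cell counts along the two lattice directions (integers
#'   >= 1).
#'
#' @return A tibble with columns `m`, `n`, `vertices`, `edges`.
#' @examples
#' ben4_counts(1, 1)
#' ben4_counts(10, 10)
#' @export
ben4_counts <- function(m, n) {
  check_grid(m, n)
  tibble(
    m = as.integer(m), n = as.integer(n),
    vertices = as.integer(5 * m * n + m + n + 1),
    edges    = as.integer(8 * m * n - n)
  )
}

#' Vertex partition of the BeN4(m, n) lattice
#'
#' Number of vertices of each degree. Degrees 1 through 4 occur; the counts
#' total `5mn + m + n + 1`.
#'
#' @inheritParams ben4_counts
#'
#' @return A tibble with columns `degree` and `count`.
#' @examples
#' ben4_vertex_partition(2, 2)
#' @export
ben4_vertex_partition <- function(m, n) {
  check_grid(m, n)
  tibble(
    degree = 1:4,
    count = as.integer(c(
      4,
      2 * m + 4 * n - 4,
      4 * m * n - 2 * n,
      m * n - m - n + 1
    ))
  )
}

# Frequency of the (3,3) edge class. `override` may be NULL (default
# 4mn - 3n), a function of (m, n), or a single number.
freq33_count <- function(m, n, override = NULL) {
  if (is.null(override)) return(4 * m * n - 3 * n)
  val <- if (is.function(override)) override(m, n) else override
  if (length(val) != 1L || !is.numeric(val) || is.na(val) || val < 0) {
    abort("`freq33` must yield a single non-negative number.",
          class = "topoent_bad_freq33")
  }
  val
}

#' Edge partition of the BeN4(m, n) lattice
#'
#' Number of edges in each unordered endpoint-degree class. Classes are
#' stored min-degree first; the counts total `8mn - n`.
#'
#' The `(3,3)` class defaults to the reference count `4mn - 3n`. Because the
#' source tables are internally inconsistent about this one class, an
#' override hook is exposed: supply a number or a `function(m, n)` to
#' substitute a different count (the value `4mn - 4n` reconciles the
#' as-published polynomials and entropy tables; see the package vignette).
#'
#' @inheritParams ben4_counts
#' @param freq33 Optional override for the `(3,3)` class count: a single
#'   non-negative number or a `function(m, n)`. `NULL` (default) keeps
#'   `4mn - 3n`.
#'
#' @return A tibble with columns `deg_a`, `deg_b` (`deg_a <= deg_b`) and
#'   `count`.
#' @examples
#' ben4_edge_partition(1, 1)
#' ben4_edge_partition(2, 2, freq33 = function(m, n) 4 * m * n - 4 * n)
#' @export
ben4_edge_partition <- function(m, n, freq33 = NULL) {
  check_grid(m, n)
  tibble(
    deg_a = c(1L, 1L, 2L, 2L, 3L, 3L),
    deg_b = c(2L, 3L, 2L, 3L, 3L, 4L),
    count = c(
      2,
      2,
      2 * n - 2,
      4 * m + 4 * n - 6,
      freq33_count(m, n, freq33),
      4 * m * n - 4 * m - 4 * n + 4
    )
  )
}

#' Consistency audit of a vertex/edge partition pair
#'
#' Runs three report-only checks: non-negativity of all counts, the
#' handshake identity (sum of degree times vertex count equals twice the
#' edge total), and the second-moment identity (sum over edge classes of
#' count times the degree sum equals the degree-squared-weighted vertex
#' total -- equivalently, the first Zagreb index computed either way).
#'
#' @param vp Vertex partition: a data frame with columns `degree`, `count`.
#' @param ep Edge partition: a data frame with columns `deg_a`, `deg_b`,
#'   `count`.
#'
#' @return A tibble with columns `check`, `lhs`, `rhs`, `pass`.
#' @examples
#' validate_partitions(ben4_vertex_partition(3, 2), ben4_edge_partition(3, 2))
#' @export
validate_partitions <- function(vp, ep) {
  stopifnot(all(c("degree", "count") %in% names(vp)),
            all(c("deg_a", "deg_b", "count") %in% names(ep)))
  degsum  <- sum(vp$degree * vp$count)
  edgetot <- sum(ep$count)
  m1_vertex <- sum(vp$degree^2 * vp$count)
  m1_edge   <- sum(ep$count * (ep$deg_a + ep$deg_b))
  tibble(
    check = c("non_negative", "handshake", "second_moment"),
    lhs   = c(min(c(vp$count, ep$count)), degsum, m1_edge),
    rhs   = c(0, 2 * edgetot, m1_vertex),
    pass  = c(
      all(vp$count >= 0) && all(ep$count >= 0),
      degsum == 2 * edgetot,
      m1_edge == m1_vertex
    )
  )
}
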