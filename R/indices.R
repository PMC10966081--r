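# The 14 degree-based topological indices and their two evaluation modes.
#
# "canonical"  : sum over edge classes of count * weight(deg_a, deg_b),
#                using the reference edge partition -- mathematically exact.
# "published"  : the closed-form polynomial c_mn*mn + c_m*m + c_n*n + c_0
#                with coefficients transcribed verbatim from the reference
#                derivations, kept even where internally inconsistent with
#                the partition (the discrepancy audit quantifies this).

.ti_weights <- list(
  R1    = function(a, b) a * b,
  RN1   = function(a, b) 1 / (a * b),
  R12   = function(a, b) sqrt(a * b),
  RN12  = function(a, b) 1 / sqrt(a * b),
  ABC   = function(a, b) sqrt((a + b - 2) / (a * b)),
  GA    = function(a, b) 2 * sqrt(a * b) / (a + b),
  M1    = function(a, b) a + b,
  M2    = function(a, b) a * b,
  HM    = function(a, b) (a + b)^2,
  F     = function(a, b) a^2 + b^2,
  AZI   = function(a, b) ((a * b) / (a + b - 2))^3,
  ReZG1 = function(a, b) (a + b) / (a * b),
  ReZG2 = function(a, b) (a * b) / (a + b),
  ReZG3 = function(a, b) (a * b) * (a + b)
)

# Verbatim closed-form coefficients (c_mn, c_m, c_n, c_0).
.ti_published <- list(
  R1    = c(84, -24, -52, 14),
  RN1   = c(0.7778, 0.3333, 0.3889, 0.5),
  R12   = c(25.8564, -4.0584, -12.0584, 1.4519),
  RN12  = c(2.4880, 0.4783, 0.1449, 0.2741),
  ABC   = c(5.2486, 0.2464, -1.0060, -0.0276),
  GA    = c(7.9589, -0.0793, -2.0397, -0.3021),
  M1    = c(52, -8, -24, 4),
  M2    = c(84, -24, -52, 14),
  HM    = c(340, -96, -208, 64),
  F     = c(172, -48, -104, 36),
  AZI   = c(100.8585, -23.2960, -52.8585, 14.0460),
  ReZG1 = c(5, 1, 0.3333, 1),
  ReZG2 = c(12.8571, -2.0571, -6.0571, 0.4905),
  ReZG3 = c(544, -208, -392, 152)
)

#' Names of the supported topological indices
#'
#' `R1`, `RN1`, `R12`, `RN12` are the Randic index with exponent 1, -1, 1/2,
#' -1/2; `ABC` atom-bond connectivity; `GA` geometric-arithmetic; `M1`/`M2`
#' first/second Zagreb; `HM` hyper-Zagreb; `F` forgotten; `AZI` augmented
#' Zagreb; `ReZG1`-`ReZG3` the redefined Zagreb indices.
#'
#' @return Character vector of the 14 index names.
#' @examples
#' index_names()
#' @export
index_names <- function() names(.ti_weights)

check_index_name <- function(name) {
  if (length(name) != 1L || !name %in% index_names()) {
    abort(paste0("Unknown index name; see index_names()."),
          class = "topoent_bad_index")
  }
  name
}

#' Edge weight of a topological index
#'
#' The symmetric per-edge weight f(a, b) of an index, evaluated at endpoint
#' degrees `a` and `b` (vectorised). `randic_weight()` gives the Randic
#' weight `(a*b)^alpha` for any real exponent.
#'
#' ABC and AZI divide by `a + b - 2` (under a square root and a cube,
#' respectively) and are undefined on an edge joining two degree-1
#' vertices; such input is rejected.
#'
#' @param name One of [index_names()].
#' @param a,b Positive integer endpoint degrees.
#' @param alpha Real Randic exponent.
#'
#' @return Numeric vector of weights.
#' @examples
#' edge_weight("GA", 3, 3)
#' edge_weight("ABC", 2, 3)
#' randic_weight(3, 4, alpha = -1 / 2)
#' @export
edge_weight <- function(name, a, b) {
  check_index_name(name)
  if (any(a < 1) || any(b < 1)) {
    abort("Degrees must be >= 1.", class = "topoent_bad_degree")
  }
  if (name %in% c("ABC", "AZI") && any(a + b <= 2)) {
    abort(paste0(name, " weight is undefined on a degree-1/degree-1 edge ",
                 "(division by a + b - 2 = 0)."),
          class = "topoent_degenerate_edge")
  }
  .ti_weights[[name]](a, b)
}

#' @rdname edge_weight
#' @export
randic_weight <- function(a, b, alpha) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L)
  if (any(a < 1) || any(b < 1)) {
    abort("Degrees must be >= 1.", class = "topoent_bad_degree")
  }
  (a * b)^alpha
}

#' Canonical index values from an edge partition
#'
#' Sum over edge classes of `count * weight(deg_a, deg_b)`. The edge
#' partition is a sufficient statistic for every degree-based index, so
#' this equals the edge-by-edge sum over any graph realising the partition.
#'
#' @param ep Edge partition: data frame with columns `deg_a`, `deg_b`,
#'   `count`.
#' @param names Indices to compute (default all 14).
#'
#' @return A tibble with columns `index` and `value`.
#' @examples
#' ben4_edge_partition(1, 1) |> compute_index()
#' @export
compute_index <- function(ep, names = index_names()) {
  stopifnot(all(c("deg_a", "deg_b", "count") %in% base::names(ep)))
  tibble(
    index = names,
    value = unname(vapply(names, function(nm) {
      sum(ep$count * edge_weight(nm, ep$deg_a, ep$deg_b))
    }, numeric(1)))
  )
}

#' As-published closed-form polynomial coefficients
#'
#' Coefficients of `value = c_mn*mn + c_m*m + c_n*n + c_0` for each index,
#' transcribed verbatim from the reference derivations (including their
#' 4-decimal rounding and their known inconsistency with the reference
#' edge partition; see [index_discrepancy()]).
#'
#' @return A tibble with columns `index`, `c_mn`, `c_m`, `c_n`, `c_0`.
#' @examples
#' published_coefficients()
#' @export
published_coefficients <- function() {
  purrr::imap_dfr(.ti_published, function(co, nm) {
    tibble(index = nm, c_mn = co[1], c_m = co[2], c_n = co[3], c_0 = co[4])
  })
}

#' As-published index values
#'
#' Evaluates the verbatim closed-form polynomials at unit-cell counts
#' `(m, n)`.
#'
#' @inheritParams ben4_counts
#' @inheritParams compute_index
#'
#' @return A tibble with columns `index`, `m`, `n`, `value`.
#' @examples
#' published_value(10, 10, "M1")
#' @export
published_value <- function(m, n, names = index_names()) {
  check_grid(m, n)
  purrr::map(names, check_index_name)
  vals <- vapply(names, function(nm) {
    co <- .ti_published[[nm]]
    co[1] * m * n + co[2] * m + co[3] * n + co[4]
  }, numeric(1))
  tibble(index = names, m = as.integer(m), n = as.integer(n),
         value = unname(vals))
}

#' Index values for the BeN4(m, n) lattice
#'
#' Convenience wrapper returning canonical and/or as-published values on a
#' grid of `(m, n)` points.
#'
#' @param grid A data frame with columns `m` and `n`, or an integer vector
#'   `i` taken as the diagonal grid `m = n = i`.
#' @inheritParams compute_index
#' @param mode `"canonical"`, `"published"`, or `"both"`.
#' @inheritParams ben4_edge_partition
#'
#' @return A tibble with columns `index`, `m`, `n`, `mode`, `value`.
#' @examples
#' ben4_index(1:3, names = "GA", mode = "published")
#' @export
ben4_index <- function(grid, names = index_names(),
                       mode = c("both", "canonical", "published"),
                       freq33 = NULL) {
  mode <- match.arg(mode)
  grid <- as_grid(grid)
  purrr::pmap_dfr(grid, function(m, n) {
    out <- list()
    if (mode %in% c("both", "canonical")) {
      out$canonical <- compute_index(ben4_edge_partition(m, n, freq33), names) |>
        dplyr::mutate(m = as.integer(m), n = as.integer(n),
                      mode = "canonical", .after = "index")
    }
    if (mode %in% c("both", "published")) {
      out$published <- published_value(m, n, names) |>
        dplyr::mutate(mode = "published", .before = "value")
    }
    dplyr::bind_rows(out)
  })
}

#' Canonical-versus-published discrepancy audit
#'
#' The verbatim closed-form polynomials are not consistent with the
#' reference edge partition (their `n` coefficients differ systematically
#' through the `(3,3)` edge class). This audit quantifies -- without
#' adjudicating -- the disagreement: `difference = canonical - published`.
#'
#' @inheritParams ben4_index
#'
#' @return A tibble with columns `index`, `m`, `n`, `canonical`,
#'   `published`, `difference`.
#' @examples
#' index_discrepancy(1, names = c("M1", "HM"))
#' @export
index_discrepancy <- function(grid, names = index_names(), freq33 = NULL) {
  ben4_index(grid, names, mode = "both", freq33 = freq33) |>
    tidyr::pivot_wider(names_from = "mode", values_from = "value") |>
    dplyr::mutate(difference = .data$canonical - .data$published)
}

# Grid coercion shared by series-producing functions: integer vector i
# means the diagonal m = n = i.
as_grid <- function(grid) {
  if (is.data.frame(grid)) {
    stopifnot(all(c("m", "n") %in% names(grid)))
    grid <- tibble(m = grid$m, n = grid$n)
  } else {
    grid <- tibble(m = grid, n = grid)
  }
  if (nrow(grid) == 0L) {
    abort("`grid` must contain at least one (m, n) point.",
          class = "topoent_bad_grid")
  }
  purrr::pwalk(grid, check_grid)
  grid
}
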