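# Generic simple-graph input path: plain edge lists in, degree partitions
# out. A graph is an ordinary tibble with integer columns `from` and `to`;
# isolated vertices can be declared through the `vertices` attribute-free
# route of supplying them to `vertex_partition()` via degree 0 rows -- by
# default the vertex set is the set of edge endpoints.

#' Validate an edge-list graph
#'
#' Checks that `edges` is a two-column (`from`, `to`) description of an
#' undirected simple graph: positive integer vertex identifiers, no
#' self-loops, no duplicate undirected edges.
#'
#' @param edges A data frame with columns `from` and `to`.
#'
#' @return The validated edge list as a tibble (invisibly usable in pipes).
#' @examples
#' as_edge_list(data.frame(from = c(1, 2), to = c(2, 3)))
#' @export
as_edge_list <- function(edges) {
  if (!is.data.frame(edges) || !all(c("from", "to") %in% names(edges))) {
    abort("`edges` must be a data frame with columns `from` and `to`.",
          class = "topoent_bad_graph")
  }
  from <- edges$from
  to <- edges$to
  ok <- is.numeric(from) && is.numeric(to) &&
    !anyNA(from) && !anyNA(to) &&
    all(from >= 1) && all(to >= 1) &&
    all(from == trunc(from)) && all(to == trunc(to))
  if (!ok) {
    abort("Vertex identifiers must be positive integers.",
          class = "topoent_bad_graph")
  }
  if (any(from == to)) {
    abort("Self-loops are not allowed.", class = "topoent_bad_graph")
  }
  key <- paste(pmin(from, to), pmax(from, to))
  if (anyDuplicated(key)) {
    abort("Duplicate undirected edges are not allowed.",
          class = "topoent_bad_graph")
  }
  tibble(from = as.integer(from), to = as.integer(to))
}

#' Read / write plain-text edge lists
#'
#' One edge per line: two whitespace-separated positive integer vertex
#' identifiers (1-based). Lines starting with `#` are ignored.
#'
#' @param path File path.
#' @param edges An edge-list data frame (columns `from`, `to`).
#'
#' @return `read_edge_list()` returns a validated edge-list tibble;
#'   `write_edge_list()` returns `path` invisibly.
#' @examples
#' f <- tempfile()
#' write_edge_list(make_graph("cycle", 5), f)
#' read_edge_list(f)
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    abort("No edges found in file.", class = "topoent_bad_graph")
  }
  parts <- strsplit(lines, "[[:space:]]+")
  if (any(lengths(parts) != 2L)) {
    abort("Each edge line must contain exactly two vertex identifiers.",
          class = "topoent_bad_graph")
  }
  mat <- suppressWarnings(vapply(parts, as.numeric, numeric(2)))
  if (anyNA(mat)) {
    abort("Vertex identifiers must be numeric.", class = "topoent_bad_graph")
  }
  as_edge_list(tibble(from = mat[1, ], to = mat[2, ]))
}

#' @rdname read_edge_list
#' @export
write_edge_list <- function(edges, path) {
  edges <- as_edge_list(edges)
  writeLines(paste(edges$from, edges$to), path)
  invisible(path)
}

graph_degrees <- function(edges) {
  ends <- c(edges$from, edges$to)
  tab <- table(ends)
  setNames(as.integer(tab), names(tab))
}

#' Degree partitions of an arbitrary simple graph
#'
#' `vertex_partition()` tallies vertex degrees; `edge_partition()` tallies
#' unordered endpoint-degree pairs; `partitions_from_graph()` returns both.
#' Vertices are taken to be the edge endpoints (an edge list cannot declare
#' isolated vertices; they would not affect any degree-based index).
#'
#' @inheritParams as_edge_list
#'
#' @return `vertex_partition()`: tibble (`degree`, `count`);
#'   `edge_partition()`: tibble (`deg_a`, `deg_b`, `count`) with
#'   `deg_a <= deg_b`; `partitions_from_graph()`: list with elements
#'   `vertex` and `edge`.
#' @examples
#' g <- make_graph("star", 5)
#' partitions_from_graph(g)
#' @export
vertex_partition <- function(edges) {
  edges <- as_edge_list(edges)
  deg <- graph_degrees(edges)
  tibble(degree = sort(unique(unname(deg)))) |>
    dplyr::mutate(count = vapply(.data$degree,
                                 function(d) sum(deg == d), integer(1)))
}

#' @rdname vertex_partition
#' @export
edge_partition <- function(edges) {
  edges <- as_edge_list(edges)
  deg <- graph_degrees(edges)
  da <- unname(deg[as.character(edges$from)])
  db <- unname(deg[as.character(edges$to)])
  tibble(deg_a = pmin(da, db), deg_b = pmax(da, db)) |>
    dplyr::count(.data$deg_a, .data$deg_b, name = "count") |>
    dplyr::arrange(.data$deg_a, .data$deg_b)
}

#' @rdname vertex_partition
#' @export
partitions_from_graph <- function(edges) {
  edges <- as_edge_list(edges)
  list(vertex = vertex_partition(edges), edge = edge_partition(edges))
}
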