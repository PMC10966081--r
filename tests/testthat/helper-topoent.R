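# Shared helpers for the suite.

# The (3,3)-class frequency that reconciles the printed polynomials and
# entropy tables with the edge-partition route (the reference tables print
# 4mn - 3n; see the methods vignette).
freq33_reconciling <- function(m, n) 4 * m * n - 4 * n

# Independent entropy oracle: Shannon entropy -sum p*ln(p) of the
# edge-weight distribution p = count*f / sum(count*f), computed without
# the ln(W) - (1/W)*sum(...) rearrangement used by the package.
shannon_edge_entropy <- function(ep, name) {
  f <- rep(edge_weight(name, ep$deg_a, ep$deg_b), times = ep$count)
  p <- f / sum(f)
  -sum(p * log(p))
}

# TRUE if the graph contains an edge joining two degree-1 vertices
# (where the ABC and AZI weights are undefined).
has_pendant_pendant_edge <- function(edges) {
  deg <- table(c(edges$from, edges$to))
  any(deg[as.character(edges$from)] == 1 & deg[as.character(edges$to)] == 1)
}

diag_grid <- function(i = 1:10) tibble::tibble(m = i, n = i)
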