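test_that("entropy matches the direct Shannon-entropy oracle in canonical mode", {
  for (seed in 1:10) {
    g <- make_graph("random", 8 + seed, p = 0.4, seed = seed)
    ep <- edge_partition(g)
    skip_names <- if (has_pendant_pendant_edge(g)) c("ABC", "AZI") else character()
    for (nm in setdiff(index_names(), skip_names)) {
      expect_equal(index_entropy(ep, nm)$entropy,
                   shannon_edge_entropy(ep, nm), tolerance = 1e-12)
    }
  }
})

test_that("uniform edge weights give maximal entropy ln|E|", {
  for (g in list(make_graph("cycle", 6), make_graph("complete", 5))) {
    ep <- edge_partition(g)
    E <- sum(ep$count)
    for (nm in index_names()) {
      expect_equal(index_entropy(ep, nm)$entropy, log(E), tolerance = 1e-12)
    }
  }
})

test_that("entropy is invariant under joint rescaling of weights and normaliser", {
  ep <- ben4_edge_partition(3, 2)
  f <- edge_weight("ReZG2", ep$deg_a, ep$deg_b)
  base <- log(sum(ep$count * f)) -
    sum(ep$count * f * log(f)) / sum(ep$count * f)
  for (c in c(0.1, 2, 37.5)) {
    cf <- c * f
    scaled <- log(sum(ep$count * cf)) -
      sum(ep$count * cf * log(cf)) / sum(ep$count * cf)
    expect_equal(scaled, base, tolerance = 1e-12)
  }
  expect_equal(index_entropy(ep, "ReZG2")$entropy, base, tolerance = 1e-12)
})

test_that("canonical lattice entropy at (1,1) matches the frozen hand value", {
  # ln(31) - (1/31) * (2*2ln2 + 2*3ln3 + 2*6ln6 + 1*9ln9)
  res <- index_entropy(ben4_edge_partition(1, 1), "R1")
  expect_equal(res$W, 31)
  expect_equal(res$entropy, 1.8004, tolerance = 1e-4)
})

test_that("published-mode GA entropy reproduces the reference row", {
  printed <- printed_tables()
  ga_row <- printed[printed$kind == "entropy" & printed$index == "GA", ]
  ours <- ben4_entropy(diag_grid(), names = "GA", mode = "published")
  expect_equal(ours$entropy, ga_row$value[order(ga_row$i)], tolerance = 2e-3)
  expect_equal(ours$entropy[1], 1.7838, tolerance = 2e-3)
  expect_equal(ours$entropy[2], 3.3287, tolerance = 2e-3)
})

test_that("GA entropy is insensitive to the (3,3)-class frequency", {
  # the GA weight on a (3,3) edge is exactly 1, so that class never
  # contributes to the weighted log sum
  for (i in c(1, 4, 9)) {
    a <- ben4_entropy(i, names = "GA", mode = "published")
    b <- ben4_entropy(i, names = "GA", mode = "published",
                      freq33 = function(m, n) 4 * m * n - 4 * n)
    expect_equal(a$entropy, b$entropy, tolerance = 1e-14)
  }
})

test_that("the reconciling (3,3) frequency reproduces every entropy table row", {
  printed <- printed_tables()
  ent <- printed[printed$kind == "entropy", ]
  ours <- ben4_entropy(diag_grid(), mode = "published",
                       freq33 = freq33_reconciling)
  for (nm in unique(ent$index)) {
    ref <- ent[ent$index == nm, ]
    got <- ours[ours$index == nm, ]
    expect_equal(got$entropy[match(ref$i, got$m)], ref$value,
                 tolerance = 2e-3,
                 info = sprintf("entropy row %s", nm))
  }
})

test_that("canonical entropy is bounded by ln of the edge count", {
  for (i in 1:10) {
    E <- ben4_counts(i, i)$edges
    ent <- ben4_entropy(i, mode = "canonical")
    expect_true(all(ent$entropy <= log(E) + 1e-12))
  }
})

test_that("canonical entropy increases along the diagonal grid", {
  ent <- ben4_entropy(1:10, mode = "canonical")
  for (nm in index_names()) {
    series <- ent$entropy[ent$index == nm]
    expect_true(all(diff(series) > 0), info = nm)
  }
})

test_that("entropy input validation", {
  ep <- ben4_edge_partition(1, 1)
  expect_error(index_entropy(ep, "GA", W = -1), class = "topoent_bad_W")
  expect_error(index_entropy(ep, "GA", W = c(1, 2)), class = "topoent_bad_W")
  expect_error(index_entropy(ep, "bogus"), class = "topoent_bad_index")
  one <- entropy_series("GA", 4, mode = "published")
  expect_equal(nrow(one), 1L)
  expect_equal(one$entropy,
               ben4_entropy(4, names = "GA", mode = "published")$entropy)
})
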