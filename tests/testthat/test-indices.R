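test_that("edge weights evaluate their defining formulas", {
  expect_equal(edge_weight("GA", 3, 3), 1)
  expect_equal(edge_weight("ABC", 2, 3), sqrt(3 / 6))
  expect_equal(edge_weight("AZI", 3, 3), (9 / 4)^3)  # cube retained
  expect_equal(edge_weight("M1", 2, 4), 6)
  expect_equal(edge_weight("HM", 3, 4), 49)
  expect_equal(edge_weight("F", 1, 4), 17)
  expect_equal(edge_weight("ReZG3", 2, 3), 30)
  # weights are symmetric in the two degrees
  for (nm in index_names()) {
    expect_equal(edge_weight(nm, 2, 5), edge_weight(nm, 5, 2))
  }
  expect_equal(randic_weight(3, 4, alpha = -1 / 2), 1 / sqrt(12))
  expect_equal(randic_weight(2, 3, alpha = 1), edge_weight("R1", 2, 3))
})

test_that("degenerate and invalid weight inputs are rejected", {
  expect_error(edge_weight("ABC", 1, 1), class = "topoent_degenerate_edge")
  expect_error(edge_weight("AZI", 1, 1), class = "topoent_degenerate_edge")
  expect_error(edge_weight("GA", 0, 2), class = "topoent_bad_degree")
  expect_error(edge_weight("nope", 2, 2), class = "topoent_bad_index")
})

test_that("canonical index values sum count times weight over classes", {
  ep11 <- ben4_edge_partition(1, 1)
  # brute-force sums over the seven edges of the (1,1) lattice
  expect_equal(compute_index(ep11, "M1")$value, 30)
  expect_equal(compute_index(ep11, "R1")$value, 31)
  expect_equal(compute_index(ep11, "HM")$value, 136)
  # regular graph: every GA weight is 1, so GA = |E|
  expect_equal(compute_index(edge_partition(make_graph("complete", 4)),
                             "GA")$value, 6)
})

test_that("Randic exponent 1 and the second Zagreb index coincide", {
  for (seed in 1:20) {
    g <- make_graph("random", 6 + seed, p = 0.3, seed = seed)
    ep <- edge_partition(g)
    expect_equal(compute_index(ep, "R1")$value,
                 compute_index(ep, "M2")$value)
  }
  co <- published_coefficients()
  expect_equal(unlist(co[co$index == "R1", -1]),
               unlist(co[co$index == "M2", -1]))
})

test_that("as-published polynomials reproduce their tabulated values", {
  expect_equal(published_value(10, 10, "M1")$value, 4884)
  expect_equal(published_value(1, 1, "HM")$value, 100)
  expect_equal(published_value(10, 10, "ReZG3")$value, 48552)
  expect_equal(published_value(1, 1, "R1")$value, 22)
  expect_error(published_value(1, 1, "XYZ"), class = "topoent_bad_index")
})

test_that("the discrepancy audit quantifies canonical minus published", {
  d <- index_discrepancy(1, names = c("M1", "HM"))
  m1 <- d[d$index == "M1", ]
  expect_equal(c(m1$canonical, m1$published, m1$difference), c(30, 24, 6))
  hm <- d[d$index == "HM", ]
  expect_equal(c(hm$canonical, hm$published, hm$difference), c(136, 100, 36))
})

test_that("canonical first Zagreb equals the vertex second moment", {
  for (m in 1:20) for (n in 1:20) {
    vp <- ben4_vertex_partition(m, n)
    expect_equal(
      compute_index(ben4_edge_partition(m, n), "M1")$value,
      sum(vp$degree^2 * vp$count)
    )
  }
})

test_that("k-regular graphs satisfy the closed-form index identities", {
  cases <- list(
    list(g = make_graph("cycle", 7), k = 2, E = 7),
    list(g = make_graph("complete", 5), k = 4, E = 10)
  )
  for (cs in cases) {
    ep <- edge_partition(cs$g)
    expect_equal(compute_index(ep, "GA")$value, cs$E)
    expect_equal(compute_index(ep, "ReZG2")$value, cs$E * cs$k / 2)
    for (alpha in c(1, -1, 1 / 2, -1 / 2)) {
      expect_equal(sum(ep$count * randic_weight(ep$deg_a, ep$deg_b, alpha)),
                   cs$E * cs$k^(2 * alpha))
    }
  }
})

test_that("canonical lattice index values increase strictly in m and n", {
  for (nm in index_names()) {
    for (i in 1:5) {
      v   <- compute_index(ben4_edge_partition(i, i), nm)$value
      vm  <- compute_index(ben4_edge_partition(i + 1, i), nm)$value
      vn  <- compute_index(ben4_edge_partition(i, i + 1), nm)$value
      expect_gt(vm, v)
      expect_gt(vn, v)
    }
  }
})

test_that("ben4_index stacks modes and grids tidily", {
  res <- ben4_index(1:3, names = c("GA", "M1"), mode = "both")
  expect_equal(nrow(res), 3 * 2 * 2)
  expect_setequal(unique(res$mode), c("canonical", "published"))
  expect_error(ben4_index(integer(0)), class = "topoent_bad_grid")
})
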