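test_that("build_graph deduplicates edges and drops self-loops", {
  g <- build_graph(rbind(c("A", "B"), c("B", "A"), c("A", "A")))
  expect_equal(igraph::vcount(g), 2L)
  expect_equal(igraph::ecount(g), 1L)

  empty <- build_graph(matrix(character(), 0, 2))
  expect_equal(igraph::vcount(empty), 0L)

  set.seed(1)
  base <- t(combn(LETTERS[1:5], 2))[sample(10, 7), ]
  with_dups <- rbind(base, base[1:2, ], base[3, 2:1])
  expect_equal(igraph::ecount(build_graph(with_dups)), 7L)

  iso <- build_graph(rbind(c("A", "B")), nodes = c("Z", "A"))
  expect_setequal(igraph::V(iso)$name, c("A", "B", "Z"))

  expect_error(build_graph(rbind(c("A", ""))), "row 1")
})

test_that("main_component returns the largest component with lexicographic ties", {
  g <- build_graph(rbind(c("a", "b"), c("b", "c"), c("c", "a")),
                   nodes = c("x", "y"))
  mc <- main_component(g)
  expect_setequal(igraph::V(mc)$name, c("a", "b", "c"))
  expect_equal(igraph::ecount(mc), 3L)

  connected <- generate_scale_free_network(30, 2, seed = 1)
  expect_equal(igraph::vcount(main_component(connected)), 30L)

  two_k3 <- build_graph(rbind(c("b", "c"), c("c", "d"), c("d", "b"),
                              c("a", "e"), c("e", "f"), c("f", "a")))
  expect_setequal(igraph::V(main_component(two_k3))$name, c("a", "e", "f"))

  expect_error(main_component(build_graph(matrix(character(), 0, 2))),
               "empty")
})

test_that("centralities match hand-computed values on canonical graphs", {
  path3 <- build_graph(rbind(c("A", "B"), c("B", "C")))
  ct <- compute_centralities(path3)
  expect_equal(ct$betweenness[ct$node == "B"], 1.0)
  expect_equal(ct$betweenness[ct$node == "A"], 0.0)

  star <- build_graph(cbind("c", paste0("leaf", 1:4)))
  cs <- compute_centralities(star)
  expect_equal(cs$closeness[cs$node == "c"], 1.0)
  expect_equal(cs$closeness[cs$node == "leaf1"], 4 / 7)
  expect_equal(cs$betweenness[cs$node == "c"], 1.0)

  # all centralities equal across a cycle
  cyc <- build_graph(cbind(paste0("n", 1:6), paste0("n", c(2:6, 1))))
  cc <- compute_centralities(cyc)
  expect_equal(diff(range(cc$degree)), 0)
  expect_equal(diff(range(cc$betweenness)), 0)
  expect_equal(diff(range(cc$closeness)), 0)

  disconnected <- build_graph(rbind(c("A", "B")), nodes = "Z")
  expect_error(compute_centralities(disconnected), "connected")
})

test_that("Brandes centralities equal geodesic-enumeration and igraph oracles", {
  for (seed in 1:10) {
    n <- sample(6:12, 1)
    g <- random_connected_graph(n, p = 0.3, seed = seed)
    got <- compute_centralities(g)
    want <- oracle_centralities(g)
    want <- want[match(got$node, want$node), ]
    expect_equal(got$betweenness, want$betweenness, tolerance = 1e-9)
    expect_equal(got$closeness, want$closeness, tolerance = 1e-9)
    expect_identical(got$degree, want$degree)

    norm <- (n - 1) * (n - 2) / 2
    ib <- igraph::betweenness(g) / norm
    expect_equal(got$betweenness, unname(ib[got$node]), tolerance = 1e-9)
    ic <- igraph::closeness(g, normalized = TRUE)
    expect_equal(got$closeness, unname(ic[got$node]), tolerance = 1e-9)
  }
})

test_that("centralities are invariant under node relabelling", {
  g <- random_connected_graph(15, p = 0.25, seed = 3)
  ct <- compute_centralities(g)
  relabel <- setNames(sprintf("x%02d", sample(15)), igraph::V(g)$name)
  g2 <- g
  igraph::V(g2)$name <- unname(relabel[igraph::V(g)$name])
  ct2 <- compute_centralities(g2)
  ct2 <- ct2[match(unname(relabel[ct$node]), ct2$node), ]
  expect_equal(ct$betweenness, ct2$betweenness, tolerance = 1e-12)
  expect_equal(ct$closeness, ct2$closeness, tolerance = 1e-12)
  expect_identical(ct$degree, ct2$degree)
})

test_that("degree_distribution_table counts nodes per degree", {
  k3 <- build_graph(rbind(c("a", "b"), c("b", "c"), c("c", "a")))
  expect_identical(degree_distribution_table(k3),
                   data.frame(k = 2L, count = 3L))
  path3 <- build_graph(rbind(c("A", "B"), c("B", "C")))
  expect_identical(degree_distribution_table(path3),
                   data.frame(k = 1:2, count = c(2L, 1L)))
  star5 <- build_graph(cbind("c", paste0("l", 1:4)))
  expect_identical(degree_distribution_table(star5),
                   data.frame(k = c(1L, 4L), count = c(4L, 1L)))

  # handshake lemma on a random graph
  g <- generate_scale_free_network(200, 3, seed = 5)
  dist <- degree_distribution_table(g)
  expect_equal(sum(dist$k * dist$count), 2 * igraph::ecount(g))
})

test_that("fit_power_law recovers exact log-linear data and flags scale-free graphs", {
  k <- c(1, 2, 4, 8)
  exact <- data.frame(k = k, count = 10 * k^(-0.5))
  fit <- fit_power_law(exact)
  expect_equal(fit$a, 10, tolerance = 1e-9)
  expect_equal(fit$b, -0.5, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1.0, tolerance = 1e-9)
  expect_equal(abs(fit$correlation), 1.0, tolerance = 1e-9)

  two <- fit_power_law(data.frame(k = c(2, 7), count = c(9, 3)))
  expect_equal(two$r_squared, 1.0, tolerance = 1e-12)

  pa <- generate_scale_free_network(2000, 2, seed = 13)
  pfit <- fit_power_law(degree_distribution_table(pa))
  expect_lt(pfit$b, -1)
  expect_equal(pfit$r_squared, pfit$correlation^2, tolerance = 1e-12)

  expect_error(fit_power_law(data.frame(k = 1, count = 5)), "two usable")
})
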