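ring_graph <- function(n) {
  ids <- paste0("v", seq_len(n))
  co_network(ids, tibble::tibble(from = ids, to = ids[c(2:n, 1)]))
}

complete_graph <- function(n) {
  ids <- paste0("v", seq_len(n))
  pairs <- t(utils::combn(ids, 2))
  co_network(ids, tibble::tibble(from = pairs[, 1], to = pairs[, 2]))
}

test_that("global properties match hand computations", {
  k4 <- global_properties(complete_graph(4))
  expect_equal(k4$density, 1)
  expect_equal(k4$transitivity, 1)
  expect_equal(k4$average_path_length, 1)

  # path a-b-c: transitivity 0, APL (1+1+2)/3
  path3 <- co_network(c("a", "b", "c"),
                      tibble::tibble(from = c("a", "b"), to = c("b", "c")))
  gp <- global_properties(path3)
  expect_equal(gp$transitivity, 0)
  expect_equal(gp$average_path_length, 4 / 3)

  # two disjoint triangles: 2-community modularity = 2*(3/6 - (6/12)^2) = 0.5
  tri2 <- co_network(letters[1:6], tibble::tibble(
    from = c("a", "b", "c", "d", "e", "f"),
    to   = c("b", "c", "a", "e", "f", "d")))
  gp <- global_properties(tri2)
  expect_equal(gp$modularity, 0.5)
  expect_equal(gp$reachable_fraction, 2 * 3 / (6 * 5) * 2)

  expect_error(global_properties(co_network("a")), "two nodes")
})

test_that("properties respond monotonically to added edges", {
  net <- random_network(15, 0.2, seed = 2)
  gp <- global_properties(net)
  non_edges <- setdiff(
    apply(t(utils::combn(net$nodes, 2)), 1, paste, collapse = "|"),
    paste(net$edges$from, net$edges$to, sep = "|"))
  add <- strsplit(non_edges[1], "|", fixed = TRUE)[[1]]
  net2 <- co_network(net$nodes, dplyr::bind_rows(
    net$edges, tibble::tibble(from = add[1], to = add[2], sign = 1L, weight = 1)))
  gp2 <- global_properties(net2)
  expect_gt(gp2$density, gp$density)
  deg1 <- igraph::degree(as_igraph(net))
  deg2 <- igraph::degree(as_igraph(net2))
  expect_true(all(deg2[names(deg1)] >= deg1))
})

test_that("bootstrap at full size reproduces the full-graph properties", {
  net <- random_network(20, 0.25, seed = 4)
  full <- global_properties(net)
  boot <- bootstrap_properties(net, subgraph_size = 20, n_iter = 20, seed = 1)
  expect_true(all(boot$density == full$density))
  expect_true(all(boot$transitivity == full$transitivity))
  expect_true(all(boot$modularity == full$modularity))

  kboot <- bootstrap_properties(complete_graph(12), 5, n_iter = 20, seed = 2)
  expect_true(all(kboot$density == 1))
})

test_that("bootstrap distributions are deterministic and centred correctly", {
  net <- random_network(20, 0.3, seed = 6)
  b1 <- bootstrap_properties(net, 10, n_iter = 100, seed = 3)
  b2 <- bootstrap_properties(net, 10, n_iter = 100, seed = 3)
  expect_identical(b1, b2)

  # independent large-replicate oracle for mean induced-subgraph density:
  # plain loop over igraph, no package bootstrap code
  g <- as_igraph(net)
  withr::with_seed(99, {
    dens <- replicate(5000, {
      sub <- igraph::induced_subgraph(g, sample(20, 10))
      2 * igraph::ecount(sub) / (10 * 9)
    })
  })
  se <- sd(b1$density) / sqrt(nrow(b1))
  expect_lt(abs(mean(b1$density) - mean(dens)), 3 * se + 3 * sd(dens) / sqrt(5000))
})

test_that("zone comparison applies one Holm family per metric", {
  withr::with_seed(7, {
    boots <- list(
      A = tibble::tibble(density = runif(100)),
      B = tibble::tibble(density = runif(100)),
      C = tibble::tibble(density = runif(100) + 5))
  })
  res <- compare_zones(boots, "density")
  expect_equal(nrow(res), 3)
  ab <- res[res$group_a == "A" & res$group_b == "B", ]
  expect_gt(ab$p_holm, 0.05)                     # identical distributions
  ac <- res[res$group_a == "A" & res$group_b == "C", ]
  expect_lt(ac$p_holm, 1e-10)                    # disjoint supports

  res2 <- compare_zones(boots[1:2], "density")
  expect_equal(res2$p_holm, res2$p_raw)          # two zones: Holm is identity
  expect_error(compare_zones(boots[1], "density"), "two zones")
})

test_that("centralities match hand values on the 5-leaf star and C4", {
  star <- co_network(c("hub", paste0("l", 1:5)),
                     tibble::tibble(from = "hub", to = paste0("l", 1:5)))
  ct <- centralities(star)
  hub <- ct[ct$node == "hub", ]
  expect_equal(hub$degree, 5)
  expect_equal(hub$betweenness, 10)   # all C(5,2) leaf pairs
  expect_equal(hub$eigenvector, 1)

  ring <- centralities(ring_graph(4))
  expect_equal(length(unique(ring$betweenness)), 1)
  expect_error(centralities(co_network(character(0))), "Empty")
})

test_that("centralities agree with brute-force oracles on a random graph", {
  net <- random_network(12, 0.3, seed = 8)
  ct <- centralities(net)
  adj <- matrix(FALSE, 12, 12, dimnames = list(net$nodes, net$nodes))
  adj[cbind(net$edges$from, net$edges$to)] <- TRUE
  adj <- adj | t(adj)
  expect_equal(ct$degree, unname(rowSums(adj)))
  expect_equal(ct$betweenness, oracle_betweenness(adj), tolerance = 1e-10)
  expect_equal(ct$closeness, oracle_closeness(adj), tolerance = 1e-10)
  expect_equal(ct$eigenvector, oracle_eigenvector(adj), tolerance = 1e-6)
})

test_that("hub detection uses the interpolated 95% quantile, strictly", {
  reg <- find_hubs(ring_graph(10))     # 2-regular: nobody exceeds the quantile
  expect_equal(nrow(reg$hubs), 0)

  # one dominant node among degree-1 nodes: a 10-leaf star plus 9 disjoint
  # edges gives degrees (10, 1 x 28); the interpolated 95% quantile sits at
  # 1, and only the centre strictly exceeds it
  nodes <- c("h", paste0("l", 1:10), paste0("p", 1:9), paste0("q", 1:9))
  net <- co_network(nodes, dplyr::bind_rows(
    tibble::tibble(from = "h", to = paste0("l", 1:10)),
    tibble::tibble(from = paste0("p", 1:9), to = paste0("q", 1:9))))
  hubs <- find_hubs(net)
  deg <- as.numeric(igraph::degree(as_igraph(net)))
  expect_equal(hubs$degree_threshold,
               as.numeric(quantile(deg, 0.95, type = 7)))
  expect_equal(hubs$hubs$node, "h")
  expect_equal(hubs$hubs$degree, 10)
})

test_that("planted hubs are recovered from noisy graphs", {
  found <- vapply(1:10, function(s) {
    net <- withr::with_seed(s, {
      n <- 50
      ids <- sprintf("n%02d", 1:n)
      hubs <- ids[1:3]
      spokes <- lapply(hubs, function(h)
        tibble::tibble(from = h, to = sample(setdiff(ids, h), 20)))
      noise_pairs <- t(utils::combn(ids[4:n], 2))
      keep <- runif(nrow(noise_pairs)) < 0.03
      edges <- dplyr::distinct(dplyr::bind_rows(
        dplyr::bind_rows(spokes),
        tibble::tibble(from = noise_pairs[keep, 1], to = noise_pairs[keep, 2])))
      # canonicalise to avoid duplicate unordered pairs
      edges <- dplyr::distinct(tibble::tibble(
        from = pmin(edges$from, edges$to), to = pmax(edges$from, edges$to)))
      co_network(ids, edges)
    })
    all(c("n01", "n02", "n03") %in% find_hubs(net)$hubs$node)
  }, logical(1))
  expect_gte(mean(found), 0.9)
})

test_that("hub set size respects the quantile bound", {
  for (s in 1:5) {
    net <- random_network(40, 0.15, seed = s)
    hubs <- find_hubs(net)
    deg <- igraph::degree(as_igraph(net))
    ties <- sum(deg == hubs$degree_threshold)
    expect_lte(nrow(hubs$hubs), ceiling(0.05 * 40) + ties)
  }
})
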