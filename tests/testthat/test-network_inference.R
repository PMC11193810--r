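test_that("CLR rows are centered and constant compositions map to zero", {
  tab <- esv_table(matrix(4, 3, 2))
  x <- clr_transform(tab)
  expect_equal(max(abs(x)), 0)

  withr::with_seed(1, tab <- esv_table(matrix(rpois(60, 8), 6, 10)))
  x <- clr_transform(tab)
  expect_lt(max(abs(rowSums(x))), 1e-9)
  expect_equal(dim(x), c(10, 6))   # samples x taxa

  # with no pseudocount, CLR is exactly depth-invariant on positive data
  pos <- matrix(c(2, 5, 9, 1, 7, 3), 3, 2)
  x1 <- clr_transform(esv_table(pos), pseudocount = 0)
  x2 <- clr_transform(esv_table(pos * 50), pseudocount = 0)
  expect_equal(x1, x2)
})

test_that("the penalty grid starts at the empty-model threshold", {
  withr::with_seed(2, x <- matrix(rnorm(200), 20, 10))
  grid <- lambda_grid(x)
  expect_length(grid, 30)
  expect_true(all(diff(grid) < 0))
  net_max <- mb_neighborhood(x, grid[1] * 1.0001)
  expect_equal(nrow(net_max$edges), 0)
  expect_equal(grid[30] / grid[1], 0.01, tolerance = 1e-10)
})

test_that("neighborhood selection finds a planted regression edge", {
  hits <- vapply(1:100, function(s) {
    withr::with_seed(s, {
      x1 <- rnorm(100); x2 <- rnorm(100)
      x3 <- x1 + rnorm(100, sd = 0.3)
    })
    x <- cbind(x1, x2, x3)
    net <- mb_neighborhood(x, lambda = 0.2)
    e <- paste(net$edges$from, net$edges$to)
    ("x1 x3" %in% e) && !("x1 x2" %in% e)
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("edge sets grow nearly monotonically along the penalty path", {
  # exact nesting is a lasso-path idealisation: coefficients can leave the
  # active set as the penalty drops, so allow a small violation fraction
  st <- small_study(seed = 3, n_samples = 40, n_taxa = 15)
  zone <- split_by_zone(st$table, st$metadata)[[1]]
  x <- clr_transform(zone)
  grid <- lambda_grid(x, n_lambda = 10)
  prev <- NULL
  counts <- integer(0)
  for (lam in grid) {
    net <- mb_neighborhood(x, lam)
    edges <- paste(net$edges$from, net$edges$to)
    counts <- c(counts, length(edges))
    if (!is.null(prev) && length(prev)) {
      expect_lte(sum(!prev %in% edges), max(1, 0.1 * length(prev)))
    }
    prev <- edges
  }
  expect_true(all(diff(counts) >= 0))   # densities grow as lambda shrinks
})

test_that("edges recover planted structure better with more data", {
  jacc <- vapply(c(30, 300), function(n) {
    spec <- precision_spec(12, "band", seed = 5)
    Om <- make_precision(spec)
    z <- zone_spec("Af", n, precision = spec, zero_inflation = 0.05)
    counts <- simulate_counts(Om, z, seed = 7)
    rownames(counts) <- sprintf("t%02d", 1:12)
    x <- clr_transform(esv_table(counts))
    net <- mb_neighborhood(x, lambda = 0.25)
    truth <- attr(Om, "support")
    est <- matrix(FALSE, 12, 12, dimnames = dimnames(truth))
    if (nrow(net$edges)) {
      rn <- rownames(counts)
      est[cbind(match(net$edges$from, rn), match(net$edges$to, rn))] <- TRUE
      est <- est | t(est)
    }
    ut <- upper.tri(truth)
    inter <- sum(est[ut] & truth[ut])
    union <- sum(est[ut] | truth[ut])
    if (union) inter / union else 0
  }, numeric(1))
  expect_gt(jacc[2], 0)
  expect_gte(jacc[2], jacc[1])
})

test_that("StARS is deterministic, bounded, and honours the beta = 0 limit", {
  st <- small_study(seed = 11, n_samples = 30, n_taxa = 12)
  x <- clr_transform(split_by_zone(st$table, st$metadata)[[1]])
  grid <- lambda_grid(x, n_lambda = 8)
  a <- stars_select(x, grid, beta = 0.05, n_subsamples = 10, seed = 5)
  b <- stars_select(x, grid, beta = 0.05, n_subsamples = 10, seed = 5)
  expect_identical(a$network$edges, b$network$edges)
  expect_identical(a$path$instability, b$path$instability)

  expect_true(all(a$path$instability >= 0 & a$path$instability <= 0.5))
  expect_true(all(diff(a$path$instability_monotone) >= 0))
  expect_gte(a$network$stars_instability, 0)

  z <- suppressWarnings(stars_select(x, grid, beta = 0, n_subsamples = 10,
                                     seed = 5))
  # the zero-instability limit keeps only penalties where subsampled graphs
  # never disagree; on structured data that collapses to the empty model at
  # the top of the grid
  expect_equal(z$network$lambda_selected, max(grid))
  expect_equal(nrow(z$network$edges), 0)
})

test_that("StARS on pure noise returns a very sparse network", {
  withr::with_seed(21, x <- matrix(rnorm(60 * 20), 60, 20))
  fit <- stars_select(x, beta = 0.01, n_subsamples = 10, seed = 2)
  n_pairs <- choose(20, 2)
  expect_lte(nrow(fit$network$edges), 0.05 * n_pairs)
})

test_that("scale-free fit is exact on an exact power law and degrades on ER", {
  # freq(d) proportional to d^-2, exactly, over six degrees
  deg <- rep(1:6, times = 3600 / (1:6)^2)
  fit <- scale_free_fit(deg)
  expect_gte(fit$r_squared, 0.99)
  expect_equal(fit$slope, -2, tolerance = 1e-6)

  withr::with_seed(31, g <- igraph::sample_gnp(500, 0.02))
  er <- scale_free_fit(as.numeric(igraph::degree(g)))
  expect_lt(er$r_squared, fit$r_squared - 0.05)

  expect_error(scale_free_fit(rep(4, 50)), "five distinct")
})

test_that("abundance-degree correlation hits its analytic extremes", {
  # lollipop ladder: node k joins every node with larger abundance, so degree
  # rank equals abundance rank exactly -> rho = 1
  n <- 8
  counts <- matrix(0, n, 2, dimnames = list(paste0("t", 1:n), c("s1", "s2")))
  counts[, 1] <- 2^(1:n)   # strictly increasing abundance
  counts[, 2] <- 1
  tab <- esv_table(counts)
  ord <- paste0("t", 1:n)
  # threshold graph: connect i-j (i<j) iff i+j > n, giving strictly
  # increasing degrees 1, 1, 2, 3, ..., n-1 along the abundance order
  pairs <- t(utils::combn(seq_len(n), 2))
  keep <- rowSums(pairs) > n
  net <- co_network(ord, tibble::tibble(from = ord[pairs[keep, 1]],
                                        to = ord[pairs[keep, 2]]))
  deg <- sapply(ord, function(nd) sum(net$edges$from == nd | net$edges$to == nd))
  rho <- abundance_degree_correlation(tab, net)
  expect_equal(rho, suppressWarnings(
    cor(rowSums(counts), deg, method = "spearman")))
  expect_gt(rho, 0.9)

  # reversing the abundance order flips the sign
  counts_rev <- counts
  counts_rev[, 1] <- rev(counts[, 1])
  expect_equal(abundance_degree_correlation(esv_table(counts_rev), net), -rho)

  expect_warning(abundance_degree_correlation(tab, co_network(ord)), "Constant")
  expect_error(abundance_degree_correlation(tab[1:3, ], net), "absent")
})

test_that("shuffled degrees decorrelate from abundance", {
  ok <- vapply(1:20, function(s) {
    withr::with_seed(s, {
      abund <- rlnorm(500)
      deg <- sample(rpois(500, 5) + 1)
    })
    abs(suppressWarnings(cor(abund, deg, method = "spearman"))) < 0.1
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("negative edge fraction is a direct count", {
  net <- toy_network()   # 1 of 3 edges negative
  expect_equal(negative_edge_fraction(net), 1 / 3)

  all_pos <- co_network(c("a", "b"), tibble::tibble(from = "a", to = "b"))
  expect_equal(negative_edge_fraction(all_pos), 0)

  big <- random_network(40, 0.2, seed = 9)
  expect_equal(negative_edge_fraction(big), mean(big$edges$sign == -1L))
  expect_error(negative_edge_fraction(co_network("a")), "no edges")
})
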