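test_that("alpha indices match their defining formulas", {
  expect_equal(shannon(c(10, 10, 10, 10)), log(4))
  expect_equal(shannon(7), 0)
  p <- (1:4) / 10
  expect_equal(shannon(1:4), -sum(p * log(p)))

  expect_equal(simpson(5), 0)
  expect_equal(simpson(c(1, 1)), 0.5)
  expect_equal(simpson(1:4), 1 - sum(p^2))

  expect_equal(chao1(c(3, 4, 5)), 3)              # no singletons/doubletons
  expect_equal(chao1(c(1, 1, 1, 2, 5)), 6.5)      # 5 + 3*2/(2*2)
  expect_equal(chao1(rep(2, 10)), 10)             # F1 = 0 -> S_obs

  expect_error(shannon(c(0, 0)), "positive")
  expect_error(chao1(numeric(0)), "positive")
})

test_that("alpha indices ignore appended zero-count taxa", {
  x <- c(4, 1, 7, 2)
  for (f in list(shannon, simpson, chao1)) {
    expect_equal(f(c(x, 0, 0, 0)), f(x))
  }
})

test_that("chao1 agrees with vegan's bias-corrected estimator", {
  withr::with_seed(5, x <- rpois(50, 2))
  expect_equal(chao1(x), unname(vegan::estimateR(x)["S.chao1"]))
})

test_that("Bray-Curtis matches hand computation and stays in [0, 1]", {
  tab <- esv_table(matrix(c(2, 1, 0, 0, 1, 3), 3, 2,
                          dimnames = list(letters[1:3], c("x", "y"))))
  d <- bray_curtis(tab)
  expect_equal(d["x", "y"], 5 / 7)

  same <- esv_table(matrix(c(1, 2, 1, 2), 2, 2))
  expect_equal(max(bray_curtis(same)), 0)
  disjoint <- esv_table(matrix(c(3, 0, 0, 4), 2, 2))
  expect_equal(bray_curtis(disjoint)[1, 2], 1)

  withr::with_seed(9, m <- matrix(rpois(80, 3), 8, 10))
  m[, colSums(m) == 0] <- 1
  d <- bray_curtis(esv_table(m))
  expect_true(all(d >= 0 & d <= 1))
  # full-matrix check against the defining formula
  for (i in 1:3) {
    for (j in 4:6) {
      expect_equal(d[i, j], oracle_bray_curtis(m[, i], m[, j]))
    }
  }

  bad <- esv_table(matrix(c(1, 0, 0, 0, 0, 0), 2, 3))
  expect_error(bray_curtis(bad), "All-zero samples")
})

test_that("Vincenty distances: zero, equatorial arc, symmetry", {
  expect_equal(vincenty_km(10, 20, 10, 20), 0)
  expect_equal(vincenty_km(0, 0, 0, 1), 111.3195, tolerance = 1e-6)
  withr::with_seed(13, {
    lat <- runif(100, -89, 89); lon <- runif(100, -180, 180)
    lat2 <- runif(100, -89, 89); lon2 <- runif(100, -180, 180)
  })
  expect_equal(vincenty_km(lat, lon, lat2, lon2),
               vincenty_km(lat2, lon2, lat, lon))
})

test_that("Mantel correlation is exact under identity and affine maps", {
  withr::with_seed(2, m <- matrix(runif(36), 6, 6))
  d <- dist_matrix((m + t(m)) / 2 * (1 - diag(6)))
  r_same <- mantel_test(d, d, exact = TRUE)
  expect_equal(r_same$r, 1)
  aff <- dist_matrix(unclass(d) * 3.7)   # positive affine transform of distances
  expect_equal(mantel_test(d, aff, exact = TRUE)$r, 1)
  expect_error(mantel_test(d, dist_matrix(matrix(0, 6, 6))), "Constant")
})

test_that("exact Mantel p equals independent exhaustive enumeration", {
  for (n in 4:5) {
    withr::with_seed(n, {
      m1 <- matrix(runif(n * n), n, n)
      m2 <- matrix(runif(n * n), n, n)
    })
    d1 <- dist_matrix((m1 + t(m1)) / 2 * (1 - diag(n)))
    d2 <- dist_matrix((m2 + t(m2)) / 2 * (1 - diag(n)))
    got <- mantel_test(d1, d2, exact = TRUE)
    expect_equal(got$p_value, oracle_mantel_p(unclass(d1), unclass(d2)))
    expect_equal(got$n_permutations, factorial(n))
  }
})

test_that("sampled Mantel p uses the add-one convention and matches vegan's r", {
  withr::with_seed(8, m <- matrix(runif(144), 12, 12))
  d1 <- dist_matrix((m + t(m)) / 2 * (1 - diag(12)))
  withr::with_seed(9, m2 <- matrix(runif(144), 12, 12))
  d2 <- dist_matrix((m2 + t(m2)) / 2 * (1 - diag(12)))
  got <- mantel_test(d1, d2, n_permutations = 199, seed = 1, exact = FALSE)
  expect_gte(got$p_value, 1 / 200)
  expect_lte(got$p_value, 1)
  veg <- vegan::mantel(as.dist(d1), as.dist(d2), permutations = 0)
  expect_equal(got$r, unname(veg$statistic))
})

test_that("NMDS embeds exactly embeddable configurations", {
  d3 <- dist_matrix(matrix(1, 3, 3) - diag(3))
  fit <- nmds_ordination(d3, k = 2, n_starts = 5, seed = 1)
  expect_lte(fit$stress, 1e-6)

  withr::with_seed(4, pts <- matrix(rnorm(20), 10, 2))
  d <- dist_matrix(as.matrix(dist(pts)))
  fit <- nmds_ordination(d, k = 2, n_starts = 10, seed = 2)
  expect_lte(fit$stress, 1e-3)

  # stress depends only on dissimilarity ranks
  fit2 <- nmds_ordination(dist_matrix(unclass(d) * 2), k = 2, n_starts = 10,
                          seed = 2)
  expect_equal(fit2$stress, fit$stress, tolerance = 1e-6)

  expect_error(nmds_ordination(d3, k = 3), "smaller")
})

test_that("PERMANOVA detects planted structure and respects relabelling", {
  withr::with_seed(6, {
    g1 <- matrix(rnorm(20, 0), 10, 2)
    g2 <- matrix(rnorm(20, 25), 10, 2)
  })
  d <- dist_matrix(as.matrix(dist(rbind(g1, g2))))
  groups <- rep(c("a", "b"), each = 10)
  res <- permanova(d, groups, n_permutations = 199, seed = 3)
  expect_gt(res$r_squared, 0.9)
  expect_equal(res$p_value, 1 / 200, tolerance = 1e-12)

  # permuting labels and matrix identically leaves pseudo-F unchanged
  perm <- sample(20)
  res2 <- permanova(dist_matrix(unclass(d)[perm, perm]), groups[perm],
                    n_permutations = 199, seed = 3)
  expect_equal(res2$pseudo_f, res$pseudo_f)

  expect_error(permanova(d, rep("a", 20)), "two groups")
})

test_that("PERMANOVA R-squared is near its null expectation on noise", {
  withr::with_seed(15, pts <- matrix(rnorm(60), 30, 2))
  d <- dist_matrix(as.matrix(dist(pts)))
  withr::with_seed(16, groups <- sample(rep(c("a", "b", "c"), each = 10)))
  res <- permanova(d, groups, n_permutations = 99, seed = 4)
  expect_equal(res$r_squared, 2 / 29, tolerance = 0.15)  # (g-1)/(n-1) +- noise
  expect_gt(res$p_value, 0.01)   # no planted structure: far from the floor
})

test_that("pairwise Wilcoxon + Holm behaves per the step-down definition", {
  expect_equal(holm_adjust(c(0.01, 0.04, 0.03)), c(0.03, 0.06, 0.06))

  withr::with_seed(18, {
    values <- c(rnorm(10), rnorm(10), rnorm(10))
    groups <- rep(c("a", "b", "c"), each = 10)
  })
  res <- pairwise_wilcoxon_holm(values, groups)
  expect_equal(nrow(res), 3)
  expect_true(all(res$p_holm >= res$p_raw))

  res1 <- pairwise_wilcoxon_holm(values[1:20], groups[1:20])
  expect_equal(res1$p_holm, res1$p_raw)      # single pair: Holm is identity

  expect_warning(
    pairwise_wilcoxon_holm(c(1, 2, 3, 1), c("a", "a", "a", "b")),
    "Skipping")
  expect_error(pairwise_wilcoxon_holm(1:3, rep("a", 3)), "two groups")
})
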