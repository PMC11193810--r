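# Shared fixtures: tiny studies and graphs built in code at test time.

tiny_table <- function() {
  esv_table(matrix(c(1, 0, 2, 3, 0, 5), nrow = 3, byrow = TRUE,
                   dimnames = list(paste0("esv", 1:3), c("s1", "s2"))))
}

# small labelled multi-zone study for filter/pipeline tests
small_study <- function(seed = 42, n_samples = c(12, 10, 8), n_taxa = 25) {
  codes <- c("Af", "BWh", "Cfb")[seq_along(n_samples)]
  zones <- lapply(seq_along(codes), function(i) {
    zone_spec(codes[i], n_samples = n_samples[i],
              precision = precision_spec(n_taxa = n_taxa, topology = "hub",
                                         hubs_count = 3, seed = i),
              bbox = c(-10 + 20 * i, 20 * i, -30, 30))
  })
  make_study(zones, seed = seed)
}

# deterministic toy signed network
toy_network <- function() {
  co_network(nodes = c("a", "b", "c", "d"),
             edges = tibble::tibble(from = c("a", "a", "b"),
                                    to = c("b", "c", "c"),
                                    sign = c(1L, -1L, 1L),
                                    weight = c(0.5, 0.2, 0.1)))
}

random_network <- function(n_nodes, p_edge, seed = 1) {
  withr::with_seed(seed, {
    nodes <- sprintf("n%03d", seq_len(n_nodes))
    pairs <- t(utils::combn(nodes, 2))
    keep <- stats::runif(nrow(pairs)) < p_edge
    co_network(nodes, tibble::tibble(
      from = pairs[keep, 1], to = pairs[keep, 2],
      sign = sample(c(-1L, 1L), sum(keep), replace = TRUE),
      weight = stats::runif(sum(keep))))
  })
}

# precision/recall of an inferred network against a support matrix
edge_recovery <- function(net, support) {
  ids <- rownames(support)
  est <- matrix(FALSE, nrow(support), ncol(support), dimnames = dimnames(support))
  if (nrow(net$edges)) {
    est[cbind(net$edges$from, net$edges$to)] <- TRUE
    est <- est | t(est)
  }
  ut <- upper.tri(support)
  tp <- sum(est[ut] & support[ut])
  fp <- sum(est[ut] & !support[ut])
  fn <- sum(!est[ut] & support[ut])
  c(precision = if (tp + fp) tp / (tp + fp) else 0,
    recall = if (tp + fn) tp / (tp + fn) else 0)
}
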