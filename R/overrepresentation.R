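#' Taxon-pair edge counts at one rank
#'
#' For every unordered pair of taxon labels at the chosen rank — including
#' same-taxon pairs (A, A) and the `Unassigned` category — counts the node
#' pairs carrying that label pair (`K`) and the realized edges among them
#' (`k`). The totals `N = n_nodes*(n_nodes-1)/2` and `n = n_edges`
#' partition exactly: `sum(K) = N` and `sum(k) = n`.
#'
#' @param net A [co_network].
#' @param taxonomy Tibble with `esv_id` and the rank column, covering every
#'   node.
#' @param rank One of kingdom, phylum, class, order, family, genus,
#'   species.
#' @return Tibble: `taxon_a`, `taxon_b` (lexically ordered), `possible_pairs`
#'   (K), `observed_edges` (k), with attributes `total_pairs` (N) and
#'   `total_edges` (n).
#' @export
taxon_pair_counts <- function(net, taxonomy, rank = "phylum") {
  net <- as_co_network(net)
  rank <- match.arg(rank, taxonomy_rank_names())
  taxonomy <- as_tibble(taxonomy)
  missing <- setdiff(net$nodes, taxonomy$esv_id)
  if (length(missing)) {
    abort(paste0("Missing taxonomy for nodes: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  lab <- taxonomy[[rank]][match(net$nodes, taxonomy$esv_id)]
  lab[is.na(lab)] <- UNASSIGNED
  n_nodes <- length(net$nodes)
  N <- n_nodes * (n_nodes - 1) / 2
  n_edges <- nrow(net$edges)

  tab <- table(lab)
  levs <- names(tab)
  cnt <- as.numeric(tab)
  # K for every unordered label pair, incl. same-label pairs
  grid <- which(upper.tri(matrix(0, length(levs), length(levs)), diag = TRUE),
                arr.ind = TRUE)
  pairs <- tibble(
    taxon_a = pmin(levs[grid[, 1]], levs[grid[, 2]]),
    taxon_b = pmax(levs[grid[, 1]], levs[grid[, 2]]),
    possible_pairs = ifelse(grid[, 1] == grid[, 2],
                            cnt[grid[, 1]] * (cnt[grid[, 1]] - 1) / 2,
                            cnt[grid[, 1]] * cnt[grid[, 2]]))
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  obs <- if (n_edges) {
    la <- lab[match(net$edges$from, net$nodes)]
    lb <- lab[match(net$edges$to, net$nodes)]
    tapply(rep(1L, n_edges), key(la, lb), sum)
  } else {
    integer(0)
  }
  pairs$observed_edges <- as.numeric(obs[key(pairs$taxon_a, pairs$taxon_b)])
  pairs$observed_edges[is.na(pairs$observed_edges)] <- 0
  pairs <- arrange(pairs, .data$taxon_a, .data$taxon_b)
  attr(pairs, "total_pairs") <- N
  attr(pairs, "total_edges") <- n_edges
  pairs
}

#' Hypergeometric overrepresentation tail probability
#'
#' Upper tail `P(X >= k)` for `X ~ Hypergeometric` with `N` node pairs in
#' the urn, `K` of them carrying the taxon pair of interest, and `n` edges
#' drawn. Small values mean the taxon pair carries more edges than a random
#' allocation of the network's edge budget would give it.
#'
#' @param K Node pairs with the label pair ("white balls").
#' @param k Observed edges among them.
#' @param N Total node pairs.
#' @param n Total edges ("draws").
#' @return Upper-tail probability (vectorised).
#' @export
hypergeom_overrep <- function(K, k, N, n) {
  ok <- k >= 0 & k <= pmin(K, n) & K <= N & n <= N
  if (any(!ok)) abort("Hypergeometric bounds violated (need 0 <= k <= min(K, n), K <= N, n <= N).")
  phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Holm step-down adjustment
#'
#' `p'_(i) = max_{j <= i} min(1, (m - j + 1) * p_(j))` over the ascending
#' order statistics, mapped back to the input order.
#'
#' @param p Vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values, always `>=` raw and `<= 1`.
#' @export
holm_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1].")
  p.adjust(p, method = "holm")
}

#' Overrepresentation report across zones and ranks
#'
#' For each zone network and taxonomic rank, computes the taxon-pair edge
#' counts, hypergeometric upper-tail p-values, and Holm adjustment (the
#' family = all pairs with `K >= 1` within that zone-rank combination;
#' untestable pairs are excluded). Pairs with `p_holm < alpha` are flagged
#' overrepresented.
#'
#' @param networks Named list of [co_network]s (one per zone).
#' @param taxonomy Taxonomy tibble covering all nodes.
#' @param ranks Character vector of ranks to test (default: all seven).
#' @param alpha Significance threshold on the adjusted p-value.
#' @return Tibble: `zone`, `rank`, `taxon_a`, `taxon_b`, `possible_pairs`,
#'   `observed_edges`, `total_pairs`, `total_edges`, `p_raw`, `p_holm`,
#'   `significant`.
#' @export
overrep_report <- function(networks, taxonomy, ranks = taxonomy_rank_names(),
                           alpha = 0.05) {
  if (is.null(names(networks))) abort("`networks` must be a named list.")
  purrr::map_dfr(names(networks), function(zone) {
    purrr::map_dfr(ranks, function(rk) {
      pc <- taxon_pair_counts(networks[[zone]], taxonomy, rk)
      N <- attr(pc, "total_pairs")
      n <- attr(pc, "total_edges")
      pc <- filter(pc, .data$possible_pairs >= 1)
      if (!nrow(pc)) return(tibble())
      pc$total_pairs <- N
      pc$total_edges <- n
      pc$p_raw <- hypergeom_overrep(pc$possible_pairs, pc$observed_edges, N, n)
      pc$p_holm <- holm_adjust(pc$p_raw)
      pc$significant <- pc$p_holm < alpha
      dplyr::bind_cols(tibble(zone = zone, rank = rk), pc)
    })
  })
}

#' Climate-specific taxon-pair edges
#'
#' Labels a taxon pair (at the given rank) climate-specific when it appears
#' as an edge in exactly one of the analysed zone networks, and reports the
#' fraction of observed taxon-pair links that are zone-specific.
#'
#' @param networks Named list of [co_network]s.
#' @param taxonomy Taxonomy tibble.
#' @param rank Rank at which pairs are pooled (default phylum).
#' @return List: `pairs` (tibble `taxon_a`, `taxon_b`, `n_zones`,
#'   `specific`) and `fraction_specific`.
#' @export
climate_specific_fraction <- function(networks, taxonomy, rank = "phylum") {
  if (length(networks) < 2) abort("Need at least two zones.")
  per_zone <- purrr::map_dfr(names(networks), function(zone) {
    pc <- taxon_pair_counts(networks[[zone]], taxonomy, rank)
    pc <- filter(pc, .data$observed_edges > 0)
    mutate(pc, zone = zone)
  })
  if (!nrow(per_zone)) {
    return(list(pairs = tibble(taxon_a = character(), taxon_b = character(),
                               n_zones = integer(), specific = logical()),
                fraction_specific = NA_real_))
  }
  pairs <- per_zone |>
    group_by(.data$taxon_a, .data$taxon_b) |>
    summarise(n_zones = dplyr::n_distinct(.data$zone), .groups = "drop") |>
    mutate(specific = .data$n_zones == 1L)
  list(pairs = pairs, fraction_specific = mean(pairs$specific))
}
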