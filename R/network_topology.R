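#' Global network properties
#'
#' Density `2m/(n(n-1))`, global transitivity (3 x triangles / connected
#' triples), Newman modularity of the fast-greedy agglomerative partition,
#' and average shortest-path length over reachable ordered pairs only
#' (subsampled networks are often disconnected), with the fraction of
#' reachable pairs reported alongside. All metrics are computed on the
#' simple, unweighted, sign-stripped graph: fast-greedy clustering and
#' shortest paths are undefined or unstable under negative weights.
#'
#' @param net A [co_network] or igraph object with at least two nodes.
#' @return One-row tibble: `n_nodes`, `n_edges`, `density`, `transitivity`,
#'   `modularity`, `average_path_length`, `reachable_fraction`.
#' @export
global_properties <- function(net) {
  g <- strip_graph(net)
  n <- igraph::vcount(g)
  if (n < 2) abort("Global properties need at least two nodes.")
  m <- igraph::ecount(g)
  trans <- igraph::transitivity(g, type = "global")
  if (is.nan(trans)) trans <- 0
  mod <- if (m > 0) {
    igraph::modularity(igraph::cluster_fast_greedy(g))
  } else {
    NA_real_
  }
  sp <- igraph::distances(g)
  finite_off <- is.finite(sp) & row(sp) != col(sp)
  apl <- if (any(finite_off)) mean(sp[finite_off]) else NA_real_
  tibble(n_nodes = n, n_edges = m,
         density = 2 * m / (n * (n - 1)),
         transitivity = trans,
         modularity = mod,
         average_path_length = apl,
         reachable_fraction = mean(finite_off[row(sp) != col(sp)]))
}

# unweighted, sign-stripped simple graph for all topology metrics
strip_graph <- function(net) {
  g <- as_igraph(net)
  for (a in intersect(c("weight", "sign"), igraph::edge_attr_names(g))) {
    g <- igraph::delete_edge_attr(g, a)
  }
  igraph::simplify(g)
}

#' Fixed-size induced-subgraph bootstrap
#'
#' Normalises topology comparisons between networks of different sizes:
#' each of `n_iter` iterations samples `subgraph_size` nodes uniformly
#' without replacement, takes the induced subgraph (the sampled nodes and
#' every edge among them), and computes the four global properties.
#' Iterations whose induced subgraph is degenerate record `NA` for the
#' affected metric.
#'
#' @param net A [co_network] or igraph.
#' @param subgraph_size Number of nodes to retain each iteration; when
#'   comparing zones use the smallest zone network's node count.
#' @param n_iter Number of iterations (study default 100).
#' @param seed Seed.
#' @return Tibble in long-ish form: `iteration`, `density`, `transitivity`,
#'   `modularity`, `average_path_length`, with attributes `subgraph_size`
#'   and `seed`.
#' @export
bootstrap_properties <- function(net, subgraph_size, n_iter = 100, seed = NULL) {
  g <- strip_graph(net)
  n <- igraph::vcount(g)
  if (subgraph_size > n) abort("`subgraph_size` exceeds the node count.")
  out <- with_seed_(seed, purrr::map_dfr(seq_len(n_iter), function(it) {
    vs <- sample.int(n, subgraph_size)
    sub <- igraph::induced_subgraph(g, vs)
    if (igraph::vcount(sub) < 2) {
      return(tibble(iteration = it, density = NA_real_,
                    transitivity = NA_real_, modularity = NA_real_,
                    average_path_length = NA_real_))
    }
    gp <- global_properties(sub)
    tibble(iteration = it, density = gp$density,
           transitivity = gp$transitivity, modularity = gp$modularity,
           average_path_length = gp$average_path_length)
  }))
  attr(out, "subgraph_size") <- subgraph_size
  attr(out, "seed") <- seed
  out
}

#' Compare zones on a bootstrapped metric
#'
#' Two-sided Wilcoxon rank tests between every pair of zones on their
#' bootstrap distributions of one global property, Holm-corrected across
#' all zone pairs as a single family.
#'
#' @param distributions Named list (one element per zone) of tibbles from
#'   [bootstrap_properties()].
#' @param metric One of `"density"`, `"transitivity"`, `"modularity"`,
#'   `"average_path_length"`.
#' @param paired Use the signed-rank test (distributions are equal length
#'   by construction, so pairing by iteration index is well defined).
#' @return Tibble `group_a`, `group_b`, `p_raw`, `p_holm`.
#' @export
compare_zones <- function(distributions, metric = "density", paired = FALSE) {
  if (length(distributions) < 2) abort("Need at least two zones to compare.")
  if (is.null(names(distributions))) {
    abort("`distributions` must be a named list (zone codes).")
  }
  vals <- purrr::map(distributions, ~ .x[[metric]])
  lens <- lengths(vals)
  if (length(unique(lens)) != 1) {
    abort("Bootstrap distributions must have equal length.")
  }
  values <- unlist(vals, use.names = FALSE)
  groups <- rep(names(distributions), times = lens)
  keep <- !is.na(values)
  pairwise_wilcoxon_holm(values[keep], groups[keep], paired = paired)
}

#' Node centralities
#'
#' Unweighted degree, betweenness (shortest-path counts with fractional
#' credit for ties), closeness (computed within components), and
#' eigenvector centrality (principal adjacency eigenvector, scaled to unit
#' maximum and sign-fixed non-negative), plus a harmonic closeness variant.
#'
#' @param net A [co_network] or igraph with at least one node.
#' @return Tibble: `node`, `degree`, `betweenness`, `closeness`,
#'   `harmonic_closeness`, `eigenvector`.
#' @export
centralities <- function(net) {
  g <- strip_graph(net)
  if (igraph::vcount(g) == 0) abort("Empty graph.")
  nodes <- igraph::vertex_attr(g, "name") %||%
    as.character(seq_len(igraph::vcount(g)))
  eig <- if (igraph::ecount(g) > 0) {
    abs(igraph::eigen_centrality(g)$vector)   # unit-max scaled
  } else {
    rep(0, igraph::vcount(g))
  }
  tibble(node = nodes,
         degree = as.numeric(igraph::degree(g)),
         betweenness = as.numeric(igraph::betweenness(g, directed = FALSE)),
         closeness = suppressWarnings(
           as.numeric(igraph::closeness(g, mode = "all"))),
         harmonic_closeness = as.numeric(
           igraph::harmonic_centrality(g, mode = "all")),
         eigenvector = as.numeric(eig))
}

#' @rdname centralities
#' @param nets Named list of networks (one per zone).
#' @return `centrality_summary`: one row per zone with the mean of each
#'   centrality over the zone's nodes.
#' @export
centrality_summary <- function(nets) {
  purrr::map_dfr(nets, function(net) {
    ct <- centralities(net)
    summarise(ct,
              mean_degree = mean(.data$degree),
              mean_betweenness = mean(.data$betweenness),
              mean_closeness = mean(.data$closeness, na.rm = TRUE),
              mean_eigenvector = mean(.data$eigenvector))
  }, .id = "zone")
}

#' Identify hub taxa
#'
#' The hub threshold is the empirical 95% quantile (linear interpolation
#' between order statistics) of the network's degree sequence; hubs are the
#' nodes whose degree strictly exceeds it. In a regular graph no node
#' exceeds the quantile and the hub set is empty.
#'
#' @param net A [co_network] or igraph with at least one node.
#' @param probs Quantile defining the threshold.
#' @return A list: `hubs` (tibble `node`, `degree`), `degree_threshold`.
#' @export
find_hubs <- function(net, probs = 0.95) {
  net <- as_co_network(net)
  if (!length(net$nodes)) abort("Network has no nodes.")
  deg <- node_degrees(net)
  thr <- as.numeric(quantile(deg, probs = probs, type = 7))
  hubs <- tibble(node = names(deg), degree = as.numeric(deg)) |>
    filter(.data$degree > thr) |>
    arrange(dplyr::desc(.data$degree))
  list(hubs = hubs, degree_threshold = thr)
}
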