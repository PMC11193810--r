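#' Signed co-occurrence network
#'
#' A `co_network` is an undirected signed graph over ESV nodes: a character
#' vector of node ids plus an edge tibble with columns `from`, `to`,
#' `sign` (+1/-1) and `weight` (non-negative regression-coefficient
#' magnitude). Networks produced by [stars_select()] also record the selected
#' penalty (`lambda_selected`) and the achieved StARS instability
#' (`stars_instability`).
#'
#' @param nodes Character vector of unique node ids.
#' @param edges Tibble/data frame with columns `from`, `to`, `sign`,
#'   `weight`. Missing `sign`/`weight` default to +1/1.
#' @param lambda_selected,stars_instability Optional selection provenance.
#' @return A `co_network` object.
#' @export
co_network <- function(nodes, edges = NULL, lambda_selected = NA_real_,
                       stars_instability = NA_real_) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) abort("Duplicate node ids.")
  if (is.null(edges) || !nrow(as.data.frame(edges))) {
    edges <- tibble(from = character(), to = character(),
                    sign = integer(), weight = double())
  } else {
    edges <- as_tibble(edges)
    if (!all(c("from", "to") %in% names(edges))) {
      abort("Edges need `from` and `to` columns.")
    }
    if (!"sign" %in% names(edges)) edges$sign <- 1L
    if (!"weight" %in% names(edges)) edges$weight <- 1
    edges$from <- as.character(edges$from)
    edges$to <- as.character(edges$to)
    edges$sign <- as.integer(edges$sign)
    edges$weight <- as.double(edges$weight)
    # canonical order: endpoints sorted within an edge, edges sorted
    swap <- edges$from > edges$to
    tmp <- edges$from[swap]
    edges$from[swap] <- edges$to[swap]
    edges$to[swap] <- tmp
    edges <- arrange(edges, .data$from, .data$to)
    if (any(edges$from == edges$to)) abort("Self-edges are not allowed.")
    if (anyDuplicated(edges[, c("from", "to")])) abort("Duplicate edges.")
    if (any(!edges$sign %in% c(-1L, 1L))) abort("Edge sign must be +1 or -1.")
    stray <- setdiff(c(edges$from, edges$to), nodes)
    if (length(stray)) {
      abort(paste0("Edge endpoints missing from node set: ",
                   paste(head(stray, 5), collapse = ", ")))
    }
  }
  structure(list(nodes = nodes, edges = edges,
                 lambda_selected = lambda_selected,
                 stars_instability = stars_instability),
            class = "co_network")
}

#' @rdname co_network
#' @param x Object to convert.
#' @export
as_igraph <- function(x) UseMethod("as_igraph")

#' @export
as_igraph.co_network <- function(x) {
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(x$nodes), name = x$nodes)
  if (nrow(x$edges)) {
    g <- igraph::add_edges(g, rbind(match(x$edges$from, x$nodes),
                                    match(x$edges$to, x$nodes)),
                           sign = x$edges$sign, weight = x$edges$weight)
  }
  g
}

#' @export
as_igraph.igraph <- function(x) x

#' @rdname co_network
#' @export
as_co_network <- function(x) UseMethod("as_co_network")

#' @export
as_co_network.co_network <- function(x) x

#' @export
as_co_network.igraph <- function(x) {
  nodes <- igraph::vertex_attr(x, "name") %||% as.character(seq_len(igraph::vcount(x)))
  el <- igraph::as_edgelist(x, names = TRUE)
  sgn <- igraph::edge_attr(x, "sign") %||% rep(1L, nrow(el))
  wt <- igraph::edge_attr(x, "weight") %||% rep(1, nrow(el))
  co_network(nodes, tibble(from = el[, 1], to = el[, 2],
                           sign = as.integer(round(sgn)), weight = wt))
}

#' @export
print.co_network <- function(x, ...) {
  neg <- if (nrow(x$edges)) mean(x$edges$sign < 0) else NA_real_
  cat(sprintf("<co_network> %d nodes, %d edges (%.0f%% negative)\n",
              length(x$nodes), nrow(x$edges), 100 * (neg %||% 0)))
  if (!is.na(x$lambda_selected)) {
    cat(sprintf("  lambda = %.4g, StARS instability = %.4g\n",
                x$lambda_selected, x$stars_instability))
  }
  invisible(x)
}

#' @export
tidy.co_network <- function(x, ...) x$edges

#' @export
glance.co_network <- function(x, ...) {
  n <- length(x$nodes)
  m <- nrow(x$edges)
  tibble(n_nodes = n, n_edges = m,
         density = if (n > 1) 2 * m / (n * (n - 1)) else NA_real_,
         negative_fraction = if (m) mean(x$edges$sign < 0) else NA_real_,
         lambda_selected = x$lambda_selected,
         stars_instability = x$stars_instability)
}

node_degrees <- function(net) {
  net <- as_co_network(net)
  deg <- setNames(integer(length(net$nodes)), net$nodes)
  if (nrow(net$edges)) {
    t1 <- table(factor(net$edges$from, levels = net$nodes))
    t2 <- table(factor(net$edges$to, levels = net$nodes))
    deg <- setNames(as.integer(t1 + t2), net$nodes)
  }
  deg
}
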