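#' Centered log-ratio transform
#'
#' Maps raw counts to an unconstrained space that respects their
#' compositional nature: each sample's counts (plus a pseudocount) are
#' logged and centered by the sample's mean log, so every transformed
#' sample sums to zero and multiplying a sample by a constant depth factor
#' leaves it (pseudocount effects aside) unchanged.
#'
#' @param table An [esv_table] (taxa x samples) or count matrix in the same
#'   orientation.
#' @param pseudocount Added to every count before the log (default 1; zeros
#'   need it).
#' @return Numeric matrix, samples in rows and taxa in columns — the data
#'   orientation the regression stage expects.
#' @export
clr_transform <- function(table, pseudocount = 1) {
  m <- unclass(as_esv_table(table))
  if (any(m < 0)) abort("Counts must be non-negative.")
  x <- t(log(m + pseudocount))        # samples x taxa
  sweep(x, 1, rowMeans(x), "-")
}

#' Penalty grid for neighborhood selection
#'
#' Thirty log-spaced penalties from `lambda_max` — the smallest penalty at
#' which every nodewise lasso is empty, computed from the data as the
#' largest absolute off-diagonal entry of the standardized cross-product
#' matrix — down to `lambda_max * min_ratio`.
#'
#' @param x CLR-transformed data matrix (samples x taxa).
#' @param n_lambda Grid size.
#' @param min_ratio Smallest penalty as a fraction of `lambda_max`.
#' @return Decreasing numeric vector of penalties.
#' @export
lambda_grid <- function(x, n_lambda = 30, min_ratio = 0.01) {
  xs <- scale_columns(x)
  n <- nrow(xs)
  cp <- abs(crossprod(xs)) / n
  diag(cp) <- 0
  lmax <- max(cp) * (1 + 1e-6)  # nudge above the entry point so the top of
  if (lmax <= 0) abort("Data are constant; no penalty grid exists.")
  # the grid is an exactly-empty model
  exp(seq(log(lmax), log(lmax * min_ratio), length.out = n_lambda))
}

# center/scale columns; constant columns flagged by attribute "dropped"
scale_columns <- function(x) {
  mu <- colMeans(x)
  sdv <- apply(x, 2, sd)
  keep <- sdv > 0
  xs <- sweep(x[, keep, drop = FALSE], 2, mu[keep], "-")
  xs <- sweep(xs, 2, sdv[keep], "/")
  attr(xs, "kept") <- which(keep)
  xs
}

# Nodewise lasso over a whole penalty grid: for each response column j,
# glmnet fits the full path against the remaining columns; returns, per
# lambda, the p x p matrix of directed coefficients B[i, j] (predictor i,
# response j). Data are standardized once here so the penalty is on a
# common scale across nodes (and glmnet is told not to re-standardize).
mb_coef_paths <- function(x, lambdas) {
  xs <- scale_columns(x)
  kept <- attr(xs, "kept")
  p_all <- ncol(x)
  p <- ncol(xs)
  if (p < 2) abort("Need at least two non-constant taxa.")
  if (p < p_all) {
    warn(paste0("Dropping ", p_all - p, " constant column(s) before regression."))
  }
  n <- nrow(xs)
  res <- array(0, dim = c(p_all, p_all, length(lambdas)))
  for (j in seq_len(p)) {
    fit <- glmnet::glmnet(xs[, -j, drop = FALSE], xs[, j],
                          family = "gaussian", alpha = 1,
                          lambda = lambdas, standardize = FALSE,
                          intercept = FALSE, thresh = 1e-9)
    cf <- as.matrix(fit$beta)  # (p-1) x n_lambda_fit
    # glmnet may truncate the path; missing tail repeats the last fit
    full <- matrix(0, p - 1, length(lambdas))
    hit <- match(signif(fit$lambda, 8), signif(lambdas, 8))
    full[, hit[!is.na(hit)]] <- cf[, !is.na(hit), drop = FALSE]
    if (anyNA(hit)) {
      warn("glmnet returned penalties outside the requested grid.")
    }
    # forward-fill truncated path tail with the densest available fit
    got <- sort(unique(hit[!is.na(hit)]))
    if (length(got) && max(got) < length(lambdas)) {
      for (k in seq(max(got) + 1L, length(lambdas))) full[, k] <- full[, max(got)]
    }
    rows <- kept[-j]
    res[rows, kept[j], ] <- full
  }
  res
}

# symmetrize directed coefficients at one lambda into a signed adjacency
symmetrize_mb <- function(B, rule = c("or", "and")) {
  rule <- match.arg(rule)
  p <- nrow(B)
  sel_i <- B != 0
  present <- if (rule == "or") sel_i | t(sel_i) else sel_i & t(sel_i)
  diag(present) <- FALSE
  mean_coef <- (B + t(B)) / 2
  sgn <- sign(mean_coef)
  # exact-zero mean with nonzero coefficients: larger-magnitude side wins
  tie <- present & sgn == 0
  if (any(tie)) {
    dominant <- ifelse(abs(B) >= abs(t(B)), sign(B), sign(t(B)))
    sgn[tie] <- dominant[tie]
  }
  list(adjacency = present, sign = sgn, weight = abs(mean_coef))
}

#' Meinshausen-Buhlmann neighborhood selection at one penalty
#'
#' Each taxon's CLR profile is lasso-regressed on all other taxa
#' (standardized predictors, penalty `lambda`); an edge joins taxa i and j
#' when either directed coefficient is nonzero (`rule = "or"`, the default)
#' or when both are (`rule = "and"`). The edge sign is the sign of the mean
#' of the two directed coefficients (an absent coefficient counts as zero;
#' an exactly-cancelling pair falls back to the larger-magnitude side) and
#' the weight is that mean's magnitude.
#'
#' @param x CLR-transformed matrix (samples x taxa) with column names.
#' @param lambda Positive penalty.
#' @param rule Symmetrization rule, `"or"` or `"and"`.
#' @return A [co_network] over the columns of `x`.
#' @export
mb_neighborhood <- function(x, lambda, rule = c("or", "and")) {
  rule <- match.arg(rule)
  stopifnot(lambda > 0)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  B <- mb_coef_paths(x, lambdas = lambda)[, , 1]
  sym <- symmetrize_mb(B, rule)
  adjacency_to_network(sym, colnames(x), lambda_selected = lambda)
}

adjacency_to_network <- function(sym, nodes, lambda_selected = NA_real_,
                                 stars_instability = NA_real_) {
  idx <- which(sym$adjacency & upper.tri(sym$adjacency), arr.ind = TRUE)
  edges <- tibble(from = nodes[idx[, 1]], to = nodes[idx[, 2]],
                  sign = as.integer(sym$sign[idx]),
                  weight = sym$weight[idx])
  co_network(nodes, edges, lambda_selected = lambda_selected,
             stars_instability = stars_instability)
}

#' StARS stability selection for the co-occurrence network
#'
#' Runs neighborhood selection along a penalty grid on `n_subsamples`
#' random subsamples of size `floor(10 * sqrt(n))` (capped at `n - 1`),
#' computes the edge-wise selection frequencies `theta_e(lambda)` and the
#' graph instability `D(lambda) = mean_e 2 * theta_e * (1 - theta_e)`, and
#' monotonizes `D` to be non-decreasing as lambda decreases. The selected
#' penalty is the smallest grid value whose monotonized instability stays
#' at or below `beta` — the densest network that is still reproducible
#' under subsampling. The returned network is refit on the full data at
#' that penalty.
#'
#' @param x CLR-transformed matrix (samples x taxa), `n >= 10`.
#' @param lambdas Decreasing penalty grid; default [lambda_grid()] of `x`.
#' @param beta Instability threshold (default 0.05; 0.01 for the stricter
#'   variant).
#' @param n_subsamples Number of subsamples.
#' @param rule MB symmetrization rule.
#' @param seed Seed for the subsample draw.
#' @return A list with `network` (the selected [co_network], carrying
#'   `lambda_selected` and the achieved instability) and `path` (a
#'   `stars_path` tibble: `lambda`, `instability`,
#'   `instability_monotone`, `n_edges_full`).
#' @export
stars_select <- function(x, lambdas = NULL, beta = 0.05, n_subsamples = 20,
                         rule = c("or", "and"), seed = NULL) {
  rule <- match.arg(rule)
  n <- nrow(x)
  if (n < 10) abort("StARS needs at least 10 samples.")
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  if (is.null(lambdas)) lambdas <- lambda_grid(x)
  lambdas <- sort(lambdas, decreasing = TRUE)
  p <- ncol(x)
  b <- min(floor(10 * sqrt(n)), n - 1)
  sel_freq <- array(0, dim = c(p, p, length(lambdas)))
  with_seed_(seed, {
    for (s in seq_len(n_subsamples)) {
      rows <- sample.int(n, b)
      Bs <- mb_coef_paths(x[rows, , drop = FALSE], lambdas)
      for (k in seq_along(lambdas)) {
        sym <- symmetrize_mb(Bs[, , k], rule)
        sel_freq[, , k] <- sel_freq[, , k] + sym$adjacency
      }
    }
  })
  theta <- sel_freq / n_subsamples
  ut <- upper.tri(matrix(0, p, p))
  instab <- vapply(seq_along(lambdas), function(k) {
    th <- theta[, , k][ut]
    mean(2 * th * (1 - th))
  }, numeric(1))
  instab_mono <- cummax(instab)  # grid is lambda-decreasing
  ok <- which(instab_mono <= beta)
  if (length(ok)) {
    sel_k <- max(ok)  # smallest lambda still within the threshold
  } else {
    warn(paste0("No penalty meets instability threshold ", beta,
                "; returning the sparsest grid point."))
    sel_k <- 1L
  }
  B_full <- mb_coef_paths(x, lambdas)
  sym <- symmetrize_mb(B_full[, , sel_k], rule)
  net <- adjacency_to_network(sym, colnames(x),
                              lambda_selected = lambdas[sel_k],
                              stars_instability = instab_mono[sel_k])
  n_edges_full <- vapply(seq_along(lambdas), function(k) {
    a <- symmetrize_mb(B_full[, , k], rule)$adjacency
    sum(a[ut])
  }, numeric(1))
  path <- tibble(lambda = lambdas, instability = instab,
                 instability_monotone = instab_mono,
                 n_edges_full = n_edges_full)
  attr(path, "subsample_count") <- n_subsamples
  attr(path, "subsample_size") <- b
  attr(path, "beta") <- beta
  attr(path, "lambda_selected") <- lambdas[sel_k]
  class(path) <- c("stars_path", class(path))
  list(network = net, path = path)
}

#' Scale-free diagnostic: log-log degree-distribution fit
#'
#' Regresses `log10` relative frequency of each positive degree on
#' `log10(degree)` by ordinary least squares (a first-degree polynomial on
#' the log-log scale). A high R-squared indicates the heavy-tailed,
#' hub-dominated degree distribution expected of scale-free-like networks.
#'
#' @param net A [co_network], igraph object, or a raw degree vector. At
#'   least five distinct positive degrees are required.
#' @return A list: `r_squared`, `p_value` (slope t-test), `slope`, and
#'   `degree_table` (tibble of degree, count, relative frequency).
#' @export
scale_free_fit <- function(net) {
  deg <- if (is.numeric(net)) net else node_degrees(as_co_network(net))
  deg <- deg[deg >= 1]
  tab <- table(deg)
  if (length(tab) < 5) {
    abort("Scale-free fit needs at least five distinct positive degrees.")
  }
  df <- tibble(degree = as.numeric(names(tab)),
               count = as.numeric(tab),
               rel_freq = as.numeric(tab) / sum(tab))
  fit <- lm(log10(rel_freq) ~ log10(degree), data = df)
  sm <- suppressWarnings(summary(fit))  # exact power laws fit perfectly
  list(r_squared = sm$r.squared,
       p_value = sm$coefficients[2, 4],
       slope = sm$coefficients[2, 1],
       degree_table = df)
}

#' Correlation between node abundance and degree
#'
#' Spearman correlation between each node's total relative abundance in the
#' count table and its degree in the network. Random (non-preferential)
#' attachment of abundant taxa shows up as |rho| < 0.1.
#'
#' @param table [esv_table] containing every network node as a row.
#' @param net A [co_network].
#' @return Spearman rho, or `NA` (with a warning) when the degree vector is
#'   constant.
#' @export
abundance_degree_correlation <- function(table, net) {
  net <- as_co_network(net)
  table <- as_esv_table(table)
  missing <- setdiff(net$nodes, rownames(table))
  if (length(missing)) {
    abort(paste0("Nodes absent from the count table: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  abund <- rowSums(table)[net$nodes] / sum(table)
  deg <- node_degrees(net)
  if (sd(deg) == 0 || sd(abund) == 0) {
    warn("Constant degree or abundance vector: correlation undefined.")
    return(NA_real_)
  }
  suppressWarnings(cor(abund, deg, method = "spearman"))
}

#' Fraction of negative edges
#'
#' @param net A [co_network] with at least one edge.
#' @return Fraction of edges with sign -1.
#' @export
negative_edge_fraction <- function(net) {
  net <- as_co_network(net)
  if (!nrow(net$edges)) abort("Network has no edges.")
  mean(net$edges$sign < 0)
}
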