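# Brute-force oracles, independent of the implementation paths they check.

# all permutations of 1..n by odometer enumeration (independent of the
# package's recursive generator)
oracle_permutations <- function(n) {
  grid <- do.call(expand.grid, rep(list(seq_len(n)), n))
  grid <- as.matrix(grid[apply(grid, 1, function(r) length(unique(r)) == n), ])
  unname(grid[, rev(seq_len(n)), drop = FALSE])
}

# exact two-sided Mantel p by direct enumeration
oracle_mantel_p <- function(d1, d2) {
  n <- nrow(d1)
  lt <- function(m) m[lower.tri(m)]
  r_obs <- stats::cor(lt(d1), lt(d2))
  perms <- oracle_permutations(n)
  r_all <- apply(perms, 1, function(p) stats::cor(lt(d1), lt(d2[p, p])))
  mean(abs(r_all) >= abs(r_obs) - 1e-12)
}

# Floyd-Warshall shortest-path distances from a logical adjacency matrix
oracle_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

# shortest-path counts by dynamic programming over distances
oracle_path_counts <- function(adj, d) {
  n <- nrow(adj)
  nsp <- matrix(0, n, n)
  diag(nsp) <- 1
  maxd <- max(d[is.finite(d)])
  for (len in seq_len(max(maxd, 1))) {
    for (s in seq_len(n)) {
      for (t in which(d[s, ] == len)) {
        nsp[s, t] <- sum(nsp[s, which(adj[, t] & d[s, ] == len - 1)])
      }
    }
  }
  nsp
}

# betweenness with fractional credit for tied shortest paths
oracle_betweenness <- function(adj) {
  d <- oracle_distances(adj)
  nsp <- oracle_path_counts(adj, d)
  n <- nrow(adj)
  bc <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in seq(s + 1, n)) {
      if (!is.finite(d[s, t]) || nsp[s, t] == 0) next
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        if (is.finite(d[s, v]) && is.finite(d[v, t]) &&
            d[s, v] + d[v, t] == d[s, t]) {
          bc[v] <- bc[v] + nsp[s, v] * nsp[v, t] / nsp[s, t]
        }
      }
    }
  }
  bc
}

oracle_closeness <- function(adj) {
  d <- oracle_distances(adj)
  vapply(seq_len(nrow(adj)), function(i) {
    reach <- is.finite(d[i, ]) & seq_len(ncol(d)) != i
    if (!any(reach)) return(NA_real_)
    1 / sum(d[i, reach])
  }, numeric(1))
}

oracle_eigenvector <- function(adj) {
  a <- adj * 1
  v <- rep(1, nrow(a))
  for (i in 1:10000) v <- as.numeric(a %*% v) / max(abs(a %*% v))
  abs(v / max(abs(v)))
}

# scan-all-cells climate lookup (south/west cell wins ties)
oracle_assign_climate <- function(lat, lon, map) {
  ord <- order(map$lat_min, map$lon_min)
  map <- map[ord, ]
  vapply(seq_along(lat), function(i) {
    for (r in seq_len(nrow(map))) {
      if (map$lat_min[r] <= lat[i] && lat[i] <= map$lat_max[r] &&
          map$lon_min[r] <= lon[i] && lon[i] <= map$lon_max[r]) {
        code <- map$code[r]
        return(if (is.na(code) || toupper(code) == "OCEAN") NA_character_ else code)
      }
    }
    NA_character_
  }, character(1))
}

oracle_bray_curtis <- function(x, y) sum(abs(x - y)) / sum(x + y)
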