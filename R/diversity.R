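#' Alpha diversity indices
#'
#' `shannon()` is the Shannon entropy in nats, `simpson()` the Gini-Simpson
#' index `1 - sum(p_i^2)`, and `chao1()` the bias-corrected Chao1 richness
#' estimate `S_obs + F1*(F1-1) / (2*(F2+1))` where `F1`/`F2` are singleton
#' and doubleton counts. All three ignore zero-count taxa, so appending
#' zeros never changes the value.
#'
#' @param counts Non-negative count vector for one sample, with at least
#'   one positive entry.
#' @return A single numeric value.
#' @examples
#' shannon(c(10, 10, 10, 10))  # log(4)
#' chao1(c(1, 1, 1, 2, 5))     # 5 + 3*2/(2*2)
#' @export
shannon <- function(counts) {
  counts <- check_alpha_input(counts)
  as.numeric(vegan::diversity(counts, index = "shannon"))
}

#' @rdname shannon
#' @export
simpson <- function(counts) {
  counts <- check_alpha_input(counts)
  as.numeric(vegan::diversity(counts, index = "simpson"))
}

#' @rdname shannon
#' @export
chao1 <- function(counts) {
  counts <- check_alpha_input(counts)
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

check_alpha_input <- function(counts) {
  counts <- as.numeric(counts)
  if (!length(counts) || all(counts == 0)) {
    abort("Alpha diversity needs at least one positive count.")
  }
  if (any(counts < 0 | !is.finite(counts))) abort("Counts must be finite and >= 0.")
  counts
}

#' Per-sample alpha diversity table
#'
#' @param table An [esv_table].
#' @param meta Optional metadata; when given, `climate_zone` is joined in.
#' @return Tibble with one row per sample: `sample_id`, optional
#'   `climate_zone`, `shannon`, `simpson`, `chao1`.
#' @export
alpha_diversity <- function(table, meta = NULL) {
  table <- as_esv_table(table)
  out <- tibble(
    sample_id = colnames(table),
    shannon = apply(unclass(table), 2, shannon),
    simpson = apply(unclass(table), 2, simpson),
    chao1 = apply(unclass(table), 2, chao1))
  if (!is.null(meta)) {
    out <- left_join(out, select(as_tibble(meta), "sample_id", "climate_zone"),
                     by = "sample_id")
    out <- select(out, "sample_id", "climate_zone", "shannon", "simpson", "chao1")
  }
  out
}

#' Bray-Curtis dissimilarity matrix
#'
#' `d(j,k) = sum|x_ij - x_ik| / sum(x_ij + x_ik)` over taxa, computed
#' between the sample columns of the table. Identical samples score 0,
#' samples with disjoint taxa score 1.
#'
#' @param table An [esv_table] with at least two samples.
#' @return A `dist_matrix`: symmetric matrix with zero diagonal and sample
#'   ids as labels.
#' @export
bray_curtis <- function(table) {
  table <- as_esv_table(table)
  if (ncol(table) < 2) abort("Bray-Curtis needs at least two samples.")
  zero <- colSums(table) == 0
  if (sum(zero) >= 2) {
    abort(paste0("All-zero samples make Bray-Curtis undefined: ",
                 paste(head(colnames(table)[zero], 5), collapse = ", ")))
  }
  d <- vegan::vegdist(t(unclass(table)), method = "bray")
  dist_matrix(as.matrix(d))
}

#' @rdname bray_curtis
#' @param values Square symmetric matrix of distances.
#' @export
dist_matrix <- function(values) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) abort("Distance matrix must be square.")
  if (any(!is.finite(values))) abort("Distances must be finite.")
  if (max(abs(values - t(values))) > 1e-8) abort("Distance matrix must be symmetric.")
  if (any(abs(diag(values)) > 1e-12)) abort("Distance matrix diagonal must be zero.")
  values <- (values + t(values)) / 2
  diag(values) <- 0
  if (is.null(rownames(values))) {
    dimnames(values) <- list(seq_len(nrow(values)), seq_len(nrow(values)))
  }
  colnames(values) <- rownames(values)
  structure(values, class = c("dist_matrix", "matrix", "array"))
}

#' Vincenty (ellipsoid) geographic distance
#'
#' Inverse geodesic distance on the WGS-84 ellipsoid, in kilometres.
#' Near-antipodal pairs for which the Vincenty iteration does not converge
#' fall back to the spherical great-circle (haversine) distance and are
#' flagged with a warning.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees (vectorised).
#' @return Numeric vector of distances in km.
#' @examples
#' vincenty_km(0, 0, 0, 1)  # ~111.319 km
#' @export
vincenty_km <- function(lat1, lon1, lat2, lon2) {
  stopifnot(all(abs(c(lat1, lat2)) <= 90), all(abs(c(lon1, lon2)) <= 180))
  p1 <- cbind(lon1, lat1)
  p2 <- cbind(lon2, lat2)
  d <- suppressWarnings(geosphere::distVincentyEllipsoid(p1, p2))
  bad <- !is.finite(d)
  if (any(bad)) {
    warn(paste0(sum(bad), " near-antipodal pair(s): using great-circle fallback."))
    d[bad] <- geosphere::distHaversine(p1[bad, , drop = FALSE],
                                       p2[bad, , drop = FALSE])
  }
  d / 1000
}

#' Pairwise geographic distance matrix for a set of samples
#'
#' @param meta Metadata tibble with `sample_id`, `latitude`, `longitude`.
#' @return A `dist_matrix` of Vincenty distances in km.
#' @export
geo_distances <- function(meta) {
  meta <- as_tibble(meta)
  n <- nrow(meta)
  if (n < 2) abort("Need at least two samples.")
  m <- matrix(0, n, n, dimnames = list(meta$sample_id, meta$sample_id))
  idx <- which(upper.tri(m), arr.ind = TRUE)
  d <- vincenty_km(meta$latitude[idx[, 1]], meta$longitude[idx[, 1]],
                   meta$latitude[idx[, 2]], meta$longitude[idx[, 2]])
  m[idx] <- d
  m[idx[, c(2, 1)]] <- d
  dist_matrix(m)
}

lower_tri <- function(m) m[lower.tri(m)]

# all permutations of 1..n (n small) in a deterministic order
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub), n - 1L)))
  }
  unname(out)
}

#' Mantel correlation test
#'
#' Pearson correlation between the strict lower triangles of two distance
#' matrices, with a two-sided permutation p-value: rows and columns of the
#' second matrix are permuted jointly and
#' `p = (1 + #{|r*| >= |r|}) / (1 + n_permutations)` (the add-one convention,
#' so p is never zero). With `exact = TRUE` (the default for up to 7 labels)
#' all `n!` permutations are enumerated and `p = #{|r*| >= |r|} / n!`, the
#' identity permutation included.
#'
#' @param d1,d2 `dist_matrix` objects with identical labels in identical
#'   order (d1 is typically community dissimilarity, d2 geographic
#'   distance).
#' @param n_permutations Number of random permutations when not exact.
#' @param seed Seed for the permutation draw.
#' @param exact `TRUE`, `FALSE`, or `NULL` (auto: exact when `n <= 7`).
#' @return A `mantel_result` with `r`, `r_squared`, `p_value`,
#'   `n_permutations`, `exact`.
#' @export
mantel_test <- function(d1, d2, n_permutations = 999, seed = NULL,
                        exact = NULL) {
  d1 <- dist_matrix(d1); d2 <- dist_matrix(d2)
  if (!identical(rownames(d1), rownames(d2))) {
    abort("Distance matrices must share labels in the same order.")
  }
  n <- nrow(d1)
  x <- lower_tri(d1)
  if (sd(x) == 0 || sd(lower_tri(d2)) == 0) {
    abort("Constant distance triangle: Mantel correlation undefined.")
  }
  r_obs <- cor(x, lower_tri(d2))
  if (is.null(exact)) exact <- n <= 7
  if (exact) {
    perms <- all_permutations(n)
    r_perm <- apply(perms, 1, function(p) cor(x, lower_tri(d2[p, p])))
    p_val <- mean(abs(r_perm) >= abs(r_obs) - 1e-12)
    n_perm <- nrow(perms)
  } else {
    r_perm <- with_seed_(seed, vapply(seq_len(n_permutations), function(i) {
      p <- sample.int(n)
      cor(x, lower_tri(d2[p, p]))
    }, numeric(1)))
    p_val <- (1 + sum(abs(r_perm) >= abs(r_obs) - 1e-12)) / (1 + n_permutations)
    n_perm <- n_permutations
  }
  structure(list(r = r_obs, r_squared = r_obs^2, p_value = p_val,
                 n_permutations = n_perm, exact = exact),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel test: r = %.4f (r^2 = %.4f), p = %.4g (%s, %d permutations)\n",
              x$r, x$r_squared, x$p_value,
              if (x$exact) "exact" else "sampled", x$n_permutations))
  invisible(x)
}

#' @export
tidy.mantel_result <- function(x, ...) {
  tibble(r = x$r, r_squared = x$r_squared, p_value = x$p_value,
         n_permutations = x$n_permutations, exact = x$exact)
}

#' Non-metric multidimensional scaling
#'
#' Kruskal stress-1 NMDS via iterative majorization with monotone (isotonic)
#' regression on the dissimilarity ranks (vegan's `monoMDS` engine), taking
#' the best of `n_starts` random initial configurations. Deterministic for
#' a fixed seed.
#'
#' @param d A `dist_matrix`.
#' @param k Embedding dimension (must be `< n`).
#' @param n_starts Number of random starts.
#' @param max_iter Maximum majorization iterations per start.
#' @param tol Convergence tolerance on stress.
#' @param seed Seed.
#' @return An `nmds_ordination` with `points` (tibble: label, NMDS1..NMDSk)
#'   and `stress` (Kruskal stress-1, in `[0, 1]`).
#' @export
nmds_ordination <- function(d, k = 2, n_starts = 20, max_iter = 500,
                            tol = 1e-7, seed = NULL) {
  d <- dist_matrix(d)
  n <- nrow(d)
  if (k >= n) abort("`k` must be smaller than the number of points.")
  dd <- as.dist(d)
  with_seed_(seed, {
    best <- NULL
    for (s in seq_len(n_starts)) {
      init <- matrix(rnorm(n * k), n, k)
      fit <- vegan::monoMDS(dd, y = init, k = k, model = "global",
                            maxit = max_iter, sratmax = 1 - tol)
      if (is.null(best) || fit$stress < best$stress) best <- fit
    }
    pts <- as_tibble(as.data.frame(best$points))
    names(pts) <- paste0("NMDS", seq_len(k))
    pts <- dplyr::bind_cols(tibble(label = rownames(d)), pts)
    structure(list(points = pts, stress = best$stress, k = k,
                   n_starts = n_starts),
              class = "nmds_ordination")
  })
}

#' @export
print.nmds_ordination <- function(x, ...) {
  cat(sprintf("NMDS ordination: k = %d, stress = %.5f (best of %d starts)\n",
              x$k, x$stress, x$n_starts))
  invisible(x)
}

#' @export
tidy.nmds_ordination <- function(x, ...) x$points

#' @export
glance.nmds_ordination <- function(x, ...) {
  tibble(k = x$k, stress = x$stress, n_starts = x$n_starts)
}

#' One-factor PERMANOVA
#'
#' Permutational multivariate analysis of variance on a distance matrix
#' (Anderson's partition of squared distances, via `vegan::adonis2`),
#' testing whether group labels explain community dissimilarity.
#'
#' @param d A `dist_matrix`.
#' @param groups Group label per sample (at least two groups).
#' @param n_permutations Number of permutations.
#' @param seed Seed.
#' @return A `permanova_result` with `pseudo_f`, `r_squared`, `p_value`,
#'   `n_permutations`.
#' @export
permanova <- function(d, groups, n_permutations = 999, seed = NULL) {
  d <- dist_matrix(d)
  groups <- as.factor(groups)
  if (length(groups) != nrow(d)) abort("`groups` must match the matrix size.")
  if (nlevels(droplevels(groups)) < 2) abort("PERMANOVA needs at least two groups.")
  df <- data.frame(grp = droplevels(groups))
  fit <- with_seed_(seed,
                    vegan::adonis2(as.dist(d) ~ grp, data = df,
                                   permutations = n_permutations))
  structure(list(pseudo_f = fit$F[1], r_squared = fit$R2[1],
                 p_value = fit$`Pr(>F)`[1], n_permutations = n_permutations),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA: pseudo-F = %.3f, R^2 = %.4f, p = %.4g (%d permutations)\n",
              x$pseudo_f, x$r_squared, x$p_value, x$n_permutations))
  invisible(x)
}

#' @export
tidy.permanova_result <- function(x, ...) {
  tibble(pseudo_f = x$pseudo_f, r_squared = x$r_squared,
         p_value = x$p_value, n_permutations = x$n_permutations)
}

#' Pairwise rank tests with Holm correction
#'
#' Compares a numeric variable between all pairs of groups with two-sided
#' Wilcoxon tests and applies the Holm step-down correction across the full
#' family of pairs. The default is the rank-sum (Mann-Whitney) test for
#' independent groups; `paired = TRUE` switches to the signed-rank test,
#' which requires equal group sizes. Pairs where either group has fewer
#' than two values are skipped with a warning.
#'
#' @param values Numeric vector.
#' @param groups Group label per value.
#' @param paired Use the signed-rank (paired) test instead of rank-sum.
#' @return Tibble with `group_a`, `group_b`, `p_raw`, `p_holm`.
#' @export
pairwise_wilcoxon_holm <- function(values, groups, paired = FALSE) {
  groups <- as.character(groups)
  stopifnot(length(values) == length(groups))
  levs <- sort(unique(groups))
  if (length(levs) < 2) abort("Need at least two groups.")
  pairs <- utils::combn(levs, 2)
  res <- purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    a <- values[groups == pairs[1, i]]
    b <- values[groups == pairs[2, i]]
    if (length(a) < 2 || length(b) < 2 || (paired && length(a) != length(b))) {
      warn(paste0("Skipping pair ", pairs[1, i], " vs ", pairs[2, i],
                  ": too few values", if (paired) " or unequal sizes for pairing"))
      return(tibble(group_a = pairs[1, i], group_b = pairs[2, i],
                    p_raw = NA_real_))
    }
    p <- suppressWarnings(wilcox.test(a, b, paired = paired,
                                      alternative = "two.sided")$p.value)
    tibble(group_a = pairs[1, i], group_b = pairs[2, i], p_raw = p)
  })
  res$p_holm <- NA_real_
  ok <- !is.na(res$p_raw)
  res$p_holm[ok] <- p.adjust(res$p_raw[ok], method = "holm")
  res
}
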