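#' Specify a ground-truth precision matrix
#'
#' Declares the sparse dependence structure from which one climate zone's
#' counts are simulated. Three support topologies are available: `hub`
#' (a few high-degree taxa, emulating the hub-dominated, scale-free-like
#' structure reported for soil co-occurrence networks), `band`
#' (banded/tridiagonal chains) and `random` (Erdos-Renyi support at a given
#' edge density).
#'
#' @param n_taxa Number of taxa (dimension of the matrix).
#' @param topology `"hub"`, `"band"` or `"random"`.
#' @param hubs_count Number of hubs (hub topology). Spokes are split evenly
#'   across hubs.
#' @param bandwidth Band half-width (band topology).
#' @param edge_density Fraction of the `n_taxa*(n_taxa-1)/2` off-diagonal
#'   pairs carrying an edge (random topology).
#' @param target_condition Condition number of the final matrix; the
#'   diagonal is shifted so the eigenvalue ratio hits this value, which sets
#'   the strength of the implied partial correlations.
#' @param edge_value Absolute off-diagonal value before conditioning.
#' @param negative_fraction Fraction of edges given a positive off-diagonal
#'   entry, i.e. a *negative* latent partial correlation (soil networks
#'   typically show 20-40% negative edges).
#' @param seed Integer seed; the spec is deterministic given the seed.
#' @return A `precision_spec` list.
#' @export
precision_spec <- function(n_taxa, topology = c("hub", "band", "random"),
                           hubs_count = max(1L, round(n_taxa / 10)),
                           bandwidth = 1L, edge_density = 0.05,
                           target_condition = 100, edge_value = 0.3,
                           negative_fraction = 0.3, seed = 1L) {
  topology <- match.arg(topology)
  stopifnot(n_taxa >= 2, target_condition > 1, edge_value > 0,
            negative_fraction >= 0, negative_fraction <= 1)
  if (topology == "random") {
    max_edges <- n_taxa * (n_taxa - 1) / 2
    if (edge_density < 0 || edge_density > 1 || round(edge_density * max_edges) < 1) {
      abort("Infeasible `edge_density` for this `n_taxa`.")
    }
  }
  if (topology == "hub" && hubs_count >= n_taxa) {
    abort("`hubs_count` must be smaller than `n_taxa`.")
  }
  structure(list(n_taxa = as.integer(n_taxa), topology = topology,
                 hubs_count = as.integer(hubs_count),
                 bandwidth = as.integer(bandwidth),
                 edge_density = edge_density,
                 target_condition = target_condition,
                 edge_value = edge_value,
                 negative_fraction = negative_fraction,
                 seed = as.integer(seed)),
            class = "precision_spec")
}

precision_support <- function(spec) {
  p <- spec$n_taxa
  A <- matrix(FALSE, p, p)
  if (spec$topology == "hub") {
    hubs <- seq_len(spec$hubs_count)
    spokes <- setdiff(seq_len(p), hubs)
    owner <- hubs[((seq_along(spokes) - 1L) %% spec$hubs_count) + 1L]
    A[cbind(owner, spokes)] <- TRUE
    A[cbind(spokes, owner)] <- TRUE
  } else if (spec$topology == "band") {
    for (k in seq_len(spec$bandwidth)) {
      idx <- seq_len(p - k)
      A[cbind(idx, idx + k)] <- TRUE
      A[cbind(idx + k, idx)] <- TRUE
    }
  } else {
    pairs <- which(upper.tri(A))
    m <- round(spec$edge_density * length(pairs))
    chosen <- sample(pairs, m)
    A[chosen] <- TRUE
    A <- A | t(A)
  }
  A
}

#' Build the ground-truth precision matrix
#'
#' Materialises a [precision_spec] into a symmetric positive-definite matrix
#' whose off-diagonal support matches the declared topology exactly. Edge
#' entries get magnitude `edge_value` with signs drawn at
#' `negative_fraction`; the diagonal is then shifted uniformly so the
#' condition number equals `target_condition` (a uniform shift never alters
#' the support).
#'
#' @param spec A [precision_spec].
#' @return A symmetric positive-definite matrix with attribute `"support"`
#'   (logical adjacency of the true conditional-dependence graph).
#' @export
make_precision <- function(spec) {
  stopifnot(inherits(spec, "precision_spec"))
  with_seed_(spec$seed, {
    A <- precision_support(spec)
    p <- spec$n_taxa
    Omega <- matrix(0, p, p)
    up <- which(upper.tri(A) & A)
    # positive off-diagonal => negative partial correlation
    sgn <- ifelse(runif(length(up)) < spec$negative_fraction, 1, -1)
    Omega[up] <- sgn * spec$edge_value
    Omega <- Omega + t(Omega)
    ev <- eigen(Omega, symmetric = TRUE, only.values = TRUE)$values
    emax <- max(ev); emin <- min(ev)
    c0 <- spec$target_condition
    t_shift <- (emax - c0 * emin) / (c0 - 1)
    if (t_shift <= -emin) t_shift <- -emin + 1e-6
    diag(Omega) <- diag(Omega) + t_shift
    attr(Omega, "support") <- A
    Omega
  })
}

#' Specify one climate zone of a synthetic study
#'
#' Bundles everything needed to simulate one zone: its Koppen-Geiger code,
#' sample count, ground-truth precision structure, sequencing-depth
#' log-normal, zero-inflated negative-binomial (ZINB) marginals, and the
#' geographic bounding box its samples are scattered over.
#'
#' @param zone_code Koppen-Geiger code (e.g. `"Cfb"`).
#' @param n_samples Number of samples in the zone.
#' @param precision A [precision_spec] for the zone's taxa.
#' @param depth_log_mean,depth_log_sd Log-normal parameters of the
#'   per-sample depth factor (defaults: median depth scale `1`, sdlog 0.3;
#'   depth multiplies the quantile-mapped counts, emulating uneven library
#'   sizes and hence compositional distortion).
#' @param zinb_mean_range Range of per-taxon negative-binomial means; means
#'   are drawn log-uniformly within it.
#' @param zinb_dispersion Negative-binomial size parameter (smaller = more
#'   overdispersed).
#' @param zero_inflation Structural zero probability in `[0, 1]`.
#' @param bbox Numeric `c(lat_min, lat_max, lon_min, lon_max)`.
#' @return A `zone_spec` list.
#' @export
zone_spec <- function(zone_code, n_samples, precision,
                      depth_log_mean = 0, depth_log_sd = 0.3,
                      zinb_mean_range = c(5, 200), zinb_dispersion = 1,
                      zero_inflation = 0.15,
                      bbox = c(-60, 70, -180, 180)) {
  stopifnot(inherits(precision, "precision_spec"), n_samples >= 1,
            zero_inflation >= 0, zero_inflation <= 1,
            length(bbox) == 4, bbox[1] < bbox[2], bbox[3] < bbox[4],
            bbox[1] >= -90, bbox[2] <= 90, bbox[3] >= -180, bbox[4] <= 180)
  structure(list(zone_code = as.character(zone_code),
                 n_samples = as.integer(n_samples), precision = precision,
                 depth_log_mean = depth_log_mean, depth_log_sd = depth_log_sd,
                 zinb_mean_range = zinb_mean_range,
                 zinb_dispersion = zinb_dispersion,
                 zero_inflation = zero_inflation, bbox = bbox),
            class = "zone_spec")
}

#' Simulate a zone's count matrix by a Gaussian copula
#'
#' Normal-to-anything (NorTA) construction: latent samples are drawn from a
#' multivariate normal with covariance the inverse of `precision` (rescaled
#' to a correlation matrix), pushed through the normal CDF to uniforms, and
#' mapped through per-taxon zero-inflated negative-binomial quantile
#' functions. Each sample's counts are then scaled by a log-normal depth
#' factor and rounded, so library sizes vary and the data are genuinely
#' compositional.
#'
#' @param precision Symmetric positive-definite matrix (e.g. from
#'   [make_precision()]).
#' @param zone A [zone_spec] giving the marginal and depth parameters.
#' @param seed Integer seed.
#' @return Integer count matrix, taxa in rows, samples in columns.
#' @export
simulate_counts <- function(precision, zone, seed = 1L) {
  stopifnot(inherits(zone, "zone_spec"))
  p <- nrow(precision)
  ev <- eigen((precision + t(precision)) / 2, symmetric = TRUE,
              only.values = TRUE)$values
  if (min(ev) <= 0) abort("`precision` must be positive definite.")
  n <- zone$n_samples
  with_seed_(seed, {
    Sigma <- solve(precision)
    R <- stats::cov2cor(Sigma)
    L <- chol(R)
    Z <- matrix(rnorm(n * p), n, p) %*% L
    U <- pnorm(Z)
    mu <- exp(runif(p, log(zone$zinb_mean_range[1]),
                    log(zone$zinb_mean_range[2])))
    pi0 <- zone$zero_inflation
    counts <- matrix(0, n, p)
    for (j in seq_len(p)) {
      u <- U[, j]
      pos <- u >= pi0
      counts[pos, j] <- qnbinom(pmin((u[pos] - pi0) / (1 - pi0), 1 - 1e-12),
                                mu = mu[j], size = zone$zinb_dispersion)
    }
    if (pi0 >= 1) counts[] <- 0
    depth <- rlnorm(n, zone$depth_log_mean, zone$depth_log_sd)
    counts <- round(counts * depth)
    t(counts)  # taxa x samples
  })
}

#' Generate a complete multi-zone synthetic study
#'
#' Builds the full testbed: a combined ESV count table over all zones, a
#' metadata tibble with coordinates drawn uniformly inside each zone's
#' bounding box and the zone's Koppen code, a synthetic 7-rank taxonomy with
#' tunable unassigned fractions, and the per-zone ground-truth signed
#' adjacencies the network stage should recover. Zones share one global ESV
#' id pool (`ESV_1`, `ESV_2`, ...): a zone with `n_taxa = p` uses the first
#' `p` ids, so taxa can be present in several zones as in a real study.
#'
#' @param zones List of [zone_spec]s with distinct zone codes.
#' @param taxonomy_profile Named numeric vector of per-rank unassigned
#'   fractions (names among kingdom...species); unnamed ranks default to 0
#'   except genus/species which default to 0.4/0.8 (most soil ESVs lack
#'   genus- or species-level assignments).
#' @param empo3 EMPO level-3 habitat label stamped on every sample.
#' @param seed Master seed; each zone's draws come from a stream derived
#'   from `(seed, zone_code)` so zones are independent of list order.
#' @return A `synthetic_study` list with elements `table` ([esv_table]),
#'   `metadata` (tibble), `taxonomy` (tibble), and `truth` (named list of
#'   per-zone signed adjacency matrices restricted to the zone's taxa).
#' @export
make_study <- function(zones, taxonomy_profile = NULL,
                       empo3 = "Soil (non-saline)", seed = 1L) {
  stopifnot(length(zones) >= 1, all(vapply(zones, inherits, TRUE, "zone_spec")))
  codes <- vapply(zones, `[[`, character(1), "zone_code")
  if (anyDuplicated(codes)) abort("Zone codes must be unique.")
  p_all <- max(vapply(zones, function(z) z$precision$n_taxa, integer(1)))
  esv_ids <- sprintf("ESV_%03d", seq_len(p_all))

  prof <- c(kingdom = 0, phylum = 0, class = 0, order = 0.1,
            family = 0.2, genus = 0.4, species = 0.8)
  if (!is.null(taxonomy_profile)) {
    bad <- setdiff(names(taxonomy_profile), names(prof))
    if (length(bad)) abort(paste0("Unknown ranks in taxonomy_profile: ",
                                  paste(bad, collapse = ", ")))
    prof[names(taxonomy_profile)] <- taxonomy_profile
  }

  blocks <- list(); meta <- list(); truth <- list()
  for (z in zones) {
    zseed <- derive_seed(seed, z$zone_code)
    prec_spec <- z$precision
    prec_spec$seed <- derive_seed(zseed, "precision")
    Omega <- make_precision(prec_spec)
    counts <- simulate_counts(Omega, z, seed = derive_seed(zseed, "counts"))
    sample_ids <- sprintf("%s_s%03d", z$zone_code, seq_len(z$n_samples))
    dimnames(counts) <- list(esv_ids[seq_len(nrow(counts))], sample_ids)
    blocks[[z$zone_code]] <- counts
    meta[[z$zone_code]] <- with_seed_(derive_seed(zseed, "coords"), tibble(
      sample_id = sample_ids,
      latitude = runif(z$n_samples, z$bbox[1], z$bbox[2]),
      longitude = runif(z$n_samples, z$bbox[3], z$bbox[4]),
      empo3 = empo3,
      climate_zone = z$zone_code))
    sup <- attr(Omega, "support")
    sgn <- -sign(Omega) * sup  # positive partial correlation = positive edge
    adj <- sgn
    dimnames(adj) <- list(esv_ids[seq_len(nrow(adj))], esv_ids[seq_len(nrow(adj))])
    truth[[z$zone_code]] <- adj
  }
  counts_all <- matrix(0, p_all, sum(vapply(zones, `[[`, integer(1), "n_samples")),
                       dimnames = list(esv_ids, unlist(lapply(meta, `[[`, "sample_id"))))
  for (code in codes) {
    b <- blocks[[code]]
    counts_all[rownames(b), colnames(b)] <- b
  }
  taxonomy <- with_seed_(derive_seed(seed, "taxonomy"),
                         synthetic_taxonomy(esv_ids, prof))
  structure(list(table = esv_table(counts_all),
                 metadata = sample_metadata(dplyr::bind_rows(meta)),
                 taxonomy = taxonomy, truth = truth, seed = as.integer(seed)),
            class = "synthetic_study")
}

# Dummy hierarchical ontology: 5 phyla, 2 classes per phylum, ... with
# requested per-rank unassigned fractions; unassigned cascades downward.
synthetic_taxonomy <- function(esv_ids, prof) {
  n <- length(esv_ids)
  ranks <- taxonomy_rank_names()
  n_cats <- c(kingdom = 1, phylum = 5, class = 10, order = 15, family = 20,
              genus = 30, species = 40)
  pick <- function(rank, parent_idx) {
    k <- n_cats[[rank]]
    idx <- ((parent_idx - 1L) %% k) + 1L
    sprintf("%s%02d", toupper(substr(rank, 1, 1)), idx)
  }
  lineage_idx <- sample.int(100, n, replace = TRUE)
  out <- matrix(UNASSIGNED, n, 7, dimnames = list(NULL, ranks))
  out[, "kingdom"] <- "Bacteria"
  for (r in 2:7) {
    out[, ranks[r]] <- pick(ranks[r], lineage_idx)
  }
  for (r in seq_len(7)) {
    drop <- runif(n) < prof[[ranks[r]]]
    if (any(drop)) out[drop, seq(r, 7)] <- UNASSIGNED
  }
  # enforce cascade (a rank unassigned blanks deeper ranks)
  for (r in 2:7) {
    blank <- out[, ranks[r - 1]] == UNASSIGNED
    out[blank, ranks[r]] <- UNASSIGNED
  }
  dplyr::bind_cols(tibble(esv_id = esv_ids),
                   as_tibble(as.data.frame(out, stringsAsFactors = FALSE)))
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("<synthetic_study> %d ESVs x %d samples, %d zones (%s), seed %d\n",
              nrow(x$table), ncol(x$table), length(x$truth),
              paste(names(x$truth), collapse = ", "), x$seed))
  invisible(x)
}
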