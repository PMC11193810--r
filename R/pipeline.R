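#' Pipeline configuration
#'
#' Bundles every setting of an end-to-end run. All stage seeds are derived
#' deterministically from `master_seed`, and per-zone streams are derived
#' from `(master_seed, zone_code)`, so adding a zone never perturbs the
#' results of another. The configuration is a plain list and serialises
#' cleanly (e.g. with `jsonlite`); its hash is stamped on every output.
#'
#' @param study A `synthetic_study` from [make_study()], or `NULL` when
#'   supplying real inputs via `table`/`metadata`/`taxonomy`.
#' @param table,metadata,taxonomy Real-mode inputs (an [esv_table], a
#'   metadata tibble with `climate_zone` assigned — see [assign_climate()] —
#'   and a taxonomy tibble). Ignored when `study` is given.
#' @param filters A [filter_config].
#' @param stars_beta StARS instability threshold.
#' @param n_subsamples StARS subsample count.
#' @param bootstrap_iter Bootstrap iterations per zone network.
#' @param n_permutations Permutations for Mantel and PERMANOVA.
#' @param overrep_ranks Taxonomic ranks tested for overrepresentation.
#' @param alpha Significance threshold for adjusted p-values.
#' @param master_seed Master seed for every stochastic stage.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(study = NULL, table = NULL, metadata = NULL,
                            taxonomy = NULL, filters = filter_config(),
                            stars_beta = 0.05, n_subsamples = 20,
                            bootstrap_iter = 100, n_permutations = 999,
                            overrep_ranks = c("phylum", "class"),
                            alpha = 0.05, master_seed = 1L) {
  if (is.null(study) && (is.null(table) || is.null(metadata) || is.null(taxonomy))) {
    abort("Provide either `study` or all of `table`, `metadata`, `taxonomy`.")
  }
  structure(list(study = study, table = table, metadata = metadata,
                 taxonomy = taxonomy, filters = filters,
                 stars_beta = stars_beta, n_subsamples = n_subsamples,
                 bootstrap_iter = bootstrap_iter,
                 n_permutations = n_permutations,
                 overrep_ranks = overrep_ranks, alpha = alpha,
                 master_seed = as.integer(master_seed)),
            class = "pipeline_config")
}

#' Run the full climate-stratified co-occurrence study
#'
#' Executes every stage in order: filtering cascade, alpha diversity with
#' pairwise zone comparisons, Bray-Curtis/geographic distance decay
#' (Mantel), NMDS ordination, PERMANOVA, per-zone StARS network inference,
#' scale-free and abundance-degree diagnostics, fixed-size bootstrap
#' topology comparison across zones, hub detection, and taxon-pair
#' overrepresentation. Identical configurations give bit-identical results.
#'
#' @param config A [pipeline_config].
#' @return A `pipeline_result` list: `filter_report`, `alpha`,
#'   `alpha_tests`, `mantel`, `nmds`, `permanova`, `networks`,
#'   `stars_paths`, `network_summary`, `bootstrap`, `bootstrap_tests`,
#'   `global_properties`, `centrality_summary`, `hubs`, `overrep`,
#'   `climate_specific`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$master_seed
  if (!is.null(config$study)) {
    table <- config$study$table
    metadata <- config$study$metadata
    taxonomy <- config$study$taxonomy
  } else {
    table <- as_esv_table(config$table)
    metadata <- as_tibble(config$metadata)
    taxonomy <- as_tibble(config$taxonomy)
  }

  run_stage <- function(stage, zone = NULL, code) {
    tryCatch(code, error = function(e) {
      abort(paste0("Pipeline stage '", stage, "'",
                   if (!is.null(zone)) paste0(" (zone ", zone, ")"),
                   " failed: ", conditionMessage(e)))
    })
  }

  filt <- run_stage("filtering", code =
    apply_filters(table, metadata, taxonomy, config$filters))
  zones <- filt$zones
  tab <- filt$filtered
  meta <- metadata[match(colnames(tab), metadata$sample_id), ]

  alpha <- run_stage("alpha_diversity", code = alpha_diversity(tab, meta))
  alpha_tests <- run_stage("alpha_tests", code = {
    ok <- !is.na(alpha$climate_zone)
    purrr::map(setNames(c("shannon", "simpson", "chao1"),
                        c("shannon", "simpson", "chao1")),
               ~ suppressWarnings(
                 pairwise_wilcoxon_holm(alpha[[.x]][ok], alpha$climate_zone[ok])))
  })

  bc <- run_stage("bray_curtis", code = bray_curtis(tab))
  gd <- run_stage("geo_distances", code = geo_distances(meta))
  mant <- run_stage("mantel", code =
    mantel_test(bc, gd, n_permutations = config$n_permutations,
                seed = derive_seed(seed, "mantel"), exact = FALSE))
  nmds <- run_stage("nmds", code =
    nmds_ordination(bc, k = 2, seed = derive_seed(seed, "nmds")))
  perm <- run_stage("permanova", code =
    permanova(bc, meta$climate_zone, n_permutations = config$n_permutations,
              seed = derive_seed(seed, "permanova")))

  networks <- list(); paths <- list()
  for (z in names(zones)) {
    fit <- run_stage("network_inference", zone = z, code = {
      x <- clr_transform(zones[[z]])
      stars_select(x, beta = config$stars_beta,
                   n_subsamples = config$n_subsamples,
                   seed = derive_seed(seed, paste0("stars:", z)))
    })
    networks[[z]] <- fit$network
    paths[[z]] <- fit$path
  }

  network_summary <- run_stage("network_summary", code =
    purrr::map_dfr(names(networks), function(z) {
      net <- networks[[z]]
      sf <- tryCatch(scale_free_fit(net),
                     error = function(e) list(r_squared = NA_real_,
                                              p_value = NA_real_))
      dplyr::bind_cols(
        tibble(zone = z), glance(net),
        tibble(scale_free_r2 = sf$r_squared, scale_free_p = sf$p_value,
               abundance_degree_rho = suppressWarnings(
                 abundance_degree_correlation(zones[[z]], net))))
    }))

  globals <- run_stage("global_properties", code =
    purrr::map_dfr(networks, global_properties, .id = "zone"))

  boot_size <- min(purrr::map_int(networks, ~ length(.x$nodes)))
  boot <- list()
  for (z in names(networks)) {
    boot[[z]] <- run_stage("bootstrap", zone = z, code =
      bootstrap_properties(networks[[z]], subgraph_size = boot_size,
                           n_iter = config$bootstrap_iter,
                           seed = derive_seed(seed, paste0("boot:", z))))
  }
  boot_tests <- if (length(networks) >= 2) {
    run_stage("bootstrap_tests", code =
      purrr::map(setNames(nm = c("density", "transitivity", "modularity",
                                 "average_path_length")),
                 ~ suppressWarnings(compare_zones(boot, metric = .x))))
  } else {
    NULL
  }

  hubs <- run_stage("hubs", code = purrr::map(networks, find_hubs))
  cents <- run_stage("centralities", code = centrality_summary(networks))
  overrep <- run_stage("overrepresentation", code =
    overrep_report(networks, taxonomy, ranks = config$overrep_ranks,
                   alpha = config$alpha))
  specific <- if (length(networks) >= 2) {
    run_stage("climate_specific", code =
      climate_specific_fraction(networks, taxonomy, rank = "phylum"))
  } else {
    NULL
  }

  cfg_hashable <- config
  manifest <- tibble(
    config_hash = rlang::hash(cfg_hashable),
    master_seed = seed,
    n_zones = length(networks),
    package_version = as.character(utils::packageVersion("climbiome")),
    r_version = paste(R.version$major, R.version$minor, sep = "."))

  structure(list(filter_report = filt$report, alpha = alpha,
                 alpha_tests = alpha_tests, mantel = mant, nmds = nmds,
                 permanova = perm, networks = networks, stars_paths = paths,
                 network_summary = network_summary, bootstrap = boot,
                 bootstrap_tests = boot_tests, global_properties = globals,
                 centrality_summary = cents, hubs = hubs, overrep = overrep,
                 climate_specific = specific, manifest = manifest),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat(sprintf("  zones: %s\n", paste(names(x$networks), collapse = ", ")))
  cat(sprintf("  Mantel r^2 = %.3f (p = %.3g); PERMANOVA R^2 = %.3f (p = %.3g)\n",
              x$mantel$r_squared, x$mantel$p_value,
              x$permanova$r_squared, x$permanova$p_value))
  cat(sprintf("  config hash %s, seed %d\n",
              x$manifest$config_hash, x$manifest$master_seed))
  invisible(x)
}

#' Write pipeline outputs as TSV files
#'
#' Emits the tabular results of a run into a directory: filter report,
#' alpha diversity, network summary, global properties, centrality summary,
#' hub lists, overrepresentation table, StARS paths, and per-zone edge
#' lists. Every table carries the run's config hash as a `config_hash`
#' column.
#'
#' @param result A `pipeline_result`.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_pipeline_outputs <- function(result, dir) {
  stopifnot(inherits(result, "pipeline_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  h <- result$manifest$config_hash
  emit <- function(df, name) {
    df$config_hash <- h
    readr::write_tsv(df, file.path(dir, paste0(name, ".tsv")), progress = FALSE)
  }
  emit(result$filter_report, "filter_report")
  emit(result$alpha, "alpha_diversity")
  emit(result$network_summary, "network_summary")
  emit(result$global_properties, "global_properties")
  emit(result$centrality_summary, "centrality_summary")
  emit(purrr::map_dfr(result$hubs, ~ .x$hubs, .id = "zone"), "hubs")
  emit(result$overrep, "overrepresentation")
  emit(purrr::map_dfr(result$stars_paths, as_tibble, .id = "zone"), "stars_paths")
  for (z in names(result$networks)) {
    write_network(result$networks[[z]],
                  file.path(dir, paste0("network_", z, ".tsv")))
  }
  readr::write_tsv(result$manifest, file.path(dir, "manifest.tsv"),
                   progress = FALSE)
  invisible(dir)
}
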