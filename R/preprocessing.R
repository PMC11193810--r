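#' Filtering configuration
#'
#' Collects the thresholds of the pre-processing stage. Defaults follow the
#' study design: keep `"Soil (non-saline)"` samples, drop ESVs below 0.001%
#' relative abundance (`strict = TRUE` switches to 0.01%) or present in
#' fewer than 30% of samples, keep Bacteria only, and keep climate zones
#' with at least five samples.
#'
#' @param empo3_keep EMPO level-3 label retained.
#' @param rel_abund_min Minimum relative abundance (fraction of the grand
#'   total; `1e-5` = 0.001%).
#' @param prevalence_min Minimum fraction of samples with a nonzero count.
#' @param domain_keep Kingdom retained.
#' @param zone_min_samples Minimum samples per climate zone.
#' @param abundance_method `"total"` (ESV total over grand total, the
#'   default) or `"mean"` (mean per-sample relative abundance).
#' @param strict If `TRUE`, overrides `rel_abund_min` with the stricter
#'   0.01% threshold used for the consistency re-run.
#' @return A `filter_config` list.
#' @export
filter_config <- function(empo3_keep = "Soil (non-saline)",
                          rel_abund_min = 1e-5, prevalence_min = 0.30,
                          domain_keep = "Bacteria", zone_min_samples = 5L,
                          abundance_method = c("total", "mean"),
                          strict = FALSE) {
  abundance_method <- match.arg(abundance_method)
  if (strict) rel_abund_min <- 1e-4
  stopifnot(rel_abund_min >= 0, rel_abund_min <= 1,
            prevalence_min >= 0, prevalence_min <= 1, zone_min_samples >= 1)
  structure(list(empo3_keep = empo3_keep, rel_abund_min = rel_abund_min,
                 prevalence_min = prevalence_min, domain_keep = domain_keep,
                 zone_min_samples = as.integer(zone_min_samples),
                 abundance_method = abundance_method),
            class = "filter_config")
}

#' Restrict samples to one EMPO level-3 habitat
#'
#' Keeps the columns whose metadata `empo3` label matches `keep`. Rows are
#' untouched; ESVs that become all-zero stay in the table (they are removed
#' later by the abundance/prevalence filter).
#'
#' @param table An [esv_table].
#' @param meta Sample metadata containing every retained sample id.
#' @param keep Label to retain.
#' @return Filtered [esv_table].
#' @export
filter_empo3 <- function(table, meta, keep = "Soil (non-saline)") {
  table <- as_esv_table(table)
  meta <- as_tibble(meta)
  if (!keep %in% meta$empo3) {
    warn(paste0("EMPO3 label '", keep, "' absent from metadata; result is empty."))
  }
  keep_ids <- meta$sample_id[!is.na(meta$empo3) & meta$empo3 == keep]
  missing <- setdiff(colnames(table), meta$sample_id)
  if (length(missing)) {
    abort(paste0("Samples missing from metadata: ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  table[, colnames(table) %in% keep_ids, drop = FALSE]
}

#' Abundance and prevalence filter
#'
#' Retains an ESV iff its relative abundance is at least `rel_abund_min`
#' AND it is present (count > 0) in at least `prevalence_min` of samples;
#' both comparisons are inclusive. Relative abundance is the ESV's total
#' count over the grand total (`method = "total"`, the default) or the mean
#' of its per-sample relative abundances (`method = "mean"`). The filter is
#' intended to run once on the full habitat-filtered table, not per zone:
#' per-zone filtering leaves too few ESVs in small zones and destabilises
#' the downstream network selection.
#'
#' @param table Non-empty [esv_table].
#' @param rel_abund_min,prevalence_min Inclusive thresholds in `[0, 1]`.
#' @param method Relative-abundance definition (see above).
#' @return Filtered [esv_table].
#' @export
filter_abundance_prevalence <- function(table, rel_abund_min = 1e-5,
                                        prevalence_min = 0.30,
                                        method = c("total", "mean")) {
  method <- match.arg(method)
  table <- as_esv_table(table)
  if (!nrow(table) || !ncol(table)) abort("Table has no rows or no samples.")
  grand <- sum(table)
  if (grand == 0) abort("Grand total of counts is zero.")
  rel <- if (method == "total") {
    rowSums(table) / grand
  } else {
    rowMeans(sweep(unclass(table), 2, pmax(colSums(table), 1), "/"))
  }
  prev <- rowMeans(unclass(table) > 0)
  table[rel >= rel_abund_min & prev >= prevalence_min, , drop = FALSE]
}

#' Restrict ESVs to one kingdom
#'
#' Applied after the abundance/prevalence filter, this drops every ESV whose
#' kingdom-rank assignment differs from `keep` (Archaea and unassigned
#' kingdoms are removed when keeping Bacteria).
#'
#' @param table An [esv_table].
#' @param taxonomy Tibble with columns `esv_id` and `kingdom` covering every
#'   ESV in `table`.
#' @param keep Kingdom label retained.
#' @return Filtered [esv_table].
#' @export
filter_domain <- function(table, taxonomy, keep = "Bacteria") {
  table <- as_esv_table(table)
  taxonomy <- as_tibble(taxonomy)
  missing <- setdiff(rownames(table), taxonomy$esv_id)
  if (length(missing)) {
    abort(paste0("No taxonomy for ESVs: ", paste(head(missing, 5), collapse = ", ")))
  }
  king <- taxonomy$kingdom[match(rownames(table), taxonomy$esv_id)]
  out <- table[!is.na(king) & king == keep, , drop = FALSE]
  if (!nrow(out)) warn(paste0("No ESVs left after keeping kingdom '", keep, "'."))
  out
}

#' Split a table into per-climate-zone tables
#'
#' Partitions the samples by their climate-zone label, drops zones with
#' fewer than `zone_min_samples` samples, and within each zone removes ESVs
#' with zero total count there (each zone's network is built only over taxa
#' actually observed in that zone). Samples without a zone label are dropped
#' with a message.
#'
#' @param table An [esv_table].
#' @param meta Sample metadata with `climate_zone`.
#' @param zone_min_samples Minimum samples a zone needs to be analysed.
#' @return Named list of per-zone [esv_table]s.
#' @export
split_by_zone <- function(table, meta, zone_min_samples = 5L) {
  table <- as_esv_table(table)
  meta <- as_tibble(meta)
  zone <- meta$climate_zone[match(colnames(table), meta$sample_id)]
  n_unlabelled <- sum(is.na(zone))
  if (n_unlabelled) {
    inform(paste0("Dropping ", n_unlabelled, " sample(s) without a climate zone."))
  }
  keep <- !is.na(zone)
  zone <- zone[keep]
  table <- table[, keep, drop = FALSE]
  sizes <- table(zone)
  zones_ok <- names(sizes)[sizes >= zone_min_samples]
  if (!length(zones_ok)) {
    abort(paste0("No climate zone has at least ", zone_min_samples, " samples."))
  }
  out <- lapply(zones_ok, function(z) {
    sub <- table[, zone == z, drop = FALSE]
    sub[rowSums(sub) > 0, , drop = FALSE]
  })
  setNames(out, zones_ok)
}

#' Run the full filtering cascade
#'
#' EMPO3 habitat filter, abundance/prevalence filter, kingdom filter, then
#' the per-zone split — in that order. Returns the per-zone tables plus a
#' stage-by-stage report of surviving dimensions.
#'
#' @param table An [esv_table].
#' @param meta Sample metadata.
#' @param taxonomy Taxonomy tibble.
#' @param config A [filter_config].
#' @return List with `zones` (named list of [esv_table]s), `filtered` (the
#'   combined post-filter table) and `report` (tibble of stage dimensions).
#' @export
apply_filters <- function(table, meta, taxonomy, config = filter_config()) {
  stopifnot(inherits(config, "filter_config"))
  stage <- function(name, tab) tibble(stage = name, n_esvs = nrow(tab),
                                      n_samples = ncol(tab))
  report <- stage("input", table)
  t1 <- filter_empo3(table, meta, config$empo3_keep)
  report <- bind_rows(report, stage("empo3", t1))
  t2 <- filter_abundance_prevalence(t1, config$rel_abund_min,
                                    config$prevalence_min,
                                    config$abundance_method)
  report <- bind_rows(report, stage("abundance_prevalence", t2))
  t3 <- filter_domain(t2, taxonomy, config$domain_keep)
  report <- bind_rows(report, stage("domain", t3))
  # drop samples that lost all counts before the zone split
  t3 <- t3[, colSums(t3) > 0, drop = FALSE]
  report <- bind_rows(report, stage("nonzero_samples", t3))
  zones <- split_by_zone(t3, meta, config$zone_min_samples)
  list(zones = zones, filtered = t3, report = report)
}
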