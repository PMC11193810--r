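#' ESV count table
#'
#' An `esv_table` is a non-negative integer matrix of read counts with exact
#' sequence variants (ESVs) in rows and samples in columns, carrying unique
#' row and column identifiers. It is the central container of the pipeline:
#' filters subset it, diversity statistics summarise its columns, and the
#' network stage transposes it into a sample-by-taxon data matrix.
#'
#' @param counts Numeric matrix of non-negative finite counts
#'   (ESVs x samples).
#' @param esv_ids Character vector of unique row identifiers. Defaults to the
#'   matrix rownames.
#' @param sample_ids Character vector of unique column identifiers. Defaults
#'   to the matrix colnames.
#'
#' @return An `esv_table`: the validated count matrix with `dimnames` set and
#'   class `"esv_table"`.
#' @examples
#' tab <- esv_table(matrix(c(1, 0, 2, 3, 0, 5), nrow = 3, byrow = TRUE,
#'                         dimnames = list(paste0("esv", 1:3), c("s1", "s2"))))
#' n_esvs(tab)
#' @export
esv_table <- function(counts, esv_ids = rownames(counts),
                      sample_ids = colnames(counts)) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (is.null(esv_ids)) esv_ids <- sprintf("esv_%d", seq_len(nrow(counts)))
  if (is.null(sample_ids)) sample_ids <- sprintf("sample_%d", seq_len(ncol(counts)))
  esv_ids <- as.character(esv_ids)
  sample_ids <- as.character(sample_ids)
  if (length(esv_ids) != nrow(counts)) {
    abort("`esv_ids` length must equal the number of rows of `counts`.")
  }
  if (length(sample_ids) != ncol(counts)) {
    abort("`sample_ids` length must equal the number of columns of `counts`.")
  }
  if (anyDuplicated(esv_ids)) {
    abort(paste0("Duplicate ESV ids: ",
                 paste(unique(esv_ids[duplicated(esv_ids)]), collapse = ", ")))
  }
  if (anyDuplicated(sample_ids)) {
    abort(paste0("Duplicate sample ids: ",
                 paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", ")))
  }
  if (length(counts) && (any(!is.finite(counts)) || any(counts < 0))) {
    abort("Counts must be finite and non-negative.")
  }
  dimnames(counts) <- list(esv_ids, sample_ids)
  structure(counts, class = c("esv_table", "matrix", "array"))
}

#' @rdname esv_table
#' @param x Object to test or coerce.
#' @export
is_esv_table <- function(x) inherits(x, "esv_table")

#' @rdname esv_table
#' @export
as_esv_table <- function(x) {
  if (is_esv_table(x)) x else esv_table(as.matrix(x))
}

#' @rdname esv_table
#' @export
n_esvs <- function(x) nrow(x)

#' @rdname esv_table
#' @export
n_samples <- function(x) ncol(x)

#' @export
print.esv_table <- function(x, ...) {
  cat(sprintf("<esv_table> %d ESVs x %d samples, total count %s\n",
              nrow(x), ncol(x), format(sum(x), big.mark = ",")))
  if (nrow(x) && ncol(x)) {
    print(unclass(x)[seq_len(min(5, nrow(x))), seq_len(min(5, ncol(x))), drop = FALSE])
    if (nrow(x) > 5 || ncol(x) > 5) cat("...\n")
  }
  invisible(x)
}

# subsetting keeps the class and re-validates id uniqueness implicitly
#' @export
`[.esv_table` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = FALSE)
  structure(out, class = c("esv_table", "matrix", "array"))
}

#' @export
as_tibble.esv_table <- function(x, ...) {
  tibble(esv_id = rep(rownames(x), times = ncol(x)),
         sample_id = rep(colnames(x), each = nrow(x)),
         count = as.vector(unclass(x)))
}

#' Sample metadata table
#'
#' Validates a per-sample metadata tibble: coordinates in bounds, required
#' columns present. `climate_zone` may be `NA` for samples that fall on
#' ocean cells of the climate map or lack coordinates.
#'
#' @param data Data frame with columns `sample_id`, `latitude`, `longitude`,
#'   `empo3` and optionally `climate_zone`.
#' @return A validated tibble with class `sample_metadata` prepended.
#' @export
sample_metadata <- function(data) {
  data <- as_tibble(data)
  needed <- c("sample_id", "latitude", "longitude", "empo3")
  missing_cols <- setdiff(needed, names(data))
  if (length(missing_cols)) {
    abort(paste0("Metadata is missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  if (!"climate_zone" %in% names(data)) data$climate_zone <- NA_character_
  if (anyDuplicated(data$sample_id)) abort("Duplicate sample ids in metadata.")
  lat <- data$latitude
  lon <- data$longitude
  bad <- (!is.na(lat) & (lat < -90 | lat > 90)) |
    (!is.na(lon) & (lon < -180 | lon > 180))
  if (any(bad)) {
    abort(paste0("Coordinates out of bounds for samples: ",
                 paste(head(data$sample_id[bad], 5), collapse = ", ")))
  }
  class(data) <- c("sample_metadata", class(data))
  data
}
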