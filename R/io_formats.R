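#' Read an ESV observation table
#'
#' Reads a count table with ESVs in rows and samples in columns. Two on-disk
#' dialects are supported: plain TSV (first column = ESV id, header row =
#' sample ids) and BIOM (JSON 1.0 or HDF5 2.1, dispatched to the biomformat
#' package). Row and column order are preserved exactly as stored.
#'
#' @param path Path to the table file.
#' @param format `"tsv"` or `"biom"`. Defaults to a guess from the file
#'   extension (`.biom` -> biom, otherwise tsv).
#' @return An [esv_table].
#' @export
read_esv_table <- function(path, format = c("auto", "tsv", "biom")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.biom$", path, ignore.case = TRUE)) "biom" else "tsv"
  }
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      abort("Reading BIOM files requires the 'biomformat' package.")
    }
    b <- tryCatch(biomformat::read_biom(path),
                  error = function(e) abort(paste0("Malformed BIOM file '", path,
                                                   "': ", conditionMessage(e))))
    m <- as(biomformat::biom_data(b), "matrix")
    return(esv_table(m))
  }
  raw <- tryCatch(
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                    name_repair = "minimal"),
    error = function(e) abort(paste0("Malformed TSV table '", path, "': ",
                                     conditionMessage(e))))
  if (ncol(raw) < 1) abort(paste0("Malformed TSV table '", path, "': no columns."))
  ids <- as.character(raw[[1]])
  m <- matrix(NA_real_, nrow = nrow(raw), ncol = ncol(raw) - 1L,
              dimnames = list(NULL, names(raw)[-1]))
  for (j in seq_len(ncol(raw) - 1L)) {
    m[, j] <- suppressWarnings(as.numeric(raw[[j + 1L]]))
  }
  if (length(m) && any(!is.finite(m))) {
    bad <- ids[which(rowSums(!is.finite(m)) > 0)[1]]
    abort(paste0("Malformed TSV table '", path, "': non-numeric count in record '",
                 bad, "'."))
  }
  rownames(m) <- ids
  esv_table(m)
}

#' @rdname read_esv_table
#' @param table An [esv_table] to write.
#' @export
write_esv_table <- function(table, path, format = c("auto", "tsv", "biom")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.biom$", path, ignore.case = TRUE)) "biom" else "tsv"
  }
  table <- as_esv_table(table)
  if (format == "biom") {
    if (!requireNamespace("biomformat", quietly = TRUE)) {
      abort("Writing BIOM files requires the 'biomformat' package.")
    }
    b <- biomformat::make_biom(unclass(table))
    biomformat::write_biom(b, path)
    return(invisible(path))
  }
  df <- data.frame(esv_id = rownames(table) %||% character(0), unclass(table),
                   check.names = FALSE, stringsAsFactors = FALSE)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

taxonomy_rank_names <- function() {
  c("kingdom", "phylum", "class", "order", "family", "genus", "species")
}

#' Sentinel label for an unassigned taxonomic rank
#' @export
UNASSIGNED <- "Unassigned"

#' Parse greengenes-style lineage strings
#'
#' Splits lineage strings of the form
#' `"k__Bacteria; p__Acidobacteria; c__..."` into the seven canonical ranks.
#' Empty rank payloads (`"g__"`), missing trailing ranks, and the bare string
#' `"Unassigned"` all map to the [UNASSIGNED] sentinel; once a rank is
#' unassigned every deeper rank is forced unassigned too, so lineages are
#' always prefix-consistent.
#'
#' @param lineage Character vector of lineage strings.
#' @param esv_id Optional character vector of ESV ids (same length); when
#'   supplied it becomes the first column of the result.
#' @return A tibble with columns `kingdom` ... `species` (and `esv_id` first
#'   when given), one row per input string.
#' @examples
#' parse_taxonomy("k__Bacteria; p__Acidobacteria; c__Acidobacteriia")
#' @export
parse_taxonomy <- function(lineage, esv_id = NULL) {
  ranks <- taxonomy_rank_names()
  prefixes <- c("k__", "p__", "c__", "o__", "f__", "g__", "s__")
  parse_one <- function(s) {
    s <- stringr::str_trim(s)
    if (is.na(s) || s == "" || tolower(s) == "unassigned") {
      return(rep(UNASSIGNED, 7L))
    }
    parts <- stringr::str_trim(stringr::str_split_1(s, ";"))
    parts <- parts[parts != ""]
    out <- rep(UNASSIGNED, 7L)
    for (p in parts) {
      hit <- match(substr(p, 1, 3), prefixes)
      if (is.na(hit)) {
        abort(paste0("Unknown rank prefix in lineage fragment '", p, "'."))
      }
      payload <- stringr::str_trim(substr(p, 4, nchar(p)))
      out[hit] <- if (nchar(payload)) payload else UNASSIGNED
    }
    # cascade: unassigned at rank r blanks all deeper ranks
    first_un <- which(out == UNASSIGNED)
    if (length(first_un)) out[seq(min(first_un), 7L)] <- UNASSIGNED
    out
  }
  mat <- t(vapply(lineage, parse_one, character(7L), USE.NAMES = FALSE))
  colnames(mat) <- ranks
  out <- as_tibble(as.data.frame(mat, stringsAsFactors = FALSE))
  if (!is.null(esv_id)) out <- dplyr::bind_cols(tibble(esv_id = esv_id), out)
  out
}

#' Read a Koppen-Geiger lookup grid
#'
#' The climate map is a TSV of rectangular cells with columns `lat_min`,
#' `lat_max`, `lon_min`, `lon_max`, `code`. Cells labelled `OCEAN` (or `NA`)
#' denote unclassified area.
#'
#' @param path Path to the TSV grid.
#' @return A tibble with class `koppen_lookup`.
#' @export
read_koppen_map <- function(path) {
  grid <- readr::read_tsv(path, col_types = readr::cols(
    lat_min = readr::col_double(), lat_max = readr::col_double(),
    lon_min = readr::col_double(), lon_max = readr::col_double(),
    code = readr::col_character()), progress = FALSE)
  koppen_lookup(grid)
}

#' @rdname read_koppen_map
#' @param grid Data frame of grid cells.
#' @export
koppen_lookup <- function(grid) {
  grid <- as_tibble(grid)
  needed <- c("lat_min", "lat_max", "lon_min", "lon_max", "code")
  if (!all(needed %in% names(grid))) {
    abort(paste0("Climate map needs columns: ", paste(needed, collapse = ", ")))
  }
  if (any(grid$lat_min >= grid$lat_max) || any(grid$lon_min >= grid$lon_max)) {
    abort("Degenerate climate-map cell (min >= max).")
  }
  # scan order fixes the boundary tie rule: south, then west, wins
  grid <- arrange(grid, .data$lat_min, .data$lon_min)
  class(grid) <- c("koppen_lookup", class(grid))
  grid
}

#' Assign Koppen-Geiger climate codes to coordinates
#'
#' Looks each point up in the climate grid. A point lying exactly on a cell
#' boundary resolves to the southern/western cell. Points falling on no cell,
#' or on a cell coded `OCEAN`, get `NA` — never a silent default.
#'
#' @param lat,lon Numeric vectors of WGS-84 decimal degrees (longitudes are
#'   normalized into `[-180, 180)`).
#' @param map A `koppen_lookup` grid.
#' @return Character vector of climate codes (`NA` = unclassified/ocean).
#' @export
assign_climate <- function(lat, lon, map) {
  stopifnot(inherits(map, "koppen_lookup"), length(lat) == length(lon))
  if (any(!is.na(lat) & (lat < -90 | lat > 90))) {
    abort("Latitude out of [-90, 90].")
  }
  lon <- ((lon + 180) %% 360) - 180
  vapply(seq_along(lat), function(i) {
    if (is.na(lat[i]) || is.na(lon[i])) return(NA_character_)
    hit <- map$lat_min <= lat[i] & lat[i] <= map$lat_max &
      map$lon_min <= lon[i] & lon[i] <= map$lon_max
    if (!any(hit)) return(NA_character_)
    code <- map$code[which(hit)[1]]   # grid sorted south/west-first
    if (is.na(code) || toupper(code) == "OCEAN") NA_character_ else code
  }, character(1))
}

#' Write and read co-occurrence networks
#'
#' The TSV dialect stores one edge per line with columns `source`, `target`,
#' `sign`, `weight`, preceded by `#node` lines so isolated nodes survive the
#' round trip; GraphML goes through igraph with `sign` and `weight` edge
#' attributes. Reading back either dialect reproduces the node set and the
#' signed edge set exactly.
#'
#' @param net A [co_network].
#' @param path Output path.
#' @param format `"tsv"` or `"graphml"` (guessed from the extension by
#'   default).
#' @return `write_network` returns the path invisibly; `read_network`
#'   returns a [co_network].
#' @export
write_network <- function(net, path, format = c("auto", "tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.graphml$", path, ignore.case = TRUE)) "graphml" else "tsv"
  }
  stopifnot(inherits(net, "co_network"))
  if (format == "graphml") {
    igraph::write_graph(as_igraph(net), path, format = "graphml")
    return(invisible(path))
  }
  con <- tryCatch(file(path, "w"),
                  error = function(e) abort(paste0("Cannot write '", path, "'.")))
  on.exit(close(con))
  if (length(net$nodes)) writeLines(paste0("#node\t", net$nodes), con)
  writeLines("source\ttarget\tsign\tweight", con)
  if (nrow(net$edges)) {
    writeLines(sprintf("%s\t%s\t%d\t%.17g", net$edges$from, net$edges$to,
                       net$edges$sign, net$edges$weight), con)
  }
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path, format = c("auto", "tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.graphml$", path, ignore.case = TRUE)) "graphml" else "tsv"
  }
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    return(as_co_network(g))
  }
  lines <- readLines(path)
  node_lines <- grepl("^#node\t", lines)
  nodes <- sub("^#node\t", "", lines[node_lines])
  body <- lines[!node_lines]
  if (!length(body) || body[1] != "source\ttarget\tsign\tweight") {
    abort(paste0("Malformed network file '", path, "': missing header."))
  }
  if (length(body) > 1) {
    edges <- readr::read_tsv(I(paste(body, collapse = "\n")),
                             col_types = "ccid", progress = FALSE)
    names(edges) <- c("from", "to", "sign", "weight")
  } else {
    edges <- tibble(from = character(), to = character(),
                    sign = integer(), weight = double())
  }
  co_network(nodes = nodes, edges = edges)
}
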