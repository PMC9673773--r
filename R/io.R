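#' @title Tabular I/O for survey data
#' @description Readers and writers for the plain-text formats every stage of
#'   the pipeline consumes: taxa-by-sample read tables, sample metadata,
#'   taxonomy assignments and trawl catch tables. TSV is the default; CSV is
#'   auto-detected from the `.csv` extension. All writers emit UTF-8,
#'   newline-terminated files with a deterministic column order, so writing
#'   and re-reading a table is an identity.
#' @name io
NULL

sep_for <- function(path) if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = sep_for(path), quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "")
  invisible(path)
}

read_delim_checked <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  # read.table silently de-duplicates header names; check the raw header
  header <- strsplit(readLines(path, n = 1), sep_for(path), fixed = TRUE)[[1]]
  if (anyDuplicated(header))
    stop("duplicate column in ", basename(path), ": ",
         paste(unique(header[duplicated(header)]), collapse = ", "), call. = FALSE)
  utils::read.table(path, sep = sep_for(path), header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE,
                    na.strings = "", quote = "", comment.char = "")
}

# Internal constructor: validates and classes a taxa x samples count matrix.
new_read_table <- function(counts) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("read table needs taxon row names and sample column names", call. = FALSE)
  if (anyDuplicated(rownames(counts)))
    stop("duplicate taxon labels: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(colnames(counts)))
    stop("duplicate sample labels: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("read counts must be non-negative integers", call. = FALSE)
  storage.mode(counts) <- "integer"
  structure(counts, class = c("read_table", "matrix", "array"))
}

#' Read / write a taxa-by-sample read table
#'
#' The file format is one header line (`taxon_id` then sample IDs) followed
#' by one row per taxon of non-negative integer counts. Negative,
#' non-integer or missing counts are rejected with the offending taxon and
#' sample named; duplicate taxon or sample labels are rejected.
#'
#' @param path File path (`.tsv`/`.txt` tab-separated, `.csv` comma).
#' @return `read_read_table()`: an integer matrix of class `read_table`
#'   (taxa in rows, samples in columns).
#' @export
read_read_table <- function(path) {
  df <- read_delim_checked(path)
  if (ncol(df) < 2) stop("read table needs a taxon column plus >= 1 sample column", call. = FALSE)
  taxa <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  bad <- which(is.na(suppressWarnings(as.numeric(m))) | suppressWarnings(as.numeric(m)) < 0 |
                 suppressWarnings(as.numeric(m)) != round(suppressWarnings(as.numeric(m))))
  if (length(bad)) {
    ij <- arrayInd(bad[1], dim(m))
    stop(sprintf("invalid count at taxon '%s', sample '%s': %s",
                 taxa[ij[1]], colnames(m)[ij[2]], m[bad[1]]), call. = FALSE)
  }
  storage.mode(m) <- "numeric"
  rownames(m) <- taxa
  new_read_table(m)
}

#' @rdname read_read_table
#' @param table A `read_table`.
#' @return `write_read_table()`: the path, invisibly.
#' @export
write_read_table <- function(table, path) {
  stopifnot(inherits(table, "read_table"))
  df <- data.frame(taxon_id = rownames(table), table, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Read sample metadata
#'
#' Expects columns `sample_id`, `station`, `location`, `bottle`, `type`
#' (`field`/`blank`). Blanks may leave `location` and `bottle` empty.
#'
#' @param path File path.
#' @return A data frame of sample records.
#' @export
read_metadata <- function(path) {
  df <- read_delim_checked(path)
  need <- c("sample_id", "station", "location", "bottle", "type")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("metadata missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample_id in metadata: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "), call. = FALSE)
  if (!all(df$type %in% c("field", "blank")))
    stop("metadata `type` must be 'field' or 'blank'", call. = FALSE)
  df[, need]
}

#' Validate metadata against a read table and infer the design
#'
#' Checks that every sample column of the read table has a metadata record,
#' infers the survey design counts from the field records, and reports (not
#' rejects) irregularities: unbalanced locations per station, bottles per
#' location, or metadata samples absent from the table.
#'
#' @param records Sample metadata data frame (see [read_metadata()]).
#' @param read_table A `read_table`, or `NULL` to validate metadata alone.
#' @return A list of class `design_summary`: `n_stations`,
#'   `locations_per_station` (modal value), `bottles_per_location` (modal),
#'   `blanks_per_station` (modal), `n_field`, `n_blank`, and a character
#'   vector `irregularities`.
#' @export
validate_metadata <- function(records, read_table = NULL) {
  stopifnot(is.data.frame(records))
  irr <- character()
  if (!is.null(read_table)) {
    missing <- setdiff(colnames(read_table), records$sample_id)
    if (length(missing))
      stop("read-table samples missing from metadata: ",
           paste(missing, collapse = ", "), call. = FALSE)
    unused <- setdiff(records$sample_id, colnames(read_table))
    if (length(unused))
      irr <- c(irr, sprintf("%d metadata samples absent from read table: %s",
                            length(unused), paste(unused, collapse = ", ")))
  }
  field <- records[records$type == "field", , drop = FALSE]
  blank <- records[records$type == "blank", , drop = FALSE]
  stations <- unique(field$station)

  loc_per_st <- tapply(field$location, field$station, function(x) length(unique(x)))
  bot_per_loc <- tapply(field$sample_id, field$location, length)
  blk_per_st <- if (nrow(blank)) table(factor(blank$station, levels = stations)) else
    stats::setNames(rep(0L, length(stations)), stations)

  modal <- function(x) as.integer(names(sort(table(x), decreasing = TRUE))[1])
  if (length(unique(loc_per_st)) > 1)
    for (s in names(loc_per_st)[loc_per_st != modal(loc_per_st)])
      irr <- c(irr, sprintf("station %s has %d/%d locations", s, loc_per_st[[s]], modal(loc_per_st)))
  if (length(unique(bot_per_loc)) > 1)
    for (l in names(bot_per_loc)[bot_per_loc != modal(bot_per_loc)])
      irr <- c(irr, sprintf("station %s location %s has %d/%d bottles",
                            field$station[match(l, field$location)], l,
                            bot_per_loc[[l]], modal(bot_per_loc)))

  structure(list(
    n_stations = length(stations),
    locations_per_station = modal(loc_per_st),
    bottles_per_location = modal(bot_per_loc),
    blanks_per_station = modal(as.integer(blk_per_st)),
    n_field = nrow(field), n_blank = nrow(blank),
    irregularities = irr
  ), class = "design_summary")
}

#' @export
print.design_summary <- function(x, ...) {
  cat(sprintf("Inferred design: %d stations, %d locations/station, %d bottles/location, %d blank(s)/station (%d field + %d blank samples)\n",
              x$n_stations, x$locations_per_station, x$bottles_per_location,
              x$blanks_per_station, x$n_field, x$n_blank))
  if (length(x$irregularities)) {
    cat("Irregularities:\n")
    for (i in x$irregularities) cat(" -", i, "\n")
  }
  invisible(x)
}

#' Convert read counts to replicate detection histories
#'
#' A species is called detected in a bottle when its read count reaches
#' `min_reads`. Bottles are grouped into sites at the chosen level
#' (locations by default, so K equals bottles per location), blanks are
#' excluded, and ragged designs are kept as per-site K rather than padded.
#'
#' @param read_table A `read_table`.
#' @param records Sample metadata covering every sample in the table.
#' @param site_level `"location"` or `"station"`.
#' @param min_reads Minimum reads to call a detection (>= 1).
#' @return An object of class `detection_array`: `y` (binary species x
#'   bottle matrix, field bottles only), `bottle_site` (site of each bottle
#'   column), `sites` (data frame site/station), `K` (named per-site
#'   replicate count), and `d` (species x site detection-count matrix).
#' @export
binarize_detections <- function(read_table, records, site_level = c("location", "station"),
                                min_reads = 1) {
  stopifnot(inherits(read_table, "read_table"))
  site_level <- match.arg(site_level)
  if (!is.numeric(min_reads) || min_reads < 1)
    stop("`min_reads` must be >= 1", call. = FALSE)
  missing <- setdiff(colnames(read_table), records$sample_id)
  if (length(missing))
    stop("samples missing from metadata: ", paste(missing, collapse = ", "), call. = FALSE)

  rec <- records[match(colnames(read_table), records$sample_id), , drop = FALSE]
  keep <- rec$type == "field"
  y <- (unclass(read_table)[, keep, drop = FALSE] >= min_reads) * 1L
  rec <- rec[keep, , drop = FALSE]
  bottle_site <- if (site_level == "location") rec$location else rec$station

  sites <- data.frame(site = unique(bottle_site), stringsAsFactors = FALSE)
  sites$station <- rec$station[match(sites$site, bottle_site)]
  K <- stats::setNames(as.integer(table(factor(bottle_site, levels = sites$site))), sites$site)

  d <- t(apply(y, 1, function(row) tapply(row, factor(bottle_site, levels = sites$site), sum)))
  if (nrow(y) == 1) {
    d <- matrix(d, nrow = 1, dimnames = list(rownames(y), sites$site))
  }
  storage.mode(d) <- "integer"

  structure(list(y = y, bottle_site = bottle_site, sites = sites, K = K, d = d,
                 site_level = site_level, min_reads = min_reads),
            class = "detection_array")
}

#' Read a trawl catch table
#'
#' Long format: `station`, `species`, `count`, optional `biomass_kg` and
#' `standard_length_mm`. Duplicate (station, species) rows are aggregated by
#' summing counts (and biomass when present).
#'
#' @param path File path.
#' @return A `trawl_table` data frame aggregated per (station, species).
#' @export
read_trawl_table <- function(path) {
  df <- read_delim_checked(path)
  need <- c("station", "species", "count")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("trawl table missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  if (nrow(df) == 0) {
    out <- data.frame(station = character(), species = character(), count = integer(),
                      stringsAsFactors = FALSE)
    class(out) <- c("trawl_table", "data.frame")
    return(out)
  }
  if (any(is.na(df$count)) || any(df$count < 0) || any(df$count != round(df$count)))
    stop("trawl counts must be non-negative integers", call. = FALSE)
  agg <- stats::aggregate(df["count"], by = df[c("station", "species")], FUN = sum)
  if ("biomass_kg" %in% names(df) && !anyNA(df$biomass_kg)) {
    bm <- stats::aggregate(df["biomass_kg"], by = df[c("station", "species")], FUN = sum)
    agg <- merge(agg, bm, by = c("station", "species"), sort = FALSE)
  }
  agg <- agg[order(agg$station, agg$species), , drop = FALSE]
  agg$count <- as.integer(agg$count)
  rownames(agg) <- NULL
  class(agg) <- c("trawl_table", "data.frame")
  agg
}

#' Read a taxonomy assignment table
#'
#' Expects `taxon_id` plus the 7-rank path `phylum`, `class`, `order`,
#' `family`, `genus`, `species` (a `superkingdom`/`domain` or extra rank
#' column is ignored with a warning) and an optional `confidence`. An empty
#' cell means unassigned at that rank; a filled rank requires all higher
#' ranks filled.
#'
#' @param path File path.
#' @return A data frame with `taxon_id`, the six rank columns and
#'   `confidence` (NA when absent).
#' @export
read_taxonomy <- function(path) {
  df <- read_delim_checked(path)
  ranks <- c("phylum", "class", "order", "family", "genus", "species")
  miss <- setdiff(c("taxon_id", ranks), names(df))
  if (length(miss)) stop("taxonomy missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  extra <- setdiff(names(df), c("taxon_id", ranks, "confidence"))
  if (length(extra))
    warning("ignoring extra taxonomy columns: ", paste(extra, collapse = ", "), call. = FALSE)
  if (anyDuplicated(df$taxon_id))
    stop("duplicate taxon_id rows in taxonomy table", call. = FALSE)
  for (i in seq_along(ranks)[-1]) {
    bad <- !is.na(df[[ranks[i]]]) & is.na(df[[ranks[i - 1]]])
    if (any(bad))
      stop(sprintf("taxon %s assigned at %s but not %s", df$taxon_id[bad][1],
                   ranks[i], ranks[i - 1]), call. = FALSE)
  }
  if (!"confidence" %in% names(df)) df$confidence <- NA_real_
  df[, c("taxon_id", ranks, "confidence")]
}
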