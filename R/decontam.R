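#' Blank-based contamination filtering
#'
#' Pre-occupancy cleanup driven by field blanks. Two strategies:
#'
#' * `max_blank_subtraction` — for each taxon, its maximum read count over
#'   blanks is subtracted from every field sample (floored at 0). The blank
#'   columns are zeroed in the output.
#' * `blank_prevalence` — a taxon is removed outright when its mean read
#'   proportion across blanks is at least `ratio` times its mean read
#'   proportion across field samples.
#'
#' Neither strategy ever increases a count, and the per-taxon reads removed
#' are returned in an audit report whose total equals the difference of the
#' table totals.
#'
#' @param read_table A `read_table` containing both field and blank columns.
#' @param records Sample metadata identifying which samples are blanks.
#' @param strategy `"max_blank_subtraction"` (default) or
#'   `"blank_prevalence"`.
#' @param ratio Prevalence threshold for `blank_prevalence` (default 1:
#'   removed when the blank proportion is at least the field proportion).
#' @return A list: `table` (filtered `read_table`, field and blank columns
#'   retained) and `report` (a `decontam_report` data frame with per-taxon
#'   action `kept`/`reduced`/`removed` and `reads_removed`).
#' @export
blank_filter <- function(read_table, records,
                         strategy = c("max_blank_subtraction", "blank_prevalence"),
                         ratio = 1) {
  stopifnot(inherits(read_table, "read_table"))
  strategy <- match.arg(strategy)
  rec <- records[match(colnames(read_table), records$sample_id), , drop = FALSE]
  if (anyNA(rec$type))
    stop("samples missing from metadata: ",
         paste(colnames(read_table)[is.na(rec$type)], collapse = ", "), call. = FALSE)
  is_blank <- rec$type == "blank"
  if (!any(is_blank))
    stop(sprintf("strategy '%s' requires blank samples but none are present", strategy),
         call. = FALSE)

  m <- unclass(read_table)
  out <- m
  blanks <- m[, is_blank, drop = FALSE]
  fields <- m[, !is_blank, drop = FALSE]

  if (strategy == "max_blank_subtraction") {
    bmax <- apply(blanks, 1, max)
    out[, !is_blank] <- pmax(sweep(fields, 1, bmax, "-"), 0L)
    out[, is_blank] <- 0L
  } else {
    ftot <- colSums(fields); btot <- colSums(blanks)
    fprop <- rowMeans(sweep(fields, 2, pmax(ftot, 1L), "/"))
    bprop <- rowMeans(sweep(blanks, 2, pmax(btot, 1L), "/"))
    remove <- bprop >= ratio * fprop & bprop > 0
    out[remove, ] <- 0L
  }

  removed_reads <- rowSums(m) - rowSums(out)
  action <- ifelse(rowSums(out) == 0 & rowSums(m) > 0, "removed",
                   ifelse(removed_reads > 0, "reduced", "kept"))
  report <- data.frame(
    taxon_id = rownames(m), strategy = strategy, action = action,
    reads_removed = as.integer(removed_reads), stringsAsFactors = FALSE)
  if (strategy == "blank_prevalence") report$ratio <- ratio
  class(report) <- c("decontam_report", "data.frame")
  storage.mode(out) <- "integer"
  list(table = new_read_table(out), report = report)
}

#' Low-abundance filtering
#'
#' Removes taxa whose total reads fall below `min_total_reads` and zeroes
#' individual cells below `min_sample_reads`. With both thresholds 0 the
#' table is returned unchanged. Cell zeroing is applied first, then the
#' total-read floor, so the removal is monotone in both thresholds.
#'
#' @param read_table A `read_table`.
#' @param min_total_reads Minimum reads summed over all samples for a taxon
#'   to be kept (>= 0).
#' @param min_sample_reads Cells below this count are zeroed (>= 0).
#' @return A list: `table` (filtered `read_table`; removed taxa keep their
#'   rows, zeroed) and `report` (`decontam_report` as in [blank_filter()]).
#' @export
abundance_filter <- function(read_table, min_total_reads = 0, min_sample_reads = 0) {
  stopifnot(inherits(read_table, "read_table"))
  if (min_total_reads < 0 || min_sample_reads < 0)
    stop("thresholds must be >= 0", call. = FALSE)
  m <- unclass(read_table)
  out <- m
  out[out < min_sample_reads] <- 0L
  low <- rowSums(out) < min_total_reads
  out[low, ] <- 0L

  removed_reads <- rowSums(m) - rowSums(out)
  action <- ifelse(rowSums(out) == 0 & rowSums(m) > 0, "removed",
                   ifelse(removed_reads > 0, "reduced", "kept"))
  report <- data.frame(
    taxon_id = rownames(m), strategy = "abundance_filter", action = action,
    reads_removed = as.integer(removed_reads),
    min_total_reads = min_total_reads, min_sample_reads = min_sample_reads,
    stringsAsFactors = FALSE)
  class(report) <- c("decontam_report", "data.frame")
  storage.mode(out) <- "integer"
  list(table = new_read_table(out), report = report)
}

#' Drop user-listed non-target taxa
#'
#' Removes taxa on an exclusion list (e.g. human reads or other non-target
#' vertebrates) before analysis, with the same audit report as the other
#' filters.
#'
#' @param read_table A `read_table`.
#' @param exclude Character vector of taxon IDs to zero out; IDs absent from
#'   the table are ignored.
#' @return A list of `table` and `report`, as in [blank_filter()].
#' @export
exclusion_filter <- function(read_table, exclude) {
  stopifnot(inherits(read_table, "read_table"))
  m <- unclass(read_table)
  out <- m
  out[rownames(out) %in% exclude, ] <- 0L
  removed_reads <- rowSums(m) - rowSums(out)
  action <- ifelse(rowSums(out) == 0 & rowSums(m) > 0, "removed",
                   ifelse(removed_reads > 0, "reduced", "kept"))
  report <- data.frame(taxon_id = rownames(m), strategy = "exclusion_list",
                       action = action, reads_removed = as.integer(removed_reads),
                       stringsAsFactors = FALSE)
  class(report) <- c("decontam_report", "data.frame")
  storage.mode(out) <- "integer"
  list(table = new_read_table(out), report = report)
}
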