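#' Build a hierarchical survey design
#'
#' Constructs the station -> location -> bottle sampling hierarchy used
#' throughout the package, together with one sample record per field bottle
#' and per field blank. The default arguments reproduce the Port-complex
#' case-study design: 7 stations, 4 locations per station, 3 replicate 1 L
#' bottles per location, and 1 field blank per station (84 field samples +
#' 7 blanks).
#'
#' @param n_stations Number of stations (>= 1).
#' @param locations_per_station Number of sampling locations at each station
#'   (>= 1).
#' @param bottles_per_location Number of replicate water bottles at each
#'   location (>= 1).
#' @param blanks_per_station Number of field blanks per station (>= 0).
#' @param pcr_replicates_per_bottle PCR replicates per bottle. Recorded as
#'   design metadata only: read counts are reported per bottle, the replicate
#'   unit of all downstream analyses.
#'
#' @return An object of class `survey_design`: a list with the five design
#'   counts plus `records`, a data frame of sample records with columns
#'   `sample_id`, `station`, `location`, `bottle`, `type` (`"field"` or
#'   `"blank"`), ordered by (station, location, bottle) with blanks last
#'   within each station block appended after all field samples.
#' @examples
#' d <- build_design(7, 4, 3, 1)
#' sum(d$records$type == "field")  # 84
#' sum(d$records$type == "blank")  # 7
#' @export
build_design <- function(n_stations = 7L, locations_per_station = 4L,
                         bottles_per_location = 3L, blanks_per_station = 1L,
                         pcr_replicates_per_bottle = 3L) {
  check_count(n_stations, "n_stations", min = 1)
  check_count(locations_per_station, "locations_per_station", min = 1)
  check_count(bottles_per_location, "bottles_per_location", min = 1)
  check_count(blanks_per_station, "blanks_per_station", min = 0)
  check_count(pcr_replicates_per_bottle, "pcr_replicates_per_bottle", min = 1)

  n_stations <- as.integer(n_stations)
  locations_per_station <- as.integer(locations_per_station)
  bottles_per_location <- as.integer(bottles_per_location)
  blanks_per_station <- as.integer(blanks_per_station)

  field <- expand.grid(
    bottle = seq_len(bottles_per_location),
    location = seq_len(locations_per_station),
    station = seq_len(n_stations),
    KEEP.OUT.ATTRS = FALSE
  )[, c("station", "location", "bottle")]
  field <- field[order(field$station, field$location, field$bottle), , drop = FALSE]
  field$station <- sprintf("S%d", field$station)
  field$location <- sprintf("%s.L%d", field$station, field$location)
  field$sample_id <- sprintf("%s.B%d", field$location, field$bottle)
  field$bottle <- sprintf("B%d", field$bottle)
  field$type <- "field"

  records <- field[, c("sample_id", "station", "location", "bottle", "type")]

  if (blanks_per_station > 0) {
    blank <- expand.grid(
      blank = seq_len(blanks_per_station),
      station = seq_len(n_stations),
      KEEP.OUT.ATTRS = FALSE
    )
    blank <- blank[order(blank$station, blank$blank), , drop = FALSE]
    blank <- data.frame(
      sample_id = sprintf("S%d.BLK%d", blank$station, blank$blank),
      station = sprintf("S%d", blank$station),
      location = NA_character_,
      bottle = NA_character_,
      type = "blank",
      stringsAsFactors = FALSE
    )
    records <- rbind(records, blank)
  }
  rownames(records) <- NULL

  structure(
    list(
      n_stations = n_stations,
      locations_per_station = locations_per_station,
      bottles_per_location = bottles_per_location,
      blanks_per_station = blanks_per_station,
      pcr_replicates_per_bottle = as.integer(pcr_replicates_per_bottle),
      records = records
    ),
    class = "survey_design"
  )
}

#' @export
print.survey_design <- function(x, ...) {
  cat(sprintf(
    "Survey design: %d stations x %d locations x %d bottles (%d field samples, %d blanks)\n",
    x$n_stations, x$locations_per_station, x$bottles_per_location,
    n_field_samples(x), x$n_stations * x$blanks_per_station
  ))
  invisible(x)
}

#' Number of field samples implied by a design
#'
#' @param design A `survey_design`.
#' @return Integer: stations x locations x bottles.
#' @export
n_field_samples <- function(design) {
  stopifnot(inherits(design, "survey_design"))
  design$n_stations * design$locations_per_station * design$bottles_per_location
}

check_count <- function(x, name, min = 0) {
  if (length(x) != 1 || !is.numeric(x) || is.na(x) || x != as.integer(x) || x < min) {
    stop(sprintf("`%s` must be a single integer >= %d (got %s)", name, min,
                 paste(format(x), collapse = ",")), call. = FALSE)
  }
  invisible(TRUE)
}
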