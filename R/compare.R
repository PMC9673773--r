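#' Per-station eDNA vs trawl detection categories
#'
#' Crosses the two gears over the union of their species lists: each
#' (station, species) pair is classified as `absent`, `trawl_only`,
#' `edna_only` or `both`. Species names are matched by exact string after
#' applying an optional synonym map (applied to both inputs; every applied
#' synonym is logged). Port-level per-method species sets are the unions
#' over stations.
#'
#' @param edna_detections Data frame (station, species) of post-filter eDNA
#'   detections, or a binary species x station matrix.
#' @param trawl A `trawl_table` (station, species, count).
#' @param synonyms Optional data frame with columns `from`, `to` mapping
#'   variant names onto canonical ones.
#' @return A list of class `method_overlap`: `categories` (data frame
#'   station, species, category), `edna_species`, `trawl_species`
#'   (port-level sets), `stations`, `synonyms_applied`.
#' @export
overlap_matrix <- function(edna_detections, trawl, synonyms = NULL) {
  if (is.matrix(edna_detections)) {
    idx <- which(edna_detections > 0, arr.ind = TRUE)
    edna_detections <- data.frame(
      station = colnames(edna_detections)[idx[, 2]],
      species = rownames(edna_detections)[idx[, 1]],
      stringsAsFactors = FALSE)
  }
  stopifnot(all(c("station", "species") %in% names(edna_detections)),
            all(c("station", "species") %in% names(trawl)))

  applied <- data.frame(from = character(), to = character(), stringsAsFactors = FALSE)
  harmonize <- function(x) {
    if (is.null(synonyms)) return(x)
    hit <- x %in% synonyms$from
    if (any(hit)) {
      applied <<- unique(rbind(applied, data.frame(
        from = x[hit], to = synonyms$to[match(x[hit], synonyms$from)],
        stringsAsFactors = FALSE)))
      x[hit] <- synonyms$to[match(x[hit], synonyms$from)]
    }
    x
  }
  edna_detections$species <- harmonize(edna_detections$species)
  trawl$species <- harmonize(trawl$species)
  trawl <- trawl[trawl$count > 0 | is.na(trawl$count), , drop = FALSE]

  st_e <- sort(unique(edna_detections$station))
  st_t <- sort(unique(trawl$station))
  extra <- c(setdiff(st_e, st_t), setdiff(st_t, st_e))
  if (length(extra) && length(st_e) && length(st_t))
    stop("station sets differ between gears: ", paste(extra, collapse = ", "), call. = FALSE)
  stations <- sort(unique(c(st_e, st_t)))
  species <- sort(unique(c(edna_detections$species, trawl$species)))

  key <- function(df) paste(df$station, df$species, sep = "\r")
  e_set <- key(edna_detections)
  t_set <- key(trawl)
  grid <- expand.grid(station = stations, species = species,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  k <- paste(grid$station, grid$species, sep = "\r")
  in_e <- k %in% e_set; in_t <- k %in% t_set
  grid$category <- ifelse(in_e & in_t, "both",
                          ifelse(in_e, "edna_only",
                                 ifelse(in_t, "trawl_only", "absent")))
  structure(list(
    categories = grid,
    edna_species = sort(unique(edna_detections$species)),
    trawl_species = sort(unique(trawl$species)),
    stations = stations, synonyms_applied = applied),
    class = "method_overlap")
}

#' Port-level Venn counts between gears
#'
#' Set cardinalities over the whole survey: species seen by both gears, by
#' eDNA only, by trawl only, and the percentage of trawl-observed species
#' recovered by eDNA, 100 * both / (both + trawl_only), rounded to one
#' decimal at serialisation only.
#'
#' @param overlap A `method_overlap`, or a list with `edna_species` and
#'   `trawl_species` character vectors.
#' @return A list: `both`, `edna_only`, `trawl_only`,
#'   `percent_trawl_recovered` (NA with `undefined = TRUE` when no trawl
#'   species exist).
#' @examples
#' venn_counts(list(edna_species = c(letters[1:16], LETTERS[1:63]),
#'                  trawl_species = letters[1:17]))
#' @export
venn_counts <- function(overlap) {
  e <- overlap$edna_species; t <- overlap$trawl_species
  both <- length(intersect(e, t))
  res <- list(both = both,
              edna_only = length(setdiff(e, t)),
              trawl_only = length(setdiff(t, e)))
  if (length(t) == 0) {
    res$percent_trawl_recovered <- NA_real_
    res$undefined <- TRUE
  } else {
    res$percent_trawl_recovered <- round(100 * both / (both + res$trawl_only), 1)
    res$undefined <- FALSE
  }
  res
}

lowest_rank <- function(tax) {
  ranks <- c("species", "genus", "family", "order", "class", "phylum")
  for (r in ranks) if (!is.na(tax[[r]]) && nzchar(tax[[r]])) return(r)
  NA_character_
}

#' Reference-database audit
#'
#' Tabulates two taxonomy assignment tables over the same ASV set the way
#' database-completeness comparisons are reported: ASVs counted at the
#' lowest rank they reach (species / genus / family, mutually exclusive),
#' unique species per database, species found by one database but not the
#' other, native species against an optional checklist, and
#' species-reassignment pairs (same ASV, different species).
#'
#' @param a,b Taxonomy tables (see [read_taxonomy()]) for databases A and B.
#' @param native_checklist Optional character vector of native species
#'   names.
#' @param labels Length-2 names for the two databases.
#' @return A list of class `db_audit_report`: `metrics` (data frame, one
#'   row per metric, one column per database), `unique_species` (list per
#'   database), `reassigned` (data frame asv, species_a, species_b).
#' @export
db_audit <- function(a, b, native_checklist = NULL, labels = c("A", "B")) {
  for (df in list(a, b)) if (anyDuplicated(df$taxon_id))
    stop("duplicate ASV rows in taxonomy table", call. = FALSE)
  asvs <- union(a$taxon_id, b$taxon_id)
  align <- function(df) df[match(asvs, df$taxon_id), , drop = FALSE]
  a <- align(a); b <- align(b)

  tab_one <- function(df) {
    lr <- apply(df, 1, function(row) {
      tx <- as.list(row)
      if (all(is.na(tx$taxon_id))) return(NA_character_)
      lowest_rank(tx)
    })
    sp <- df$species[!is.na(df$species) & nzchar(df$species)]
    c(asv_species = sum(lr == "species", na.rm = TRUE),
      asv_genus = sum(lr == "genus", na.rm = TRUE),
      asv_family = sum(lr == "family", na.rm = TRUE),
      unique_species = length(unique(sp)),
      native_species = if (is.null(native_checklist)) NA_integer_ else
        length(intersect(unique(sp), native_checklist)))
  }
  ma <- tab_one(a); mb <- tab_one(b)
  sp_a <- unique(a$species[!is.na(a$species)])
  sp_b <- unique(b$species[!is.na(b$species)])
  uniq <- list(setdiff(sp_a, sp_b), setdiff(sp_b, sp_a))
  names(uniq) <- labels

  re <- data.frame(asv = asvs, species_a = a$species, species_b = b$species,
                   stringsAsFactors = FALSE)
  re <- re[!is.na(re$species_a) & !is.na(re$species_b) &
             re$species_a != re$species_b, , drop = FALSE]
  rownames(re) <- NULL

  metrics <- data.frame(metric = names(ma), check.names = FALSE,
                        stringsAsFactors = FALSE)
  metrics[[labels[1]]] <- unname(ma)
  metrics[[labels[2]]] <- unname(mb)
  structure(list(metrics = metrics, unique_species = uniq, reassigned = re),
            class = "db_audit_report")
}

#' Assemble the end-to-end run report
#'
#' A machine-readable bundle of every stage's headline numbers: species
#' totals without and with the occupancy filter (their difference is the
#' removed-species count), Venn counts, the per-station heat-table of
#' detection categories, completeness summaries, and the PERMANOVA table.
#' Missing stages are marked absent rather than failing the report.
#'
#' @param species_total_before,species_total_after Species totals without /
#'   with the occupancy filter.
#' @param venn Output of [venn_counts()] (optional).
#' @param overlap A `method_overlap` (optional; provides the heat table).
#' @param completeness Output of [hierarchy_completeness()] (optional).
#' @param permanova_table A `permanova_result` (optional).
#' @param seed,config Bookkeeping recorded verbatim in the report.
#' @return A list of class `run_report`; serialise with
#'   [write_run_report()].
#' @export
run_report <- function(species_total_before, species_total_after,
                       venn = NULL, overlap = NULL, completeness = NULL,
                       permanova_table = NULL, seed = NA_integer_, config = NULL) {
  if (species_total_after > species_total_before)
    stop("occupancy filtering cannot add species", call. = FALSE)
  rep <- list(
    occupancy_impact = list(
      species_total_before = species_total_before,
      species_total_after = species_total_after,
      species_removed = species_total_before - species_total_after),
    venn = if (is.null(venn)) "absent" else venn,
    heat_table = if (is.null(overlap)) "absent" else overlap$categories,
    completeness = if (is.null(completeness)) "absent" else completeness,
    permanova = if (is.null(permanova_table)) "absent" else
      as.data.frame(permanova_table),
    seed = seed,
    config = if (is.null(config)) "absent" else config,
    package_version = as.character(utils::packageVersion("ednaport")))
  class(rep) <- "run_report"
  rep
}

#' Write a run report to disk
#'
#' Emits `report.json` plus TSVs for the tabular sections (heat table,
#' completeness, PERMANOVA) into a directory. JSON output is deterministic
#' for identical report content.
#'
#' @param report A `run_report`.
#' @param dir Output directory.
#' @return Invisibly, the path of the JSON file.
#' @export
write_run_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  js <- report
  class(js) <- NULL
  for (nm in c("heat_table", "completeness", "permanova")) {
    if (is.data.frame(js[[nm]])) {
      write_tsv(js[[nm]], file.path(dir, paste0(nm, ".tsv")))
      js[[nm]] <- paste0(nm, ".tsv")
    }
  }
  path <- file.path(dir, "report.json")
  jsonlite::write_json(js, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}
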