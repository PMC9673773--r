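#' Build a species parameter table for simulation
#'
#' Each simulated species carries the parameters of the two-state occupancy
#' model with false positives (psi, p11, p10), a mean relative abundance
#' driving read allocation, a log-scale station heterogeneity SD, and a trawl
#' catchability. Defaults describe a fish assemblage of the kind the
#' case-study design targets: most species patchily occupied, well detected
#' when present, with a small per-replicate false-positive rate.
#'
#' @param n_species Number of species to generate.
#' @param psi,p11,p10 Occupancy, true-detection and false-detection
#'   probabilities; scalars or vectors of length `n_species`.
#' @param mean_relative_abundance Positive relative abundance weights
#'   (recycled); these are normalised within samples during read simulation.
#' @param station_effect_sd Log-scale SD of between-station abundance
#'   heterogeneity (0 = spatially homogeneous communities).
#' @param trawl_catchability Per-species probability scale linking true
#'   abundance to expected trawl catch; in [0, 1].
#' @return A data frame of class `species_params` with one row per species,
#'   including a 7-rank taxonomy path (placeholder lineages).
#' @examples
#' sp <- species_params(5, psi = 0.6, p11 = 0.8, p10 = 0.05)
#' @export
species_params <- function(n_species, psi = 0.6, p11 = 0.8, p10 = 0.05,
                           mean_relative_abundance = 1,
                           station_effect_sd = 0,
                           trawl_catchability = 0.5) {
  check_count(n_species, "n_species", min = 1)
  n <- as.integer(n_species)
  rec <- function(x, nm, lo = 0, hi = 1) {
    x <- rep_len(x, n)
    if (any(!is.finite(x)) || any(x < lo) || any(x > hi))
      stop(sprintf("`%s` must lie in [%s, %s]", nm, lo, hi), call. = FALSE)
    x
  }
  psi <- rec(psi, "psi"); p11 <- rec(p11, "p11"); p10 <- rec(p10, "p10")
  if (any(p11 < p10))
    stop("generated scenarios require p11 >= p10 for every species", call. = FALSE)
  mra <- rec(mean_relative_abundance, "mean_relative_abundance", lo = 1e-12, hi = Inf)
  ses <- rec(station_effect_sd, "station_effect_sd", lo = 0, hi = Inf)
  q <- rec(trawl_catchability, "trawl_catchability")

  out <- data.frame(
    species_id = sprintf("sp%03d", seq_len(n)),
    phylum = "Chordata", class = "Actinopteri", order = "Perciformes",
    family = sprintf("fam%02d", (seq_len(n) - 1L) %% 20L + 1L),
    genus = sprintf("gen%03d", seq_len(n)),
    species = sprintf("gen%03d sp%03d", seq_len(n), seq_len(n)),
    psi = psi, p11 = p11, p10 = p10,
    mean_relative_abundance = mra,
    station_effect_sd = ses,
    trawl_catchability = q,
    stringsAsFactors = FALSE
  )
  class(out) <- c("species_params", "data.frame")
  out
}

# Deterministic per-stage substreams from one user seed, so each stage is
# independently reproducible. Offsets are arbitrary fixed constants; the sum
# stays below 2^31.
stage_seed <- function(seed, stage) {
  off <- c(community = 101L, reads = 211L, trawl = 307L, pipeline = 401L)
  s <- (as.integer(seed) %% 2000000000L) + off[[stage]]
  as.integer(s)
}

#' Simulate latent occupancy and replicate detections
#'
#' Draws the latent occupancy state z for every species x site with
#' probability psi, then per-bottle detections with probability p11 at
#' occupied sites and p10 at unoccupied sites. Every detection at an
#' unoccupied site is recorded as a false positive in the provenance log.
#' Per-station abundance multipliers (log-normal with SD
#' `station_effect_sd`) are drawn here so that read and trawl simulation
#' share the same underlying spatial abundance field.
#'
#' @param design A `survey_design` from [build_design()].
#' @param species A `species_params` table.
#' @param seed Integer seed; identical seeds reproduce all fields exactly.
#' @param site_level `"location"` (default; sites are the K-bottle location
#'   units) or `"station"`.
#' @return An object of class `synthetic_truth`: design, species table, site
#'   table (site, station), latent matrix `z` (species x sites), binary
#'   `detections` (species x field bottles), `station_abundance`
#'   (species x stations), false-positive log `fp_log`, and the seed.
#' @export
simulate_community <- function(design, species, seed, site_level = c("location", "station")) {
  stopifnot(inherits(design, "survey_design"))
  site_level <- match.arg(site_level)
  if (!is.data.frame(species) || nrow(species) == 0)
    stop("`species` must be a non-empty species_params table", call. = FALSE)
  check_count(seed, "seed")

  rec <- design$records
  field <- rec[rec$type == "field", , drop = FALSE]
  site_of <- if (site_level == "location") field$location else field$station
  sites <- unique(data.frame(
    site = site_of,
    station = field$station[!duplicated(site_of)][match(unique(site_of), unique(site_of))],
    stringsAsFactors = FALSE
  ))
  sites <- data.frame(site = unique(site_of), stringsAsFactors = FALSE)
  sites$station <- field$station[match(sites$site, site_of)]

  n_sp <- nrow(species)
  n_site <- nrow(sites)

  set.seed(stage_seed(seed, "community"))
  z <- matrix(
    stats::rbinom(n_sp * n_site, 1L, rep(species$psi, times = n_site)),
    nrow = n_sp, ncol = n_site,
    dimnames = list(species$species_id, sites$site)
  )

  stations <- unique(rec$station)
  station_abundance <- matrix(
    species$mean_relative_abundance *
      exp(stats::rnorm(n_sp * length(stations),
                       sd = rep(species$station_effect_sd, times = length(stations)))),
    nrow = n_sp, ncol = length(stations),
    dimnames = list(species$species_id, stations)
  )

  bottle_site <- match(site_of, sites$site)
  p_det <- matrix(0, n_sp, nrow(field))
  occ <- z[, bottle_site, drop = FALSE] == 1L
  p_det[occ] <- rep(species$p11, times = nrow(field))[occ]
  p_det[!occ] <- rep(species$p10, times = nrow(field))[!occ]
  detections <- matrix(
    stats::rbinom(length(p_det), 1L, p_det),
    nrow = n_sp, ncol = nrow(field),
    dimnames = list(species$species_id, field$sample_id)
  )

  fp <- which(detections == 1L & !occ, arr.ind = TRUE)
  fp_log <- data.frame(
    species = rownames(detections)[fp[, 1]],
    sample = colnames(detections)[fp[, 2]],
    site = sites$site[bottle_site[fp[, 2]]],
    kind = rep("false_positive_detection", nrow(fp)),
    stringsAsFactors = FALSE
  )
  fp_log <- fp_log[order(fp_log$species, fp_log$sample), , drop = FALSE]
  rownames(fp_log) <- NULL

  structure(
    list(design = design, species = species, site_level = site_level,
         sites = sites, z = z, detections = detections,
         station_abundance = station_abundance, fp_log = fp_log, seed = as.integer(seed)),
    class = "synthetic_truth"
  )
}

#' Simulate a taxa-by-sample read-count table
#'
#' Per-sample sequencing depth is negative binomial (overdispersion typical
#' of amplicon libraries); within a sample, reads are allocated to the
#' bottle's detected species by a multinomial draw weighted by the species'
#' station-level abundance. Every detected (species, bottle) pair receives at
#' least one read whenever the sample's depth is at least the number of
#' detected species in it, so detection histories survive the round trip
#' through read counts. Field blanks receive contamination only: per species
#' a Bernoulli event with geometric read count, all logged.
#'
#' @param truth A `synthetic_truth` from [simulate_community()].
#' @param depth_mean,depth_dispersion Negative-binomial mean and size of the
#'   per-sample total read count; both must be positive.
#' @param contamination_rate Per-(species, blank) probability of a
#'   contamination event.
#' @param contamination_mean Mean reads of a contamination event
#'   (geometric, >= 1).
#' @param dropout_samples Number of field samples dropped from the output
#'   (sampling failures); columns are removed at random but reproducibly.
#' @param seed Integer seed.
#' @return A list of class `read_sim`: `table` (a `read_table`),
#'   `contamination_log` (species, sample, reads) and the seed.
#' @export
simulate_reads <- function(truth, depth_mean = 20000, depth_dispersion = 5,
                           contamination_rate = 0.02, contamination_mean = 10,
                           dropout_samples = 0, seed = truth$seed) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (!is.numeric(depth_mean) || depth_mean <= 0 ||
      !is.numeric(depth_dispersion) || depth_dispersion <= 0)
    stop("depth parameters must be positive", call. = FALSE)
  if (contamination_rate < 0 || contamination_rate > 1 || contamination_mean < 1)
    stop("contamination_rate must be in [0,1]; contamination_mean >= 1", call. = FALSE)
  check_count(dropout_samples, "dropout_samples")

  rec <- truth$design$records
  field <- rec[rec$type == "field", , drop = FALSE]
  blanks <- rec[rec$type == "blank", , drop = FALSE]
  sp <- truth$species
  n_sp <- nrow(sp)

  set.seed(stage_seed(seed, "reads"))
  counts <- matrix(0L, n_sp, nrow(rec),
                   dimnames = list(sp$species_id, rec$sample_id))

  depths <- stats::rnbinom(nrow(field), size = depth_dispersion, mu = depth_mean)
  for (b in seq_len(nrow(field))) {
    det <- which(truth$detections[, field$sample_id[b]] == 1L)
    if (length(det) == 0 || depths[b] == 0) next
    w <- truth$station_abundance[det, field$station[b]]
    if (depths[b] >= length(det)) {
      extra <- depths[b] - length(det)
      alloc <- if (extra > 0) stats::rmultinom(1, extra, prob = w)[, 1] else 0L
      counts[det, field$sample_id[b]] <- 1L + as.integer(alloc)
    } else {
      # depth too shallow to give every detected species a read
      keep <- sample(det, depths[b], prob = w)
      counts[keep, field$sample_id[b]] <- 1L
    }
  }

  clog <- list()
  if (nrow(blanks) > 0 && contamination_rate > 0) {
    for (k in seq_len(nrow(blanks))) {
      hit <- which(stats::rbinom(n_sp, 1L, contamination_rate) == 1L)
      if (length(hit) == 0) next
      reads <- 1L + stats::rgeom(length(hit), prob = 1 / contamination_mean)
      counts[hit, blanks$sample_id[k]] <- as.integer(reads)
      clog[[length(clog) + 1L]] <- data.frame(
        species = sp$species_id[hit], sample = blanks$sample_id[k],
        reads = as.integer(reads), stringsAsFactors = FALSE)
    }
  }
  clog <- if (length(clog)) do.call(rbind, clog) else
    data.frame(species = character(), sample = character(), reads = integer(),
               stringsAsFactors = FALSE)

  if (dropout_samples > 0) {
    if (dropout_samples >= nrow(field))
      stop("dropout_samples must be smaller than the number of field samples", call. = FALSE)
    drop_ids <- sample(field$sample_id, dropout_samples)
    counts <- counts[, !colnames(counts) %in% drop_ids, drop = FALSE]
  }

  list_out <- list(
    table = new_read_table(counts),
    contamination_log = clog,
    seed = as.integer(seed)
  )
  class(list_out) <- "read_sim"
  list_out
}

#' Simulate paired trawl catches
#'
#' Station-level true abundance of a species is its station abundance
#' multiplier summed over the station's occupied sites and scaled by
#' `effort`; the observed catch is Poisson(catchability x abundance).
#' Species with catchability 0, or absent (z = 0) from every site of a
#' station, never appear in that station's catch.
#'
#' @param truth A `synthetic_truth`.
#' @param effort Expected individuals caught per unit of (abundance x
#'   catchability); calibrates catch magnitude to a 5-minute tow.
#' @param mean_mass_kg Per-individual mass used for the biomass column.
#' @param seed Integer seed.
#' @return A long-format data frame (station, species, count, biomass_kg)
#'   of class `trawl_table`, rows with count > 0 only.
#' @export
simulate_trawl <- function(truth, effort = 5, mean_mass_kg = 0.25, seed = truth$seed) {
  stopifnot(inherits(truth, "synthetic_truth"))
  if (!is.numeric(effort) || effort <= 0) stop("`effort` must be positive", call. = FALSE)
  sp <- truth$species
  stations <- colnames(truth$station_abundance)
  set.seed(stage_seed(seed, "trawl"))

  rows <- list()
  for (st in stations) {
    st_sites <- truth$sites$site[truth$sites$station == st]
    occ_frac <- rowMeans(truth$z[, st_sites, drop = FALSE])
    lambda <- sp$trawl_catchability * effort *
      truth$station_abundance[, st] * occ_frac
    cnt <- stats::rpois(length(lambda), lambda)
    keep <- cnt > 0
    if (any(keep)) {
      rows[[length(rows) + 1L]] <- data.frame(
        station = st, species = sp$species[keep], count = as.integer(cnt[keep]),
        biomass_kg = round(cnt[keep] * mean_mass_kg, 3),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(station = character(), species = character(),
               count = integer(), biomass_kg = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("trawl_table", "data.frame")
  out
}

#' Write a simulated survey to disk
#'
#' Emits the same TSV formats the ingest functions read: sample metadata,
#' read table, trawl table, a per-(species, site) truth table and a JSON
#' scenario record (seed plus design counts).
#'
#' @param truth A `synthetic_truth`.
#' @param reads A `read_sim` from [simulate_reads()].
#' @param trawl A `trawl_table` from [simulate_trawl()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_survey <- function(truth, reads, trawl, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    metadata = file.path(dir, "metadata.tsv"),
    reads = file.path(dir, "reads.tsv"),
    trawl = file.path(dir, "trawl.tsv"),
    truth = file.path(dir, "truth.tsv"),
    scenario = file.path(dir, "scenario.json")
  )
  write_tsv(truth$design$records, paths[["metadata"]])
  write_read_table(reads$table, paths[["reads"]])
  write_tsv(as.data.frame(trawl), paths[["trawl"]])

  sp <- truth$species
  tt <- expand.grid(species_id = sp$species_id, site = truth$sites$site,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tt$z <- as.integer(truth$z[cbind(match(tt$species_id, rownames(truth$z)),
                                   match(tt$site, colnames(truth$z)))])
  tt <- cbind(tt, sp[match(tt$species_id, sp$species_id), c("psi", "p11", "p10")])
  write_tsv(tt, paths[["truth"]])

  d <- truth$design
  scen <- list(seed = truth$seed, site_level = truth$site_level,
               n_stations = d$n_stations,
               locations_per_station = d$locations_per_station,
               bottles_per_location = d$bottles_per_location,
               blanks_per_station = d$blanks_per_station,
               n_species = nrow(sp))
  jsonlite::write_json(scen, paths[["scenario"]], auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}
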