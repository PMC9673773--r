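test_that("overlap categories follow set logic, checked against an independent recount", {
  edna <- data.frame(station = c("S1", "S1", "S2"),
                     species = c("fish a", "fish b", "fish a"),
                     stringsAsFactors = FALSE)
  trawl <- data.frame(station = c("S1", "S2", "S2"),
                      species = c("fish a", "fish c", "fish a"),
                      count = c(2L, 1L, 4L), stringsAsFactors = FALSE)
  ov <- overlap_matrix(edna, trawl)
  cat_of <- function(st, sp) ov$categories$category[
    ov$categories$station == st & ov$categories$species == sp]
  expect_identical(cat_of("S1", "fish a"), "both")
  expect_identical(cat_of("S1", "fish b"), "edna_only")
  expect_identical(cat_of("S2", "fish c"), "trawl_only")
  expect_identical(cat_of("S1", "fish c"), "absent")

  # independent set-logic recount over the whole grid
  for (i in seq_len(nrow(ov$categories))) {
    row <- ov$categories[i, ]
    in_e <- any(edna$station == row$station & edna$species == row$species)
    in_t <- any(trawl$station == row$station & trawl$species == row$species)
    want <- if (in_e && in_t) "both" else if (in_e) "edna_only" else
      if (in_t) "trawl_only" else "absent"
    expect_identical(row$category, want)
  }
  # port-level sets are unions over stations
  expect_setequal(ov$edna_species, c("fish a", "fish b"))
  expect_setequal(ov$trawl_species, c("fish a", "fish c"))
})

test_that("overlap on synthetic truth matches an independent recount", {
  sv <- tiny_survey(seed = 97, n_species = 15)
  det <- det_from_truth(sv$truth)
  tw <- simulate_trawl(sv$truth)
  st_det <- sapply(unique(det$sites$station), function(st) {
    cols <- det$sites$site[det$sites$station == st]
    (rowSums(det$d[, cols, drop = FALSE]) > 0) * 1L
  })
  rownames(st_det) <- sv$species$species[match(rownames(st_det), sv$species$species_id)]
  if (nrow(tw) > 0) {
    ov <- overlap_matrix(st_det, tw)
    vc <- venn_counts(ov)
    expect_identical(vc$both + vc$edna_only, length(ov$edna_species))
    expect_identical(vc$both + vc$trawl_only, length(ov$trawl_species))
  } else {
    succeed()
  }
})

test_that("venn percentages match hand-computed worked values", {
  # 16 shared, 1 trawl-only, 63 eDNA-only
  ov <- list(edna_species = c(sprintf("shared%02d", 1:16), sprintf("e%02d", 1:63)),
             trawl_species = c(sprintf("shared%02d", 1:16), "t1"))
  vc <- venn_counts(ov)
  expect_identical(vc$both, 16L)
  expect_identical(vc$trawl_only, 1L)
  expect_identical(vc$edna_only, 63L)
  expect_identical(vc$percent_trawl_recovered, 94.1)

  expect_identical(venn_counts(list(edna_species = character(),
                                    trawl_species = letters[1:5]))$percent_trawl_recovered, 0)
  expect_identical(venn_counts(list(edna_species = letters[1:5],
                                    trawl_species = letters[1:5]))$percent_trawl_recovered, 100)
  und <- venn_counts(list(edna_species = letters[1:3], trawl_species = character()))
  expect_true(und$undefined)
})

test_that("synonym harmonisation is applied, logged and idempotent", {
  edna <- data.frame(station = "S1", species = "Sebastes goodei",
                     stringsAsFactors = FALSE)
  trawl <- data.frame(station = "S1", species = "S. goodei", count = 1L,
                      stringsAsFactors = FALSE)
  syn <- data.frame(from = "S. goodei", to = "Sebastes goodei",
                    stringsAsFactors = FALSE)
  ov <- overlap_matrix(edna, trawl, synonyms = syn)
  expect_identical(ov$categories$category, "both")
  expect_identical(nrow(ov$synonyms_applied), 1L)
  # applying the map to already-canonical names changes nothing
  ov2 <- overlap_matrix(edna, data.frame(station = "S1",
                                         species = "Sebastes goodei",
                                         count = 1L), synonyms = syn)
  expect_identical(ov2$categories$category, "both")
})

test_that("mismatched station sets are rejected with the offenders listed", {
  edna <- data.frame(station = c("S1", "S2"), species = "x")
  trawl <- data.frame(station = c("S1", "S3"), species = "x", count = 1L)
  expect_error(overlap_matrix(edna, trawl), "S2|S3")
})

test_that("db audit tabulates exclusive ranks, unique and reassigned species", {
  a <- data.frame(taxon_id = c("asv1", "asv2"),
                  phylum = "Chordata", class = "Actinopteri", order = "Perciformes",
                  family = "Gobiidae", genus = c("Gillichthys", "Clevelandia"),
                  species = c("Gillichthys mirabilis", NA),
                  confidence = NA_real_, stringsAsFactors = FALSE)
  b <- a
  b$species <- c("Gillichthys mirabilis", "Clevelandia ios")
  audit <- db_audit(a, b, native_checklist = "Gillichthys mirabilis",
                    labels = c("limited", "comprehensive"))
  mt <- audit$metrics
  get <- function(db, metric) mt[[db]][mt$metric == metric]
  expect_identical(get("limited", "asv_species"), 1L)
  expect_identical(get("limited", "asv_genus"), 1L)
  expect_identical(get("comprehensive", "asv_species"), 2L)
  expect_identical(get("comprehensive", "unique_species"), 2L)
  expect_identical(get("limited", "native_species"), 1L)
  expect_identical(audit$unique_species$comprehensive, "Clevelandia ios")
  expect_length(audit$unique_species$limited, 0)
  expect_identical(nrow(audit$reassigned), 0L)

  # identical tables: nothing unique on either side
  same <- db_audit(b, b)
  expect_length(same$unique_species$A, 0)
  expect_length(same$unique_species$B, 0)

  dup <- rbind(a, a[1, ])
  expect_error(db_audit(dup, b), "duplicate ASV")
})

test_that("run report conserves the removed-species identity", {
  rep <- run_report(125, 83)
  expect_identical(rep$occupancy_impact$species_removed, 42)
  rep0 <- run_report(50, 50)
  expect_identical(rep0$occupancy_impact$species_removed, 0)
  expect_error(run_report(10, 12), "cannot add")
  expect_identical(rep$venn, "absent")
})

test_that("written report JSON reproduces every number from stage outputs", {
  out <- run_pipeline(seed = 19, design = build_design(2, 2, 2, 1),
                      species = species_params(15, psi = 0.6, p11 = 0.85,
                                               p10 = 0.03, station_effect_sd = 0.5,
                                               trawl_catchability = 0.6),
                      depth_mean = 3000, n_perm = 99)
  dir <- withr::local_tempdir()
  path <- suppressWarnings(write_run_report(out$report, dir))
  js <- jsonlite::read_json(path)
  oi <- js$occupancy_impact
  expect_identical(oi$species_removed, oi$species_total_before - oi$species_total_after)
  # recompute the before/after totals independently from stage outputs
  before <- sum(rowSums(out$detections$d) > 0)
  after <- length(out$filter$species_kept)
  expect_identical(oi$species_total_before, as.integer(before))
  expect_identical(oi$species_total_after, as.integer(after))
  if (!identical(js$venn, "absent")) {
    expect_identical(js$venn$both + js$venn$edna_only,
                     length(out$overlap$edna_species))
  }
})
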