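test_that("eDNA index matches hand arithmetic and its invariances", {
  m <- matrix(c(10, 30, 90, 70), 2, byrow = TRUE,
              dimnames = list(c("t1", "t2"), c("s1", "s2")))
  idx <- edna_index(m)
  expect_equal(unname(idx["t1", ]), c(1 / 3, 1), tolerance = 1e-12)
  expect_equal(unname(idx["t2", ]), c(1, 7 / 9), tolerance = 1e-12)

  # single sample: every taxon index = 1
  one <- matrix(c(5, 2), 2, 1, dimnames = list(c("a", "b"), "s1"))
  expect_true(all(edna_index(one) == 1))

  # invariant to per-sample depth scaling
  m2 <- m; m2[, 1] <- m2[, 1] * 10
  expect_equal(edna_index(m2), idx, tolerance = 1e-12)

  # all-zero taxon dropped with warning
  m3 <- rbind(m, t3 = c(0, 0))
  expect_warning(idx3 <- edna_index(m3), "all-zero")
  expect_identical(rownames(idx3), c("t1", "t2"))
})

test_that("distance matrices match the standard formulas", {
  m <- matrix(c(1, 1, 0, 0, 1, 1), 3, 2,
              dimnames = list(paste0("t", 1:3), c("s1", "s2")))
  D <- distance_matrix(m, "jaccard")
  expect_equal(D["s1", "s2"], 1 - 1 / 3, tolerance = 1e-12)
  expect_identical(unname(diag(D)), c(0, 0))

  # identical samples at distance 0, disjoint at bray = 1
  m2 <- cbind(a = c(2, 0, 3), b = c(2, 0, 3), c = c(0, 4, 0))
  rownames(m2) <- paste0("t", 1:3)
  B <- distance_matrix(m2, "bray_curtis")
  expect_identical(B["a", "b"], 0)
  expect_identical(B["a", "c"], 1)
  expect_equal(as.vector(B), as.vector(t(B)), tolerance = 1e-15)
})

test_that("distances agree with vegan::vegdist", {
  skip_if_not_installed("vegan")
  set.seed(61)
  m <- matrix(rpois(8 * 30, 3), 30, 8,
              dimnames = list(paste0("t", 1:30), paste0("s", 1:8)))
  B <- distance_matrix(m, "bray_curtis")
  expect_equal(as.vector(B), as.vector(as.matrix(vegan::vegdist(t(m), "bray"))),
               tolerance = 1e-12)
  mb <- (m > 2) * 1
  mb <- mb[, colSums(mb) > 0]
  J <- distance_matrix(mb, "jaccard")
  expect_equal(as.vector(J),
               as.vector(as.matrix(vegan::vegdist(t(mb), "jaccard", binary = TRUE))),
               tolerance = 1e-12)
})

test_that("two-point PCoA has eigenvalue d^2/2 and coordinates +-d/2", {
  D <- matrix(c(0, 3, 3, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  ord <- pcoa(D)
  expect_length(ord$eigenvalues, 1)
  expect_equal(ord$eigenvalues[1], 4.5, tolerance = 1e-10)
  expect_equal(unname(sort(ord$coordinates[, 1])), c(-1.5, 1.5), tolerance = 1e-10)
})

test_that("PCoA recovers planar configurations up to rotation/reflection", {
  set.seed(67)
  X <- cbind(runif(10, 0, 5), runif(10, 0, 5))
  rownames(X) <- paste0("p", 1:10)
  D <- as.matrix(dist(X))
  ord <- pcoa(D)
  expect_lte(ord$negative_mass, 1e-8)
  expect_lt(procrustes_error(X, ord$coordinates[, 1:2]), 1e-8)
})

test_that("equidistant triplet yields two equal positive eigenvalues", {
  D <- matrix(1, 3, 3); diag(D) <- 0
  dimnames(D) <- list(letters[1:3], letters[1:3])
  ord <- pcoa(D)
  expect_length(ord$eigenvalues, 2)
  expect_equal(ord$eigenvalues[1], ord$eigenvalues[2], tolerance = 1e-10)
})

test_that("PERMANOVA on the Euclidean toy equals classical one-way ANOVA", {
  x <- c(0, 1, 3, 4)
  md <- data.frame(group = c("a", "a", "b", "b"))
  D <- as.matrix(dist(x))
  dimnames(D) <- list(paste0("s", 1:4), paste0("s", 1:4))
  res <- permanova(D, md, "group", n_perm = 999, seed = 1)
  expect_equal(res$SS[res$term == "Total"], 10, tolerance = 1e-10)
  expect_equal(res$SS[res$term == "group"], 9, tolerance = 1e-10)
  expect_equal(res$F[res$term == "group"], 18, tolerance = 1e-10)
  expect_equal(res$R2[res$term == "group"], 0.9, tolerance = 1e-10)
  aov_fit <- anova(lm(x ~ md$group))
  expect_equal(res$SS[1], aov_fit$`Sum Sq`[1], tolerance = 1e-10)
  expect_equal(res$F[1], aov_fit$`F value`[1], tolerance = 1e-10)
})

test_that("PERMANOVA agrees with vegan::adonis2 on a nested design", {
  skip_if_not_installed("vegan")
  set.seed(73)
  sv <- tiny_survey(seed = 73, n_species = 25)
  det <- det_from_truth(sv$truth)
  y <- det$y[rowSums(det$y) > 0, , drop = FALSE]
  D <- distance_matrix(y, "jaccard")
  md <- sv$design$records[match(colnames(y), sv$design$records$sample_id), ]
  mine <- permanova(D, md, c("station", "location"), n_perm = 99, seed = 2)
  ref <- vegan::adonis2(as.dist(D) ~ station + location, data = md,
                        permutations = 99, by = "terms")
  expect_equal(mine$SS[1:2], ref$SumOfSqs[1:2], tolerance = 1e-8)
  expect_equal(mine$R2[1:2], ref$R2[1:2], tolerance = 1e-8)
  expect_equal(mine$F[1:2], ref$F[1:2], tolerance = 1e-8)
})

test_that("R2 sums to one and p-values are seed-reproducible on the grid", {
  sv <- tiny_survey(seed = 79, n_species = 20)
  det <- det_from_truth(sv$truth)
  y <- det$y[rowSums(det$y) > 0, , drop = FALSE]
  D <- distance_matrix(y, "jaccard")
  md <- sv$design$records[match(colnames(y), sv$design$records$sample_id), ]
  r1 <- permanova(D, md, c("station", "location"), n_perm = 199, seed = 11)
  r2 <- permanova(D, md, c("station", "location"), n_perm = 199, seed = 11)
  expect_identical(r1, r2)
  terms_r2 <- r1$R2[r1$term != "Total"]
  expect_equal(sum(terms_r2), 1, tolerance = 1e-10)
  p <- r1$p[!is.na(r1$p)]
  expect_true(all(p >= 1 / 200 & p <= 1))
  expect_true(all(abs(p * 200 - round(p * 200)) < 1e-9))
})

test_that("PERMANOVA is invariant to sample order", {
  sv <- tiny_survey(seed = 83, n_species = 20)
  det <- det_from_truth(sv$truth)
  y <- det$y[rowSums(det$y) > 0, , drop = FALSE]
  D <- distance_matrix(y, "jaccard")
  md <- sv$design$records[match(colnames(y), sv$design$records$sample_id), ]
  perm <- sample(ncol(y))
  r1 <- permanova(D, md, c("station", "location"), n_perm = 99, seed = 5)
  r2 <- permanova(D[perm, perm], md[perm, ], c("station", "location"),
                  n_perm = 99, seed = 5)
  expect_equal(r1$SS, r2$SS, tolerance = 1e-10)
  expect_equal(r1$R2, r2$R2, tolerance = 1e-10)
})

test_that("station R2 increases with between-station divergence", {
  r2_at <- function(sd_eff) {
    design <- build_design(4, 2, 3, 0)
    sp <- species_params(40, psi = 0.5, p11 = 0.9, p10 = 0.02,
                         station_effect_sd = sd_eff)
    truth <- simulate_community(design, sp, seed = 89)
    reads <- simulate_reads(truth, depth_mean = 3000, contamination_rate = 0, seed = 89)
    idx <- suppressWarnings(edna_index(reads$table[, grep("BLK",
      colnames(reads$table), invert = TRUE), drop = FALSE]))
    D <- distance_matrix(idx, "bray_curtis")
    md <- design$records[match(colnames(idx), design$records$sample_id), ]
    permanova(D, md, "station", n_perm = 99, seed = 3)$R2[1]
  }
  # station abundance heterogeneity drives compositional divergence
  expect_gt(r2_at(2), r2_at(0))
})

test_that("degenerate terms are rejected and few permutations warn", {
  D <- as.matrix(dist(1:4)); dimnames(D) <- list(1:4, 1:4)
  expect_error(permanova(D, data.frame(g = rep("x", 4)), "g", seed = 1),
               "single level")
  expect_warning(permanova(D, data.frame(g = c("a", "a", "b", "b")), "g",
                           n_perm = 20, seed = 1),
                 "99")
})
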