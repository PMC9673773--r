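test_that("incidence tallies match hand counting and a brute-force recount", {
  m <- matrix(c(1, 1, 1,   # A in all 3 units
                1, 0, 0,   # B in 1
                0, 0, 1),  # C in 1
              nrow = 3, byrow = TRUE,
              dimnames = list(c("A", "B", "C"), paste0("u", 1:3)))
  s <- incidence_summary(m)
  expect_identical(s$T, 3L)
  expect_identical(s$S_obs, 3L)
  expect_identical(s$Q1, 2L)
  expect_identical(s$Q2, 0L)
  expect_identical(s$U, 5L)

  # all species everywhere
  full <- matrix(1, 4, 3, dimnames = list(letters[1:4], paste0("u", 1:3)))
  sf <- incidence_summary(full)
  expect_identical(sf$Q1 + sf$Q2, 0L)
  expect_identical(sf$U, sf$S_obs * sf$T)

  # simulated matrix vs an independent per-species loop recount
  set.seed(19)
  big <- matrix(rbinom(50 * 28, 1, 0.25), 50,
                dimnames = list(paste0("sp", 1:50), paste0("u", 1:28)))
  sb <- incidence_summary(big)
  Y2 <- integer(0)
  for (i in seq_len(nrow(big))) {
    y <- 0L
    for (j in seq_len(ncol(big))) if (big[i, j] > 0) y <- y + 1L
    if (y > 0) Y2 <- c(Y2, y)
  }
  expect_identical(sb$S_obs, length(Y2))
  expect_identical(sb$U, sum(Y2))
  expect_identical(sb$Q1, sum(Y2 == 1L))
  expect_identical(sb$Q2, sum(Y2 == 2L))
})

test_that("sample coverage matches hand-computed toys and its limits", {
  s1 <- structure(list(T = 3L, Y = NULL, Q1 = 2L, Q2 = 0L, U = 5L, S_obs = 3L),
                  class = "incidence_summary")
  expect_equal(sample_coverage(s1), 0.6, tolerance = 1e-12)
  s2 <- structure(list(T = 3L, Y = NULL, Q1 = 1L, Q2 = 1L, U = 6L, S_obs = 3L),
                  class = "incidence_summary")
  expect_equal(sample_coverage(s2), 1 - (1 / 6) * (2 / 4), tolerance = 1e-12)
  s3 <- structure(list(T = 3L, Y = NULL, Q1 = 0L, Q2 = 2L, U = 9L, S_obs = 3L),
                  class = "incidence_summary")
  expect_identical(sample_coverage(s3), 1)
  s0 <- structure(list(T = 2L, Y = NULL, Q1 = 0L, Q2 = 0L, U = 0L, S_obs = 0L),
                  class = "incidence_summary")
  expect_error(sample_coverage(s0), "U = 0")
})

test_that("Chao2 matches hand arithmetic in both branches", {
  s_doub <- structure(list(T = 3L, Q1 = 2L, Q2 = 1L, U = 8L, S_obs = 4L),
                      class = "incidence_summary")
  expect_equal(chao2(s_doub), 4 + (2 / 3) * 4 / 2, tolerance = 1e-12)
  s_nodoub <- structure(list(T = 3L, Q1 = 2L, Q2 = 0L, U = 6L, S_obs = 4L),
                        class = "incidence_summary")
  expect_equal(chao2(s_nodoub), 4 + (2 / 3) * (2 * 1) / 2, tolerance = 1e-12)
  s_q0 <- structure(list(T = 3L, Q1 = 0L, Q2 = 0L, U = 9L, S_obs = 3L),
                    class = "incidence_summary")
  expect_identical(chao2(s_q0), 3)
  expect_error(chao2(structure(list(T = 1L), class = "incidence_summary")), "2 sampling units")
})

test_that("Chao2 agrees with vegan::specpool on a random matrix", {
  skip_if_not_installed("vegan")
  set.seed(23)
  m <- matrix(rbinom(40 * 10, 1, 0.2), 40,
              dimnames = list(paste0("sp", 1:40), paste0("u", 1:10)))
  m <- m[rowSums(m) > 0, ]
  s <- incidence_summary(m)
  vp <- vegan::specpool(t(m))
  expect_equal(chao2(s), vp$chao, tolerance = 1e-8)
})

test_that("interpolated rarefaction matches hand toys and endpoints", {
  m <- matrix(c(1, 1, 1, 0), 2, byrow = TRUE,
              dimnames = list(c("A", "B"), c("u1", "u2")))
  s <- incidence_summary(m)
  curve <- rarefy_extrapolate(s, t_grid = 1:2)
  expect_equal(curve$S[1], 1.5, tolerance = 1e-12)
  expect_equal(curve$S[2], 2, tolerance = 1e-12)   # S(T) = S_obs
  expect_false(any(curve$extrapolated))

  set.seed(29)
  big <- matrix(rbinom(30 * 8, 1, 0.3), 30,
                dimnames = list(paste0("sp", 1:30), paste0("u", 1:8)))
  sb <- incidence_summary(big)
  cb <- rarefy_extrapolate(sb)
  expect_equal(cb$S[sb$T], sb$S_obs)
  expect_true(all(diff(cb$S) > -1e-12))  # non-decreasing
})

test_that("analytic rarefaction equals Monte-Carlo subsampling within MC error", {
  set.seed(37)
  m <- matrix(rbinom(50 * 12, 1, 0.25), 50,
              dimnames = list(paste0("sp", 1:50), paste0("u", 1:12)))
  m <- m[rowSums(m) > 0, , drop = FALSE]
  s <- incidence_summary(m)
  curve <- rarefy_extrapolate(s)
  for (t in c(2, 5, 9)) {
    mc <- mc_rarefaction(m, t, n_draws = 10000)
    expect_lt(abs(curve$S[t] - mc["mean"]), 3 * max(mc["se"], 1e-9))
  }
})

test_that("extrapolation is flat at S_obs when no singletons remain", {
  m <- matrix(1, 5, 4, dimnames = list(paste0("sp", 1:5), paste0("u", 1:4)))
  s <- incidence_summary(m)
  curve <- rarefy_extrapolate(s, t_grid = c(2, 4, 8, 12))
  expect_true(all(curve$S[curve$extrapolated] == s$S_obs))
  expect_true(all(curve$extrapolated == (curve$t > 4)))
})

test_that("extrapolated richness rises toward Chao2 and stays below it", {
  set.seed(41)
  m <- matrix(rbinom(40 * 6, 1, 0.15), 40,
              dimnames = list(paste0("sp", 1:40), paste0("u", 1:6)))
  m <- m[rowSums(m) > 0, , drop = FALSE]
  s <- incidence_summary(m)
  curve <- rarefy_extrapolate(s, t_grid = c(6, 12, 30, 60))
  ch <- attr(curve, "chao2")
  ext <- curve$S[curve$extrapolated]
  expect_true(all(diff(ext) >= 0))
  expect_true(all(ext <= ch + 1e-9))
})

test_that("hierarchy completeness reports all three levels with T = design counts", {
  sv <- tiny_survey(seed = 53, n_species = 20)
  det <- det_from_truth(sv$truth)
  hc <- hierarchy_completeness(det, sv$design$records)
  expect_setequal(unique(hc$level), c("bottle", "location", "station"))
  expect_true(all(hc$T[hc$level == "bottle"] == 2))
  expect_true(all(hc$T[hc$level == "location"] == 3))
  expect_identical(hc$T[hc$level == "station"], 2L)
  expect_true(all(hc$coverage >= 0 & hc$coverage <= 1))
})

test_that("units_to_saturation reports both operationalisations", {
  m <- matrix(rbinom(40 * 10, 1, 0.5), 40,
              dimnames = list(paste0("sp", 1:40), paste0("u", 1:10)))
  m[1, ] <- 1
  s <- incidence_summary(m)
  u <- units_to_saturation(s)
  expect_true(is.finite(u$chao2))
  expect_true(is.na(u$t_coverage) || u$t_coverage >= 1)
  expect_true(is.na(u$t_richness) || u$t_richness >= 1)
})
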