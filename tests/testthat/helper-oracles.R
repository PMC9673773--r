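# Independent oracles used across the suite. Deliberately brute-force and
# slow: they must not share code paths with the implementation they check.

# Exhaustive latent-state enumeration of the occupancy likelihood:
# sum over all 2^J occupancy configurations z of
#   prod_j psi^z_j (1-psi)^(1-z_j) * p^d_j (1-p)^(K_j-d_j),  p = p11 or p10.
enumerate_log_likelihood <- function(psi, p11, p10, d, K) {
  K <- rep_len(K, length(d))
  J <- length(d)
  total <- 0
  for (code in 0:(2^J - 1)) {
    z <- as.integer(intToBits(code))[seq_len(J)]
    term <- 1
    for (j in seq_len(J)) {
      p <- if (z[j] == 1L) p11 else p10
      term <- term * (if (z[j] == 1L) psi else 1 - psi) *
        p^d[j] * (1 - p)^(K[j] - d[j])
    }
    total <- total + term
  }
  log(total)
}

# Monte-Carlo incidence rarefaction: mean richness over draws of t units
# without replacement. Returns mean and its standard error.
mc_rarefaction <- function(mat, t, n_draws = 10000) {
  m <- (mat > 0) * 1L
  vals <- replicate(n_draws, {
    cols <- sample(ncol(m), t)
    sum(rowSums(m[, cols, drop = FALSE]) > 0)
  })
  c(mean = mean(vals), se = stats::sd(vals) / sqrt(n_draws))
}

# Procrustes error after optimal translation + rotation/reflection
# (no scaling): returns the residual sum of squares.
procrustes_error <- function(X, Y) {
  Xc <- scale(X, scale = FALSE)
  Yc <- scale(Y, scale = FALSE)
  k <- min(ncol(Xc), ncol(Yc))
  Xc <- cbind(Xc, matrix(0, nrow(Xc), max(0, k - ncol(Xc))))[, seq_len(k), drop = FALSE]
  Yc <- cbind(Yc, matrix(0, nrow(Yc), max(0, k - ncol(Yc))))[, seq_len(k), drop = FALSE]
  s <- svd(crossprod(Yc, Xc))
  R <- s$u %*% t(s$v)
  sum((Yc %*% R - Xc)^2)
}

# Build a detection_array directly from simulated truth (bypassing the
# read-simulation path) so occupancy tests exercise only the model.
det_from_truth <- function(truth) {
  y <- truth$detections
  field <- truth$design$records[truth$design$records$type == "field", ]
  site_of <- if (truth$site_level == "location") field$location else field$station
  sites <- truth$sites
  K <- stats::setNames(as.integer(table(factor(site_of, levels = sites$site))),
                       sites$site)
  d <- t(apply(y, 1, function(r) tapply(r, factor(site_of, levels = sites$site), sum)))
  storage.mode(d) <- "integer"
  structure(list(y = y, bottle_site = site_of, sites = sites, K = K, d = d,
                 site_level = truth$site_level, min_reads = 1),
            class = "detection_array")
}

# Small balanced survey used by several suites.
tiny_survey <- function(seed = 5, n_species = 12) {
  design <- build_design(2, 3, 2, 1)
  sp <- species_params(n_species, psi = 0.6, p11 = 0.8, p10 = 0.05,
                       station_effect_sd = 0.5, trawl_catchability = 0.6)
  truth <- simulate_community(design, sp, seed = seed)
  reads <- simulate_reads(truth, depth_mean = 5000, depth_dispersion = 5,
                          contamination_rate = 0.05, seed = seed)
  list(design = design, species = sp, truth = truth, reads = reads)
}
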