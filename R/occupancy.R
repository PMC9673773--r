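#' Marginal log-likelihood of a detection history
#'
#' The two-state site-occupancy model with false positives. Each site j is
#' occupied with probability psi; given occupancy, each of its K_j
#' replicates detects with probability p11, and given non-occupancy with the
#' false-positive probability p10. Marginalising the latent state gives the
#' per-site mixture
#' \deqn{L_j = \psi\, p_{11}^{d_j} (1-p_{11})^{K_j-d_j} +
#'   (1-\psi)\, p_{10}^{d_j} (1-p_{10})^{K_j-d_j},}
#' and the log-likelihood is the sum of log L_j. Binomial coefficients are
#' omitted throughout: they cancel in the occupancy posterior and shift the
#' log-likelihood by a data-only constant, so values are comparable across
#' parameter sets on the same histories but not with likelihoods that
#' include them.
#'
#' @param psi,p11,p10 Model probabilities in [0, 1].
#' @param d Integer vector of detection counts per site.
#' @param K Integer replicate counts per site (scalar or vector like `d`).
#' @return The log-likelihood (scalar).
#' @examples
#' marginal_log_likelihood(0.6, 0.8, 0.05, d = c(1, 3), K = 3)
#' @export
marginal_log_likelihood <- function(psi, p11, p10, d, K) {
  check_occ_args(psi, p11, p10, d, K)
  K <- rep_len(K, length(d))
  lj <- psi * p11^d * (1 - p11)^(K - d) + (1 - psi) * p10^d * (1 - p10)^(K - d)
  sum(log(lj))
}

check_occ_args <- function(psi, p11, p10, d, K) {
  probs <- c(psi = psi, p11 = p11, p10 = p10)
  if (any(!is.finite(probs)) || any(probs < 0) || any(probs > 1))
    stop("psi, p11, p10 must lie in [0, 1]", call. = FALSE)
  K <- rep_len(K, length(d))
  if (any(d < 0) || any(d > K))
    stop("detection counts must satisfy 0 <= d <= K at every site", call. = FALSE)
  invisible(TRUE)
}

#' Posterior probability of occupancy given a detection history
#'
#' Bayes' rule on the two-state model:
#' \deqn{P(z=1 \mid d) = \frac{\psi\, p_{11}^{d} (1-p_{11})^{K-d}}
#'   {\psi\, p_{11}^{d}(1-p_{11})^{K-d} + (1-\psi)\, p_{10}^{d}(1-p_{10})^{K-d}}.}
#' Strictly increasing in d whenever p11 > p10; equals 1 exactly when
#' p10 = 0 and d >= 1 (false positives impossible).
#'
#' @inheritParams marginal_log_likelihood
#' @param d Detection count(s); vectorised.
#' @param K Replicates per site (recycled).
#' @return Posterior occupancy probabilities in [0, 1], one per element of
#'   `d`.
#' @examples
#' posterior_occupancy(0.6, 0.8, 0.05, d = 1:3, K = 3)
#' @export
posterior_occupancy <- function(psi, p11, p10, d, K) {
  check_occ_args(psi, p11, p10, d, K)
  K <- rep_len(K, length(d))
  a <- psi * p11^d * (1 - p11)^(K - d)
  b <- (1 - psi) * p10^d * (1 - p10)^(K - d)
  denom <- a + b
  out <- ifelse(denom == 0, 0, a / denom)
  pmin(pmax(out, 0), 1)
}

# Map an unconstrained optimiser vector to (psi, p11, p10) with p11 >= p10
# enforced by construction: p11 = p10 + (1 - p10) * logistic(theta3).
theta_to_params <- function(theta) {
  psi <- stats::plogis(theta[1])
  p10 <- stats::plogis(theta[2])
  p11 <- p10 + (1 - p10) * stats::plogis(theta[3])
  c(psi = psi, p11 = p11, p10 = p10)
}

# Weak Beta penalties (MAP, not pure MLE). psi and p11 get a symmetric
# Beta(a, a) that keeps estimates off the 0/1 boundaries; p10 gets an
# asymmetric Beta(a, b10) encoding that per-replicate false positives are
# rare — without it, histories that carry no information about p10
# (e.g. saturated detections) drift to the non-identifiable p11 = p10
# ridge, where the penalty rather than the data decides.
penalty_log <- function(p, strength, fp_shape2) {
  (strength - 1) * (log(p[["psi"]]) + log1p(-p[["psi"]]) +
                      log(p[["p11"]]) + log1p(-p[["p11"]])) +
    (strength - 1) * log(p[["p10"]]) + (fp_shape2 - 1) * log1p(-p[["p10"]])
}

#' Fit the false-positive occupancy model to one detection history
#'
#' Maximum a posteriori fit of (psi, p11, p10) by quasi-Newton optimisation
#' of the penalised marginal log-likelihood on an unconstrained scale, with
#' the identifiability constraint p11 >= p10 built into the
#' parameterisation and a weak Beta(`penalty`, `penalty`) penalty on each
#' probability. A fixed grid of multi-starts makes the fit deterministic.
#'
#' Degenerate inputs are flagged rather than fitted: histories with no
#' detections at all, with detections everywhere, or with fewer than two
#' sites or fewer than three total replicates carry too little information
#' to separate true from false positives.
#'
#' @param d Integer detections per site.
#' @param K Replicates per site (scalar or vector).
#' @param penalty Beta shape of the boundary penalty on psi and p11
#'   (default 2; 1 = pure maximum likelihood).
#' @param fp_shape2 Second Beta shape of the p10 penalty, Beta(`penalty`,
#'   `fp_shape2`); the default 20 places the penalty mode near 0.05,
#'   encoding that per-replicate false positives are rare.
#' @param starts Number of deterministic starting points (>= 5).
#' @return A list of class `occupancy_fit`: `psi`, `p11`, `p10`,
#'   `log_likelihood` (unpenalised, at the optimum), `converged`,
#'   `identifiable`, `n_sites`, `K`, `d`, and `posterior` (per-site
#'   P(z = 1 | d_j)).
#' @export
fit_occupancy <- function(d, K, penalty = 2, fp_shape2 = 20, starts = 6) {
  K <- rep_len(K, length(d))
  if (any(d < 0) || any(d > K)) stop("0 <= d <= K violated", call. = FALSE)
  if (starts < 5) stop("`starts` must be >= 5", call. = FALSE)

  identifiable <- length(d) >= 2 && sum(K) >= 3 && sum(d) > 0
  obj <- function(theta) {
    p <- theta_to_params(theta)
    -(marginal_log_likelihood(p["psi"], p["p11"], p["p10"], d, K) +
        penalty_log(p, penalty, fp_shape2))
  }

  start_grid <- expand.grid(
    psi = c(0.2, 0.5, 0.8), p10 = c(0.02, 0.1), inc = c(0.6, 0.9),
    KEEP.OUT.ATTRS = FALSE)
  start_grid <- start_grid[seq_len(min(nrow(start_grid), max(starts, 5))), , drop = FALSE]

  best <- NULL
  for (i in seq_len(nrow(start_grid))) {
    th0 <- c(stats::qlogis(start_grid$psi[i]), stats::qlogis(start_grid$p10[i]),
             stats::qlogis((start_grid$inc[i] - start_grid$p10[i]) /
                             (1 - start_grid$p10[i])))
    fit <- tryCatch(
      stats::optim(th0, obj, method = "BFGS", control = list(maxit = 500)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) {
    return(structure(list(psi = NA_real_, p11 = NA_real_, p10 = NA_real_,
                          log_likelihood = NA_real_, converged = FALSE,
                          identifiable = identifiable, n_sites = length(d),
                          K = K, d = d, posterior = rep(NA_real_, length(d))),
                     class = "occupancy_fit"))
  }
  p <- theta_to_params(best$par)
  ll <- marginal_log_likelihood(p["psi"], p["p11"], p["p10"], d, K)
  structure(list(
    psi = unname(p["psi"]), p11 = unname(p["p11"]), p10 = unname(p["p10"]),
    log_likelihood = ll, converged = best$convergence == 0,
    identifiable = identifiable, n_sites = length(d), K = K, d = d,
    posterior = posterior_occupancy(p["psi"], p["p11"], p["p10"], d, K)),
    class = "occupancy_fit")
}

#' @export
print.occupancy_fit <- function(x, ...) {
  cat(sprintf("Occupancy fit (%d sites): psi=%.3f p11=%.3f p10=%.3f logL=%.2f%s%s\n",
              x$n_sites, x$psi, x$p11, x$p10, x$log_likelihood,
              if (!x$converged) " [not converged]" else "",
              if (!x$identifiable) " [non-identifiable]" else ""))
  invisible(x)
}

#' Fit the occupancy model to every species in a detection array
#'
#' Species with zero detections everywhere are skipped (listed, not
#' fitted); species whose optimiser fails on every start are routed to the
#' unresolved list.
#'
#' @param det A `detection_array` from [binarize_detections()].
#' @inheritParams fit_occupancy
#' @return A list of class `occupancy_fits`: `fits` (named list of
#'   `occupancy_fit`), `skipped` (species with no detections),
#'   `unresolved` (species whose fit failed to converge).
#' @export
fit_occupancy_all <- function(det, penalty = 2, fp_shape2 = 20, starts = 6) {
  stopifnot(inherits(det, "detection_array"))
  fits <- list(); skipped <- character(); unresolved <- character()
  for (s in rownames(det$d)) {
    ds <- det$d[s, ]
    if (sum(ds) == 0) { skipped <- c(skipped, s); next }
    f <- fit_occupancy(ds, det$K, penalty = penalty, fp_shape2 = fp_shape2,
                       starts = starts)
    if (!f$converged) unresolved <- c(unresolved, s)
    fits[[s]] <- f
  }
  structure(list(fits = fits, skipped = skipped, unresolved = unresolved),
            class = "occupancy_fits")
}

#' Filter detections on posterior occupancy
#'
#' The decontamination step itself: a (species, site) detection is retained
#' when its posterior occupancy reaches `tau`; a species is retained in the
#' study when retained at one or more sites. Optionally a minimum replicate
#' count per site is applied as an alternative/additional rule. Species with
#' no detections are dropped trivially; species flagged unresolved are
#' dropped with a report rather than silently.
#'
#' @param det A `detection_array`.
#' @param fits An `occupancy_fits` from [fit_occupancy_all()].
#' @param tau Posterior-occupancy retention threshold in (0, 1); default
#'   0.8.
#' @param min_detections Optional fallback rule: also require d_j >=
#'   `min_detections` (default 1, i.e. inactive beyond having a detection).
#' @return A list of class `occupancy_filter_result`: `retained` (binary
#'   species x site matrix over retained detections), `decisions` (one row
#'   per species x site with d > 0: species, site, d, K, posterior, tau,
#'   retained), `species_kept`, `species_removed`, `unresolved`.
#' @export
occupancy_filter <- function(det, fits, tau = 0.8, min_detections = 1) {
  stopifnot(inherits(det, "detection_array"), inherits(fits, "occupancy_fits"))
  if (tau <= 0 || tau >= 1) stop("`tau` must be in (0, 1)", call. = FALSE)

  dec <- list()
  retained <- matrix(0L, nrow(det$d), ncol(det$d), dimnames = dimnames(det$d))
  for (s in rownames(det$d)) {
    ds <- det$d[s, ]
    pos <- which(ds > 0)
    if (length(pos) == 0) next
    f <- fits$fits[[s]]
    if (is.null(f))
      stop("species has detections but no fit: ", s, call. = FALSE)
    if (!f$converged) next  # unresolved: dropped, reported below
    post <- posterior_occupancy(f$psi, f$p11, f$p10, ds[pos], det$K[pos])
    keep <- post >= tau & ds[pos] >= min_detections
    retained[s, pos] <- as.integer(keep)
    dec[[length(dec) + 1L]] <- data.frame(
      species = s, site = names(ds)[pos], d = ds[pos], K = det$K[pos],
      posterior = post, tau = tau, retained = keep,
      stringsAsFactors = FALSE)
  }
  decisions <- if (length(dec)) do.call(rbind, dec) else
    data.frame(species = character(), site = character(), d = integer(),
               K = integer(), posterior = numeric(), tau = numeric(),
               retained = logical(), stringsAsFactors = FALSE)
  rownames(decisions) <- NULL
  kept <- rownames(retained)[rowSums(retained) > 0]
  had_det <- rownames(det$d)[rowSums(det$d) > 0]
  structure(list(
    retained = retained, decisions = decisions,
    species_kept = kept, species_removed = setdiff(had_det, kept),
    unresolved = fits$unresolved, tau = tau),
    class = "occupancy_filter_result")
}
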