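#' Incidence summary of a binary species-by-unit matrix
#'
#' Tallies the quantities all incidence-based completeness estimators use:
#' number of sampling units T, per-species incidence frequencies Y_i (units
#' containing the species), singleton and doubleton counts Q1 and Q2, total
#' incidence U = sum(Y_i), and observed richness S_obs. Species absent from
#' every unit are excluded from the tallies.
#'
#' @param mat Binary (0/1) species x unit matrix; columns are the sampling
#'   units (bottles, locations or stations depending on the chosen level).
#' @return A list of class `incidence_summary` with `T`, `Y` (named
#'   incidence frequencies, detected species only), `Q1`, `Q2`, `U`,
#'   `S_obs`.
#' @export
incidence_summary <- function(mat) {
  if (is.null(dim(mat)) || nrow(mat) == 0 || ncol(mat) == 0)
    stop("incidence matrix must have >= 1 species row and >= 1 unit column", call. = FALSE)
  m <- (mat > 0) * 1L
  Y <- as.integer(rowSums(m))
  names(Y) <- rownames(m)
  Y <- Y[Y > 0]
  structure(list(
    T = ncol(m), Y = Y,
    Q1 = sum(Y == 1L), Q2 = sum(Y == 2L),
    U = sum(Y), S_obs = length(Y)),
    class = "incidence_summary")
}

#' Incidence-based sample coverage
#'
#' Estimated fraction of the total incidence probability captured by the T
#' units sampled:
#' \deqn{\hat C = 1 - \frac{Q_1}{U}\cdot
#'   \frac{(T-1)Q_1}{(T-1)Q_1 + 2Q_2}.}
#' With no singletons the estimate is exactly 1 (nothing suggests unseen
#' species remain).
#'
#' @param s An `incidence_summary`.
#' @return Coverage estimate in [0, 1].
#' @export
sample_coverage <- function(s) {
  stopifnot(inherits(s, "incidence_summary"))
  if (s$U == 0) stop("coverage undefined: no incidences (U = 0)", call. = FALSE)
  if (s$Q1 == 0) return(1)
  denom <- (s$T - 1) * s$Q1 + 2 * s$Q2
  if (denom == 0) return(1)  # T = 1 with no doubletons: degenerate, fully "covered" by definition
  1 - (s$Q1 / s$U) * ((s$T - 1) * s$Q1 / denom)
}

#' Chao2 incidence-based richness estimate
#'
#' Bias-corrected nonparametric lower bound on species richness:
#' S_obs + ((T-1)/T) Q1^2 / (2 Q2) when doubletons exist, and
#' S_obs + ((T-1)/T) Q1 (Q1 - 1) / (2 (Q2 + 1)) otherwise.
#'
#' @param s An `incidence_summary` with T >= 2.
#' @return Estimated richness (always >= S_obs).
#' @export
chao2 <- function(s) {
  stopifnot(inherits(s, "incidence_summary"))
  if (s$T < 2) stop("Chao2 requires at least 2 sampling units", call. = FALSE)
  corr <- (s$T - 1) / s$T
  if (s$Q2 > 0) s$S_obs + corr * s$Q1^2 / (2 * s$Q2)
  else s$S_obs + corr * s$Q1 * (s$Q1 - 1) / (2 * (s$Q2 + 1))
}

# log C(n, k) with C(n, k) = 0 for k > n; vectorised over n.
lchoose0 <- function(n, k) ifelse(k > n, -Inf, lchoose(n, k))

#' Incidence-based rarefaction and extrapolation
#'
#' Expected species richness at t sampling units. Interpolation (t <= T) is
#' the exact combinatorial form
#' \deqn{S(t) = S_{obs} - \sum_i \binom{T-Y_i}{t} \big/ \binom{T}{t},}
#' computed in log space. Extrapolation (t > T) uses the Chao2 estimate of
#' undetected richness Q0_hat = Chao2 - S_obs:
#' \deqn{S(T+t^*) = S_{obs} + \hat Q_0\left[1 - \left(1 -
#'   \frac{Q_1}{T\hat Q_0 + Q_1}\right)^{t^*}\right],}
#' flat at S_obs when Q1 = 0. A coverage estimate accompanies each
#' interpolated point (the analytic finite-t coverage); extrapolated points
#' report the asymptotic direction only.
#'
#' @param s An `incidence_summary`.
#' @param t_grid Positive integer unit counts; defaults to 1..T.
#' @param level Optional label (`"bottle"`, `"location"`, `"station"`)
#'   carried into the output.
#' @return A data frame of class `rarefaction_curve`: `level`, `t`, `S`
#'   (expected richness), `coverage` (NA on extrapolated points),
#'   `extrapolated`. The Chao2 estimate and its Q0_hat are attached as
#'   attributes `chao2` and `Q0`.
#' @export
rarefy_extrapolate <- function(s, t_grid = NULL, level = NA_character_) {
  stopifnot(inherits(s, "incidence_summary"))
  if (is.null(t_grid)) t_grid <- seq_len(s$T)
  if (any(t_grid < 1) || any(t_grid != round(t_grid)))
    stop("`t_grid` must be positive integers", call. = FALSE)
  t_grid <- sort(unique(as.integer(t_grid)))

  ch <- if (s$T >= 2) chao2(s) else s$S_obs
  Q0 <- ch - s$S_obs

  S_interp <- function(t) {
    s$S_obs - sum(exp(lchoose0(s$T - s$Y, t) - lchoose(s$T, t)))
  }
  # finite-t coverage: expected singleton deficit after t units (analytic
  # form of the coverage estimator applied to the rarefied sample)
  C_interp <- function(t) {
    if (t >= s$T) return(sample_coverage(s))
    exp_Q1_t <- sum(s$Y / s$T * exp(lchoose0(s$T - s$Y, t) - lchoose0(s$T - 1, t)) * t)
    U_t <- t * s$U / s$T
    if (U_t == 0) return(NA_real_)
    max(0, min(1, 1 - exp_Q1_t / U_t))
  }

  S <- numeric(length(t_grid)); cv <- numeric(length(t_grid))
  extr <- t_grid > s$T
  for (i in seq_along(t_grid)) {
    t <- t_grid[i]
    if (t <= s$T) {
      S[i] <- S_interp(t); cv[i] <- C_interp(t)
    } else {
      tstar <- t - s$T
      S[i] <- if (Q0 <= 0 || s$Q1 == 0) s$S_obs else
        s$S_obs + Q0 * (1 - (1 - s$Q1 / (s$T * Q0 + s$Q1))^tstar)
      cv[i] <- NA_real_
    }
  }
  out <- data.frame(level = level, t = t_grid, S = S, coverage = cv,
                    extrapolated = extr, stringsAsFactors = FALSE)
  attr(out, "chao2") <- ch
  attr(out, "Q0") <- Q0
  class(out) <- c("rarefaction_curve", "data.frame")
  out
}

#' Units needed to saturate diversity
#'
#' Two operationalisations of "enough sampling units", both reported: the
#' smallest t whose estimated coverage reaches `coverage_target`, and the
#' smallest t whose expected richness reaches `richness_fraction` of the
#' Chao2 estimate. Searches the interpolated range and, for the richness
#' rule, the extrapolated range up to `max_t`.
#'
#' @param s An `incidence_summary`.
#' @param coverage_target Coverage threshold (default 0.95).
#' @param richness_fraction Fraction of Chao2 richness (default 0.95).
#' @param max_t Search limit for extrapolation (default 3 T).
#' @return A list: `t_coverage`, `t_richness` (NA when the target is not
#'   reached by `max_t`), plus the targets used.
#' @export
units_to_saturation <- function(s, coverage_target = 0.95,
                                richness_fraction = 0.95, max_t = 3 * s$T) {
  curve <- rarefy_extrapolate(s, t_grid = seq_len(max_t))
  ch <- attr(curve, "chao2")
  t_cov <- curve$t[!is.na(curve$coverage) & curve$coverage >= coverage_target]
  t_rich <- curve$t[curve$S >= richness_fraction * ch]
  list(t_coverage = if (length(t_cov)) min(t_cov) else NA_integer_,
       t_richness = if (length(t_rich)) min(t_rich) else NA_integer_,
       coverage_target = coverage_target, richness_fraction = richness_fraction,
       chao2 = ch)
}

#' Completeness summary across the survey hierarchy
#'
#' Computes coverage and Chao2 at each level of the design: bottles within
#' each location, locations within each station, and stations within the
#' whole survey. Incidence at an aggregate level counts a species present in
#' a unit when it was detected in any of the unit's bottles.
#'
#' @param det A `detection_array` built at the location level.
#' @param records Sample metadata (to map locations to stations).
#' @return A data frame with one row per (level, unit): `level`, `unit`,
#'   `T`, `S_obs`, `coverage`, `chao2`.
#' @export
hierarchy_completeness <- function(det, records) {
  stopifnot(inherits(det, "detection_array"))
  rows <- list()
  add <- function(level, unit, m) {
    if (sum(m) == 0) return()
    s <- incidence_summary(m)
    rows[[length(rows) + 1L]] <<- data.frame(
      level = level, unit = unit, T = s$T, S_obs = s$S_obs,
      coverage = sample_coverage(s),
      chao2 = if (s$T >= 2) chao2(s) else NA_real_,
      stringsAsFactors = FALSE)
  }
  # bottles within each location
  for (loc in det$sites$site) {
    cols <- det$bottle_site == loc
    add("bottle", loc, det$y[, cols, drop = FALSE])
  }
  # locations within each station (species present in any bottle of the location)
  pres_loc <- (det$d > 0) * 1L
  for (st in unique(det$sites$station)) {
    cols <- det$sites$site[det$sites$station == st]
    add("location", st, pres_loc[, cols, drop = FALSE])
  }
  # stations within the survey
  pres_st <- sapply(unique(det$sites$station), function(st) {
    cols <- det$sites$site[det$sites$station == st]
    (rowSums(pres_loc[, cols, drop = FALSE]) > 0) * 1L
  })
  add("station", "port", pres_st)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
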