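#' eDNA index transformation
#'
#' The double transformation used to compare a taxon's signal across
#' samples: read counts are first converted to within-sample proportions
#' (removing library-depth differences), then each taxon's row is scaled by
#' its own maximum, so every retained taxon spans (0, 1] and attains 1 in
#' the sample where its relative signal peaks. Cross-taxon comparisons of
#' index values are meaningless by construction; the index tracks each
#' taxon's signal across space.
#'
#' @param read_table A `read_table` (or any non-negative taxa x samples
#'   matrix).
#' @return A numeric taxa x samples matrix in [0, 1]. All-zero taxa are
#'   dropped with a warning (their row maximum is undefined); all-zero
#'   samples are left as zero columns.
#' @examples
#' m <- matrix(c(10, 90, 30, 70), 2, dimnames = list(c("a", "b"), c("s1", "s2")))
#' edna_index(m)
#' @export
edna_index <- function(read_table) {
  m <- unclass(read_table)
  storage.mode(m) <- "double"
  zero_tax <- rowSums(m) == 0
  if (any(zero_tax)) {
    warning("dropping ", sum(zero_tax), " all-zero taxa from eDNA index", call. = FALSE)
    m <- m[!zero_tax, , drop = FALSE]
  }
  if (nrow(m) == 0) stop("no taxa with positive counts", call. = FALSE)
  tot <- colSums(m)
  prop <- sweep(m, 2, ifelse(tot == 0, 1, tot), "/")
  sweep(prop, 1, apply(prop, 1, max), "/")
}

#' Community dissimilarity matrix between samples
#'
#' Jaccard (presence/absence: 1 - shared / union) or Bray-Curtis
#' (sum |x - y| / sum (x + y), suitable for the eDNA index or counts)
#' distances between the columns of a taxa x samples table. Jaccard input
#' is auto-binarised with a warning when quantitative. Two all-zero samples
#' are assigned distance 0 with a warning.
#'
#' @param table Taxa x samples matrix.
#' @param metric `"jaccard"` or `"bray_curtis"`.
#' @return A symmetric `dist_matrix` (samples x samples) with zero
#'   diagonal; the metric name is attached as attribute `metric`.
#' @export
distance_matrix <- function(table, metric = c("jaccard", "bray_curtis")) {
  metric <- match.arg(metric)
  m <- unclass(table)
  storage.mode(m) <- "double"
  if (metric == "jaccard" && any(m != 0 & m != 1)) {
    warning("binarising quantitative input for Jaccard distance", call. = FALSE)
    m <- (m > 0) * 1
  }
  n <- ncol(m)
  if (n < 2) stop("need at least 2 samples", call. = FALSE)
  D <- matrix(0, n, n, dimnames = list(colnames(m), colnames(m)))
  warned <- FALSE
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    x <- m[, i]; y <- m[, j]
    if (metric == "jaccard") {
      un <- sum(x > 0 | y > 0)
      d <- if (un == 0) 0 else 1 - sum(x > 0 & y > 0) / un
      if (un == 0 && !warned) { warning("all-zero sample pair: distance set to 0", call. = FALSE); warned <- TRUE }
    } else {
      s <- sum(x + y)
      d <- if (s == 0) 0 else sum(abs(x - y)) / s
      if (s == 0 && !warned) { warning("all-zero sample pair: distance set to 0", call. = FALSE); warned <- TRUE }
    }
    D[i, j] <- D[j, i] <- d
  }
  structure(D, metric = metric, class = c("dist_matrix", "matrix", "array"))
}

gower_center <- function(D) {
  n <- nrow(D)
  A <- -0.5 * D^2
  J <- diag(n) - matrix(1 / n, n, n)
  J %*% A %*% J
}

#' Principal coordinates analysis
#'
#' Embeds a distance matrix into coordinates via Gower double-centering
#' G = -1/2 J D^2 J and eigendecomposition. Coordinates are eigenvectors
#' scaled by the square root of their (positive) eigenvalues; axes are
#' ordered by decreasing eigenvalue and explained-variance proportions are
#' computed over positive eigenvalues only. Negative eigenvalues (from
#' non-Euclidean distances) are dropped and their absolute mass reported —
#' no Lingoes/Cailliez correction is applied.
#'
#' @param D A `dist_matrix` (or symmetric matrix with zero diagonal).
#' @return A list of class `pcoa_ordination`: `coordinates` (samples x
#'   axes), `eigenvalues` (positive ones), `proportion` (variance share per
#'   axis), `negative_mass` (sum of |negative eigenvalues|).
#' @export
pcoa <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) < 2) stop("need at least 2 samples", call. = FALSE)
  if (max(abs(D - t(D))) > 1e-12) stop("distance matrix must be symmetric", call. = FALSE)
  G <- gower_center(D)
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  tol <- max(abs(e$values)) * 1e-10
  pos <- e$values > tol
  neg_mass <- sum(abs(e$values[e$values < -tol]))
  lam <- e$values[pos]
  coords <- e$vectors[, pos, drop = FALSE] %*% diag(sqrt(lam), nrow = length(lam))
  rownames(coords) <- rownames(D)
  colnames(coords) <- paste0("Axis", seq_len(ncol(coords)))
  structure(list(coordinates = coords, eigenvalues = lam,
                 proportion = lam / sum(lam), negative_mass = neg_mass),
            class = "pcoa_ordination")
}

hat_matrix <- function(X) {
  q <- qr(X)
  Q <- qr.Q(q)[, seq_len(q$rank), drop = FALSE]
  Q %*% t(Q)
}

#' Permutational multivariate analysis of variance (nested design)
#'
#' Partitions the variation of a distance matrix among sequential terms via
#' the Gower-centred matrix G and nested hat-matrix projections:
#' SS(term) = tr((H_k - H_(k-1)) G), SS_resid = tr((I - H_full) G),
#' SS_total = tr(G) (the McArdle-Anderson identity; on Euclidean distances
#' this reproduces classical ANOVA partitioning exactly). Pseudo-F per term
#' uses the overall residual; R^2 = SS / SS_total sums to 1 over terms plus
#' residual.
#'
#' Permutation p-values respect the hierarchy: the first term is tested by
#' free permutation of samples; each later term by permutation of samples
#' within the levels of the first term (the restricted scheme for a factor
#' nested in the first). P-values are (b + 1) / (B + 1) and reproducible by
#' seed.
#'
#' @param D A `dist_matrix` (samples x samples).
#' @param metadata Data frame with one row per sample of `D`, in `D`'s
#'   order, containing the term columns.
#' @param terms Character vector of metadata columns, outermost first
#'   (e.g. `c("station", "location")`); later terms are treated as nested
#'   within the first.
#' @param n_perm Number of permutations (warning below 99).
#' @param seed Integer seed for the permutation stream.
#' @return A data frame of class `permanova_result` with rows per term plus
#'   `Residual` and `Total`: `df`, `SS`, `R2`, `F`, `p`. Attributes
#'   `n_perm` and `seed`.
#' @export
permanova <- function(D, metadata, terms, n_perm = 999, seed = 1) {
  D <- as.matrix(D)
  n <- nrow(D)
  stopifnot(nrow(metadata) == n)
  if (!all(terms %in% names(metadata)))
    stop("terms missing from metadata: ",
         paste(setdiff(terms, names(metadata)), collapse = ", "), call. = FALSE)
  for (tm in terms) {
    if (length(unique(metadata[[tm]])) < 2)
      stop(sprintf("term '%s' has a single level", tm), call. = FALSE)
  }
  if (n_perm < 99) warning("fewer than 99 permutations: p-values are coarse", call. = FALSE)

  G <- gower_center(D)
  factors <- lapply(terms, function(tm) factor(metadata[[tm]]))
  names(factors) <- terms

  # nested sequential projections: dummy columns for terms 1..k
  Xs <- list(matrix(1, n, 1))
  for (k in seq_along(terms)) {
    dummies <- lapply(seq_len(k), function(i) {
      f <- factors[[i]]
      stats::model.matrix(~ 0 + f)
    })
    Xs[[k + 1]] <- do.call(cbind, c(list(matrix(1, n, 1)), dummies))
  }
  Hs <- lapply(Xs, hat_matrix)
  ranks <- vapply(Xs, function(X) qr(X)$rank, integer(1))

  SS_total <- sum(diag(G))
  K <- length(terms)
  SS <- df <- numeric(K)
  for (k in seq_len(K)) {
    SS[k] <- sum((Hs[[k + 1]] - Hs[[k]]) * t(G))  # tr(AB) = sum(A * t(B))
    df[k] <- ranks[k + 1] - ranks[k]
  }
  H_full <- Hs[[K + 1]]
  SS_res <- sum((diag(n) - H_full) * t(G))
  df_res <- n - ranks[K + 1]
  Fv <- (SS / df) / (SS_res / df_res)

  # permutation tests
  term_F <- function(Gp, k) {
    ssk <- sum((Hs[[k + 1]] - Hs[[k]]) * t(Gp))
    ssr <- sum((diag(n) - H_full) * t(Gp))
    (ssk / df[k]) / (ssr / df_res)
  }
  set.seed(as.integer(seed) %% 2000000000L)
  p <- rep(NA_real_, K)
  exceed <- integer(K)
  top <- factors[[1]]
  for (b in seq_len(n_perm)) {
    perm_free <- sample.int(n)
    Gf <- G[perm_free, perm_free]
    if (term_F(Gf, 1) >= Fv[1] - 1e-12) exceed[1] <- exceed[1] + 1L
    if (K > 1) {
      perm_within <- seq_len(n)
      for (lev in levels(top)) {
        idx <- which(top == lev)
        perm_within[idx] <- idx[sample.int(length(idx))]
      }
      Gw <- G[perm_within, perm_within]
      for (k in 2:K)
        if (term_F(Gw, k) >= Fv[k] - 1e-12) exceed[k] <- exceed[k] + 1L
    }
  }
  p <- (exceed + 1) / (n_perm + 1)

  out <- data.frame(
    term = c(terms, "Residual", "Total"),
    df = c(df, df_res, n - 1),
    SS = c(SS, SS_res, SS_total),
    R2 = c(SS, SS_res, SS_total) / SS_total,
    F = c(Fv, NA, NA),
    p = c(p, NA, NA),
    stringsAsFactors = FALSE)
  attr(out, "n_perm") <- n_perm
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("permanova_result", "data.frame")
  out
}
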