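# The statistical layer: Spearman correlation, PERMANOVA with Euclidean
# distances, permutation test for homogeneity of multivariate
# dispersions, and group-size-corrected indicator value (IndVal.g)
# analysis. Permutation p-values use the add-one convention
# p = (1 + b) / (1 + m), so the attainable floor at 999 permutations is
# exactly 0.001.

#' Spearman rank correlation
#'
#' Pearson correlation of average-ranked values (ties receive average
#' ranks). Pairs with a missing member are deleted first.
#'
#' @param x,y numeric vectors of equal length.
#' @return list of class `correlation_result` with `rho` and `n` (number
#'   of complete pairs used).
#' @export
spearman <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("fewer than 3 complete pairs", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  if (stats::var(rx) == 0 || stats::var(ry) == 0) {
    stop("correlation undefined: zero rank variance", call. = FALSE)
  }
  structure(list(rho = stats::cor(rx, ry), n = length(x)),
            class = "correlation_result")
}

perm_indices <- function(n, n_perm, seed) {
  set.seed(seed)
  lapply(seq_len(n_perm), function(i) sample.int(n))
}

# squared Euclidean distances, full matrix
sq_dists <- function(X) {
  d <- as.matrix(stats::dist(X, method = "euclidean"))
  d^2
}

permanova_ss <- function(d2, groups) {
  n <- nrow(d2)
  ss_total <- sum(d2[upper.tri(d2)]) / n
  ss_within <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    ss_within <- ss_within + sum(d2[idx, idx]) / 2 / length(idx)
  }
  c(total = ss_total, within = ss_within)
}

#' Permutational multivariate analysis of variance
#'
#' One-way PERMANOVA on Euclidean distances. The pseudo-F statistic is
#' computed from the partition of the summed squared interpoint
#' distances; significance by permutation of the group labels. In one
#' dimension with Euclidean distances the pseudo-F equals the classical
#' one-way ANOVA F exactly.
#'
#' @param X numeric samples x features matrix (or vector).
#' @param groups group labels, length `nrow(X)`; every group needs at
#'   least 2 members.
#' @param n_perm number of permutations (default 999).
#' @param seed RNG seed for the permutations.
#' @return list of class `permanova_result`: `pseudo_F`, `R2`, `p`,
#'   `n_perm`, `seed`, `df`.
#' @export
permanova <- function(X, groups, n_perm = 999, seed = 1L) {
  X <- as.matrix(X)
  groups <- as.character(groups)
  stopifnot(nrow(X) == length(groups))
  sizes <- table(groups)
  if (length(sizes) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(sizes < 2L)) stop("every group needs at least 2 samples", call. = FALSE)
  n <- nrow(X); k <- length(sizes)
  d2 <- sq_dists(X)
  if (all(d2 == 0)) stop("degenerate data: all rows identical", call. = FALSE)

  f_of <- function(g) {
    ss <- permanova_ss(d2, g)
    ((ss[["total"]] - ss[["within"]]) / (k - 1)) / (ss[["within"]] / (n - k))
  }
  ss <- permanova_ss(d2, groups)
  f_obs <- ((ss[["total"]] - ss[["within"]]) / (k - 1)) /
    (ss[["within"]] / (n - k))
  r2 <- 1 - ss[["within"]] / ss[["total"]]
  perms <- perm_indices(n, n_perm, seed)
  f_perm <- vapply(perms, function(p) f_of(groups[p]), numeric(1L))
  p <- (1 + sum(f_perm >= f_obs)) / (n_perm + 1)
  structure(list(pseudo_F = f_obs, R2 = r2, p = p, n_perm = n_perm,
                 seed = seed, df = c(k - 1L, n - k)),
            class = "permanova_result")
}

#' Permutation test for homogeneity of multivariate dispersions
#'
#' Each sample's Euclidean distance to its own group centroid is
#' computed; the test statistic is the one-way ANOVA F of those
#' distances across groups, with significance by permuting the group
#' labels over the fixed distance values. With Euclidean distances on
#' the raw coordinates no negative-eigenvalue correction arises.
#'
#' @inheritParams permanova
#' @return list of class `dispersion_result`: `F`, `p`,
#'   `group_mean_dists`, `n_perm`, `seed`.
#' @export
dispersion_test <- function(X, groups, n_perm = 999, seed = 1L) {
  X <- as.matrix(X)
  groups <- as.character(groups)
  stopifnot(nrow(X) == length(groups))
  sizes <- table(groups)
  if (length(sizes) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(sizes < 2L)) stop("every group needs at least 2 samples", call. = FALSE)
  dists <- numeric(nrow(X))
  for (g in unique(groups)) {
    idx <- which(groups == g)
    centroid <- colMeans(X[idx, , drop = FALSE])
    dists[idx] <- sqrt(rowSums((X[idx, , drop = FALSE] -
                                  rep(centroid, each = length(idx)))^2))
  }
  anova_f <- function(v, g) {
    gm <- tapply(v, g, mean); ns <- tapply(v, g, length)
    ss_b <- sum(ns * (gm - mean(v))^2)
    ss_w <- sum((v - gm[g])^2)
    k <- length(gm); n <- length(v)
    if (ss_w == 0) return(if (ss_b == 0) 0 else Inf)
    (ss_b / (k - 1)) / (ss_w / (n - k))
  }
  f_obs <- anova_f(dists, groups)
  perms <- perm_indices(length(dists), n_perm, seed)
  f_perm <- vapply(perms, function(p) anova_f(dists, groups[p]), numeric(1L))
  p <- (1 + sum(f_perm >= f_obs)) / (n_perm + 1)
  gmd <- tapply(dists, groups, mean)
  structure(list(F = f_obs, p = p, group_mean_dists = gmd,
                 n_perm = n_perm, seed = seed),
            class = "dispersion_result")
}

indval_stats <- function(M, groups, group_levels) {
  # per-group mean abundance and occupancy; A is group-size corrected
  k <- length(group_levels)
  means <- matrix(0, nrow = k, ncol = ncol(M),
                  dimnames = list(group_levels, colnames(M)))
  occ <- means
  for (g in group_levels) {
    sub <- M[groups == g, , drop = FALSE]
    means[g, ] <- colMeans(sub)
    occ[g, ] <- colMeans(sub > 0)
  }
  denom <- colSums(means)
  A <- sweep(means, 2L, denom, "/")
  A[, denom == 0] <- NA_real_
  stat <- sqrt(A * occ)
  list(A = A, B = occ, stat = stat)
}

#' Indicator value analysis (IndVal.g)
#'
#' For each feature and group, specificity `A` is the group's mean
#' abundance over the sum of all groups' mean abundances (the
#' group-size-corrected form), fidelity `B` is the fraction of the
#' group's samples where the feature occurs, and the indicator statistic
#' is `sqrt(A * B)`. Each feature is assigned its best (argmax) group;
#' significance by permuting sample labels and comparing the permuted
#' best-group statistic against the observed one. Features absent
#' everywhere are reported with `NA` statistics.
#'
#' @param M numeric samples x features abundance matrix (nonnegative).
#' @param groups group labels (at least 2 groups).
#' @param n_perm number of permutations (default 999).
#' @param seed RNG seed.
#' @return list of class `indicator_result` with data.frame `table`
#'   (feature, best_group, A, B, stat, p) plus `n_perm`, `seed`.
#' @export
indval <- function(M, groups, n_perm = 999, seed = 1L) {
  M <- as.matrix(M)
  groups <- as.character(groups)
  stopifnot(nrow(M) == length(groups))
  if (any(M < 0)) stop("abundances must be nonnegative", call. = FALSE)
  levels <- sort(unique(groups))
  if (length(levels) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (is.null(colnames(M))) colnames(M) <- paste0("f", seq_len(ncol(M)))

  obs <- indval_stats(M, groups, levels)
  best_idx <- apply(obs$stat, 2L, function(s) {
    if (all(is.na(s))) NA_integer_ else which.max(s)
  })
  best_stat <- vapply(seq_len(ncol(M)), function(j) {
    if (is.na(best_idx[[j]])) NA_real_ else obs$stat[best_idx[[j]], j]
  }, numeric(1L))

  perms <- perm_indices(nrow(M), n_perm, seed)
  exceed <- integer(ncol(M))
  for (p in perms) {
    ps <- indval_stats(M, groups[p], levels)$stat
    pmax_stat <- suppressWarnings(apply(ps, 2L, max, na.rm = TRUE))
    exceed <- exceed + as.integer(!is.na(best_stat) & pmax_stat >= best_stat)
  }
  pval <- ifelse(is.na(best_stat), NA_real_, (1 + exceed) / (n_perm + 1))

  tab <- data.frame(
    feature = colnames(M),
    best_group = ifelse(is.na(best_idx), NA_character_, levels[best_idx]),
    A = vapply(seq_len(ncol(M)), function(j)
      if (is.na(best_idx[[j]])) NA_real_ else obs$A[best_idx[[j]], j], numeric(1L)),
    B = vapply(seq_len(ncol(M)), function(j)
      if (is.na(best_idx[[j]])) NA_real_ else obs$B[best_idx[[j]], j], numeric(1L)),
    stat = best_stat,
    p = pval,
    stringsAsFactors = FALSE)
  tab <- tab[order(-replace(tab$stat, is.na(tab$stat), -1), tab$feature), ]
  rownames(tab) <- NULL
  structure(list(table = tab, n_perm = n_perm, seed = seed),
            class = "indicator_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA (Euclidean): pseudo-F = %.4f, R2 = %.4f, p = %.4g (%d permutations)\n",
              x$pseudo_F, x$R2, x$p, x$n_perm))
  invisible(x)
}

#' @export
print.indicator_result <- function(x, ...) {
  cat(sprintf("IndVal.g over %d features (%d permutations)\n",
              nrow(x$table), x$n_perm))
  print(utils::head(x$table, 10L))
  invisible(x)
}
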