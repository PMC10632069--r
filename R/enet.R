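# Elastic-net feature selection via cross-validated glmnet, with the
# one-standard-error rule for choosing the regularization strength.

#' Elastic-net feature selection
#'
#' Fits a penalized generalized linear model over a decreasing lambda
#' path, picks lambda by K-fold cross-validation, and reports the
#' features with nonzero coefficients at the chosen penalty. The default
#' rule is the one-standard-error rule: the largest lambda whose
#' cross-validated error is within one standard error of the minimum.
#' Predictors are standardized internally; coefficients are reported on
#' the original scale. The mixing parameter defaults to `alpha = 1`
#' (pure lasso, the glmnet default); set `alpha < 1` to blend in a ridge
#' penalty. Fold assignment is a seeded random permutation, stratified
#' by class for the binomial family, so results are reproducible from
#' `(seed, n_folds)`.
#'
#' @param X numeric samples x features matrix with column names.
#' @param y response: numeric (gaussian) or two-level (binomial).
#' @param family `"gaussian"` or `"binomial"`.
#' @param alpha elastic-net mixing parameter in (0, 1].
#' @param n_folds number of CV folds (default 10); must not exceed `n`.
#' @param rule `"lambda_1se"` (default) or `"lambda_min"`.
#' @param seed RNG seed for fold assignment.
#' @param lambda optional explicit lambda path.
#' @param ... further arguments passed to [glmnet::cv.glmnet()] (e.g.
#'   `thresh` for a tighter convergence tolerance).
#' @return list of class `enet_result`: `family`, `alpha`, `lambda_path`,
#'   `cv_mean`, `cv_se`, `lambda_min`, `lambda_1se`, `lambda_used`,
#'   `intercept`, `coefficients` (named, all features), `selected`
#'   (features with nonzero coefficient), `seed`, `n_folds`.
#' @export
elastic_net_select <- function(X, y, family = c("gaussian", "binomial"),
                               alpha = 1.0, n_folds = 10L,
                               rule = c("lambda_1se", "lambda_min"),
                               seed = 1L, lambda = NULL, ...) {
  family <- match.arg(family)
  rule <- match.arg(rule)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- nrow(X)
  stopifnot(length(y) == n)
  if (!is.numeric(alpha) || alpha <= 0 || alpha > 1) {
    stop("alpha must lie in (0, 1]", call. = FALSE)
  }
  if (n_folds > n) stop("n_folds exceeds the number of samples", call. = FALSE)

  if (family == "binomial") {
    lv <- sort(unique(as.character(y)))
    if (length(lv) != 2L) stop("binomial response must have exactly 2 levels",
                               call. = FALSE)
    ybin <- as.integer(as.character(y) == lv[[2L]])
    foldid <- stratified_folds(ybin, n_folds, seed)
    y_use <- ybin
  } else {
    y_use <- as.numeric(y)
    if (stats::var(y_use) == 0) {
      # degenerate: constant response carries no signal, return null model
      coefs <- stats::setNames(rep(0, ncol(X)), colnames(X))
      return(structure(list(family = family, alpha = alpha,
                            lambda_path = numeric(), cv_mean = numeric(),
                            cv_se = numeric(), lambda_min = NA_real_,
                            lambda_1se = NA_real_, lambda_used = NA_real_,
                            intercept = mean(y_use), coefficients = coefs,
                            selected = character(), seed = seed,
                            n_folds = n_folds),
                       class = "enet_result"))
    }
    set.seed(seed)
    foldid <- sample(rep_len(seq_len(n_folds), n))
  }

  cv <- glmnet::cv.glmnet(X, y_use, family = family, alpha = alpha,
                          foldid = foldid, lambda = lambda,
                          standardize = TRUE, ...)
  lam <- switch(rule, lambda_1se = cv$lambda.1se, lambda_min = cv$lambda.min)
  beta <- as.numeric(stats::coef(cv, s = lam))
  names(beta) <- c("(Intercept)", colnames(X))
  coefs <- beta[-1L]
  structure(list(family = family, alpha = alpha,
                 lambda_path = cv$lambda, cv_mean = cv$cvm, cv_se = cv$cvsd,
                 lambda_min = cv$lambda.min, lambda_1se = cv$lambda.1se,
                 lambda_used = lam, intercept = beta[[1L]],
                 coefficients = coefs,
                 selected = names(coefs)[coefs != 0],
                 seed = seed, n_folds = n_folds),
            class = "enet_result")
}

stratified_folds <- function(ybin, n_folds, seed) {
  set.seed(seed)
  foldid <- integer(length(ybin))
  for (cls in unique(ybin)) {
    idx <- which(ybin == cls)
    foldid[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  foldid
}

#' @export
print.enet_result <- function(x, ...) {
  cat(sprintf("elastic net (%s, alpha=%.2f): %d/%d features selected at lambda=%.4g\n",
              x$family, x$alpha, length(x$selected), length(x$coefficients),
              x$lambda_used))
  invisible(x)
}

#' Z-scale selected elastic-net coefficients
#'
#' Centers and scales the nonzero coefficients of a fitted model to
#' z-scores (sample standard deviation), the scale used to rank species
#' coefficients across regressions. Also reports the absolute z-scores
#' of the negative-coefficient features — the features whose abundance
#' increases as the response decreases.
#'
#' @param result an `enet_result` with at least 2 selected features.
#' @return list with `z` (named z-scores over selected features, mean 0)
#'   and `abs_z_negative` (absolute z of negative-coefficient features,
#'   decreasing).
#' @export
zscale_coefficients <- function(result) {
  stopifnot(inherits(result, "enet_result"))
  b <- result$coefficients[result$selected]
  if (length(b) < 2L) stop("need at least 2 selected coefficients", call. = FALSE)
  s <- stats::sd(b)
  if (s == 0) stop("selected coefficients are all equal: zero sd", call. = FALSE)
  z <- (b - mean(b)) / s
  neg <- abs(z[b < 0])
  list(z = z, abs_z_negative = sort(neg, decreasing = TRUE))
}
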