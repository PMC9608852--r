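#' Partial least squares regression (NIPALS, univariate response)
#'
#' Fits a PLS regression of a single response on a predictor matrix by
#' iterative latent-variable extraction. Each component starts from the
#' SVD of the cross-product of the current (deflated) predictor and
#' response matrices; with a univariate response the first left singular
#' vector is simply the normalized cross-product vector. Per component:
#' the weight vector `w` and score `t = E w` (normalized to unit length)
#' are extracted, loadings `p = E't` and `q = F't` are computed, and the
#' working matrices are deflated by the outer products `t p'` and `t q'`.
#' After `ncomp` components the weights are mapped back to the original
#' predictor space through \eqn{R = W (P' W)^{-1}} and the coefficient
#' vector is \eqn{B = R b} with \eqn{b = (T'T)^{-1} T' y}.
#'
#' Scores are normalized to unit Euclidean norm; the final coefficients
#' are invariant to the score normalization convention. The sign of each
#' weight vector is fixed so its largest-magnitude entry is positive,
#' making output reproducible across linear-algebra backends. Extraction
#' stops early (with a message recorded in the object) once the residual
#' predictor matrix or the cross-product is numerically zero.
#'
#' @param X numeric predictor matrix, n x p.
#' @param y numeric response vector of length n.
#' @param ncomp number of latent variables to extract; must not exceed
#'   `min(n - 1, p)`.
#' @param scale logical; if `TRUE` predictor columns are scaled to unit
#'   sample variance in addition to centering. Default `FALSE`: the
#'   relationship-augmented design matrices are already on a common scale
#'   through the kinship roots.
#' @return an object of class `pls_nipals` with components `W`, `T`, `P`,
#'   `Q`, `R` (weights, scores, X-loadings, y-loadings, transformed
#'   weights), `B` (coefficients on centered predictors), `b` (inner
#'   regression coefficients), `ncomp` (effective number of components),
#'   centering/scaling statistics, fitted values and residuals.
#' @examples
#' X <- matrix(rnorm(48), 12, 4)
#' y <- X[, 1] - 2 * X[, 3] + rnorm(12, sd = 0.1)
#' fit <- pls_fit(X, y, ncomp = 2)
#' predict(fit, X)
#' @export
pls_fit <- function(X, y, ncomp, scale = FALSE) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("length of y must equal nrow(X)")
  if (n < 2L) stop("need at least 2 observations")
  if (!all(is.finite(X)) || !all(is.finite(y)))
    stop("X and y must be finite")
  if (ncomp < 1L) stop("ncomp must be at least 1")
  if (ncomp > min(n - 1L, p))
    stop("ncomp must not exceed min(n - 1, p) = ", min(n - 1L, p))
  if (stats::var(y) == 0) stop("response has zero variance")

  x_center <- colMeans(X)
  E <- sweep(X, 2L, x_center)
  if (scale) {
    x_scale <- apply(X, 2L, stats::sd)
    x_scale[x_scale == 0] <- 1   # constant columns stay (centered) zero
    E <- sweep(E, 2L, x_scale, "/")
  } else {
    x_scale <- NULL
  }
  y_center <- mean(y)
  f <- y - y_center
  Xc <- E
  x_norm <- sqrt(sum(E^2))

  W <- P <- matrix(0, p, ncomp)
  Tm <- U <- matrix(0, n, ncomp)
  Q <- numeric(ncomp)
  a_eff <- 0L
  for (a in seq_len(ncomp)) {
    if (sqrt(sum(E^2)) < 1e-12 * x_norm) break
    s <- crossprod(E, f)                      # p x 1 cross-product
    s_norm <- sqrt(sum(s^2))
    if (s_norm < 1e-12 * max(x_norm, 1)) break
    w <- s / s_norm
    imax <- which.max(abs(w))
    if (w[imax] < 0) w <- -w                  # deterministic sign
    t_vec <- drop(E %*% w)
    t_norm <- sqrt(sum(t_vec^2))
    if (t_norm < 1e-12 * max(x_norm, 1)) break
    t_vec <- t_vec / t_norm
    p_vec <- drop(crossprod(E, t_vec))
    q_a <- sum(f * t_vec)
    W[, a] <- w; Tm[, a] <- t_vec; P[, a] <- p_vec; Q[a] <- q_a
    U[, a] <- f                               # y scores, pre-deflation
    E <- E - tcrossprod(t_vec, p_vec)
    f <- f - t_vec * q_a                      # y deflation (redundant for
    a_eff <- a                                # univariate y, kept as stated)
  }
  if (a_eff == 0L) stop("no latent variable could be extracted")
  W <- W[, seq_len(a_eff), drop = FALSE]
  Tm <- Tm[, seq_len(a_eff), drop = FALSE]
  P <- P[, seq_len(a_eff), drop = FALSE]
  U <- U[, seq_len(a_eff), drop = FALSE]
  Q <- Q[seq_len(a_eff)]

  R <- W %*% solve(crossprod(P, W))
  yc <- y - y_center
  b <- drop(solve(crossprod(Tm), crossprod(Tm, yc)))
  B <- drop(R %*% b)
  fitted <- drop(Xc %*% B) + y_center

  structure(list(W = W, T = Tm, P = P, Q = Q, U = U, R = R,
                 B = B, b = b, ncomp = a_eff, ncomp_requested = ncomp,
                 x_center = x_center, x_scale = x_scale,
                 y_center = y_center, scale = scale,
                 fitted.values = fitted, residuals = y - fitted,
                 y = y, n = n, p = p,
                 colnames = colnames(X),
                 call = match.call()),
            class = "pls_nipals")
}

# coefficient vector truncated to the first `a` components
pls_coef_a <- function(object, a) {
  a <- min(a, object$ncomp)
  drop(object$R[, seq_len(a), drop = FALSE] %*% object$b[seq_len(a)])
}

#' Predict from a fitted PLS model
#'
#' New predictors are centered (and scaled, if the model was fitted with
#' scaling) using the training statistics, then multiplied by the
#' coefficient vector: \eqn{\hat y = X_{new} B + \bar y}. This is
#' algebraically identical to projecting onto new scores,
#' \eqn{T_{new} = X_{new} R}, and applying the inner regression.
#'
#' @param object a `pls_nipals` model.
#' @param newdata numeric matrix with the same number of columns as the
#'   training predictors.
#' @param ncomp optionally predict with only the first `ncomp` latent
#'   variables (at most the fitted number).
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.pls_nipals <- function(object, newdata, ncomp = NULL, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$p)
    stop("newdata has ", ncol(newdata), " columns; model expects ", object$p)
  Xc <- sweep(newdata, 2L, object$x_center)
  if (object$scale) Xc <- sweep(Xc, 2L, object$x_scale, "/")
  B <- if (is.null(ncomp)) object$B else pls_coef_a(object, ncomp)
  drop(Xc %*% B) + object$y_center
}

#' @export
coef.pls_nipals <- function(object, ncomp = NULL, ...) {
  B <- if (is.null(ncomp)) object$B else pls_coef_a(object, ncomp)
  names(B) <- object$colnames
  B
}

#' @export
fitted.pls_nipals <- function(object, ...) object$fitted.values

#' @export
residuals.pls_nipals <- function(object, ...) object$residuals

#' @export
print.pls_nipals <- function(x, ...) {
  cat(sprintf("Partial least squares regression (NIPALS), %d observations, %d predictors\n",
              x$n, x$p))
  cat(sprintf("Latent variables: %d%s\n", x$ncomp,
              if (x$ncomp < x$ncomp_requested)
                sprintf(" (requested %d; extraction stopped early)", x$ncomp_requested)
              else ""))
  invisible(x)
}

#' @export
summary.pls_nipals <- function(object, ...) {
  yc <- object$y - object$y_center
  tss <- sum(yc^2)
  r2 <- vapply(seq_len(object$ncomp), function(a) {
    res <- yc - (object$T[, seq_len(a), drop = FALSE] %*%
                   object$b[seq_len(a)])
    1 - sum(res^2) / tss
  }, numeric(1))
  out <- list(ncomp = object$ncomp, r2_cumulative = r2,
              rmse_train = sqrt(mean(object$residuals^2)))
  class(out) <- "summary.pls_nipals"
  out
}

#' @export
print.summary.pls_nipals <- function(x, ...) {
  cat("PLS fit summary\n")
  cat(sprintf("  latent variables: %d\n", x$ncomp))
  cat("  cumulative R2 by component:",
      paste(sprintf("%.4f", x$r2_cumulative), collapse = " "), "\n")
  cat(sprintf("  training RMSE: %.6g\n", x$rmse_train))
  invisible(x)
}

#' Choose the number of latent variables by cross-validated RMSEP
#'
#' Splits the rows into `k_folds` random folds (seeded, reproducible),
#' refits the PLS model on each training portion and accumulates squared
#' prediction errors on the held-out rows for every component count from 1
#' to `ncomp_max`. The root mean squared error of prediction (RMSEP) is
#' computed over all held-out points pooled; the selected `ncomp` is the
#' smallest count attaining the minimum RMSEP (ties break toward fewer
#' components).
#'
#' @param X,y predictors and response as in [pls_fit()].
#' @param k_folds number of cross-validation folds (default 10).
#' @param ncomp_max largest component count to evaluate. Default
#'   `min(n_train - 1, p, 30)`: RMSEP curves for relationship-augmented
#'   genomic designs flatten early, and the cap keeps tuning cheap.
#' @param seed integer seed for the fold partition.
#' @param scale passed to [pls_fit()].
#' @return list with `ncomp` (selected count), `rmsep` (the curve, one
#'   entry per component count) and `folds` (fold assignment used).
#' @export
select_ncomp <- function(X, y, k_folds = 10L, ncomp_max = NULL, seed = 1L,
                         scale = FALSE) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X)
  if (k_folds < 2L) stop("k_folds must be at least 2")
  if (k_folds > n) stop("more folds than observations")
  n_train_min <- n - ceiling(n / k_folds)
  if (is.null(ncomp_max)) ncomp_max <- min(n_train_min - 1L, ncol(X), 30L)
  if (ncomp_max < 1L) stop("ncomp_max must be at least 1")
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old_seed))
  set.seed(as.integer(seed))
  folds <- sample(rep_len(seq_len(k_folds), n))
  sse <- numeric(ncomp_max)
  for (k in seq_len(k_folds)) {
    test <- folds == k
    if (sum(!test) < 2L) stop("fold leaves fewer than 2 training rows")
    a_fit <- min(ncomp_max, sum(!test) - 1L, ncol(X))
    fit <- pls_fit(X[!test, , drop = FALSE], y[!test], ncomp = a_fit,
                   scale = scale)
    for (a in seq_len(ncomp_max)) {
      pred <- predict(fit, X[test, , drop = FALSE],
                      ncomp = min(a, fit$ncomp))
      sse[a] <- sse[a] + sum((y[test] - pred)^2)
    }
  }
  rmsep <- sqrt(sse / n)
  list(ncomp = which.min(rmsep), rmsep = rmsep, folds = folds)
}

restore_seed <- function(old_seed) {
  if (is.null(old_seed)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old_seed, envir = globalenv())
  }
}
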