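## The three predictors.
##
## KMER and KRR are the same dual-form ridge machine applied to different
## kernel matrices: KMER builds its kernel from MMD distances between
## spectra-as-distributions, KRR from Euclidean distances between bin-power
## feature vectors. RR is ordinary (primal) ridge regression on the bin
## powers. The outer RBF kernel maps a distance d to exp(-gamma d^2); for a
## Hilbertian metric (which the MMD is) this kernel matrix is positive
## semidefinite.

#' Outer RBF kernel on a distance matrix
#'
#' Converts subject-by-subject distances into similarities via
#' `K = exp(-gamma D^2)`. On a square zero-diagonal distance matrix the
#' result has unit diagonal and entries in (0, 1].
#'
#' @param D An `mmd_dist` object or a numeric (cross-)distance matrix with
#'   non-negative entries.
#' @param gamma Positive outer bandwidth.
#' @return Numeric kernel matrix with the dimnames of `D`.
#' @export
outer_kernel <- function(D, gamma = 1) {
  if (inherits(D, "mmd_dist")) D <- D$values
  if (gamma < 0) stop("gamma must be non-negative")
  if (any(D < 0)) stop("distances must be non-negative (clamp upstream)")
  exp(-gamma * D^2)
}

#' Fit dual-form (kernel) ridge regression
#'
#' Solves `(K + alpha I) beta = y - mean(y)` by a symmetric factorisation
#' (never an explicit inverse). Targets are mean-centered before the solve
#' and the mean is restored at prediction, which plays the role of an
#' unpenalised intercept.
#'
#' @param K Square `n x n` kernel matrix (training subjects).
#' @param y Numeric trait vector of length `n` (e.g. age in years).
#' @param alpha Ridge regularisation, `>= 0`.
#' @param kind Model label, `"kmer"` or `"krr"` (bookkeeping only).
#' @return A `dual_ridge` model: `beta`, `alpha`, `intercept`,
#'   `train_ids`, `kind`.
#' @export
fit_dual_ridge <- function(K, y, alpha, kind = "kmer") {
  K <- as.matrix(K)
  n <- nrow(K)
  if (ncol(K) != n) stop("K must be square")
  if (length(y) != n) stop("length(y) must match nrow(K)")
  if (alpha < 0) stop("alpha must be >= 0")
  intercept <- mean(y)
  yc <- y - intercept
  M <- K + diag(alpha, n)
  beta <- tryCatch(
    drop(chol2inv_solve(M, yc)),
    error = function(e) {
      if (alpha == 0)
        stop("kernel system is singular at alpha = 0; use alpha > 0",
             call. = FALSE)
      ## one shot of jitter, then a least-squares fallback
      beta <- tryCatch(drop(chol2inv_solve(M + diag(1e-10, n), yc)),
                       error = function(e2) NULL)
      if (is.null(beta)) beta <- drop(qr.solve(M, yc, tol = 1e-12))
      beta
    })
  structure(list(beta = beta, alpha = alpha, intercept = intercept,
                 train_ids = rownames(K), kind = kind),
            class = "dual_ridge")
}

## Cholesky solve of a symmetric system M x = b.
chol2inv_solve <- function(M, b) {
  R <- chol(M)
  backsolve(R, forwardsolve(t(R), b))
}

#' Predict from a dual ridge model
#'
#' `yhat_t = sum_i beta_i K_cross[t, i] + intercept`, where row `t` of
#' `K_cross` holds the kernel between test subject `t` and each training
#' subject, in the training order of the fitted model.
#'
#' @param model A `dual_ridge` from [fit_dual_ridge()].
#' @param K_cross `test x train` kernel block; when both it and the model
#'   carry training ids, the column order is checked.
#' @return Numeric vector of predictions.
#' @export
predict_dual <- function(model, K_cross) {
  K_cross <- rbind(K_cross)  # promote a single test row
  if (ncol(K_cross) != length(model$beta))
    stop("K_cross must have one column per training subject")
  if (!is.null(model$train_ids) && !is.null(colnames(K_cross)) &&
      !identical(colnames(K_cross), model$train_ids))
    stop("K_cross columns are not in the model's training-subject order")
  drop(K_cross %*% model$beta) + model$intercept
}

#' Fit linear ridge regression on bin-power features
#'
#' Minimises `||y - X w - b||^2 + alpha ||w||^2` with an unpenalised
#' intercept `b` (features and targets are centered internally). Solved in
#' closed form from the normal equations.
#'
#' @param X `subjects x bins` feature matrix.
#' @param y Trait vector.
#' @param alpha Ridge regularisation, `>= 0`.
#' @return A `linear_ridge` model: `coefficients`, `intercept`, `alpha`,
#'   `feature_means`.
#' @export
fit_rr <- function(X, y, alpha) {
  X <- as.matrix(X)
  if (anyNA(X) || anyNA(y)) stop("missing values are not allowed")
  if (nrow(X) != length(y)) stop("nrow(X) must match length(y)")
  if (alpha < 0) stop("alpha must be >= 0")
  mx <- colMeans(X)
  Xc <- sweep(X, 2L, mx)
  my <- mean(y)
  yc <- y - my
  A <- crossprod(Xc) + diag(alpha, ncol(X))
  w <- tryCatch(drop(chol2inv_solve(A, crossprod(Xc, yc))),
                error = function(e)
                  stop("normal equations are singular (collinear features ",
                       "at alpha = 0); use alpha > 0", call. = FALSE))
  structure(list(coefficients = w, intercept = my, alpha = alpha,
                 feature_means = mx),
            class = "linear_ridge")
}

#' @rdname fit_rr
#' @param model A `linear_ridge` model.
#' @return `predict_rr`: numeric vector of predictions.
#' @export
predict_rr <- function(model, X) {
  X <- if (is.null(dim(X))) matrix(X, nrow = 1L) else as.matrix(X)
  if (ncol(X) != length(model$coefficients))
    stop("feature dimension mismatch")
  drop(sweep(X, 2L, model$feature_means) %*% model$coefficients) +
    model$intercept
}

#' RBF kernel block on feature vectors (KRR)
#'
#' `K[a, b] = exp(-gamma ||x_a - x_b||^2)` on bin-power features; fitting
#' and prediction then reuse [fit_dual_ridge()] / [predict_dual()].
#'
#' @param X_a,X_b Feature matrices with equal column counts (`X_b` defaults
#'   to `X_a`).
#' @param gamma Non-negative bandwidth; `gamma = 0` degenerates to the
#'   all-ones kernel (predictions collapse to the target mean).
#' @return `nrow(X_a) x nrow(X_b)` kernel matrix.
#' @export
krr_kernel <- function(X_a, X_b = NULL, gamma = 1) {
  X_a <- as.matrix(X_a)
  X_b <- if (is.null(X_b)) X_a else as.matrix(X_b)
  if (ncol(X_a) != ncol(X_b)) stop("feature dimension mismatch")
  sq <- outer(rowSums(X_a^2), rowSums(X_b^2), "+") - 2 * tcrossprod(X_a, X_b)
  sq[sq < 0] <- 0
  K <- exp(-gamma * sq)
  dimnames(K) <- list(rownames(X_a), rownames(X_b))
  K
}

#' Save / load a fitted model as JSON
#'
#' Serialises a `dual_ridge` or `linear_ridge` model (weights at full
#' precision, kernel provenance, training ids) so a reloaded model
#' reproduces predictions bit-identically.
#'
#' @param model The fitted model.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_model <- function(model, path) {
  kind <- class(model)[1L]
  if (!kind %in% c("dual_ridge", "linear_ridge"))
    stop("unsupported model class: ", kind)
  jsonlite::write_json(c(list(model_class = kind), unclass(model)),
                       path, auto_unbox = TRUE, digits = I(17), null = "null")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  kind <- obj$model_class
  obj$model_class <- NULL
  structure(obj, class = kind)
}
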