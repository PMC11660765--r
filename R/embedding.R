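## Empirical maximum mean discrepancy (MMD) between unit-mass spectra.
##
## Each spectrum is a distribution over frequency; its kernel mean
## embedding is never materialised — only inner products of the inner
## kernel k(.,.) on frequency values enter, so every MMD reduces to a
## quadratic form in the bin weights:
##   MMD^2(P,Q) = w'Kw + v'Kv - 2 w'Kv,  K[a,b] = k(f_a, f_b).
## This is the biased V-statistic (self-pairs included), exactly as the
## empirical estimator is defined; an unbiased U-statistic variant is
## available for sample mode.

#' Inner kernel specification
#'
#' The kernel k(x, z) on frequency values (in raw Hz) used inside the MMD.
#'
#' @param family `"rbf"` (`exp(-gamma (x-z)^2)`), `"linear"` (`x z`) or
#'   `"polynomial"` (`(x z + coef0)^degree`).
#' @param gamma Positive bandwidth for the RBF family; default 1.
#' @param degree Positive integer degree (polynomial only).
#' @param coef0 Offset (polynomial only).
#' @return An object of class `inner_kernel_spec`.
#' @export
inner_kernel_spec <- function(family = c("rbf", "linear", "polynomial"),
                              gamma = 1, degree = 2L, coef0 = 1) {
  family <- match.arg(family)
  if (gamma <= 0) stop("gamma must be positive")
  degree <- as.integer(degree)
  if (degree < 1L) stop("degree must be >= 1")
  structure(list(family = family, gamma = gamma, degree = degree,
                 coef0 = coef0),
            class = "inner_kernel_spec")
}

#' Evaluate an inner kernel
#'
#' @param x,z Numeric vectors of frequencies in Hz (recycled elementwise).
#' @param spec An [inner_kernel_spec()].
#' @return Numeric vector of kernel values; symmetric in `(x, z)`.
#' @export
inner_kernel_eval <- function(x, z, spec = inner_kernel_spec()) {
  switch(spec$family,
         rbf = exp(-spec$gamma * (x - z)^2),
         linear = x * z,
         polynomial = (x * z + spec$coef0)^spec$degree)
}

## Gram matrix k(f_a, f_b) over two frequency supports.
inner_kernel_gram <- function(f1, f2, spec) {
  switch(spec$family,
         rbf = exp(-spec$gamma * outer(f1, f2, "-")^2),
         linear = outer(f1, f2),
         polynomial = (outer(f1, f2) + spec$coef0)^spec$degree)
}

#' Deterministic sampling of a unit-mass spectrum
#'
#' Converts a unit-mass spectrum into `n` samples at the bin-center
#' frequencies: a bin of height 0.2 receives 0.2 n samples. When `n w_i`
#' are not all integers, counts are apportioned by the largest-remainder
#' (Hamilton) rule — floor each `n w_i`, then hand the leftover samples to
#' the largest fractional remainders, ties broken toward lower frequency —
#' so the counts always sum to exactly `n`.
#'
#' @param spectrum A [channel_spectrum()] with unit total mass.
#' @param n Total number of samples (positive integer).
#' @return A `weighted_sample`: list with `support` (Hz), `counts` and
#'   `n_total`.
#' @examples
#' g <- frequency_grid(c(8, 10, 12))
#' s <- channel_spectrum(c(0.5, 0.2, 0.3), g)
#' deterministic_sample(s, 1000)$counts  # 500 200 300
#' @export
deterministic_sample <- function(spectrum, n) {
  if (!inherits(spectrum, "channel_spectrum"))
    stop("spectrum must be a channel_spectrum")
  if (length(n) != 1L || is.na(n) || n < 1)
    stop("n must be a positive integer")
  n <- as.integer(n)
  w <- spectrum$weights
  if (abs(sum(w) - 1) > 1e-9)
    stop("spectrum must be unit mass; call rescale_unit_mass() first")
  target <- n * w
  counts <- floor(target)
  short <- n - sum(counts)
  if (short > 0L) {
    rem <- target - counts
    ## ties toward lower frequency: order by remainder desc, frequency asc
    take <- order(-rem, spectrum$grid$bin_centers)[seq_len(short)]
    counts[take] <- counts[take] + 1L
  }
  structure(list(support = spectrum$grid$bin_centers,
                 counts = as.integer(counts), n_total = n),
            class = "weighted_sample")
}

#' Squared MMD between two deterministic samples
#'
#' The empirical squared maximum mean discrepancy between samples X (size
#' n) and Z (size m):
#' `1/n^2 sum k(x,x') + 1/m^2 sum k(z,z') - 2/(nm) sum k(x,z)`,
#' computed through count-weighted sums so the n*m pairs are never
#' materialised. The default is the biased V-statistic (diagonal self-pairs
#' included); `u_statistic = TRUE` removes the self-pairs from the
#' within-sample terms.
#'
#' @param P,Q `weighted_sample` objects from [deterministic_sample()].
#' @param spec An [inner_kernel_spec()].
#' @param u_statistic Use the unbiased U-statistic? Default `FALSE`.
#' @param clamp Clamp tiny negative results (roundoff, or U-statistic) to
#'   zero? Default `TRUE`.
#' @return Squared MMD (non-negative when clamped).
#' @export
mmd_squared_samples <- function(P, Q, spec = inner_kernel_spec(),
                                u_statistic = FALSE, clamp = TRUE) {
  for (s in list(P, Q))
    if (!inherits(s, "weighted_sample") || s$n_total < 1L)
      stop("P and Q must be non-empty weighted_sample objects")
  n <- P$n_total; m <- Q$n_total
  cp <- as.numeric(P$counts); cq <- as.numeric(Q$counts)
  Kpp <- inner_kernel_gram(P$support, P$support, spec)
  Kqq <- inner_kernel_gram(Q$support, Q$support, spec)
  Kpq <- inner_kernel_gram(P$support, Q$support, spec)
  spp <- drop(cp %*% Kpp %*% cp)
  sqq <- drop(cq %*% Kqq %*% cq)
  spq <- drop(cp %*% Kpq %*% cq)
  if (u_statistic) {
    if (n < 2L || m < 2L) stop("U-statistic needs at least 2 samples each")
    dp <- sum(cp * diag(Kpp)); dq <- sum(cq * diag(Kqq))
    out <- (spp - dp) / (n * (n - 1)) + (sqq - dq) / (m * (m - 1)) -
      2 * spq / (n * m)
  } else {
    out <- spp / n^2 + sqq / m^2 - 2 * spq / (n * m)
  }
  if (clamp && out < 0 && out > -1e-9) out <- 0
  out
}

#' Squared MMD between two spectra using exact bin weights
#'
#' The deterministic-sampling limit of [mmd_squared_samples()]: bin weights
#' stand in for sample proportions, giving
#' `w'Kw + v'Kv - 2 w'Kv` on the shared grid. Coincides exactly with
#' sample mode whenever `n w_i` and `m v_j` are all integers.
#'
#' @param P,Q [channel_spectrum()] objects on the same grid, unit mass.
#' @param spec An [inner_kernel_spec()].
#' @param clamp Clamp tiny negative roundoff to zero? Default `TRUE`.
#' @return Squared MMD.
#' @export
mmd_squared_weighted <- function(P, Q, spec = inner_kernel_spec(),
                                 clamp = TRUE) {
  for (s in list(P, Q)) {
    if (!inherits(s, "channel_spectrum")) stop("P and Q must be channel_spectrum")
    if (abs(sum(s$weights) - 1) > 1e-9) stop("spectra must be unit mass")
  }
  if (length(P$weights) != length(Q$weights) ||
      any(abs(P$grid$bin_centers - Q$grid$bin_centers) > GRID_ALIGN_TOL))
    stop("P and Q must share one frequency grid")
  K <- inner_kernel_gram(P$grid$bin_centers, P$grid$bin_centers, spec)
  d <- P$weights - Q$weights
  out <- drop(d %*% K %*% d)
  if (clamp && out < 0 && out > -1e-9) out <- 0
  out
}

#' Pairwise MMD distance matrix for one channel
#'
#' Computes `sqrt(max(0, MMD^2))` between every unordered pair of subjects'
#' spectra on one channel. `mode = "weighted"` (default) uses exact bin
#' weights; `mode = "samples"` first converts each spectrum to `n_samples`
#' deterministic samples, reproducing the sampling procedure literally.
#'
#' @param cohort An [eeg_cohort()] with unit-mass spectra.
#' @param channel Channel name.
#' @param spec An [inner_kernel_spec()].
#' @param mode `"weighted"` or `"samples"`.
#' @param n_samples Sample budget per spectrum in `"samples"` mode.
#' @param u_statistic Unbiased U-statistic (samples mode only).
#' @return An `mmd_dist` object: list with `values` (N x N symmetric,
#'   zero-diagonal matrix of distances), `subject_ids`, `channel`, `spec`,
#'   `mode`.
#' @export
mmd_distance_matrix <- function(cohort, channel, spec = inner_kernel_spec(),
                                mode = c("weighted", "samples"),
                                n_samples = 1000L, u_statistic = FALSE) {
  mode <- match.arg(mode)
  W <- cohort_spectra(cohort, channel)
  if (any(abs(rowSums(W) - 1) > 1e-9))
    stop("spectra must be unit mass; call rescale_cohort() first")
  f <- cohort$grid$bin_centers
  if (mode == "samples") {
    C <- t(vapply(seq_len(nrow(W)), function(i)
      as.numeric(deterministic_sample(
        channel_spectrum(W[i, ], cohort$grid), n_samples)$counts),
      numeric(length(f))))
    A <- C / n_samples
  } else {
    if (u_statistic)
      stop("u_statistic applies to samples mode only")
    A <- W
  }
  K <- inner_kernel_gram(f, f, spec)
  G <- A %*% K %*% t(A)
  g <- diag(G)
  d2 <- outer(g, g, "+") - 2 * G
  if (mode == "samples" && u_statistic) {
    n <- n_samples
    S <- drop((A * n) %*% diag(K))       # per-subject sum of self-kernels
    uii <- (n^2 * g - S) / (n * (n - 1)) # unbiased within-sample terms
    d2 <- outer(uii, uii, "+") - 2 * G
  }
  d2[d2 < 0] <- 0
  D <- sqrt(d2)
  D <- (D + t(D)) / 2
  diag(D) <- 0
  ids <- rownames(W)
  dimnames(D) <- list(ids, ids)
  structure(list(values = D, subject_ids = ids, channel = channel,
                 spec = spec, mode = mode,
                 n_samples = if (mode == "samples") n_samples else NULL,
                 u_statistic = u_statistic),
            class = "mmd_dist")
}

#' Pairwise Euclidean distance matrix on bin-power features
#'
#' Plain Euclidean distances between subjects' bin-weight vectors. Feeding
#' these into the same outer kernel / dual ridge pipeline reproduces kernel
#' ridge regression exactly, which is the pipeline-equivalence check used
#' in the tests.
#'
#' @param X `subjects x bins` feature matrix.
#' @param channel Channel label to record.
#' @return An `mmd_dist`-shaped object with `mode = "euclidean"`.
#' @export
euclidean_distance_matrix <- function(X, channel = "features") {
  D <- as.matrix(stats::dist(X))
  ids <- rownames(X)
  dimnames(D) <- list(ids, ids)
  structure(list(values = D, subject_ids = ids, channel = channel,
                 spec = NULL, mode = "euclidean", n_samples = NULL,
                 u_statistic = FALSE),
            class = "mmd_dist")
}

#' @export
print.mmd_dist <- function(x, ...) {
  cat(sprintf("distance matrix: %d x %d, channel %s, mode %s\n",
              nrow(x$values), ncol(x$values), x$channel, x$mode))
  invisible(x)
}

#' Write / read a distance matrix as CSV
#'
#' CSV layout: header `subject_id,<id1>,<id2>,...`; one row per subject. A
#' JSON sidecar (`<path>.json`) records the channel, mode and inner kernel
#' spec.
#'
#' @param d An `mmd_dist` object.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_distance_matrix <- function(d, path) {
  ids <- d$subject_ids
  header <- paste(c("subject_id", ids), collapse = ",")
  body <- vapply(seq_along(ids), function(i)
    paste(c(ids[i], fmt_num(d$values[i, ])), collapse = ","), "")
  writeLines(c(header, body), path)
  side <- list(channel = d$channel, mode = d$mode,
               n_samples = d$n_samples, u_statistic = d$u_statistic,
               spec = if (!is.null(d$spec)) unclass(d$spec))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = I(17), null = "null")
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = c(subject_id = "character"))
  ids <- df$subject_id
  D <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(D) <- "double"
  dimnames(D) <- list(ids, ids)
  side_path <- paste0(path, ".json")
  side <- if (file.exists(side_path))
    jsonlite::read_json(side_path, simplifyVector = TRUE) else list()
  spec <- side$spec
  if (!is.null(spec))
    spec <- inner_kernel_spec(spec$family, spec$gamma, spec$degree, spec$coef0)
  structure(list(values = D, subject_ids = ids,
                 channel = side$channel %||% NA_character_,
                 spec = spec, mode = side$mode %||% "weighted",
                 n_samples = side$n_samples,
                 u_statistic = isTRUE(side$u_statistic)),
            class = "mmd_dist")
}

## In-memory distance cache keyed by content: spectra bytes + kernel spec +
## mode. Used to skip recomputation across CV folds and CLI reruns.
.dist_cache <- new.env(parent = emptyenv())

dist_cache_key <- function(cohort, channel, spec, mode, n_samples, u_statistic) {
  W <- cohort_spectra(cohort, channel)
  payload <- list(W, cohort$grid$bin_centers, unclass(spec),
                  mode, n_samples, u_statistic)
  paste(channel, rlang::hash(payload), sep = "|")
}

#' Distance matrix with content-addressed caching
#'
#' Wraps [mmd_distance_matrix()] with an in-memory cache keyed by the
#' spectra content, kernel spec and mode, so repeated requests (e.g. across
#' cross-validation folds or CLI reruns) are served without recomputation.
#'
#' @inheritParams mmd_distance_matrix
#' @param verbose Report cache hits via `message()`?
#' @return An `mmd_dist` object; attribute `"cache_hit"` says whether it
#'   came from the cache.
#' @export
cached_distance_matrix <- function(cohort, channel, spec = inner_kernel_spec(),
                                   mode = c("weighted", "samples"),
                                   n_samples = 1000L, u_statistic = FALSE,
                                   verbose = FALSE) {
  mode <- match.arg(mode)
  key <- dist_cache_key(cohort, channel, spec, mode, n_samples, u_statistic)
  if (!is.null(.dist_cache[[key]])) {
    if (verbose) message("distance cache hit: channel ", channel)
    out <- .dist_cache[[key]]
    attr(out, "cache_hit") <- TRUE
    return(out)
  }
  out <- mmd_distance_matrix(cohort, channel, spec, mode, n_samples,
                             u_statistic)
  .dist_cache[[key]] <- out
  attr(out, "cache_hit") <- FALSE
  out
}

#' Empty the in-memory distance cache
#' @return Invisibly, the number of entries removed.
#' @export
clear_distance_cache <- function() {
  n <- length(ls(.dist_cache))
  rm(list = ls(.dist_cache), envir = .dist_cache)
  invisible(n)
}
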