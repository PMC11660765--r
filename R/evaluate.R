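## Site-grouped evaluation protocol.
##
## Acquisition sites (batches) are never split across cross-validation
## folds: predicting a site's subjects uses no training data from that
## site. Hyperparameters are chosen by nested cross-validation whose inner
## folds are built from the outer-training sites only, so model selection
## never touches outer test data. Scores are pooled over all out-of-sample
## predictions; per-fold breakdowns are also kept.

#' Build a cross-validation fold plan that never splits sites
#'
#' @param cohort An [eeg_cohort()].
#' @param mode `"leave-site-out"` (one fold per site, the default
#'   protocol), `"grouped-k-fold"` (whole sites assigned to `k` folds,
#'   greedily balancing subject counts: largest site first into the
#'   currently smallest fold) or `"within-site-k-fold"` (subject-level
#'   k-fold inside a single site).
#' @param k Number of folds for the k-fold modes.
#' @param seed Seed for the within-site shuffle.
#' @param site Site name for `"within-site-k-fold"`; may be omitted for a
#'   single-site cohort.
#' @return A `fold_plan`: list of folds, each with `train_idx`, `test_idx`
#'   (row indices into the cohort) and, for grouped modes, `train_sites` /
#'   `test_sites`.
#' @export
make_site_folds <- function(cohort,
                            mode = c("leave-site-out", "grouped-k-fold",
                                     "within-site-k-fold"),
                            k = 5L, seed = 1L, site = NULL) {
  mode <- match.arg(mode)
  sites <- cohort$meta$site
  site_names <- sort(unique(sites))
  folds <- list()
  if (mode == "leave-site-out") {
    if (length(site_names) < 2L)
      stop("leave-site-out needs at least 2 sites")
    folds <- lapply(site_names, function(s) {
      list(test_idx = which(sites == s), train_idx = which(sites != s),
           test_sites = s, train_sites = setdiff(site_names, s))
    })
  } else if (mode == "grouped-k-fold") {
    if (length(site_names) < 2L)
      stop("grouped folds need at least 2 sites")
    if (k > length(site_names))
      stop("k = ", k, " exceeds the number of sites (", length(site_names), ")")
    counts <- table(sites)[site_names]
    ord <- order(-as.integer(counts), site_names)  # largest first, name ties
    assign <- integer(length(site_names))
    load <- numeric(k)
    for (i in ord) {
      f <- which.min(load)
      assign[i] <- f
      load[f] <- load[f] + counts[[i]]
    }
    folds <- lapply(seq_len(k), function(f) {
      ts <- site_names[assign == f]
      list(test_idx = which(sites %in% ts),
           train_idx = which(!sites %in% ts),
           test_sites = ts, train_sites = setdiff(site_names, ts))
    })
  } else {
    if (is.null(site)) {
      if (length(site_names) != 1L)
        stop("within-site-k-fold needs `site` when the cohort has several")
      site <- site_names
    }
    idx <- which(sites == site)
    if (length(idx) < k) stop("site ", site, " has fewer subjects than k")
    ## shuffle sorted ids so the plan is invariant to cohort row order
    ids <- cohort$meta$subject_id[idx]
    idx <- idx[order(ids)]
    perm <- with_seed(seed, sample(length(idx)))
    membership <- rep_len(seq_len(k), length(idx))[order(perm)]
    folds <- lapply(seq_len(k), function(f) {
      list(test_idx = idx[membership == f], train_idx = idx[membership != f],
           test_sites = site, train_sites = site)
    })
  }
  structure(list(folds = folds, mode = mode, k = k, seed = seed,
                 site = site %||% NA_character_, n = n_subjects(cohort)),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("fold_plan: %s, %d folds over %d subjects\n",
              x$mode, length(x$folds), x$n))
  invisible(x)
}

#' Prediction scores
#'
#' Explained variance `R^2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)`
#' and mean absolute error.
#'
#' @param y True trait values (length >= 2).
#' @param yhat Predictions, same length.
#' @return List with `r2`, `mae` and `n`. When `y` has zero variance,
#'   `r2` is `NA` with a warning.
#' @export
score <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("y and yhat lengths differ")
  if (length(y) < 2L) stop("need at least 2 observations to score")
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot <= 0) {
    warning("y has zero variance; R^2 undefined")
    NA_real_
  } else 1 - sum((y - yhat)^2) / ss_tot
  list(r2 = r2, mae = mean(abs(y - yhat)), n = length(y))
}

#' Brain-age delta
#'
#' The signed difference between predicted and chronological trait value,
#' `delta_i = yhat_i - y_i` (positive: older-appearing than chronological).
#'
#' @param y,yhat Equal-length numeric vectors.
#' @return Numeric vector of deltas.
#' @export
compute_delta <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("y and yhat lengths differ")
  yhat - y
}

#' Summarise deltas by group
#'
#' @param delta Numeric deltas from [compute_delta()].
#' @param groups Grouping labels (e.g. site or sex), same length.
#' @return Data frame with per-group n, mean, sd and quartiles.
#' @export
delta_summary <- function(delta, groups) {
  if (length(delta) != length(groups)) stop("length mismatch")
  gs <- sort(unique(as.character(groups)))
  out <- lapply(gs, function(g) {
    d <- delta[groups == g]
    q <- stats::quantile(d, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(group = g, n = length(d), mean = mean(d),
               sd = stats::sd(d), q25 = q[1L], q50 = q[2L], q75 = q[3L])
  })
  do.call(rbind, out)
}

#' Post-hoc bias correction of trait predictions
#'
#' Brain-age predictions systematically under-predict older ages. The
#' correction regresses the training residual `r = y - yhat` on the
#' chronological trait (`r = a + b y`) and adds the fitted trend back into
#' the test predictions: `yhat' = yhat + a + b y_test`. This uses the test
#' subject's chronological age, which is legitimate for delta analyses (it
#' orthogonalises residual and age) but makes the corrected value a
#' corrected *delta*, not a blind prediction.
#'
#' @param train_y,train_yhat Training trait values and predictions
#'   (length >= 3; `train_y` must not be constant).
#' @param test_y,test_yhat Test trait values and predictions.
#' @return Corrected test predictions.
#' @export
bias_correct <- function(train_y, train_yhat, test_y, test_yhat) {
  if (length(train_y) != length(train_yhat) ||
      length(test_y) != length(test_yhat))
    stop("paired vectors must have equal lengths")
  if (length(train_y) < 3L) stop("need at least 3 training subjects")
  vy <- stats::var(train_y)
  if (!is.finite(vy) || vy <= 0) stop("training trait is constant")
  r <- train_y - train_yhat
  b <- stats::cov(train_y, r) / vy
  a <- mean(r) - b * mean(train_y)
  test_yhat + a + b * test_y
}

#' Paired sign-flip permutation test
#'
#' Tests whether paired scores differ (e.g. per-channel accuracies of two
#' methods, or male vs female per-channel scores). The statistic is the
#' mean paired difference; the null is built by independent sign flips of
#' the differences (channels being the paired units), and
#' `p = (1 + #{|T_perm| >= |T_obs|}) / (1 + n_perm)`, two-sided.
#'
#' @param scores_a,scores_b Equal-length paired score vectors.
#' @param n_perm Number of permutations (>= 100).
#' @param seed RNG seed; results are deterministic given the seed.
#' @return A `perm_test`: `statistic`, `n_perm`, `p_value`, `seed`.
#' @export
permutation_test_paired <- function(scores_a, scores_b, n_perm = 10000L,
                                    seed = 1L) {
  if (length(scores_a) != length(scores_b))
    stop("paired score vectors must have equal length")
  if (n_perm < 100L) stop("n_perm must be at least 100")
  d <- scores_a - scores_b
  C <- length(d)
  t_obs <- mean(d)
  signs <- with_seed(seed,
    matrix(sample(c(-1, 1), n_perm * C, replace = TRUE), nrow = n_perm))
  t_perm <- drop(signs %*% d) / C
  p <- (1 + sum(abs(t_perm) >= abs(t_obs) - 1e-12)) / (1 + n_perm)
  structure(list(statistic = t_obs, n_perm = as.integer(n_perm),
                 p_value = p, seed = seed),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("paired sign-flip permutation test: T = %.4g, p = %.4g (%d perms)\n",
              x$statistic, x$p_value, x$n_perm))
  invisible(x)
}

default_eval_options <- function(options = list()) {
  defaults <- list(inner_k = 5L, log_space = FALSE, bias_correct = FALSE,
                   normalize_bins = FALSE,
                   inner_kernel = inner_kernel_spec(),
                   mode = "weighted", n_samples = 1000L,
                   u_statistic = FALSE, distance = "mmd",
                   gamma_scale = "median", seed = 1L, verbose = FALSE)
  defaults[names(options)] <- options
  defaults
}

#' Default hyperparameter grids
#'
#' Decade-spaced ridge penalties and outer-kernel bandwidths. Bandwidths
#' are relative: by default they are rescaled per training fold by the
#' median squared training distance (the median heuristic), so one grid
#' serves distance matrices of any scale.
#'
#' @return List with `alpha` (7 points, 1e-3..1e3) and `gamma` (6 points,
#'   1e-3..1e2).
#' @export
default_grids <- function() {
  list(alpha = 10^seq(-3, 3), gamma = 10^seq(-3, 2))
}

## Inner folds over the outer-training subjects, honouring the grouping
## rule of the outer plan; falls back to subject-level k-fold (with a
## warning) when fewer than 2 training sites remain.
build_inner_folds <- function(meta, train_idx, outer_mode, inner_k, seed) {
  sites <- meta$site[train_idx]
  site_names <- sort(unique(sites))
  grouped <- outer_mode %in% c("leave-site-out", "grouped-k-fold")
  if (grouped && length(site_names) >= 2L) {
    if (outer_mode == "leave-site-out") {
      return(lapply(site_names, function(s) {
        list(test = train_idx[sites == s], train = train_idx[sites != s])
      }))
    }
    k <- min(inner_k, length(site_names))
    counts <- table(sites)[site_names]
    ord <- order(-as.integer(counts), site_names)
    assign <- integer(length(site_names)); load <- numeric(k)
    for (i in ord) {
      f <- which.min(load); assign[i] <- f; load[f] <- load[f] + counts[[i]]
    }
    return(lapply(seq_len(k), function(f) {
      ts <- site_names[assign == f]
      list(test = train_idx[sites %in% ts],
           train = train_idx[!sites %in% ts])
    }))
  }
  if (grouped)
    warning("fewer than 2 training sites; inner selection falls back to ",
            "subject-level ", inner_k, "-fold")
  ids <- meta$subject_id[train_idx]
  o <- order(ids)
  idx <- train_idx[o]
  perm <- with_seed(seed, sample(length(idx)))
  k <- min(inner_k, length(idx))
  membership <- rep_len(seq_len(k), length(idx))[order(perm)]
  lapply(seq_len(k), function(f) {
    list(test = idx[membership == f], train = idx[membership != f])
  })
}

## Median heuristic: robust scale of a squared-distance matrix restricted
## to the training block (off-diagonal entries only).
median_sq_distance <- function(D, idx) {
  d <- D[idx, idx]
  v <- d[upper.tri(d)]^2
  m <- stats::median(v[v > 0])
  if (!is.finite(m) || m <= 0) 1 else m
}

#' Nested site-grouped cross-validated prediction
#'
#' Runs one prediction method on one channel under a site-grouped fold
#' plan. For each outer fold, hyperparameters are selected on inner folds
#' built from the outer-training sites only (minimum inner mean MAE in
#' years; ties prefer smaller alpha, then smaller gamma), the winner is
#' refit on the full outer-training set and applied once to the outer test
#' set, so every subject receives exactly one out-of-sample prediction.
#'
#' @param cohort An [eeg_cohort()] with unit-mass spectra and recorded ages.
#' @param channel Channel to analyse.
#' @param method `"kmer"` (outer RBF kernel on MMD distances between
#'   spectra-as-distributions), `"krr"` (outer RBF kernel on Euclidean
#'   bin-power distances) or `"rr"` (linear ridge on bin powers).
#' @param fold_plan A [make_site_folds()] plan.
#' @param grids Hyperparameter grids, see [default_grids()]. `rr` uses
#'   `alpha` only.
#' @param options Named list overriding: `inner_k` (5), `log_space`
#'   (`FALSE`; train on log(age), exponentiate predictions back),
#'   `bias_correct` (`FALSE`; post-hoc residual-on-age correction),
#'   `normalize_bins` (`FALSE`; per-bin unit variance from training
#'   subjects, feature methods only), `inner_kernel`
#'   ([inner_kernel_spec()]), `mode` (`"weighted"`/`"samples"`),
#'   `n_samples` (1000), `u_statistic` (`FALSE`), `distance`
#'   (`"mmd"`/`"euclidean"`, KMER only), `gamma_scale`
#'   (`"median"`/`"none"`), `seed`, `verbose`.
#' @return A `kmer_eval` object: `predictions` (one row per subject: age,
#'   prediction, corrected prediction when requested, delta, fold, site,
#'   sex), pooled `metrics`, per-fold `fold_summary` with the selected
#'   hyperparameters, and the options used.
#' @export
nested_cv_fit_predict <- function(cohort, channel,
                                  method = c("kmer", "krr", "rr"),
                                  fold_plan, grids = default_grids(),
                                  options = list()) {
  method <- match.arg(method)
  opt <- default_eval_options(options)
  meta <- cohort$meta
  if (anyNA(meta$age)) stop("all subjects must have a recorded age")
  y <- meta$age
  if (opt$log_space && any(y <= 0))
    stop("log-space prediction needs strictly positive ages")
  y_fit_all <- if (opt$log_space) log(y) else y
  if (!length(grids$alpha)) stop("alpha grid is empty")
  if (method != "rr" && !length(grids$gamma)) stop("gamma grid is empty")

  W <- cohort_spectra(cohort, channel)
  kernelised <- method %in% c("kmer", "krr")

  ## full pairwise distances, computed once when fold-independent
  D_full <- NULL
  if (method == "kmer") {
    D_full <- if (identical(opt$distance, "euclidean"))
      euclidean_distance_matrix(W, channel)$values
    else
      cached_distance_matrix(cohort, channel, opt$inner_kernel,
                             mode = opt$mode, n_samples = opt$n_samples,
                             u_statistic = opt$u_statistic,
                             verbose = opt$verbose)$values
  } else if (method == "krr" && !opt$normalize_bins) {
    D_full <- euclidean_distance_matrix(W, channel)$values
  }

  back <- if (opt$log_space) exp else identity
  preds <- rep(NA_real_, nrow(meta))
  preds_corr <- if (opt$bias_correct) rep(NA_real_, nrow(meta)) else NULL
  fold_rows <- list()
  fold_of <- rep(NA_integer_, nrow(meta))

  for (fi in seq_along(fold_plan$folds)) {
    fold <- fold_plan$folds[[fi]]
    tr <- fold$train_idx; te <- fold$test_idx
    fold_of[te] <- fi

    if (method == "rr") {
      Xf <- W
      if (opt$normalize_bins) {
        sc <- apply(W[tr, , drop = FALSE], 2L, stats::sd)
        sc[!is.finite(sc) | sc <= 0] <- 1
        Xf <- sweep(W, 2L, sc, "/")
      }
      D <- NULL
    } else {
      if (method == "krr" && opt$normalize_bins) {
        sc <- apply(W[tr, , drop = FALSE], 2L, stats::sd)
        sc[!is.finite(sc) | sc <= 0] <- 1
        D <- euclidean_distance_matrix(sweep(W, 2L, sc, "/"), channel)$values
      } else D <- D_full
      Xf <- NULL
    }

    gamma_eff <- if (kernelised) {
      g <- grids$gamma
      if (identical(opt$gamma_scale, "median"))
        g / median_sq_distance(D, tr)
      else g
    } else NA_real_

    inner <- build_inner_folds(meta, tr, fold_plan$mode, opt$inner_k,
                               derive_seed(opt$seed, fi))

    ## grid of candidate settings, ordered so ties resolve to smaller
    ## alpha, then smaller gamma
    combos <- if (kernelised)
      expand.grid(ai = seq_along(grids$alpha), gi = seq_along(grids$gamma))
    else data.frame(ai = seq_along(grids$alpha), gi = NA_integer_)
    combos <- combos[order(combos$ai, combos$gi), , drop = FALSE]
    mae_sum <- numeric(nrow(combos))

    for (inn in inner) {
      itr <- inn$train; ite <- inn$test
      if (kernelised) {
        for (gi in unique(combos$gi)) {
          Ktr <- exp(-gamma_eff[gi] * D[itr, itr, drop = FALSE]^2)
          Kte <- exp(-gamma_eff[gi] * D[ite, itr, drop = FALSE]^2)
          rows <- which(combos$gi == gi)
          for (r in rows) {
            fit <- fit_dual_ridge(Ktr, y_fit_all[itr],
                                  grids$alpha[combos$ai[r]], kind = method)
            yh <- back(predict_dual(fit, Kte))
            mae_sum[r] <- mae_sum[r] + mean(abs(y[ite] - yh))
          }
        }
      } else {
        for (r in seq_len(nrow(combos))) {
          fit <- fit_rr(Xf[itr, , drop = FALSE], y_fit_all[itr],
                        grids$alpha[combos$ai[r]])
          yh <- back(predict_rr(fit, Xf[ite, , drop = FALSE]))
          mae_sum[r] <- mae_sum[r] + mean(abs(y[ite] - yh))
        }
      }
    }
    best <- which.min(mae_sum)  # first minimum = smallest alpha, then gamma
    ai <- combos$ai[best]; gi <- combos$gi[best]

    if (kernelised) {
      Ktr <- exp(-gamma_eff[gi] * D[tr, tr, drop = FALSE]^2)
      Kte <- exp(-gamma_eff[gi] * D[te, tr, drop = FALSE]^2)
      fit <- fit_dual_ridge(Ktr, y_fit_all[tr], grids$alpha[ai], kind = method)
      yh_te <- back(predict_dual(fit, Kte))
      yh_tr <- back(predict_dual(fit, Ktr))
    } else {
      fit <- fit_rr(Xf[tr, , drop = FALSE], y_fit_all[tr], grids$alpha[ai])
      yh_te <- back(predict_rr(fit, Xf[te, , drop = FALSE]))
      yh_tr <- back(predict_rr(fit, Xf[tr, , drop = FALSE]))
    }
    preds[te] <- yh_te
    if (opt$bias_correct)
      preds_corr[te] <- bias_correct(y[tr], yh_tr, y[te], yh_te)

    fold_rows[[fi]] <- data.frame(
      fold = fi,
      test_sites = paste(fold$test_sites, collapse = "+"),
      n_test = length(te),
      alpha = grids$alpha[ai],
      gamma = if (kernelised) gamma_eff[gi] else NA_real_,
      gamma_grid = if (kernelised) grids$gamma[gi] else NA_real_,
      test_mae = mean(abs(y[te] - yh_te)))
  }

  tested <- which(!is.na(fold_of))
  predictions <- data.frame(
    subject_id = meta$subject_id[tested],
    site = meta$site[tested], sex = meta$sex[tested],
    age = y[tested], y_pred = preds[tested],
    fold = fold_of[tested], method = method, channel = channel,
    stringsAsFactors = FALSE)
  predictions$delta <- compute_delta(predictions$age, predictions$y_pred)
  if (opt$bias_correct) {
    predictions$y_pred_corrected <- preds_corr[tested]
    predictions$delta_corrected <-
      compute_delta(predictions$age, predictions$y_pred_corrected)
  }

  metrics <- score(predictions$age, predictions$y_pred)
  if (opt$bias_correct)
    metrics$corrected <- score(predictions$age, predictions$y_pred_corrected)
  if (opt$log_space)
    metrics$log_domain <- score(log(predictions$age),
                                log(pmax(predictions$y_pred, 1e-12)))

  structure(list(predictions = predictions, metrics = metrics,
                 fold_summary = do.call(rbind, fold_rows),
                 channel = channel, method = method,
                 options = opt, grids = grids, mode = fold_plan$mode),
            class = "kmer_eval")
}

#' @export
print.kmer_eval <- function(x, ...) {
  cat(sprintf("%s on channel %s (%s): R^2 = %.3f, MAE = %.2f over %d subjects\n",
              toupper(x$method), x$channel, x$mode,
              x$metrics$r2, x$metrics$mae, x$metrics$n))
  if (!is.null(x$metrics$corrected))
    cat(sprintf("  bias-corrected: R^2 = %.3f, MAE = %.2f\n",
                x$metrics$corrected$r2, x$metrics$corrected$mae))
  invisible(x)
}

#' Recompute scores within subgroups
#'
#' Splits the out-of-sample predictions of a [nested_cv_fit_predict()]
#' result by sex or site and rescores each group. Nothing is refit: the
#' same predictions are sliced. Groups with fewer than 3 subjects are
#' skipped with a warning.
#'
#' @param result A `kmer_eval` object.
#' @param grouping `"sex"` or `"site"`.
#' @param corrected Score the bias-corrected predictions instead?
#' @return Data frame with one row per retained group: `group`, `n`, `r2`,
#'   `mae`.
#' @export
subgroup_eval <- function(result, grouping = c("sex", "site"),
                          corrected = FALSE) {
  grouping <- match.arg(grouping)
  preds <- result$predictions
  yhat <- if (corrected) {
    if (is.null(preds$y_pred_corrected))
      stop("no bias-corrected predictions in this result")
    preds$y_pred_corrected
  } else preds$y_pred
  labels <- preds[[grouping]]
  out <- list()
  for (g in sort(unique(labels))) {
    sel <- labels == g
    if (sum(sel) < 3L) {
      warning("group ", g, " has fewer than 3 subjects; skipped")
      next
    }
    s <- score(preds$age[sel], yhat[sel])
    out[[g]] <- data.frame(group = g, n = s$n, r2 = s$r2, mae = s$mae,
                           stringsAsFactors = FALSE)
  }
  if (!length(out)) stop("no group has at least 3 subjects")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Run several methods over several channels
#'
#' Convenience loop over [nested_cv_fit_predict()].
#'
#' @inheritParams nested_cv_fit_predict
#' @param channels Channels to analyse (default: all in the cohort).
#' @param methods Methods to run.
#' @return A `kmer_eval_set`: named list of `kmer_eval` results
#'   (`<channel>.<method>`) plus a `summary` data frame of per-channel,
#'   per-method pooled scores.
#' @export
evaluate_channels <- function(cohort, channels = NULL,
                              methods = c("kmer", "krr", "rr"),
                              fold_plan, grids = default_grids(),
                              options = list()) {
  channels <- channels %||% cohort$channels
  results <- list()
  rows <- list()
  for (ch in channels) {
    for (m in methods) {
      r <- nested_cv_fit_predict(cohort, ch, m, fold_plan, grids, options)
      key <- paste(ch, m, sep = ".")
      results[[key]] <- r
      rows[[key]] <- data.frame(
        channel = ch, method = m, r2 = r$metrics$r2, mae = r$metrics$mae,
        r2_corrected = r$metrics$corrected$r2 %||% NA_real_,
        mae_corrected = r$metrics$corrected$mae %||% NA_real_,
        n = r$metrics$n, stringsAsFactors = FALSE)
    }
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  structure(list(results = results, summary = summary),
            class = "kmer_eval_set")
}

#' Write evaluation results to disk
#'
#' Emits the tidy per-subject predictions (`predictions.csv`: one row per
#' subject x channel x method) and a versioned JSON summary of per-channel
#' scores (`summary.json`).
#'
#' @param eval_set A `kmer_eval_set` from [evaluate_channels()].
#' @param dir Output directory (created if missing).
#' @param extra Named list merged into the JSON summary (e.g. seed, grids).
#' @return Invisibly, the two paths.
#' @export
write_eval_results <- function(eval_set, dir, extra = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  preds <- do.call(rbind, lapply(eval_set$results, function(r) {
    p <- r$predictions
    if (is.null(p$y_pred_corrected)) {
      p$y_pred_corrected <- NA_real_
      p$delta_corrected <- NA_real_
    }
    p
  }))
  rownames(preds) <- NULL
  cols <- c("subject_id", "channel", "method", "site", "sex", "age",
            "y_pred", "y_pred_corrected", "delta", "delta_corrected", "fold")
  preds <- preds[, cols]
  pred_path <- file.path(dir, "predictions.csv")
  num <- vapply(preds, is.numeric, TRUE)
  body <- do.call(paste, c(lapply(seq_along(preds), function(j)
    if (num[j]) fmt_num(preds[[j]]) else as.character(preds[[j]])),
    sep = ","))
  writeLines(c(paste(cols, collapse = ","), body), pred_path)
  summary_path <- file.path(dir, "summary.json")
  jsonlite::write_json(
    c(list(schema_version = 1L, scores = eval_set$summary), extra),
    summary_path, auto_unbox = TRUE, digits = NA, null = "null",
    dataframe = "rows")
  invisible(list(predictions = pred_path, summary = summary_path))
}
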