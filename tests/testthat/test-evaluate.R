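test_that("leave-site-out folds hold out exactly one whole site each", {
  co <- toy_cohort(n = 15L, sites = c("a", "b", "c"))
  plan <- make_site_folds(co, "leave-site-out")
  expect_equal(length(plan$folds), 3L)
  all_test <- integer(0)
  for (fold in plan$folds) {
    expect_length(fold$test_sites, 1L)
    expect_setequal(unique(co$meta$site[fold$test_idx]), fold$test_sites)
    expect_false(fold$test_sites %in% co$meta$site[fold$train_idx])
    expect_length(intersect(fold$train_idx, fold$test_idx), 0L)
    all_test <- c(all_test, fold$test_idx)
  }
  expect_setequal(all_test, seq_len(15L))

  single <- toy_cohort(n = 6L, sites = "solo")
  expect_error(make_site_folds(single, "leave-site-out"), "at least 2 sites")
})

test_that("grouped k-fold assigns whole sites and balances subject counts", {
  sites <- rep(c("s1", "s2", "s3", "s4", "s5"), times = c(5, 4, 3, 2, 1))
  co <- toy_cohort(n = 15L, sites = "x")
  co$meta$site <- sites
  plan <- make_site_folds(co, "grouped-k-fold", k = 2L)
  expect_equal(length(plan$folds), 2L)
  test_site_sets <- lapply(plan$folds, `[[`, "test_sites")
  expect_setequal(unlist(test_site_sets), paste0("s", 1:5))
  expect_equal(sum(lengths(lapply(plan$folds, `[[`, "test_idx"))), 15L)
  # greedy balancing: 15 subjects over 2 folds can split no better than 8/7
  sizes <- sort(lengths(lapply(plan$folds, `[[`, "test_idx")))
  expect_equal(sizes, c(7L, 8L))
  expect_error(make_site_folds(co, "grouped-k-fold", k = 9L), "exceeds")
})

test_that("within-site k-fold partitions one site, invariant to row order", {
  co <- toy_cohort(n = 23L, sites = "solo")
  plan <- make_site_folds(co, "within-site-k-fold", k = 5L, seed = 3L)
  sizes <- lengths(lapply(plan$folds, `[[`, "test_idx"))
  expect_equal(sum(sizes), 23L)
  expect_lte(diff(range(sizes)), 1L)
  expect_setequal(unlist(lapply(plan$folds, `[[`, "test_idx")), 1:23)

  # same subjects land in the same folds after shuffling cohort rows
  p <- with(list(), {set.seed(8); sample(23)})
  co2 <- eeg_cohort(transform(co$meta[p, ]),
                    lapply(co$spectra, function(m) m[p, ]), co$grid)
  plan2 <- make_site_folds(co2, "within-site-k-fold", k = 5L, seed = 3L)
  ids1 <- lapply(plan$folds, function(f) sort(co$meta$subject_id[f$test_idx]))
  ids2 <- lapply(plan2$folds, function(f) sort(co2$meta$subject_id[f$test_idx]))
  expect_identical(ids1, ids2)

  expect_error(make_site_folds(toy_cohort(n = 4L, sites = "solo"),
                               "within-site-k-fold", k = 5L), "fewer subjects")
  expect_error(make_site_folds(co2, "within-site-k-fold", k = 2L,
                               site = "nowhere"), "fewer subjects|nowhere")
})

test_that("score reports R^2 and MAE with edge cases handled", {
  s <- score(c(1, 2, 3), c(1, 2, 3))
  expect_equal(s$r2, 1); expect_equal(s$mae, 0); expect_equal(s$n, 3L)
  s2 <- score(c(0, 10), c(5, 5))
  expect_equal(s2$r2, 0); expect_equal(s2$mae, 5)
  expect_warning(s3 <- score(c(2, 2, 2), c(1, 2, 3)), "zero variance")
  expect_true(is.na(s3$r2))
  expect_error(score(1:3, 1:2), "lengths differ")
  expect_error(score(1, 1), "at least 2")
})

test_that("delta is prediction minus truth, summarised by group", {
  y <- c(10, 20, 30, 40); yhat <- c(12, 18, 35, 40)
  expect_equal(compute_delta(y, yhat), c(2, -2, 5, 0))
  ds <- delta_summary(compute_delta(y, yhat), c("a", "a", "b", "b"))
  expect_equal(ds$group, c("a", "b"))
  expect_equal(ds$mean, c(0, 2.5))
  expect_equal(ds$n, c(2L, 2L))
})

test_that("bias correction removes the residual-age trend", {
  # compressive predictor yhat = 0.5 y is corrected exactly
  train_y <- c(10, 20, 30, 40, 50, 60)
  test_y <- c(15, 35, 55)
  corrected <- bias_correct(train_y, 0.5 * train_y, test_y, 0.5 * test_y)
  expect_equal(corrected, test_y, tolerance = 1e-12)

  # an unbiased predictor is left untouched
  expect_equal(bias_correct(train_y, train_y, test_y, 0.7 * test_y),
               0.7 * test_y)

  # after correction, training residuals are orthogonal to age
  set.seed(51)
  ty <- stats::runif(50, 10, 80)
  tyh <- 0.6 * ty + 8 + stats::rnorm(50, 0, 3)
  fixed <- bias_correct(ty, tyh, ty, tyh)
  expect_lt(abs(stats::cov(ty - fixed, ty)), 1e-10)

  expect_error(bias_correct(c(1, 2), c(1, 2), test_y, test_y), "at least 3")
  expect_error(bias_correct(c(5, 5, 5), c(4, 5, 6), test_y, test_y),
               "constant")
})

test_that("paired sign-flip permutation test behaves at the extremes", {
  expect_error(permutation_test_paired(1:5, 5:1, n_perm = 10), "at least 100")

  same <- stats::rnorm(12)
  pt <- permutation_test_paired(same, same, n_perm = 500, seed = 2)
  expect_equal(pt$statistic, 0)
  expect_equal(pt$p_value, 1)

  # determinism and two-sided symmetry
  set.seed(52)
  a <- stats::rnorm(18, 0.5); b <- stats::rnorm(18)
  p1 <- permutation_test_paired(a, b, n_perm = 1000, seed = 7)
  p2 <- permutation_test_paired(a, b, n_perm = 1000, seed = 7)
  expect_identical(p1$p_value, p2$p_value)
  p_swap <- permutation_test_paired(b, a, n_perm = 1000, seed = 7)
  expect_equal(p_swap$p_value, p1$p_value)
  expect_equal(p_swap$statistic, -p1$statistic)

  # p is bounded below by the enumeration floor 1 / (n_perm + 1)
  big <- permutation_test_paired(rep(1, 18), rep(0, 18), n_perm = 1000, seed = 1)
  expect_gte(big$p_value, 1 / 1001)
  expect_lt(big$p_value, 0.05)
})

test_that("inner folds respect the grouping rule and stay inside the training set", {
  co <- toy_cohort(n = 24L, sites = c("a", "b", "c", "d"))
  train_idx <- which(co$meta$site != "d")
  inner <- kmereg:::build_inner_folds(co$meta, train_idx, "leave-site-out",
                                      inner_k = 5L, seed = 1L)
  expect_equal(length(inner), 3L)  # one inner fold per training site
  for (f in inner) {
    expect_true(all(c(f$train, f$test) %in% train_idx))
    expect_length(intersect(f$train, f$test), 0L)
    expect_length(unique(co$meta$site[f$test]), 1L)
  }
  expect_setequal(unlist(lapply(inner, `[[`, "test")), train_idx)

  # single training site falls back to subject-level k-fold with a warning
  solo_idx <- which(co$meta$site == "a")
  expect_warning(
    fb <- kmereg:::build_inner_folds(co$meta, solo_idx, "leave-site-out",
                                     inner_k = 3L, seed = 1L),
    "fewer than 2 training sites")
  expect_equal(length(fb), 3L)
  expect_setequal(unlist(lapply(fb, `[[`, "test")), solo_idx)
})

test_that("nested CV gives every subject one out-of-sample prediction, deterministically", {
  co <- rescale_cohort(toy_cohort(n = 30L, sites = c("a", "b", "c"), seed = 61))
  plan <- make_site_folds(co, "leave-site-out")
  grids <- list(alpha = c(0.1, 1), gamma = c(0.5, 1))
  r1 <- nested_cv_fit_predict(co, "C3", "kmer", plan, grids)
  expect_equal(nrow(r1$predictions), 30L)
  expect_identical(sort(r1$predictions$subject_id), sort(co$meta$subject_id))
  expect_equal(anyDuplicated(r1$predictions$subject_id), 0L)
  expect_equal(r1$predictions$delta,
               r1$predictions$y_pred - r1$predictions$age)
  expect_equal(nrow(r1$fold_summary), 3L)
  expect_true(all(r1$fold_summary$alpha %in% grids$alpha))

  # exact rerun determinism
  r2 <- nested_cv_fit_predict(co, "C3", "kmer", plan, grids)
  expect_identical(r2$predictions$y_pred, r1$predictions$y_pred)

  # permuting cohort rows permutes, but does not change, the predictions
  p <- with(list(), {set.seed(6); sample(30)})
  co_p <- eeg_cohort(transform(co$meta[p, ]),
                     lapply(co$spectra, function(m) m[p, ]), co$grid)
  r3 <- nested_cv_fit_predict(co_p, "C3", "kmer",
                              make_site_folds(co_p, "leave-site-out"), grids)
  m3 <- r3$predictions[match(r1$predictions$subject_id,
                             r3$predictions$subject_id), ]
  expect_equal(m3$y_pred, r1$predictions$y_pred, tolerance = 1e-9)
})

test_that("a single-point grid reduces nested CV to plain grouped CV", {
  co <- rescale_cohort(toy_cohort(n = 24L, sites = c("a", "b", "c"), seed = 62))
  plan <- make_site_folds(co, "leave-site-out")
  grids <- list(alpha = 1, gamma = 0.8)
  r <- nested_cv_fit_predict(co, "C3", "kmer", plan, grids,
                             options = list(gamma_scale = "none"))

  D <- mmd_distance_matrix(co, "C3", inner_kernel_spec())$values
  manual <- rep(NA_real_, 24)
  for (fold in plan$folds) {
    tr <- fold$train_idx; te <- fold$test_idx
    fit <- fit_dual_ridge(outer_kernel(D[tr, tr], 0.8), co$meta$age[tr], 1)
    manual[te] <- predict_dual(fit, outer_kernel(D[te, tr, drop = FALSE], 0.8))
  }
  got <- r$predictions$y_pred[match(co$meta$subject_id,
                                    r$predictions$subject_id)]
  expect_equal(got, manual, tolerance = 1e-12)
})

test_that("rr ignores the gamma grid and fold summaries record selections", {
  co <- rescale_cohort(toy_cohort(n = 24L, sites = c("a", "b"), seed = 63))
  plan <- make_site_folds(co, "leave-site-out")
  w <- capture_warnings(
    r <- nested_cv_fit_predict(co, "C3", "rr", plan,
                               grids = list(alpha = c(0.1, 1, 10))))
  # 2-site leave-site-out leaves 1 training site in each of the 2 folds
  expect_length(w, 2L)
  expect_match(w, "fewer than 2 training sites", all = TRUE)
  expect_true(all(is.na(r$fold_summary$gamma)))
  expect_equal(nrow(r$predictions), 24L)
})

test_that("log-space fitting helps under multiplicative age structure", {
  # ages log-uniform; one spectral bin carries log(age) plus noise, so the
  # target is (noisily) exponential in the features
  set.seed(64)
  n <- 120L
  ages <- round(exp(stats::runif(n, log(6), log(90))), 1)
  lat <- log(ages) + stats::rnorm(n, 0, 0.1)
  x1 <- pmin(pmax(lat / 6, 0.01), 0.99)  # keep weights in (0, 1)
  W <- cbind(x1, 1 - x1)
  meta <- data.frame(subject_id = sprintf("L%03d", 1:n), age = ages,
                     sex = "F", site = rep(c("a", "b", "c"), length.out = n),
                     stringsAsFactors = FALSE)
  co <- eeg_cohort(meta, list(C3 = W), toy_grid(2L))
  plan <- make_site_folds(co, "leave-site-out")
  grids <- list(alpha = 10^seq(-4, 1))

  lin <- nested_cv_fit_predict(co, "C3", "rr", plan, grids)
  logd <- nested_cv_fit_predict(co, "C3", "rr", plan, grids,
                                options = list(log_space = TRUE))
  expect_true(all(logd$predictions$y_pred > 0))
  expect_false(is.null(logd$metrics$log_domain))
  expect_gte(logd$metrics$r2, lin$metrics$r2)
})

test_that("bias-corrected predictions are reported alongside raw ones", {
  co <- rescale_cohort(toy_cohort(n = 30L, sites = c("a", "b", "c"), seed = 65))
  plan <- make_site_folds(co, "leave-site-out")
  r <- nested_cv_fit_predict(co, "C3", "rr", plan, list(alpha = c(1, 10)),
                             options = list(bias_correct = TRUE))
  expect_false(is.null(r$predictions$y_pred_corrected))
  expect_false(is.null(r$metrics$corrected))
  expect_equal(r$predictions$delta_corrected,
               r$predictions$y_pred_corrected - r$predictions$age)
})

test_that("subgroup_eval rescores slices of the predictions without refitting", {
  preds <- data.frame(
    subject_id = sprintf("S%02d", 1:10),
    site = rep(c("a", "b"), each = 5),
    sex = c(rep("F", 8), "M", "M"),
    age = c(10, 20, 30, 40, 50, 15, 25, 35, 45, 55),
    y_pred = c(12, 19, 33, 38, 52, 14, 27, 33, 47, 52),
    stringsAsFactors = FALSE)
  res <- structure(list(predictions = preds), class = "kmer_eval")
  by_site <- subgroup_eval(res, "site")
  expect_equal(by_site$group, c("a", "b"))
  sel <- preds$site == "a"
  manual <- score(preds$age[sel], preds$y_pred[sel])
  expect_equal(by_site$r2[1], manual$r2)
  expect_equal(by_site$mae[1], manual$mae)

  expect_warning(by_sex <- subgroup_eval(res, "sex"), "fewer than 3")
  expect_identical(by_sex$group, "F")
  expect_error(subgroup_eval(res, "sex", corrected = TRUE),
               "no bias-corrected")
})

test_that("evaluate_channels aggregates and write_eval_results round-trips", {
  co <- rescale_cohort(toy_cohort(n = 24L, sites = c("a", "b", "c"), seed = 66))
  plan <- make_site_folds(co, "leave-site-out")
  res <- evaluate_channels(co, c("C3", "O1"), c("rr", "kmer"), plan,
                           grids = list(alpha = c(0.1, 1), gamma = 1))
  expect_equal(nrow(res$summary), 4L)
  expect_setequal(names(res$results),
                  c("C3.rr", "C3.kmer", "O1.rr", "O1.kmer"))

  dir <- withr::local_tempdir()
  paths <- write_eval_results(res, dir, extra = list(seed = 1L))
  expect_true(file.exists(paths$predictions))
  expect_true(file.exists(paths$summary))
  s <- jsonlite::read_json(paths$summary, simplifyVector = TRUE)
  expect_equal(s$schema_version, 1L)
  expect_equal(s$seed, 1L)
  expect_equal(nrow(s$scores), 4L)
  expect_equal(s$scores$r2, res$summary$r2)
  preds <- utils::read.csv(paths$predictions)
  expect_equal(nrow(preds), 4L * 24L)
})
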