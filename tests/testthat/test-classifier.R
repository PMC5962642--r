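test_that("Mann-Whitney AUC matches the ROC integral oracle", {
  skip_if_not_installed("pROC")
  withr::with_seed(11, {
    for (i in 1:5) {
      scores <- rnorm(40)
      pos <- runif(40) < 0.4
      if (sum(pos) == 0 || sum(!pos) == 0) next
      ref <- suppressMessages(
        as.numeric(pROC::auc(pROC::roc(pos, scores, quiet = TRUE,
                                       direction = "<")))
      )
      expect_equal(auc_mw(scores, pos), ref, tolerance = 1e-12)
    }
  })
  expect_equal(auc_mw(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE)), 1)
  expect_equal(auc_mw(c(4, 3, 2, 1), c(FALSE, FALSE, TRUE, TRUE)), 0)
})

test_that("KS selection keeps separated features and drops constants", {
  x <- cbind(
    sep = c(1, 2, 3, 4, 5, 10, 11, 12, 13, 14),
    const = rep(1, 10),
    noise = c(2, 9, 4, 7, 5, 3, 8, 1, 6, 10)
  )
  y <- rep(c("a", "b"), each = 5)
  sel <- ks_select(x, y, alpha = 0.05)
  expect_true("sep" %in% sel$feature)
  expect_false("const" %in% sel$feature)
  # complete separation: exact two-sample KS p = 2 / C(10, 5)
  expect_equal(sel$ks_p[sel$feature == "sep"], 2 / choose(10, 5),
               tolerance = 1e-9)

  # under the null a feature is retained about alpha of the time
  withr::with_seed(12, {
    hits <- mean(vapply(1:400, function(i) {
      xx <- matrix(rnorm(20), ncol = 1,
                   dimnames = list(NULL, "f"))
      nrow(ks_select(xx, y, alpha = 0.05)) == 1
    }, logical(1)))
    expect_lt(abs(hits - 0.05), 0.04)
  })
})

test_that("correlation filter drops duplicates, keeps the boundary", {
  u <- rep(c(1, 1, -1, -1), 5)
  v <- rep(c(1, -1, 1, -1), 5)
  x <- cbind(f1 = u, f2 = 2 * u, f3 = 0.8 * u + 0.6 * v)
  expect_equal(cor(x[, "f1"], x[, "f3"]), 0.8, tolerance = 1e-12)
  kept <- correlation_filter(x, c("f1", "f2", "f3"), threshold = 0.8)
  expect_equal(kept, c("f1", "f3")) # r = 1 dropped, r = 0.8 kept

  withr::with_seed(13, {
    xx <- matrix(rnorm(94 * 2), 94, dimnames = list(NULL, c("a", "b")))
    expect_equal(correlation_filter(xx, c("a", "b")), c("a", "b"))
  })
})

test_that("SVM tuning separates separable data and is seeded", {
  fm <- make_feature_matrix(n_per_class = 15, n_noise = 3, shift = 4)
  x <- as.matrix(fm$features[, -1])
  r1 <- withr::with_seed(14, tune_svm(x, fm$labels,
                                      svm_config(cv_folds = 5,
                                                 cv_repeats = 2)))
  r2 <- withr::with_seed(14, tune_svm(x, fm$labels,
                                      svm_config(cv_folds = 5,
                                                 cv_repeats = 2)))
  expect_equal(r1$cv_auc, 1)
  expect_identical(r1[c("cost", "gamma", "cv_auc")],
                   r2[c("cost", "gamma", "cv_auc")])
})

test_that("iterative classification is reproducible and leak-free", {
  fm <- make_feature_matrix(n_per_class = 30, n_noise = 10, shift = 3)
  cfg <- svm_config(cv_folds = 5, cv_repeats = 2,
                    cost_grid = c(1, 10), gamma_scale = c(1))
  r1 <- run_iterations(fm$features, fm$labels, n_iter = 6,
                       rng_seed = 15, config = cfg)
  r2 <- run_iterations(fm$features, fm$labels, n_iter = 6,
                       rng_seed = 15, config = cfg)
  expect_identical(r1$runs, r2$runs)
  expect_identical(r1$selection_counts, r2$selection_counts)
  expect_gt(r1$summary$mean_auc, 0.9)
  expect_error(run_iterations(fm$features, fm$labels, n_iter = 0),
               "at least 1")

  # shuffling the held-out labels cannot change what training selected
  x <- as.matrix(fm$features[, -1]); rownames(x) <- fm$features$compound
  y <- fm$labels
  train_idx <- c(1:24, 31:54)
  a <- withr::with_seed(16,
    stressdyn:::classifier_split_run(x, y, train_idx, cfg))
  y_shuf <- y
  y_shuf[-train_idx] <- rev(y_shuf[-train_idx])
  b <- withr::with_seed(16,
    stressdyn:::classifier_split_run(x, y_shuf, train_idx, cfg))
  expect_identical(a$selected, b$selected)
  expect_identical(a$tuned[c("cost", "gamma", "cv_auc")],
                   b$tuned[c("cost", "gamma", "cv_auc")])
  expect_identical(a$scores, b$scores)
})

test_that("stability report applies the strict selection threshold", {
  fm <- make_feature_matrix(n_per_class = 30, n_noise = 4, shift = 3)
  cfg <- svm_config(cv_folds = 5, cv_repeats = 1,
                    cost_grid = c(1), gamma_scale = c(1))
  runs <- run_iterations(fm$features, fm$labels, n_iter = 8,
                         rng_seed = 17, config = cfg)
  rep8 <- stability_report(runs, stable_threshold = 6)
  counts <- rep8$feature_counts
  expect_true(all(counts$times_selected >= 0 &
                    counts$times_selected <= 8))
  expect_setequal(rep8$stable_features,
                  counts$feature[counts$times_selected > 6])
  # boundary: a count equal to the threshold is excluded
  at_thr <- counts$feature[counts$times_selected == 6]
  expect_false(any(at_thr %in% rep8$stable_features))
  cp <- rep8$compound_predictions
  expect_true(all(cp$correct_fraction >= 0 & cp$correct_fraction <= 1,
                  na.rm = TRUE))
  never <- cp$times_tested == 0
  expect_true(all(is.na(cp$correct_fraction[never])))
})

test_that("feature extraction reproduces closed-form course features", {
  # linear rise 0 -> 1 over 0-24 h
  lin <- stressdyn:::course_stats(seq(0, 24, length.out = 24),
                                  seq(0, 1, length.out = 24))
  expect_equal(lin$early_slope, 1 / 24, tolerance = 1e-9)
  expect_equal(lin$late_slope, 1 / 24, tolerance = 1e-9)
  expect_equal(lin$auc, 12, tolerance = 1e-9)
  expect_equal(lin$max_mag, 1)
  expect_equal(lin$t_max, 24)

  zero <- stressdyn:::course_stats(seq(0, 24, length.out = 24),
                                   rep(0, 24))
  expect_equal(unlist(zero[c("max_mag", "auc", "early_slope",
                             "late_slope")]),
               c(max_mag = 0, auc = 0, early_slope = 0, late_slope = 0))
})

test_that("screen feature matrix is finite and flags censored BMCs", {
  d <- tiny_descriptors()
  scr <- tiny_screen()
  ann <- tiny_annotations()
  mx <- max_over_time_table(d$scaled)
  bmc <- bmc_table(mx, ann)
  feats <- extract_dynamic_features(d$scaled, d$cytotox, bmc, ann)
  expect_equal(nrow(feats), sum(!ann$is_control))
  expect_true(all(vapply(feats[, -1], is.numeric, logical(1))))
  expect_true(all(is.finite(as.matrix(feats[, -1]))))
  manifest <- attr(feats, "manifest")
  expect_equal(nrow(manifest), ncol(feats) - 1)

  # censored BMC features sit at the max tested concentration with flag
  cen <- bmc %>%
    dplyr::filter(.data$censored, .data$descriptor == "frac_2m")
  if (nrow(cen) > 0) {
    cmp <- cen$compound[1]; rep <- cen$reporter[1]
    expect_equal(
      feats[[paste0(rep, "_log10_bmc_cmax")]][feats$compound == cmp],
      log10(100))
    expect_equal(
      feats[[paste0(rep, "_bmc_censored")]][feats$compound == cmp], 1)
  }
  labs <- classifier_labels(feats, ann)
  expect_setequal(unique(labs), c("severe", "non_severe"))
})
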