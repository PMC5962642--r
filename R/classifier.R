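#' Area under the ROC curve via the Mann-Whitney statistic
#'
#' @param scores Numeric scores, larger = more likely positive.
#' @param positive Logical vector, `TRUE` for the positive class.
#' @return AUC in [0, 1].
#' @export
auc_mw <- function(scores, positive) {
  n_pos <- sum(positive); n_neg <- sum(!positive)
  if (n_pos == 0 || n_neg == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[positive]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Classifier settings
#'
#' The support-vector machine uses a radial-basis kernel; `cost_grid` and
#' `gamma_scale` (multiples of the 1/p heuristic) define the tuning grid
#' searched with `cv_repeats` repeats of `cv_folds`-fold stratified
#' cross-validation scored by pooled out-of-fold ROC-AUC; ties break
#' toward the smallest cost, then the smallest kernel width.
#'
#' @param ks_alpha Kolmogorov-Smirnov retention threshold.
#' @param cor_threshold Absolute pairwise correlation above which a
#'   feature is dropped (strict inequality).
#' @param cost_grid SVM cost values.
#' @param gamma_scale Multipliers of `1 / n_features` for the RBF width.
#' @param cv_repeats,cv_folds Cross-validation design.
#' @param class_weights Optional named class weights for the SVM.
#' @return A list of settings with class `stressdyn_svm_config`.
#' @export
svm_config <- function(ks_alpha = 0.05, cor_threshold = 0.8,
                       cost_grid = 2^seq(-2, 6, by = 2),
                       gamma_scale = c(0.25, 1, 4),
                       cv_repeats = 10, cv_folds = 10,
                       class_weights = NULL) {
  structure(as.list(environment()), class = "stressdyn_svm_config")
}

#' Kolmogorov-Smirnov feature selection
#'
#' Two-sample KS test of each feature between the two classes on the
#' training data; features with p below `alpha` are retained, ordered by
#' ascending p.  Constant features give p = 1 and are dropped.
#'
#' @param x Feature matrix (rows = training compounds).
#' @param y Class labels (two classes).
#' @param alpha Retention threshold.
#' @return Tibble `feature, ks_p` of retained features, ascending p.
#' @export
ks_select <- function(x, y, alpha = 0.05) {
  cls <- unique(y)
  if (length(cls) != 2) abort("ks_select needs exactly two classes")
  a <- y == cls[1]
  p <- vapply(seq_len(ncol(x)), function(j) {
    xa <- x[a, j]; xb <- x[!a, j]
    if (length(unique(c(xa, xb))) == 1) return(1)
    suppressWarnings(ks.test(xa, xb)$p.value)
  }, numeric(1))
  out <- tibble(feature = colnames(x), ks_p = p) %>%
    filter(.data$ks_p < alpha) %>%
    arrange(.data$ks_p)
  out
}

#' Greedy pairwise correlation filter
#'
#' Walks the candidate features in the given order (best KS p first) and
#' drops any feature whose absolute Pearson correlation with an
#' already-kept feature exceeds the threshold (strict inequality, so
#' |r| exactly at the threshold is kept).
#'
#' @param x Feature matrix (training rows).
#' @param features Candidate feature names, in priority order.
#' @param threshold Absolute correlation cut (default 0.8).
#' @return Character vector of kept features, in input order.
#' @export
correlation_filter <- function(x, features, threshold = 0.8) {
  kept <- character(0)
  for (f in features) {
    if (length(kept) == 0) { kept <- f; next }
    r <- suppressWarnings(
      abs(stats::cor(x[, f], x[, kept, drop = FALSE]))
    )
    r[is.na(r)] <- 0
    if (all(r <= threshold)) kept <- c(kept, f)
  }
  kept
}

# stratified fold assignment: shuffles within class then deals folds
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep(seq_len(k), length.out = length(idx))
  }
  fold
}

svm_scores <- function(model, x, positive = "severe") {
  pr <- predict(model, x, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  lab <- colnames(dv)[1]
  s <- dv[, 1]
  # decision values are oriented toward the first label in "A/B"
  if (!startsWith(lab, paste0(positive, "/"))) s <- -s
  list(scores = s, class = as.character(pr))
}

#' Tune an RBF support-vector machine by repeated cross-validation
#'
#' Standardizes the training features (training mean/sd), then grid
#' searches cost and kernel width with repeated stratified k-fold
#' cross-validation; each repeat's out-of-fold decision values are pooled
#' into one ROC-AUC and repeats are averaged.
#'
#' @param x Training feature matrix (selected features only).
#' @param y Training labels (`"severe"` / `"non_severe"`).
#' @param config Settings from [svm_config()].
#' @return List: `cost`, `gamma`, `cv_auc`, `center`, `scale`,
#'   `features`, and the fitted `model` on the full training set.
#' @export
tune_svm <- function(x, y, config = svm_config()) {
  if (min(table(y)) < config$cv_folds) {
    abort("tune_svm needs at least cv_folds training compounds per class")
  }
  y <- factor(y, levels = c("non_severe", "severe"))
  center <- colMeans(x)
  scl <- apply(x, 2, sd)
  scl[scl == 0] <- 1
  xs <- scale(x, center = center, scale = scl)
  grid <- tidyr::expand_grid(cost = config$cost_grid,
                             gamma = config$gamma_scale / ncol(x))
  fold_sets <- purrr::map(seq_len(config$cv_repeats), function(r) {
    stratified_folds(y, config$cv_folds)
  })
  grid$cv_auc <- vapply(seq_len(nrow(grid)), function(g) {
    aucs <- vapply(fold_sets, function(fold) {
      sc <- numeric(length(y))
      for (f in seq_len(config$cv_folds)) {
        tr <- fold != f
        m <- e1071::svm(xs[tr, , drop = FALSE], y[tr],
                        kernel = "radial", cost = grid$cost[g],
                        gamma = grid$gamma[g], scale = FALSE,
                        class.weights = config$class_weights)
        sc[!tr] <- svm_scores(m, xs[!tr, , drop = FALSE])$scores
      }
      auc_mw(sc, y == "severe")
    }, numeric(1))
    mean(aucs)
  }, numeric(1))
  best <- grid %>%
    arrange(dplyr::desc(.data$cv_auc), .data$cost, .data$gamma) %>%
    slice(1)
  model <- e1071::svm(xs, y, kernel = "radial", cost = best$cost,
                      gamma = best$gamma, scale = FALSE,
                      class.weights = config$class_weights)
  list(cost = best$cost, gamma = best$gamma, cv_auc = best$cv_auc,
       center = center, scale = scl, features = colnames(x),
       model = model)
}

# one train/test run with a fixed split: KS selection, correlation filter,
# SVM tuning on the training compounds only, then test-set prediction
classifier_split_run <- function(x, y, train_idx, config = svm_config()) {
  xtr <- x[train_idx, , drop = FALSE]
  ytr <- y[train_idx]
  ks <- ks_select(xtr, ytr, alpha = config$ks_alpha)
  selected <- correlation_filter(xtr, ks$feature,
                                 threshold = config$cor_threshold)
  if (length(selected) < 2) {
    # fall back to the best-ranked features so the SVM stays fittable
    ord <- order(vapply(seq_len(ncol(xtr)), function(j) {
      xa <- xtr[ytr == ytr[1], j]; xb <- xtr[ytr != ytr[1], j]
      if (length(unique(c(xa, xb))) == 1) return(1)
      suppressWarnings(ks.test(xa, xb)$p.value)
    }, numeric(1)))
    selected <- unique(c(selected, colnames(xtr)[ord]))[1:2]
  }
  tuned <- tune_svm(xtr[, selected, drop = FALSE], ytr, config)
  xte <- x[-train_idx, selected, drop = FALSE]
  xte <- scale(xte, center = tuned$center, scale = tuned$scale)
  pred <- svm_scores(tuned$model, xte)
  list(selected = selected, tuned = tuned,
       test_idx = setdiff(seq_len(nrow(x)), train_idx),
       scores = pred$scores, predicted = pred$class)
}

#' Iterative feature-selection / SVM severity classification
#'
#' Runs `n_iter` iterations of: class-stratified 80/20 train/test split,
#' Kolmogorov-Smirnov feature selection and pairwise correlation filtering
#' on the training set, SVM tuning by repeated cross-validation, and
#' test-set prediction (positive class = severe).  Reported metrics are
#' averages over the iterations' test sets; feature selection counts and
#' per-compound correct-prediction fractions are accumulated across
#' iterations.
#'
#' @param features Wide feature tibble: `compound` column plus numeric
#'   feature columns (one row per compound).
#' @param labels Named character vector (or tibble column) of
#'   `"severe"` / `"non_severe"` labels aligned with `features$compound`.
#' @param n_iter Number of train/test iterations.
#' @param test_fraction Held-out fraction per class.
#' @param rng_seed Master seed; iteration i uses substream
#'   `rng_seed + i`.
#' @param config Settings from [svm_config()].
#' @return Object of class `dili_svm_runs`: per-iteration metrics,
#'   selection counts, per-compound predictions and a summary.
#' @export
run_iterations <- function(features, labels, n_iter = 200,
                           test_fraction = 0.2, rng_seed = 1L,
                           config = svm_config()) {
  if (n_iter < 1) abort("n_iter must be at least 1")
  x <- as.matrix(features %>% select(-"compound"))
  rownames(x) <- features$compound
  stopifnot(all(is.finite(x)))
  y <- as.character(labels)
  if (length(y) != nrow(x)) abort("labels must match feature rows")
  n <- nrow(x)
  sel_counts <- setNames(integer(ncol(x)), colnames(x))
  comp_tested <- setNames(integer(n), features$compound)
  comp_correct <- setNames(integer(n), features$compound)
  runs <- purrr::map_dfr(seq_len(n_iter), function(i) {
    with_seed(rng_seed + i, {
      test_idx <- unlist(lapply(unique(y), function(cl) {
        idx <- which(y == cl)
        sample(idx, max(1, round(test_fraction * length(idx))))
      }))
      train_idx <- setdiff(seq_len(n), test_idx)
      run <- classifier_split_run(x, y, train_idx, config)
      truth <- y[run$test_idx]
      correct <- run$predicted == truth
      sel_counts[run$selected] <<- sel_counts[run$selected] + 1L
      comp_tested[run$test_idx] <<- comp_tested[run$test_idx] + 1L
      comp_correct[run$test_idx] <<- comp_correct[run$test_idx] +
        as.integer(correct)
      tibble(
        iteration = i,
        n_selected = length(run$selected),
        cost = run$tuned$cost, gamma = run$tuned$gamma,
        cv_auc = run$tuned$cv_auc,
        test_auc = auc_mw(run$scores, truth == "severe"),
        sensitivity = mean(run$predicted[truth == "severe"] == "severe"),
        specificity = mean(run$predicted[truth == "non_severe"] ==
                             "non_severe")
      )
    })
  })
  summary <- tibble(
    n_iter = n_iter,
    mean_auc = mean(runs$test_auc, na.rm = TRUE),
    mean_sensitivity = mean(runs$sensitivity, na.rm = TRUE),
    mean_specificity = mean(runs$specificity, na.rm = TRUE)
  )
  structure(list(runs = runs,
                 selection_counts = sel_counts,
                 compound_tested = comp_tested,
                 compound_correct = comp_correct,
                 summary = summary,
                 rng_seed = rng_seed, config = config),
            class = "dili_svm_runs")
}

#' @export
print.dili_svm_runs <- function(x, ...) {
  s <- x$summary
  cat("DILI severity SVM:", s$n_iter, "train/test iterations\n")
  cat(sprintf("  mean test AUC %.3f  sensitivity %.3f  specificity %.3f\n",
              s$mean_auc, s$mean_sensitivity, s$mean_specificity))
  invisible(x)
}

#' @export
tidy.dili_svm_runs <- function(x, ...) x$runs

#' @export
glance.dili_svm_runs <- function(x, ...) x$summary

#' Feature-stability and per-compound prediction report
#'
#' @param runs A `dili_svm_runs` object.
#' @param stable_threshold Minimum selection count (strictly exceeded)
#'   for a feature to enter the stable set.
#' @return List with class `stressdyn_stability`: `feature_counts`
#'   (tibble), `stable_features` (character), `compound_predictions`
#'   (tibble with correct-prediction fractions; NA when a compound never
#'   entered a test set).
#' @export
stability_report <- function(runs, stable_threshold = 150) {
  fc <- tibble(feature = names(runs$selection_counts),
               times_selected = unname(runs$selection_counts)) %>%
    arrange(dplyr::desc(.data$times_selected))
  stable <- fc$feature[fc$times_selected > stable_threshold]
  cp <- tibble(
    compound = names(runs$compound_tested),
    times_tested = unname(runs$compound_tested),
    times_correct = unname(runs$compound_correct)
  ) %>%
    mutate(correct_fraction = if_else(.data$times_tested > 0,
                                      .data$times_correct /
                                        .data$times_tested,
                                      NA_real_))
  structure(list(feature_counts = fc, stable_features = stable,
                 stable_threshold = stable_threshold,
                 compound_predictions = cp),
            class = "stressdyn_stability")
}

#' @export
print.stressdyn_stability <- function(x, ...) {
  cat("Stable features (> ", x$stable_threshold, " selections): ",
      length(x$stable_features), "\n", sep = "")
  invisible(x)
}
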