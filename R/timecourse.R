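#' Condense replicate time courses with natural cubic splines
#'
#' Fits a natural cubic spline basis (8 degrees of freedom) to each
#' replicate's time course by least squares, evaluates each fit on 24
#' equidistant timepoints spanning the observed range, and averages the
#' replicates pointwise.
#'
#' @param series Tibble with columns `replicate_id`, `time_h`, `value`
#'   (one row per replicate-timepoint).
#' @param n_points Number of equidistant output timepoints.
#' @param df Spline degrees of freedom.
#' @return Tibble with `time_h` (length `n_points`) and `value`
#'   (replicate-mean spline values).
#' @export
condense_course <- function(series, n_points = 24, df = 8) {
  reps <- split(series, series$replicate_id)
  t_out <- seq(min(series$time_h), max(series$time_h),
               length.out = n_points)
  per_rep <- purrr::map(reps, function(r) {
    r <- r[order(r$time_h), ]
    if (length(unique(r$time_h)) < df + 1) {
      abort(paste0("condense_course needs at least df+1 = ", df + 1,
                   " distinct timepoints per replicate"))
    }
    basis <- splines::ns(r$time_h, df = df)
    fit <- lm.fit(cbind(1, basis), r$value)
    newb <- predict(basis, t_out)
    drop(cbind(1, newb) %*% fit$coefficients)
  })
  tibble(time_h = t_out,
         value = Reduce(`+`, per_rep) / length(per_rep))
}

#' Linear interpolation to 100 equidistant timepoints
#'
#' Piecewise-linear resampling of a single time course onto `n`
#' equidistant points spanning the observed time range; a high-resolution
#' grid that retains the original noise structure for the functional
#' ANOVA.
#'
#' @param values Observed values.
#' @param times_h Observed times (>= 2 points).
#' @param n Number of output points.
#' @return Numeric vector of length `n`.
#' @export
interpolate_100 <- function(values, times_h, n = 100) {
  if (length(values) < 2) abort("interpolate_100 needs at least 2 points")
  approx(times_h, values, n = n)$y
}

# pooled-variance standardized integrated mean-difference statistic for
# row-matrices A (treated) and B (control) on a common grid
fanova_statistic <- function(A, B, direction) {
  mA <- colMeans(A); mB <- colMeans(B)
  ssA <- colSums(sweep(A, 2, mA)^2)
  ssB <- colSums(sweep(B, 2, mB)^2)
  v <- (ssA + ssB) / (nrow(A) + nrow(B) - 2)
  d <- mA - mB
  if (direction == "up") d <- pmax(d, 0)
  mean(ifelse(v == 0 & d == 0, 0, d^2 / (v + 1e-12)))
}

#' Permutation one-way functional ANOVA against controls
#'
#' Compares treated replicate time courses with control courses on a
#' common grid using an integrated standardized mean-difference statistic:
#' the mean over the grid of the squared group-mean difference divided by
#' the pooled pointwise variance.  The null distribution is obtained by
#' permuting replicate labels: exhaustively when the number of distinct
#' group assignments does not exceed `n_perm`, otherwise by `n_perm`
#' random permutations (with the observed assignment included).
#' Induction reporters (SRXN1/CHOP/P21) are tested one-sided for
#' upregulation by zeroing negative pointwise differences; ICAM1 is tested
#' two-sided.
#'
#' @param treated Numeric matrix, one row per treated replicate course.
#' @param control Numeric matrix, one row per control course (same number
#'   of columns).
#' @param direction `"up"` (one-sided upregulation) or `"two_sided"`.
#' @param n_perm Maximum number of permutations.
#' @param rng_seed Optional seed for random permutations.
#' @return One-row tibble: `statistic`, `p_value`, `n_perm_used`,
#'   `exhaustive`, `direction`.
#' @export
functional_anova <- function(treated, control,
                             direction = c("up", "two_sided"),
                             n_perm = 1999, rng_seed = NULL) {
  direction <- match.arg(direction)
  treated <- as.matrix(treated); control <- as.matrix(control)
  if (ncol(treated) != ncol(control)) {
    abort("treated and control courses must share a common grid")
  }
  if (nrow(treated) < 2 || nrow(control) < 2) {
    abort("functional_anova needs at least 2 replicates per group")
  }
  obs <- fanova_statistic(treated, control, direction)
  if (obs == 0) {
    return(tibble(statistic = 0, p_value = 1, n_perm_used = 0L,
                  exhaustive = TRUE, direction = direction))
  }
  X <- rbind(treated, control)
  nA <- nrow(treated); n <- nrow(X)
  n_all <- choose(n, nA)
  with_seed(rng_seed, {
    if (n_all <= n_perm) {
      combos <- combn(n, nA)
      stats <- apply(combos, 2, function(idx) {
        fanova_statistic(X[idx, , drop = FALSE],
                         X[-idx, , drop = FALSE], direction)
      })
      p <- mean(stats >= obs - 1e-12)
      tibble(statistic = obs, p_value = p, n_perm_used = ncol(combos),
             exhaustive = TRUE, direction = direction)
    } else {
      stats <- vapply(seq_len(n_perm), function(k) {
        idx <- sample.int(n, nA)
        fanova_statistic(X[idx, , drop = FALSE],
                         X[-idx, , drop = FALSE], direction)
      }, numeric(1))
      p <- (1 + sum(stats >= obs - 1e-12)) / (n_perm + 1)
      tibble(statistic = obs, p_value = p, n_perm_used = n_perm,
             exhaustive = FALSE, direction = direction)
    }
  })
}

#' Benjamini-Hochberg FDR adjustment
#'
#' @param p_values Numeric vector of p-values.
#' @param alpha Significance cut applied to the adjusted values.
#' @return Tibble with `p_value`, `q_value` and `significant`
#'   (`q_value < alpha`).
#' @export
fdr_adjust <- function(p_values, alpha = 0.01) {
  q <- p.adjust(p_values, method = "BH")
  tibble(p_value = p_values, q_value = q, significant = q < alpha)
}

#' Mean Manhattan distance across reporters
#'
#' Computes, per reporter, the pairwise L1 distance between item
#' time-course vectors and averages the distance matrices over reporters.
#' Items missing a reporter contribute the mean over the reporters
#' available for each pair (pairwise-complete); such items are flagged.
#'
#' @param courses Long tibble with columns `item`, `reporter`, `value`;
#'   within an item x reporter, rows must be in a consistent vector order
#'   (e.g. concentration-major, time-minor).
#' @return A symmetric distance matrix (zero diagonal) with attribute
#'   `"incomplete_items"`.
#' @export
multireporter_distance <- function(courses) {
  items <- unique(courses$item)
  reps <- unique(courses$reporter)
  mats <- purrr::map(reps, function(rp) {
    sub <- courses[courses$reporter == rp, ]
    lens <- table(sub$item)
    if (length(unique(lens)) > 1) {
      abort(paste0("dimension mismatch in reporter ", rp,
                   ": course lengths differ across items"))
    }
    wide <- do.call(rbind, split(sub$value, factor(sub$item,
                                                   levels = items)))
    as.matrix(stats::dist(wide, method = "manhattan"))
  })
  n <- length(items)
  acc <- matrix(0, n, n, dimnames = list(items, items))
  cnt <- matrix(0, n, n, dimnames = list(items, items))
  for (k in seq_along(mats)) {
    present <- rownames(mats[[k]])
    idx <- match(present, items)
    acc[idx, idx] <- acc[idx, idx] + mats[[k]]
    cnt[idx, idx] <- cnt[idx, idx] + 1
  }
  if (any(cnt == 0 & row(cnt) != col(cnt))) {
    abort("some item pairs share no reporter; distance undefined")
  }
  out <- acc / pmax(cnt, 1)
  diag(out) <- 0
  incomplete <- items[vapply(items, function(it) {
    sum(vapply(mats, function(m) it %in% rownames(m), logical(1))) <
      length(mats)
  }, logical(1))]
  attr(out, "incomplete_items") <- incomplete
  out
}

#' Ward hierarchical clustering of a distance matrix
#'
#' Agglomerative clustering with Ward linkage (`ward.D2`), returning the
#' merge tree, cluster labels at the requested cut and a Newick encoding
#' of the dendrogram.
#'
#' @param d Distance matrix (symmetric, zero diagonal) or `dist` object.
#' @param k Number of clusters to cut into (optional).
#' @param h Cut height (optional alternative to `k`).
#' @return List with class `stressdyn_clustering`: `hclust`, `labels`
#'   (named integer vector, `NULL` when no cut requested) and `newick`.
#' @export
ward_cluster <- function(d, k = NULL, h = NULL) {
  if (!inherits(d, "dist")) d <- as.dist(d)
  if (attr(d, "Size") < 2) abort("ward_cluster needs at least 2 items")
  hc <- hclust(d, method = "ward.D2")
  labels <- if (!is.null(k) || !is.null(h)) cutree(hc, k = k, h = h)
  newick <- ape::write.tree(ape::as.phylo(hc))
  structure(list(hclust = hc, labels = labels, newick = newick),
            class = "stressdyn_clustering")
}

#' @export
print.stressdyn_clustering <- function(x, ...) {
  cat("Ward clustering of", length(x$hclust$labels), "items\n")
  if (!is.null(x$labels)) {
    cat("  cluster sizes:", paste(table(x$labels), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Functional-ANOVA significance table for a descriptor
#'
#' Runs the permutation functional ANOVA for every (compound,
#' concentration, reporter) series of one descriptor against the pooled
#' control courses of the same reporter, interpolates all courses to a
#' common 100-point grid first, and applies Benjamini-Hochberg correction
#' across all tests.
#'
#' @param descriptors Long descriptor table (treated wells).
#' @param control_courses Long descriptor table for control wells (from
#'   [control_descriptor_courses()]), pooled per reporter.
#' @param descriptor Descriptor to test (default `frac_2m` for induction
#'   reporters and `icam_diff_2` for ICAM1).
#' @param n_perm,rng_seed Passed to [functional_anova()].
#' @param alpha FDR significance cut.
#' @return Tibble `compound, conc_xcmax, reporter, statistic, p_value,
#'   q_value, significant`.
#' @export
timecourse_anova <- function(descriptors, control_courses,
                             descriptor = NULL,
                             n_perm = 1999, rng_seed = NULL,
                             alpha = 0.01) {
  pick_desc <- function(rep) {
    if (!is.null(descriptor)) return(descriptor)
    if (rep == "ICAM1") "icam_diff_2" else "frac_2m"
  }
  keys <- descriptors %>%
    distinct(.data$compound, .data$conc_xcmax, .data$reporter)
  res <- purrr::map_dfr(seq_len(nrow(keys)), function(i) {
    ky <- keys[i, ]
    dsc <- pick_desc(ky$reporter)
    tr <- descriptors %>%
      filter(.data$compound == ky$compound,
             .data$conc_xcmax == ky$conc_xcmax,
             .data$reporter == ky$reporter,
             .data$descriptor == dsc)
    ct <- control_courses %>%
      filter(.data$reporter == ky$reporter, .data$descriptor == dsc)
    tmat <- course_matrix(tr, .data_col = "replicate_id")
    cmat <- course_matrix(ct, .data_col = "course_id")
    fa <- functional_anova(
      tmat, cmat,
      direction = if (ky$reporter == "ICAM1") "two_sided" else "up",
      n_perm = n_perm,
      rng_seed = if (is.null(rng_seed)) NULL else rng_seed + i
    )
    bind_cols(ky, fa)
  })
  adj <- fdr_adjust(res$p_value, alpha = alpha)
  res$q_value <- adj$q_value
  res$significant <- adj$significant
  res
}

# interpolate each course of a long table onto the common 100-point grid
# and stack as a matrix (one row per course)
course_matrix <- function(tbl, .data_col, n = 100) {
  ids <- unique(tbl[[.data_col]])
  rows <- purrr::map(ids, function(id) {
    sub <- tbl[tbl[[.data_col]] == id, ]
    sub <- sub[order(sub$time_h), ]
    interpolate_100(sub$value, sub$time_h, n = n)
  })
  do.call(rbind, rows)
}
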