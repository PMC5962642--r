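test_that("spline condensation reproduces simple course shapes", {
  tt <- 0:24
  const <- tibble::tibble(replicate_id = rep(1:2, each = 25),
                          time_h = rep(tt, 2), value = 3.7)
  cc <- condense_course(const)
  expect_equal(nrow(cc), 24)
  expect_equal(cc$value, rep(3.7, 24), tolerance = 1e-9)

  lin <- tibble::tibble(replicate_id = rep(1:2, each = 25),
                        time_h = rep(tt, 2),
                        value = 2 + 0.5 * rep(tt, 2))
  cl <- condense_course(lin)
  expect_equal(cl$value, 2 + 0.5 * cl$time_h, tolerance = 1e-9)

  # noiseless logistic recovered within 2% of its range
  f <- function(t) 1 / (1 + exp(-0.6 * (t - 10)))
  logi <- tibble::tibble(replicate_id = rep(1:3, each = 25),
                         time_h = rep(tt, 3), value = f(rep(tt, 3)))
  cg <- condense_course(logi)
  expect_lt(max(abs(cg$value - f(cg$time_h))), 0.02 * diff(range(f(tt))))

  expect_error(condense_course(tibble::tibble(replicate_id = 1,
                                              time_h = 0:5,
                                              value = 1:6)),
               "df\\+1")
})

test_that("spline condensation commutes with affine value transforms", {
  withr::with_seed(8, {
    base <- tibble::tibble(replicate_id = rep(1:2, each = 25),
                           time_h = rep(0:24, 2),
                           value = rnorm(50))
    shifted <- dplyr::mutate(base, value = 3 * value - 1.5)
    expect_equal(condense_course(shifted)$value,
                 3 * condense_course(base)$value - 1.5,
                 tolerance = 1e-9)
  })
})

test_that("linear interpolation to 100 points preserves knots", {
  v <- interpolate_100(c(0, 24), c(0, 24))
  expect_equal(length(v), 100)
  expect_equal(v, seq(0, 24, length.out = 100))
  expect_equal(interpolate_100(rep(2.5, 5), 0:4), rep(2.5, 100))
  # grid endpoint coincides with a knot
  v2 <- interpolate_100(c(1, 5, 2), c(0, 12, 24))
  expect_equal(v2[1], 1)
  expect_equal(v2[100], 2)
  expect_error(interpolate_100(1, 1), "at least 2")
})

test_that("functional ANOVA gives exact answers for degenerate designs", {
  flat <- matrix(1, 3, 100)
  r <- functional_anova(flat, flat)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  # disjoint constant groups, 3 vs 3, exhaustive: p = 1 / C(6,3)
  up <- matrix(10, 3, 100)
  down <- matrix(0, 3, 100)
  r2 <- functional_anova(up, down, direction = "up")
  expect_true(r2$exhaustive)
  expect_equal(r2$p_value, 1 / choose(6, 3))

  # treated below control is a non-signal one-sided
  r3 <- functional_anova(down, up, direction = "up")
  expect_equal(r3$statistic, 0)
  expect_equal(r3$p_value, 1)

  expect_error(functional_anova(matrix(1, 1, 10), matrix(1, 3, 10)),
               "at least 2")
  expect_error(functional_anova(matrix(1, 3, 10), matrix(1, 3, 9)),
               "common grid")
})

test_that("BH adjustment matches hand computation", {
  expect_equal(fdr_adjust(0.04)$q_value, 0.04)
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04))$q_value,
               rep(0.04, 4))
  expect_equal(fdr_adjust(rep(1, 5))$q_value, rep(1, 5))
  r <- fdr_adjust(c(0.001, 0.5), alpha = 0.01)
  expect_equal(r$significant, c(TRUE, FALSE))
})

test_that("multi-reporter distances average per-reporter L1 metrics", {
  one <- tibble::tibble(item = rep(c("a", "b"), each = 3),
                        reporter = "R1",
                        value = c(0, 0, 0, 1, 2, 3))
  d1 <- multireporter_distance(one)
  expect_equal(d1["a", "b"], 6)
  expect_equal(diag(d1), c(a = 0, b = 0))

  two <- dplyr::bind_rows(
    one,
    tibble::tibble(item = rep(c("a", "b"), each = 3), reporter = "R2",
                   value = c(0, 0, 0, 1, 1, 0))
  )
  expect_equal(multireporter_distance(two)["a", "b"], 4)

  # identical items at distance zero; metric properties on random data
  withr::with_seed(2, {
    items <- paste0("i", 1:5)
    rnd <- tidyr::expand_grid(item = items, reporter = c("R1", "R2"),
                              idx = 1:6) %>%
      dplyr::mutate(value = rnorm(dplyr::n()))
    dd <- multireporter_distance(rnd %>% dplyr::select(-idx))
    expect_equal(dd, t(dd))
    for (i in 1:5) for (j in 1:5) for (k in 1:5) {
      expect_lte(dd[i, j], dd[i, k] + dd[k, j] + 1e-12)
    }
  })
})

test_that("Ward clustering recovers planted groups deterministically", {
  withr::with_seed(3, {
    g1 <- matrix(rnorm(5 * 10, 0, 0.1), 5)
    g2 <- matrix(rnorm(5 * 10, 8, 0.1), 5)
    X <- rbind(g1, g2)
    rownames(X) <- paste0("s", 1:10)
    d <- as.matrix(dist(X, method = "manhattan"))
    cl <- ward_cluster(d, k = 2)
    expect_equal(length(unique(cl$labels[1:5])), 1)
    expect_equal(length(unique(cl$labels[6:10])), 1)
    expect_true(cl$labels[1] != cl$labels[10])
    expect_match(cl$newick, "^\\(")

    # permuting the input order permutes, but does not change, the cut
    perm <- sample(10)
    cl2 <- ward_cluster(d[perm, perm], k = 2)
    agree <- outer(cl$labels[perm], cl$labels[perm], "==") ==
      outer(cl2$labels, cl2$labels, "==")
    expect_true(all(agree))

    # duplicated items merge at height zero
    dd <- rbind(X[1, ], X[1, ], X[6, ])
    cl3 <- ward_cluster(as.matrix(dist(dd)), k = 2)
    expect_equal(min(cl3$hclust$height), 0)
    expect_error(ward_cluster(matrix(0, 1, 1)), "at least 2")
  })
})

test_that("screen-level ANOVA flags a responsive exposure", {
  d <- tiny_descriptors()
  scr <- tiny_screen()
  truth <- scr$truth
  resp <- truth[truth$reporter == "SRXN1" & truth$responsive &
                  truth$bmc_true_xcmax < 30, ]
  skip_if(nrow(resp) == 0, "no responsive compound drawn in fixture")
  cmp <- resp$abbreviation[1]
  sub <- d$scaled %>%
    dplyr::filter(.data$reporter == "SRXN1",
                  .data$compound == cmp,
                  .data$conc_xcmax == 100)
  res <- timecourse_anova(sub, d$controls, n_perm = 199, rng_seed = 4)
  expect_true(all(res$p_value <= 0.05))
  expect_true(all(res$q_value >= res$p_value - 1e-12))
})
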