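test_that("noiseless 4PL data is recovered to high precision", {
  conc <- c(1, 5, 10, 50, 100)
  y <- ll4(conc, b = -1.2, c = 0.05, d = 0.85, e = 20)
  fit <- fit_4pl(conc, y, response_range = c(0, 1))
  expect_true(fit$converged)
  expect_equal(fit$b, -1.2, tolerance = 1e-3)
  expect_equal(fit$c, 0.05, tolerance = 1e-3)
  expect_equal(fit$d, 0.85, tolerance = 1e-3)
  expect_equal(fit$e, 20, tolerance = 1e-3 * 20)
  expect_lt(fit$rss, 1e-10)

  td <- tidy(fit)
  expect_equal(td$term, c("b", "c", "d", "e"))
  expect_equal(glance(fit)$n, 5)
})

test_that("degenerate and monotone responses are handled honestly", {
  conc <- c(1, 5, 10, 50, 100)
  flat <- fit_4pl(conc, rep(0.3, 5))
  expect_true(flat$converged)
  expect_false(flat$b_identifiable)
  expect_equal(flat$c, 0.3)
  expect_equal(flat$d, 0.3)
  expect_true(compute_bmc(flat)$censored)

  rising <- fit_4pl(conc, c(0.05, 0.1, 0.3, 0.7, 0.8),
                    response_range = c(0, 1))
  expect_lt(rising$b, 0) # negative steepness = increasing curve
  expect_error(fit_4pl(c(1, 5, 10), c(0, 0.5, 1)), "at least 4")
})

test_that("BMC inversion matches the worked example and censors", {
  fit <- structure(list(b = -1, c = 0.1, d = 0.9, e = 10,
                        converged = TRUE, b_identifiable = TRUE,
                        rss = 0, data = NULL,
                        response_range = c(0, 1)),
                   class = "curve_fit_4pl")
  r <- compute_bmc(fit, delta = 0.25)
  expect_false(r$censored)
  expect_equal(r$bmc_xcmax, 10 / 2.2, tolerance = 1e-12)
  expect_equal(ll4(r$bmc_xcmax, -1, 0.1, 0.9, 10), 0.35,
               tolerance = 1e-12)

  shallow <- fit; shallow$d <- 0.29 # plateau 0.19 above baseline
  expect_equal(compute_bmc(shallow)$censor_reason, "plateau shortfall")

  # suppression curve with delta = -0.25, baseline at the upper asymptote
  supp <- structure(list(b = 1, c = 0.05, d = 0.8, e = 20,
                         converged = TRUE, b_identifiable = TRUE,
                         rss = 0, data = NULL,
                         response_range = c(-1, 1)),
                    class = "curve_fit_4pl")
  rs <- compute_bmc(supp, delta = -0.25)
  expect_false(rs$censored)
  expect_equal(rs$baseline, 0.8)
  expect_equal(ll4(rs$bmc_xcmax, 1, 0.05, 0.8, 20), 0.55,
               tolerance = 1e-12)
  # wrong-signed delta for an increasing curve is censored
  expect_true(compute_bmc(supp, delta = 0.25)$censored)
})

test_that("closed-form BMC agrees with a grid-search oracle", {
  withr::with_seed(10, {
    grid_x <- exp(seq(log(1), log(100), length.out = 10000))
    step <- max(diff(grid_x))
    for (i in 1:30) {
      b <- -runif(1, 0.5, 4)
      c0 <- runif(1, 0, 0.2)
      d0 <- runif(1, 0.45, 1)
      e0 <- exp(runif(1, log(0.5), log(150)))
      fit <- structure(list(b = b, c = c0, d = d0, e = e0,
                            converged = TRUE, b_identifiable = TRUE,
                            rss = 0, data = NULL,
                            response_range = c(0, 1)),
                       class = "curve_fit_4pl")
      r <- compute_bmc(fit, delta = 0.25)
      curve_vals <- ll4(grid_x, b, c0, d0, e0)
      target <- c0 + 0.25
      reach <- (d0 - c0) >= 0.25
      if (!reach) {
        expect_true(r$censored)
      } else {
        gx <- grid_x[which.min(abs(curve_vals - target))]
        if (!r$censored) {
          expect_lt(abs(r$bmc_xcmax - gx), step * 2)
        } else {
          # censoring only because the crossing leaves the tested range
          expect_true(gx < 1 + 2 * step || gx > 100 - 2 * step ||
                        r$bmc_xcmax < 1 || r$bmc_xcmax > 100)
        }
      }
    }
  })
})

test_that("BMC is invariant to concentration unit relabeling", {
  conc <- c(1, 5, 10, 50, 100)
  y <- ll4(conc, -1.5, 0.05, 0.9, 12)
  f1 <- fit_4pl(conc, y, response_range = c(0, 1))
  f2 <- fit_4pl(conc * 1000, y, response_range = c(0, 1))
  b1 <- compute_bmc(f1, 0.25, conc_range = c(1, 100))
  b2 <- compute_bmc(f2, 0.25, conc_range = c(1000, 100000))
  expect_equal(b2$bmc_xcmax / b1$bmc_xcmax, 1000, tolerance = 1e-6)
})

test_that("Welch test on BMC ratios behaves at the extremes", {
  x <- c(0.5, 1, 2, 4)
  r <- bmc_class_welch(c(x, x), rep(c("severe", "non_severe"), each = 4))
  expect_equal(r$t_statistic, 0)
  expect_equal(r$p_value, 1)

  few <- bmc_class_welch(c(1, NA, NA, 2, 3, 4),
                         rep(c("severe", "non_severe"), each = 3))
  expect_true(is.na(few$p_value))
  expect_equal(few$n_severe, 1)

  withr::with_seed(5, {
    sev <- 10^rnorm(20, 0.9, 0.4)
    non <- 10^rnorm(20, 1.6, 0.4)
    rr <- bmc_class_welch(c(sev, non),
                          rep(c("severe", "non_severe"), each = 20))
    expect_lt(rr$p_value, 0.01)
    expect_lt(rr$mean_log10_severe, rr$mean_log10_non_severe)
  })
})

test_that("nested linear model detects a class offset on log BMC", {
  withr::with_seed(6, {
    n <- 60
    sev <- rep(c("severe", "non_severe"), each = n / 2)
    lcmax <- rnorm(n, 0.5, 1)
    lbmc_null <- 1 + 0.8 * lcmax + rnorm(n, 0, 0.3)
    r0 <- bmc_class_lm(lbmc_null, lcmax, sev)
    expect_gt(r0$p_value, 0.001) # no planted effect

    lbmc <- lbmc_null - 0.7 * (sev == "severe")
    r1 <- bmc_class_lm(lbmc, lcmax, sev)
    expect_lt(r1$p_value, 0.01)
    expect_lt(r1$coef_severity, 0)

    expect_error(bmc_class_lm(lbmc, lcmax, rep("severe", n)),
                 "no variation")
  })
})

test_that("screen-level BMC estimates order with simulated potency", {
  d <- tiny_descriptors()
  scr <- tiny_screen()
  mx <- max_over_time_table(d$scaled)
  bmc <- bmc_table(mx, read_compound_table())
  expect_true(all(bmc$bmc_xcmax[!bmc$censored] >= 1 - 1e-9))
  expect_true(all(bmc$bmc_xcmax[!bmc$censored] <= 100 + 1e-9))
  expect_equal(bmc$bmc_over_cmax, bmc$bmc_xcmax)
  expect_equal(bmc$bmc_uM[!bmc$censored],
               (bmc$bmc_xcmax * bmc$cmax_uM)[!bmc$censored])
})
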