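#' Four-parameter log-logistic model value
#'
#' `f(x) = c + (d - c) / (1 + exp(b * (log(x) - log(e))))`: lower/upper
#' asymptotes `c` and `d`, steepness `b` (negative for curves increasing
#' with concentration) and inflection concentration `e`.
#'
#' @param x Concentration (same units as `e`; here C-max multiples).
#' @param b,c,d,e Model parameters.
#' @return Model response.
#' @export
ll4 <- function(x, b, c, d, e) {
  c + (d - c) / (1 + exp(b * (log(x) - log(e))))
}

#' Fit a four-parameter log-logistic concentration-response curve
#'
#' Bounded least squares on log-concentration with multi-start
#' initialisation (Levenberg-Marquardt via minpack.lm, with an
#' L-BFGS-B fallback).  Constant responses return a degenerate but
#' converged fit (`c == d`, `b` flagged unidentifiable).
#'
#' @param conc_xcmax Tested concentrations (>= 4 distinct, positive).
#' @param response Replicate-mean responses (same length).
#' @param response_range Optional bounds for the asymptotes `c` and `d`
#'   (e.g. `c(0, 1)` for scaled descriptors, `c(-1, 1)` for ICAM1).
#'   Defaults to the observed response range widened by half its span.
#' @return Object of class `curve_fit_4pl`: parameters, `converged`,
#'   `b_identifiable`, `rss` and the fitted data.
#' @export
fit_4pl <- function(conc_xcmax, response, response_range = NULL) {
  ok <- is.finite(conc_xcmax) & is.finite(response) & conc_xcmax > 0
  conc <- conc_xcmax[ok]; y <- response[ok]
  if (length(unique(conc)) < 4) {
    abort("fit_4pl needs at least 4 distinct concentrations")
  }
  span <- diff(range(y))
  if (is.null(response_range)) {
    response_range <- range(y) + c(-0.5, 0.5) * max(span, 1e-3)
  }
  if (span == 0) {
    fit <- list(b = NA_real_, c = y[1], d = y[1],
                e = exp(mean(log(range(conc)))),
                converged = TRUE, b_identifiable = FALSE, rss = 0,
                data = tibble(conc_xcmax = conc, response = y),
                response_range = response_range)
    return(structure(fit, class = "curve_fit_4pl"))
  }
  lx <- log(conc)
  rss_fun <- function(p) {
    pred <- p[2] + (p[3] - p[2]) / (1 + exp(p[1] * (lx - p[4])))
    sum((y - pred)^2)
  }
  lower <- c(-20, response_range[1], response_range[1],
             min(lx) - log(100))
  upper <- c(20, response_range[2], response_range[2],
             max(lx) + log(100))
  starts <- tidyr::expand_grid(
    b = c(-5, -2, -0.5, 0.5, 2, 5),
    le = quantile(lx, c(0.25, 0.5, 0.75), names = FALSE)
  )
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    p0 <- c(starts$b[i], min(y), max(y), starts$le[i])
    cand <- tryCatch({
      fit <- minpack.lm::nlsLM(
        y ~ c + (d - c) / (1 + exp(b * (lx - le))),
        start = list(b = p0[1], c = p0[2], d = p0[3], le = p0[4]),
        lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200,
                                             ftol = 1e-12, ptol = 1e-12)
      )
      p <- coef(fit)
      list(par = unname(p[c("b", "c", "d", "le")]),
           rss = sum(stats::residuals(fit)^2), converged = TRUE)
    }, error = function(e) NULL)
    if (is.null(cand)) {
      opt <- optim(p0, rss_fun, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 500, factr = 1e4))
      cand <- list(par = opt$par, rss = opt$value,
                   converged = opt$convergence == 0)
    }
    if (is.null(best) || cand$rss < best$rss) best <- cand
  }
  p <- best$par
  # (b, c, d) and (-b, d, c) describe the same curve; canonicalize so the
  # lower asymptote is c
  if (p[2] > p[3]) p <- c(-p[1], p[3], p[2], p[4])
  fit <- list(b = p[1], c = p[2], d = p[3], e = exp(p[4]),
              converged = isTRUE(best$converged),
              b_identifiable = TRUE, rss = best$rss,
              data = tibble(conc_xcmax = conc, response = y),
              response_range = response_range)
  structure(fit, class = "curve_fit_4pl")
}

#' @export
print.curve_fit_4pl <- function(x, ...) {
  cat("4PL fit: b =", signif(x$b, 4), " c =", signif(x$c, 4),
      " d =", signif(x$d, 4), " e =", signif(x$e, 4),
      " rss =", signif(x$rss, 4),
      if (!x$converged) " (not converged)", "\n")
  invisible(x)
}

#' @export
tidy.curve_fit_4pl <- function(x, ...) {
  tibble(term = c("b", "c", "d", "e"),
         estimate = c(x$b, x$c, x$d, x$e))
}

#' @export
glance.curve_fit_4pl <- function(x, ...) {
  tibble(converged = x$converged, b_identifiable = x$b_identifiable,
         rss = x$rss, n = nrow(x$data))
}

#' Extract the benchmark concentration from a fitted curve
#'
#' The benchmark concentration (BMC) is the concentration at which the
#' fitted curve departs from its low-concentration asymptote (the
#' baseline) by a fixed absolute amount `delta` (+0.25 on the scaled
#' response; -0.25 for ICAM1 suppression).  It is solved in closed form by
#' inverting the log-logistic.  The result is censored when the fitted
#' plateau never departs from baseline by `|delta|`, when the departure
#' has the wrong sign, or when the solution falls outside the tested
#' concentration range.
#'
#' @param fit A `curve_fit_4pl` object.
#' @param delta Response departure defining the point of departure
#'   (+0.25 or -0.25).
#' @param conc_range Tested concentration range (C-max multiples).
#' @return One-row tibble: `delta`, `baseline`, `bmc_xcmax`, `censored`,
#'   `censor_reason`.
#' @export
compute_bmc <- function(fit, delta = 0.25, conc_range = c(1, 100)) {
  censored <- function(reason) {
    tibble(delta = delta, baseline = NA_real_, bmc_xcmax = NA_real_,
           censored = TRUE, censor_reason = reason)
  }
  if (!inherits(fit, "curve_fit_4pl")) abort("fit must be a curve_fit_4pl")
  if (!fit$converged) return(censored("fit did not converge"))
  if (!fit$b_identifiable || fit$c == fit$d) {
    return(censored("flat response"))
  }
  # x -> 0 sends the exponent to +Inf for b < 0 (curve -> c) and to -Inf
  # for b > 0 (curve -> d)
  baseline <- if (fit$b < 0) fit$c else fit$d
  plateau <- if (fit$b < 0) fit$d else fit$c
  if (abs(plateau - baseline) < abs(delta)) {
    return(tibble(delta = delta, baseline = baseline,
                  bmc_xcmax = NA_real_, censored = TRUE,
                  censor_reason = "plateau shortfall"))
  }
  if (sign(plateau - baseline) != sign(delta)) {
    return(tibble(delta = delta, baseline = baseline,
                  bmc_xcmax = NA_real_, censored = TRUE,
                  censor_reason = "response direction opposite to delta"))
  }
  target <- baseline + delta
  u <- (fit$d - fit$c) / (target - fit$c) - 1
  if (u <= 0) {
    return(tibble(delta = delta, baseline = baseline,
                  bmc_xcmax = NA_real_, censored = TRUE,
                  censor_reason = "target outside curve range"))
  }
  bmc <- fit$e * exp(log(u) / fit$b)
  if (bmc < conc_range[1] || bmc > conc_range[2]) {
    return(tibble(delta = delta, baseline = baseline, bmc_xcmax = bmc,
                  censored = TRUE,
                  censor_reason = "outside tested range"))
  }
  tibble(delta = delta, baseline = baseline, bmc_xcmax = bmc,
         censored = FALSE, censor_reason = NA_character_)
}

#' Concentration-response fits and BMCs for a whole screen
#'
#' Fits one four-parameter log-logistic curve per (compound, reporter,
#' descriptor) to the replicate means of the maximum-over-time summaries
#' and extracts the benchmark concentration.  For ICAM1 difference
#' descriptors both the +0.25 (enhancement) and -0.25 (suppression)
#' departures are tried and the more potent uncensored one is reported
#' (both are retained in `bmc_up` / `bmc_down`).
#'
#' @param max_table Output of [max_over_time_table()].
#' @param annotations Annotation tibble (for C-max values).
#' @param descriptors Descriptors to fit; defaults to the headline
#'   concentration-response descriptors `frac_2m` (SRXN1/CHOP/P21) and
#'   `icam_diff_2` (ICAM1).
#' @param conc_range Tested concentration range in C-max multiples.
#' @return Tibble with fit parameters, `bmc_xcmax`, `bmc_uM`,
#'   `bmc_over_cmax` and censoring status per compound x reporter x
#'   descriptor.
#' @export
bmc_table <- function(max_table, annotations,
                      descriptors = c("frac_2m", "icam_diff_2"),
                      conc_range = c(1, 100)) {
  resp <- max_table %>%
    filter(.data$descriptor %in% descriptors) %>%
    group_by(.data$compound, .data$reporter, .data$descriptor,
             .data$conc_xcmax) %>%
    summarise(response = mean(.data$max_value), .groups = "drop")
  keys <- resp %>% distinct(.data$compound, .data$reporter,
                            .data$descriptor)
  cmax <- annotations %>% select(compound = "abbreviation", "cmax_uM")
  purrr::map_dfr(seq_len(nrow(keys)), function(i) {
    ky <- keys[i, ]
    sub <- resp %>%
      filter(.data$compound == ky$compound,
             .data$reporter == ky$reporter,
             .data$descriptor == ky$descriptor) %>%
      arrange(.data$conc_xcmax)
    # asymptotes may extrapolate beyond the observed scaling range (the
    # scaled maximum is set by the strongest responder), so the bounds
    # widen the descriptor range by half its span
    rng <- if (grepl("^icam_diff", ky$descriptor)) c(-1, 1) else c(0, 1)
    rng <- rng + c(-0.5, 0.5) * diff(rng)
    fit <- fit_4pl(sub$conc_xcmax, sub$response, response_range = rng)
    if (grepl("^icam_diff", ky$descriptor)) {
      up <- compute_bmc(fit, 0.25, conc_range)
      down <- compute_bmc(fit, -0.25, conc_range)
      both <- bind_rows(up, down) %>% filter(!.data$censored)
      bmc <- if (nrow(both) == 0) {
        up %>% mutate(censored = TRUE)
      } else {
        both %>% arrange(.data$bmc_xcmax) %>% slice(1)
      }
      bmc$bmc_up <- up$bmc_xcmax
      bmc$bmc_down <- down$bmc_xcmax
    } else {
      bmc <- compute_bmc(fit, 0.25, conc_range)
      bmc$bmc_up <- bmc$bmc_xcmax
      bmc$bmc_down <- NA_real_
    }
    bind_cols(ky, tibble(b = fit$b, c = fit$c, d = fit$d, e = fit$e,
                         converged = fit$converged, rss = fit$rss),
              bmc)
  }) %>%
    left_join(cmax, by = "compound") %>%
    mutate(bmc_over_cmax = .data$bmc_xcmax,
           bmc_uM = .data$bmc_xcmax * .data$cmax_uM)
}

#' Welch test of C-max-normalised BMC between severity classes
#'
#' Welch two-sample t-test on log10(BMC / C-max) between severe and
#' non-severe compounds; censored BMCs are excluded.
#'
#' @param bmc_over_cmax BMC / C-max ratios (NA for censored).
#' @param severity `"severe"` / `"non_severe"` labels.
#' @return One-row tibble `t_statistic, p_value, n_severe, n_non_severe,
#'   mean_log10_severe, mean_log10_non_severe` (all NA when a class has
#'   fewer than 2 uncensored values).
#' @export
bmc_class_welch <- function(bmc_over_cmax, severity) {
  keep <- is.finite(bmc_over_cmax) & bmc_over_cmax > 0 &
    severity %in% c("severe", "non_severe")
  x <- log10(bmc_over_cmax[keep & severity == "severe"])
  y <- log10(bmc_over_cmax[keep & severity == "non_severe"])
  if (length(x) < 2 || length(y) < 2) {
    return(tibble(t_statistic = NA_real_, p_value = NA_real_,
                  n_severe = length(x), n_non_severe = length(y),
                  mean_log10_severe = NA_real_,
                  mean_log10_non_severe = NA_real_))
  }
  tt <- t.test(x, y, var.equal = FALSE)
  tibble(t_statistic = unname(tt$statistic), p_value = tt$p.value,
         n_severe = length(x), n_non_severe = length(y),
         mean_log10_severe = mean(x), mean_log10_non_severe = mean(y))
}

#' Nested linear-model test of a severity effect on log BMC
#'
#' Compares `log10(BMC) ~ log10(C-max)` (null) against
#' `log10(BMC) ~ log10(C-max) + severity` (full) with an F-test.
#'
#' @param log10_bmc log10 absolute BMC values (uncensored).
#' @param log10_cmax Matching log10 C-max values.
#' @param severity Matching class labels.
#' @return One-row tibble `f_statistic, p_value, df, n, coef_severity`.
#' @export
bmc_class_lm <- function(log10_bmc, log10_cmax, severity) {
  keep <- is.finite(log10_bmc) & is.finite(log10_cmax) &
    severity %in% c("severe", "non_severe")
  dat <- tibble(y = log10_bmc[keep], x = log10_cmax[keep],
                severity = factor(severity[keep],
                                  c("non_severe", "severe")))
  if (dplyr::n_distinct(dat$severity) < 2) {
    abort("severity has no variation; nested comparison undefined")
  }
  null_fit <- lm(y ~ x, data = dat)
  full_fit <- lm(y ~ x + severity, data = dat)
  an <- anova(null_fit, full_fit)
  tibble(f_statistic = an$F[2], p_value = an$`Pr(>F)`[2],
         df = an$Df[2], n = nrow(dat),
         coef_severity = unname(coef(full_fit)["severitysevere"]))
}

#' Per-reporter class statistics of the BMC table
#'
#' @param bmc BMC table from [bmc_table()].
#' @param annotations Annotation tibble (for severity and C-max).
#' @return Tibble with one row per reporter x descriptor: the Welch test
#'   on BMC / C-max and the nested linear-model test on absolute BMC.
#' @export
bmc_class_stats <- function(bmc, annotations) {
  ann <- annotations %>%
    mutate(severity = assign_severity(.data$dili_concern)) %>%
    select(compound = "abbreviation", "severity", "cmax_uM")
  joined <- bmc %>%
    select("compound", "reporter", "descriptor", "bmc_xcmax",
           "bmc_over_cmax", "censored") %>%
    left_join(ann, by = "compound") %>%
    filter(!.data$censored)
  joined %>%
    group_by(.data$reporter, .data$descriptor) %>%
    group_modify(function(g, key) {
      welch <- bmc_class_welch(g$bmc_over_cmax, g$severity)
      lmres <- tryCatch(
        bmc_class_lm(log10(g$bmc_xcmax * g$cmax_uM),
                     log10(g$cmax_uM), g$severity),
        error = function(e) tibble(f_statistic = NA_real_,
                                   p_value = NA_real_, df = NA,
                                   n = nrow(g), coef_severity = NA_real_)
      )
      bind_cols(welch,
                lmres %>% rename(lm_f = "f_statistic",
                                 lm_p = "p_value", lm_df = "df",
                                 lm_n = "n",
                                 lm_coef_severity = "coef_severity"))
    }) %>%
    ungroup()
}
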