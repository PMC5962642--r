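#' Plot descriptor time courses for one compound
#'
#' @param descriptors Long descriptor table.
#' @param compound Compound abbreviation.
#' @param descriptor Descriptor to show (default: headline fraction per
#'   reporter).
#' @return A ggplot object: one panel per reporter, colour per
#'   concentration, one line per replicate.
#' @export
plot_timecourse <- function(descriptors, compound, descriptor = NULL) {
  d <- descriptors %>% filter(.data$compound == !!compound)
  d <- if (is.null(descriptor)) {
    d %>% filter((.data$reporter != "ICAM1" &
                    .data$descriptor == "frac_2m") |
                   (.data$reporter == "ICAM1" &
                      .data$descriptor == "icam_diff_2"))
  } else {
    d %>% filter(.data$descriptor == !!descriptor)
  }
  ggplot(d, aes(x = .data$time_h, y = .data$value,
                colour = factor(.data$conc_xcmax),
                group = interaction(.data$conc_xcmax,
                                    .data$replicate_id))) +
    geom_line(alpha = 0.8) +
    facet_wrap(~reporter, scales = "free_y") +
    labs(x = "time (h)", y = "descriptor value",
         colour = "conc (x C-max)", title = compound) +
    theme_bw()
}

#' @export
autoplot.curve_fit_4pl <- function(object, ...) {
  dat <- object$data
  grid <- tibble(
    conc_xcmax = exp(seq(log(min(dat$conc_xcmax)),
                         log(max(dat$conc_xcmax)), length.out = 200))
  )
  grid$response <- if (object$b_identifiable) {
    ll4(grid$conc_xcmax, object$b, object$c, object$d, object$e)
  } else {
    rep(object$c, nrow(grid))
  }
  ggplot(dat, aes(x = .data$conc_xcmax, y = .data$response)) +
    geom_point(size = 2) +
    geom_line(data = grid, colour = "steelblue") +
    scale_x_log10() +
    labs(x = "concentration (x C-max)", y = "response",
         title = "four-parameter log-logistic fit") +
    theme_bw()
}

#' BMC versus C-max scatter per reporter
#'
#' @param bmc BMC table from [bmc_table()].
#' @param annotations Annotation tibble (for severity).
#' @return A ggplot object of absolute BMC against C-max, coloured by
#'   severity, one panel per reporter; censored compounds are omitted.
#' @export
plot_bmc_cmax <- function(bmc, annotations) {
  ann <- annotations %>%
    mutate(severity = assign_severity(.data$dili_concern)) %>%
    select(compound = "abbreviation", "severity")
  d <- bmc %>%
    filter(!.data$censored) %>%
    left_join(ann, by = "compound")
  ggplot(d, aes(x = .data$cmax_uM, y = .data$bmc_uM,
                colour = .data$severity)) +
    geom_point(alpha = 0.8) +
    scale_x_log10() + scale_y_log10() +
    facet_wrap(~reporter) +
    labs(x = "C-max (uM)", y = "BMC (uM)", colour = "DILI class") +
    theme_bw()
}

#' @export
autoplot.dili_svm_runs <- function(object, ...) {
  ggplot(object$runs, aes(x = .data$test_auc)) +
    geom_histogram(bins = 20, fill = "steelblue", colour = "white") +
    geom_vline(xintercept = object$summary$mean_auc,
               linetype = "dashed") +
    labs(x = "test-set ROC AUC", y = "iterations",
         title = sprintf("mean AUC %.3f over %d iterations",
                         object$summary$mean_auc,
                         object$summary$n_iter)) +
    theme_bw()
}
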