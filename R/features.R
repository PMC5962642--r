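# trapezoidal area under a sampled curve
trapezoid_auc <- function(time, value) {
  sum(diff(time) * (head(value, -1) + value[-1]) / 2)
}

# summary statistics of one condensed 24-point course
course_stats <- function(time, value, early_cut_h = 8) {
  i <- which.max(abs(value))
  early <- time <= early_cut_h
  late <- time >= early_cut_h
  tibble(
    max_mag = value[i],
    t_max = time[i],
    auc = trapezoid_auc(time, value),
    early_slope = feature_slope(value[early], time[early]),
    late_slope = feature_slope(value[late], time[late])
  )
}

#' Assemble the per-compound feature matrix for DILI classification
#'
#' Builds, for every non-control compound, the dynamic and
#' concentration-response features the classifier consumes:
#' \itemize{
#'   \item per reporter x descriptor x concentration, from the
#'     spline-condensed replicate-mean course: maximum magnitude, time of
#'     maximum, trapezoid area under the curve, early (0-8 h) and late
#'     (8-24 h) ordinary least-squares slopes;
#'   \item per concentration: control-subtracted cell-death fraction and
#'     cell-count / speed / nuclear-size / Hoechst slopes, averaged over
#'     the induction-reporter plates, plus the TNFa-background cell-death
#'     fraction from the ICAM1 plates;
#'   \item per reporter: log10 BMC/C-max and log10 absolute BMC (censored
#'     values imputed at the maximum tested concentration with a companion
#'     indicator feature);
#'   \item log10 C-max.
#' }
#' Compounds missing a reporter course get zero-imputed course features
#' and a per-reporter missingness indicator.
#'
#' @param descriptors Scaled long descriptor table.
#' @param cytotox Cytotoxicity summary from [cytotox_summary()].
#' @param bmc BMC table from [bmc_table()].
#' @param annotations Annotation tibble.
#' @param feature_descriptors Course descriptors to extract (default:
#'   `frac_2m` and `intensity_mean` for induction reporters,
#'   `icam_diff_2` and `intensity_mean` for ICAM1).
#' @param n_points,df Spline condensation settings.
#' @param early_cut_h Boundary between early and late slopes (h).
#' @return Wide tibble (`compound` + numeric features) with attribute
#'   `"manifest"`, a tibble describing each feature's family.
#' @export
extract_dynamic_features <- function(descriptors, cytotox, bmc,
                                     annotations,
                                     feature_descriptors =
                                       c("frac_2m", "icam_diff_2",
                                         "intensity_mean"),
                                     n_points = 24, df = 8,
                                     early_cut_h = 8) {
  drugs <- annotations %>% filter(!.data$is_control)

  course <- descriptors %>%
    filter(.data$descriptor %in% feature_descriptors) %>%
    group_by(.data$compound, .data$reporter, .data$conc_xcmax,
             .data$descriptor) %>%
    group_modify(function(g, key) {
      cc <- condense_course(g, n_points = n_points, df = df)
      course_stats(cc$time_h, cc$value, early_cut_h = early_cut_h)
    }) %>%
    ungroup() %>%
    tidyr::pivot_longer(cols = c("max_mag", "t_max", "auc",
                                 "early_slope", "late_slope"),
                        names_to = "stat", values_to = "value") %>%
    mutate(feature = paste(.data$reporter, .data$descriptor,
                           paste0("c", .data$conc_xcmax), .data$stat,
                           sep = "_"))

  # reporter coverage -> missingness indicators
  coverage <- tidyr::expand_grid(compound = drugs$abbreviation,
                                 reporter = unique(descriptors$reporter)) %>%
    left_join(course %>% distinct(.data$compound, .data$reporter) %>%
                mutate(seen = 1),
              by = c("compound", "reporter")) %>%
    mutate(value = if_else(is.na(.data$seen), 1, 0),
           feature = paste0(.data$reporter, "_missing")) %>%
    select("compound", "feature", "value")

  course_wide <- course %>%
    select("compound", "feature", "value") %>%
    bind_rows(coverage)

  tox_long <- bind_rows(
    cytotox %>%
      filter(.data$reporter != "ICAM1") %>%
      group_by(.data$compound, .data$conc_xcmax) %>%
      summarise(celldeath = mean(.data$pi_fraction_norm),
                slope_cell_count = mean(.data$slope_cell_count),
                slope_speed = mean(.data$slope_speed),
                slope_nuclear_size = mean(.data$slope_nuclear_size),
                slope_hoechst = mean(.data$slope_hoechst),
                .groups = "drop") %>%
      tidyr::pivot_longer(cols = -c("compound", "conc_xcmax"),
                          names_to = "stat", values_to = "value") %>%
      mutate(feature = paste0(.data$stat, "_c", .data$conc_xcmax)),
    cytotox %>%
      filter(.data$reporter == "ICAM1") %>%
      select("compound", "conc_xcmax", value = "pi_fraction_norm") %>%
      mutate(feature = paste0("celldeath_tnfa_c", .data$conc_xcmax))
  ) %>%
    select("compound", "feature", "value")

  max_conc <- 100
  bmc_long <- bmc %>%
    filter(.data$descriptor %in% c("frac_2m", "icam_diff_2")) %>%
    mutate(
      bmc_imputed = if_else(.data$censored, max_conc, .data$bmc_xcmax),
      l10_bmc_cmax = log10(.data$bmc_imputed),
      l10_bmc_uM = log10(.data$bmc_imputed * .data$cmax_uM),
      flag = as.numeric(.data$censored)
    ) %>%
    select("compound", "reporter", "l10_bmc_cmax", "l10_bmc_uM",
           "flag") %>%
    tidyr::pivot_longer(cols = c("l10_bmc_cmax", "l10_bmc_uM", "flag"),
                        names_to = "stat", values_to = "value") %>%
    mutate(feature = case_when(
      .data$stat == "l10_bmc_cmax" ~ paste0(.data$reporter,
                                            "_log10_bmc_cmax"),
      .data$stat == "l10_bmc_uM" ~ paste0(.data$reporter,
                                          "_log10_bmc_uM"),
      TRUE ~ paste0(.data$reporter, "_bmc_censored")
    )) %>%
    select("compound", "feature", "value")

  cmax_long <- drugs %>%
    transmute(compound = .data$abbreviation,
              feature = "log10_cmax",
              value = log10(.data$cmax_uM))

  long <- bind_rows(course_wide, tox_long, bmc_long, cmax_long) %>%
    filter(.data$compound %in% drugs$abbreviation)

  wide <- long %>%
    tidyr::pivot_wider(names_from = "feature", values_from = "value") %>%
    arrange(match(.data$compound, drugs$abbreviation))
  # zero-impute course features of missing reporters (flagged above)
  wide <- wide %>%
    mutate(across(-"compound", ~ if_else(is.na(.x) | !is.finite(.x),
                                         0, .x)))

  manifest <- tibble(feature = setdiff(names(wide), "compound")) %>%
    mutate(family = case_when(
      grepl("_missing$", .data$feature) ~ "missingness",
      grepl("^celldeath_tnfa", .data$feature) ~ "cytotox_tnfa",
      grepl("^celldeath", .data$feature) ~ "cytotox",
      grepl("^slope_", .data$feature) ~ "cytotox_slope",
      grepl("_bmc_censored$", .data$feature) ~ "bmc_censoring",
      grepl("_log10_bmc", .data$feature) ~ "bmc",
      .data$feature == "log10_cmax" ~ "cmax",
      grepl("_early_slope$|_late_slope$", .data$feature) ~
        "course_slope",
      grepl("_max_mag$|_t_max$", .data$feature) ~ "course_magnitude",
      grepl("_auc$", .data$feature) ~ "course_auc",
      TRUE ~ "other"
    ))
  attr(wide, "manifest") <- manifest
  wide
}

#' Severity labels aligned with a feature matrix
#'
#' @param features Feature tibble with a `compound` column.
#' @param annotations Annotation tibble.
#' @return Character vector of `"severe"` / `"non_severe"` labels in
#'   feature-row order.
#' @export
classifier_labels <- function(features, annotations) {
  ann <- annotations %>%
    mutate(severity = assign_severity(.data$dili_concern))
  sev <- setNames(ann$severity, ann$abbreviation)
  out <- unname(sev[features$compound])
  if (any(is.na(out) | out == "control")) {
    abort("feature matrix contains unannotated or control compounds")
  }
  out
}
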