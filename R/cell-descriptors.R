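#' Per-plate background control statistics
#'
#' Summarises the vehicle-control cells of each plate at each timepoint:
#' population mean and sd of GFP (background for the GFP-positive fraction
#' thresholds), linear-interpolation quartiles and IQR (fences for the
#' ICAM1 up/down fractions), and, at the final frame, the PI-positive
#' fraction.
#'
#' @param cells Per-cell record tibble (any mix of plates); control wells
#'   are identified by a non-missing `control_kind`.
#' @param min_cells Minimum control cells per timepoint before a warning is
#'   raised.
#' @return A tibble keyed by `plate_id`, `control_kind`, `time_h` with
#'   columns `mean_gfp`, `sd_gfp`, `q1_gfp`, `q3_gfp`, `iqr_gfp`,
#'   `n_cells`, `pi_positive_fraction` (final frame only, else `NA`).
#' @export
control_stats <- function(cells, min_cells = 20) {
  ctrl <- cells %>% filter(!is.na(.data$control_kind))
  if (nrow(ctrl) == 0) {
    abort("no control wells found; plate(s) unusable")
  }
  missing_plates <- setdiff(unique(cells$plate_id), unique(ctrl$plate_id))
  if (length(missing_plates) > 0) {
    abort(paste0("plate(s) without control wells: ",
                 paste(missing_plates, collapse = ", ")))
  }
  out <- ctrl %>%
    group_by(.data$plate_id, .data$control_kind, .data$time_h) %>%
    summarise(
      mean_gfp = mean(.data$gfp_intensity),
      sd_gfp = sd(.data$gfp_intensity),
      q1_gfp = quantile(.data$gfp_intensity, 0.25, names = FALSE, type = 7),
      q3_gfp = quantile(.data$gfp_intensity, 0.75, names = FALSE, type = 7),
      n_cells = dplyr::n(),
      pi_positive_fraction = if (all(is.na(.data$pi_overlap_area_px))) {
        NA_real_
      } else {
        mean(pi_flag(.data$pi_overlap_area_px, .data$nucleus_area_px))
      },
      .groups = "drop"
    ) %>%
    mutate(iqr_gfp = .data$q3_gfp - .data$q1_gfp,
           sd_gfp = if_else(is.na(.data$sd_gfp), 0, .data$sd_gfp))
  if (any(out$n_cells < min_cells)) {
    warn(paste0("some plate timepoints have fewer than ", min_cells,
                " control cells"))
  }
  out
}

#' GFP-positive fraction of a cell population
#'
#' Fraction of cells whose GFP intensity exceeds a background threshold
#' derived from the plate's vehicle controls: twice the control mean
#' (`"2m"`), three times the control mean (`"3m"`), or the control mean
#' plus three control standard deviations (`"m3sd"`).
#'
#' @param gfp Numeric vector of single-cell GFP intensities (>= 1 cell).
#' @param control_mean,control_sd Background control statistics.
#' @param rule One of `"2m"`, `"3m"`, `"m3sd"`.
#' @return Fraction in [0, 1].
#' @examples
#' frac_positive(c(90, 150, 210, 250, 400, 95, 100, 120, 180, 310), 100)
#' @export
frac_positive <- function(gfp, control_mean, control_sd = NULL,
                          rule = c("2m", "3m", "m3sd")) {
  rule <- match.arg(rule)
  if (length(gfp) == 0) abort("frac_positive needs at least one cell")
  thr <- switch(rule,
    "2m" = 2 * control_mean,
    "3m" = 3 * control_mean,
    "m3sd" = {
      if (is.null(control_sd)) abort("rule 'm3sd' needs control_sd")
      control_mean + 3 * control_sd
    }
  )
  mean(gfp > thr)
}

#' ICAM1 up/down fractions against TNFa control IQR fences
#'
#' Because the ICAM1 intensity distribution is skewed, responding cells are
#' counted against interquartile-range fences of the TNFa + DMSO control
#' population: up-responders above `Q3 + k * IQR`, down-responders below
#' `Q1 - k * IQR`, with `k` in 1.5, 2, 3.
#'
#' @param gfp Numeric vector of single-cell GFP intensities.
#' @param q1,q3,iqr TNFa control quartiles and IQR.
#' @param k Fence multiplier (1.5, 2 or 3).
#' @return A tibble with columns `up`, `down`, `diff` (`up - down`).
#' @export
icam_fractions <- function(gfp, q1, q3, iqr, k = c(1.5, 2, 3)) {
  k <- match.arg(as.character(k[1]), c("1.5", "2", "3"))
  k <- as.numeric(k)
  if (length(gfp) == 0) abort("icam_fractions needs at least one cell")
  up <- mean(gfp > q3 + k * iqr)
  down <- mean(gfp < q1 - k * iqr)
  tibble(up = up, down = down, diff = up - down)
}

#' Flag cells as dead from their PI/nucleus overlap
#'
#' A cell is dead when its propidium-iodide overlap area is at least 10%
#' of its nuclear area (boundary inclusive).
#'
#' @param pi_overlap_area_px PI overlap area (final frame; must not be NA).
#' @param nucleus_area_px Nuclear area.
#' @return Logical vector, `TRUE` = dead.
#' @export
pi_flag <- function(pi_overlap_area_px, nucleus_area_px) {
  if (any(is.na(pi_overlap_area_px))) {
    abort("pi_flag needs final-frame records with PI overlap present")
  }
  pi_overlap_area_px / nucleus_area_px >= 0.10
}

#' Control-subtracted PI-positive fraction
#'
#' @param treated_fraction PI-positive fraction of a treated well.
#' @param control_fraction PI-positive fraction of the matched vehicle
#'   control (DMSO, or TNFa + DMSO for ICAM1 plates).
#' @return Difference (may be negative).
#' @export
pi_fraction_normalized <- function(treated_fraction, control_fraction) {
  treated_fraction - control_fraction
}

#' Ordinary least-squares slope of a feature over time
#'
#' @param values Feature values.
#' @param times_h Matching times in hours (>= 3 points).
#' @return Slope per hour.
#' @examples
#' feature_slope(c(100, 110, 120, 130), 0:3)
#' @export
feature_slope <- function(values, times_h) {
  keep <- is.finite(values) & is.finite(times_h)
  values <- values[keep]; times_h <- times_h[keep]
  if (length(values) < 3) abort("feature_slope needs at least 3 timepoints")
  tc <- times_h - mean(times_h)
  sum(tc * (values - mean(values))) / sum(tc^2)
}

#' Min-max scale a descriptor series to [0, 1]
#'
#' Applies `(x - x_min) / (x_max - x_min)` with the minimum and maximum
#' taken over the descriptor's values across the whole replicate.  Fraction
#' descriptors are already in [0, 1] and bypass scaling upstream.
#'
#' @param values Numeric values.
#' @param x_min,x_max Replicate-wide extremes.
#' @return Scaled values; if `x_max == x_min` an all-zero series with a
#'   warning.
#' @export
scale_minmax <- function(values, x_min, x_max) {
  if (x_max <= x_min) {
    warn("degenerate descriptor range; returning all-zero series")
    return(rep(0, length(values)))
  }
  (values - x_min) / (x_max - x_min)
}

#' Maximum-over-time summary of a descriptor series
#'
#' For signed ICAM1 difference descriptors the signed extreme (largest
#' absolute value, keeping its sign) is taken, so suppression and
#' enhancement both register.
#'
#' @param values Descriptor values over time.
#' @param signed Take the signed extreme instead of the plain maximum.
#' @return Scalar summary.
#' @export
max_over_time <- function(values, signed = FALSE) {
  values <- values[is.finite(values)]
  if (length(values) == 0) abort("max_over_time needs a nonempty series")
  if (!signed) return(max(values))
  values[which.max(abs(values))]
}

# nearest-timepoint control lookup: for each requested plate/time pair pick
# the control-stat row of that plate with minimal |time difference|
nearest_control <- function(ctrl, plate_times) {
  purrr::map_dfr(seq_len(nrow(plate_times)), function(i) {
    p <- plate_times$plate_id[i]; t <- plate_times$time_h[i]
    cand <- ctrl[ctrl$plate_id == p, ]
    cand[which.min(abs(cand$time_h - t)), ] %>%
      mutate(time_h = t)
  })
}

#' Compute well-level descriptor time series from per-cell records
#'
#' Converts a per-cell table into the long descriptor table: for every
#' (compound, concentration, reporter, replicate, timepoint) the population
#' mean GFP intensity and, against the plate's matched-timepoint control
#' background, the GFP-positive fractions (2m / 3m / m3sd) for SRXN1, CHOP
#' and P21, or the IQR-fence up/down/difference fractions (k = 1.5, 2, 3)
#' for ICAM1.  If a timepoint lacks control cells the nearest control
#' timepoint on the same plate is used.
#'
#' @param cells Per-cell record tibble.
#' @return Long tibble `compound, conc_xcmax, reporter, replicate_id,
#'   descriptor, time_h, value` with `scaled = FALSE`.
#' @export
compute_descriptors <- function(cells) {
  ctrl <- control_stats(cells)
  treated <- cells %>% filter(is.na(.data$control_kind))
  if (nrow(treated) == 0) abort("no treated wells in cell table")
  need <- distinct(treated, .data$plate_id, .data$time_h)
  have <- distinct(ctrl, .data$plate_id, .data$time_h) %>%
    mutate(has_ctrl = TRUE)
  lookup <- need %>%
    left_join(have, by = c("plate_id", "time_h"))
  if (any(is.na(lookup$has_ctrl))) {
    miss <- lookup %>% filter(is.na(.data$has_ctrl)) %>%
      select("plate_id", "time_h")
    ctrl <- bind_rows(ctrl, nearest_control(ctrl, miss))
  }
  joined <- treated %>%
    left_join(ctrl %>% select("plate_id", "time_h", "mean_gfp", "sd_gfp",
                              "q1_gfp", "q3_gfp", "iqr_gfp"),
              by = c("plate_id", "time_h"))

  descriptor_summaries(joined, c("compound_abbrev", "conc_xcmax",
                                 "reporter", "replicate_id",
                                 "plate_id")) %>%
    rename(compound = "compound_abbrev") %>%
    mutate(scaled = FALSE) %>%
    arrange(.data$reporter, .data$compound, .data$conc_xcmax,
            .data$replicate_id, .data$descriptor, .data$time_h)
}

# well-level descriptor summaries against joined control background stats;
# shared by the treated-well and control-well drivers
descriptor_summaries <- function(joined, group_cols) {
  base <- joined %>% group_by(across(all_of(c(group_cols, "time_h"))))

  non_icam <- base %>%
    filter(.data$reporter != "ICAM1") %>%
    summarise(
      intensity_mean = mean(.data$gfp_intensity),
      frac_2m = mean(.data$gfp_intensity > 2 * .data$mean_gfp),
      frac_3m = mean(.data$gfp_intensity > 3 * .data$mean_gfp),
      frac_m3sd = mean(.data$gfp_intensity >
                         .data$mean_gfp + 3 * .data$sd_gfp),
      .groups = "drop"
    )

  icam <- base %>%
    filter(.data$reporter == "ICAM1") %>%
    summarise(
      intensity_mean = mean(.data$gfp_intensity),
      icam_up_1.5 = mean(.data$gfp_intensity >
                           .data$q3_gfp + 1.5 * .data$iqr_gfp),
      icam_down_1.5 = mean(.data$gfp_intensity <
                             .data$q1_gfp - 1.5 * .data$iqr_gfp),
      icam_up_2 = mean(.data$gfp_intensity >
                         .data$q3_gfp + 2 * .data$iqr_gfp),
      icam_down_2 = mean(.data$gfp_intensity <
                           .data$q1_gfp - 2 * .data$iqr_gfp),
      icam_up_3 = mean(.data$gfp_intensity >
                         .data$q3_gfp + 3 * .data$iqr_gfp),
      icam_down_3 = mean(.data$gfp_intensity <
                           .data$q1_gfp - 3 * .data$iqr_gfp),
      .groups = "drop"
    ) %>%
    mutate(icam_diff_1.5 = .data$icam_up_1.5 - .data$icam_down_1.5,
           icam_diff_2 = .data$icam_up_2 - .data$icam_down_2,
           icam_diff_3 = .data$icam_up_3 - .data$icam_down_3)

  id_cols <- c(group_cols, "time_h")
  bind_rows(
    if (nrow(non_icam) > 0) {
      tidyr::pivot_longer(non_icam, cols = -all_of(id_cols),
                          names_to = "descriptor", values_to = "value")
    },
    if (nrow(icam) > 0) {
      tidyr::pivot_longer(icam, cols = -all_of(id_cols),
                          names_to = "descriptor", values_to = "value")
    }
  )
}

#' Descriptor time courses of the control wells themselves
#'
#' Computes the same well-level descriptors for each vehicle-control well,
#' against its plate's pooled control background; these per-well control
#' courses form the comparison group of the functional ANOVA (controls are
#' pooled across all plates of a reporter to enlarge the permutation
#' space).
#'
#' @param cells Per-cell record tibble.
#' @return Long tibble `course_id, reporter, control_kind, descriptor,
#'   time_h, value`.
#' @export
control_descriptor_courses <- function(cells) {
  ctrl <- control_stats(cells)
  ctrl_cells <- cells %>% filter(!is.na(.data$control_kind))
  joined <- ctrl_cells %>%
    left_join(ctrl %>% select("plate_id", "time_h", "mean_gfp", "sd_gfp",
                              "q1_gfp", "q3_gfp", "iqr_gfp"),
              by = c("plate_id", "time_h"))
  descriptor_summaries(joined, c("plate_id", "well_id", "reporter",
                                 "control_kind")) %>%
    mutate(course_id = paste(.data$plate_id, .data$well_id, sep = "/")) %>%
    select("course_id", "reporter", "control_kind", "descriptor",
           "time_h", "value")
}

# descriptors that are fractions (already on a fixed scale)
is_fraction_descriptor <- function(descriptor) {
  grepl("^frac_|^icam_", descriptor)
}

#' Scale descriptor series for concentration-response analysis
#'
#' Intensity descriptors are min-max scaled to [0, 1] with extremes taken
#' per descriptor x reporter across all compounds, concentrations and
#' timepoints within a replicate (set `scope = "plate"` to scale within
#' each plate instead).  Fraction descriptors are already on a fixed scale
#' and bypass scaling.  The ICAM1 mean-intensity descriptor is scaled to
#' [-1, 1]: the TNFa control trajectory maps to 0 and the largest absolute
#' departure from it within the replicate maps to +/-1.
#'
#' @param descriptors Long descriptor table from [compute_descriptors()].
#' @param cells The originating per-cell table (needed for the ICAM1
#'   control trajectory).
#' @param scope `"replicate"` (default) or `"plate"`.
#' @return The descriptor table with `value` replaced by its scaled
#'   version, `scaled = TRUE`, and `raw_min` / `raw_max` columns recording
#'   the extremes used.
#' @export
scale_descriptors <- function(descriptors, cells,
                              scope = c("replicate", "plate")) {
  scope <- match.arg(scope)
  grp <- if (scope == "replicate") {
    c("reporter", "replicate_id", "descriptor")
  } else {
    c("reporter", "replicate_id", "descriptor", "plate_id")
  }

  frac <- descriptors %>%
    filter(is_fraction_descriptor(.data$descriptor)) %>%
    mutate(scaled = TRUE, raw_min = 0, raw_max = 1)

  inten <- descriptors %>%
    filter(!is_fraction_descriptor(.data$descriptor))

  non_icam <- inten %>%
    filter(.data$reporter != "ICAM1") %>%
    group_by(across(all_of(grp))) %>%
    mutate(raw_min = min(.data$value), raw_max = max(.data$value),
           value = if_else(rep(first(.data$raw_max) > first(.data$raw_min),
                               dplyr::n()),
                           (.data$value - .data$raw_min) /
                             (.data$raw_max - .data$raw_min),
                           rep(0, dplyr::n())),
           scaled = TRUE) %>%
    ungroup()

  icam <- inten %>% filter(.data$reporter == "ICAM1")
  if (nrow(icam) > 0) {
    ctrl_traj <- cells %>%
      filter(.data$reporter == "ICAM1", !is.na(.data$control_kind)) %>%
      group_by(.data$replicate_id, .data$time_h) %>%
      summarise(ctrl_gfp = mean(.data$gfp_intensity), .groups = "drop")
    icam <- icam %>%
      left_join(ctrl_traj, by = c("replicate_id", "time_h")) %>%
      group_by(across(all_of(grp))) %>%
      mutate(dev = .data$value - .data$ctrl_gfp,
             denom = max(abs(.data$dev)),
             raw_min = min(.data$value), raw_max = max(.data$value),
             value = if_else(rep(max(abs(.data$dev)) > 0, dplyr::n()),
                             .data$dev / max(abs(.data$dev)),
                             rep(0, dplyr::n())),
             scaled = TRUE) %>%
      ungroup() %>%
      select(-"ctrl_gfp", -"dev", -"denom")
  }
  bind_rows(frac, non_icam, icam) %>%
    arrange(.data$reporter, .data$compound, .data$conc_xcmax,
            .data$replicate_id, .data$descriptor, .data$time_h)
}

#' Maximum-over-time summaries per descriptor series
#'
#' Reduces each (compound, concentration, reporter, descriptor, replicate)
#' time course to its maximum over time (signed extreme for ICAM1
#' difference descriptors); these summaries feed the concentration-response
#' fits.
#'
#' @param descriptors Scaled long descriptor table.
#' @return Tibble with one `max_value` per series.
#' @export
max_over_time_table <- function(descriptors) {
  descriptors %>%
    group_by(.data$compound, .data$conc_xcmax, .data$reporter,
             .data$replicate_id, .data$descriptor) %>%
    summarise(
      max_value = max_over_time(.data$value,
                                signed = grepl("^icam_diff",
                                               first(.data$descriptor))),
      .groups = "drop"
    )
}

#' Cytotoxicity summaries per compound and concentration
#'
#' Per well: the PI-positive fraction at the final frame minus the matched
#' control fraction, and ordinary least-squares slopes over time of the
#' cell count (as a fraction of the initial count), the mean cell speed
#' (displacement per hour from consecutive positions), the mean nuclear
#' area and the mean Hoechst intensity.  Slopes are averaged over plates
#' (replicates) to give one summary per compound-concentration-reporter.
#'
#' @param cells Per-cell record tibble.
#' @return Tibble keyed by `compound, conc_xcmax, reporter` with columns
#'   `pi_fraction_norm`, `slope_cell_count`, `slope_speed`,
#'   `slope_nuclear_size`, `slope_hoechst`.
#' @export
cytotox_summary <- function(cells) {
  final_t <- max(cells$time_h)

  # per-cell hourly displacement (vectorized: rows sorted by trajectory,
  # lagged differences masked at trajectory boundaries)
  speed <- cells %>%
    arrange(.data$plate_id, .data$well_id, .data$cell_id, .data$time_h)
  nr <- nrow(speed)
  same_cell <- c(FALSE,
                 speed$plate_id[-1] == speed$plate_id[-nr] &
                   speed$well_id[-1] == speed$well_id[-nr] &
                   speed$cell_id[-1] == speed$cell_id[-nr])
  dxv <- c(NA, diff(speed$x_px))
  dyv <- c(NA, diff(speed$y_px))
  dtv <- c(NA, diff(speed$time_h))
  spd <- sqrt(dxv^2 + dyv^2) / dtv
  spd[!same_cell] <- NA
  speed$speed_px_h <- spd

  well_t <- speed %>%
    group_by(.data$plate_id, .data$well_id, .data$compound_abbrev,
             .data$conc_xcmax, .data$control_kind, .data$reporter,
             .data$replicate_id, .data$time_h) %>%
    summarise(n_cells = dplyr::n(),
              mean_speed = mean(.data$speed_px_h, na.rm = TRUE),
              mean_area = mean(.data$nucleus_area_px),
              mean_hoechst = mean(.data$hoechst_intensity),
              pi_frac = if (all(is.na(.data$pi_overlap_area_px))) {
                NA_real_
              } else {
                mean(pi_flag(.data$pi_overlap_area_px,
                             .data$nucleus_area_px))
              },
              .groups = "drop")

  well_slopes <- well_t %>%
    group_by(.data$plate_id, .data$well_id, .data$compound_abbrev,
             .data$conc_xcmax, .data$control_kind, .data$reporter,
             .data$replicate_id) %>%
    summarise(
      slope_cell_count = feature_slope(.data$n_cells /
                                         first(.data$n_cells),
                                       .data$time_h),
      slope_speed = feature_slope(.data$mean_speed, .data$time_h),
      slope_nuclear_size = feature_slope(.data$mean_area, .data$time_h),
      slope_hoechst = feature_slope(.data$mean_hoechst, .data$time_h),
      pi_frac = .data$pi_frac[.data$time_h == final_t][1],
      .groups = "drop"
    )

  ctrl_pi <- well_slopes %>%
    filter(!is.na(.data$control_kind)) %>%
    group_by(.data$plate_id) %>%
    summarise(ctrl_pi_frac = mean(.data$pi_frac), .groups = "drop")

  well_slopes %>%
    filter(is.na(.data$control_kind)) %>%
    left_join(ctrl_pi, by = "plate_id") %>%
    mutate(pi_norm = pi_fraction_normalized(.data$pi_frac,
                                            .data$ctrl_pi_frac)) %>%
    group_by(.data$compound_abbrev, .data$conc_xcmax, .data$reporter) %>%
    summarise(pi_fraction_norm = mean(.data$pi_norm),
              slope_cell_count = mean(.data$slope_cell_count),
              slope_speed = mean(.data$slope_speed),
              slope_nuclear_size = mean(.data$slope_nuclear_size),
              slope_hoechst = mean(.data$slope_hoechst),
              .groups = "drop") %>%
    rename(compound = "compound_abbrev")
}
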