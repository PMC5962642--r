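#' Simulation settings for the synthetic reporter screen
#'
#' Bundles every tunable of the synthetic-screen generator: the
#' class-dependent distributions that compound effect parameters are drawn
#' from, and the cell-level measurement model.  Concentrations are in
#' multiples of each compound's C-max throughout; times in hours.
#'
#' Class-effect defaults encode the screen's qualitative structure: severe-
#' DILI compounds activate reporters at lower C-max-normalised
#' concentrations (mean log10 point of departure 0.9 vs 1.6, sd 0.4,
#' truncated to the tested decade range [0, 2.3]) and are responsive and
#' cytotoxic with higher probability than non-severe compounds.
#'
#' @param mu_log10_bmc Named numeric, mean log10 true point of departure
#'   (in C-max multiples) per class.
#' @param sd_log10_bmc Standard deviation of the log10 draw.
#' @param log10_bmc_range Truncation range of the log10 draw.
#' @param responsive_prob Named numeric, probability that a compound
#'   induces a given reporter, per class.
#' @param emax_range Range of the uniform draw for the response plateau
#'   (scaled response units, within [0, 1]).
#' @param hill_range Range of the uniform Hill-coefficient draw.
#' @param t50_range_h Range of the half-maximal induction time draw (h).
#' @param onset_range Range of the onset-rate draw (per hour).
#' @param icam_multiplier_log_range Log-range of the ICAM1 modulation
#'   multiplier draw (<1 suppression, >1 enhancement of the TNFa ramp).
#' @param tox_prob Named numeric, probability that a compound is cytotoxic
#'   within the tested range, per class.
#' @param mu_log10_tox Named numeric, mean log10 death-threshold
#'   concentration per class (C-max multiples).
#' @param sd_log10_tox Standard deviation of the log10 tox-threshold draw.
#' @param log10_tox_range Truncation range of the tox-threshold draw.
#' @param death_rate Hazard scale (per hour per log10 concentration above
#'   the death threshold).
#' @param growth_rate Control proliferation rate (per hour).
#' @param noise_cv Per-cell lognormal coefficient of variation of GFP.
#' @param baseline_gfp Baseline GFP intensity (a.u.).
#' @param gfp_gain Fold-induction gain: mean GFP is
#'   `baseline_gfp * (1 + gfp_gain * response)`.
#' @param hoechst_mean,hoechst_cv Hoechst intensity model (a.u.).
#' @param nucleus_area_mean,nucleus_area_cv Nuclear area model (pixels).
#' @param tnfa_ramp_A,tnfa_ramp_tau_h TNFa-induced ICAM1 control ramp
#'   `r(t) = A * t / (t + tau)`.
#' @param motility_step_px Hourly random-walk step sd (pixels).
#' @param field_px Side of the square imaging field (pixels).
#' @return A list of settings with class `stressdyn_effect_config`.
#' @export
sim_effect_config <- function(
    mu_log10_bmc = c(severe = 0.9, non_severe = 1.6),
    sd_log10_bmc = 0.4,
    log10_bmc_range = c(0, 2.3),
    responsive_prob = c(severe = 0.8, non_severe = 0.45),
    emax_range = c(0.5, 0.9),
    hill_range = c(1.2, 3),
    t50_range_h = c(6, 14),
    onset_range = c(0.4, 1),
    icam_multiplier_log_range = log(c(0.3, 2.5)),
    tox_prob = c(severe = 0.6, non_severe = 0.3),
    mu_log10_tox = c(severe = 1.2, non_severe = 1.7),
    sd_log10_tox = 0.3,
    log10_tox_range = c(0.5, 2),
    death_rate = 0.1,
    growth_rate = 0.02,
    noise_cv = 0.3,
    baseline_gfp = 500,
    gfp_gain = 4,
    hoechst_mean = 1000,
    hoechst_cv = 0.2,
    nucleus_area_mean = 180,
    nucleus_area_cv = 0.15,
    tnfa_ramp_A = 0.8,
    tnfa_ramp_tau_h = 4,
    motility_step_px = 12,
    field_px = 500) {
  cfg <- as.list(environment())
  structure(cfg, class = "stressdyn_effect_config")
}

#' Plate layout settings for the synthetic screen
#'
#' One plate carries one reporter at one concentration (in C-max multiples);
#' every compound occupies one well and each plate additionally carries
#' vehicle-control wells (DMSO, or TNFa + DMSO on ICAM1 plates).  Hourly
#' frames over 24 h; propidium iodide is recorded at the final frame only.
#'
#' @param reporters Reporters to simulate.
#' @param concentrations Tested concentrations (C-max multiples).
#' @param replicates Number of biological replicates (plates) per
#'   reporter x concentration.
#' @param n_cells_0 Cells seeded per well.
#' @param hours Imaging time grid (h).
#' @param n_control_wells Control wells per plate.
#' @return A list of settings with class `stressdyn_layout_config`.
#' @export
sim_layout_config <- function(reporters = REPORTERS,
                              concentrations = CONC_LEVELS,
                              replicates = 3,
                              n_cells_0 = 200,
                              hours = 0:24,
                              n_control_wells = 4) {
  structure(as.list(environment()), class = "stressdyn_layout_config")
}

# Hill occupancy term: x^h / (x^h + e^h), computed on log scale for stability
hill_term <- function(x, e, h) {
  ifelse(x <= 0, 0, 1 / (1 + exp(-h * (log(x) - log(e)))))
}

# inverse-CDF draw from a normal truncated to [lo, hi]
rtruncnorm <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(pmin(pmax(mean, lo), hi), n))
  plo <- pnorm(lo, mean, sd)
  phi <- pnorm(hi, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

# analytic mean of a normal truncated to [lo, hi]; oracle for draw tests
truncnorm_mean <- function(mean, sd, lo, hi) {
  a <- (lo - mean) / sd
  b <- (hi - mean) / sd
  mean + sd * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
}

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Draw ground-truth effect parameters for one compound
#'
#' Samples, per reporter, whether the compound induces the reporter, its
#' true point of departure (log10, class-dependent truncated normal), the
#' Hill steepness, induction timing, ICAM1 modulation multiplier and the
#' cytotoxicity threshold.
#'
#' @param annotation A single-row annotation tibble (non-control compound).
#' @param effect_config Settings from [sim_effect_config()].
#' @param rng_seed Integer seed; the draw is deterministic given the seed.
#' @return A tibble with one row per reporter (columns `abbreviation`,
#'   `severity`, `reporter`, `responsive`, `emax`, `bmc_true_xcmax`,
#'   `hill`, `t50_h`, `onset_rate`, `icam_multiplier`, `tox_conc_xcmax`).
#' @export
draw_compound_params <- function(annotation,
                                 effect_config = sim_effect_config(),
                                 rng_seed = NULL) {
  if (nrow(annotation) != 1) abort("draw_compound_params takes one row")
  if (isTRUE(annotation$is_control)) {
    abort("control compounds carry no effect parameters")
  }
  cfg <- effect_config
  cls <- assign_severity(annotation$dili_concern)
  with_seed(rng_seed, {
    nr <- length(REPORTERS)
    responsive <- runif(nr) < cfg$responsive_prob[[cls]]
    l10bmc <- rtruncnorm(nr, cfg$mu_log10_bmc[[cls]], cfg$sd_log10_bmc,
                         cfg$log10_bmc_range[1], cfg$log10_bmc_range[2])
    emax <- runif(nr, cfg$emax_range[1], cfg$emax_range[2])
    hill <- runif(nr, cfg$hill_range[1], cfg$hill_range[2])
    t50 <- runif(nr, cfg$t50_range_h[1], cfg$t50_range_h[2])
    onset <- runif(nr, cfg$onset_range[1], cfg$onset_range[2])
    icam_mult <- exp(runif(nr, cfg$icam_multiplier_log_range[1],
                           cfg$icam_multiplier_log_range[2]))
    icam_mult[REPORTERS != "ICAM1"] <- 1
    icam_mult[REPORTERS == "ICAM1" & !responsive] <- 1
    is_toxic <- runif(1) < cfg$tox_prob[[cls]]
    tox <- if (is_toxic) {
      10^rtruncnorm(1, cfg$mu_log10_tox[[cls]], cfg$sd_log10_tox,
                    cfg$log10_tox_range[1], cfg$log10_tox_range[2])
    } else Inf
    tibble(
      abbreviation = annotation$abbreviation,
      severity = cls,
      reporter = REPORTERS,
      responsive = responsive,
      emax = if_else(responsive, emax, 0),
      bmc_true_xcmax = 10^l10bmc,
      hill = hill,
      t50_h = t50,
      onset_rate = onset,
      icam_multiplier = icam_mult,
      tox_conc_xcmax = tox
    )
  })
}

# Population mean scaled response of one well over the time grid.
# Non-ICAM reporters follow emax * Hill(conc) * logistic onset; ICAM1 wells
# follow the TNFa ramp multiplied by a Hill-modulated ICAM1 multiplier.
well_mean_response <- function(params, conc_xcmax, reporter, hours, cfg,
                               is_control = FALSE) {
  if (reporter == "ICAM1") {
    ramp <- cfg$tnfa_ramp_A * hours / (hours + cfg$tnfa_ramp_tau_h)
    if (is_control || is.null(params)) return(ramp)
    hx <- hill_term(conc_xcmax, params$bmc_true_xcmax, params$hill)
    mult <- 1 + (params$icam_multiplier - 1) *
      (if (isTRUE(params$responsive)) hx else 0)
    return(ramp * mult)
  }
  if (is_control || is.null(params) || !isTRUE(params$responsive)) {
    return(rep(0, length(hours)))
  }
  hx <- hill_term(conc_xcmax, params$bmc_true_xcmax, params$hill)
  params$emax * hx / (1 + exp(-params$onset_rate * (hours - params$t50_h)))
}

#' Mean scaled response implied by ground-truth parameters
#'
#' Analytic population mean response used by the generator, exposed so that
#' parameter-recovery tests can compute truth without re-deriving the model.
#'
#' @param params One row of a truth table from [draw_compound_params()].
#' @param conc_xcmax Concentration (C-max multiples); 0 gives the control.
#' @param hours Time grid (h).
#' @param effect_config Settings from [sim_effect_config()].
#' @return Numeric vector of mean scaled responses along `hours`.
#' @export
sim_mean_response <- function(params, conc_xcmax, hours = 0:24,
                              effect_config = sim_effect_config()) {
  well_mean_response(as.list(params), conc_xcmax, params$reporter[[1]],
                     hours, effect_config,
                     is_control = identical(conc_xcmax, 0))
}

# death hazard per hour; zero at/below the threshold, increasing above
death_hazard <- function(conc_xcmax, tox_conc_xcmax, death_rate) {
  if (!is.finite(tox_conc_xcmax) || conc_xcmax <= tox_conc_xcmax) return(0)
  death_rate * log10(conc_xcmax / tox_conc_xcmax)
}

#' Simulate the per-cell records of one well
#'
#' Generates hourly single-cell GFP and Hoechst intensities, nuclear areas,
#' positions (a random walk, slowed by toxicity) and, at the final frame,
#' propidium-iodide overlap areas.  Dead cells stop moving, shrink, show
#' condensed (brighter) Hoechst signal and receive a PI overlap of at least
#' 10% of their nuclear area; the population grows at the control rate
#' reduced under toxicity.
#'
#' @param params One-row list/tibble of effect parameters for this
#'   compound-reporter (from [draw_compound_params()]); `NULL` for control
#'   wells.
#' @param conc_xcmax Concentration in C-max multiples (0 for controls).
#' @param reporter Reporter of the plate.
#' @param n_cells_0 Cells seeded in the well (must be positive).
#' @param hours Time grid (h).
#' @param effect_config Settings from [sim_effect_config()].
#' @param rng_seed Optional integer seed; `NULL` continues the current RNG
#'   stream (used for plate-level substreams).
#' @param control_kind `NA` for treated wells, else `"DMSO"` or
#'   `"TNFa_DMSO"`.
#' @param plate_id,well_id,replicate_id,compound_abbrev Identifiers copied
#'   into the records.
#' @return A tibble of per-cell, per-frame records.
#' @export
simulate_well <- function(params, conc_xcmax, reporter,
                          n_cells_0 = 200, hours = 0:24,
                          effect_config = sim_effect_config(),
                          rng_seed = NULL,
                          control_kind = NA_character_,
                          plate_id = "P1", well_id = "W01",
                          replicate_id = 1L,
                          compound_abbrev = NULL) {
  if (!is.numeric(n_cells_0) || n_cells_0 <= 0) {
    abort("n_cells_0 must be a positive integer")
  }
  if (!reporter %in% REPORTERS) abort("unknown reporter")
  is_ctrl <- !is.na(control_kind)
  if (!is_ctrl && !conc_xcmax %in% CONC_LEVELS) {
    abort("treated wells must use a tested concentration")
  }
  cfg <- effect_config
  if (!is.null(params)) params <- as.list(params)
  if (is.null(compound_abbrev)) {
    compound_abbrev <- if (is_ctrl) control_kind else params$abbreviation
  }
  with_seed(rng_seed, {
    nt <- length(hours)
    m <- well_mean_response(params, conc_xcmax, reporter, hours, cfg,
                            is_control = is_ctrl)
    lam <- if (is_ctrl || is.null(params)) 0 else {
      death_hazard(conc_xcmax, params$tox_conc_xcmax, cfg$death_rate)
    }
    g_eff <- cfg$growth_rate * exp(-2 * lam)
    births_cum <- floor(n_cells_0 * (exp(g_eff * (hours - hours[1])) - 1))
    n_tot <- n_cells_0 + births_cum[nt]
    birth_frame <- c(rep(1L, n_cells_0),
                     rep(seq_len(nt)[-1], diff(births_cum)))
    death_t <- if (lam > 0) stats::rexp(n_tot, lam) else rep(Inf, n_tot)
    present <- outer(birth_frame, seq_len(nt), "<=")
    alive <- outer(death_t, hours - hours[1], ">")

    # GFP: mean trajectory x multiplicative lognormal cell/frame noise
    mean_gfp <- cfg$baseline_gfp * (1 + cfg$gfp_gain * m)
    sig <- sqrt(log(1 + cfg$noise_cv^2))
    noise <- if (sig > 0) {
      matrix(stats::rlnorm(n_tot * nt, -sig^2 / 2, sig), n_tot, nt)
    } else matrix(1, n_tot, nt)
    gfp <- sweep(noise, 2, mean_gfp, "*")

    # Hoechst and nuclear area: per-cell baselines; corpses condense/shrink
    sig_h <- sqrt(log(1 + cfg$hoechst_cv^2))
    hoechst0 <- stats::rlnorm(n_tot, log(cfg$hoechst_mean) - sig_h^2 / 2,
                              sig_h)
    sig_a <- sqrt(log(1 + cfg$nucleus_area_cv^2))
    area0 <- stats::rlnorm(n_tot, log(cfg$nucleus_area_mean) - sig_a^2 / 2,
                           sig_a)
    hoechst <- hoechst0 * ifelse(alive, 1, 1.4)
    area <- area0 * ifelse(alive, 1, 0.7)

    # positions: random walk, step reduced by toxicity, frozen after death
    step_sd <- cfg$motility_step_px * exp(-4 * lam)
    dx <- matrix(rnorm(n_tot * nt, 0, step_sd), n_tot, nt) * alive
    dy <- matrix(rnorm(n_tot * nt, 0, step_sd), n_tot, nt) * alive
    dx[, 1] <- runif(n_tot, 0, cfg$field_px)
    dy[, 1] <- runif(n_tot, 0, cfg$field_px)
    x <- t(apply(dx, 1, cumsum))
    y <- t(apply(dy, 1, cumsum))

    # PI overlap at the final frame only
    dead_final <- !alive[, nt]
    pi_ratio <- ifelse(dead_final, runif(n_tot, 0.10, 0.8),
                       runif(n_tot, 0, 0.05))
    pi_area <- matrix(NA_real_, n_tot, nt)
    pi_area[, nt] <- pi_ratio * area[, nt]

    idx <- which(present)
    row_i <- ((idx - 1) %% n_tot) + 1
    col_i <- ((idx - 1) %/% n_tot) + 1
    tibble(
      plate_id = plate_id,
      well_id = well_id,
      compound_abbrev = compound_abbrev,
      conc_xcmax = if (is_ctrl) 0 else conc_xcmax,
      control_kind = control_kind,
      reporter = reporter,
      replicate_id = as.integer(replicate_id),
      time_h = hours[col_i],
      cell_id = row_i,
      gfp_intensity = gfp[idx],
      hoechst_intensity = hoechst[idx],
      nucleus_area_px = area[idx],
      pi_overlap_area_px = pi_area[idx],
      x_px = x[idx],
      y_px = y[idx]
    )
  })
}

#' Simulate a full synthetic reporter screen
#'
#' Lays out one plate per reporter x concentration x replicate; each plate
#' carries one well per non-control compound plus vehicle-control wells
#' (DMSO, or TNFa + DMSO on ICAM1 plates).  Effect parameters are drawn
#' once per compound; plates use deterministic seed substreams
#' (`rng_seed + plate index`) so the screen is byte-reproducible from the
#' single master seed.
#'
#' @param annotations Annotation tibble from [read_compound_table()]
#'   (controls are ignored for treated wells; control wells are always
#'   simulated).
#' @param effect_config Settings from [sim_effect_config()].
#' @param layout_config Settings from [sim_layout_config()].
#' @param rng_seed Integer master seed.
#' @return A list with class `stressdyn_screen`: `cells` (per-cell record
#'   tibble), `truth` (ground-truth parameter tibble, one row per
#'   compound x reporter) and `plates` (plate layout tibble).
#' @export
simulate_screen <- function(annotations,
                            effect_config = sim_effect_config(),
                            layout_config = sim_layout_config(),
                            rng_seed = 1L) {
  validate_compound_table(annotations)
  lay <- layout_config
  drugs <- annotations[!annotations$is_control, , drop = FALSE]
  truth <- purrr::map2_dfr(
    seq_len(nrow(drugs)), drugs$abbreviation,
    function(i, ab) {
      draw_compound_params(drugs[i, , drop = FALSE], effect_config,
                           rng_seed = rng_seed + 100000L + i)
    }
  )
  plates <- tidyr::expand_grid(
    reporter = lay$reporters,
    conc_xcmax = lay$concentrations,
    replicate_id = seq_len(lay$replicates)
  ) %>%
    mutate(plate_index = row_number(),
           plate_id = sprintf("%s_c%03d_r%d", .data$reporter,
                              .data$conc_xcmax, .data$replicate_id))
  cells <- purrr::map_dfr(seq_len(nrow(plates)), function(p) {
    pl <- plates[p, ]
    ctrl_kind <- if (pl$reporter == "ICAM1") "TNFa_DMSO" else "DMSO"
    with_seed(rng_seed + pl$plate_index, {
      treated <- purrr::map_dfr(seq_len(nrow(drugs)), function(i) {
        pars <- truth %>%
          filter(.data$abbreviation == drugs$abbreviation[i],
                 .data$reporter == pl$reporter)
        simulate_well(pars, pl$conc_xcmax, pl$reporter,
                      n_cells_0 = lay$n_cells_0, hours = lay$hours,
                      effect_config = effect_config, rng_seed = NULL,
                      plate_id = pl$plate_id,
                      well_id = sprintf("W%03d", i),
                      replicate_id = pl$replicate_id)
      })
      ctrls <- purrr::map_dfr(seq_len(lay$n_control_wells), function(j) {
        simulate_well(NULL, 0, pl$reporter,
                      n_cells_0 = lay$n_cells_0, hours = lay$hours,
                      effect_config = effect_config, rng_seed = NULL,
                      control_kind = ctrl_kind,
                      plate_id = pl$plate_id,
                      well_id = sprintf("C%03d", j),
                      replicate_id = pl$replicate_id)
      })
      bind_rows(treated, ctrls)
    })
  })
  structure(list(cells = cells, truth = truth, plates = plates,
                 effect_config = effect_config,
                 layout_config = lay, rng_seed = rng_seed),
            class = "stressdyn_screen")
}

#' @export
print.stressdyn_screen <- function(x, ...) {
  cat("Synthetic reporter screen\n")
  cat("  plates:", nrow(x$plates),
      " wells:", dplyr::n_distinct(paste(x$cells$plate_id, x$cells$well_id)),
      " cell-frames:", nrow(x$cells), "\n")
  cat("  compounds:", dplyr::n_distinct(x$truth$abbreviation),
      " reporters:", paste(unique(x$plates$reporter), collapse = ", "), "\n")
  invisible(x)
}

#' Write / read a per-cell table as delimited text
#'
#' @param cells Per-cell record tibble.
#' @param path CSV path.
#' @return `path` (write) or the cell tibble (read).
#' @export
write_cell_table <- function(cells, path) {
  utils::write.csv(cells, path, row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_cell_table
#' @export
read_cell_table <- function(path) {
  as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
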