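test_that("effect parameter draws are class-structured and seeded", {
  ann <- read_compound_table()
  sev_row <- ann[ann$abbreviation == "APAP", ]
  ctrl_row <- ann[ann$abbreviation == "DMSO", ]
  expect_error(draw_compound_params(ctrl_row), "control")

  p1 <- draw_compound_params(sev_row, rng_seed = 11)
  p2 <- draw_compound_params(sev_row, rng_seed = 11)
  expect_identical(p1, p2)
  expect_equal(nrow(p1), 4)
  expect_true(all(p1$bmc_true_xcmax > 0))
  expect_true(all(p1$icam_multiplier[p1$reporter != "ICAM1"] == 1))

  # zero spread pins the draw at the class mean
  cfg0 <- sim_effect_config(sd_log10_bmc = 0)
  p0 <- draw_compound_params(sev_row, cfg0, rng_seed = 3)
  expect_equal(p0$bmc_true_xcmax,
               rep(10^cfg0$mu_log10_bmc[["severe"]], 4))
})

test_that("log10 BMC draws match the truncated-normal oracle", {
  cfg <- sim_effect_config()
  ann <- read_compound_table()
  sev_row <- ann[ann$abbreviation == "APAP", ]
  ns_row <- ann[ann$abbreviation == "BET", ]
  n_draw <- 2500 # compounds x 4 reporters = 10000 draws per class
  draws <- function(row, offset) {
    unlist(lapply(seq_len(n_draw), function(i) {
      log10(draw_compound_params(row, cfg,
                                 rng_seed = offset + i)$bmc_true_xcmax)
    }))
  }
  d_sev <- draws(sev_row, 0)
  d_ns <- draws(ns_row, 500000)
  mu_s <- stressdyn:::truncnorm_mean(cfg$mu_log10_bmc[["severe"]],
                                     cfg$sd_log10_bmc, 0, 2.3)
  mu_ns <- stressdyn:::truncnorm_mean(cfg$mu_log10_bmc[["non_severe"]],
                                      cfg$sd_log10_bmc, 0, 2.3)
  se <- sqrt(var(d_sev) / length(d_sev) + var(d_ns) / length(d_ns))
  expect_lt(abs((mean(d_sev) - mean(d_ns)) - (mu_s - mu_ns)), 3 * se)
})

test_that("well simulation honours the response model limits", {
  cfg <- sim_effect_config(noise_cv = 0)
  pars <- tibble::tibble(
    abbreviation = "X", severity = "severe", reporter = "SRXN1",
    responsive = TRUE, emax = 0.8, bmc_true_xcmax = 10, hill = 2,
    t50_h = 8, onset_rate = 0.8, icam_multiplier = 1,
    tox_conc_xcmax = Inf
  )
  expect_error(simulate_well(pars, 10, "SRXN1", n_cells_0 = 0),
               "positive")

  # half-maximal occupancy at the true point of departure, late plateau
  resp <- sim_mean_response(pars, 10, hours = c(0, 1e6), effect_config = cfg)
  expect_equal(resp[2], 0.4, tolerance = 1e-9)
  # vanishing concentration leaves baseline GFP exactly (noiseless)
  w <- simulate_well(pars, 0, "SRXN1", n_cells_0 = 25, hours = 0:24,
                     effect_config = cfg, rng_seed = 5,
                     control_kind = "DMSO")
  expect_true(all(abs(w$gfp_intensity - cfg$baseline_gfp) < 1e-9))

  # noiseless treated well follows baseline * (1 + gain * m) exactly
  wt <- simulate_well(pars, 50, "SRXN1", n_cells_0 = 25, hours = 0:24,
                      effect_config = cfg, rng_seed = 5)
  m <- sim_mean_response(pars, 50, hours = 0:24, effect_config = cfg)
  expected <- cfg$baseline_gfp * (1 + cfg$gfp_gain * m)
  got <- dplyr::distinct(wt, time_h, gfp_intensity)
  expect_equal(got$gfp_intensity, expected[match(got$time_h, 0:24)],
               tolerance = 1e-9)
})

test_that("ICAM1 multiplier of one reproduces the TNFa control ramp", {
  cfg <- sim_effect_config(noise_cv = 0)
  pars <- tibble::tibble(
    abbreviation = "X", severity = "severe", reporter = "ICAM1",
    responsive = TRUE, emax = 0.8, bmc_true_xcmax = 5, hill = 2,
    t50_h = 8, onset_rate = 0.8, icam_multiplier = 1,
    tox_conc_xcmax = Inf
  )
  treated <- sim_mean_response(pars, 100, hours = 0:24,
                               effect_config = cfg)
  ramp <- cfg$tnfa_ramp_A * (0:24) / (0:24 + cfg$tnfa_ramp_tau_h)
  expect_equal(treated, ramp, tolerance = 1e-12)

  pars$icam_multiplier <- 0.4
  supp <- sim_mean_response(pars, 100, hours = 0:24, effect_config = cfg)
  expect_true(all(supp[-1] < ramp[-1]))
})

test_that("death fraction is nondecreasing in concentration", {
  haz <- vapply(c(1, 5, 10, 50, 100), stressdyn:::death_hazard,
                numeric(1), tox_conc_xcmax = 8, death_rate = 0.1)
  expect_true(all(diff(haz) >= 0))
  expect_equal(haz[1:2], c(0, 0)) # at or below the threshold no death

  pars <- tibble::tibble(
    abbreviation = "X", severity = "severe", reporter = "SRXN1",
    responsive = FALSE, emax = 0, bmc_true_xcmax = 10, hill = 2,
    t50_h = 8, onset_rate = 0.8, icam_multiplier = 1,
    tox_conc_xcmax = 8
  )
  dead_frac <- vapply(c(10, 100), function(conc) {
    w <- simulate_well(pars, conc, "SRXN1", n_cells_0 = 400,
                       hours = 0:24, rng_seed = 21)
    fin <- w[w$time_h == 24, ]
    mean(pi_flag(fin$pi_overlap_area_px, fin$nucleus_area_px))
  }, numeric(1))
  expect_gt(dead_frac[2], dead_frac[1])
})

test_that("screen layout and determinism contracts hold", {
  ann <- tiny_annotations(c("APAP", "BET"))
  lay <- sim_layout_config(reporters = c("SRXN1", "ICAM1"),
                           concentrations = c(1, 100), replicates = 2,
                           n_cells_0 = 15, n_control_wells = 2)
  s1 <- simulate_screen(ann, layout_config = lay, rng_seed = 9)
  s2 <- simulate_screen(ann, layout_config = lay, rng_seed = 9)
  expect_identical(s1$cells, s2$cells)
  expect_identical(s1$truth, s2$truth)
  expect_equal(nrow(s1$plates), 2 * 2 * 2)
  expect_equal(nrow(s1$truth), 2 * 4) # per compound x reporter
  # ICAM1 plates carry TNFa-background controls, others DMSO
  kinds <- dplyr::distinct(s1$cells[!is.na(s1$cells$control_kind), ],
                           reporter, control_kind)
  expect_equal(kinds$control_kind[kinds$reporter == "ICAM1"],
               "TNFa_DMSO")
  expect_equal(kinds$control_kind[kinds$reporter == "SRXN1"], "DMSO")
  # PI present exactly at the final frame
  expect_true(all(is.na(s1$cells$pi_overlap_area_px[
    s1$cells$time_h < 24])))
  expect_true(all(!is.na(s1$cells$pi_overlap_area_px[
    s1$cells$time_h == 24])))
})

test_that("control-well positive fractions match the lognormal tail", {
  cfg <- sim_effect_config() # noise_cv = 0.3
  w <- simulate_well(NULL, 0, "SRXN1", n_cells_0 = 8000, hours = 0,
                     effect_config = cfg, rng_seed = 77,
                     control_kind = "DMSO")
  sig <- sqrt(log(1 + cfg$noise_cv^2))
  # analytic tail mass beyond 2x the population mean
  p2m <- 1 - plnorm(2 * cfg$baseline_gfp,
                    log(cfg$baseline_gfp) - sig^2 / 2, sig)
  obs <- frac_positive(w$gfp_intensity, cfg$baseline_gfp, rule = "2m")
  se <- sqrt(p2m * (1 - p2m) / nrow(w))
  expect_lt(abs(obs - p2m), 3 * se + 1e-6)
})
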