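# shared fixtures, built once per test run

suppressPackageStartupMessages({
  library(dplyr)
  library(withr)
})

memo <- local({
  cache <- list()
  function(key, build) {
    if (is.null(cache[[key]])) cache[[key]] <<- build()
    cache[[key]]
  }
})

# small subset of the packaged annotation table (mixed classes + controls)
tiny_annotations <- function(abbrevs = c("APAP", "TRG", "DCF", "BET",
                                         "MF", "WAR")) {
  ann <- read_compound_table()
  dplyr::bind_rows(
    ann[ann$abbreviation %in% abbrevs, ],
    ann[ann$is_control, ]
  )
}

# one small simulated screen shared by descriptor/feature tests
tiny_screen <- function() {
  memo("tiny_screen", function() {
    simulate_screen(
      tiny_annotations(),
      layout_config = sim_layout_config(replicates = 2, n_cells_0 = 40,
                                        n_control_wells = 3),
      rng_seed = 424L
    )
  })
}

tiny_descriptors <- function() {
  memo("tiny_descriptors", function() {
    scr <- tiny_screen()
    raw <- compute_descriptors(scr$cells)
    list(raw = raw,
         scaled = scale_descriptors(raw, scr$cells),
         controls = control_descriptor_courses(scr$cells),
         cytotox = cytotox_summary(scr$cells))
  })
}

# hand-built per-cell records for unit-level descriptor tests
make_cells <- function(gfp, time_h = 0, plate_id = "P1", well_id = "W1",
                       compound = "CMP", conc = 10, reporter = "SRXN1",
                       replicate_id = 1L, control_kind = NA_character_,
                       nucleus_area = 100, pi_overlap = NA_real_) {
  n <- length(gfp)
  tibble::tibble(
    plate_id = plate_id, well_id = well_id,
    compound_abbrev = compound,
    conc_xcmax = if (!is.na(control_kind)) 0 else conc,
    control_kind = control_kind,
    reporter = reporter, replicate_id = replicate_id,
    time_h = time_h, cell_id = seq_len(n),
    gfp_intensity = gfp,
    hoechst_intensity = 1000,
    nucleus_area_px = nucleus_area,
    pi_overlap_area_px = pi_overlap,
    x_px = 0, y_px = 0
  )
}

# separable synthetic feature matrix for classifier unit tests
make_feature_matrix <- function(n_per_class = 30, n_noise = 20,
                                shift = 2, seed = 1) {
  withr::with_seed(seed, {
    n <- 2 * n_per_class
    labels <- rep(c("severe", "non_severe"), each = n_per_class)
    info1 <- rnorm(n) + ifelse(labels == "severe", shift, 0)
    info2 <- rnorm(n) - ifelse(labels == "severe", shift, 0)
    noise <- matrix(rnorm(n * n_noise), n)
    colnames(noise) <- paste0("noise_", seq_len(n_noise))
    feats <- tibble::as_tibble(noise) %>%
      dplyr::mutate(compound = paste0("CMP", seq_len(n)),
                    info_up = info1, info_down = info2,
                    .before = 1)
    list(features = feats, labels = labels)
  })
}
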