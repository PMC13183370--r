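test_that("cohort generation is deterministic and controls emit no USVs", {
  cfg <- cohort_config(list(region_spec("R", c(1, 2), 20)), master_seed = 11)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$cells, b$cells)
  expect_identical(a$mice, b$mice)
  expect_true(all(a$mice$usv_count[a$mice$group == "no-exposure"] == 0))
  expect_true(all(a$mice$usv_count[a$mice$group == "female-exposure"] >= 0))
})

test_that("within-series section spacing equals thickness times series count", {
  cfg <- cohort_config(list(region_spec("R", c(-1, 1), 20)), master_seed = 3)
  expect_equal(cfg$section_spacing_um, 360)
  coh <- generate_cohort(cfg)
  for (mid in coh$mice$mouse_id) {
    b <- sort(unique(coh$cells$bregma_mm[coh$cells$mouse_id == mid]))
    if (length(b) > 1) expect_equal(diff(b), rep(0.360, length(b) - 1))
  }
})

test_that("invalid configurations are rejected with a message", {
  expect_error(region_spec("R", c(1, 2), -5), "baseline_density")
  expect_error(region_spec("R", c(1, 2), 5, usv_coupling = 1.2), "usv_coupling")
  expect_error(region_spec("R", c(1, 2), 5, roi_area_mm2 = 0), "roi_area_mm2")
  expect_error(cohort_config(list(region_spec("R", c(1, 2), 5)), n_exposed = 2),
               ">= 3 mice")
})

test_that("null-model cohorts are marked unrelated in the truth ledger", {
  regions <- list(region_spec("a", c(1, 2), 15), region_spec("b", c(0, 1), 25))
  coh <- generate_cohort(cohort_config(regions, master_seed = 4))
  expect_true(all(vapply(coh$truth, `[[`, "", "category") == "unrelated"))
})

test_that("place_cells follows the Poisson density model", {
  poly <- unit_square  # 1 mm^2
  set.seed(42)
  counts <- replicate(1000, sum(place_cells(poly, 20)$channel == "tdTomato"))
  # Poisson(20): 95% CI on the mean of 1000 draws is +/- 0.28
  expect_lt(abs(mean(counts) - 20), 1.5)
  expect_equal(nrow(place_cells(poly, 0, cfos_density = 0)), 0)
  expect_error(place_cells(rbind(c(0, 0), c(1, 1), c(2, 2)), 10), "area")
})

test_that("forced reactivation pairs every tdTomato cell within 2 um", {
  set.seed(9)
  tab <- place_cells(unit_square, 50, cfos_density = 0, reactivation_prob = 1)
  td <- tab[tab$channel == "tdTomato", ]
  fos <- tab[tab$channel == "cFos", ]
  expect_equal(nrow(td), nrow(fos))
  d <- sqrt(outer(td$x_um, fos$x_um, "-")^2 + outer(td$y_um, fos$y_um, "-")^2)
  expect_true(all(apply(d, 1, min) <= 2))
})

test_that("the coupling construction recovers its target correlation", {
  rs <- vapply(1:40, function(s) {
    reg <- region_spec("R", c(1.5, 2.2), 20, exposure_multiplier = 1.5,
                       usv_coupling = 0.9)
    coh <- suppressWarnings(
      generate_cohort(cohort_config(list(reg), master_seed = s)))
    coh$truth$R$realized_r
  }, 0)
  expect_lt(abs(mean(rs) - 0.9), 0.15)
})

test_that("uncoupled regions rarely reach the strong-correlation bar", {
  hits <- vapply(1:60, function(s) {
    reg <- region_spec("R", c(1.5, 2.2), 20)
    coh <- generate_cohort(cohort_config(list(reg), master_seed = s + 2000))
    abs(coh$truth$R$realized_r) < 0.7
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("cohort fixtures round-trip through the plain-text writers", {
  coh <- generate_cohort(cohort_config(list(region_spec("R", c(1, 2), 25)),
                                       master_seed = 8))
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  mice <- read.csv(file.path(dir, "mice.csv"))
  expect_equal(mice$usv_count, coh$mice$usv_count)
  rois <- read_roi_geojson(file.path(dir, "rois.geojson"))
  expect_length(rois, 2)  # two hemispheres for one region
  expect_equal(sum(vapply(rois, `[[`, 0, "area_mm2")), 1, tolerance = 1e-6)
  cells <- read.csv(file.path(dir, sprintf("cells_%s.csv", coh$mice$mouse_id[1])))
  expect_equal(nrow(cells), sum(coh$cells$mouse_id == coh$mice$mouse_id[1]))
})

test_that("synthetic audio matches its truth ledger by construction", {
  spec0 <- usv_audio_spec(data.frame(start_s = numeric(0), duration_s = numeric(0),
                                     f_start_khz = numeric(0), f_end_khz = numeric(0),
                                     amplitude_db = numeric(0)))
  set.seed(1)
  au0 <- generate_usv_audio(spec0)
  expect_equal(nrow(au0$truth_events), 0)
  expect_lt(max(abs(au0$waveform)), 10^(-60 / 20) * 6)  # pure noise

  spec1 <- usv_audio_spec(data.frame(start_s = 0.05, duration_s = 0.05,
                                     f_start_khz = 70, f_end_khz = 70,
                                     amplitude_db = -40))
  au1 <- generate_usv_audio(spec1)
  expect_equal(au1$truth_events$end_s - au1$truth_events$start_s, 0.05)
  expect_equal(au1$truth_events$f_start_khz, au1$truth_events$f_end_khz)

  expect_error(generate_usv_audio(
    usv_audio_spec(data.frame(start_s = 0, duration_s = 0.01, f_start_khz = 70,
                              f_end_khz = 140, amplitude_db = -40),
                   sample_rate_hz = 250000)), "Nyquist")
})

test_that("striatal sections hit the striosome fraction and stay inside the CP", {
  set.seed(21)
  sec <- generate_striatal_section(striatal_section_spec())
  frac <- sum(vapply(sec$striosomes, polygon_area, 0)) / polygon_area(sec$cp_polygon)
  expect_gte(frac, 0.09); expect_lte(frac, 0.15)
  for (sp in sec$striosomes)
    expect_true(all(points_in_polygon(sp[, 1], sp[, 2], sec$cp_polygon)))
  # zero fraction: no mask, every cell is matrix
  sec0 <- generate_striatal_section(striatal_section_spec(striosome_fraction = 0))
  expect_length(sec0$striosomes, 0)
  expect_true(all(sec0$cells$compartment == "matrix"))
})

test_that("striosome/matrix density couplings are recovered from sections", {
  set.seed(77)
  tot <- c(s_n = 0, s_a = 0, m_n = 0, m_a = 0)
  for (i in 1:50) {
    sec <- generate_striatal_section(
      striatal_section_spec(striosome_coupling = 2, matrix_coupling = 1,
                            base_density = 10))
    cd <- compartment_density(sec$cells, sec$partition, sec$striosomes)
    tot <- tot + c(sum(cd$n_cells[cd$compartment == "striosome"]),
                   sum(cd$area_mm2[cd$compartment == "striosome"]),
                   sum(cd$n_cells[cd$compartment == "matrix"]),
                   sum(cd$area_mm2[cd$compartment == "matrix"]))
  }
  ratio <- (tot["s_n"] / tot["s_a"]) / (tot["m_n"] / tot["m_a"])
  expect_gte(ratio, 1.6); expect_lte(ratio, 2.4)
})

test_that("impossible blob packing errors with advice", {
  expect_error(generate_striatal_section(
    striatal_section_spec(striosome_fraction = 0.45,
                          striosome_blob_radius_um = 700)),
    "smaller")
})
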