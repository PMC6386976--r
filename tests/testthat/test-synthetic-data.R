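# Synthetic instrument + canopy generator.

test_that("vegetation endmember has the canonical green-peak/red-edge shape", {
  wl <- native_grid()
  veg <- make_vegetation_endmember(wl, nir_plateau = 0.45, green_peak = 0.12,
                                   red_edge = 715)
  at <- function(x) veg[which.min(abs(wl - x))]
  expect_lt(at(670), at(550))   # red trough below green peak
  expect_lt(at(550), at(800))   # green peak below NIR plateau
  expect_true(all(veg >= 0 & veg <= 1))
  # continuity: no jumps between adjacent native bands
  expect_lt(max(abs(diff(veg))), 0.05)
  # red-edge inflection (max first difference) near the nominal position
  infl <- wl[which.max(diff(veg))]
  expect_gte(infl, 700)
  expect_lte(infl, 730)
})

test_that("all-zero endmember parameters give an all-dark spectrum", {
  veg <- make_vegetation_endmember(nir_plateau = 0, green_peak = 0)
  expect_true(all(veg == 0))
})

test_that("endmember parameters are validated", {
  expect_error(make_vegetation_endmember(nir_plateau = 1.2), "nir_plateau")
  expect_error(make_vegetation_endmember(red_edge = 650), "red_edge")
  expect_error(canopy_model(veg = rep(1.5, 513)), "0, 1")
})

test_that("fractional cover follows the saturating overlap law", {
  can <- canopy_model(cover_coefficient = c(V1 = 0.03, V3 = 0.05))
  expect_identical(fractional_cover(0, "V1", can), 0)
  # closed form: 1 - exp(-0.03 * 30)
  expect_equal(fractional_cover(30, "V1", can), 1 - exp(-0.9), tolerance = 1e-12)
  p <- seq(0, 200, by = 0.5)
  f <- fractional_cover(p, "V1", can)
  expect_true(all(diff(f) >= 0))          # monotone
  expect_true(all(diff(diff(f)) < 0))     # strictly concave for k = 1
  expect_gt(fractional_cover(1e4, "V1", can), 0.999)
  # larger cover coefficient dominates at every population
  expect_true(all(fractional_cover(p, "V3", can) >=
                    fractional_cover(p, "V1", can)))
  expect_error(fractional_cover(-1, "V1", can), "nonnegative")
  expect_error(fractional_cover(10, "V9", can), "unknown stage")
})

test_that("canopy reflectance is the exact soil-vegetation mixture", {
  can <- canopy_model()
  expect_equal(canopy_reflectance(0, can), can$soil)
  expect_equal(canopy_reflectance(1, can), can$veg)
  expect_equal(canopy_reflectance(0.5, can), (can$veg + can$soil) / 2)
  r <- canopy_reflectance(0.3, can)
  expect_true(all(r >= pmin(can$veg, can$soil) - 1e-12 &
                    r <= pmax(can$veg, can$soil) + 1e-12))
})

test_that("noise-free sequences round-trip through radiometry at any scale", {
  # high full well: the property under test is the ratio arithmetic, not
  # the saturation physics, and scale 20 would saturate the default sensor
  sens <- noise_free_sensor(full_well = 1e9)
  refl <- random_reflectance(3)
  tm <- throughput_model()
  for (scale in c(0.05, 0.3, 1, 5, 20)) {
    sq <- simulate_sequence(refl, fixed_illum("cloudy", scale), sens, seed = 9)
    r <- relative_reflectance(sq, tm)
    expect_lt(max(abs(r$values - refl) / pmax(refl, 1e-12)), 1e-10)
  }
})

test_that("a pure illumination magnitude change scales counts, not reflectance", {
  sens <- noise_free_sensor(full_well = 1e9)
  refl <- random_reflectance(4)
  sq1 <- simulate_sequence(refl, fixed_illum("sunny", 1), sens, seed = 5)
  sq5 <- simulate_sequence(refl, fixed_illum("sunny", 5), sens, seed = 5)
  net1 <- sq1$frames$up_target$counts - sq1$frames$up_dark$counts
  net5 <- sq5$frames$up_target$counts - sq5$frames$up_dark$counts
  expect_equal(net5, 5 * net1, tolerance = 1e-12)
  tm <- throughput_model()
  expect_equal(relative_reflectance(sq1, tm)$values,
               relative_reflectance(sq5, tm)$values, tolerance = 1e-12)
})

test_that("shot-noise recovery is unbiased over replicate sequences", {
  sens <- sensor_model(shot_noise = TRUE, dark_sd = 5)
  refl <- random_reflectance(6)
  tm <- throughput_model()
  n <- 200L
  vals <- vapply(seq_len(n), function(i) {
    sq <- simulate_sequence(refl, fixed_illum("sunny", 1), sens,
                            seed = derive_seed(77, i))
    relative_reflectance(sq, tm)$values
  }, numeric(length(refl)))
  m <- rowMeans(vals)
  se <- apply(vals, 1L, sd) / sqrt(n)
  z <- abs(m - refl) / se
  expect_gte(mean(z <= 2), 0.90)  # ~95% of bands expected inside 2 SE
  expect_lt(max(z), 5)
})

test_that("sequence simulation is deterministic in its seed", {
  sens <- sensor_model()
  refl <- random_reflectance(8)
  il <- illumination_model("cloudy")
  expect_identical(simulate_sequence(refl, il, sens, seed = 123),
                   simulate_sequence(refl, il, sens, seed = 123))
  a <- simulate_sequence(refl, il, sens, seed = 123)
  b <- simulate_sequence(refl, il, sens, seed = 124)
  expect_false(identical(a$frames$up_target$counts,
                         b$frames$up_target$counts))
})

test_that("degenerate illumination is rejected", {
  sens <- noise_free_sensor()
  dark_il <- illumination_model("sunny",
                                base_irradiance = function(wl) numeric(length(wl)))
  expect_error(simulate_sequence(random_reflectance(1), dark_il, sens, seed = 1),
               "degenerate")
})

test_that("saturating signal is re-drawn and flagged, and QC rejects it", {
  # tiny full well forces saturation whatever the integration time
  sens <- sensor_model(full_well = 1000, gain = 200, shot_noise = FALSE,
                       dark_sd = 0)
  sq <- simulate_sequence(random_reflectance(2), fixed_illum("sunny", 1),
                          sens, seed = 3)
  expect_true(sq$frames$down_target$saturated)
  expect_true(all(sq$frames$down_target$counts <= sens$full_well))
  qc <- sequence_qc(sq)
  expect_false(qc$pass)
  expect_true("saturated" %in% qc$flags)
  expect_error(relative_reflectance(sq), "saturated")
})

test_that("trial generation honours the factorial design", {
  des <- trial_design(samples_per_row = 2L, rows_per_plot = 2L, seed = 42)
  tr <- generate_trial(des, neutral_canopy(), noise_free_sensor(),
                       list(sunny = fixed_illum("sunny", 1),
                            cloudy = fixed_illum("cloudy", 0.3)))
  expect_equal(nrow(tr$plots), 896L)                       # 2*4*2*2*2*14
  expect_equal(sum(tr$plots$stage == "V2"), 224L)
  expect_equal(length(tr$sequences), 896L * 4L)
  expect_true(all(table(vapply(tr$sequences, `[[`, "", "plot_id")) == 4L))
  # condition schedule: rep 1 sunny at V1, rep 2 sunny at V3, cloudy elsewhere
  expect_true(all(tr$plots$condition[tr$plots$replicate == 1 &
                                       tr$plots$stage == "V1"] == "sunny"))
  expect_true(all(tr$plots$condition[tr$plots$replicate == 2 &
                                       tr$plots$stage == "V3"] == "sunny"))
  expect_equal(sum(tr$plots$condition == "sunny"), 224L)
})

test_that("perfect emergence makes measured population equal seeding rate", {
  des <- trial_design(replicates = 1L, stages = "V3",
                      emergence_mean = 1, emergence_sd = 0,
                      samples_per_row = 1L, rows_per_plot = 1L, seed = 2,
                      condition_schedule = data.frame(
                        replicate = 1L, stage = "V3", condition = "cloudy"))
  tr <- generate_trial(des, neutral_canopy(), noise_free_sensor(),
                       list(cloudy = fixed_illum("cloudy", 0.3)))
  expect_equal(tr$plots$measured_population, tr$plots$seeding_rate)
})

test_that("trial generation is a pure function of design and seed", {
  des <- trial_design(replicates = 1L, stages = "V1",
                      samples_per_row = 1L, rows_per_plot = 1L, seed = 31,
                      condition_schedule = data.frame(
                        replicate = 1L, stage = "V1", condition = "sunny"))
  t1 <- generate_trial(des)
  t2 <- generate_trial(des)
  expect_identical(t1$plots, t2$plots)
  expect_identical(t1$truth, t2$truth)
  expect_identical(t1$sequences, t2$sequences)
})

test_that("mean NIR reflectance is nondecreasing in population (noise off)", {
  des <- trial_design(replicates = 1L, stages = c("V1", "V3"),
                      emergence_mean = 1, emergence_sd = 0,
                      samples_per_row = 1L, rows_per_plot = 1L, seed = 8,
                      condition_schedule = data.frame(
                        replicate = 1L, stage = c("V1", "V3"),
                        condition = "cloudy"))
  tr <- generate_trial(des, neutral_canopy(), noise_free_sensor(),
                       list(cloudy = fixed_illum("cloudy", 0.3)))
  wl <- native_grid()
  nir <- rowMeans(tr$truth[, wl >= 760 & wl <= 900])
  for (st in c("V1", "V3")) {
    idx <- tr$plots$stage == st
    ord <- order(tr$plots$measured_population[idx])
    expect_true(all(diff(nir[idx][ord]) >= -1e-12))
  }
})

test_that("trial design validation catches bad inputs", {
  expect_error(trial_design(seeding_rates = 1:10), "14 strictly increasing")
  expect_error(trial_design(condition_schedule = data.frame(
    replicate = 1L, stage = "V1", condition = "cloudy")), "cover every")
})

test_that("sequence CSV round-trips byte-identically", {
  sens <- sensor_model(shot_noise = TRUE)
  sqs <- lapply(1:3, function(i)
    simulate_sequence(random_reflectance(i), illumination_model("cloudy"),
                      sens, seed = i, sequence_id = sprintf("s%d", i),
                      plot_id = "pA", row_index = 1L))
  path <- withr::local_tempfile(fileext = ".csv")
  write_sequences_csv(sqs, path)
  back <- read_sequences_csv(path)
  expect_length(back, 3L)
  for (i in 1:3) {
    expect_equal(back[[i]]$frames$up_target$counts,
                 sqs[[i]]$frames$up_target$counts)
    expect_equal(back[[i]]$frames$down_dark$integration_time,
                 sqs[[i]]$frames$down_dark$integration_time)
    expect_identical(back[[i]]$sequence_id, sqs[[i]]$sequence_id)
  }
})
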