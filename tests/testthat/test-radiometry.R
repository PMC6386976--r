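# Radiometric correction: dark subtraction, the reflectance equation, QC.

test_that("dark subtraction is elementwise and preserves negatives", {
  t_fr <- mini_frame("up", FALSE, 14, c(100, 200))
  d_fr <- mini_frame("up", TRUE, 14, c(10, 20))
  net <- dark_subtract(t_fr, d_fr)
  expect_equal(as.numeric(net), c(90, 180))

  same <- dark_subtract(mini_frame("up", FALSE, 14, c(10, 20)), d_fr)
  expect_equal(as.numeric(same), c(0, 0))

  # dark exceeding target: value retained (not clamped), band flagged
  dk <- raw_frame("up", TRUE, 14, 1:10, c(100, rep(10, 9)))
  tg <- raw_frame("up", FALSE, 14, 1:10, c(10, rep(12, 9)))
  net <- dark_subtract(tg, dk)
  expect_equal(net[1], -90)
  expect_true(1 %in% attr(net, "negative_flags"))
})

test_that("frame pairing is validated", {
  t_fr <- mini_frame("up", FALSE, 14, c(100, 200))
  expect_error(dark_subtract(t_fr, mini_frame("down", TRUE, 14, c(1, 2))),
               "channels")
  expect_error(dark_subtract(t_fr, mini_frame("up", TRUE, 13, c(1, 2))),
               "integration times")
  expect_error(dark_subtract(t_fr, mini_frame("up", TRUE, 14, c(1, 2),
                                              wl = c(500, 601))),
               "grids")
  expect_error(dark_subtract(t_fr, t_fr), "dark frame")
})

test_that("the reflectance equation reproduces hand-computed values", {
  tm <- throughput_model(400, 600, K = 1)   # g_down/g_up = 2.25
  # equal nets, equal times, equal throughput -> R = 1
  r1 <- relative_reflectance(
    mini_sequence(c(50, 50), c(50, 50), it_up = 10, it_down = 10),
    throughput_model(throughput_ratio_override = 1))
  expect_equal(r1$values, c(1, 1), tolerance = 1e-12)
  # up 50 @ 15 ms vs down 200 @ 5 ms with area ratio 2.25:
  # (50/15) / (200/(5*2.25)) = 0.1875
  r2 <- relative_reflectance(mini_sequence(c(50, 50), c(200, 200)), tm)
  expect_equal(r2$values, c(0.1875, 0.1875), tolerance = 1e-12)
})

test_that("reflectance is invariant to joint scaling of both channels", {
  tm <- throughput_model()
  base <- relative_reflectance(mini_sequence(c(40, 80), c(160, 240)), tm)
  for (c_scale in c(0.01, 0.7, 1, 13, 250)) {
    sc <- relative_reflectance(
      mini_sequence(c_scale * c(40, 80), c_scale * c(160, 240)), tm)
    expect_equal(sc$values, base$values, tolerance = 1e-12)
  }
})

test_that("integration-time normalisation compensates proportional counts", {
  tm <- throughput_model()
  a <- relative_reflectance(mini_sequence(c(60, 90), c(200, 300),
                                          it_up = 14), tm)
  b <- relative_reflectance(mini_sequence(c(30, 45), c(200, 300),
                                          it_up = 7), tm)
  expect_equal(a$values, b$values, tolerance = 1e-12)
})

test_that("reflectance matches generator ground truth on noise-free sequences", {
  tm <- throughput_model()
  sens <- noise_free_sensor(full_well = 1e9)
  for (i in 1:10) {
    refl <- random_reflectance(100 + i)
    scale <- local_seed_draw(200 + i, runif(1, 0.05, 20))
    sq <- simulate_sequence(refl, fixed_illum("cloudy", scale), sens,
                            seed = 300 + i)
    r <- relative_reflectance(sq, tm)
    expect_lt(max(abs(r$values - refl) / pmax(refl, 1e-12)), 1e-10)
  }
})

test_that("weak downwelling signal becomes missing with a flag", {
  r <- relative_reflectance(mini_sequence(c(50, 50), c(0.5, 200)),
                            throughput_model(), min_irradiance = 1)
  expect_true(is.na(r$values[1]))
  expect_equal(r$band_flags$low_irradiance, 1L)
  expect_false(is.na(r$values[2]))
  expect_error(relative_reflectance(mini_sequence(c(5, 5), c(0.5, 0.2)),
                                    throughput_model()),
               "degenerate")
})

test_that("bands outside 400-900 nm are flagged as detector edges", {
  sens <- noise_free_sensor()
  sq <- simulate_sequence(random_reflectance(9), fixed_illum("sunny", 1),
                          sens, seed = 4)
  r <- relative_reflectance(sq, throughput_model())
  wl <- r$wavelengths
  expect_identical(r$band_flags$edge, which(wl < 400 | wl > 900))
})

test_that("sequence QC passes clean data and catches operator errors", {
  sens <- noise_free_sensor()
  sq <- simulate_sequence(random_reflectance(11), fixed_illum("sunny", 1),
                          sens, seed = 6)
  qc <- sequence_qc(sq)
  expect_true(qc$pass)
  expect_length(qc$flags, 0L)

  # upwelling pair duplicated wholesale into the downwelling slots: the
  # throughput-corrected ratio collapses to g_down/g_up = 2.25 > ceiling
  up_t <- sq$frames$up_target
  up_d <- sq$frames$up_dark
  dup <- measurement_sequence(list(
    up_dark = up_d,
    up_target = up_t,
    down_target = raw_frame("down", FALSE, up_t$integration_time,
                            up_t$wavelengths, up_t$counts),
    down_dark = raw_frame("down", TRUE, up_d$integration_time,
                          up_d$wavelengths, up_d$counts)))
  qc2 <- sequence_qc(dup)
  expect_false(qc2$pass)
  expect_true("implausible_ratio" %in% qc2$flags)

  # out-of-range integration time
  bad_it <- sequence_qc(sq, limits = qc_limits(it_up_range = c(1, 2)))
  expect_false(bad_it$pass)
  expect_true("integration_time" %in% bad_it$flags)
})

test_that("negative net irradiance over many bands fails QC", {
  wl <- native_grid()
  n <- length(wl)
  dark <- rep(100, n)
  down <- dark + c(rep(-5, 100), rep(50, n - 100))  # 19% of bands negative
  sq <- measurement_sequence(list(
    up_dark = raw_frame("up", TRUE, 14, wl, rep(10, n)),
    up_target = raw_frame("up", FALSE, 14, wl, rep(20, n)),
    down_target = raw_frame("down", FALSE, 5, wl, down),
    down_dark = raw_frame("down", TRUE, 5, wl, dark)))
  qc <- sequence_qc(sq)
  expect_false(qc$pass)
  expect_true("negative_irradiance" %in% qc$flags)
})
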