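# Response-pipeline algebra on synthetic (closed-form) curves; the full
# device-coupled pipeline is exercised in the dual-polarity and
# KD-recovery tests.

langmuir_fraction_curve <- function(i_of_f, n = 21) {
  f <- seq(0, 1, length.out = n)
  response_curve(f, "fraction", i_of_f(f))
}

test_that("calibration composes the fraction curve with the Langmuir map", {
  kd <- 1.47e-9
  m <- binding_model(kd)
  curve_f <- langmuir_fraction_curve(function(f) 1e-9 * (1 - 0.4 * f))
  conc <- c(0, kd, 1e6 * kd)
  cal <- calibration_curve(curve_f, m, conc)
  expect_equal(cal$current[1], 1e-9)                     # f = 0 endpoint
  expect_equal(cal$current[2], 1e-9 * (1 - 0.2),
               tolerance = 1e-9)                         # f = 0.5 at c = KD
  expect_equal(cal$current[3], 1e-9 * 0.6, tolerance = 1e-5)  # saturation
  short <- response_curve(seq(0, 1, 0.5), "fraction", c(1, 2, 3) * 1e-9)
  expect_error(calibration_curve(short, m, conc), ">= 11")
  part <- response_curve(seq(0.2, 1, length.out = 12), "fraction",
                         seq(1, 2, length.out = 12) * 1e-9)
  expect_error(calibration_curve(part, m, conc), "outside")
})

test_that("relative response recovers closed-form suppression metrics", {
  kd <- 1e-9
  m <- binding_model(kd)
  conc <- c(0, 10^seq(-11, -6, by = 0.1))
  i0 <- 2e-9
  cur <- i0 * (1 - 0.5 * bound_fraction(conc, m))
  rs <- relative_response(response_curve(conc, "concentration", cur))
  expect_equal(rs$i0, i0)
  expect_equal(rs$max_relative_response, 0.5, tolerance = 1e-3)
  expect_equal(rs$response_sign, "suppression")
  # |dI/I0| = 0.5 f(c): half its max at f = 0.5, i.e. exactly c = KD
  expect_equal(rs$half_response_concentration, kd, tolerance = 0.02)
})

test_that("relative response handles enhancement and degenerate input", {
  flat <- response_curve(c(0, 1e-9), "concentration", c(1e-9, 1e-9))
  expect_equal(relative_response(flat)$max_relative_response, 0)
  enh <- response_curve(c(0, 1e-9), "concentration", c(1e-9, 2e-9))
  rs <- relative_response(enh)
  expect_equal(rs$max_relative_response, 1)
  expect_equal(rs$response_sign, "enhancement")
  zero <- response_curve(c(0, 1e-9), "concentration", c(0, 1e-9))
  expect_error(relative_response(zero), "baseline")
})

test_that("response magnitude saturates beyond 10 KD", {
  kd <- 1e-9
  m <- binding_model(kd)
  conc <- c(0, 10^seq(-11, -6, by = 0.25))
  cur <- 1e-9 * (1 + 0.8 * bound_fraction(conc, m))
  rs <- relative_response(response_curve(conc, "concentration", cur))
  rel <- abs(rs$table$delta_i_over_i0[-1])
  expect_true(all(diff(rel) >= -1e-12))          # non-decreasing
  gain_per_step <- diff(rel)
  beyond <- which(conc[-1] > 10 * kd)[1]
  expect_true(all(diff(gain_per_step[beyond:length(gain_per_step)]) < 1e-12))
})

test_that("KD inversion round-trips a noiseless synthetic pipeline", {
  for (kd in c(1.47e-9, 0.31e-9)) {
    m <- binding_model(kd)
    # nonlinear but monotone fraction-to-current map
    curve_f <- langmuir_fraction_curve(function(f) 1e-9 * exp(-0.8 * f))
    conc <- c(0, 10^seq(-11, -7, by = 0.2))
    cal <- calibration_curve(curve_f, m, conc)
    expect_equal(invert_response_for_kd(cal, curve_f), kd,
                 tolerance = 0.05)
  }
  flat <- langmuir_fraction_curve(function(f) rep(1e-9, length(f)))
  cal <- calibration_curve(flat, binding_model(1e-9), c(0, 1e-9))
  expect_error(invert_response_for_kd(cal, flat), "monotone")
})

test_that("response curves serialize with metadata and derived columns", {
  conc <- c(0, 1e-9, 1e-8)
  rc <- response_curve(conc, "concentration", c(1e-9, 8e-10, 6e-10),
                       metadata = list(fixture = "aptamer_cea", v_ds = -0.1))
  path <- withr::local_tempfile(fileext = ".csv")
  write_response_curve(rc, path)
  lines <- readLines(path)
  expect_true(any(grepl("^# fixture=aptamer_cea", lines)))
  df <- utils::read.csv(path, comment.char = "#")
  expect_named(df, c("concentration_M", "i_d_A", "delta_i_over_i0"))
  expect_equal(df$delta_i_over_i0, c(0, -0.2, -0.4), tolerance = 1e-12)
  expect_error(response_curve(c(1, 0), "fraction", c(1, 2)), "sorted")
  expect_error(response_curve(1, "fraction", c(1, 2)), "length")
})
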