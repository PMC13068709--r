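test_that("free energy <-> dissociation constant conversions are exact inverses", {
  expect_equal(kd_from_free_energy(0, 298), 1)
  expect_equal(free_energy_from_kd(1, 298), 0)
  # closed-form inversion: KD = 1 nM corresponds to dG = R T ln(1e-9)
  dg_1nM <- 1.9872e-3 * 298 * log(1e-9)
  expect_equal(kd_from_free_energy(dg_1nM, 298), 1e-9, tolerance = 1e-12)
  # protease-inhibitor affinity of 0.31 nM
  expect_equal(free_energy_from_kd(0.31e-9, 298), -12.96558,
               tolerance = 1e-6)
  for (kd in c(1e-12, 1e-9, 1e-6)) {
    expect_equal(kd_from_free_energy(free_energy_from_kd(kd, 298), 298),
                 kd, tolerance = 1e-12)
  }
  expect_error(kd_from_free_energy(NaN, 298), "finite")
  expect_error(kd_from_free_energy(-12, -1), "> 0")
  expect_error(free_energy_from_kd(0, 298), "> 0")
})

test_that("Langmuir occupancy has the defining half-saturation and limits", {
  m <- binding_model(kd = 1.47e-9)
  expect_identical(bound_fraction(1.47e-9, m), 0.5)  # exact in floating point
  expect_identical(bound_fraction(0, m), 0)
  expect_equal(bound_fraction(100e-9, m), 100 / 101.47, tolerance = 1e-12)
  expect_error(bound_fraction(-1e-9, m), ">= 0")
})

test_that("occupancy is strictly monotone in concentration and in KD", {
  set.seed(42)
  for (rep in 1:25) {
    kd <- 10^stats::runif(1, -12, -6)
    conc <- sort(10^stats::runif(6, -12, -5))
    f <- bound_fraction(conc, binding_model(kd))
    expect_true(all(diff(f) > 0))
    expect_true(all(f >= 0 & f <= 1))
    # same concentration, larger KD -> smaller occupancy
    f2 <- bound_fraction(conc, binding_model(kd * 10^stats::runif(1, 0.1, 2)))
    expect_true(all(f2 < f))
  }
})

test_that("binding_curve validates its grid and saturates", {
  m <- binding_model(kd = 1.47e-9)
  conc <- 10^seq(-11, -7, by = 0.1)
  bc <- binding_curve(conc, m)
  expect_true(all(diff(bc$bound_fraction) > 0))
  expect_error(binding_curve(rev(conc), m), "increasing")
  expect_error(binding_curve(numeric(0), m), "non-empty")
  expect_equal(binding_curve(0, m)$bound_fraction, 0)
  sat <- binding_curve(m$kd * 1e6, m)
  expect_true(all(sat$bound_fraction > 0.999999))
})

test_that("KD is read back off a binding curve by the f = 0.5 crossing", {
  kd <- 1.47e-9
  m <- binding_model(kd)
  conc <- 10^seq(-11, -7, length.out = 81)  # 20 points per decade
  bc <- binding_curve(conc, m)
  expect_equal(kd_from_binding_curve(bc), kd, tolerance = 0.01)
  # a 2-point bracket still localizes KD between its endpoints
  two <- data.frame(concentration_M = c(kd / 10, 10 * kd),
                    bound_fraction = c(1 / 11, 10 / 11))
  est <- kd_from_binding_curve(two)
  expect_gt(est, kd / 10)
  expect_lt(est, kd * 10)
  low <- binding_curve(10^seq(-12, -11, by = 0.2), m)  # all f < 0.5
  expect_error(kd_from_binding_curve(low), "bracket")
})

test_that("binding curves round-trip through the CSV format with KD header", {
  m <- binding_model(kd = 0.31e-9)
  bc <- binding_curve(10^seq(-11, -7, by = 0.25), m)
  path <- withr::local_tempfile(fileext = ".csv")
  write_binding_curve(bc, path)
  expect_match(readLines(path, n = 1), "^# kd_M=")
  back <- read_binding_curve(path)
  expect_equal(back$concentration_M, bc$concentration_M)
  expect_equal(back$bound_fraction, bc$bound_fraction)
  expect_equal(attr(back, "kd"), m$kd)
})
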