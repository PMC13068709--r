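pqr_lines <- c(
  "REMARK  synthetic three-atom probe",
  "ATOM      1  P   MOL     1      0.000   0.000  20.000  -0.500  1.800",
  "ATOM      2  P   MOL     1      0.000   0.000  40.000  -0.500  1.800",
  "HETATM    3  N   LIG     1      1.000   0.000  30.000   0.200  1.500")

test_that("PQR reading extracts atom records and converts angstrom to nm", {
  atoms <- read_pqr(pqr_lines)
  expect_equal(nrow(atoms), 3)
  expect_equal(atoms$z, c(2, 4, 3))          # 20 A -> 2 nm
  expect_equal(atoms$charge, c(-0.5, -0.5, 0.2))
  st <- probe_state_from_atoms(atoms, 0, "unbound")
  expect_equal(st$net_charge, -0.8, tolerance = 1e-12)
  expect_error(read_pqr(c("REMARK only", "END")), "empty")
  bad <- c("ATOM 1 P MOL 1 0.0 0.0 xx.0 -0.5 1.8")
  expect_error(read_pqr(bad), "line 1")
})

test_that("10- and 11-column PQR dialects parse to the same record", {
  no_chain <- "ATOM 1 P MOL 7 1.0 2.0 3.0 -0.5 1.8"
  with_chain <- "ATOM 1 P MOL A 7 1.0 2.0 3.0 -0.5 1.8"
  a <- read_pqr(no_chain); b <- read_pqr(with_chain)
  expect_equal(a[, -1], b[, -1])
})

test_that("PQR writing round-trips to identical records", {
  atoms <- read_pqr(pqr_lines)
  path <- withr::local_tempfile(fileext = ".pqr")
  write_pqr(atoms, path)
  back <- read_pqr(path)
  expect_equal(back$z, atoms$z, tolerance = 1e-4)
  expect_equal(back$charge, atoms$charge, tolerance = 1e-4)
  expect_equal(back$radius, atoms$radius, tolerance = 1e-4)
})

test_that("probe state reduction: centroid, fallback, permutation invariance", {
  one <- data.frame(name = "P", x = 0, y = 0, z = 5, charge = -1, radius = 0.2)
  st <- probe_state_from_atoms(one, 0, "unbound")
  expect_equal(st$net_charge, -1); expect_equal(st$height, 5)
  two <- data.frame(name = c("P", "P"), x = 0, y = 0, z = c(2, 4),
                    charge = c(-1, -1), radius = 0.2)
  st2 <- probe_state_from_atoms(two, 0, "bound")
  expect_equal(st2$net_charge, -2); expect_equal(st2$height, 3)
  # neutral distribution falls back to the geometric centroid
  zero <- data.frame(name = c("C", "C"), x = 0, y = 0, z = c(1, 3),
                     charge = c(0, 0), radius = 0.2)
  st0 <- probe_state_from_atoms(zero, 0, "unbound")
  expect_equal(st0$net_charge, 0); expect_equal(st0$height, 2)
  mixed <- data.frame(name = letters[1:4], x = 0, y = 0, z = c(1, 7, 3, 5),
                      charge = c(-1, 0.25, -0.5, 1), radius = 0.2)
  a <- probe_state_from_atoms(mixed, 0, "unbound")
  b <- probe_state_from_atoms(mixed[c(3, 1, 4, 2), ], 0, "unbound")
  expect_equal(a$net_charge, b$net_charge, tolerance = 1e-12)
  expect_equal(a$height, b$height, tolerance = 1e-12)
  expect_error(probe_state_from_atoms(mixed[0, ], 0, "unbound"), "empty")
})

test_that("shipped synthetic PQR profiles reduce to consistent probe states", {
  ub <- read_pqr(system.file("extdata", "synthetic_probe_unbound.pqr",
                             package = "rfetsense"))
  bd <- read_pqr(system.file("extdata", "synthetic_probe_bound.pqr",
                             package = "rfetsense"))
  su <- probe_state_from_atoms(ub, 0, "unbound")
  sb <- probe_state_from_atoms(bd, 0, "bound")
  expect_equal(su$net_charge, -5)
  expect_equal(sb$net_charge, -5.5)
  # the bound profile is elongated: its charge centroid sits higher
  expect_gt(sb$height, su$height)
})

test_that("fixtures reproduce the case-study defaults and orderings", {
  apt <- make_fixture("aptamer_cea")
  expect_equal(apt$unbound$height, 7.15)
  expect_equal(apt$bound$height, 9.13)
  expect_equal(apt$kd, 1.47e-9)
  # CEA adds negative charge: bound at least as negative as unbound
  expect_lte(apt$bound$net_charge, apt$unbound$net_charge)
  pro <- make_fixture("protease_inhibitor")
  expect_equal(pro$kd, 0.31e-9)
  # inhibitor binding makes the complex strictly more positive
  expect_gt(pro$bound$net_charge, pro$unbound$net_charge)
  expect_error(make_fixture("unknown_case"))
})

test_that("fixture overrides and seeded jitter are deterministic", {
  f1 <- make_fixture("aptamer_cea", overrides = list(q_target = -5))
  expect_equal(f1$bound$net_charge, -44)
  expect_error(make_fixture("aptamer_cea", overrides = list(bogus = 1)),
               "unknown fixture override")
  j1 <- make_fixture("protease_inhibitor",
                     overrides = list(jitter = 0.05), seed = 7)
  j2 <- make_fixture("protease_inhibitor",
                     overrides = list(jitter = 0.05), seed = 7)
  expect_identical(j1$unbound$net_charge, j2$unbound$net_charge)
  expect_identical(j1$bound$height, j2$bound$height)
  expect_error(make_fixture("protease_inhibitor",
                            overrides = list(jitter = 0.05)), "seed")
})

test_that("fixture exports as a parseable config fragment", {
  txt <- fixture_to_config(make_fixture("aptamer_cea"))
  parsed <- yaml::yaml.load(txt)
  expect_equal(parsed$fixture$unbound$height_nm, 7.15)
  expect_equal(parsed$fixture$kd_M, 1.47e-9)
})
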