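test_that("device discretization maps gates and contacts per the layout", {
  dev <- small_device()
  x_nm <- dev$xs * 1e9
  expect_equal(range(x_nm), c(0, 1000))
  # CG abuts the source, PG abuts the drain, 120 nm spacer between
  expect_true(all(x_nm[dev$gate_id == 1] <= 440 + 1e-6))
  expect_true(all(x_nm[dev$gate_id == 2] >= 560 - 1e-6))
  expect_true(any(dev$gate_id == 0))
  # zero spacer is allowed; overlap is not
  expect_silent(build_device(device_spec(gate_length_pg = 500,
                                         gate_length_cg = 500,
                                         mesh_nx = 101, mesh_ny = 7)))
  expect_error(device_spec(gate_length_pg = 600, gate_length_cg = 600),
               "exceed")
  expect_error(build_device(device_spec(gate_length_pg = 20,
                                        gate_length_cg = 440,
                                        mesh_nx = 21, mesh_ny = 5)),
               "coarse")
})

test_that("Scharfetter-Gummel flux reduces to central-difference diffusion", {
  B <- rfetsense:::.bernoulli
  na <- 2.0e20; nb <- 1.0e20
  u <- 1e-7  # vanishing potential drop across the edge
  sg <- nb * B(u) - na * B(-u)
  expect_equal(sg, nb - na, tolerance = 1e-6)
  # robustness across the full argument range
  u <- c(-800, -50, -1e-12, 0, 1e-12, 50, 800)
  vals <- B(u)
  expect_true(all(is.finite(vals) & vals >= 0))
  expect_equal(vals[4], 1)
  expect_equal(B(-60), 60, tolerance = 1e-10)  # B(-u) -> -u for large drops
})

test_that("equilibrium potential is mirror-symmetric and responds to sheet charge", {
  dev <- small_device()
  eq <- solve_poisson_equilibrium(dev)
  expect_true(eq$converged)
  expect_identical(eq$current_drain, 0)
  p <- eq$potential
  expect_lt(max(abs(p - p[rev(seq_len(nrow(p))), ])), 1e-12)
  # negative sigma lowers the potential under the PG, monotonically in |sigma|
  under_pg <- which(dev$gate_id == 2)
  psi_pg <- vapply(c(0, -1e-6, -2e-6), function(s) {
    st <- solve_poisson_equilibrium(dev, bias_point(sigma_pg = s))
    mean(st$potential[under_pg, 1])
  }, 0)
  expect_true(all(diff(psi_pg) < 0))
})

test_that("no drive, no current: v_ds = 0 stays below the 1 fA floor", {
  dev <- small_device()
  st <- solve_bias_point(dev, bias_point(v_pg = 2, v_cg = -1, v_ds = 0))
  expect_true(st$converged)
  expect_lt(abs(st$current_drain), 1e-15)
})

test_that("gate programming switches the device on and conserves current", {
  dev <- small_device()
  on <- solve_bias_point(dev, bias_point(5, 5, 0.1))
  off <- solve_bias_point(dev, bias_point(5, 0, 0.1))
  expect_gt(on$current_drain, off$current_drain)
  expect_gt(on$current_drain / off$current_drain, 100)
  for (st in list(on, off)) {
    expect_true(st$converged)
    expect_lt(abs(st$current_drain + st$current_source) /
                max(abs(st$current_drain), 1e-15), 1e-3)
  }
  # carrier densities stay positive everywhere
  expect_true(all(on$n > 0) && all(on$p > 0))
})

test_that("full sign flip mirrors the ambipolar device exactly", {
  dev <- build_device(device_spec(mesh_nx = 101, mesh_ny = 7),
                      symmetric_materials())
  a <- solve_bias_point(dev, bias_point(5, 5, 0.1, 2e-7))
  b <- solve_bias_point(dev, bias_point(-5, -5, -0.1, -2e-7))
  expect_equal(b$current_drain, -a$current_drain,
               tolerance = 0.01)
})

test_that("transfer curves follow the dual-polarity programming protocols", {
  dev <- small_device()
  # p-type: both gates negative, v_ds = -0.1 V; |I| shrinks as v_cg -> 0
  tp <- program_polarity("p")
  expect_equal(tp$bias$v_ds, -0.1)
  expect_equal(program_polarity("n")$v_cg_sweep, c(0, 5))
  curve_p <- transfer_curve(dev, seq(-5, 0, length.out = 5),
                            v_pg = tp$bias$v_pg, v_ds = tp$bias$v_ds)
  expect_true(all(diff(abs(curve_p$current)) < 0))
  # n-type: positive range, current grows with v_cg
  tn <- program_polarity("n")
  curve_n <- transfer_curve(dev, seq(0, 5, length.out = 5),
                            v_pg = tn$bias$v_pg, v_ds = tn$bias$v_ds)
  expect_true(all(diff(curve_n$current) > 0))
  # templates are exact sign mirrors
  expect_equal(tn$bias$v_pg, -tp$bias$v_pg)
  expect_equal(tn$bias$v_ds, -tp$bias$v_ds)
  expect_error(transfer_curve(dev, numeric(0), 5, 0.1), "empty")
})

test_that("molecular charge shifts the transfer characteristics as virtual doping", {
  dev <- small_device()
  # n-programmed: negative sheet charge opposes electron conduction
  i_ref <- solve_bias_point(dev, bias_point(1, 5, 0.1, 0))$current_drain
  i_neg <- solve_bias_point(dev, bias_point(1, 5, 0.1, -1e-6))$current_drain
  expect_lt(i_neg, i_ref)
  # p-programmed: positive sheet charge suppresses hole conduction
  i_refp <- solve_bias_point(dev, bias_point(-1, -5, -0.1, 0))$current_drain
  i_pos <- solve_bias_point(dev, bias_point(-1, -5, -0.1, 1e-6))$current_drain
  expect_lt(abs(i_pos), abs(i_refp))
})

test_that("mesh refinement leaves the ON current stable within 5%", {
  b <- bias_point(0, 5, 0.1, 6e-7)
  i_coarse <- solve_bias_point(small_device(101, 7), b)$current_drain
  i_fine <- solve_bias_point(small_device(201, 13), b)$current_drain
  expect_equal(i_fine / i_coarse, 1, tolerance = 0.05)
})

test_that("density-gradient correction runs and preserves the transport picture", {
  dev <- build_device(device_spec(mesh_nx = 101, mesh_ny = 7,
                                  density_gradient = TRUE))
  st <- solve_bias_point(dev, bias_point(5, 5, 0.1))
  expect_true(st$converged)
  expect_true(is.finite(st$current_drain) && st$current_drain > 0)
})
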