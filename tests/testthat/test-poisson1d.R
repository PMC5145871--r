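test_that("binning conserves charge exactly", {
  # a single unit charge lands in one bin with density 1/(A h)
  cfg <- pseudo_configuration(matrix(c(1, 1, 0.55), ncol = 3),
                              charges = 1, species = "ION",
                              box = c(2, 2, 4))
  pr <- bin_charge_density(cfg, bin_width = 0.5)
  h <- diff(pr$bin_edges)[1]
  expect_equal(sum(pr$rho > 0), 1L)
  expect_equal(max(pr$rho), 1 / (pr$area * h))
  expect_equal(sum(pr$rho * diff(pr$bin_edges)) * pr$area, 1)

  # synthetic neutral system integrates to zero
  s <- pops15_stack(D = 4)
  cfg2 <- build_configuration(s, box_xy = 12, seed = 3)
  pr2 <- bin_charge_density(cfg2, 0.1)
  expect_lt(abs(sum(pr2$rho * diff(pr2$bin_edges)) * pr2$area), 1e-9)
  expect_equal(sum(pr2$rho * diff(pr2$bin_edges)) * pr2$area,
               sum(cfg2$charges))
})

test_that("binned R2 density matches the target within counting error", {
  s <- pops15_stack(D = 4)
  cfg <- build_configuration(s, box_xy = 16, seed = 11)
  pr <- bin_charge_density(cfg, 0.1)
  mids <- (pr$bin_edges[-1] + pr$bin_edges[-length(pr$bin_edges)]) / 2
  interior <- mids > -s$D / 2 + 0.2 & mids < s$D / 2 - 0.2
  mean_rho <- mean(pr$rho[interior])
  # Poisson error on the total interior ion count
  vol <- sum(interior) * diff(pr$bin_edges)[1] * pr$area
  n_expect <- s$rho2 * vol
  sigma <- sqrt(n_expect) / vol
  expect_lt(abs(mean_rho - s$rho2), 3 * sigma)
})

test_that("binning rejects degenerate input", {
  cfg <- pseudo_configuration(matrix(numeric(0), ncol = 3),
                              charges = numeric(0),
                              species = character(0), box = c(2, 2, 2))
  expect_error(bin_charge_density(cfg), "no particles")
  cfg2 <- pseudo_configuration(matrix(c(1, 1, 0), ncol = 3), 1, "ION",
                               c(2, 2, 2))
  expect_error(bin_charge_density(cfg2, bin_width = 0), "bin_width")
})

test_that("integration of a zero profile gives zero potential", {
  pr <- charge_profile(seq(-2, 2, by = 0.1), rep(0, 40), area = 10)
  pot <- integrate_potential(pr, eps_r = 3)
  expect_true(all(pot$phi == 0))
})

test_that("numeric integration reproduces the closed form", {
  s <- pops15_stack(D = 4)
  pr <- charge_profile_from_stack(s, bin_width = 0.05)
  pot <- integrate_potential(pr, eps_r = s$eps_r)
  expect_lt(max(abs(pot$phi -
                      memvolt:::eval_stack_potential(s, pot$z))), 1e-3)
  # asymmetric stack as well
  s2 <- random_neutral_stack(21)
  pr2 <- charge_profile_from_stack(s2, bin_width = 0.02)
  pot2 <- integrate_potential(pr2, eps_r = s2$eps_r)
  expect_lt(max(abs(pot2$phi -
                      memvolt:::eval_stack_potential(s2, pot2$z))), 1e-3)
})

test_that("potential reference and symmetry behave as declared", {
  s <- pops15_stack(D = 3)
  pr <- charge_profile_from_stack(s, bin_width = 0.05)
  pot <- integrate_potential(pr, eps_r = 3)
  expect_equal(approx(pot$z, pot$phi, xout = 0)$y, 0, tolerance = 1e-12)
  at <- function(z) approx(pot$z, pot$phi, xout = z)$y
  zz <- seq(0.1, max(pot$z) - 0.1, length.out = 50)
  expect_lt(max(abs(at(zz) - at(-zz))), 1e-6)
  expect_error(integrate_potential(pr, eps_r = 0), "eps_r")
  expect_error(integrate_potential(pr, eps_r = 3, reference_z = 99),
               "reference_z")
})

test_that("second finite difference recovers the source term", {
  s <- pops15_stack(D = 4)
  pr <- charge_profile_from_stack(s, bin_width = 0.1)
  pot <- integrate_potential(pr, eps_r = 3)
  h <- diff(pot$z)[1]
  kv <- memvolt_constants()$volt_per_e_per_nm
  d2 <- diff(diff(pot$phi)) / h^2
  src <- -(pr$rho[-1] + pr$rho[-length(pr$rho)]) / 2 * kv / 3
  expect_lt(max(abs(d2 - src)), 1e-9)
})

test_that("membrane voltages are gauge invariant", {
  s <- random_neutral_stack(8)
  b <- locate_membranes(s)
  pr <- charge_profile_from_stack(s, bin_width = 0.05)
  pot <- integrate_potential(pr, eps_r = s$eps_r)
  dv <- measure_voltage(pot, b)
  shifted <- pot; shifted$phi <- pot$phi + 0.37
  expect_equal(measure_voltage(shifted, b), dv)
  # moving the reference point changes nothing either
  pot2 <- integrate_potential(pr, eps_r = s$eps_r,
                              reference_z = min(pot$z) + 0.3)
  expect_equal(measure_voltage(pot2, b), dv, tolerance = 1e-12)
  # zero potential gives zero voltages
  pot0 <- pot; pot0$phi[] <- 0
  expect_equal(unname(measure_voltage(pot0, b)), c(0, 0))
  # bounds outside the grid are rejected
  bad <- membrane_bounds(m1 = c(90, 94), m2 = b$m2)
  expect_error(measure_voltage(pot, bad), "outside")
})

test_that("halving the bin width refines the measured voltage", {
  # distance chosen so layer faces do not align with any of the bin grids
  s <- pops15_stack(D = 3.3)
  b <- locate_membranes(s)
  dv_true <- transmembrane_voltages(s)[["dV1"]]
  err <- vapply(c(0.32, 0.16, 0.08, 0.04), function(h) {
    pr <- charge_profile_from_stack(s, bin_width = h)
    abs(measure_voltage(integrate_potential(pr, 3), b)[["dV1"]] - dv_true)
  }, numeric(1))
  expect_true(all(diff(err) < 0))      # monotone improvement
  expect_lt(err[4], err[1] / 8)        # at least first-order convergence
})

test_that("declared geometry gives exact membrane faces", {
  s <- pops15_stack(D = 3)  # H_m = 4
  b <- locate_membranes(s)
  expect_equal(b$m1, c(1.5, 5.5))
  expect_equal(b$m2, c(-5.5, -1.5))
  cfg <- build_configuration(s, box_xy = 8, seed = 2)
  expect_equal(locate_membranes(cfg), b)
})

test_that("membranes are recovered from particles alone", {
  s <- pops15_stack(D = 3)
  # face sheets localize to one bin; volumetric plateaus to two
  tol <- c(sheet = 0.1, volumetric = 0.2)
  for (style in c("volumetric", "sheet")) {
    cfg <- build_configuration(s, box_xy = 10, seed = 4, head_style = style)
    b <- locate_membranes(cfg, bin_width = 0.1, use_declared = FALSE)
    expect_lt(max(abs(b$m1 - c(1.5, 5.5))), tol[[style]] + 1e-9)
    expect_lt(max(abs(b$m2 - c(-5.5, -1.5))), tol[[style]] + 1e-9)
  }
})

test_that("a single membrane is rejected with candidates listed", {
  s <- pops15_stack(D = 3)
  cfg <- build_configuration(s, box_xy = 10, seed = 4)
  keep <- !(startsWith(cfg$species, "HEAD") & cfg$positions[, 3] > 0)
  cfg1 <- pseudo_configuration(cfg$positions[keep, ], cfg$charges[keep],
                               cfg$species[keep], cfg$box)
  expect_error(locate_membranes(cfg1, use_declared = FALSE),
               "expected two membrane slabs")
})
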