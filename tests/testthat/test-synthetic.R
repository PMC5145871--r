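test_that("stack building closes neutrality with uniform counter-ions", {
  s <- build_stack_params(lipid_mix_pops(0.15), D = 4)
  expect_lt(abs(neutrality_residual(s)), 1e-9)
  expect_lt(s$rho_m1, 0)
  expect_equal(s$rho1, s$rho2)
  expect_equal(s$rho2, s$rho3)
  # neutral membrane: everything zero, voltage zero at any distance
  s0 <- build_stack_params(lipid_mix_pops(0), D = 4)
  expect_equal(s0$rho_m1, 0)
  expect_equal(s0$rho2, 0)
  expect_equal(unname(transmembrane_voltages(s0)), c(0, 0))
})

test_that("ion concentrations land in the physiological window", {
  # the studied compositions imply ~0.04-0.15 mol/L potassium
  for (p in c(0.045, 0.15)) {
    s <- build_stack_params(lipid_mix_pops(p), D = 4)
    cfg <- build_configuration(s, box_xy = 23, seed = 1)
    conc <- ion_concentration(cfg)
    overall <- conc$mol_per_L[conc$region == "aqueous"]
    expect_gt(overall, 0.03)
    expect_lt(overall, 0.16)
  }
})

test_that("ion concentration arithmetic is exact", {
  s <- build_stack_params(lipid_mix_pops(0.15), D = 4)
  cfg <- build_configuration(s, box_xy = 10, seed = 5)
  conc <- ion_concentration(cfg)
  n_r2 <- conc$n_ions[conc$region == "R2"]
  v_r2 <- conc$volume_nm3[conc$region == "R2"]
  expect_equal(v_r2, 10 * 10 * 4)
  expect_equal(conc$mol_per_L[conc$region == "R2"],
               n_r2 / (6.02214076e23 * v_r2 * 1e-24))
  # 100 ions in 100 nm^3 would be 1.66 mol/L
  expect_equal(100 / (6.02214076e23 * 100 * 1e-24), 1.660539,
               tolerance = 1e-6)
})

test_that("configurations are exactly neutral and deterministic", {
  s <- build_stack_params(lipid_mix_pops(0.12), D = 3.5)
  a <- build_configuration(s, box_xy = 9, seed = 42)
  b <- build_configuration(s, box_xy = 9, seed = 42)
  expect_identical(a$positions, b$positions)
  expect_identical(a$charges, b$charges)
  expect_equal(sum(a$charges), 0)
  c2 <- build_configuration(s, box_xy = 9, seed = 43)
  expect_false(identical(a$positions, c2$positions))
  # 0% POPS: no ions, no charged heads
  s0 <- build_stack_params(lipid_mix_pops(0), D = 3.5)
  cfg0 <- build_configuration(s0, box_xy = 9, seed = 1)
  expect_equal(sum(cfg0$species == "ION"), 0L)
  expect_true(all(cfg0$charges == 0))
})

test_that("binned density converges to the stack with box size", {
  s <- build_stack_params(lipid_mix_pops(0.15), D = 4)
  err_for_box <- function(L) {
    cfg <- build_configuration(s, box_xy = L, seed = 2)
    pr <- bin_charge_density(cfg, 0.2)
    mids <- (pr$bin_edges[-1] + pr$bin_edges[-length(pr$bin_edges)]) / 2
    interior <- mids > -s$D / 2 + 0.3 & mids < s$D / 2 - 0.3
    abs(mean(pr$rho[interior]) - s$rho2)
  }
  expect_lt(err_for_box(28), err_for_box(7) + 1e-3)
})

test_that("the generic headgroup route realizes arbitrary neutral stacks", {
  s <- random_neutral_stack(6)
  cfg <- build_configuration(s, box_xy = 10, seed = 9)
  expect_equal(sum(cfg$charges), 0)
  expect_true("HEAD_CHARGED" %in% cfg$species)
  pr <- bin_charge_density(cfg, 0.1)
  dv <- measure_voltage(integrate_potential(pr, s$eps_r),
                        locate_membranes(s))
  expect_lt(max(abs(dv - transmembrane_voltages(s))), 1.0)  # noisy but sane
})

test_that("pore schedules follow their contracts", {
  expect_error(pore_schedule("constant", t_open = -1), "t_open")
  expect_error(pore_schedule("constant", r0 = -0.5), "radius")
  t <- seq(0, 20, by = 0.5)
  expect_true(all(schedule_radius(pore_schedule("none"), t) == 0))
  rf <- schedule_radius(pore_schedule("reseal_fast", t_open = 2, r0 = 0.75), t)
  expect_true(all(rf[t < 2] == 0))
  expect_equal(rf[t == 2], 0.75)
  expect_equal(rf[t == 20], 0)               # closed within the window
  rs <- schedule_radius(pore_schedule("reseal_slow", t_open = 2, r0 = 0.75), t)
  expect_gt(rs[t == 20], 0)                  # still open ...
  expect_lt(rs[t == 20], 0.75)               # ... but shrunk
  rd <- schedule_radius(pore_schedule("dilate", t_open = 2, r0 = 0.75), t)
  expect_true(all(diff(rd[t >= 2]) >= 0))    # monotone growth
  expect_gte(rd[t == 20], 2 * 0.75)
})

test_that("trajectories carry planted pores from t_open onward", {
  s <- build_stack_params(lipid_mix_pops(0.15), D = 3)
  sch <- pore_schedule("constant", t_open = 2, r0 = 0.75)
  tr <- build_trajectory(s, box_xy = 6, frames = 41, dt = 0.5,
                         schedule = sch, include_bulk_water = FALSE)
  expect_equal(length(tr$frames), 41L)
  expect_true(!is.unsorted(tr$times, strictly = TRUE))
  planted <- vapply(tr$frames, function(f) attr(f, "planted_radius"),
                    numeric(1))
  has_col <- vapply(tr$frames, function(f) {
    any(f$species == "WATER_MARK" & abs(f$positions[, 3]) > s$D / 2)
  }, logical(1))
  expect_equal(has_col, tr$times >= 2)
  expect_equal(min(tr$times[has_col]), 2)
  expect_true(all(planted[tr$times >= 2] == 0.75))
  # zero-radius schedule never spans the membranes
  tr0 <- build_trajectory(s, box_xy = 6, frames = 5, dt = 1,
                          schedule = pore_schedule("none"),
                          include_bulk_water = TRUE)
  spans <- vapply(tr0$frames, function(f) {
    any(f$species == "WATER_MARK" & abs(f$positions[, 3]) > s$D / 2 &
          abs(f$positions[, 3]) < s$D / 2 + s$H_m)
  }, logical(1))
  expect_true(all(!spans))
})

test_that("ion leakage relocates R2 ions after opening", {
  s <- build_stack_params(lipid_mix_pops(0.15), D = 3)
  tr <- build_trajectory(s, box_xy = 8, frames = 5, dt = 1,
                         schedule = pore_schedule("constant", t_open = 2,
                                                  r0 = 0.5),
                         include_bulk_water = FALSE, leak_ions = 10)
  n_r2 <- vapply(tr$frames, function(f) {
    sum(f$species == "ION" & abs(f$positions[, 3]) < s$D / 2)
  }, numeric(1))
  expect_equal(n_r2[1], n_r2[2])             # before opening
  expect_equal(n_r2[3], n_r2[1] - 10)        # after opening
  # net charge unchanged by relocation
  expect_equal(sum(tr$frames[[4]]$charges), 0)
})

test_that("GRO round-trip preserves the configuration", {
  s <- build_stack_params(lipid_mix_pops(0.15), D = 4)
  cfg <- build_configuration(s, box_xy = 6, seed = 13)
  dir <- withr::local_tempdir()
  path <- file.path(dir, "cfg.gro")
  write_gro(cfg, path)
  back <- read_configuration(path, file.path(dir, "cfg_charges.tsv"))
  expect_equal(back$box, cfg$box, tolerance = 1e-5)
  expect_equal(back$positions, cfg$positions, tolerance = 6e-4,
               ignore_attr = TRUE)
  expect_equal(sort(unique(back$species)), sort(unique(cfg$species)))
  # charge table reproduces charges except COMP rounding residual particle
  expect_equal(sum(back$charges), sum(cfg$charges), tolerance = 1e-9)
})
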