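make_pore_frame <- function(r = 0.75, box_xy = 6, D = 3,
                            center = NULL, bulk = FALSE, seed = 1) {
  s <- build_stack_params(lipid_mix_pops(0.15), D = D)
  sch <- if (r > 0)
    pore_schedule("constant", t_open = 0, r0 = r, center_xy = center)
  else pore_schedule("none")
  tr <- build_trajectory(s, box_xy = box_xy, frames = 1, dt = 1,
                         schedule = sch, seed = seed,
                         include_bulk_water = bulk)
  list(frame = tr$frames[[1]], bounds = locate_membranes(s), stack = s)
}

test_that("intact frames contain no pores", {
  x <- make_pore_frame(r = 0, bulk = TRUE)
  rec <- detect_pores(x$frame, x$bounds)
  expect_equal(nrow(rec$pores), 0L)
})

test_that("planted cylinders are recovered at the planted size", {
  for (r in c(0.5, 0.75, 1.0)) {
    x <- make_pore_frame(r = r, bulk = TRUE)
    rec <- detect_pores(x$frame, x$bounds, cell_size = 0.2)
    expect_equal(nrow(rec$pores), 2L)  # one pore per membrane
    expect_equal(sort(rec$pores$membrane), c("m1", "m2"))
    expect_lt(max(abs(rec$pores$equivalent_diameter - 2 * r)), 0.4)
  }
})

test_that("two separated columns give two components", {
  x1 <- make_pore_frame(r = 0.5, center = c(1.5, 1.5))
  x2 <- make_pore_frame(r = 0.5, center = c(4.5, 4.5))
  f1 <- x1$frame; f2 <- x2$frame
  col2 <- f2$species == "WATER_MARK"
  merged <- pseudo_configuration(
    rbind(f1$positions, f2$positions[col2, , drop = FALSE]),
    c(f1$charges, f2$charges[col2]),
    c(f1$species, f2$species[col2]),
    f1$box, frame_time = 0)
  rec <- detect_pores(merged, x1$bounds)
  expect_equal(sum(rec$pores$membrane == "m1"), 2L)
  expect_equal(sum(rec$pores$membrane == "m2"), 2L)
})

test_that("detection is invariant to XY translation with periodic wrap", {
  x <- make_pore_frame(r = 0.75, box_xy = 6)
  base <- detect_pores(x$frame, x$bounds, cell_size = 0.2)
  # shift by whole cells: exactly identical areas, pore crosses the seam
  for (shift in list(c(0.4, 0), c(2.8, 2.8), c(-0.6, 1.2))) {
    f <- x$frame
    f$positions[, 1] <- (f$positions[, 1] + shift[1]) %% f$box[1]
    f$positions[, 2] <- (f$positions[, 2] + shift[2]) %% f$box[2]
    rec <- detect_pores(f, x$bounds, cell_size = 0.2)
    expect_equal(nrow(rec$pores), nrow(base$pores))
    expect_equal(sort(rec$pores$area), sort(base$pores$area))
  }
  # arbitrary sub-cell shift: size equal within the discretization bound
  f <- x$frame
  f$positions[, 1] <- (f$positions[, 1] + 0.13) %% f$box[1]
  rec <- detect_pores(f, x$bounds, cell_size = 0.2)
  expect_equal(nrow(rec$pores), 2L)
  expect_lt(max(abs(rec$pores$equivalent_diameter -
                      base$pores$equivalent_diameter)), 0.4)
})

test_that("pore centroids track the planted centre", {
  x <- make_pore_frame(r = 0.75, center = c(1.0, 5.0))
  rec <- detect_pores(x$frame, x$bounds)
  expect_lt(max(abs(rec$pores$centroid_x - 1.0)), 0.25)
  expect_lt(max(abs(rec$pores$centroid_y - 5.0)), 0.25)
})

test_that("diameter definition matches the reported area", {
  x <- make_pore_frame(r = 1.0)
  rec <- detect_pores(x$frame, x$bounds)
  expect_equal(rec$pores$equivalent_diameter,
               2 * sqrt(rec$pores$area / pi))
  expect_true(all(rec$pores$area > 0))
})

test_that("formation time is the first frame with a detected pore", {
  s <- build_stack_params(lipid_mix_pops(0.15), D = 3)
  b <- locate_membranes(s)
  tr <- build_trajectory(s, box_xy = 6, frames = 41, dt = 0.5,
                         schedule = pore_schedule("constant", t_open = 2,
                                                  r0 = 0.75),
                         include_bulk_water = FALSE)
  ft <- pore_formation_time(tr, b)
  expect_true(ft$formed)
  expect_equal(ft$time, 2.0)
  # no pore within the window
  tr0 <- build_trajectory(s, box_xy = 6, frames = 11, dt = 2,
                          schedule = pore_schedule("none"),
                          include_bulk_water = FALSE)
  ft0 <- pore_formation_time(tr0, b)
  expect_false(ft0$formed)
  expect_true(is.na(ft0$time))
  # opening just inside the window is caught at frame resolution
  tr_late <- build_trajectory(s, box_xy = 6, frames = 41, dt = 0.5,
                              schedule = pore_schedule("constant",
                                                       t_open = 19.9,
                                                       r0 = 0.75),
                              include_bulk_water = FALSE)
  ft_late <- pore_formation_time(tr_late, b)
  expect_true(ft_late$formed)
  expect_equal(ft_late$time, 20.0)  # smallest frame time >= 19.9
})

test_that("Gaussian fit recovers the generating parameters", {
  d <- memvolt:::with_seed(99, rnorm(200, mean = 1.5, sd = 0.25))
  fit <- pore_size_distribution(d)
  expect_true(fit$fit_available)
  expect_lt(abs(fit$mean - 1.5) / 1.5, 0.10)
  expect_lt(abs(fit$sigma - 0.25) / 0.25, 0.10)
})

test_that("distribution contracts for degenerate inputs hold", {
  # too few observations: histogram only
  small <- pore_size_distribution(c(1.4, 1.5, 1.6))
  expect_false(small$fit_available)
  expect_equal(small$n, 3L)
  # identical diameters: mean exact, spread collapses
  same <- pore_size_distribution(rep(1.5, 50))
  expect_true(same$fit_available)
  expect_equal(same$mean, 1.5, tolerance = 1e-6)
  expect_lt(same$sigma, 0.05)
  # records are pooled
  x <- make_pore_frame(r = 0.75)
  rec <- detect_pores(x$frame, x$bounds)
  pooled <- pore_size_distribution(list(rec, rec, rec, rec, rec))
  expect_equal(pooled$n, 10L)
})

test_that("the three tension regimes classify correctly from detection", {
  s <- build_stack_params(lipid_mix_pops(0.15), D = 3)
  b <- locate_membranes(s)
  run <- function(template) {
    tr <- build_trajectory(s, box_xy = 8, frames = 41, dt = 0.5,
                           schedule = pore_schedule(template, t_open = 2,
                                                    r0 = 0.75),
                           include_bulk_water = FALSE)
    ser <- pore_size_series(tr, b)
    ser[ser$t >= 2, ]
  }
  fates <- list(reseal_fast = "RESEAL_FAST",
                reseal_slow = "RESEAL_SLOW",
                dilate = "DILATE")
  for (tmpl in names(fates)) {
    ser <- run(tmpl)
    expect_identical(classify_fate(ser)$label, fates[[tmpl]],
                     info = tmpl)
    # robust to +/- one-cell diameter noise on open pores
    noisy <- ser
    jitter <- memvolt:::with_seed(7, runif(nrow(ser), -0.2, 0.2))
    noisy$diameter <- pmax(0, ifelse(ser$diameter > 0,
                                     ser$diameter + jitter, 0))
    expect_identical(classify_fate(noisy)$label, fates[[tmpl]],
                     info = paste(tmpl, "noisy"))
  }
})

test_that("fate classification honours its explicit contracts", {
  # constant diameter: still open, not grown -> slow reseal
  ser <- data.frame(t = seq(0, 20, by = 1), diameter = 1.5)
  f <- classify_fate(ser)
  expect_identical(f$label, "RESEAL_SLOW")
  expect_true(is.na(f$close_time))
  # closure time recorded for fast reseal
  ser2 <- data.frame(t = 0:10, diameter = c(seq(1.5, 0, length.out = 8),
                                            0, 0, 0))
  f2 <- classify_fate(ser2)
  expect_identical(f2$label, "RESEAL_FAST")
  expect_equal(f2$close_time, 7)
  expect_error(classify_fate(data.frame(t = numeric(0),
                                        diameter = numeric(0))), "empty")
})
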