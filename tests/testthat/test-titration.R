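# Three-phase titration analysis: segmentation, phase fits, sparse
# intersection and total generation.

noiseless_curve <- function(...) generate_titration(titration_truth(...))

test_that("titration_curve validates and sorts its points", {
  expect_error(titration_curve(c(1, 2, 3), c(1, 2, 3), 32),
               class = "rostrack_domain_error")       # too few points
  expect_error(titration_curve(c(1, 2, 3, 4, 5, 5), 1:6, 32),
               class = "rostrack_domain_error")       # duplicate DMPO
  expect_error(titration_curve(1:6, 1:6, 0), class = "rostrack_domain_error")
  shuffled <- titration_curve(c(3, 1, 6, 2, 5, 4), c(3, 1, 6, 2, 5, 4), 10)
  expect_equal(shuffled$dmpo_mM, 1:6)
  expect_error(to_density_axis(data.frame(a = 1)),
               class = "rostrack_domain_error")
})

test_that("density axis transform applies the cube-root rule per point", {
  curve <- to_density_axis(noiseless_curve())
  expect_equal(curve$density_per_um[1], 67.0, tolerance = 1e-3)   # 0.5 mM
  expect_equal(curve$density_per_um[10], 1004.9, tolerance = 1e-4) # 1685 mM
  expect_equal(curve$density_per_um,
               concentration_to_linear_density(curve$dmpo_mM, "mmol/L"))
})

test_that("phase-line fits match hand least squares", {
  curve <- to_density_axis(noiseless_curve())
  model <- fit_phase_lines(curve, rep(1:3, times = c(3, 5, 2)))
  x <- curve$density_per_um
  y <- curve$dmpoh_uM
  # phase 1/3: origin-constrained slope sum(xy)/sum(x^2), recomputed here
  expect_equal(model$s1, sum(x[1:3] * y[1:3]) / sum(x[1:3]^2))
  expect_equal(model$s3, sum(x[9:10] * y[9:10]) / sum(x[9:10]^2))
  # phase 2: ordinary least squares, oracle = stats::lm
  f2 <- stats::lm(y[4:8] ~ x[4:8])
  expect_equal(model$a2, unname(stats::coef(f2)[1]))
  expect_equal(model$b2, unname(stats::coef(f2)[2]))
  # generative values: s1 = A_s/d_s + A_d/d_d, a2 = A_s, b2 = A_d/d_d
  expect_equal(model$s1, 6.1 / 160 + 51.7 / 1e4, tolerance = 1e-12)
  expect_equal(model$a2, 6.10, tolerance = 1e-3)
  expect_equal(model$b2, 0.00517, tolerance = 1e-3)
  expect_error(fit_phase_lines(curve, rep(1:3, times = c(1, 7, 2))),
               class = "rostrack_domain_error")  # phase with < 2 points
  expect_error(fit_phase_lines(curve, c(rep(1, 3), 3, 3, 2, 2, 2, 3, 3)),
               class = "rostrack_domain_error")  # non-contiguous
})

test_that("hand-calculable origin fit: two points from the phase-3 tail", {
  x <- c(712, 1005)
  y <- c(9.78, 11.30)
  expect_equal(sum(x * y) / sum(x^2), 0.012077, tolerance = 1e-4)
})

test_that("segmentation finds the documented partition on the noiseless fixture", {
  curve <- to_density_axis(noiseless_curve())
  model <- segment_phases(curve)
  expect_identical(tabulate(model$assignment, 3L), c(3L, 5L, 2L))
  # phase boundaries in density: <=126 / 166-500 / 712-1005
  expect_lte(max(curve$density_per_um[model$assignment == 1]), 126)
  expect_gte(min(curve$density_per_um[model$assignment == 3]), 712)
})

test_that("segmentation equals the independent exhaustive oracle", {
  grids <- list(DMPO_SERIES_MM,
                sort(c(DMPO_SERIES_MM, 100, 400)))  # 10- and 12-point inputs
  for (grid in grids) {
    for (noise in c(0, 0.2)) {
      for (seed in 1:3) {
        curve <- to_density_axis(generate_titration(
          titration_truth(noise_sd = noise), dmpo_mM = grid, seed = seed))
        model <- segment_phases(curve)
        oracle <- oracle_segmentation(curve$density_per_um, curve$dmpoh_uM)
        expect_identical(tabulate(model$assignment, 3L), as.integer(oracle$sizes))
        expect_equal(model$sse, oracle$sse, tolerance = 1e-10)
        if (noise == 0) break  # noiseless case is seed-independent
      }
    }
  }
})

test_that("single-line input raises 'no plateau detected'", {
  curve <- titration_curve(DMPO_SERIES_MM, 0.01 * DMPO_SERIES_MM, 32)
  expect_error(segment_phases(curve), "no plateau",
               class = "rostrack_domain_error")
})

test_that("manual phase override and too-few-points error", {
  curve <- noiseless_curve()
  model <- segment_phases(curve, phases = c(3, 4, 3))
  expect_identical(tabulate(model$assignment, 3L), c(3L, 4L, 3L))
  expect_error(segment_phases(curve, phases = c(5, 5, 5)),
               class = "rostrack_domain_error")
  short <- titration_curve(1:6, c(1, 2, 3, 3, 3, 3), 1)
  expect_error(segment_phases(short, min_per_phase = 3),
               class = "rostrack_domain_error")
})

test_that("sparse intersection is the closed form a2/(s1-b2)", {
  unit_model <- structure(list(s1 = 1, a2 = 1, b2 = 0), class = "phase_model")
  expect_equal(intersect_sparse(unit_model),
               list(sparse_density = 1, sparse_amount = 1))
  m <- structure(list(s1 = 0.0433, a2 = 6.10, b2 = 0.00517),
                 class = "phase_model")
  got <- intersect_sparse(m)
  expect_equal(got$sparse_density, 160.0, tolerance = 1e-3)
  expect_equal(got$sparse_amount, 6.93, tolerance = 1e-3)
  # doubling a2 doubles both coordinates
  m2 <- structure(list(s1 = 0.0433, a2 = 12.20, b2 = 0.00517),
                  class = "phase_model")
  got2 <- intersect_sparse(m2)
  expect_equal(got2$sparse_density, 2 * got$sparse_density)
  expect_equal(got2$sparse_amount, 2 * got$sparse_amount)
  expect_error(intersect_sparse(structure(list(s1 = 1, a2 = 1, b2 = 2),
                                          class = "phase_model")),
               class = "rostrack_domain_error")
})

test_that("total generation is linear in the reference density", {
  model <- segment_phases(noiseless_curve())
  expect_equal(total_oh(model, 1000), model$s3 * 1000)
  expect_equal(total_oh(model, 1000), 12.07, tolerance = 1e-3)
  ref <- c(500, 1000, 2000)
  expect_equal(total_oh(model, ref[3]), 4 * total_oh(model, ref[1]))
  flat <- structure(list(s3 = 0), class = "phase_model")
  expect_equal(total_oh(flat, 1000), 0)
  # the slope implied by the 11.3 umol/L worked example
  expect_equal(total_oh(structure(list(s3 = 0.0113), class = "phase_model")),
               11.3)
})

test_that("end-to-end analysis reproduces the X-ray worked example", {
  est <- analyze_titration(noiseless_curve())
  expect_equal(est$sparse_density, 160, tolerance = 1e-9)
  expect_equal(signif(est$sparse_concentration_mM, 2), 6.8)
  # intersection amount carries the documented dense-term bias:
  # y* = A_s + d_s * A_d / d_d
  expect_equal(est$sparse_amount_uM, 6.1 + 160 * 51.7 / 1e4, tolerance = 1e-9)
  expect_equal(est$total_amount_uM, 12.07, tolerance = 1e-3)
})

test_that("analysis is scale-equivariant and order-invariant", {
  base <- noiseless_curve()
  est <- analyze_titration(base)
  doubled <- titration_curve(base$dmpo_mM, 2 * base$dmpoh_uM, 32)
  est2 <- analyze_titration(doubled)
  expect_equal(est2$sparse_amount_uM, 2 * est$sparse_amount_uM)
  expect_equal(est2$total_amount_uM, 2 * est$total_amount_uM)
  expect_equal(est2$sparse_density, est$sparse_density)
  perm <- sample(nrow(base))
  shuffled <- titration_curve(base$dmpo_mM[perm], base$dmpoh_uM[perm], 32)
  est3 <- analyze_titration(shuffled)
  expect_equal(est3$sparse_density, est$sparse_density)
  expect_equal(est3$total_amount_uM, est$total_amount_uM)
})

test_that("noisy recovery: median sparse density within 10% over 200 replicates", {
  densities <- vapply(seq_len(200), function(rep) {
    curve <- generate_titration(titration_truth(noise_sd = 0.2),
                                seed = 4000 + rep)
    tryCatch(analyze_titration(curve)$sparse_density,
             rostrack_error = function(e) NA_real_)
  }, numeric(1))
  expect_lt(mean(is.na(densities)), 0.05)  # analysis almost always succeeds
  expect_lt(abs(stats::median(densities, na.rm = TRUE) - 160) / 160, 0.10)
})
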