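# Per-Gy budgets, ratios, carbon aggregates and the oxidation partition.

test_that("bundled budget table loads and validates", {
  tab <- load_table1()
  expect_s3_class(tab, "ros_budget")
  expect_identical(nrow(tab), 6L)
  expect_identical(tab$condition[1], "X-ray")
  xrow <- tab[tab$condition == "X-ray", ]
  expect_equal(xrow$total_oxidation, 2.74)
  hi <- tab[tab$condition == ">100 keV/um", ]
  expect_equal(hi$h2o2, 0.17)
  expect_equal(hi$o2_consumption, 0.05)
  # a corrupted fixture is rejected
  broken <- tab
  broken$ratio_h2o2_o2[2] <- 9.99
  tmp <- withr::local_tempfile(fileext = ".csv")
  write.csv(broken, tmp, row.names = FALSE)
  expect_error(load_table1(tmp), class = "rostrack_fixture_error")
  expect_error(load_table1("/nonexistent.csv"),
               class = "rostrack_fixture_error")
})

test_that("per-Gy normalization and display rounding", {
  expect_equal(display_round(per_gray(6.1, 32)), 0.19)
  expect_equal(display_round(per_gray(11.3, 32)), 0.35)
  expect_equal(per_gray(0, 5), 0)
  expect_equal(per_gray(6.1, 32), 6.1 / 32)  # full precision internally
  expect_error(per_gray(1, 0), class = "rostrack_domain_error")
})

test_that("H2O2/O2 ratios reproduce the stored ratio row", {
  tab <- load_table1()
  expect_equal(display_round(h2o2_o2_ratio(tab$h2o2, tab$o2_consumption)),
               tab$ratio_h2o2_o2)
  expect_equal(display_round(h2o2_o2_ratio(0.26, 0.41)), 0.63)
  expect_equal(display_round(h2o2_o2_ratio(0.17, 0.05)), 3.40)
  expect_equal(h2o2_o2_ratio(0.2, 0.2), 1)
  expect_warning(r <- h2o2_o2_ratio(0.2, 0), class = "rostrack_warning")
  expect_true(is.na(r))
  expect_error(h2o2_o2_ratio(0.2, -0.1), class = "rostrack_domain_error")
})

test_that("carbon aggregation matches the brute-force mean/sd", {
  tab <- load_table1()
  agg <- aggregate_carbon(tab, "total_oh")
  carbon_vals <- tab$total_oh[tab$condition != "X-ray"]
  expect_equal(unname(agg["mean"]), sum(carbon_vals) / 5)
  expect_equal(unname(agg["sd"]),
               sqrt(sum((carbon_vals - mean(carbon_vals))^2) / 4))
  expect_equal(display_round(unname(agg["mean"])), 0.31)
  dens <- aggregate_carbon(tab, "sparse_density")
  expect_equal(round(unname(dens["mean"])), 147)
  expect_equal(round(unname(dens["sd"])), 8)
  expect_equal(round(unname(aggregate_carbon(tab, "sparse_conc_mM")["mean"]), 1),
               5.6)
  # invariant under row permutation; X-ray row genuinely excluded
  perm <- tab[c(4, 1, 6, 2, 5, 3), ]
  expect_equal(aggregate_carbon(perm, "total_oh"), agg)
  expect_error(aggregate_carbon(tab[1:2, ][-2, ], "total_oh"),
               class = "rostrack_domain_error")
  expect_error(aggregate_carbon(tab, "no_such_field"),
               class = "rostrack_domain_error")
  # degenerate spread
  same <- data.frame(condition = c("a", "b"), v = c(2, 2))
  expect_equal(unname(aggregate_carbon(same, "v")["sd"]), 0)
})

test_that("hydroxyl contribution curve: plateau, knot continuity, slope recovery", {
  # synthetic hypoxic points exactly on a line through the (70, 0.35) knot
  lets <- c(13, 20, 30, 40, 55)
  truth_slope <- 0.0025
  hyp <- data.frame(let_keV_um = lets,
                    total_oxidation = 0.35 + truth_slope * (lets - 70))
  curve <- oh_contribution_curve(hyp)
  expect_equal(attr(curve, "slope"), truth_slope, tolerance = 1e-12)
  expect_equal(curve(100), 0.35)
  expect_equal(curve(70), 0.35)  # continuity at the knot
  expect_equal(curve(20), 0.35 + truth_slope * (20 - 70))
  expect_equal(curve(NA), 0.35)  # undefined LET -> plateau
  # no data below the onset -> constant with warning
  expect_warning(flat <- oh_contribution_curve(NULL),
                 class = "rostrack_warning")
  expect_equal(flat(c(10, 200)), c(0.35, 0.35))
})

test_that("oxidation partition sums exactly and clamps transparently", {
  suppressWarnings(curve <- oh_contribution_curve(NULL))
  tab <- load_table1()
  # the >100 keV/um total (0.34) is below the 0.35 plateau -> expected clamp
  expect_warning(
    part <- partition_oxidation(tab$total_oxidation, tab$let_keV_um, curve),
    class = "rostrack_warning")
  expect_equal(part$oh_contribution + part$ho2_contribution, part$total)
  # 80 keV/um: 0.66 total - 0.35 plateau = 0.31 hydroperoxyl
  expect_equal(part$ho2_contribution[tab$let_keV_um %in% 80], 0.31)
  # X-ray row (NA LET) uses the plateau: 2.74 - 0.35 = 2.39
  expect_equal(part$ho2_contribution[1], 2.39)
  # total equal to the contribution -> zero remainder
  none <- partition_oxidation(0.35, 90, curve)
  expect_equal(none$ho2_contribution, 0)
  # total below the curve -> clamped with warning, sum identity preserved
  expect_warning(cl <- partition_oxidation(0.2, 120, curve),
                 class = "rostrack_warning")
  expect_true(cl$clamped)
  expect_equal(cl$oh_contribution, 0.2)
  expect_equal(cl$oh_contribution + cl$ho2_contribution, cl$total)
})
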