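test_that("max growth maximizes a strain's biomass under all constraints", {
  # one-strain toy: biomass pathway at cost 0.5 against pool 1 -> growth 2
  m <- strain_model(
    id = "grower",
    mets = metabolites(c("glc_e", "x_c")),
    reactions = list(
      reaction("EX_glc_e_reverse", c(glc_e = 1), ub = 1000, kind = "exchange"),
      reaction("ASSIM", c(glc_e = -1, x_c = 1), enzyme = list(kcat = 2, mw = 1)),
      reaction("BIOMASS", c(x_c = -1), kind = "biomass")
    ),
    biomass_id = "BIOMASS", pool = pool_budget(1, 1, 1))
  res <- max_growth(m)
  expect_equal(res$objective, 2, tolerance = 1e-9)
  # substrate bound 0 -> zero growth (still optimal status, not an error)
  res0 <- max_growth(m, substrate = c(EX_glc_e_reverse = 0))
  expect_equal(res0$status, "optimal")
  expect_equal(res0$objective, 0, tolerance = 1e-12)
  expect_error(max_growth(make_toy2(), strain = "A"), "biomass")
})

test_that("overflow scan shows zero byproduct below threshold, onset above", {
  m <- make_overflow_toy()
  tab <- overflow_scan(m, uptake_grid = 1:20,
                       substrate_exchange = "EX_glc_e_reverse")
  expect_equal(nrow(tab), 20)
  expect_true(all(diff(tab$objective) >= -1e-9))  # monotone in uptake
  expect_true(all(tab$EX_ac_e[tab$uptake <= 10] < 1e-9))
  above <- tab$uptake > 10
  expect_true(all(tab$EX_ac_e[above] > 1e-9))
  expect_equal(tab$EX_ac_e[tab$uptake == 20], 25, tolerance = 1e-9)
  expect_equal(tab$objective[tab$uptake == 5], 130, tolerance = 1e-9)
  expect_error(overflow_scan(m, numeric(), "EX_glc_e_reverse"), "empty")
})

test_that("ratio sweeps locate the optimum and keep infeasible points", {
  sw <- ratio_sweep(make_toy2())
  expect_equal(sw$argmax_label, "2:1")
  expect_equal(sw$max, 3, tolerance = 1e-9)
  expect_equal(nrow(sw$table), 8)
  # grid order is preserved
  expect_equal(sw$table$ratio,
               vapply(default_ratio_grid(c("A", "B")),
                      consortiafba:::ratio_label, ""))
  # sweep is deterministic: identical tables across runs
  sw2 <- ratio_sweep(make_toy2())
  expect_identical(sw$table, sw2$table)
  # a broken grid point is flagged, not dropped
  cm <- make_toy2()
  grid <- default_ratio_grid(c("A", "B"))
  grid[[3]] <- c(A = -1, B = 1)
  sw3 <- ratio_sweep(cm, grid = grid)
  expect_equal(nrow(sw3$table), 8)
  expect_false(sw3$table$status[3] == "optimal")
  expect_equal(sw3$table$v_product[3], 0)
})

test_that("yields, estimation error, and NRMSE follow their definitions", {
  expect_equal(mass_yield(2, 90, 10, 180), 0.1)
  expect_equal(mass_yield(0, 90, 10, 180), 0)
  expect_error(mass_yield(2, 90, 0, 180), "undefined")

  expect_equal(estimation_error(1.1, 1.0), 0.1)
  expect_equal(estimation_error(1.0, 1.0), 0)
  expect_equal(estimation_error(0.9, 1.0), -0.1)
  # antisymmetric under equal over/under-prediction
  expect_equal(estimation_error(1.2, 1.0), -estimation_error(0.8, 1.0))
  expect_error(estimation_error(1, 0), "zero")

  expect_equal(nrmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(nrmse(c(2, 2), c(1, 3)), 0.5)
  expect_equal(nrmse(10 * c(2, 2), 10 * c(1, 3)), 0.5)  # scale invariant
  expect_error(nrmse(c(1, 2), c(1, 2, 3)), "lengths")
  expect_error(nrmse(c(1, 2), c(2, 2)), "constant")
  expect_error(nrmse(1, 2), "two grid points")
})

test_that("sweeps can report mass yields against the substrate uptake", {
  sw <- ratio_sweep(make_toy2(), substrate_exchange = "EX_glc_e_shared_reverse",
                    mw_product = 104, mw_substrate = 180)
  best <- sw$table[sw$table$ratio == "2:1", ]
  # at 2:1 the product flux is 3 against 4.5 glucose: yield by definition
  expect_equal(best$yield,
               mass_yield(best$v_product, 104, best$v_substrate, 180))
  expect_equal(sw$metric, "yield")
})

test_that("strategy comparison separates allocations only under enzyme rows", {
  strategies <- list(
    all_downstream = make_toy2(cost_up = 0, cost_down = 1.5),
    split_burden = make_toy2()
  )
  cmp <- compare_strategies(strategies)
  tab <- cmp$table
  basic <- tab$best[tab$mode == "basic"]
  # stoichiometry cannot distinguish the strategies...
  expect_equal(basic[1], basic[2], tolerance = 1e-9)
  # ...but the enzyme-constrained model does
  ec <- tab$best[tab$mode == "enzyme"]
  expect_gt(abs(ec[1] - ec[2]), 0.5)
  # oracle-checked winners: all-burden-downstream peaks at 9:1 with 20/3,
  # split burden at its interior optimum 2:1 with 3
  expect_equal(tab$best[tab$strategy == "all_downstream" & tab$mode == "enzyme"],
               20 / 3, tolerance = 1e-9)
  expect_equal(tab$best_ratio[tab$strategy == "split_burden" & tab$mode == "enzyme"],
               "2:1")
  expect_error(compare_strategies(list(make_toy2())), "named")
  # single strategy degenerates to its sweep
  single <- compare_strategies(list(only = make_toy2()))
  expect_equal(single$winner, "only")
  expect_equal(single$table$best[single$table$mode == "enzyme"], 3,
               tolerance = 1e-9)
})

test_that("burden placement shapes the sweep: monotone vs interior optimum", {
  # all heterologous burden in one module: yield varies monotonically along
  # the downstream-fraction grid (the unburdened module's share amplifies)
  swI <- ratio_sweep(make_toy2(cost_up = 0, cost_down = 1.5))
  expect_true(all(diff(swI$table$v_product) < 1e-12))
  # split burden: interior grid optimum, strictly better than both ends
  swII <- ratio_sweep(make_toy2())
  expect_equal(swII$argmax_label, "2:1")
  expect_gt(swII$max, swII$table$v_product[1])
  expect_gt(swII$max, swII$table$v_product[nrow(swII$table)])
})

test_that("three-module split beats both two-module merges on their grids", {
  best3 <- ratio_sweep(make_toy3())$max
  for (mg in c("CA+SAA", "SAA+RA", "CA+RA")) {
    best2 <- ratio_sweep(make_toy3(merge = mg))$max
    expect_gt(best3, best2 + 1)
  }
})
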