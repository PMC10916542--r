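test_that("LP construction is deterministic and correctly sized", {
  cm <- make_toy2()
  lp1 <- build_lp(cm, "EX_prod_e_shared")
  lp2 <- build_lp(cm, "EX_prod_e_shared")
  expect_identical(lp1, lp2)
  expect_equal(ncol(lp1$S), length(cm$reactions))
  expect_equal(nrow(lp1$S), nrow(cm$metabolites))
  expect_length(lp1$enz, 2)
  expect_error(build_lp(cm, "NOPE"), "unknown objective")
  expect_error(build_lp(tiny_model(), "BIO"), "negative lower bounds")
})

test_that("simplex handles the textbook degenerate and infeasible cases", {
  # max x1 + x2 s.t. x1 + x2 <= 4, x1 <= 3
  s <- consortiafba:::simplex_solve(c(1, 1),
                                    A_ub = rbind(c(1, 1), c(1, 0)),
                                    b_ub = c(4, 3))
  expect_equal(s$objective, 4)
  # equality-constrained: max x1 s.t. x1 - x2 = 0, x1 + x2 <= 6
  s2 <- consortiafba:::simplex_solve(c(1, 0),
                                     A_eq = rbind(c(1, -1)), b_eq = 0,
                                     A_ub = rbind(c(1, 1)), b_ub = 6)
  expect_equal(s2$objective, 3)
  # infeasible: x1 = -1 with x1 >= 0
  s3 <- consortiafba:::simplex_solve(c(1), A_eq = rbind(c(1)), b_eq = -1)
  expect_equal(s3$status, "infeasible")
  # unbounded
  s4 <- consortiafba:::simplex_solve(c(1))
  expect_equal(s4$status, "unbounded")
})

test_that("objective on a knocked-out reaction is zero", {
  cm <- make_toy2()
  cm$reactions$EX_prod_e_shared$ub <- 0
  expect_equal(solve_fba(cm, "EX_prod_e_shared")$objective, 0, tolerance = 1e-12)
})

test_that("a model with no substrate uptake carries no flux", {
  cm <- make_toy2(glc_cap = 0)
  res <- solve_fba(cm, "EX_prod_e_shared")
  expect_equal(res$objective, 0, tolerance = 1e-12)
})

test_that("solver optimum matches the exact vertex oracle on random toys", {
  set.seed(1905)
  for (i in 1:10) {
    cm <- random_toy2()
    res <- solve_fba(cm, "EX_prod_e_shared")
    vo <- vertex_oracle(cm, "EX_prod_e_shared")
    expect_equal(res$objective, vo$objective, tolerance = 1e-6,
                 label = sprintf("random toy %d (solver %g vs oracle %g)",
                                 i, res$objective, vo$objective))
  }
})

test_that("splitting reversible reactions preserves the optimal value", {
  # reversible transporter (-5, 10) in the tiny model: the optimum of the
  # split model equals the hand-derived net-flux optimum
  m <- split_reversible(tiny_model())
  res <- solve_fba(m, "BIO", enzyme = FALSE)
  # BIO is fed through T_a (ub 10) and CONV (ub 8): net optimum is 8
  expect_equal(res$objective, 8, tolerance = 1e-9)
  vo <- vertex_oracle(m, "BIO")
  res_ec <- solve_fba(m, "BIO")
  expect_equal(res_ec$objective, vo$objective, tolerance = 1e-6)
})

test_that("scaling all bounds and pools by lambda scales the optimum", {
  lam <- 3
  base <- solve_fba(make_toy2(), "EX_prod_e_shared")$objective
  scaled <- solve_fba(make_toy2(pool_up = lam, pool_down = lam,
                                glc_cap = 10 * lam, ratio = c(A = 2, B = 1)),
                      "EX_prod_e_shared")$objective
  expect_equal(scaled, lam * base, tolerance = 1e-9)
})

test_that("relaxing any single bound never decreases the optimum", {
  base <- solve_fba(make_toy2(), "EX_prod_e_shared")$objective
  expect_gte(solve_fba(make_toy2(glc_cap = 12), "EX_prod_e_shared")$objective,
             base - 1e-12)
  expect_gte(solve_fba(make_toy2(pool_down = 1.5), "EX_prod_e_shared")$objective,
             base - 1e-12)
})

test_that("pFBA reproduces unique optima and minimizes flux under degeneracy", {
  cm <- make_toy2()
  plain <- solve_fba(cm, "EX_prod_e_shared")
  pars <- pfba(cm, "EX_prod_e_shared")
  expect_equal(pars$objective, plain$objective, tolerance = 1e-8)
  expect_equal(pars$fluxes, plain$fluxes, tolerance = 1e-6)  # non-degenerate
  # two equal parallel paths: flux split is arbitrary, total flux is not
  par <- make_parallel_toy(cap = 4)
  res <- pfba(par, "EX_p")
  expect_equal(res$objective, 4, tolerance = 1e-9)
  expect_equal(res$total_flux, 12, tolerance = 1e-6)  # 4 + (4 split) + 4
  expect_equal(res$fluxes[["P1"]] + res$fluxes[["P2"]], 4, tolerance = 1e-9)
  # forced-zero objective gives the all-zero parsimonious vector
  par0 <- par
  par0$reactions$SRC$ub <- 0
  res0 <- pfba(par0, "EX_p")
  expect_equal(res0$total_flux, 0, tolerance = 1e-9)
})

test_that("validation passes true optima and names corrupted rows", {
  cm <- make_toy2()
  res <- solve_fba(cm, "EX_prod_e_shared")
  expect_true(res$check$pass)
  bad <- res$fluxes
  bad[["CONVup@A"]] <- bad[["CONVup@A"]] + 0.5
  rep <- validate_solution(bad, res$problem, tol = 1e-9)
  expect_false(rep$pass)
  expect_true(any(grepl("steady_state|enzyme_pool", rep$violations$constraint)))
  # tol = 0 rejects even genuine floating-point optima: why 1e-9 is default
  rep0 <- validate_solution(res$fluxes + 1e-14, res$problem, tol = 0)
  expect_false(rep0$pass)
})

test_that("oracle refuses oversized problems and reports exact rationals", {
  big <- make_toy3()
  expect_error(vertex_oracle(big, "EX_prod_e_shared", max_vars = 5),
               "refuses")
  vo <- vertex_oracle(make_toy2(), "EX_prod_e_shared")
  expect_identical(vo$objective_rat, c(3, 1))
  # infeasible product export: optimum 0 at the zero vertex
  cm <- make_toy2()
  cm$reactions$EX_prod_e_shared$ub <- 0
  vo0 <- vertex_oracle(cm, "EX_prod_e_shared")
  expect_equal(vo0$objective, 0)
  expect_true(any(apply(vo0$vertices, 1, function(v) all(v == 0))))
})
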