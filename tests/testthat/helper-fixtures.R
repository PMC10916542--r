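# Shared fixtures, built in code at test time.

# Small strain model exercising reversible bounds, gene rules, enzyme
# annotations, and every reaction kind.
tiny_model <- function() {
  strain_model(
    id = "tiny",
    mets = metabolites(c("a_e", "a_c", "b_c"),
                       formula = c("C6H12O6", "C6H12O6", "C3H6O3")),
    reactions = list(
      reaction("EX_a_e", c(a_e = -1), lb = -10, ub = 1000, kind = "exchange"),
      reaction("T_a", c(a_e = -1, a_c = 1), lb = -5, ub = 10,
               gene_rule = "g1 and g2",
               enzyme = list(kcat = 3600, mw = 40)),
      reaction("CONV", c(a_c = -1, b_c = 1), ub = 8,
               gene_rule = "g1 or g2",
               enzyme = list(kcat = 1800, mw = 30)),
      reaction("BIO", c(b_c = -1), ub = 1000, kind = "biomass")
    ),
    biomass_id = "BIO",
    pool = pool_budget(0.5, 0.8, 0.5)
  )
}

# Random round-number TOY2 variant; all parameters exact small rationals so
# the vertex oracle stays exact.
random_toy2 <- function() {
  make_toy2(cost_up = sample(c(0.2, 0.25, 0.5, 1, 2), 1),
            cost_down = sample(c(0.25, 0.5, 1, 2), 1),
            pool_up = sample(c(0.5, 1, 2), 1),
            pool_down = sample(c(0.5, 1, 2), 1),
            glc_cap = sample(c(4, 10, 25), 1),
            ratio = stats::setNames(sample(1:9, 2, replace = TRUE), c("A", "B")))
}

random_ratio <- function(tags) {
  stats::setNames(sample(1:9, length(tags), replace = TRUE), tags)
}

expect_objective <- function(model, objective, expected, tol = 1e-9) {
  res <- solve_fba(model, objective)
  expect_equal(res$status, "optimal")
  expect_equal(res$objective, expected, tolerance = tol)
  invisible(res)
}
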