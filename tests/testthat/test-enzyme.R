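test_that("pool budgets multiply out and reject out-of-range inputs", {
  p <- pool_budget(0.56, 0.406, 0.5)
  expect_equal(p$enz, 0.11368)
  expect_equal(pool_budget(0.3, 0.5, 1)$enz, 0.15)  # sigma = 1 boundary
  expect_error(pool_budget(0.5, 0, 0.5), "f must be")
  expect_error(pool_budget(0.5, 1.2, 0.5), "f must be")
  expect_error(pool_budget(-1, 0.5, 0.5), "ptot")
  expect_error(pool_budget(0.5, 0.5, 0), "sigma")
})

test_that("enzyme cost is v*mw/kcat with guarded inputs", {
  expect_equal(enzyme_cost(2, 40, 4000), 0.02)
  expect_equal(enzyme_cost(0, 40, 4000), 0)
  expect_equal(enzyme_cost(3, 10, 200), 2 * enzyme_cost(3, 10, 400))
  expect_error(enzyme_cost(1, 10, 0), "kcat")
  expect_error(enzyme_cost(-1, 10, 10), ">= 0")
})

test_that("enzyme tables load, convert units, and reject bad rows", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("reaction_id\tkcat\tkcat_unit\tmw\tprovenance",
               "CONV\t1\t1/s\t30\tmanual",
               "T_a\t7200\t1/h\t40\tmanual",
               "BIO\t100\t1/h\t5\tmanual"), path)
  tab <- load_enzyme_table(path)
  expect_equal(nrow(tab), 3)
  expect_equal(tab$kcat[tab$reaction_id == "CONV"], 3600)  # 1/s -> 1/h
  expect_equal(tab$kcat[tab$reaction_id == "T_a"], 7200)

  dup <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("reaction_id,kcat,mw", "R1,10,5", "R1,20,5"), dup)
  expect_error(load_enzyme_table(dup), "duplicate.*R1")

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("reaction_id,kcat,mw", "R1,10,5", "R2,-3,5"), bad)
  expect_error(load_enzyme_table(bad), "row\\(s\\) 3")
  expect_error(load_enzyme_table(withr::local_tempfile(fileext = ".csv")),
               "not found|cannot")
})

test_that("attach matches on base id through tags and _reverse suffixes", {
  m <- split_reversible(namespace_model(tiny_model(), "A"))
  tab <- as_enzyme_table(data.frame(
    reaction_id = c("T_a", "CONV", "BIO"),
    kcat = c(100, 200, 400), mw = c(10, 20, 40)))
  m2 <- attach_enzymes(m, tab)
  expect_equal(m2$reactions[["T_a@A"]]$enzyme, list(kcat = 100, mw = 10))
  expect_equal(m2$reactions[["T_a@A_reverse"]]$enzyme, list(kcat = 100, mw = 10))
  rep <- enzyme_coverage(m2)
  expect_equal(attr(rep, "coverage"), 100)
  expect_true(all(rep$source == "table"))
})

test_that("fallback handling: exclude drops terms, default_kcat uses medians", {
  m <- tiny_model()
  tab <- as_enzyme_table(data.frame(reaction_id = c("T_a", "BIO"),
                                    kcat = c(100, 400), mw = c(10, 40)))
  ex <- attach_enzymes(m, tab, fallback = "exclude")
  expect_null(ex$reactions$CONV$enzyme)
  expect_equal(enzyme_coverage(ex)$source[enzyme_coverage(ex)$reaction == "CONV"],
               "excluded")
  rows <- constraint_rows(ex)
  expect_false("CONV" %in% names(rows[[1]]$coef))

  de <- attach_enzymes(m, tab, fallback = "default_kcat")
  # medians of the matched set: kcat 250, mw 25
  expect_equal(de$reactions$CONV$enzyme, list(kcat = 250, mw = 25))
  expect_equal(enzyme_coverage(de)$source[enzyme_coverage(de)$reaction == "CONV"],
               "default")
  # coverage percent counts only table matches
  expect_equal(attr(enzyme_coverage(de), "coverage"), 100 * 2 / 3)
})

test_that("exchanges and links never receive enzyme cost", {
  cm <- make_toy2()
  tab <- as_enzyme_table(data.frame(reaction_id = c("EX_glc_e_shared",
                                                    "LNK_ita_e", "CONVup"),
                                    kcat = c(1, 1, 2), mw = c(1, 1, 1)))
  cm2 <- attach_enzymes(cm, tab)
  expect_null(cm2$reactions$EX_glc_e_shared$enzyme)
  expect_null(cm2$reactions[["LNK_ita_e@A"]]$enzyme)
  expect_false(any(grepl("^EX_|^LNK_", enzyme_coverage(cm2)$reaction)))
})

test_that("constraint rows are one per strain with disjoint support", {
  cm <- make_toy2()
  rows <- constraint_rows(cm)
  expect_length(rows, 2)
  expect_setequal(vapply(rows, `[[`, "", "strain"), c("A", "B"))
  byA <- rows[[which(vapply(rows, `[[`, "", "strain") == "A")]]
  byB <- rows[[which(vapply(rows, `[[`, "", "strain") == "B")]]
  expect_length(intersect(names(byA$coef), names(byB$coef)), 0)
  expect_equal(unname(byA$coef["CONVup@A"]), 0.5)  # mw/kcat = 1/2
  expect_equal(unname(byB$coef["CONVdn@B"]), 1.0)
  expect_equal(byA$rhs, 1)
  # strain with no annotations: vacuous, warns, produces no row
  m <- make_overflow_toy()
  m$reactions$RESP$enzyme <- NULL
  m$reactions$FERM$enzyme <- NULL
  expect_warning(r0 <- constraint_rows(m), "vacuous")
  expect_length(r0, 0)
  # pool missing but annotations present: hard error
  m2 <- make_overflow_toy()
  m2$pool <- NULL
  expect_error(constraint_rows(m2), "no pool")
})

test_that("enzyme usage at any optimum respects every strain budget", {
  for (cm in list(make_toy2(), make_toy3())) {
    res <- solve_fba(cm, "EX_prod_e_shared")
    for (u in res$enzyme_usage)
      expect_lte(u[["usage"]], u[["budget"]] + 1e-9)
  }
})

test_that("relaxing the pools monotonically raises the optimum to plain FBA", {
  base <- solve_fba(make_toy2(), "EX_prod_e_shared")$objective
  lam2 <- solve_fba(make_toy2(pool_up = 2, pool_down = 2),
                    "EX_prod_e_shared")$objective
  expect_gte(lam2, base - 1e-12)
  # enz -> infinity converges to the stoichiometric optimum
  huge <- solve_fba(make_toy2(pool_up = 1e7, pool_down = 1e7),
                    "EX_prod_e_shared")$objective
  plain <- solve_fba(make_toy2(), "EX_prod_e_shared", enzyme = FALSE)$objective
  expect_equal(huge, plain, tolerance = 1e-6)
})
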