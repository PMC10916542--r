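test_that("JSON round-trip preserves ids, stoichiometry, bounds, gene rules", {
  m <- tiny_model()
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m, path)
  m2 <- read_gem(path)
  expect_setequal(names(m2$reactions), names(m$reactions))
  expect_setequal(m2$metabolites$id, m$metabolites$id)
  for (id in names(m$reactions)) {
    r <- m$reactions[[id]]; r2 <- m2$reactions[[id]]
    expect_equal(r2$stoich[names(r$stoich)], r$stoich)
    expect_equal(r2$lb, r$lb)
    expect_equal(r2$ub, r$ub)
    expect_equal(r2$gene_rule, r$gene_rule)
    expect_equal(r2$kind, r$kind)
    expect_equal(r2$enzyme, r$enzyme)
  }
  expect_equal(m2$biomass_id, "BIO")
  expect_equal(m2$pool$enz, m$pool$enz)
})

test_that("SBML round-trip preserves ids, stoichiometry, bounds, gene rules", {
  m <- tiny_model()
  path <- withr::local_tempfile(fileext = ".xml")
  write_model(m, path)
  m2 <- read_gem(path)
  expect_setequal(names(m2$reactions), names(m$reactions))
  for (id in names(m$reactions)) {
    r <- m$reactions[[id]]; r2 <- m2$reactions[[id]]
    expect_equal(r2$stoich[names(r$stoich)], r$stoich)
    expect_equal(c(r2$lb, r2$ub), c(r$lb, r$ub))
    expect_equal(r2$enzyme, r$enzyme)
  }
  # boolean structure survives even if formatting differs
  expect_true(eval_gene_rule(m2$reactions$T_a$gene_rule, "g1") ==
                eval_gene_rule("g1 and g2", "g1"))
  expect_equal(m2$metabolites[order(m2$metabolites$id), "formula"],
               m$metabolites[order(m$metabolites$id), "formula"])
})

test_that("namespaced community models round-trip through both formats", {
  cm <- make_toy2()
  for (ext in c(".json", ".xml")) {
    path <- withr::local_tempfile(fileext = ext)
    write_model(cm, path)
    cm2 <- read_gem(path)
    expect_s3_class(cm2, "community_model")
    expect_equal(sort(names(cm2$reactions)), sort(names(cm$reactions)))
    expect_equal(cm2$ratio, cm$ratio)
    expect_equal(cm2$tags, cm$tags)
    # solving the round-tripped model gives the identical optimum
    expect_equal(solve_fba(cm2, "EX_prod_e_shared")$objective, 3.0,
                 tolerance = 1e-9)
  }
})

test_that("reading rejects malformed files with informative errors", {
  bad <- withr::local_tempfile(fileext = ".json")
  writeLines('{"metabolites": [{"id": "a_c"}], "reactions": [
    {"id": "R1", "metabolites": {"ghost_c": -1}, "lower_bound": 0,
     "upper_bound": 10}]}', bad)
  expect_error(read_gem(bad), "ghost_c")
  nofile <- file.path(tempdir(), "does_not_exist.json")
  expect_error(read_gem(nofile), "not found")
})

test_that("SBML reactions without resolvable fbc bounds are reported by id", {
  m <- tiny_model()
  path <- withr::local_tempfile(fileext = ".xml")
  write_model(m, path)
  txt <- readLines(path)
  txt <- vapply(txt, function(l)
    if (grepl('id="R_CONV"', l))
      sub('fbc:upperFluxBound="[^"]*"', 'fbc:upperFluxBound="nope"', l)
    else l, "", USE.NAMES = FALSE)
  writeLines(txt, path)
  expect_error(read_gem(path), "CONV")
})

test_that("write_model refuses models violating invariants", {
  m <- tiny_model()
  m$reactions$CONV$stoich <- c(ghost_c = -1, b_c = 1)
  expect_error(write_model(m, tempfile(fileext = ".json")), "ghost_c")
})

test_that("split_reversible produces irreversible sibling pairs", {
  m <- split_reversible(tiny_model())
  expect_true(all(vapply(m$reactions, `[[`, 0, "lb") == 0))
  # (-10, 1000) exchange splits into (0,1000) + reverse (0,10)
  expect_equal(m$reactions$EX_a_e$ub, 1000)
  expect_equal(m$reactions$EX_a_e_reverse$ub, 10)
  expect_equal(m$reactions$EX_a_e_reverse$stoich, c(a_e = 1))
  # (-5, 10) internal reaction: negated stoichiometry, enzyme copied
  expect_equal(m$reactions$T_a_reverse$ub, 5)
  expect_equal(m$reactions$T_a_reverse$stoich, c(a_e = 1, a_c = -1))
  expect_equal(m$reactions$T_a_reverse$enzyme, m$reactions$T_a$enzyme)
  # irreversible reactions pass through without a sibling
  expect_false("CONV_reverse" %in% names(m$reactions))
  expect_equal(m$reactions$CONV$ub, 8)
  # idempotent
  expect_identical(split_reversible(m), m)
})

test_that("split refuses models with pre-existing _reverse collisions", {
  m <- tiny_model()
  m$reactions[["T_a_reverse"]] <- reaction("T_a_reverse", c(a_c = -1, a_e = 1))
  expect_error(split_reversible(m), "T_a_reverse")
})

test_that("knockouts zero bounds, keep rows, and never touch the input", {
  m <- tiny_model()
  before <- m
  m2 <- apply_edits(m, knockouts = c("CONV", "BIO"))
  expect_identical(m, before)  # non-destructive
  expect_equal(length(m2$reactions), length(m$reactions))
  expect_equal(m2$reactions$CONV$ub, 0)
  expect_equal(m2$reactions$BIO$ub, 0)
  m3 <- apply_edits(m, knockouts = "CONV", delete = TRUE)
  expect_false("CONV" %in% names(m3$reactions))
  expect_error(apply_edits(m, knockouts = "NOPE"), "NOPE")
})

test_that("gene knockouts map through and/or rules", {
  m <- tiny_model()
  # T_a needs g1 AND g2: deleting g1 closes it
  ko1 <- apply_edits(m, knockouts = "g1")
  expect_equal(ko1$reactions$T_a$ub, 0)
  # CONV is g1 OR g2: g1 alone leaves it open, both close it
  expect_equal(ko1$reactions$CONV$ub, 8)
  ko12 <- apply_edits(m, knockouts = c("g1", "g2"))
  expect_equal(ko12$reactions$CONV$ub, 0)
  # full truth table on a nested rule
  rule <- "gA and (gB or gC)"
  expect_true(eval_gene_rule(rule, character()))
  expect_false(eval_gene_rule(rule, "gA"))
  expect_true(eval_gene_rule(rule, "gB"))
  expect_false(eval_gene_rule(rule, c("gB", "gC")))
  expect_setequal(rule_genes(parse_gene_rule(rule)), c("gA", "gB", "gC"))
})

test_that("heterologous pathway additions extend the network", {
  m <- tiny_model()
  # five-step chain from the native product node, TAL->...->NOMT style
  steps <- c("TAL", "FCL", "CHS", "CHI", "NOMT")
  mets_chain <- paste0("x", seq_along(steps), "_c")
  adds <- lapply(seq_along(steps), function(i) {
    from <- if (i == 1) "b_c" else mets_chain[i - 1]
    list(id = steps[i],
         stoich = stats::setNames(c(-1, 1), c(from, mets_chain[i])),
         metabolites = metabolites(mets_chain[i]),
         enzyme = list(kcat = 100, mw = 50))
  })
  m2 <- apply_edits(m, additions = adds)
  expect_true(all(steps %in% names(m2$reactions)))
  expect_true(all(mets_chain %in% m2$metabolites$id))
  # the chain is reachable: adding a sink for the end product carries flux
  m2 <- apply_edits(m2, additions = list(list(
    id = "DM_x5", stoich = c(x5_c = -1))))
  m2 <- split_reversible(m2)
  res <- solve_fba(m2, "DM_x5", enzyme = FALSE)
  expect_gt(res$objective, 0)
  expect_error(apply_edits(m, additions = list(list(id = "CONV", stoich = c(b_c = 1)))),
               "collides")
})

test_that("bound changes apply to named reactions", {
  m <- apply_edits(tiny_model(), bound_changes = list(CONV = c(0, 3)))
  expect_equal(m$reactions$CONV$ub, 3)
})
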