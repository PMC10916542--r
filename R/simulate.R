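#' Predict the maximum growth rate of one strain
#'
#' Maximizes the biomass flux of the chosen strain under all community
#' constraints (steady state, bounds, enzyme pools, link scaling).
#'
#' @param model A `community_model` (or a `strain_model` with a biomass
#'   reaction).
#' @param strain Strain tag (community models; ignored otherwise).
#' @param substrate Optional named list/vector of exchange-reaction upper
#'   bounds applied before solving, e.g.
#'   `c(EX_glc_e_shared_reverse = 10)`.
#' @param ... Passed to [solve_fba()].
#' @return An `fba_result`; the growth rate (h^-1) is its `objective`.
#'   Infeasibility is reported through `status`, never as a silent zero.
#' @export
max_growth <- function(model, strain = NULL, substrate = NULL, ...) {
  biomass <- if (inherits(model, "community_model")) {
    if (is.null(strain) || !strain %in% names(model$biomass))
      stop("strain '", strain, "' has no registered biomass reaction")
    model$biomass[[strain]]
  } else {
    if (is.null(model$biomass_id))
      stop("model has no biomass reaction")
    model$biomass_id
  }
  if (!is.null(substrate))
    for (id in names(substrate)) {
      get_reaction(model, id)
      model$reactions[[id]]$ub <- as.numeric(substrate[[id]])
    }
  solve_fba(model, biomass, ...)
}

#' Scan substrate uptake for overflow metabolism
#'
#' Solves the model across a grid of substrate uptake bounds and reports
#' the optimal objective with all secretion fluxes (forward exchange
#' reactions), using parsimonious flux distributions. When the enzyme pool
#' rather than substrate limits the efficient route, low-cost fermentation
#' switches on and byproducts appear above a sharp uptake threshold.
#'
#' @param model A `strain_model` (one strain; uses its enzyme pool).
#' @param uptake_grid Numeric vector of uptake bounds.
#' @param substrate_exchange Id of the uptake reaction whose bound is
#'   scanned.
#' @param objective Objective reaction id (default: the model's
#'   `"objective"` attribute).
#' @return A data.frame: `uptake`, `status`, `objective`, one column per
#'   secreting exchange reaction.
#' @export
overflow_scan <- function(model, uptake_grid, substrate_exchange,
                          objective = attr(model, "objective")) {
  if (!length(uptake_grid)) stop("empty uptake grid")
  get_reaction(model, substrate_exchange)
  secretions <- names(Filter(function(r)
    r$kind == "exchange" && any(r$stoich < 0), model$reactions))
  rows <- lapply(uptake_grid, function(u) {
    m <- model
    m$reactions[[substrate_exchange]]$ub <- u
    res <- pfba(m, objective)
    out <- data.frame(uptake = u, status = res$status,
                      objective = res$objective)
    for (s in secretions) out[[s]] <- unname(res$fluxes[s])
    out
  })
  do.call(rbind, rows)
}

#' Mass yield of product on substrate
#'
#' `(v_product * mw_product) / (v_substrate * mw_substrate)`: molar fluxes
#' weighted by molecular mass cancel to g product per g substrate.
#'
#' @param v_product,v_substrate Fluxes (mmol gDW^-1 h^-1); `v_substrate`
#'   must be positive.
#' @param mw_product,mw_substrate Molecular weights (g mol^-1).
#' @return Mass yield (g/g).
#' @export
mass_yield <- function(v_product, mw_product, v_substrate, mw_substrate) {
  if (any(v_substrate == 0))
    stop("undefined yield: substrate flux is zero")
  (v_product * mw_product) / (v_substrate * mw_substrate)
}

#' Signed relative estimation error
#'
#' `(yield_sim - yield_exp) / yield_exp`; over-prediction is positive,
#' under-prediction negative.
#'
#' @param yield_sim Simulated yield(s).
#' @param yield_exp Experimental yield(s), > 0.
#' @return Signed relative error. Vectorized.
#' @export
estimation_error <- function(yield_sim, yield_exp) {
  if (any(yield_exp == 0)) stop("experimental yield of zero: error undefined")
  (yield_sim - yield_exp) / yield_exp
}

#' Normalized root-mean-square error over a ratio grid
#'
#' `sqrt(mean((sim - exp)^2)) / (max(exp) - min(exp))`. The root contains
#' the mean of the squared deviations (standard RMSE convention); the
#' normalization is the range of the experimental series.
#'
#' @param sim,exp Equal-length yield series (>= 2 points); `exp` must be
#'   non-constant.
#' @return Nonnegative scalar.
#' @examples
#' nrmse(c(2, 2), c(1, 3))  # 0.5
#' @export
nrmse <- function(sim, exp) {
  if (length(sim) != length(exp)) stop("series lengths differ")
  if (length(exp) < 2) stop("need at least two grid points")
  rng <- max(exp) - min(exp)
  if (rng == 0) stop("constant experimental series: zero normalization range")
  sqrt(mean((sim - exp)^2)) / rng
}

ratio_label <- function(r) paste(format(unname(r)), collapse = ":")

#' Sweep inoculation ratios and locate the optimum
#'
#' For each grid ratio: [set_ratio()], rebuild the LP, solve, and record
#' the objective (product) flux; optionally convert to mass yield against
#' the substrate uptake flux of a parsimonious solution. Infeasible grid
#' points are kept with yield 0 and a status flag, so grids stay
#' rectangular; solver errors never abort the sweep.
#'
#' @param community A `community_model`.
#' @param grid List of named ratio vectors; default
#'   [default_ratio_grid()] over the community's strains.
#' @param objective Product (objective) reaction id; defaults to the
#'   model's `"objective"` attribute.
#' @param substrate_exchange Optional uptake reaction id used for yields.
#' @param mw_product,mw_substrate Molecular weights (g mol^-1) enabling
#'   the `yield` column.
#' @param enzyme `FALSE` drops the enzyme rows ("basic GEM" mode).
#' @return An object of class `"sweep_result"`: `table` (one row per
#'   ratio), `argmax` (best ratio vector), `max` (its objective value).
#' @export
ratio_sweep <- function(community, grid = NULL,
                        objective = attr(community, "objective"),
                        substrate_exchange = NULL,
                        mw_product = NULL, mw_substrate = NULL,
                        enzyme = TRUE) {
  if (is.null(grid)) grid <- default_ratio_grid(community$tags)
  if (is.null(objective)) stop("no objective reaction given")
  rows <- list()
  for (i in seq_along(grid)) {
    r <- grid[[i]]
    row <- data.frame(ratio = ratio_label(r), stringsAsFactors = FALSE)
    for (tg in community$tags) row[[tg]] <- unname(r[[tg]])
    res <- tryCatch({
      cm <- set_ratio(community, r)
      solve_fba(cm, objective, enzyme = enzyme,
                parsimonious = !is.null(substrate_exchange))
    }, error = function(e) e)
    if (inherits(res, "error") || res$status != "optimal") {
      row$status <- if (inherits(res, "error")) conditionMessage(res)
                    else res$status
      row$v_product <- 0; row$v_substrate <- NA_real_
      if (!is.null(mw_product)) row$yield <- 0
    } else {
      row$status <- "optimal"
      row$v_product <- res$objective
      row$v_substrate <- if (!is.null(substrate_exchange))
        unname(res$fluxes[substrate_exchange]) else NA_real_
      if (!is.null(mw_product) && !is.null(mw_substrate)) {
        row$yield <- if (isTRUE(row$v_substrate > 0))
          mass_yield(row$v_product, mw_product, row$v_substrate, mw_substrate)
          else 0
      }
    }
    rows[[i]] <- row
  }
  table <- do.call(rbind, rows)
  score <- if ("yield" %in% names(table)) table$yield else table$v_product
  best <- which.max(score)
  structure(list(table = table, grid = grid,
                 argmax = grid[[best]], argmax_label = table$ratio[best],
                 max = score[best],
                 metric = if ("yield" %in% names(table)) "yield" else "v_product"),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("<sweep_result> ", nrow(x$table), " ratio points, metric: ",
      x$metric, "\n", sep = "")
  print(x$table, row.names = FALSE)
  cat("optimum at ", x$argmax_label, " (", x$metric, " = ",
      format(x$max, digits = 10), ")\n", sep = "")
  invisible(x)
}

#' Compare pathway-allocation strategies
#'
#' Sweeps each candidate community over the same ratio grid in
#' enzyme-constrained mode and again with the enzyme rows removed ("basic
#' GEM" mode, the purely stoichiometric relaxation). The winner is the
#' strategy with the highest enzyme-constrained optimum; the basic-GEM
#' column shows what a stoichiometry-only model can(not) distinguish.
#'
#' @param strategies Named list of `community_model`s sharing the same
#'   objective (product) reaction id.
#' @param grid Ratio grid per strategy: a list (one grid per strategy,
#'   recycled if a single grid) or `NULL` for per-community defaults.
#' @param objective Product reaction id common to all strategies.
#' @param ... Passed to [ratio_sweep()].
#' @return An object of class `"strategy_comparison"`: `table` (strategy,
#'   mode, best ratio, best value), `winner`, `sweeps`.
#' @export
compare_strategies <- function(strategies, grid = NULL, objective = NULL, ...) {
  if (is.null(names(strategies)) || any(!nzchar(names(strategies))))
    stop("strategies must be a named list")
  objs <- vapply(strategies, function(s)
    objective %||% attr(s, "objective") %||% NA_character_, "")
  if (anyNA(objs) || length(unique(objs)) != 1L)
    stop("strategies must share one product (objective) reaction id; got: ",
         paste(unique(objs), collapse = ", "))
  rows <- list(); sweeps <- list()
  for (nm in names(strategies)) {
    cm <- strategies[[nm]]
    g <- if (is.null(grid)) default_ratio_grid(cm$tags)
         else if (is.list(grid[[1]])) grid[[nm]] else grid
    for (mode in c("enzyme", "basic")) {
      sw <- ratio_sweep(cm, grid = g, objective = objs[[nm]],
                        enzyme = mode == "enzyme", ...)
      sweeps[[paste(nm, mode, sep = ".")]] <- sw
      rows[[paste(nm, mode, sep = ".")]] <-
        data.frame(strategy = nm, mode = mode,
                   best_ratio = sw$argmax_label, best = sw$max,
                   stringsAsFactors = FALSE)
    }
  }
  table <- do.call(rbind, rows)
  ec <- table[table$mode == "enzyme", ]
  structure(list(table = table, winner = ec$strategy[which.max(ec$best)],
                 sweeps = sweeps),
            class = "strategy_comparison")
}

#' @export
print.strategy_comparison <- function(x, ...) {
  cat("<strategy_comparison>\n")
  print(x$table, row.names = FALSE)
  cat("winner (enzyme-constrained): ", x$winner, "\n", sep = "")
  invisible(x)
}
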