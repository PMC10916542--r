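#' Build the community linear program
#'
#' Assembles `maximize c'v` subject to steady state `S v = 0`, flux bounds
#' `0 <= v <= ub`, and one enzyme-pool inequality per strain. Variable and
#' row ordering is the sorted reaction/metabolite id order, so repeated
#' builds of the same model are bit-identical.
#'
#' @param model A `strain_model` or `community_model` (irreversible form:
#'   all lower bounds 0).
#' @param objective Reaction id to maximize, or a named coefficient vector.
#' @param enzyme Include the enzyme-pool rows (`FALSE` gives the plain
#'   stoichiometric "basic GEM" relaxation).
#' @return An object of class `"lp_problem"`: `vars`, `mets`, `S`, `c`,
#'   `ub`, `enz` (list of per-strain rows).
#' @export
build_lp <- function(model, objective, enzyme = TRUE) {
  vars <- sort(names(model$reactions))
  mets <- sort(model$metabolites$id)
  if (any(vapply(model$reactions, `[[`, 0, "lb") < 0))
    stop("model has negative lower bounds; call split_reversible() first")
  S <- matrix(0, length(mets), length(vars), dimnames = list(mets, vars))
  for (r in model$reactions) S[names(r$stoich), r$id] <- unname(r$stoich)
  ub <- vapply(vars, function(v) model$reactions[[v]]$ub, 0)
  if (is.character(objective)) {
    if (!objective %in% vars)
      stop("unknown objective reaction '", objective, "'")
    c_obj <- stats::setNames(numeric(length(vars)), vars)
    c_obj[objective] <- 1
  } else {
    unknown <- setdiff(names(objective), vars)
    if (length(unknown))
      stop("unknown objective reaction(s): ", paste(unknown, collapse = ", "))
    c_obj <- stats::setNames(numeric(length(vars)), vars)
    c_obj[names(objective)] <- objective
  }
  enz_rows <- if (enzyme) constraint_rows_quiet(model) else list()
  structure(list(vars = vars, mets = mets, S = S, c = c_obj, ub = ub,
                 enz = enz_rows, model_id = model$id),
            class = "lp_problem")
}

# constraint_rows without the vacuous-strain warning (sweeps would spam it)
constraint_rows_quiet <- function(model) {
  suppressWarnings(constraint_rows(model))
}

lp_matrices <- function(problem) {
  n <- length(problem$vars)
  A_ub <- matrix(0, 0, n)
  b_ub <- numeric()
  rn <- character()
  for (row in problem$enz) {
    r <- stats::setNames(numeric(n), problem$vars)
    r[names(row$coef)] <- row$coef
    A_ub <- rbind(A_ub, r)
    b_ub <- c(b_ub, row$rhs)
    rn <- c(rn, paste0("enzyme_pool:", row$strain))
  }
  finite <- which(is.finite(problem$ub))
  if (length(finite)) {
    I <- matrix(0, length(finite), n)
    I[cbind(seq_along(finite), finite)] <- 1
    A_ub <- rbind(A_ub, I)
    b_ub <- c(b_ub, problem$ub[finite])
    rn <- c(rn, paste0("ub:", problem$vars[finite]))
  }
  rownames(A_ub) <- rn
  list(A_ub = A_ub, b_ub = b_ub)
}

#' Solve a flux balance analysis problem
#'
#' Runs the deterministic simplex on the LP from [build_lp()] and re-checks
#' feasibility of the returned point (steady-state residuals, bounds,
#' enzyme rows) with independent arithmetic before reporting it.
#'
#' @param model A model, or an `lp_problem` from [build_lp()].
#' @param objective Objective reaction id (ignored when `model` is already
#'   an `lp_problem`).
#' @param enzyme Include enzyme-pool rows (see [build_lp()]).
#' @param parsimonious After optimizing, minimize total flux among
#'   solutions within relative `1e-12` of the optimum (pFBA) so reported flux
#'   distributions are reproducible across alternate optima.
#' @param tol Solver tolerance.
#' @return An object of class `"fba_result"`: `status`, `objective`,
#'   `fluxes` (named), `enzyme_usage` (per strain: usage, budget, slack),
#'   `binding` (binding-constraint labels), `total_flux`, `check`.
#' @export
solve_fba <- function(model, objective = NULL, enzyme = TRUE,
                      parsimonious = FALSE, tol = 1e-9) {
  problem <- if (inherits(model, "lp_problem")) model
             else build_lp(model, objective, enzyme = enzyme)
  mats <- lp_matrices(problem)
  sol <- simplex_solve(problem$c, A_eq = problem$S,
                       b_eq = numeric(nrow(problem$S)),
                       A_ub = mats$A_ub, b_ub = mats$b_ub, tol = tol)
  if (sol$status != "optimal") {
    return(structure(list(status = sol$status, objective = sol$objective,
                          fluxes = stats::setNames(rep(NA_real_,
                                                       length(problem$vars)),
                                                   problem$vars),
                          enzyme_usage = NULL, binding = character(),
                          total_flux = NA_real_, check = NULL,
                          problem = problem),
                     class = "fba_result"))
  }
  z <- sol$objective
  x <- sol$x
  if (parsimonious) {
    # keep the optimum (within relative 1e-12), minimize total flux
    n <- length(problem$vars)
    floor_row <- -problem$c
    floor_rhs <- -(z - 1e-12 * max(1, abs(z)))
    sol2 <- simplex_solve(rep(-1, n), A_eq = problem$S,
                          b_eq = numeric(nrow(problem$S)),
                          A_ub = rbind(mats$A_ub, floor_row),
                          b_ub = c(mats$b_ub, floor_rhs), tol = tol)
    if (sol2$status == "optimal") x <- sol2$x
  }
  fluxes <- stats::setNames(x, problem$vars)
  usage <- lapply(problem$enz, function(row) {
    u <- sum(row$coef * fluxes[names(row$coef)])
    c(usage = u, budget = row$rhs, slack = row$rhs - u)
  })
  names(usage) <- vapply(problem$enz, `[[`, "", "strain")
  binding <- c(
    names(usage)[vapply(usage, function(u) u[["slack"]] <= 1e-6, logical(1))],
    problem$vars[is.finite(problem$ub) &
                   fluxes >= problem$ub - 1e-6 & problem$ub > 0]
  )
  res <- structure(list(status = "optimal", objective = z, fluxes = fluxes,
                        enzyme_usage = usage, binding = binding,
                        total_flux = sum(x), check = NULL, problem = problem),
                   class = "fba_result")
  res$check <- validate_solution(res, problem, tol = 1e-6)
  if (!res$check$pass)
    warning("solver returned a point violating feasibility checks; ",
            "see result$check")
  res
}

#' Parsimonious re-solve of an optimal FBA problem
#'
#' @param model Model or `lp_problem`.
#' @param objective Objective reaction id.
#' @param ... Passed to [solve_fba()].
#' @return An `fba_result` whose flux vector minimizes total flux among
#'   near-optimal solutions.
#' @export
pfba <- function(model, objective = NULL, ...) {
  solve_fba(model, objective, parsimonious = TRUE, ...)
}

#' Independently validate an FBA solution
#'
#' Re-checks the steady-state residuals `|S v|`, the flux bounds, and the
#' per-strain enzyme rows of a solved point with plain arithmetic,
#' independent of the solver's own claims.
#'
#' @param result An `fba_result` (or a named flux vector).
#' @param problem The `lp_problem` it solves (or the model).
#' @param tol Largest tolerated violation.
#' @return `list(pass = , violations = <data.frame row per violation>)`.
#' @export
validate_solution <- function(result, problem, tol = 1e-9) {
  fluxes <- if (inherits(result, "fba_result")) result$fluxes else result
  if (!inherits(problem, "lp_problem"))
    problem <- build_lp(problem, names(which(fluxes == max(fluxes)))[1])
  viol <- list()
  resid <- as.numeric(problem$S %*% fluxes[problem$vars])
  bad <- which(abs(resid) > tol)
  for (i in bad)
    viol[[length(viol) + 1L]] <- data.frame(
      constraint = paste0("steady_state:", problem$mets[i]),
      violation = abs(resid[i]))
  low <- which(fluxes[problem$vars] < -tol)
  high <- which(fluxes[problem$vars] > problem$ub + tol)
  for (i in low)
    viol[[length(viol) + 1L]] <- data.frame(
      constraint = paste0("lb:", problem$vars[i]),
      violation = -fluxes[[problem$vars[i]]])
  for (i in high)
    viol[[length(viol) + 1L]] <- data.frame(
      constraint = paste0("ub:", problem$vars[i]),
      violation = fluxes[[problem$vars[i]]] - problem$ub[[i]])
  for (row in problem$enz) {
    u <- sum(row$coef * fluxes[names(row$coef)])
    if (u > row$rhs + tol)
      viol[[length(viol) + 1L]] <- data.frame(
        constraint = paste0("enzyme_pool:", row$strain),
        violation = u - row$rhs)
  }
  violations <- if (length(viol)) do.call(rbind, viol)
                else data.frame(constraint = character(), violation = numeric())
  list(pass = nrow(violations) == 0L, violations = violations)
}

#' @export
print.fba_result <- function(x, ...) {
  cat("<fba_result> status: ", x$status, "\n", sep = "")
  if (x$status == "optimal") {
    cat("  objective:  ", format(x$objective, digits = 10), "\n", sep = "")
    cat("  total flux: ", format(x$total_flux, digits = 10), "\n", sep = "")
    if (length(x$enzyme_usage)) {
      cat("  enzyme usage (g/gDW):\n")
      for (tg in names(x$enzyme_usage)) {
        u <- x$enzyme_usage[[tg]]
        cat(sprintf("    %-10s %.6g / %.6g (slack %.3g)\n",
                    tg, u[["usage"]], u[["budget"]], u[["slack"]]))
      }
    }
    nz <- sum(abs(x$fluxes) > 1e-9)
    cat("  nonzero fluxes: ", nz, " of ", length(x$fluxes), "\n", sep = "")
  }
  invisible(x)
}

#' @export
coef.fba_result <- function(object, ...) object$fluxes

#' Extract the flux vector of a solved model
#'
#' @param result An `fba_result`.
#' @param nonzero Keep only fluxes above `tol` in absolute value.
#' @param tol Threshold used when `nonzero = TRUE`.
#' @return Named numeric vector of fluxes.
#' @export
fluxes <- function(result, nonzero = FALSE, tol = 1e-9) {
  f <- result$fluxes
  if (nonzero) f <- f[abs(f) > tol]
  f
}
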