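#' Create a reaction
#'
#' Reactions are the atoms of a [strain_model()]. Stoichiometry is a named
#' numeric vector over metabolite ids; negative coefficients are consumed,
#' positive produced. After [split_reversible()] every reaction is
#' irreversible (`lb = 0`), which is the canonical internal form all
#' downstream machinery (community assembly, LP construction) assumes.
#'
#' @param id Reaction identifier, unique within a model.
#' @param stoich Named numeric vector, metabolite id -> coefficient.
#' @param lb,ub Lower/upper flux bound (mmol gDW^-1 h^-1). `lb` may be
#'   negative only before reversibility splitting.
#' @param name Human-readable name.
#' @param gene_rule Optional boolean gene association string, e.g.
#'   `"b0001 and (b0002 or b0003)"`.
#' @param origin Strain tag the reaction belongs to, or `"shared"`.
#' @param kind One of `"internal"`, `"exchange"`, `"link"`, `"biomass"`.
#' @param enzyme Optional `list(kcat = , mw = )` with kcat in h^-1 and
#'   molecular weight in g mmol^-1 (numerically kDa).
#' @return A list of class `"reaction"`.
#' @export
reaction <- function(id, stoich, lb = 0, ub = 1000, name = id,
                     gene_rule = NULL, origin = NA_character_,
                     kind = c("internal", "exchange", "link", "biomass"),
                     enzyme = NULL) {
  kind <- match.arg(kind)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (length(stoich) > 0 && is.null(names(stoich)))
    stop("stoichiometry of '", id, "' must be a named numeric vector")
  if (!is.null(enzyme)) {
    if (!is.list(enzyme) || is.null(enzyme$kcat) || is.null(enzyme$mw))
      stop("enzyme annotation of '", id, "' needs kcat and mw")
    if (enzyme$kcat <= 0 || enzyme$mw <= 0)
      stop("enzyme annotation of '", id, "' must have kcat > 0 and mw > 0")
    enzyme <- list(kcat = as.numeric(enzyme$kcat), mw = as.numeric(enzyme$mw))
  }
  if (kind %in% c("exchange", "link") && !is.null(gene_rule))
    stop("reaction '", id, "' of kind '", kind, "' cannot carry a gene rule")
  structure(list(
    id = id, name = name, stoich = stoich[names(stoich)],
    lb = as.numeric(lb), ub = as.numeric(ub),
    gene_rule = gene_rule, origin = origin, kind = kind, enzyme = enzyme
  ), class = "reaction")
}

#' Build a metabolite table
#'
#' @param id Character vector of metabolite ids (BiGG-style, compartment
#'   suffix such as `_c` / `_e`).
#' @param compartment Compartment token per metabolite (`"c"`, `"e"`,
#'   `"shared"`, ...). Defaults to the id suffix after the last underscore.
#' @param name,formula Optional annotation vectors.
#' @param base_id Pre-namespacing id; defaults to `id`.
#' @param origin Strain tag or `"shared"`.
#' @return A data.frame with one row per metabolite.
#' @export
metabolites <- function(id, compartment = NULL, name = id,
                        formula = NA_character_, base_id = id,
                        origin = NA_character_) {
  if (is.null(compartment)) compartment <- sub("^.*_", "", id)
  data.frame(id = id, base_id = base_id, name = name,
             compartment = rep_len(compartment, length(id)),
             formula = rep_len(formula, length(id)),
             origin = rep_len(origin, length(id)),
             stringsAsFactors = FALSE)
}

#' Create a single-strain metabolic model
#'
#' @param id Model identifier.
#' @param mets Metabolite table from [metabolites()].
#' @param reactions List of [reaction()] objects.
#' @param biomass_id Optional id of the biomass reaction.
#' @param pool Optional [pool_budget()] enzyme pool.
#' @param tag Strain tag once namespaced (set by [namespace_model()]).
#' @param validate Check model invariants on construction.
#' @return An object of class `"strain_model"`.
#' @export
strain_model <- function(id, mets, reactions, biomass_id = NULL, pool = NULL,
                         tag = NULL, validate = TRUE) {
  names(reactions) <- vapply(reactions, `[[`, "", "id")
  m <- structure(list(
    id = id, tag = tag, metabolites = mets, reactions = reactions,
    biomass_id = biomass_id, pool = pool
  ), class = "strain_model")
  if (validate) validate_model(m)
  m
}

#' Validate model invariants
#'
#' Checks id uniqueness, that every stoichiometry key resolves to a declared
#' metabolite, bound sanity (`lb <= ub`), biomass resolution, and positive
#' enzyme parameters. Community models additionally require that no reaction
#' spans two strain namespaces: all inter-strain flow passes through shared
#' metabolites.
#'
#' @param model A `strain_model` or `community_model`.
#' @return Invisibly `TRUE`; stops with a named violation otherwise.
#' @export
validate_model <- function(model) {
  mets <- model$metabolites
  if (anyDuplicated(mets$id))
    stop("duplicate metabolite id(s): ",
         paste(unique(mets$id[duplicated(mets$id)]), collapse = ", "))
  rids <- names(model$reactions)
  if (anyDuplicated(rids))
    stop("duplicate reaction id(s): ",
         paste(unique(rids[duplicated(rids)]), collapse = ", "))
  for (r in model$reactions) {
    unknown <- setdiff(names(r$stoich), mets$id)
    if (length(unknown))
      stop("reaction '", r$id, "' references undeclared metabolite(s): ",
           paste(unknown, collapse = ", "))
    if (r$lb > r$ub)
      stop("reaction '", r$id, "' has lb > ub")
    if (!is.null(r$enzyme) && (r$enzyme$kcat <= 0 || r$enzyme$mw <= 0))
      stop("reaction '", r$id, "' has nonpositive enzyme parameters")
  }
  if (!is.null(model$biomass_id) && !model$biomass_id %in% rids)
    stop("biomass reaction '", model$biomass_id, "' not present in model")
  if (inherits(model, "community_model")) {
    strain_of <- stats::setNames(mets$origin, mets$id)
    for (r in model$reactions) {
      touched <- unique(strain_of[names(r$stoich)])
      touched <- setdiff(touched, c("shared", NA))
      if (length(touched) > 1)
        stop("reaction '", r$id, "' connects two strain namespaces directly: ",
             paste(touched, collapse = ", "))
    }
  }
  invisible(TRUE)
}

#' @export
print.strain_model <- function(x, ...) {
  cat("<strain_model> ", x$id,
      if (!is.null(x[["tag"]])) paste0(" [tag: ", x[["tag"]], "]"), "\n", sep = "")
  cat("  metabolites: ", nrow(x$metabolites),
      "   reactions: ", length(x$reactions), "\n", sep = "")
  n_enz <- sum(vapply(x$reactions, function(r) !is.null(r$enzyme), logical(1)))
  cat("  enzyme-annotated reactions: ", n_enz, "\n", sep = "")
  if (!is.null(x[["pool"]]))
    cat("  enzyme pool: ", format(x[["pool"]]$enz), " g gDW^-1\n", sep = "")
  if (!is.null(x$biomass_id))
    cat("  biomass: ", x$biomass_id, "\n", sep = "")
  invisible(x)
}

#' @export
summary.strain_model <- function(object, ...) {
  kinds <- table(vapply(object$reactions, `[[`, "", "kind"))
  out <- list(id = object$id, tag = object[["tag"]],
              n_metabolites = nrow(object$metabolites),
              n_reactions = length(object$reactions),
              kinds = kinds,
              n_enzyme = sum(vapply(object$reactions,
                                    function(r) !is.null(r$enzyme), logical(1))),
              pool = object[["pool"]])
  class(out) <- "summary.strain_model"
  out
}

#' @export
print.summary.strain_model <- function(x, ...) {
  cat("strain model", x$id, "\n")
  cat("  ", x$n_metabolites, "metabolites,", x$n_reactions, "reactions\n")
  print(x$kinds)
  invisible(x)
}

# internal: fetch a reaction or fail loudly
get_reaction <- function(model, id) {
  r <- model$reactions[[id]]
  if (is.null(r)) stop("unknown reaction id '", id, "'")
  r
}
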