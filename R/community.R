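#' Normalize an inoculation-ratio specification
#'
#' Raw ratios such as `c(A = 2, B = 1)` are scaled to fractions summing to
#' one, so that `c(2, 1)` and `c(4, 2)` describe the same community and
#' objective values are comparable across sweeps.
#'
#' @param ratio Named positive numeric vector, strain tag -> weight.
#' @return Named fractions summing to 1 (within 1e-12).
#' @export
normalize_ratio <- function(ratio) {
  if (is.null(names(ratio)) || any(!nzchar(names(ratio))))
    stop("ratio must be a named vector of strain tags")
  if (any(!is.finite(ratio)) || any(ratio <= 0))
    stop("all ratio fractions must be > 0; drop a strain instead of ",
         "setting its fraction to zero")
  ratio / sum(ratio)
}

#' Namespace a strain model
#'
#' Suffixes every metabolite and reaction id with `<sep><tag>` (default
#' `"@tag"`; pass `sep = "__"` for an SBML-charset-safe fallback), keeps
#' `base_id` recoverable, and stamps `origin = tag` everywhere. Refuses to
#' namespace an already-namespaced model.
#'
#' @param model A `strain_model`.
#' @param tag Nonempty strain tag, unique within an assembly.
#' @param sep Separator between base id and tag.
#' @return The namespaced model.
#' @export
namespace_model <- function(model, tag, sep = "@") {
  if (!is.character(tag) || length(tag) != 1L || !nzchar(tag))
    stop("tag must be a nonempty string")
  if (!is.null(model[["tag"]]))
    stop("model '", model$id, "' is already namespaced with tag '",
         model[["tag"]], "'; refusing to namespace twice")
  suffix <- function(x) paste0(x, sep, tag)
  mets <- model$metabolites
  mets$base_id <- mets$id
  mets$id <- suffix(mets$id)
  mets$origin <- tag
  model$metabolites <- mets
  model$reactions <- lapply(model$reactions, function(r) {
    r$id <- suffix(r$id)
    names(r$stoich) <- suffix(names(r$stoich))
    r$origin <- tag
    r
  })
  names(model$reactions) <- vapply(model$reactions, `[[`, "", "id")
  if (!is.null(model$biomass_id)) model$biomass_id <- suffix(model$biomass_id)
  model$tag <- tag
  if (!is.null(model[["pool"]])) model$pool$tag <- tag
  validate_model(model)
  model
}

shared_met_id <- function(base_id) paste0(base_id, "_shared")

link_ids <- function(base_id, tag, sep = "@") {
  fwd <- paste0("LNK_", base_id, sep, tag)
  c(fwd = fwd, rev = paste0(fwd, "_reverse"))
}

# internal: build the two irreversible halves of one interaction link.
# Forward direction is strain -> shared: 1.0 strain-side metabolite
# converts to 1/m shared-side units; the reverse half is the negation.
make_link_pair <- function(base_id, tag, strain_met, frac, direction, sep,
                           link_ub = 1000) {
  ids <- link_ids(base_id, tag, sep)
  sh <- shared_met_id(base_id)
  fwd_st <- stats::setNames(c(-1, 1 / frac), c(strain_met, sh))
  list(
    reaction(ids[["fwd"]], fwd_st, ub = if (direction == "import") 0 else link_ub,
             name = paste0("link ", base_id, " ", tag, " -> shared"),
             origin = tag, kind = "link"),
    reaction(ids[["rev"]], -fwd_st, ub = if (direction == "export") 0 else link_ub,
             name = paste0("link ", base_id, " shared -> ", tag),
             origin = tag, kind = "link")
  )
}

#' Assemble namespaced sub-models into a community model
#'
#' Creates one shared-pool metabolite per shared base id and, for every
#' (shared id, strain) pair where the strain carries that extracellular
#' metabolite, an interaction link whose stoichiometry is
#' `{1.0 strain-side, 1/m_x shared-side}` with `m_x` the strain's
#' normalized inoculation fraction. Links are conceptually reversible and
#' stored as split irreversible pairs; directed transfer is imposed by the
#' `directions` argument, which bounds one half to zero.
#'
#' @param submodels List of namespaced, reversibility-split strain models.
#' @param shared_ids Base ids of the extracellular metabolites to share
#'   (curated, not every extracellular species).
#' @param ratio Named inoculation ratio (normalized internally; a message
#'   is emitted when normalization changes the values).
#' @param directions Optional named character vector restricting links:
#'   names are `"<base_id>"` (all strains) or `"<base_id><sep><tag>"`,
#'   values one of `"both"`, `"export"` (strain to shared only),
#'   `"import"`. Default `"both"`.
#' @param sep Namespace separator used when the sub-models were tagged.
#' @param link_ub Upper bound of each link direction.
#' @return An object of class `"community_model"`.
#' @export
assemble_community <- function(submodels, shared_ids, ratio,
                               directions = NULL, sep = "@",
                               link_ub = 1000) {
  tags <- vapply(submodels, function(m) m[["tag"]] %||% NA_character_, "")
  if (anyNA(tags)) stop("all sub-models must be namespaced before assembly")
  if (anyDuplicated(tags))
    stop("duplicate strain tag(s): ", paste(tags[duplicated(tags)], collapse = ", "))
  for (m in submodels) {
    if (any(vapply(m$reactions, `[[`, 0, "lb") < 0))
      stop("sub-model '", m$tag, "' has reversible reactions; ",
           "call split_reversible() before assembly")
  }
  missing <- setdiff(tags, names(ratio))
  if (length(missing))
    stop("ratio is missing strain(s): ", paste(missing, collapse = ", "))
  raw <- normalize_ratio(ratio[tags])
  if (abs(sum(ratio[tags]) - 1) > 1e-12)
    message("ratio normalized to fractions: ",
            paste(sprintf("%s=%.4g", names(raw), raw), collapse = ", "))
  ratio <- raw

  mets <- do.call(rbind, lapply(submodels, `[[`, "metabolites"))
  reactions <- do.call(c, lapply(submodels, `[[`, "reactions"))
  links <- list(); link_rows <- list()
  for (base in shared_ids) {
    carriers <- Filter(function(m) base %in% m$metabolites$base_id, submodels)
    if (!length(carriers))
      stop("shared metabolite '", base, "' is absent from all sub-models")
    mets <- rbind(mets, metabolites(id = shared_met_id(base), base_id = base,
                                    compartment = "shared", origin = "shared"))
    for (m in carriers) {
      key_strain <- paste0(base, sep, m$tag)
      dir <- "both"
      if (!is.null(directions)) {
        if (key_strain %in% names(directions)) dir <- directions[[key_strain]]
        else if (base %in% names(directions)) dir <- directions[[base]]
      }
      pair <- make_link_pair(base, m$tag, strain_met = key_strain,
                             frac = ratio[[m$tag]], direction = dir,
                             sep = sep, link_ub = link_ub)
      for (r in pair) links[[r$id]] <- r
      link_rows[[length(link_rows) + 1L]] <-
        data.frame(reaction_id = vapply(pair, `[[`, "", "id"),
                   base_id = base, strain = m$tag,
                   shared_id = shared_met_id(base),
                   direction = c("export", "import"), stringsAsFactors = FALSE)
    }
  }
  biomass <- unlist(lapply(submodels, function(m)
    if (!is.null(m$biomass_id)) stats::setNames(m$biomass_id, m$tag)))
  pools <- lapply(submodels, `[[`, "pool")
  names(pools) <- tags
  cm <- structure(list(
    id = paste0("community_", paste(tags, collapse = "_")),
    metabolites = mets, reactions = c(reactions, links),
    tags = tags, ratio = ratio, shared_ids = shared_ids,
    biomass = biomass, links = do.call(rbind, link_rows),
    pools = pools[!vapply(pools, is.null, logical(1))], sep = sep
  ), class = c("community_model", "strain_model"))
  validate_model(cm)
  cm
}

#' Add an exchange pair on a shared-pool metabolite
#'
#' Shared exchanges carry substrate into and product out of the whole
#' community: the forward reaction secretes (shared metabolite leaves the
#' system), the `_reverse` reaction is uptake.
#'
#' @param community A `community_model`.
#' @param base_id Base id of a shared metabolite.
#' @param uptake_ub Upper bound of the uptake direction (mmol gDW^-1 h^-1).
#' @param secretion_ub Upper bound of the secretion direction.
#' @return The extended community model.
#' @export
add_shared_exchange <- function(community, base_id, uptake_ub = 0,
                                secretion_ub = 1000) {
  sh <- shared_met_id(base_id)
  if (!sh %in% community$metabolites$id)
    stop("no shared metabolite for '", base_id,
         "'; list it in shared_ids at assembly")
  ex_id <- paste0("EX_", sh)
  if (ex_id %in% names(community$reactions))
    stop("exchange '", ex_id, "' already exists")
  community$reactions[[ex_id]] <-
    reaction(ex_id, stats::setNames(-1, sh), ub = secretion_ub,
             name = paste("secretion of", base_id), origin = "shared",
             kind = "exchange")
  rev_id <- paste0(ex_id, "_reverse")
  community$reactions[[rev_id]] <-
    reaction(rev_id, stats::setNames(+1, sh), ub = uptake_ub,
             name = paste("uptake of", base_id), origin = "shared",
             kind = "exchange")
  validate_model(community)
  community
}

#' Re-scale substrate uptake bounds to a fixed ratio
#'
#' Sets the upper bounds of the named uptake reactions so that their
#' pairwise proportions match `ratios` while the total uptake capacity
#' equals `total`.
#'
#' @param community A `community_model` (or any model).
#' @param ratios Named positive weights, uptake reaction id -> weight,
#'   e.g. `c(EX_glc_shared_reverse = 4, EX_xyl_shared_reverse = 1)`.
#' @param total Total uptake capacity to distribute; defaults to the sum of
#'   the named reactions' current upper bounds.
#' @return The model with rescaled bounds.
#' @export
set_substrate_ratio <- function(community, ratios, total = NULL) {
  if (any(!is.finite(ratios)) || any(ratios <= 0))
    stop("substrate ratio weights must be > 0")
  for (id in names(ratios)) get_reaction(community, id)
  if (is.null(total))
    total <- sum(vapply(names(ratios),
                        function(id) community$reactions[[id]]$ub, 0))
  share <- ratios / sum(ratios)
  for (id in names(ratios))
    community$reactions[[id]]$ub <- unname(total * share[[id]])
  community
}

#' Set the inoculation ratio of an assembled community
#'
#' Rebuilds every interaction-link coefficient as `1/m_x` from the
#' normalized fractions, leaving the rest of the model untouched, so ratio
#' sweeps do not reassemble the model. Idempotent.
#'
#' @param community A `community_model`.
#' @param ratio Named ratio covering every strain tag (normalized
#'   internally).
#' @return The updated community model.
#' @export
set_ratio <- function(community, ratio) {
  missing <- setdiff(community$tags, names(ratio))
  if (length(missing))
    stop("ratio is missing strain(s): ", paste(missing, collapse = ", "))
  frac <- normalize_ratio(ratio[community$tags])
  for (i in seq_len(nrow(community$links))) {
    l <- community$links[i, ]
    r <- community$reactions[[l$reaction_id]]
    r$stoich[[l$shared_id]] <- sign(r$stoich[[l$shared_id]]) / frac[[l$strain]]
    community$reactions[[l$reaction_id]] <- r
  }
  community$ratio <- frac
  community
}

#' @export
print.community_model <- function(x, ...) {
  cat("<community_model> ", x$id, "\n", sep = "")
  cat("  strains: ", paste(x$tags, collapse = ", "), "\n", sep = "")
  cat("  ratio:   ", paste(sprintf("%s=%.4g", names(x$ratio), x$ratio),
                           collapse = ", "), "\n", sep = "")
  cat("  metabolites: ", nrow(x$metabolites),
      "   reactions: ", length(x$reactions),
      " (", nrow(x$links), " link halves)\n", sep = "")
  cat("  shared metabolites: ", paste(x$shared_ids, collapse = ", "), "\n", sep = "")
  invisible(x)
}
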