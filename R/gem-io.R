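#' Read a genome-scale metabolic model
#'
#' Reads a BiGG-style JSON model or an SBML Level 3 (fbc) file into the
#' internal representation. Reversibility information (negative lower
#' bounds) is retained untouched until [split_reversible()] is called.
#'
#' @param path Path to the model file.
#' @param format `"json"`, `"sbml"`, or `"auto"` (by file extension).
#' @return A [strain_model()] (or a `community_model` if the file was
#'   written from one by [write_model()]).
#' @export
read_gem <- function(path, format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml" else "json"
  }
  switch(format, json = read_gem_json(path), sbml = read_gem_sbml(path))
}

note_or <- function(notes, key, default) {
  v <- notes[[key]]
  if (is.null(v)) default else v
}

read_gem_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$metabolites) || is.null(doc$reactions))
    stop("parse error in '", path, "': missing 'metabolites' or 'reactions' element")
  met_rows <- lapply(doc$metabolites, function(m) {
    if (is.null(m$id)) stop("parse error in '", path, "': metabolite without id")
    notes <- if (is.null(m$notes)) list() else m$notes
    metabolites(id = m$id,
                compartment = note_or(m, "compartment", sub("^.*_", "", m$id)),
                name = note_or(m, "name", m$id),
                formula = if (is.null(m$formula)) NA_character_ else m$formula,
                base_id = note_or(notes, "base_id", m$id),
                origin = note_or(notes, "origin", NA_character_))
  })
  mets <- do.call(rbind, met_rows)
  rxns <- lapply(doc$reactions, function(r) {
    if (is.null(r$id)) stop("parse error in '", path, "': reaction without id")
    st <- unlist(r$metabolites)
    notes <- if (is.null(r$notes)) list() else r$notes
    enz <- NULL
    if (!is.null(notes$kcat) && !is.null(notes$mw))
      enz <- list(kcat = as.numeric(notes$kcat), mw = as.numeric(notes$mw))
    kind <- note_or(notes, "kind",
                    if (length(st) == 1L) "exchange" else "internal")
    gr <- r$gene_reaction_rule
    if (!is.null(gr) && !nzchar(gr)) gr <- NULL
    reaction(id = r$id, stoich = st,
             lb = note_or(r, "lower_bound", 0),
             ub = note_or(r, "upper_bound", 1000),
             name = note_or(r, "name", r$id),
             gene_rule = if (kind %in% c("exchange", "link")) NULL else gr,
             origin = note_or(notes, "origin", NA_character_),
             kind = kind, enzyme = enz)
  })
  notes <- if (is.null(doc$notes)) list() else doc$notes
  pool <- NULL
  if (!is.null(notes$pool))
    pool <- pool_budget(notes$pool$ptot, notes$pool$f, notes$pool$sigma)
  biomass_id <- notes$biomass_id
  if (is.null(biomass_id)) {
    ids <- vapply(rxns, `[[`, "", "id")
    hit <- ids[grepl("biomass", ids, ignore.case = TRUE)]
    if (length(hit) == 1L) biomass_id <- hit
  }
  m <- strain_model(id = note_or(doc, "id", basename(path)), mets = mets,
                    reactions = rxns, biomass_id = biomass_id, pool = pool,
                    tag = notes$tag)
  if (!is.null(notes$community)) m <- rebuild_community(m, notes$community)
  m
}

community_meta <- function(model) {
  list(tags = model$tags,
       ratio = as.list(model$ratio),
       shared_ids = model$shared_ids,
       biomass = as.list(model$biomass),
       links = lapply(seq_len(nrow(model$links)), function(i) as.list(model$links[i, ])),
       pools = lapply(model$pools, function(p) p[c("ptot", "f", "sigma")]),
       sep = model$sep)
}

rebuild_community <- function(m, meta) {
  links <- do.call(rbind, lapply(meta$links, function(l)
    data.frame(reaction_id = l$reaction_id, base_id = l$base_id,
               strain = l$strain, shared_id = l$shared_id,
               direction = l$direction, stringsAsFactors = FALSE)))
  pools <- lapply(meta$pools, function(p) pool_budget(p$ptot, p$f, p$sigma))
  structure(list(
    id = m$id, metabolites = m$metabolites, reactions = m$reactions,
    tags = unlist(meta$tags), ratio = unlist(meta$ratio),
    shared_ids = unlist(meta$shared_ids),
    biomass = if (length(meta$biomass)) unlist(meta$biomass) else NULL,
    links = links, pools = pools, sep = note_or(meta, "sep", "@")
  ), class = c("community_model", "strain_model"))
}

#' Write a model to disk
#'
#' Model invariants are checked first; a model violating them is refused
#' with the named violation. `read_gem(write_model(m))` reproduces `m` on
#' ids, stoichiometry, bounds, and gene rules for both formats. Reaction
#' `kind`/`origin` and enzyme annotations travel in the notes field.
#'
#' @param model A `strain_model` or `community_model`.
#' @param path Output path.
#' @param format `"json"`, `"sbml"`, or `"auto"` (by extension).
#' @return Invisibly `path`.
#' @export
write_model <- function(model, path, format = c("auto", "json", "sbml")) {
  format <- match.arg(format)
  validate_model(model)
  if (format == "auto") {
    format <- if (grepl("\\.(xml|sbml)$", path, ignore.case = TRUE)) "sbml" else "json"
  }
  switch(format,
         json = write_model_json(model, path),
         sbml = write_model_sbml(model, path))
  invisible(path)
}

write_model_json <- function(model, path) {
  mets <- model$metabolites
  met_list <- lapply(seq_len(nrow(mets)), function(i) {
    m <- as.list(mets[i, ])
    out <- list(id = m$id, name = m$name, compartment = m$compartment,
                notes = list(base_id = m$base_id))
    if (!is.na(m$formula)) out$formula <- m$formula
    if (!is.na(m$origin)) out$notes$origin <- m$origin
    out
  })
  rxn_list <- lapply(model$reactions, function(r) {
    notes <- list(kind = r$kind)
    if (!is.na(r$origin)) notes$origin <- r$origin
    if (!is.null(r$enzyme)) { notes$kcat <- r$enzyme$kcat; notes$mw <- r$enzyme$mw }
    list(id = r$id, name = r$name, metabolites = as.list(r$stoich),
         lower_bound = r$lb, upper_bound = r$ub,
         gene_reaction_rule = if (is.null(r$gene_rule)) "" else r$gene_rule,
         notes = notes)
  })
  genes <- unique(unlist(lapply(model$reactions, function(r)
    if (!is.null(r$gene_rule)) rule_genes(parse_gene_rule(r$gene_rule)))))
  notes <- list()
  if (!is.null(model[["tag"]])) notes$tag <- model[["tag"]]
  if (!is.null(model$biomass_id)) notes$biomass_id <- model$biomass_id
  if (!is.null(model[["pool"]])) notes$pool <- model[["pool"]][c("ptot", "f", "sigma")]
  if (inherits(model, "community_model")) notes$community <- community_meta(model)
  doc <- list(id = model$id, metabolites = met_list,
              reactions = unname(rxn_list),
              genes = lapply(genes, function(g) list(id = g, name = g)),
              notes = notes, version = "1")
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Split reversible reactions into irreversible pairs
#'
#' Every reaction with a negative lower bound `(lb < 0, ub)` is replaced by
#' a forward copy with bounds `(0, max(ub, 0))` and a sibling named
#' `<id>_reverse` with bounds `(0, -lb)` and negated stoichiometry, so net
#' flux is forward minus reverse and all flux variables are nonnegative.
#' Idempotent on already-split models. Enzyme annotations are copied to the
#' reverse sibling (catalysis costs enzyme in either direction).
#'
#' @param model A `strain_model`.
#' @return The split model; input is not modified.
#' @export
split_reversible <- function(model) {
  out <- list()
  for (r in model$reactions) {
    if (r$lb >= 0) { out[[r$id]] <- r; next }
    rev_id <- paste0(r$id, "_reverse")
    if (rev_id %in% names(model$reactions))
      stop("cannot split '", r$id, "': id '", rev_id, "' already exists")
    fwd <- r; fwd$lb <- 0; fwd$ub <- max(r$ub, 0)
    rev <- r
    rev$id <- rev_id; rev$name <- paste0(r$name, " (reverse)")
    rev$stoich <- -r$stoich; rev$lb <- 0; rev$ub <- -r$lb
    out[[fwd$id]] <- fwd
    out[[rev_id]] <- rev
  }
  model$reactions <- out
  validate_model(model)
  model
}

#' Apply knockouts, reaction additions, and bound changes
#'
#' Knockouts accept reaction ids or gene names. Gene knockouts are mapped
#' through the boolean gene rules: a reaction closes when its rule
#' evaluates false under the combined deleted-gene set (`and` = complex,
#' `or` = isozymes). Knocked-out reactions keep their row in the model with
#' both bounds set to 0 so the edit is auditable and reversible; pass
#' `delete = TRUE` to remove them instead. The input model is never
#' modified.
#'
#' @param model A `strain_model`.
#' @param knockouts Character vector of reaction ids and/or gene names.
#' @param additions List of reaction specs: each a list with `id`,
#'   `stoich`, optional `ub`, `gene_rule`, `enzyme`, and optional
#'   `metabolites` (a data.frame from [metabolites()] declaring new species
#'   inline).
#' @param bound_changes Named list: reaction id -> `c(lb, ub)` or a single
#'   upper bound.
#' @param delete Remove knocked-out reactions instead of zeroing bounds.
#' @return The edited model.
#' @export
apply_edits <- function(model, knockouts = character(), additions = list(),
                        bound_changes = list(), delete = FALSE) {
  all_genes <- unique(unlist(lapply(model$reactions, function(r)
    if (!is.null(r$gene_rule)) rule_genes(parse_gene_rule(r$gene_rule)))))
  is_rxn <- knockouts %in% names(model$reactions)
  is_gene <- knockouts %in% all_genes
  unknown <- knockouts[!(is_rxn | is_gene)]
  if (length(unknown))
    stop("unknown knockout id(s), neither reaction nor gene: ",
         paste(unknown, collapse = ", "))
  ko_rxns <- knockouts[is_rxn]
  ko_genes <- knockouts[is_gene & !is_rxn]
  if (length(ko_genes)) {
    closed <- vapply(model$reactions, function(r)
      !is.null(r$gene_rule) && !eval_gene_rule(r$gene_rule, ko_genes), logical(1))
    ko_rxns <- union(ko_rxns, names(model$reactions)[closed])
  }
  for (id in ko_rxns) {
    model$reactions[[id]]$lb <- 0
    model$reactions[[id]]$ub <- 0
  }
  if (delete && length(ko_rxns))
    model$reactions <- model$reactions[setdiff(names(model$reactions), ko_rxns)]
  for (spec in additions) {
    if (is.null(spec$id)) stop("reaction addition without id")
    if (spec$id %in% names(model$reactions))
      stop("added reaction '", spec$id, "' collides with an existing id")
    if (!is.null(spec$metabolites)) {
      new_m <- spec$metabolites[!spec$metabolites$id %in% model$metabolites$id, ,
                               drop = FALSE]
      model$metabolites <- rbind(model$metabolites, new_m)
    }
    r <- reaction(id = spec$id, stoich = unlist(spec$stoich),
                  lb = 0, ub = if (is.null(spec$ub)) 1000 else spec$ub,
                  name = if (is.null(spec$name)) spec$id else spec$name,
                  gene_rule = spec$gene_rule,
                  origin = if (is.null(spec$origin)) model[["tag"]] %||% NA_character_ else spec$origin,
                  kind = "internal", enzyme = spec$enzyme)
    unknown <- setdiff(names(r$stoich), model$metabolites$id)
    if (length(unknown))
      stop("added reaction '", r$id, "' references unresolvable metabolite(s): ",
           paste(unknown, collapse = ", "))
    model$reactions[[r$id]] <- r
  }
  for (id in names(bound_changes)) {
    r <- get_reaction(model, id)
    b <- bound_changes[[id]]
    if (length(b) == 1L) r$ub <- as.numeric(b)
    else { r$lb <- as.numeric(b[[1]]); r$ub <- as.numeric(b[[2]]) }
    model$reactions[[id]] <- r
  }
  validate_model(model)
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a
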