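# Config-file front end: model edits and community assembly described as
# JSON or YAML documents, so a whole consortium design is reproducible
# from declarative files plus the sub-model GEMs.

read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyVector = FALSE)
}

#' Apply a structured edit config to a model
#'
#' The config (JSON or YAML) may contain sections `knockouts` (list of
#' reaction ids / gene names), `additions` (list of reaction specs as in
#' [apply_edits()], with metabolites declared inline as a list of
#' `{id, compartment, name}`), and `bounds` (map reaction id ->
#' `[lb, ub]` or a single upper bound).
#'
#' @param model A `strain_model`.
#' @param path Path to the edit config.
#' @return The edited model.
#' @export
apply_edit_config <- function(model, path) {
  cfg <- read_config(path)
  additions <- lapply(cfg$additions, function(a) {
    if (!is.null(a$metabolites) && !is.data.frame(a$metabolites)) {
      ids <- vapply(a$metabolites, `[[`, "", "id")
      a$metabolites <- metabolites(
        ids,
        compartment = vapply(a$metabolites, function(m)
          m$compartment %||% sub("^.*_", "", m$id), ""),
        name = vapply(a$metabolites, function(m) m$name %||% m$id, ""))
    }
    a$stoich <- unlist(a$stoich)
    if (!is.null(a$enzyme)) a$enzyme <- list(kcat = a$enzyme$kcat, mw = a$enzyme$mw)
    a
  })
  apply_edits(model,
              knockouts = unlist(cfg$knockouts) %||% character(),
              additions = additions %||% list(),
              bound_changes = cfg$bounds %||% list())
}

#' Build a community model from an assembly config
#'
#' The config (JSON or YAML) lists the design in one document:
#'
#' ```yaml
#' submodels:
#'   - path: strainA.json   # or an id resolved via `models`
#'     tag: A
#'     edits: editsA.json   # optional apply_edit_config() file
#'     pool: {ptot: 0.56, f: 0.406, sigma: 0.5}
#' shared: [glc__D_e, tyr__L_e]
#' ratio: {A: 2, B: 1}
#' directions: {"tyr__L_e@A": export, "tyr__L_e@B": import}
#' exchanges:
#'   - {metabolite: glc__D_e, uptake_ub: 10, secretion_ub: 0}
#' substrate_ratio: {ratios: {EX_glc__D_e_shared_reverse: 4}, total: 10}
#' objective: EX_prod_shared
#' ```
#'
#' Each sub-model is read, edited, reversibility-split, namespaced, and
#' assembled with ratio-scaled links; shared exchanges and substrate
#' ratios are applied afterwards.
#'
#' @param path Path to the assembly config.
#' @param models Optional named list of pre-loaded `strain_model`s,
#'   keyed by the config's `path` entries (bypasses file reads; useful
#'   for generated models and tests).
#' @param base_dir Directory against which relative sub-model paths are
#'   resolved; defaults to the config's directory.
#' @return A `community_model`, with the config's `objective` (if any)
#'   attached as the `"objective"` attribute.
#' @export
assemble_from_config <- function(path, models = NULL, base_dir = NULL) {
  cfg <- read_config(path)
  if (is.null(base_dir)) base_dir <- dirname(path)
  if (is.null(cfg$submodels) || !length(cfg$submodels))
    stop("assembly config needs a 'submodels' section")
  resolve <- function(p) if (grepl("^/", p)) p else file.path(base_dir, p)
  subs <- lapply(cfg$submodels, function(s) {
    m <- if (!is.null(models[[s$path]])) models[[s$path]]
         else read_gem(resolve(s$path))
    if (!is.null(s$edits)) m <- apply_edit_config(m, resolve(s$edits))
    if (!is.null(s$pool))
      m$pool <- pool_budget(s$pool$ptot, s$pool$f, s$pool$sigma)
    namespace_model(split_reversible(m), s$tag)
  })
  cm <- assemble_community(subs,
                           shared_ids = unlist(cfg$shared),
                           ratio = unlist(cfg$ratio),
                           directions = unlist(cfg$directions))
  for (ex in cfg$exchanges)
    cm <- add_shared_exchange(cm, ex$metabolite,
                              uptake_ub = ex$uptake_ub %||% 0,
                              secretion_ub = ex$secretion_ub %||% 1000)
  if (!is.null(cfg$substrate_ratio))
    cm <- set_substrate_ratio(cm, unlist(cfg$substrate_ratio$ratios),
                              total = cfg$substrate_ratio$total)
  if (!is.null(cfg$objective)) attr(cm, "objective") <- cfg$objective
  cm
}
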