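#' Compute a strain's total enzyme budget
#'
#' The enzyme pool available to a strain is `enz = ptot * f * sigma`, the
#' product of the total protein fraction of biomass, the mass fraction of
#' that protein which is metabolic enzyme, and the average enzyme
#' saturation. It caps the summed enzyme demand of the strain's reactions.
#'
#' @param ptot Total protein fraction (g protein gDW^-1), > 0.
#' @param f Enzyme mass fraction, in (0, 1].
#' @param sigma Average saturation, in (0, 1].
#' @param tag Optional strain tag.
#' @return An object of class `"enzyme_pool"` with fields `ptot`, `f`,
#'   `sigma`, `enz` (g enzyme gDW^-1).
#' @examples
#' pool_budget(0.56, 0.406, 0.5)$enz  # 0.11368
#' @export
pool_budget <- function(ptot, f, sigma, tag = NULL) {
  if (!is.numeric(ptot) || ptot <= 0) stop("ptot must be > 0")
  if (!is.numeric(f) || f <= 0 || f > 1) stop("f must be in (0, 1]")
  if (!is.numeric(sigma) || sigma <= 0 || sigma > 1)
    stop("sigma must be in (0, 1]")
  structure(list(tag = tag, ptot = as.numeric(ptot), f = as.numeric(f),
                 sigma = as.numeric(sigma),
                 enz = as.numeric(ptot * f * sigma)),
            class = "enzyme_pool")
}

#' @export
print.enzyme_pool <- function(x, ...) {
  cat("<enzyme_pool>", if (!is.null(x$tag)) x$tag, "\n")
  cat("  ptot =", x$ptot, " f =", x$f, " sigma =", x$sigma, "\n")
  cat("  enz  =", x$enz, "g enzyme / gDW\n")
  invisible(x)
}

#' Load an enzyme kinetics table
#'
#' Reads a TSV/CSV table with columns `reaction_id`, `kcat`, `mw`, and
#' optionally `kcat_unit` (`"1/h"` default; `"1/s"` entries are converted
#' to h^-1) and `provenance`. Canonical units are kcat in h^-1 and mw in
#' g mmol^-1 (numerically kDa), so a flux in mmol gDW^-1 h^-1 times mw/kcat
#' gives an enzyme demand in g gDW^-1.
#'
#' @param path Path to the table; delimiter by extension (`.tsv` = tab).
#' @return A data.frame of class `"enzyme_table"` with columns
#'   `reaction_id`, `kcat` (h^-1), `mw`, `provenance`.
#' @export
load_enzyme_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, strip.white = TRUE)
  need <- c("reaction_id", "kcat", "mw")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("enzyme table '", path, "' lacks column(s): ",
         paste(miss, collapse = ", "))
  as_enzyme_table(tab, origin = path)
}

#' @rdname load_enzyme_table
#' @param tab A data.frame with the same columns, built in code.
#' @param origin Label used in error messages.
#' @export
as_enzyme_table <- function(tab, origin = "enzyme table") {
  bad <- which(!is.finite(tab$kcat) | tab$kcat <= 0 |
               !is.finite(tab$mw) | tab$mw <= 0)
  if (length(bad))
    stop(origin, ": nonpositive kcat/mw in row(s) ",
         paste(bad + 1L, collapse = ", "), " (line numbers include header)")
  dup <- unique(tab$reaction_id[duplicated(tab$reaction_id)])
  if (length(dup))
    stop(origin, ": duplicate reaction id(s): ", paste(dup, collapse = ", "))
  if (!is.null(tab$kcat_unit)) {
    per_s <- grepl("s", tab$kcat_unit) & !grepl("h", tab$kcat_unit)
    tab$kcat[per_s] <- tab$kcat[per_s] * 3600
    tab$kcat_unit <- NULL
  }
  if (is.null(tab$provenance)) tab$provenance <- NA_character_
  out <- tab[c("reaction_id", "kcat", "mw", "provenance")]
  class(out) <- c("enzyme_table", "data.frame")
  out
}

strip_suffixes <- function(id, sep = "@") {
  id <- sub(paste0(sep, "[^", sep, "]*$"), "", id)
  sub("_reverse$", "", id)
}

#' Attach enzyme annotations to a model
#'
#' Matches table rows to reactions on the pre-namespacing base id (strain
#' tags and `_reverse` suffixes are stripped before matching). Exchange and
#' link reactions never carry enzyme cost. Unmatched internal reactions are
#' handled per `fallback`: `"exclude"` leaves them outside the enzyme-pool
#' sum (the constraint is removed for them), `"default_kcat"` assigns the
#' median kcat and median mw of the matched set.
#'
#' @param model A `strain_model` (raw or namespaced).
#' @param entries An `enzyme_table` from [load_enzyme_table()] /
#'   [as_enzyme_table()].
#' @param fallback `"exclude"` or `"default_kcat"`.
#' @return The annotated model; the coverage report (one row per costable
#'   reaction with `reaction`, `base_id`, `source`, `kcat`, `mw`, plus a
#'   `coverage` attribute in percent) is attached as attribute
#'   `"enzyme_coverage"` and retrievable with [enzyme_coverage()].
#' @export
attach_enzymes <- function(model, entries, fallback = c("exclude", "default_kcat")) {
  fallback <- match.arg(fallback)
  stopifnot(inherits(entries, "data.frame"))
  if (nrow(entries) == 0) warning("empty enzyme table: all reactions excluded")
  rows <- list()
  matched_kcat <- numeric(); matched_mw <- numeric()
  costable <- vapply(model$reactions, function(r)
    r$kind %in% c("internal", "biomass"), logical(1))
  for (r in model$reactions[costable]) {
    base <- strip_suffixes(r$id)
    hit <- match(base, entries$reaction_id)
    if (!is.na(hit)) {
      model$reactions[[r$id]]$enzyme <- list(kcat = entries$kcat[hit],
                                             mw = entries$mw[hit])
      matched_kcat <- c(matched_kcat, entries$kcat[hit])
      matched_mw <- c(matched_mw, entries$mw[hit])
      rows[[r$id]] <- data.frame(reaction = r$id, base_id = base,
                                 source = "table", kcat = entries$kcat[hit],
                                 mw = entries$mw[hit], stringsAsFactors = FALSE)
    } else {
      rows[[r$id]] <- data.frame(reaction = r$id, base_id = base,
                                 source = "unmatched", kcat = NA_real_,
                                 mw = NA_real_, stringsAsFactors = FALSE)
    }
  }
  report <- do.call(rbind, rows)
  if (is.null(report))
    report <- data.frame(reaction = character(), base_id = character(),
                         source = character(), kcat = numeric(), mw = numeric())
  unmatched <- report$reaction[report$source == "unmatched"]
  if (fallback == "default_kcat" && length(unmatched)) {
    if (!length(matched_kcat))
      stop("fallback 'default_kcat' needs at least one matched reaction")
    k_med <- stats::median(matched_kcat); m_med <- stats::median(matched_mw)
    for (id in unmatched) {
      model$reactions[[id]]$enzyme <- list(kcat = k_med, mw = m_med)
      report[report$reaction == id, c("source", "kcat", "mw")] <-
        list("default", k_med, m_med)
    }
  } else {
    for (id in unmatched) model$reactions[[id]]$enzyme <- NULL
    report$source[report$source == "unmatched"] <- "excluded"
  }
  attr(report, "coverage") <-
    if (nrow(report)) 100 * mean(report$source == "table") else NA_real_
  attr(model, "enzyme_coverage") <- report
  model
}

#' @rdname attach_enzymes
#' @export
enzyme_coverage <- function(model) attr(model, "enzyme_coverage")

#' Enzyme cost of carrying a flux
#'
#' The enzyme mass a reaction occupies at flux `v` is `v * mw / kcat`
#' (g gDW^-1 for flux in mmol gDW^-1 h^-1, mw in g mmol^-1, kcat in h^-1).
#'
#' @param v Flux, >= 0.
#' @param mw Molecular weight (g mmol^-1).
#' @param kcat Turnover number (h^-1), > 0.
#' @return Enzyme demand in g gDW^-1. Vectorized.
#' @examples
#' enzyme_cost(2, 40, 4000)  # 0.02
#' @export
enzyme_cost <- function(v, mw, kcat) {
  if (any(kcat <= 0)) stop("kcat must be > 0")
  if (any(mw <= 0)) stop("mw must be > 0")
  if (any(v < 0)) stop("flux must be >= 0 (split reversible reactions first)")
  v * mw / kcat
}

# internal: strains of a model with their reactions
strain_partition <- function(model) {
  if (inherits(model, "community_model")) {
    origins <- vapply(model$reactions, `[[`, "", "origin")
    lapply(stats::setNames(model$tags, model$tags), function(tg)
      model$reactions[!is.na(origins) & origins == tg])
  } else {
    tg <- model[["tag"]] %||% model$id
    stats::setNames(list(model$reactions), tg)
  }
}

# internal: pool lookup per strain
strain_pools <- function(model) {
  if (inherits(model, "community_model")) model$pools
  else stats::setNames(list(model[["pool"]]), model[["tag"]] %||% model$id)
}

#' Assemble per-strain enzyme-pool inequality rows
#'
#' One inequality per strain: the sum over that strain's enzyme-annotated
#' reactions of `v_i * mw_i / kcat_i` is bounded by the strain's total
#' enzyme budget `enz`. Supports are disjoint across strains, so each
#' sub-model remains independently constrained inside the community LP.
#'
#' @param model A `strain_model` with a pool, or a `community_model`.
#' @return A list of rows, each `list(strain =, coef = <named numeric
#'   mw/kcat>, rhs = enz)`. Strains with no annotated reaction contribute
#'   no row (with a warning: the constraint is vacuous).
#' @export
constraint_rows <- function(model) {
  parts <- strain_partition(model)
  pools <- strain_pools(model)
  rows <- list()
  for (tg in names(parts)) {
    annotated <- Filter(function(r) !is.null(r$enzyme), parts[[tg]])
    pool <- pools[[tg]]
    if (!length(annotated)) {
      warning("strain '", tg, "' has no enzyme-annotated reactions; ",
              "its pool constraint is vacuous")
      next
    }
    if (is.null(pool))
      stop("strain '", tg, "' has enzyme-annotated reactions but no pool; ",
           "set one with pool_budget()")
    coef <- vapply(annotated, function(r) r$enzyme$mw / r$enzyme$kcat, 0)
    names(coef) <- vapply(annotated, `[[`, "", "id")
    rows[[tg]] <- list(strain = tg, coef = coef, rhs = pool$enz)
  }
  rows
}
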