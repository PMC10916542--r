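# Compact SBML Level 3 Version 1 + fbc version 2 dialect. Covers what the
# package itself produces: compartments, species, flux-bound parameters,
# gene product associations (nested and/or), and notes carrying the
# kind/origin/enzyme annotations that SBML has no native slot for.
# Namespaced ids contain "@", which is not a legal SBML SId character; it
# is encoded as "__AT__" on write and decoded on read.

SBML_CORE_NS <- "http://www.sbml.org/sbml/level3/version1/core"
SBML_FBC_NS <- "http://www.sbml.org/sbml/level3/version1/fbc/version2"

sid_encode <- function(x) gsub("@", "__AT__", x, fixed = TRUE)
sid_decode <- function(x) gsub("__AT__", "@", x, fixed = TRUE)

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

notes_block <- function(kv, indent) {
  kv <- kv[!vapply(kv, is.null, logical(1))]
  if (!length(kv)) return(character())
  pad <- strrep(" ", indent)
  c(paste0(pad, "<notes>"),
    paste0(pad, '  <body xmlns="http://www.w3.org/1999/xhtml">'),
    vapply(names(kv), function(k)
      paste0(pad, "    <p>", k, ": ", xml_escape(as.character(kv[[k]])), "</p>"), ""),
    paste0(pad, "  </body>"),
    paste0(pad, "</notes>"))
}

gpa_xml <- function(tree, indent) {
  pad <- strrep(" ", indent)
  if (is.character(tree))
    return(paste0(pad, '<fbc:geneProductRef fbc:geneProduct="G_',
                  sid_encode(tree), '"/>'))
  tag <- paste0("fbc:", tree$op)
  c(paste0(pad, "<", tag, ">"),
    unlist(lapply(tree$args, gpa_xml, indent = indent + 2)),
    paste0(pad, "</", tag, ">"))
}

write_model_sbml <- function(model, path) {
  mets <- model$metabolites
  comps <- unique(mets$compartment)
  bounds <- sort(unique(c(vapply(model$reactions, `[[`, 0, "lb"),
                          vapply(model$reactions, `[[`, 0, "ub"))))
  bnd_id <- stats::setNames(sprintf("bnd_%d", seq_along(bounds) - 1L),
                            vapply(bounds, format, "", digits = 17))
  bref <- function(v) bnd_id[[format(v, digits = 17)]]
  genes <- unique(unlist(lapply(model$reactions, function(r)
    if (!is.null(r$gene_rule)) rule_genes(parse_gene_rule(r$gene_rule)))))

  L <- c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    paste0('<sbml xmlns="', SBML_CORE_NS, '" xmlns:fbc="', SBML_FBC_NS,
           '" level="3" version="1" fbc:required="false">'),
    paste0('  <model id="', sid_encode(model$id), '" fbc:strict="true">'))
  model_notes <- list(tag = model[["tag"]], biomass_id = model$biomass_id)
  if (!is.null(model[["pool"]])) {
    model_notes$pool_ptot <- model[["pool"]]$ptot
    model_notes$pool_f <- model[["pool"]]$f
    model_notes$pool_sigma <- model[["pool"]]$sigma
  }
  if (inherits(model, "community_model"))
    model_notes$community_json <- jsonlite::toJSON(community_meta(model),
                                                   auto_unbox = TRUE, digits = NA)
  L <- c(L, notes_block(model_notes, 4))
  L <- c(L, "    <listOfCompartments>",
         vapply(comps, function(cp)
           paste0('      <compartment id="', sid_encode(cp),
                  '" constant="true"/>'), ""),
         "    </listOfCompartments>")
  L <- c(L, "    <listOfSpecies>")
  for (i in seq_len(nrow(mets))) {
    m <- mets[i, ]
    attrs <- paste0('id="M_', sid_encode(m$id), '" name="', xml_escape(m$name),
                    '" compartment="', sid_encode(m$compartment),
                    '" hasOnlySubstanceUnits="false" boundaryCondition="false"',
                    ' constant="false"')
    if (!is.na(m$formula))
      attrs <- paste0(attrs, ' fbc:chemicalFormula="', xml_escape(m$formula), '"')
    kv <- list(base_id = if (m$base_id != m$id) m$base_id else NULL,
               origin = if (is.na(m$origin)) NULL else m$origin)
    if (all(vapply(kv, is.null, logical(1)))) {
      L <- c(L, paste0("      <species ", attrs, "/>"))
    } else {
      L <- c(L, paste0("      <species ", attrs, ">"),
             notes_block(kv, 8),
             "      </species>")
    }
  }
  L <- c(L, "    </listOfSpecies>")
  L <- c(L, "    <listOfParameters>",
         vapply(seq_along(bounds), function(i)
           paste0('      <parameter id="', bnd_id[[i]], '" value="',
                  format(bounds[i], digits = 17),
                  '" constant="true"/>'), ""),
         "    </listOfParameters>")
  if (length(genes)) {
    L <- c(L, "    <fbc:listOfGeneProducts>",
           vapply(genes, function(g)
             paste0('      <fbc:geneProduct fbc:id="G_', sid_encode(g),
                    '" fbc:label="', xml_escape(g), '"/>'), ""),
           "    </fbc:listOfGeneProducts>")
  }
  L <- c(L, "    <listOfReactions>")
  for (r in model$reactions) {
    L <- c(L, paste0('      <reaction id="R_', sid_encode(r$id), '" name="',
                     xml_escape(r$name), '" reversible="', tolower(r$lb < 0),
                     '" fast="false" fbc:lowerFluxBound="', bref(r$lb),
                     '" fbc:upperFluxBound="', bref(r$ub), '">'))
    kv <- list(kind = r$kind,
               origin = if (is.na(r$origin)) NULL else r$origin)
    if (!is.null(r$enzyme)) { kv$kcat <- r$enzyme$kcat; kv$mw <- r$enzyme$mw }
    L <- c(L, notes_block(kv, 8))
    reac <- r$stoich[r$stoich < 0]
    prod <- r$stoich[r$stoich > 0]
    sp_ref <- function(ids, coefs)
      vapply(seq_along(ids), function(i)
        paste0('          <speciesReference species="M_', sid_encode(ids[i]),
               '" stoichiometry="', format(coefs[i], digits = 17),
               '" constant="true"/>'), "")
    if (length(reac))
      L <- c(L, "        <listOfReactants>",
             sp_ref(names(reac), -unname(reac)), "        </listOfReactants>")
    if (length(prod))
      L <- c(L, "        <listOfProducts>",
             sp_ref(names(prod), unname(prod)), "        </listOfProducts>")
    if (!is.null(r$gene_rule)) {
      L <- c(L, "        <fbc:geneProductAssociation>",
             gpa_xml(parse_gene_rule(r$gene_rule), 10),
             "        </fbc:geneProductAssociation>")
    }
    L <- c(L, "      </reaction>")
  }
  L <- c(L, "    </listOfReactions>", "  </model>", "</sbml>")
  writeLines(L, path)
}

parse_notes <- function(node) {
  if (is.na(node) || length(node) == 0) return(list())
  ps <- xml2::xml_find_all(node, ".//*[local-name()='p']")
  out <- list()
  for (p in ps) {
    txt <- xml2::xml_text(p)
    i <- regexpr(": ", txt, fixed = TRUE)
    if (i > 0) out[[substr(txt, 1, i - 1)]] <- substr(txt, i + 2, nchar(txt))
  }
  out
}

parse_gpa <- function(node) {
  nm <- xml2::xml_name(node)
  if (nm == "geneProductRef") {
    g <- xml2::xml_attr(node, "geneProduct")
    return(sid_decode(sub("^G_", "", g)))
  }
  kids <- xml2::xml_find_all(node, "./*")
  list(op = nm, args = lapply(kids, parse_gpa))
}

read_gem_sbml <- function(path) {
  doc <- xml2::read_xml(path)
  model_node <- xml2::xml_find_first(doc, ".//*[local-name()='model']")
  if (is.na(model_node)) stop("parse error in '", path, "': no <model> element")

  params <- xml2::xml_find_all(model_node,
    "./*[local-name()='listOfParameters']/*[local-name()='parameter']")
  pval <- stats::setNames(as.numeric(xml2::xml_attr(params, "value")),
                          xml2::xml_attr(params, "id"))

  sp_nodes <- xml2::xml_find_all(model_node,
    "./*[local-name()='listOfSpecies']/*[local-name()='species']")
  met_rows <- lapply(sp_nodes, function(s) {
    id <- sid_decode(sub("^M_", "", xml2::xml_attr(s, "id")))
    notes <- parse_notes(xml2::xml_find_first(s, "./*[local-name()='notes']"))
    formula <- xml2::xml_attr(s, "chemicalFormula")
    nm <- xml2::xml_attr(s, "name")
    metabolites(id = id,
                compartment = sid_decode(xml2::xml_attr(s, "compartment")),
                name = if (is.na(nm)) id else nm,
                formula = if (is.na(formula)) NA_character_ else formula,
                base_id = note_or(notes, "base_id", id),
                origin = note_or(notes, "origin", NA_character_))
  })
  mets <- do.call(rbind, met_rows)

  rxn_nodes <- xml2::xml_find_all(model_node,
    "./*[local-name()='listOfReactions']/*[local-name()='reaction']")
  missing_bounds <- character()
  rxns <- list()
  for (rn in rxn_nodes) {
    id <- sid_decode(sub("^R_", "", xml2::xml_attr(rn, "id")))
    lb_ref <- xml2::xml_attr(rn, "lowerFluxBound")
    ub_ref <- xml2::xml_attr(rn, "upperFluxBound")
    if (is.na(lb_ref) || is.na(ub_ref) ||
        !lb_ref %in% names(pval) || !ub_ref %in% names(pval)) {
      missing_bounds <- c(missing_bounds, id)
      next
    }
    ref_sign <- function(xp, sgn) {
      refs <- xml2::xml_find_all(rn, xp)
      if (!length(refs)) return(numeric())
      stats::setNames(sgn * as.numeric(xml2::xml_attr(refs, "stoichiometry")),
                      sid_decode(sub("^M_", "", xml2::xml_attr(refs, "species"))))
    }
    st_neg <- ref_sign("./*[local-name()='listOfReactants']/*", -1)
    st_pos <- ref_sign("./*[local-name()='listOfProducts']/*", +1)
    st <- c(st_neg, st_pos)
    notes <- parse_notes(xml2::xml_find_first(rn, "./*[local-name()='notes']"))
    enz <- NULL
    if (!is.null(notes$kcat) && !is.null(notes$mw))
      enz <- list(kcat = as.numeric(notes$kcat), mw = as.numeric(notes$mw))
    gpa <- xml2::xml_find_first(rn, "./*[local-name()='geneProductAssociation']/*")
    gr <- if (!is.na(gpa)) deparse_gene_rule(parse_gpa(gpa)) else NULL
    kind <- note_or(notes, "kind", if (length(st) == 1L) "exchange" else "internal")
    rname <- xml2::xml_attr(rn, "name")
    rxns[[id]] <- reaction(id = id, stoich = st,
                           lb = pval[[lb_ref]], ub = pval[[ub_ref]],
                           name = if (is.na(rname)) id else rname,
                           gene_rule = if (kind %in% c("exchange", "link")) NULL else gr,
                           origin = note_or(notes, "origin", NA_character_),
                           kind = kind, enzyme = enz)
  }
  if (length(missing_bounds))
    stop("missing fbc flux bounds for reaction(s): ",
         paste(missing_bounds, collapse = ", "))

  mnotes <- parse_notes(xml2::xml_find_first(model_node, "./*[local-name()='notes']"))
  pool <- NULL
  if (!is.null(mnotes$pool_ptot))
    pool <- pool_budget(as.numeric(mnotes$pool_ptot), as.numeric(mnotes$pool_f),
                        as.numeric(mnotes$pool_sigma))
  m <- strain_model(id = sid_decode(xml2::xml_attr(model_node, "id")),
                    mets = mets, reactions = rxns,
                    biomass_id = mnotes$biomass_id, pool = pool,
                    tag = mnotes$tag)
  if (!is.null(mnotes$community_json))
    m <- rebuild_community(m, jsonlite::fromJSON(mnotes$community_json,
                                                 simplifyVector = FALSE))
  m
}
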