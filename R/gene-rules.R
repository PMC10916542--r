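# Gene-protein-reaction rule handling: boolean and/or trees in the usual
# COBRA convention ("and" = enzyme complex, every member required;
# "or" = isozymes, any member suffices).

tokenize_rule <- function(rule) {
  rule <- gsub("\\(", " ( ", rule)
  rule <- gsub("\\)", " ) ", rule)
  toks <- strsplit(trimws(rule), "\\s+")[[1]]
  toks[nzchar(toks)]
}

#' Parse a gene association rule
#'
#' @param rule Rule string, e.g. `"g1 and (g2 or g3)"` (case-insensitive
#'   `and`/`or`, parentheses allowed).
#' @return A nested list tree: either a gene name (leaf) or
#'   `list(op = "and"|"or", args = list(...))`. `NULL` for empty rules.
#' @export
parse_gene_rule <- function(rule) {
  if (is.null(rule) || !nzchar(trimws(rule))) return(NULL)
  toks <- tokenize_rule(rule)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  advance <- function() { pos <<- pos + 1L; toks[pos - 1L] }
  parse_expr <- function() {
    args <- list(parse_term())
    while (!is.na(peek()) && tolower(peek()) == "or") {
      advance()
      args[[length(args) + 1L]] <- parse_term()
    }
    if (length(args) == 1L) args[[1L]] else list(op = "or", args = args)
  }
  parse_term <- function() {
    args <- list(parse_factor())
    while (!is.na(peek()) && tolower(peek()) == "and") {
      advance()
      args[[length(args) + 1L]] <- parse_factor()
    }
    if (length(args) == 1L) args[[1L]] else list(op = "and", args = args)
  }
  parse_factor <- function() {
    tok <- peek()
    if (is.na(tok)) stop("unexpected end of gene rule: '", rule, "'")
    if (tok == "(") {
      advance()
      inner <- parse_expr()
      if (is.na(peek()) || peek() != ")")
        stop("unbalanced parentheses in gene rule: '", rule, "'")
      advance()
      return(inner)
    }
    if (tok == ")" || tolower(tok) %in% c("and", "or"))
      stop("malformed gene rule near '", tok, "': '", rule, "'")
    advance()
  }
  tree <- parse_expr()
  if (pos <= length(toks))
    stop("trailing tokens in gene rule: '", rule, "'")
  tree
}

#' Evaluate a gene rule under knockouts
#'
#' @param rule Rule string or parsed tree.
#' @param knocked Character vector of deleted genes.
#' @return `TRUE` if the reaction remains catalyzable, `FALSE` if the
#'   knockouts close it. Empty rules evaluate `TRUE` (no gene dependency).
#' @export
eval_gene_rule <- function(rule, knocked = character()) {
  if (is.character(rule)) rule <- parse_gene_rule(rule)
  if (is.null(rule)) return(TRUE)
  rec <- function(node) {
    if (is.character(node)) return(!node %in% knocked)
    vals <- vapply(node$args, rec, logical(1))
    if (node$op == "and") all(vals) else any(vals)
  }
  rec(rule)
}

#' List the genes appearing in a rule
#'
#' @param rule Rule string or parsed tree.
#' @return Character vector of gene names (unique, in appearance order).
#' @export
rule_genes <- function(rule) {
  if (is.character(rule) && length(rule) == 1L && grepl("\\s|\\(", rule))
    rule <- parse_gene_rule(rule)
  if (is.null(rule)) return(character())
  if (is.character(rule)) return(rule)
  rec <- function(node) {
    if (is.character(node)) return(node)
    unlist(lapply(node$args, rec))
  }
  unique(rec(rule))
}

# internal: render a parsed tree back to a canonical rule string
deparse_gene_rule <- function(tree, parent_op = NULL) {
  if (is.null(tree)) return(NULL)
  if (is.character(tree)) return(tree)
  parts <- vapply(tree$args, deparse_gene_rule, "", parent_op = tree$op)
  s <- paste(parts, collapse = paste0(" ", tree$op, " "))
  if (!is.null(parent_op) && !identical(parent_op, tree$op)) s <- paste0("(", s, ")")
  s
}
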