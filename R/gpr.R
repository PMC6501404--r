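#' Gene-protein-reaction (GPR) boolean rules
#'
#' A GPR rule is a boolean tree over gene ids: \code{AND} nodes represent
#' enzyme complexes (all subunits required), \code{OR} nodes isozymes (any
#' one suffices). Trees are nested lists with an \code{op} field equal to
#' \code{"gene"}, \code{"and"} or \code{"or"}.
#'
#' @param gene gene id.
#' @name gpr
NULL

#' @rdname gpr
#' @export
gpr_gene <- function(gene) list(op = "gene", gene = gene)

#' @rdname gpr
#' @param ... child nodes (rule trees).
#' @export
gpr_and <- function(...) list(op = "and", children = list(...))

#' @rdname gpr
#' @export
gpr_or <- function(...) list(op = "or", children = list(...))

#' Parse a GPR boolean expression
#'
#' Grammar: \code{expr := term ("or" term)*; term := factor ("and" factor)*;
#' factor := gene | "(" expr ")"}. \code{and} binds tighter than \code{or};
#' keywords are case-insensitive. Consecutive identical operators are
#' flattened into one n-ary node.
#'
#' @param text expression string, e.g. \code{"(g1 and g2) or g3"}.
#' @return a GPR rule tree.
#' @export
parse_gpr_expression <- function(text) {
  toks <- regmatches(text, gregexpr("[A-Za-z0-9_.\\-]+|\\(|\\)", text))[[1]]
  if (!length(toks)) stop("empty GPR expression")
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  take <- function() { t <- peek(); pos <<- pos + 1L; t }
  parse_expr <- function() {
    kids <- list(parse_term())
    while (!is.na(peek()) && tolower(peek()) == "or") {
      take(); kids[[length(kids) + 1L]] <- parse_term()
    }
    if (length(kids) == 1L) kids[[1L]] else list(op = "or", children = kids)
  }
  parse_term <- function() {
    kids <- list(parse_factor())
    while (!is.na(peek()) && tolower(peek()) == "and") {
      take(); kids[[length(kids) + 1L]] <- parse_factor()
    }
    if (length(kids) == 1L) kids[[1L]] else list(op = "and", children = kids)
  }
  parse_factor <- function() {
    t <- take()
    if (is.na(t)) stop("unexpected end of GPR expression: ", text)
    if (t == "(") {
      e <- parse_expr()
      if (!identical(take(), ")")) stop("missing ')' in GPR: ", text)
      return(e)
    }
    if (t == ")" || tolower(t) %in% c("and", "or"))
      stop("unexpected token '", t, "' in GPR: ", text)
    gpr_gene(t)
  }
  out <- parse_expr()
  if (pos <= length(toks))
    stop("trailing tokens in GPR: ", paste(toks[pos:length(toks)], collapse = " "))
  out
}

#' Deparse a GPR rule tree back to its expression string
#' @param rule a GPR rule tree.
#' @return character scalar.
#' @export
deparse_gpr <- function(rule) {
  if (rule$op == "gene") return(rule$gene)
  parts <- vapply(rule$children, function(ch) {
    s <- deparse_gpr(ch)
    # parenthesize an "or" child under an "and" parent to preserve precedence
    if (rule$op == "and" && ch$op == "or") paste0("(", s, ")") else s
  }, character(1))
  paste(parts, collapse = paste0(" ", rule$op, " "))
}

#' Gene ids appearing in a rule
#' @param rule a GPR rule tree.
#' @return character vector of distinct gene ids (leaves).
#' @export
gpr_leaves <- function(rule) {
  if (rule$op == "gene") return(rule$gene)
  unique(unlist(lapply(rule$children, gpr_leaves)))
}

#' Is a reaction still functional after deleting genes?
#'
#' AND nodes require every child functional (complex broken by any missing
#' subunit); OR nodes require any child functional (an isozyme survives).
#'
#' @param rule a GPR rule tree.
#' @param deleted character vector of deleted gene ids; ids not present in
#'   the rule are ignored.
#' @return logical scalar.
#' @export
evaluate_deletion <- function(rule, deleted) {
  switch(rule$op,
         gene = !(rule$gene %in% deleted),
         and = all(vapply(rule$children, evaluate_deletion, logical(1),
                          deleted = deleted)),
         or = any(vapply(rule$children, evaluate_deletion, logical(1),
                         deleted = deleted)),
         stop("bad GPR node"))
}

#' Map gene expression states onto a reaction state
#'
#' Gene states live in \{-1, 0, 1\} (low/absent, moderate, high). AND nodes
#' take the minimum of their children (a complex is only as available as its
#' scarcest subunit), OR nodes the maximum (the strongest isozyme carries the
#' reaction). Genes missing from \code{states} count as 0: absence of
#' measurement is not evidence of absence.
#'
#' @param rule a GPR rule tree.
#' @param states named integer vector of gene states.
#' @return integer in \{-1, 0, 1\}.
#' @export
reaction_expression_state <- function(rule, states) {
  switch(rule$op,
         gene = {
           s <- states[rule$gene]
           if (is.na(s)) 0L else as.integer(s)
         },
         and = min(vapply(rule$children, reaction_expression_state,
                          integer(1), states = states)),
         or = max(vapply(rule$children, reaction_expression_state,
                         integer(1), states = states)),
         stop("bad GPR node"))
}

#' Count reactions by number of associated genes
#'
#' @param model a \code{metabolic_model}.
#' @return named integer vector \code{c(single=, multi=, none=)}: reactions
#'   whose GPR names exactly one distinct gene, more than one, or that have
#'   no GPR at all. The three counts partition the reaction set.
#' @export
classify_reactions_by_gene_count <- function(model) {
  k <- vapply(model$reactions, function(r)
    if (is.null(r$gpr)) 0L else length(gpr_leaves(r$gpr)), integer(1))
  c(single = sum(k == 1L), multi = sum(k > 1L), none = sum(k == 0L))
}

# reaction ids rendered non-functional by a deletion set
reactions_disabled_by <- function(model, deleted) {
  ids <- vapply(model$reactions, `[[`, "", "id")
  off <- vapply(model$reactions, function(r)
    !is.null(r$gpr) && !evaluate_deletion(r$gpr, deleted), logical(1))
  ids[off]
}
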