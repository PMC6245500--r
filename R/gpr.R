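## Gene-protein-reaction rule parsing and evaluation.
##
## Grammar (AND binds tighter than OR, parentheses override):
##   expr   := term  ( OR  term  )*
##   term   := factor( AND factor)*
##   factor := GENE | '(' expr ')'
## Evaluation maps AND -> min (enzymatic complex, limited by the scarcest
## subunit) and OR -> max (isozymes, carried by the most expressed one).

tokenizeGPR <- function(rule) {
  pat <- "\\(|\\)|[^()[:space:]]+"
  m <- gregexpr(pat, rule)[[1]]
  if (m[1] == -1) return(data.frame(tok = character(0), pos = integer(0)))
  tok <- regmatches(rule, gregexpr(pat, rule))[[1]]
  data.frame(tok = tok, pos = as.integer(m), stringsAsFactors = FALSE)
}

#' Parse a GPR rule
#'
#' Parses a boolean gene rule (identifiers combined with \code{AND}/\code{OR},
#' case-insensitive, and parentheses) into an abstract syntax tree. An empty
#' or whitespace-only rule returns \code{NULL} (no gene association).
#'
#' @param rule a GPR rule string.
#' @return \code{NULL} for the empty rule, otherwise a nested list with
#'   elements \code{op} (\code{"gene"}, \code{"and"}, \code{"or"}) and either
#'   \code{gene} or \code{args}.
#' @examples
#' parseGPR("(g1 AND g2) OR g3")
#' @export
parseGPR <- function(rule) {
  stopifnot(is.character(rule), length(rule) == 1L)
  if (is.na(rule) || !nzchar(trimws(rule))) return(NULL)
  toks <- tokenizeGPR(rule)
  i <- 1L
  n <- nrow(toks)
  peek <- function() if (i <= n) toks$tok[i] else NA_character_
  fail <- function(what) {
    pos <- if (i <= n) toks$pos[i] else nchar(rule) + 1L
    stop(sprintf("GPR parse error at position %d in %s: %s", pos,
                 deparse(rule), what), call. = FALSE)
  }
  isOp <- function(tk, op) !is.na(tk) && tolower(tk) == op

  parseExpr <- function() {
    args <- list(parseTerm())
    while (isOp(peek(), "or")) {
      i <<- i + 1L
      args[[length(args) + 1L]] <- parseTerm()
    }
    if (length(args) == 1L) args[[1L]] else list(op = "or", args = args)
  }
  parseTerm <- function() {
    args <- list(parseFactor())
    while (isOp(peek(), "and")) {
      i <<- i + 1L
      args[[length(args) + 1L]] <- parseFactor()
    }
    if (length(args) == 1L) args[[1L]] else list(op = "and", args = args)
  }
  parseFactor <- function() {
    tk <- peek()
    if (is.na(tk)) fail("unexpected end of rule")
    if (tk == "(") {
      i <<- i + 1L
      e <- parseExpr()
      if (!identical(peek(), ")")) fail("expected ')'")
      i <<- i + 1L
      return(e)
    }
    if (tk == ")" || isOp(tk, "and") || isOp(tk, "or"))
      fail(sprintf("unexpected token '%s'", tk))
    i <<- i + 1L
    list(op = "gene", gene = tk)
  }

  ast <- parseExpr()
  if (i <= n) fail(sprintf("trailing token '%s'", peek()))
  ast
}

gprGenes <- function(ast) {
  if (is.null(ast)) return(character(0))
  if (ast$op == "gene") return(ast$gene)
  unique(unlist(lapply(ast$args, gprGenes)))
}

evalGPRAst <- function(ast, expr, missing = 1) {
  if (ast$op == "gene") {
    v <- expr[ast$gene]
    if (is.na(v)) missing else unname(v)
  } else {
    vals <- vapply(ast$args, evalGPRAst, numeric(1), expr = expr,
                   missing = missing)
    if (ast$op == "and") min(vals) else max(vals)
  }
}

#' Reaction expression from a GPR rule
#'
#' Summarises the expression of a reaction's genes into a single scalar:
#' AND-joined terms combine by \code{min} and OR-joined terms by \code{max}.
#' The empty rule evaluates to 1 (the neutral point of the bound map), and
#' genes absent from the profile take \code{missing} so incomplete data does
#' not shut reactions down.
#'
#' @param gpr a GPR rule string (or a parsed AST from \code{\link{parseGPR}}).
#' @param geneExpr named numeric vector of non-negative gene expression values.
#' @param missing value used for genes not present in \code{geneExpr}.
#' @return a single non-negative reaction expression value.
#' @examples
#' reactionExpression("g1 AND g2", c(g1 = 2, g2 = 0.5))   # 0.5
#' reactionExpression("g1 OR g2",  c(g1 = 2, g2 = 0.5))   # 2
#' @export
reactionExpression <- function(gpr, geneExpr, missing = 1) {
  ast <- if (is.character(gpr)) parseGPR(gpr) else gpr
  if (is.null(ast)) return(1)
  evalGPRAst(ast, geneExpr, missing = missing)
}
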