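#' Parse a gene-protein-reaction (GPR) rule
#'
#' GPR rules link genes to reaction availability as a boolean expression
#' whose leaves are gene identifiers and whose internal nodes are
#' \code{AND} (enzyme complexes: all members required) and \code{OR}
#' (isozymes: any member suffices). Operators are case-insensitive and
#' parentheses group subexpressions. An empty or all-whitespace string
#' yields the empty rule, which is never disabled by gene deletion
#' (transport, exchange and spontaneous reactions behave this way).
#'
#' @param text GPR string, e.g. \code{"(g1 and g2) or g3"}.
#' @return An object of class \code{gprRule}: either the empty rule, a
#'   gene leaf, or an AND/OR node with child rules. Serializes back with
#'   \code{\link{gprToString}}.
#' @examples
#' r <- parseGPR("(hk1 or hk2) and pkm")
#' evaluateGPR(r, c("hk2", "pkm"))
#' @export
parseGPR <- function(text) {
  if (is.null(text) || length(text) == 0 || is.na(text) || !nzchar(trimws(text))) {
    return(structure(list(op = "empty"), class = "gprRule"))
  }
  toks <- .gprTokenize(text)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  rule <- .gprParseOr(st)
  if (st$pos <= nrow(st$toks)) {
    stop(sprintf("GPR parse error: unexpected token '%s' at position %d",
                 st$toks$token[st$pos], st$toks$at[st$pos]), call. = FALSE)
  }
  rule
}

.gprTokenize <- function(text) {
  pat <- "\\(|\\)|[^()[:space:]]+"
  m <- gregexpr(pat, text)[[1]]
  if (m[1] == -1) stop("GPR parse error: no tokens found", call. = FALSE)
  token <- regmatches(text, gregexpr(pat, text))[[1]]
  data.frame(token = token, at = as.integer(m), stringsAsFactors = FALSE)
}

.gprPeek <- function(st) {
  if (st$pos > nrow(st$toks)) NULL else st$toks$token[st$pos]
}

.gprTake <- function(st) {
  tk <- .gprPeek(st)
  st$pos <- st$pos + 1L
  tk
}

.gprParseOr <- function(st) {
  args <- list(.gprParseAnd(st))
  while (!is.null(tk <- .gprPeek(st)) && tolower(tk) == "or") {
    .gprTake(st)
    args <- c(args, list(.gprParseAnd(st)))
  }
  if (length(args) == 1L) args[[1L]]
  else structure(list(op = "or", args = args), class = "gprRule")
}

.gprParseAnd <- function(st) {
  args <- list(.gprParseAtom(st))
  while (!is.null(tk <- .gprPeek(st)) && tolower(tk) == "and") {
    .gprTake(st)
    args <- c(args, list(.gprParseAtom(st)))
  }
  if (length(args) == 1L) args[[1L]]
  else structure(list(op = "and", args = args), class = "gprRule")
}

.gprParseAtom <- function(st) {
  tk <- .gprPeek(st)
  if (is.null(tk)) {
    last <- st$toks$at[nrow(st$toks)] + nchar(st$toks$token[nrow(st$toks)])
    stop(sprintf("GPR parse error: unexpected end of expression at position %d",
                 last), call. = FALSE)
  }
  at <- st$toks$at[st$pos]
  if (tk == "(") {
    .gprTake(st)
    inner <- .gprParseOr(st)
    cl <- .gprPeek(st)
    if (is.null(cl) || cl != ")") {
      stop(sprintf("GPR parse error: unmatched '(' at position %d", at),
           call. = FALSE)
    }
    .gprTake(st)
    return(inner)
  }
  if (tk == ")") {
    stop(sprintf("GPR parse error: unexpected ')' at position %d", at),
         call. = FALSE)
  }
  if (tolower(tk) %in% c("and", "or")) {
    stop(sprintf("GPR parse error: operator '%s' at position %d lacks an operand",
                 tk, at), call. = FALSE)
  }
  .gprTake(st)
  structure(list(op = "gene", gene = tk), class = "gprRule")
}

#' Serialize a GPR rule back to text
#'
#' The output round-trips through \code{\link{parseGPR}} to an equivalent
#' rule (identical truth table over its genes).
#'
#' @param rule A \code{gprRule}.
#' @return Character scalar; \code{""} for the empty rule.
#' @export
gprToString <- function(rule) {
  stopifnot(inherits(rule, "gprRule"))
  switch(rule$op,
    empty = "",
    gene = rule$gene,
    and = paste(vapply(rule$args, .gprStringWrap, "", parent = "and"),
                collapse = " and "),
    or = paste(vapply(rule$args, .gprStringWrap, "", parent = "or"),
               collapse = " or "))
}

.gprStringWrap <- function(rule, parent) {
  s <- gprToString(rule)
  # 'or' child under an 'and' parent needs parentheses; everything else not
  if (parent == "and" && rule$op == "or") paste0("(", s, ")") else s
}

#' Evaluate a GPR rule over a set of active genes
#'
#' AND nodes are true when all children are true, OR nodes when any child
#' is true; a gene leaf is true iff the gene is in \code{activeGenes}.
#' The empty rule always evaluates true.
#'
#' @param rule A \code{gprRule}.
#' @param activeGenes Character vector of active gene identifiers.
#' @return Logical scalar.
#' @export
evaluateGPR <- function(rule, activeGenes) {
  stopifnot(inherits(rule, "gprRule"))
  switch(rule$op,
    empty = TRUE,
    gene = rule$gene %in% activeGenes,
    and = all(vapply(rule$args, evaluateGPR, logical(1), activeGenes = activeGenes)),
    or = any(vapply(rule$args, evaluateGPR, logical(1), activeGenes = activeGenes)))
}

#' Genes appearing in a GPR rule
#'
#' @param rule A \code{gprRule}.
#' @return Character vector of distinct gene identifiers (leaf set).
#' @export
gprGenes <- function(rule) {
  stopifnot(inherits(rule, "gprRule"))
  switch(rule$op,
    empty = character(0),
    gene = rule$gene,
    unique(unlist(lapply(rule$args, gprGenes))))
}

#' @exportS3Method base::print
print.gprRule <- function(x, ...) {
  s <- gprToString(x)
  cat("<gprRule> ", if (nzchar(s)) s else "(empty)", "\n", sep = "")
  invisible(x)
}
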