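# Gene-protein-reaction (GPR) rules: boolean expressions over gene ids where
# AND encodes enzyme complexes and OR encodes isozymes. For mapping continuous
# gene statistics onto reactions we use the standard continuous relaxation
# AND = min (limiting subunit), OR = max (best-expressed isozyme).

#' Parse a gene-protein-reaction rule
#'
#' Grammar: \code{expr := term ("or" term)*}, \code{term := factor ("and"
#' factor)*}, \code{factor := GENE | "(" expr ")"}. Keywords are
#' case-insensitive; \code{and} binds tighter than \code{or}.
#'
#' @param rule rule text; empty or \code{NA} yields \code{NULL} (no rule).
#' @return a parse tree: a leaf is \code{list(op = "gene", gene = <id>)}, an
#'   internal node \code{list(op = "and"|"or", children = <list>)}.
#' @examples
#' parse_gpr("(g1 and g2) or g3")
#' @export
parse_gpr <- function(rule) {
  if (is.null(rule) || is.na(rule) || !nzchar(trimws(rule))) return(NULL)
  toks <- gpr_tokenize(rule)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$pos <- 1L
  expr <- gpr_parse_or(st)
  if (st$pos <= length(st$toks))
    stop("GPR parse error at position ", st$toks[[st$pos]]$at,
         ": unexpected '", st$toks[[st$pos]]$text, "'")
  expr
}

gpr_tokenize <- function(rule) {
  toks <- list()
  i <- 1L
  n <- nchar(rule)
  while (i <= n) {
    ch <- substr(rule, i, i)
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    if (ch %in% c("(", ")")) {
      toks[[length(toks) + 1L]] <- list(type = ch, text = ch, at = i)
      i <- i + 1L
      next
    }
    m <- regmatches(substr(rule, i, n),
                    regexpr("^[^\\s()]+", substr(rule, i, n), perl = TRUE))
    word <- m[1]
    type <- switch(tolower(word), "and" = "and", "or" = "or", "gene")
    toks[[length(toks) + 1L]] <- list(type = type, text = word, at = i)
    i <- i + nchar(word)
  }
  toks
}

gpr_peek <- function(st) if (st$pos <= length(st$toks)) st$toks[[st$pos]] else NULL

gpr_parse_or <- function(st) {
  children <- list(gpr_parse_and(st))
  repeat {
    tk <- gpr_peek(st)
    if (is.null(tk) || tk$type != "or") break
    st$pos <- st$pos + 1L
    children[[length(children) + 1L]] <- gpr_parse_and(st)
  }
  if (length(children) == 1L) children[[1L]]
  else list(op = "or", children = children)
}

gpr_parse_and <- function(st) {
  children <- list(gpr_parse_factor(st))
  repeat {
    tk <- gpr_peek(st)
    if (is.null(tk) || tk$type != "and") break
    st$pos <- st$pos + 1L
    children[[length(children) + 1L]] <- gpr_parse_factor(st)
  }
  if (length(children) == 1L) children[[1L]]
  else list(op = "and", children = children)
}

gpr_parse_factor <- function(st) {
  tk <- gpr_peek(st)
  if (is.null(tk))
    stop("GPR parse error at end of rule: operand expected")
  if (tk$type == "(") {
    st$pos <- st$pos + 1L
    e <- gpr_parse_or(st)
    tk2 <- gpr_peek(st)
    if (is.null(tk2) || tk2$type != ")")
      stop("GPR parse error at position ", tk$at, ": unbalanced parenthesis")
    st$pos <- st$pos + 1L
    return(e)
  }
  if (tk$type != "gene")
    stop("GPR parse error at position ", tk$at,
         ": operand expected, found '", tk$text, "'")
  st$pos <- st$pos + 1L
  list(op = "gene", gene = tk$text)
}

#' Evaluate a GPR parse tree over gene values
#'
#' AND nodes take the minimum of their children (a complex is limited by its
#' scarcest subunit), OR nodes the maximum (isozymes substitute for each
#' other). Genes absent from \code{gene_values} contribute \code{default}:
#' with log fold changes, an unmeasured gene is treated as unchanged.
#'
#' @param expr tree from [parse_gpr()]; \code{NULL} returns \code{default}.
#' @param gene_values named numeric vector, gene id -> value.
#' @param default value for genes not in \code{gene_values}.
#' @return a single numeric value.
#' @export
evaluate_gpr <- function(expr, gene_values, default = 0) {
  if (is.null(expr)) return(default)
  switch(expr$op,
    gene = {
      v <- unname(gene_values[expr$gene])
      if (length(v) != 1 || is.na(v)) default else v
    },
    and = min(vapply(expr$children, evaluate_gpr, 0,
                     gene_values = gene_values, default = default)),
    or = max(vapply(expr$children, evaluate_gpr, 0,
                    gene_values = gene_values, default = default)),
    stop("invalid GPR node op: ", expr$op))
}

#' Genes referenced by a GPR tree
#'
#' @param expr tree from [parse_gpr()].
#' @return character vector of unique gene ids (empty for \code{NULL}).
#' @export
gpr_genes <- function(expr) {
  if (is.null(expr)) return(character())
  if (expr$op == "gene") return(expr$gene)
  unique(unlist(lapply(expr$children, gpr_genes)))
}
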