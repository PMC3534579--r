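#' Parse a gene-protein-reaction (GPR) rule
#'
#' Parses a boolean GPR expression over gene identifiers into a tree.
#' \code{and} nodes encode enzyme complexes (all subunit genes
#' required), \code{or} nodes encode isozymes (any one gene suffices).
#' Operators are case-insensitive; parentheses group as usual. An empty
#' or whitespace-only rule yields \code{NULL} (a reaction with no gene
#' requirement).
#'
#' The tree is a nested list: a leaf is a length-one character vector
#' (the gene id); an internal node is \code{list(op = "and"|"or",
#' args = list(...))}.
#'
#' @param ruleText character scalar, e.g. \code{"(g1 and g2) or g3"}.
#' @return a GPR tree, or \code{NULL} for an empty rule.
#' @examples
#' tr <- parseGPR("(g1 and g2) or g3")
#' evalGPR(tr, present = "g3")   # TRUE: isozyme g3 suffices
#' evalGPR(tr, present = "g1")   # FALSE: complex incomplete
#' @seealso [evalGPR()], [gprGenes()], [classifyGene()]
#' @export
parseGPR <- function(ruleText) {
  stopifnot(is.character(ruleText), length(ruleText) == 1L)
  toks <- gprTokenize(ruleText)
  if (length(toks$type) == 0L) return(NULL)
  st <- new.env(parent = emptyenv())
  st$i <- 1L
  st$toks <- toks
  tree <- gprParseOr(st)
  if (st$i <= length(st$toks$type)) {
    stop("GPR syntax error at position ", st$toks$pos[st$i],
         ": unexpected '", st$toks$text[st$i], "'")
  }
  tree
}

gprTokenize <- function(txt) {
  type <- character(); text <- character(); pos <- integer()
  chars <- strsplit(txt, "", fixed = TRUE)[[1]]
  i <- 1L; n <- length(chars)
  while (i <= n) {
    ch <- chars[i]
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    if (ch == "(" || ch == ")") {
      type <- c(type, ch); text <- c(text, ch); pos <- c(pos, i)
      i <- i + 1L; next
    }
    j <- i
    while (j <= n && !grepl("^[\\s()]$", chars[j], perl = TRUE)) j <- j + 1L
    word <- paste(chars[i:(j - 1L)], collapse = "")
    lw <- tolower(word)
    if (lw == "and" || lw == "or") {
      type <- c(type, lw)
    } else {
      type <- c(type, "gene")
    }
    text <- c(text, word); pos <- c(pos, i)
    i <- j
  }
  list(type = type, text = text, pos = pos)
}

gprPeek <- function(st) {
  if (st$i > length(st$toks$type)) NA_character_ else st$toks$type[st$i]
}

gprParseOr <- function(st) {
  args <- list(gprParseAnd(st))
  while (identical(gprPeek(st), "or")) {
    st$i <- st$i + 1L
    args <- c(args, list(gprParseAnd(st)))
  }
  if (length(args) == 1L) args[[1]] else list(op = "or", args = args)
}

gprParseAnd <- function(st) {
  args <- list(gprParseAtom(st))
  while (identical(gprPeek(st), "and")) {
    st$i <- st$i + 1L
    args <- c(args, list(gprParseAtom(st)))
  }
  if (length(args) == 1L) args[[1]] else list(op = "and", args = args)
}

gprParseAtom <- function(st) {
  tt <- gprPeek(st)
  if (is.na(tt))
    stop("GPR syntax error: unexpected end of rule (dangling operator?)")
  if (tt == "(") {
    open <- st$toks$pos[st$i]
    st$i <- st$i + 1L
    inner <- gprParseOr(st)
    if (!identical(gprPeek(st), ")"))
      stop("GPR syntax error: unbalanced parenthesis opened at position ", open)
    st$i <- st$i + 1L
    return(inner)
  }
  if (tt == "gene") {
    g <- st$toks$text[st$i]
    st$i <- st$i + 1L
    return(g)
  }
  stop("GPR syntax error at position ", st$toks$pos[st$i],
       ": unexpected '", st$toks$text[st$i], "'")
}

#' Evaluate a GPR tree under a gene-presence assignment
#'
#' @param tree a GPR tree from [parseGPR()], or \code{NULL}.
#' @param present character vector of genes considered present;
#'   ignored when \code{absent} is given.
#' @param absent character vector of genes considered absent (all
#'   others present); the usual mode for knockdown screens.
#' @return logical scalar; a \code{NULL} (empty) tree evaluates
#'   \code{TRUE} (the reaction needs no gene).
#' @seealso [parseGPR()]
#' @export
evalGPR <- function(tree, present = character(), absent = NULL) {
  if (is.null(tree)) return(TRUE)
  if (is.character(tree)) {
    if (!is.null(absent)) return(!(tree %in% absent))
    return(tree %in% present)
  }
  vals <- vapply(tree$args, evalGPR, logical(1),
                 present = present, absent = absent)
  if (tree$op == "and") all(vals) else any(vals)
}

#' Genes referenced by a GPR tree
#'
#' @param tree a GPR tree from [parseGPR()], or \code{NULL}.
#' @return character vector of distinct gene ids (empty for \code{NULL}).
#' @export
gprGenes <- function(tree) {
  if (is.null(tree)) return(character())
  if (is.character(tree)) return(tree)
  unique(unlist(lapply(tree$args, gprGenes)))
}

#' Render a GPR tree back to rule text
#'
#' Inverse of [parseGPR()] up to whitespace and redundant parentheses.
#'
#' @param tree a GPR tree, or \code{NULL}.
#' @return character scalar ("" for \code{NULL}).
#' @export
deparseGPR <- function(tree) {
  if (is.null(tree)) return("")
  if (is.character(tree)) return(tree)
  inner <- vapply(tree$args, deparseGPR, character(1))
  paste0("(", paste(inner, collapse = paste0(" ", tree$op, " ")), ")")
}
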