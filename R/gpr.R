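#' Parse a gene-protein-reaction (GPR) rule
#'
#' GPR rules are boolean expressions over gene identifiers in which `and`
#' denotes an enzyme complex (all subunits required) and `or` denotes
#' isozymes (any one suffices). The grammar accepts case-insensitive
#' `and`/`or`, parentheses, and arbitrary non-whitespace gene identifiers;
#' `and` binds tighter than `or`, following the COBRA-JSON convention.
#'
#' @param text GPR string, e.g. `"g1 and (g2 or g3)"`. The empty string (or
#'   `NA`) yields the empty rule, meaning the reaction has no gene
#'   dependency.
#' @return An object of class `gpr`: `NULL` for the empty rule, otherwise a
#'   nested list of `and`/`or` nodes with gene leaves.
#' @examples
#' parse_gpr("g1 or g2 and g3")   # or(g1, and(g2, g3))
#' parse_gpr("")                  # empty rule
#' @seealso [evaluate_gpr()], [gpr_to_string()], [gpr_genes()]
#' @export
parse_gpr <- function(text) {
  if (length(text) != 1L || is.na(text)) text <- ""
  text <- trimws(text)
  if (!nzchar(text)) return(structure(list(), class = "gpr", empty = TRUE))

  toks <- gpr_tokenize(text)
  state <- new.env(parent = emptyenv())
  state$toks <- toks
  state$pos <- 1L

  tree <- gpr_parse_or(state)
  if (state$pos <= length(state$toks$type)) {
    stop(sprintf("GPR parse error at position %d: unexpected '%s'",
                 state$toks$at[state$pos], state$toks$value[state$pos]),
         call. = FALSE)
  }
  structure(tree, class = "gpr", empty = FALSE)
}

gpr_tokenize <- function(text) {
  type <- character(); value <- character(); at <- integer()
  i <- 1L; n <- nchar(text)
  while (i <= n) {
    ch <- substr(text, i, i)
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    if (ch == "(") { type <- c(type, "lpar"); value <- c(value, "("); at <- c(at, i); i <- i + 1L; next }
    if (ch == ")") { type <- c(type, "rpar"); value <- c(value, ")"); at <- c(at, i); i <- i + 1L; next }
    j <- i
    while (j <= n && !grepl("^[\\s()]$", substr(text, j, j), perl = TRUE)) j <- j + 1L
    word <- substr(text, i, j - 1L)
    lw <- tolower(word)
    if (lw %in% c("and", "&", "&&")) type <- c(type, "and")
    else if (lw %in% c("or", "|", "||")) type <- c(type, "or")
    else type <- c(type, "gene")
    value <- c(value, word); at <- c(at, i)
    i <- j
  }
  list(type = type, value = value, at = at)
}

gpr_peek <- function(state) {
  if (state$pos > length(state$toks$type)) return(NULL)
  list(type = state$toks$type[state$pos],
       value = state$toks$value[state$pos],
       at = state$toks$at[state$pos])
}

gpr_advance <- function(state) state$pos <- state$pos + 1L

gpr_parse_or <- function(state) {
  args <- list(gpr_parse_and(state))
  repeat {
    tk <- gpr_peek(state)
    if (is.null(tk) || tk$type != "or") break
    gpr_advance(state)
    args <- c(args, list(gpr_parse_and(state)))
  }
  if (length(args) == 1L) args[[1L]] else gpr_node("or", args)
}

gpr_parse_and <- function(state) {
  args <- list(gpr_parse_atom(state))
  repeat {
    tk <- gpr_peek(state)
    if (is.null(tk) || tk$type != "and") break
    gpr_advance(state)
    args <- c(args, list(gpr_parse_atom(state)))
  }
  if (length(args) == 1L) args[[1L]] else gpr_node("and", args)
}

gpr_parse_atom <- function(state) {
  tk <- gpr_peek(state)
  if (is.null(tk)) stop("GPR parse error: dangling operator at end of rule", call. = FALSE)
  if (tk$type == "lpar") {
    gpr_advance(state)
    inner <- gpr_parse_or(state)
    tk2 <- gpr_peek(state)
    if (is.null(tk2) || tk2$type != "rpar") {
      stop(sprintf("GPR parse error at position %d: unbalanced parenthesis", tk$at),
           call. = FALSE)
    }
    gpr_advance(state)
    return(inner)
  }
  if (tk$type == "gene") {
    gpr_advance(state)
    return(list(op = "gene", gene = tk$value))
  }
  stop(sprintf("GPR parse error at position %d: unexpected '%s'", tk$at, tk$value),
       call. = FALSE)
}

# flatten same-op children so associativity is canonical
gpr_node <- function(op, args) {
  flat <- list()
  for (a in args) {
    if (!is.null(a$op) && a$op == op) flat <- c(flat, a$args) else flat <- c(flat, list(a))
  }
  list(op = op, args = flat)
}

#' Test whether a GPR rule is empty (no gene association)
#' @param gpr a `gpr` object
#' @return logical
#' @export
gpr_is_empty <- function(gpr) {
  is.null(gpr) || isTRUE(attr(gpr, "empty")) ||
    (length(gpr) == 0L && is.null(gpr$op))
}

#' Evaluate a GPR rule under a set of deleted genes
#'
#' A leaf is active iff its gene is not deleted; `and` nodes require all
#' children active, `or` nodes any child. The empty rule evaluates to
#' `TRUE`: a reaction without gene association is never disabled by gene
#' deletion.
#'
#' @param gpr a `gpr` object from [parse_gpr()]
#' @param deleted character vector of deleted gene ids
#' @return logical: is the reaction still catalysed?
#' @export
evaluate_gpr <- function(gpr, deleted = character()) {
  if (gpr_is_empty(gpr)) return(TRUE)
  eval_node <- function(node) {
    switch(node$op,
      gene = !(node$gene %in% deleted),
      and  = all(vapply(node$args, eval_node, logical(1))),
      or   = any(vapply(node$args, eval_node, logical(1))),
      stop("corrupt GPR node op: ", node$op)
    )
  }
  eval_node(gpr)
}

#' Genes referenced by a GPR rule
#' @param gpr a `gpr` object
#' @return character vector of unique gene ids (empty for the empty rule)
#' @export
gpr_genes <- function(gpr) {
  if (gpr_is_empty(gpr)) return(character())
  walk <- function(node) {
    if (node$op == "gene") return(node$gene)
    unlist(lapply(node$args, walk), use.names = FALSE)
  }
  unique(walk(gpr))
}

#' Canonical string form of a GPR rule
#'
#' Round-trips with [parse_gpr()]: `parse_gpr(gpr_to_string(g))` has the
#' same truth table as `g`. `or` children of an `and` node are
#' parenthesised; redundant parentheses are dropped.
#'
#' @param gpr a `gpr` object
#' @return a GPR string ("" for the empty rule)
#' @export
gpr_to_string <- function(gpr) {
  if (gpr_is_empty(gpr)) return("")
  render <- function(node, parent_op = NULL) {
    if (node$op == "gene") return(node$gene)
    sep <- if (node$op == "and") " and " else " or "
    s <- paste(vapply(node$args, render, character(1), parent_op = node$op),
               collapse = sep)
    if (node$op == "or" && identical(parent_op, "and")) paste0("(", s, ")") else s
  }
  render(gpr)
}

#' @export
print.gpr <- function(x, ...) {
  if (gpr_is_empty(x)) cat("<gpr: no gene association>\n")
  else cat("<gpr> ", gpr_to_string(x), "\n", sep = "")
  invisible(x)
}
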