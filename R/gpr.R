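#' Gene-protein-reaction (GPR) rules
#'
#' A GPR rule is a boolean expression over gene identifiers with `and`, `or`
#' and parentheses (case-insensitive keywords), describing which gene
#' products enable a reaction: `and` models enzyme complexes (all subunits
#' required), `or` models isozymes (any suffices). [parse_gpr()] builds a
#' parse tree with the usual precedence (`and` binds tighter than `or`);
#' [evaluate_gpr()] maps trilean gene states (-1 low, 0 moderate, +1 high)
#' to a reaction state with `and` = minimum and `or` = maximum, the standard
#' convention for expression-state propagation; [gpr_to_text()] serializes a
#' tree back to text so that parse -> deparse -> parse is the identity.
#'
#' Associative chains are flattened (`a or b or c` is one `or` node with
#' three children), which makes the textual round trip exact.
#'
#' @param text a GPR rule; empty, `NA` or whitespace-only text yields the
#'   empty expression, which evaluates to 0 (no gene evidence).
#' @return `parse_gpr()` returns an object of class `gpr_expression`.
#' @examples
#' e <- parse_gpr("g1 or g2 and g3")
#' gpr_to_text(e)
#' evaluate_gpr(e, c(g1 = -1, g2 = 1, g3 = 1))
#' @export
parse_gpr <- function(text) {
  if (is.null(text) || length(text) == 0L || is.na(text) ||
      !nzchar(trimws(text))) {
    return(structure(list(type = "empty"), class = "gpr_expression"))
  }
  toks <- gpr_tokens(text)
  st <- new.env(parent = emptyenv())
  st$toks <- toks
  st$i <- 1L
  expr <- gpr_parse_or(st)
  if (st$i <= length(toks)) {
    stop("GPR parse error in '", text, "': unexpected token '",
         toks[st$i], "'", call. = FALSE)
  }
  structure(expr, class = "gpr_expression")
}

gpr_tokens <- function(text) {
  text <- gsub("([()])", " \\1 ", text)
  toks <- strsplit(trimws(text), "\\s+")[[1]]
  toks[nzchar(toks)]
}

gpr_peek <- function(st) {
  if (st$i > length(st$toks)) NA_character_ else st$toks[st$i]
}

gpr_parse_or <- function(st) {
  terms <- list(gpr_parse_and(st))
  while (!is.na(tok <- gpr_peek(st)) && tolower(tok) == "or") {
    st$i <- st$i + 1L
    terms <- c(terms, list(gpr_parse_and(st)))
  }
  gpr_node("or", terms)
}

gpr_parse_and <- function(st) {
  factors <- list(gpr_parse_factor(st))
  while (!is.na(tok <- gpr_peek(st)) && tolower(tok) == "and") {
    st$i <- st$i + 1L
    factors <- c(factors, list(gpr_parse_factor(st)))
  }
  gpr_node("and", factors)
}

gpr_parse_factor <- function(st) {
  tok <- gpr_peek(st)
  if (is.na(tok)) {
    stop("GPR parse error: dangling operator or empty group", call. = FALSE)
  }
  if (tok == "(") {
    st$i <- st$i + 1L
    e <- gpr_parse_or(st)
    if (is.na(gpr_peek(st)) || gpr_peek(st) != ")") {
      stop("GPR parse error: unbalanced parentheses", call. = FALSE)
    }
    st$i <- st$i + 1L
    return(e)
  }
  if (tok == ")" || tolower(tok) %in% c("and", "or")) {
    stop("GPR parse error: unexpected '", tok, "'", call. = FALSE)
  }
  st$i <- st$i + 1L
  list(type = "gene", gene = tok)
}

# n-ary node constructor; collapses single children and flattens nested
# nodes of the same type so trees are canonical.
gpr_node <- function(type, children) {
  if (length(children) == 1L) return(children[[1L]])
  flat <- list()
  for (ch in children) {
    if (identical(ch$type, type)) flat <- c(flat, ch$children)
    else flat <- c(flat, list(ch))
  }
  list(type = type, children = flat)
}

#' @rdname parse_gpr
#' @param expr a `gpr_expression`.
#' @export
gpr_to_text <- function(expr) {
  deparse_node <- function(node, parent) {
    switch(node$type,
      empty = "",
      gene = node$gene,
      and = ,
      or = {
        txt <- paste(vapply(node$children, deparse_node, "",
                            parent = node$type),
                     collapse = paste0(" ", node$type, " "))
        # an `or` inside an `and` needs parentheses; anything else does not
        if (node$type == "or" && identical(parent, "and")) {
          paste0("(", txt, ")")
        } else {
          txt
        }
      },
      stop("unknown GPR node type: ", node$type))
  }
  deparse_node(unclass(expr), parent = NA_character_)
}

#' @rdname parse_gpr
#' @param gene_states named numeric/integer vector of trilean gene states in
#'   `{-1, 0, 1}`; genes absent from the map evaluate as 0 (moderate), so
#'   model genes missing from the expression table never force an activity
#'   claim.
#' @export
evaluate_gpr <- function(expr, gene_states) {
  if (length(gene_states) &&
      !all(gene_states %in% c(-1L, 0L, 1L))) {
    stop("gene states must be in {-1, 0, 1}", call. = FALSE)
  }
  eval_node <- function(node) {
    switch(node$type,
      empty = 0L,
      gene = {
        v <- gene_states[node$gene]
        if (is.na(v)) 0L else as.integer(v)
      },
      and = min(vapply(node$children, eval_node, 0L)),
      or = max(vapply(node$children, eval_node, 0L)),
      stop("unknown GPR node type: ", node$type))
  }
  eval_node(unclass(expr))
}

#' @rdname parse_gpr
#' @export
gpr_genes <- function(expr) {
  collect <- function(node) {
    switch(node$type,
      empty = character(),
      gene = node$gene,
      unique(unlist(lapply(node$children, collect))))
  }
  collect(unclass(expr))
}

#' @export
print.gpr_expression <- function(x, ...) {
  txt <- gpr_to_text(x)
  cat("<GPR> ", if (nzchar(txt)) txt else "(empty)", "\n", sep = "")
  invisible(x)
}
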