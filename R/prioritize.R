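RULE_FLAGS <- c("root_specific", "root_enriched", "periderm_enriched",
                "meja_up", "subfamily_of_known_regulators")

# recursive-descent parser for the evidence-rule grammar:
#   expr   := term ('OR' term)*
#   term   := factor ('AND' factor)*
#   factor := flag | '(' expr ')'
# No negation, so nominations are monotone in the flags.

ruleTokens <- function(rule) {
  pat <- "\\(|\\)|[A-Za-z_]+"
  m <- gregexpr(pat, rule)[[1L]]
  if (m[1L] == -1L) stop("rule config error at position 1: empty rule")
  toks <- regmatches(rule, gregexpr(pat, rule))[[1L]]
  pos <- as.integer(m)
  # anything not matched (besides whitespace) is an error
  covered <- unlist(mapply(function(p, l) p:(p + l - 1L), pos,
                           attr(m, "match.length"), SIMPLIFY = FALSE))
  stray <- setdiff(which(strsplit(rule, "")[[1L]] != " "), covered)
  if (length(stray))
    stop("rule config error at position ", stray[1L], ": unexpected '",
         substr(rule, stray[1L], stray[1L]), "'")
  list(tokens = toks, pos = pos)
}

#' Parse a candidate-nomination rule
#'
#' The rule is a boolean expression over the evidence flags
#' `root_specific`, `root_enriched`, `periderm_enriched`, `meja_up`,
#' `subfamily_of_known_regulators`, combined with `AND`, `OR` and
#' parentheses (no negation).  Malformed rules raise a config error naming
#' the offending position.
#'
#' @param rule rule string.
#' @return a parse tree (nested lists), suitable for [formatRule()] and
#'   [evaluateRule()].
#' @examples
#' r <- parseRule("(meja_up AND root_enriched) OR root_specific")
#' formatRule(r)
#' @export
parseRule <- function(rule) {
  tk <- ruleTokens(rule)
  toks <- tk$tokens; pos <- tk$pos
  i <- 1L
  peek <- function() if (i <= length(toks)) toks[i] else NA_character_
  take <- function() { t <- toks[i]; i <<- i + 1L; t }
  err <- function(msg) {
    p <- if (i <= length(pos)) pos[i] else nchar(rule) + 1L
    stop("rule config error at position ", p, ": ", msg)
  }
  factor_ <- function() {
    t <- peek()
    if (is.na(t)) err("unexpected end of rule")
    if (t == "(") {
      take()
      e <- expr_()
      if (!identical(peek(), ")")) err("expected ')'")
      take()
      return(e)
    }
    if (t %in% c(")", "AND", "OR")) err(paste0("unexpected '", t, "'"))
    if (!t %in% RULE_FLAGS) err(paste0("unknown flag '", t, "'"))
    take()
    list(op = "flag", name = t)
  }
  term_ <- function() {
    left <- factor_()
    while (identical(peek(), "AND")) {
      take()
      left <- list(op = "and", args = list(left, factor_()))
    }
    left
  }
  expr_ <- function() {
    left <- term_()
    while (identical(peek(), "OR")) {
      take()
      left <- list(op = "or", args = list(left, term_()))
    }
    left
  }
  out <- expr_()
  if (!is.na(peek())) err(paste0("unexpected '", peek(), "'"))
  out
}

#' @rdname parseRule
#' @param tree a parse tree from `parseRule`.
#' @export
formatRule <- function(tree) {
  fmt <- function(node, parentOp) {
    if (node$op == "flag") return(node$name)
    sep <- if (node$op == "and") " AND " else " OR "
    s <- paste(vapply(node$args, fmt, character(1), parentOp = node$op),
               collapse = sep)
    # parenthesise OR under AND to preserve precedence
    if (node$op == "or" && identical(parentOp, "and"))
      s <- paste0("(", s, ")")
    s
  }
  fmt(tree, NA_character_)
}

#' @rdname parseRule
#' @param flags named logical vector (or one-row data.frame slice) giving
#'   each evidence flag for one gene.
#' @export
evaluateRule <- function(tree, flags) {
  ev <- function(node) {
    switch(node$op,
           flag = isTRUE(as.logical(flags[[node$name]])),
           and = all(vapply(node$args, ev, logical(1))),
           or = any(vapply(node$args, ev, logical(1))))
  }
  ev(tree)
}

DEFAULT_RULE <- paste("(meja_up AND root_enriched)",
                      "OR (root_specific AND periderm_enriched)",
                      "OR (meja_up AND subfamily_of_known_regulators)")

#' Nominate candidate regulator genes
#'
#' Intersects the evidence streams: per member, boolean flags for root
#' specificity, root enrichment (vs the other organs), periderm enrichment
#' (vs the other root tissues), MeJA up-regulation, and membership of a
#' subfamily containing known regulators.  The configurable `rule` decides
#' nomination; the default is
#' `(meja_up AND root_enriched) OR (root_specific AND periderm_enriched)
#' OR (meja_up AND subfamily_of_known_regulators)`.
#'
#' @param members member table from [identifyFamily()].
#' @param specificity data.frame from [detectionAndSpecificity()] over the
#'   organ group (gene ids).
#' @param rootEnriched,peridermEnriched,mejaUp character vectors of gene
#'   ids passing the respective filters.
#' @param subfamilies named character vector: member name -> subfamily.
#' @param regulatorSubfamilies subfamily labels holding known regulators
#'   (default none).
#' @param rule rule string (default above).
#' @return data.frame with one row per member: the five flags, the
#'   evidence count, `nominated`, `subfamily`; sorted by evidence count
#'   (desc) then name.
#' @export
nominate <- function(members, specificity, rootEnriched, peridermEnriched,
                     mejaUp, subfamilies,
                     regulatorSubfamilies = character(0),
                     rule = DEFAULT_RULE) {
  tree <- parseRule(rule)
  sp <- stats::setNames(specificity$specific_to, specificity$gene_id)
  df <- data.frame(
    name = members$name,
    gene_id = members$gene_id,
    subfamily = unname(subfamilies[members$name]),
    root_specific = !is.na(sp[members$gene_id]) &
      sp[members$gene_id] == "root",
    root_enriched = members$gene_id %in% rootEnriched,
    periderm_enriched = members$gene_id %in% peridermEnriched,
    meja_up = members$gene_id %in% mejaUp,
    row.names = NULL)
  df$subfamily_of_known_regulators <- df$subfamily %in% regulatorSubfamilies
  df$evidence_count <- rowSums(df[, c("root_specific", "root_enriched",
                                      "periderm_enriched", "meja_up")])
  df$nominated <- vapply(seq_len(nrow(df)), function(i)
    evaluateRule(tree, df[i, ]), logical(1))
  df[order(-df$evidence_count, df$name), , drop = FALSE]
}
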