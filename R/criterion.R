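# Significance criteria: boolean expressions over per-gene statistics, e.g.
# "(log2FC < -0.58 OR log2FC > 0.58) AND pvalue < 0.05".

CRITERION_VARS <- c("log2FC", "pvalue")

#' Parse a significance criterion
#'
#' A criterion is a boolean expression over the per-gene variables `log2FC`
#' and `pvalue` with comparison operators `<`, `>`, `<=`, `>=`, `=`, the
#' logical connectives `AND`, `OR`, `NOT` (case-insensitive), and
#' parentheses. Comparisons are evaluated exactly as written — strict
#' operators stay strict, so a gene sitting exactly on a threshold is not
#' selected by a strict inequality.
#'
#' @param text criterion string.
#' @return An object of class `criterion` holding the parsed expression.
#' @export
parse_criterion <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  token_re <- paste0(
    "^(\\s+",                                  # whitespace
    "|[A-Za-z][A-Za-z0-9_]*",                  # identifier / keyword
    "|[0-9]+\\.?[0-9]*([eE][+-]?[0-9]+)?",     # number
    "|\\.[0-9]+([eE][+-]?[0-9]+)?",
    "|<=|>=|<|>|=",
    "|\\(|\\)|-|\\+)")
  rest <- text
  pos <- 1L
  out <- character()
  while (nzchar(rest)) {
    m <- regmatches(rest, regexpr(token_re, rest))
    if (!length(m) || !nzchar(m))
      stop(sprintf("criterion syntax error at position %d: %s", pos,
                   substr(rest, 1, 10)), call. = FALSE)
    tok <- m
    if (!grepl("^\\s+$", tok)) {
      if (grepl("^[A-Za-z]", tok)) {
        up <- toupper(tok)
        if (up == "AND") tok <- "&"
        else if (up == "OR") tok <- "|"
        else if (up == "NOT") tok <- "!"
        else if (!(tok %in% CRITERION_VARS))
          stop(sprintf("criterion validation error: unknown variable \"%s\" at position %d (allowed: %s)",
                       tok, pos, paste(CRITERION_VARS, collapse = ", ")),
               call. = FALSE)
      } else if (tok == "=") tok <- "=="
      out <- c(out, tok)
    }
    pos <- pos + nchar(m)
    rest <- substr(rest, nchar(m) + 1L, nchar(rest))
  }
  if (!length(out))
    stop("criterion syntax error: empty expression", call. = FALSE)
  expr <- tryCatch(str2lang(paste(out, collapse = " ")),
                   error = function(e)
                     stop("criterion syntax error: ", conditionMessage(e),
                          call. = FALSE))
  structure(list(text = text, expr = expr), class = "criterion")
}

#' @export
print.criterion <- function(x, ...) {
  cat("criterion:", x$text, "\n")
  invisible(x)
}

as_criterion <- function(x) {
  if (inherits(x, "criterion")) x else parse_criterion(x)
}

#' Evaluate a criterion over a gene statistics table
#'
#' @param criterion a [parse_criterion()] object or a criterion string.
#' @param table a `gene_stat_table` (see [map_and_merge()]) or any data frame
#'   with columns `gene_id`, `log2fc`, `pvalue`.
#' @return Character vector of the gene ids satisfying the criterion. Genes
#'   with missing statistics never satisfy any criterion.
#' @export
evaluate_criterion <- function(criterion, table) {
  criterion <- as_criterion(criterion)
  if (!nrow(table)) return(character())
  env <- list2env(list(log2FC = table$log2fc, pvalue = table$pvalue),
                  parent = baseenv())
  val <- eval(criterion$expr, env)
  if (!is.logical(val))
    stop("criterion validation error: expression is not boolean-valued",
         call. = FALSE)
  val <- rep_len(val, nrow(table))
  val[is.na(val)] <- FALSE
  table$gene_id[val]
}
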