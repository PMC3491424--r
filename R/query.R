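#' Query expressions
#'
#' The query algebra over keyword documents: `Term` (exact word), `Prefix`
#' (trailing `*`), `Range` (`low--high`, inclusive at word granularity),
#' `And` (whitespace), `Or` (`|`, binding tighter than And), and `GeneMatch`
#' (`@gene(...)`) whose sub-expression runs over the gene documents and may
#' additionally use a substring atom `~text` matching any annotation term
#' containing that text.  `q_*` constructors build expression trees directly;
#' [parse_query()] builds them from query strings.
#'
#' @param word,prefix,lo,hi,text Atom payloads.
#' @param exprs A list of sub-expressions.
#' @param expr A sub-expression over gene documents (GeneMatch never nests).
#' @return A `query_expr` tree.
#' @name query_expr
NULL

q_node <- function(type, ...) {
  structure(list(type = type, ...), class = "query_expr")
}

#' @rdname query_expr
#' @export
q_term <- function(word) q_node("term", word = word)

#' @rdname query_expr
#' @export
q_prefix <- function(prefix) q_node("prefix", prefix = prefix)

#' @rdname query_expr
#' @export
q_range <- function(lo, hi) {
  if (!str_le_c(lo, hi)) stop("range low endpoint must be <= high: ",
                              lo, " -- ", hi)
  q_node("range", lo = lo, hi = hi)
}

#' @rdname query_expr
#' @export
q_substr <- function(text) q_node("substr", text = text)

#' @rdname query_expr
#' @export
q_and <- function(exprs) q_node("and", args = exprs)

#' @rdname query_expr
#' @export
q_or <- function(exprs) q_node("or", args = exprs)

#' @rdname query_expr
#' @export
q_gene <- function(expr) {
  if (has_gene_atom(expr)) stop("@gene(...) cannot nest")
  q_node("gene", expr = expr)
}

has_gene_atom <- function(expr) {
  if (expr$type == "gene") return(TRUE)
  if (expr$type %in% c("and", "or")) {
    return(any(vapply(expr$args, has_gene_atom, logical(1))))
  }
  FALSE
}

# Byte-order (C locale) string comparison, independent of session locale.
str_le_c <- function(a, b) {
  if (a == b) return(TRUE)
  identical(sort(c(a, b), method = "radix")[1], a)
}

word_pattern <- "^[A-Za-z0-9_.]+(:[A-Za-z0-9_.]+)*$"

check_query_word <- function(word, what = "word") {
  if (!grepl(word_pattern, word)) {
    stop("malformed ", what, " in query: '", word, "'")
  }
  word
}

#' Parse a query string
#'
#' Grammar: whitespace-separated atoms combine by And; `|`-separated
#' alternatives inside an atom combine by Or (binding tighter than And);
#' `low--high` is a Range over the closed lexicographic word interval (both
#' endpoints must share the attribute path before the final component);
#' a trailing `*` makes a Prefix; `@gene(<sub-query>)` restricts to regions
#' linked to a gene whose document matches the sub-query, inside which
#' `~text` matches any gene whose annotation terms contain `text`.
#'
#' @param text Query string, e.g.
#'   `"overlap:CGI dnaseq:freq:CG:010--dnaseq:freq:CG:050"`.
#' @return A `query_expr`.
#' @examples
#' parse_query("overlap:CGI overlap:H3K4me3")
#' parse_query("dnameth:ES:ratio:00--dnameth:ES:ratio:33|dnameth:ES:ratio:66--dnameth:ES:ratio:99")
#' parse_query("@gene(~regulation)")
#' @export
parse_query <- function(text) {
  tokens <- tokenize_query(text)
  if (length(tokens) == 0) stop("empty query")
  exprs <- lapply(tokens, parse_token, gene_context = FALSE)
  if (length(exprs) == 1) exprs[[1]] else q_and(exprs)
}

# Split on whitespace, keeping @gene(...) groups (which may contain spaces)
# as single tokens.
tokenize_query <- function(text) {
  tokens <- character(0)
  i <- 1
  n <- nchar(text)
  while (i <= n) {
    ch <- substr(text, i, i)
    if (grepl("^\\s$", ch)) { i <- i + 1; next }
    rest <- substring(text, i)
    if (startsWith(rest, "@gene(")) {
      depth <- 0
      j <- i + 5   # position of '('
      close <- NA
      while (j <= n) {
        cj <- substr(text, j, j)
        if (cj == "(") depth <- depth + 1
        if (cj == ")") {
          depth <- depth - 1
          if (depth == 0) { close <- j; break }
        }
        j <- j + 1
      }
      if (is.na(close)) stop("unbalanced parenthesis in @gene(...)")
      tokens <- c(tokens, substr(text, i, close))
      i <- close + 1
    } else {
      m <- regexpr("\\s", rest)
      end <- if (m == -1) n else i + m - 2
      tokens <- c(tokens, substr(text, i, end))
      i <- end + 1
    }
  }
  tokens
}

parse_token <- function(tok, gene_context) {
  if (startsWith(tok, "@gene(")) {
    if (gene_context) stop("@gene(...) cannot nest")
    inner <- substr(tok, 7, nchar(tok) - 1)
    sub_tokens <- tokenize_query(inner)
    if (length(sub_tokens) == 0) stop("empty @gene(...) sub-query")
    exprs <- lapply(sub_tokens, parse_token, gene_context = TRUE)
    return(q_gene(if (length(exprs) == 1) exprs[[1]] else q_and(exprs)))
  }
  alts <- strsplit(tok, "|", fixed = TRUE)[[1]]
  if (length(alts) == 0 || any(!nzchar(alts)) ||
      startsWith(tok, "|") || endsWith(tok, "|")) {
    stop("empty alternative in query token '", tok, "'")
  }
  exprs <- lapply(alts, parse_atom, gene_context = gene_context)
  if (length(exprs) == 1) exprs[[1]] else q_or(exprs)
}

parse_atom <- function(a, gene_context) {
  if (startsWith(a, "~")) {
    if (!gene_context) {
      stop("substring atom '", a, "' is only valid inside @gene(...)")
    }
    s <- substring(a, 2)
    if (!nzchar(s)) stop("empty substring atom")
    return(q_substr(tolower(s)))
  }
  if (grepl("--", a, fixed = TRUE)) {
    ends <- strsplit(a, "--", fixed = TRUE)[[1]]
    if (length(ends) != 2 || any(!nzchar(ends))) {
      stop("malformed range atom '", a, "'")
    }
    check_query_word(ends[1], "range endpoint")
    check_query_word(ends[2], "range endpoint")
    p1 <- sub(":[^:]*$", "", ends[1])
    p2 <- sub(":[^:]*$", "", ends[2])
    if (p1 != p2) {
      stop("range endpoints have mismatched attribute paths: '", a, "'")
    }
    if (!str_le_c(ends[1], ends[2])) {
      stop("range low endpoint exceeds high endpoint: '", a, "'")
    }
    return(q_range(ends[1], ends[2]))
  }
  if (grepl("*", a, fixed = TRUE)) {
    p <- substr(a, 1, nchar(a) - 1)
    if (!endsWith(a, "*") || !nzchar(p) ||
        !grepl("^[A-Za-z0-9_.:]+$", p)) {
      stop("malformed prefix atom '", a, "'")
    }
    return(q_prefix(p))
  }
  q_term(check_query_word(a, "term"))
}

#' Render a query expression back to its string form
#' @param expr A `query_expr`.
#' @return A query string that re-parses to an equivalent expression.
#' @export
deparse_query <- function(expr) {
  switch(expr$type,
    term = expr$word,
    prefix = paste0(expr$prefix, "*"),
    range = paste0(expr$lo, "--", expr$hi),
    substr = paste0("~", expr$text),
    gene = paste0("@gene(", deparse_query(expr$expr), ")"),
    and = paste(vapply(expr$args, deparse_query, character(1)),
                collapse = " "),
    or = paste(vapply(expr$args, deparse_query, character(1)),
               collapse = "|"),
    stop("unknown expression type ", expr$type)
  )
}

#' @export
print.query_expr <- function(x, ...) {
  cat("<query_expr>", deparse_query(x), "\n")
  invisible(x)
}
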