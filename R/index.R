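#' Build a search index over region and gene documents
#'
#' An in-process word -> document index with a lexicographically sorted
#' dictionary (byte order) and sorted, duplicate-free posting lists, kept in
#' two namespaces: region documents and gene documents.  Prefix and range
#' queries resolve to contiguous dictionary slices; the index is a pure
#' function of the document multiset, so insertion order does not matter.
#'
#' @param region_docs A `document_set` of region documents.
#' @param gene_docs Optional `document_set` of gene documents (ids must carry
#'   the `gene:` prefix).
#' @return An object of class `search_index`.
#' @export
build_search_index <- function(region_docs, gene_docs = NULL) {
  stopifnot(inherits(region_docs, "document_set"))
  if (length(region_docs) > 0) {
    if (anyDuplicated(names(region_docs))) stop("duplicate region doc_id")
    if (any(startsWith(names(region_docs), "gene:"))) {
      stop("region doc ids must not use the reserved 'gene:' prefix")
    }
  }
  gene_ids <- character(0)
  gene_side <- index_side(structure(list(), class = "document_set"))
  if (!is.null(gene_docs)) {
    stopifnot(inherits(gene_docs, "document_set"))
    if (anyDuplicated(names(gene_docs))) stop("duplicate gene doc_id")
    if (!all(startsWith(names(gene_docs), "gene:"))) {
      stop("gene doc ids must start with 'gene:'")
    }
    gene_ids <- sort(names(gene_docs), method = "radix")
    gene_side <- index_side(gene_docs)
  }
  region_ids <- if (length(region_docs) == 0) character(0) else {
    sort(names(region_docs), method = "radix")
  }
  structure(list(
    region = index_side(region_docs),
    gene = gene_side,
    region_ids = region_ids,
    gene_ids = gene_ids
  ), class = "search_index")
}

index_side <- function(docs) {
  if (length(docs) == 0) {
    return(list(dict = character(0), postings = list()))
  }
  word <- unlist(docs, use.names = FALSE)
  if (is.null(word)) word <- character(0)
  doc <- rep(names(docs), lengths(docs))
  dict <- sort(unique(word), method = "radix")
  postings <- lapply(split(doc, factor(word, levels = dict)),
                     function(d) sort(unique(d), method = "radix"))
  list(dict = dict, postings = postings)
}

#' @export
print.search_index <- function(x, ...) {
  cat(sprintf(paste0("<search_index> %d region doc(s) / %d word(s); ",
                     "%d gene doc(s) / %d word(s)\n"),
              length(x$region_ids), length(x$region$dict),
              length(x$gene_ids), length(x$gene$dict)))
  invisible(x)
}

# Dictionary slice for the closed byte-order interval [lo, hi].
dict_slice <- function(dict, lo, hi) {
  if (length(dict) == 0) return(character(0))
  u <- sort(unique(c(dict, lo, hi)), method = "radix")
  r <- match(dict, u)
  dict[r >= match(lo, u) & r <= match(hi, u)]
}

side_postings <- function(side, words) {
  present <- words[words %in% side$dict]
  if (length(present) == 0) return(character(0))
  sort(unique(unlist(side$postings[present], use.names = FALSE)),
       method = "radix")
}

eval_gene_side <- function(index, expr) {
  side <- index$gene
  switch(expr$type,
    term = side_postings(side, expr$word),
    prefix = side_postings(side,
                           side$dict[startsWith(side$dict, expr$prefix)]),
    range = side_postings(side, dict_slice(side$dict, expr$lo, expr$hi)),
    substr = side_postings(side, side$dict[
      startsWith(side$dict, "geneannot:") &
        grepl(expr$text, side$dict, fixed = TRUE)]),
    and = Reduce(intersect, lapply(expr$args,
                                   function(e) eval_gene_side(index, e)),
                 accumulate = FALSE),
    or = sort(unique(unlist(lapply(expr$args,
                                   function(e) eval_gene_side(index, e)))),
              method = "radix"),
    gene = stop("@gene(...) cannot nest"),
    stop("unknown expression type ", expr$type)
  )
}

eval_region_side <- function(index, expr) {
  side <- index$region
  switch(expr$type,
    term = side_postings(side, expr$word),
    prefix = side_postings(side,
                           side$dict[startsWith(side$dict, expr$prefix)]),
    range = side_postings(side, dict_slice(side$dict, expr$lo, expr$hi)),
    and = Reduce(intersect, lapply(expr$args,
                                   function(e) eval_region_side(index, e)),
                 accumulate = FALSE),
    or = sort(unique(unlist(lapply(expr$args,
                                   function(e) eval_region_side(index, e)))),
              method = "radix"),
    gene = side_postings(side, eval_gene_side(index, expr$expr)),
    substr = stop("substring atoms are only valid inside @gene(...)"),
    stop("unknown expression type ", expr$type)
  )
}

#' Evaluate a query against an index
#'
#' Terms return their posting list; prefixes and ranges the union over the
#' matching dictionary slice; And intersects; Or unions; `@gene(...)` returns
#' the regions carrying a `gene:<id>` word for any gene document matched by
#' the sub-expression.  A word absent from the dictionary yields the empty
#' set, not an error.  When `base` is given the result is intersected with it
#' (iterative refinement).
#'
#' @param index A [build_search_index()] object.
#' @param expr A `query_expr` (see [parse_query()]) or a query string.
#' @param base Optional character vector of region doc ids to refine.
#' @return Sorted character vector of matching region doc ids.
#' @export
evaluate <- function(index, expr, base = NULL) {
  stopifnot(inherits(index, "search_index"))
  if (is.character(expr)) expr <- parse_query(expr)
  res <- eval_region_side(index, expr)
  if (!is.null(base)) res <- intersect(res, base)
  sort(res, method = "radix")
}

#' Prefix completion with per-completion region counts
#'
#' Lists all dictionary words extending a prefix together with the number of
#' (base) regions matching each completion — the backend of percent-overlap
#' summaries.  With `rollup_level = k` completions are grouped by the next
#' `k` path components below the prefix and each group counts the regions
#' matching the grouped sub-prefix (union semantics: a region counts once per
#' group).  Zero-count entries are omitted.
#'
#' @param index A `search_index`.
#' @param prefix Non-empty word prefix; a trailing `*` is accepted and
#'   stripped.
#' @param base Optional region doc id subset.
#' @param rollup_level Optional positive integer.
#' @return An object of class `completion_result`: a list with `entries`
#'   (data.frame `word`, `count`) and `total` (regions matching the prefix
#'   itself).
#' @export
complete_prefix <- function(index, prefix, base = NULL, rollup_level = NULL) {
  stopifnot(inherits(index, "search_index"))
  prefix <- sub("\\*$", "", prefix)
  if (!nzchar(prefix)) stop("empty prefix")
  side <- index$region
  words <- side$dict[startsWith(side$dict, prefix)]
  count_docs <- function(ws) {
    docs <- side_postings(side, ws)
    if (!is.null(base)) docs <- intersect(docs, base)
    length(docs)
  }
  total <- count_docs(words)
  if (is.null(rollup_level)) {
    counts <- vapply(words, function(w) count_docs(w), integer(1))
    entries <- data.frame(word = words, count = unname(counts),
                          stringsAsFactors = FALSE)
  } else {
    stopifnot(rollup_level >= 1)
    n0 <- lengths(regmatches(prefix, gregexpr(":", prefix, fixed = TRUE)))
    depth <- n0 + rollup_level
    keys <- vapply(strsplit(words, ":", fixed = TRUE), function(cs) {
      paste(cs[seq_len(min(depth, length(cs)))], collapse = ":")
    }, character(1))
    groups <- split(words, keys)
    counts <- vapply(groups, count_docs, integer(1))
    entries <- data.frame(word = names(groups), count = unname(counts),
                          stringsAsFactors = FALSE)
  }
  entries <- entries[entries$count > 0, , drop = FALSE]
  entries <- entries[order(entries$word, method = "radix"), , drop = FALSE]
  rownames(entries) <- NULL
  structure(list(prefix = prefix, entries = entries, total = total,
                 rollup_level = rollup_level),
            class = "completion_result")
}

#' @export
print.completion_result <- function(x, ...) {
  cat(sprintf("<completion_result> %s* : %d completion(s), %d region(s)\n",
              x$prefix, nrow(x$entries), x$total))
  if (nrow(x$entries)) print(x$entries, row.names = FALSE)
  invisible(x)
}

#' Histogram of a numeric attribute via prefix completion
#'
#' Retrieves the distribution of an encoded numeric attribute with a single
#' prefix query over its bin keywords — the engine behind area-chart
#' histograms.
#'
#' @param index A `search_index`.
#' @param codec The attribute's [numeric_codec()].
#' @param base Optional region doc id subset.
#' @return Data.frame `code`, `lo`, `hi`, `count` (one row per occupied bin);
#'   counts sum to the number of (base) regions carrying the attribute.
#' @export
histogram_via_completion <- function(index, codec, base = NULL) {
  comp <- complete_prefix(index, paste0(codec$path, ":"), base = base)
  e <- comp$entries
  tails <- substring(e$word, nchar(codec$path) + 2)
  keep <- grepl(sprintf("^[0-9]{%d}$", codec$width), tails)
  e <- e[keep, , drop = FALSE]
  code <- as.integer(tails[keep])
  out <- data.frame(code = code, lo = code / codec$scale,
                    hi = (code + 1) / codec$scale, count = e$count,
                    stringsAsFactors = FALSE)
  out[order(out$code), , drop = FALSE]
}

#' Serialize / reload a search index
#'
#' The index is stored as its canonical document dump (see
#' [write_documents()]): one sorted line per document, region and gene
#' documents mixed, gene documents identified by their `gene:` id prefix.
#' Rebuilding from the dump reproduces the index exactly, and the dump is a
#' pure function of the document multiset.
#'
#' @param index A `search_index`.
#' @param path File path.
#' @export
write_search_index <- function(index, path) {
  docs <- index_documents(index)
  ids <- c(index$region_ids, index$gene_ids)
  write_documents(structure(docs[ids], class = "document_set", names = ids),
                  path)
}

#' @rdname write_search_index
#' @export
read_search_index <- function(path) {
  docs <- read_documents(path)
  is_gene <- startsWith(names(docs), "gene:")
  region_docs <- structure(docs[!is_gene], class = "document_set")
  gene_docs <- if (any(is_gene)) {
    structure(docs[is_gene], class = "document_set")
  } else NULL
  build_search_index(region_docs, gene_docs)
}

# Reconstruct id -> words from the posting lists.
index_documents <- function(index) {
  docs <- rep(list(character(0)),
              length(index$region_ids) + length(index$gene_ids))
  names(docs) <- c(index$region_ids, index$gene_ids)
  for (side in list(index$region, index$gene)) {
    for (k in seq_along(side$dict)) {
      w <- side$dict[k]
      for (d in side$postings[[k]]) docs[[d]] <- c(docs[[d]], w)
    }
  }
  lapply(docs, sort, method = "radix")
}
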