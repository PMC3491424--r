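#' Serializable filter chains
#'
#' An ordered list of labelled query steps.  Running a chain against an index
#' produces nested region subsets `S0 >= S1 >= ... >= Sk` (each step
#' evaluates with the previous step's result as base, so cardinalities are
#' monotone non-increasing) together with a per-step survivor ledger — the
#' reproducible form of an iterative refinement session.
#'
#' @param labels Character vector of step labels.
#' @param queries Character vector of query strings (parsed eagerly, so a
#'   malformed step fails at construction naming the step).
#' @return An object of class `filter_chain`.
#' @export
filter_chain <- function(labels, queries) {
  stopifnot(length(labels) == length(queries), length(labels) >= 1)
  for (i in seq_along(queries)) {
    tryCatch(parse_query(queries[i]), error = function(e) {
      stop("filter chain step ", i, " ('", labels[i], "') does not parse: ",
           conditionMessage(e), call. = FALSE)
    })
  }
  structure(data.frame(label = labels, query = queries,
                       stringsAsFactors = FALSE),
            class = c("filter_chain", "data.frame"))
}

#' Run a filter chain
#'
#' @param index A `search_index`.
#' @param chain A [filter_chain()].
#' @param base Optional starting set (defaults to all region documents).
#' @return List with `ledger` (data.frame `step`, `label`, `query`, `n`;
#'   step 0 is the starting set) and `final` (the surviving doc ids, ready
#'   for export via [write_bed()]).
#' @export
run_filter_chain <- function(index, chain, base = NULL) {
  stopifnot(inherits(chain, "filter_chain"))
  current <- if (is.null(base)) index$region_ids else {
    sort(base, method = "radix")
  }
  ledger <- data.frame(step = 0L, label = "all", query = "",
                       n = length(current), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(chain))) {
    expr <- tryCatch(parse_query(chain$query[i]), error = function(e) {
      stop("filter chain step ", i, " failed to parse: ",
           conditionMessage(e), call. = FALSE)
    })
    current <- evaluate(index, expr, base = current)
    ledger <- rbind(ledger, data.frame(step = i, label = chain$label[i],
                                       query = chain$query[i],
                                       n = length(current),
                                       stringsAsFactors = FALSE))
  }
  list(ledger = ledger, final = current)
}

#' Read / write a filter chain config file
#'
#' Flat tab-separated format `label<TAB>query`, one step per line, so a
#' refinement session can be stored, shared and replayed exactly.
#'
#' @param chain A [filter_chain()].
#' @param path File path.
#' @export
write_filter_chain <- function(chain, path) {
  writeLines(sprintf("%s\t%s", chain$label, chain$query), path)
  invisible(path)
}

#' @rdname write_filter_chain
#' @export
read_filter_chain <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 2
  if (any(bad)) stop("malformed filter chain line(s): ",
                     paste(which(bad), collapse = ", "))
  filter_chain(vapply(parts, `[`, character(1), 1),
               vapply(parts, function(p) paste(p[-1], collapse = "\t"),
                      character(1)))
}

#' Export the survivors of a filter run as BED
#'
#' @param set The annotated [region_set()] the index was built from.
#' @param doc_ids Character vector of surviving region doc ids.
#' @param path Output BED path.
#' @param ucsc_track_line Optional track label (see [write_bed()]).
#' @return `path`, invisibly.
#' @export
export_regions <- function(set, doc_ids, path, ucsc_track_line = NULL) {
  stopifnot(inherits(set, "region_set"))
  keep <- set$regions$region_id %in% doc_ids
  sub <- region_set(paste0(set$set_id, "_filtered"), set$assembly,
                    set$regions[keep, , drop = FALSE])
  write_bed(sub, path, ucsc_track_line = ucsc_track_line)
}
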