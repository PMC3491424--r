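#' Keyword builders
#'
#' Region annotations are expressed as hierarchical keywords.  Binary
#' (overlap) attributes use the `overlap:` prefix followed by the attribute
#' path; numeric attributes append a zero-padded bin code (see
#' [encode_numeric()]); gene links use `gene:<id>`.
#'
#' @param path A valid attribute path.
#' @return The keyword string.
#' @examples
#' encode_binary("CGI")                      # "overlap:CGI"
#' encode_binary("histones:H3K4me3:H1hESC")
#' @export
encode_binary <- function(path) {
  check_attribute_path(path)
  paste0("overlap:", path)
}

# Free-text components (gene ids): replace reserved characters, keep case.
sanitize_component <- function(x) {
  out <- gsub("[^A-Za-z0-9_.]+", "_", x)
  out <- gsub("^_+|_+$", "", out)
  out
}

#' Normalize an annotation term for keyword use
#'
#' Lower-cases and maps runs of non-alphanumeric characters to `_`, so
#' `"cell differentiation"` becomes `"cell_differentiation"`.  Original term
#' strings should be retained separately for display.
#'
#' @param term Character vector of raw terms.
#' @return Normalized terms.
#' @export
normalize_term <- function(term) {
  out <- tolower(term)
  out <- gsub("[^a-z0-9]+", "_", out)
  gsub("^_+|_+$", "", out)
}

#' Build keyword documents for every region of an annotated set
#'
#' Each region becomes a text document: a deduplicated set of keywords
#' covering its chromosome, length, optional score, every overlap flag and
#' overlap ratio, sequence-composition frequencies, methylation mean and
#' CpG count (absent when no position was measured), nearest-gene distance,
#' and one `gene:<id>` word per linked gene.
#'
#' @param ann A [region_annotations()] accumulator.
#' @param codecs A `codec_registry`; defaults to [auto_codecs()] over the
#'   accumulated attributes.  An attribute lacking a codec aborts (schema
#'   drift).
#' @return A named list of class `document_set`: `doc_id -> sorted character
#'   vector of words`.
#' @export
build_region_documents <- function(ann, codecs = auto_codecs(ann)) {
  stopifnot(inherits(ann, "region_annotations"))
  df <- ann$set$regions
  n <- nrow(df)
  need <- function(path) {
    cd <- codecs[[path]]
    if (is.null(cd)) stop("no codec registered for numeric attribute '",
                          path, "'")
    cd
  }
  docs <- vector("list", n)
  len_words <- encode_numeric(need("region:length"), df$end - df$start)
  for (i in seq_len(n)) {
    w <- c(paste0("region:chrom:", sanitize_component(df$chrom[i])),
           len_words[i])
    if (!is.na(df$score[i])) {
      w <- c(w, encode_numeric(need("region:score"), df$score[i]))
    }
    for (path in names(ann$overlaps)) {
      ov <- ann$overlaps[[path]]
      if (ov$flag[i]) w <- c(w, encode_binary(path))
      w <- c(w, encode_numeric(need(paste0("overlapratio:", path)),
                               ov$ratio[i]))
      for (lab in names(ov$categories)) {
        if (ov$categories[[lab]][i]) {
          w <- c(w, encode_binary(paste0(path, ":", lab)))
        }
      }
    }
    for (path in names(ann$methylation)) {
      me <- ann$methylation[[path]]
      if (me$count[i] > 0) {
        w <- c(w,
               encode_numeric(need(paste0(path, ":ratio")), me$mean_ratio[i]),
               encode_numeric(need(paste0(path, ":cov")), me$count[i]))
      }
    }
    if (!is.null(ann$seqcomp)) {
      w <- c(w,
             encode_numeric(need("dnaseq:freq:CG"), ann$seqcomp$cpg_freq[i]),
             encode_numeric(need("dnaseq:freq:GC"), ann$seqcomp$gc_freq[i]))
    }
    if (!is.null(ann$genes)) {
      for (g in ann$genes$links[[i]]) {
        w <- c(w, paste0("gene:", sanitize_component(g)))
      }
      if (!is.na(ann$genes$nearest[i])) {
        w <- c(w, encode_numeric(need("distance:genes"),
                                 ann$genes$nearest[i]))
      }
    }
    docs[[i]] <- sort(unique(w), method = "radix")
  }
  structure(stats::setNames(docs, df$region_id), class = "document_set")
}

#' Default codecs for the attributes present in an accumulator
#'
#' Builds a `codec_registry` covering every numeric attribute the
#' accumulator produced, using the standard codec templates (see
#' [codec_registry()] for the table).
#'
#' @param ann A [region_annotations()] accumulator.
#' @return A `codec_registry`.
#' @export
auto_codecs <- function(ann) {
  reg <- default_codec_registry()
  for (path in names(ann$overlaps)) {
    reg <- register_codec(reg, percent_codec(paste0("overlapratio:", path)))
  }
  for (path in names(ann$methylation)) {
    reg <- register_codec(reg, percent_codec(paste0(path, ":ratio")))
    reg <- register_codec(reg, count_codec(paste0(path, ":cov")))
  }
  reg
}

#' Build keyword documents for genes
#'
#' Genes and their lengthy textual annotations are kept as separate
#' documents: the document for gene `BRCA2` is named `gene:BRCA2` — exactly
#' the linking word stored in the documents of overlapping/nearby regions —
#' and contains one namespace-prefixed keyword per annotation term, e.g.
#' `geneannot:go:cell_differentiation`.
#'
#' @param genes A [gene_records()] object.
#' @return A `document_set` of gene documents (possibly with empty word
#'   sets; such genes remain joinable by id).
#' @export
build_gene_documents <- function(genes) {
  stopifnot(inherits(genes, "gene_records"))
  ids <- genes$genes$gene_id
  docs <- rep(list(character(0)), length(ids))
  names(docs) <- paste0("gene:", sanitize_component(ids))
  if (nrow(genes$terms) > 0) {
    norm <- normalize_term(genes$terms$term)
    keep <- nzchar(norm)
    words <- paste0("geneannot:", tolower(genes$terms$namespace[keep]), ":",
                    norm[keep])
    key <- paste0("gene:", sanitize_component(genes$terms$gene_id[keep]))
    sp <- split(words, key)
    for (k in names(sp)) docs[[k]] <- sort(unique(sp[[k]]), method = "radix")
  }
  structure(docs, class = "document_set")
}

#' Read / write a document dump
#'
#' One line per document: `doc_id<TAB>word word word...` with words sorted,
#' stable across runs for diffing.  A single dump may mix region and gene
#' documents; documents whose id starts with `gene:` belong to the gene
#' namespace.
#'
#' @param docs A `document_set`.
#' @param path File path.
#' @export
write_documents <- function(docs, path) {
  ids <- names(docs)
  lines <- vapply(seq_along(docs), function(i) {
    paste0(ids[i], "\t",
           paste(sort(unique(docs[[i]]), method = "radix"), collapse = " "))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_documents
#' @export
read_documents <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[`, character(1), 1)
  docs <- lapply(parts, function(p) {
    if (length(p) < 2 || !nzchar(p[2])) character(0)
    else strsplit(p[2], " ", fixed = TRUE)[[1]]
  })
  structure(stats::setNames(docs, ids), class = "document_set")
}

#' @export
print.document_set <- function(x, ...) {
  nw <- sum(lengths(x))
  cat(sprintf("<document_set> %d document(s), %d word occurrence(s)\n",
              length(x), nw))
  invisible(x)
}
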