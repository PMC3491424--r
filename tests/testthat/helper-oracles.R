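# Independent brute-force oracles and small fixture builders.  Everything
# here recomputes results from first principles (per-bp sets, all-pairs
# scans, per-document interpretation) so the package's interval/index code is
# never checked against itself.

toy_assembly <- function(lens = c(chrA = 100000, chrB = 60000)) {
  genome_assembly("toy", lens)
}

make_regions <- function(assembly, chrom, start, end, ...) {
  region_set("test", assembly,
             data.frame(chrom = chrom, start = start, end = end, ...,
                        stringsAsFactors = FALSE))
}

make_track <- function(assembly, chrom, start, end, path = "marks:A",
                       kind = "interval", ...) {
  annotation_track(path, kind,
                   data.frame(chrom = chrom, start = start, end = end, ...,
                              stringsAsFactors = FALSE),
                   assembly)
}

# per-bp set intersection
bf_overlap_bp <- function(a, b) {
  if (a$chrom != b$chrom) return(0L)
  length(intersect(seq(a$start, a$end - 1), seq(b$start, b$end - 1)))
}

# all-pairs minimum gap (half-open interval arithmetic)
bf_nearest <- function(region, iv_df) {
  sub <- iv_df[iv_df$chrom == region$chrom, , drop = FALSE]
  if (nrow(sub) == 0) return(NA_integer_)
  gaps <- vapply(seq_len(nrow(sub)), function(i) {
    if (sub$start[i] < region$end && region$start < sub$end[i]) return(0)
    max(sub$start[i] - region$end, region$start - sub$end[i])
  }, numeric(1))
  as.integer(min(gaps))
}

# boolean-mask union coverage
bf_coverage <- function(iv_df, assembly) {
  covered <- 0
  for (ch in names(assembly$chromosomes)) {
    sub <- iv_df[iv_df$chrom == ch, , drop = FALSE]
    if (nrow(sub) == 0) next
    mask <- logical(assembly$chromosomes[[ch]])
    for (i in seq_len(nrow(sub))) {
      mask[seq(sub$start[i] + 1, sub$end[i])] <- TRUE
    }
    covered <- covered + sum(mask)
  }
  covered / assembly$total_length
}

# per-bp count of region bases covered by the track union
bf_covered_bp <- function(region, iv_df) {
  sub <- iv_df[iv_df$chrom == region$chrom, , drop = FALSE]
  if (nrow(sub) == 0) return(0L)
  mask <- logical(region$end - region$start)
  for (i in seq_len(nrow(sub))) {
    lo <- max(sub$start[i], region$start)
    hi <- min(sub$end[i], region$end)
    if (hi > lo) mask[seq(lo - region$start + 1, hi - region$start)] <- TRUE
  }
  sum(mask)
}

# byte-order comparison, written independently of the package internals
bf_str_le <- function(a, b) {
  if (a == b) return(TRUE)
  ra <- utf8ToInt(a); rb <- utf8ToInt(b)
  n <- min(length(ra), length(rb))
  for (i in seq_len(n)) {
    if (ra[i] != rb[i]) return(ra[i] < rb[i])
  }
  length(ra) < length(rb)
}

# per-document query interpreter
bf_doc_matches <- function(words, expr, gene_docs = list()) {
  switch(expr$type,
    term = expr$word %in% words,
    prefix = any(startsWith(words, expr$prefix)),
    range = any(vapply(words, function(w) {
      bf_str_le(expr$lo, w) && bf_str_le(w, expr$hi)
    }, logical(1))),
    and = all(vapply(expr$args, function(e) {
      bf_doc_matches(words, e, gene_docs)
    }, logical(1))),
    or = any(vapply(expr$args, function(e) {
      bf_doc_matches(words, e, gene_docs)
    }, logical(1))),
    substr = any(startsWith(words, "geneannot:") &
                   grepl(expr$text, words, fixed = TRUE)),
    gene = {
      ok <- vapply(gene_docs, function(gw) {
        bf_doc_matches(gw, expr$expr, gene_docs)
      }, logical(1))
      any(names(gene_docs)[ok] %in% words)
    },
    genewords = any(expr$words %in% words),
    stop("unknown type")
  )
}

# pre-resolve gene sub-queries once per expression (pure speed-up; the
# per-gene-document interpretation is unchanged)
bf_resolve_genes <- function(expr, gene_docs) {
  if (expr$type == "gene") {
    ok <- vapply(gene_docs, function(gw) {
      bf_doc_matches(gw, expr$expr, gene_docs)
    }, logical(1))
    words <- if (length(gene_docs)) names(gene_docs)[ok] else character(0)
    list(type = "genewords", words = words)
  } else if (expr$type %in% c("and", "or")) {
    expr$args <- lapply(expr$args, bf_resolve_genes, gene_docs)
    expr
  } else {
    expr
  }
}

bf_evaluate <- function(region_docs, expr, gene_docs = list(), base = NULL) {
  expr <- bf_resolve_genes(expr, gene_docs)
  hits <- names(region_docs)[vapply(region_docs, bf_doc_matches, logical(1),
                                    expr = expr, gene_docs = gene_docs)]
  if (!is.null(base)) hits <- intersect(hits, base)
  sort(hits, method = "radix")
}

# random document collection over a structured vocabulary, plus gene docs
random_docs <- function(seed, n_regions = 300, n_genes = 60) {
  set.seed(seed)
  marks <- paste0("overlap:marks:M", 1:4)
  tissues <- c("ES", "HepG2", "K562")
  mark_words <- as.vector(outer(marks, tissues, paste, sep = ":"))
  gene_ids <- paste0("gene:G", seq_len(n_genes))
  terms <- c(paste0("geneannot:go:regulation_of_process_", 1:5),
             paste0("geneannot:go:term_", 1:10),
             paste0("geneannot:omim:disease_", 1:5))
  gene_docs <- lapply(seq_len(n_genes), function(i) {
    sort(sample(terms, sample(0:4, 1)), method = "radix")
  })
  names(gene_docs) <- gene_ids
  region_docs <- lapply(seq_len(n_regions), function(i) {
    w <- c(sprintf("attr:val:%02d", sample(0:99, 1)),
           sprintf("region:length:%08d", sample(100:5000, 1)),
           sample(mark_words, sample(0:4, 1)),
           if (runif(1) < 0.6) sample(gene_ids, sample(1:3, 1)))
    sort(unique(w), method = "radix")
  })
  names(region_docs) <- paste0("R", seq_len(n_regions))
  list(region_docs = structure(region_docs, class = "document_set"),
       gene_docs = structure(gene_docs, class = "document_set"))
}

# random query expression over the vocabulary of `docs`
random_query <- function(docs, depth = 2) {
  dict <- sort(unique(unlist(docs$region_docs)), method = "radix")
  gdict <- sort(unique(unlist(docs$gene_docs)), method = "radix")
  atom <- function(gene_ok) {
    kind <- sample(c("term", "prefix", "range", if (gene_ok) "gene"), 1,
                   prob = c(0.4, 0.25, 0.25, if (gene_ok) 0.1))
    switch(kind,
      term = q_term(sample(dict, 1)),
      prefix = {
        w <- sample(dict, 1)
        q_prefix(substr(w, 1, sample(seq_len(nchar(w)), 1)))
      },
      range = {
        codes <- sort(sample(0:99, 2))
        q_range(sprintf("attr:val:%02d", codes[1]),
                sprintf("attr:val:%02d", codes[2]))
      },
      gene = {
        inner <- if (runif(1) < 0.5 && length(gdict) > 0) {
          q_term(sample(gdict, 1))
        } else {
          q_substr(sample(c("regulation", "term", "disease", "process"), 1))
        }
        q_gene(inner)
      })
  }
  build <- function(d) {
    if (d == 0 || runif(1) < 0.35) return(atom(gene_ok = TRUE))
    k <- sample(2:3, 1)
    args <- lapply(seq_len(k), function(i) {
      if (d > 1 && runif(1) < 0.3) build(d - 1) else atom(gene_ok = TRUE)
    })
    if (runif(1) < 0.5) q_and(args) else {
      # Or over non-gene atoms only (the string grammar keeps | inside atoms)
      q_or(lapply(seq_len(k), function(i) atom(gene_ok = FALSE)))
    }
  }
  build(depth)
}
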