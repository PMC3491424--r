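#' Annotation tracks
#'
#' An annotation track is a named genome-wide feature map regions are
#' annotated against.  Four kinds are supported:
#'
#' * `"interval"` — plain intervals (peak tracks, CpG islands, repeats, a
#'   second region set used as annotation).
#' * `"categorical-interval"` — intervals carrying a category label
#'   (chromatin-state segmentations); each label becomes a sub-attribute.
#' * `"position-numeric"` — single-bp measurements carrying a ratio in
#'   \[0,1\] and a non-negative integer read coverage (per-CpG DNA
#'   methylation).
#' * `"gene"` — transcribed gene intervals with ids (see
#'   [read_gene_table()] for term annotations).
#'
#' The `attribute_path` is the track's position in the hierarchical keyword
#' vocabulary, components joined by `:` (e.g. `histones:H3K4me1:H1hESC`).
#' Components may use only letters, digits, `_` and `.` — the characters
#' `:`, `*`, `|`, `-`, `~`, `@` and whitespace are reserved by the query
#' grammar.
#'
#' @param attribute_path Hierarchical track name.
#' @param kind One of `"interval"`, `"categorical-interval"`,
#'   `"position-numeric"`, `"gene"`.
#' @param data A data.frame: for interval kinds `chrom`, `start`, `end` and
#'   (categorical) `category` or (gene) `gene_id`; for position-numeric
#'   `chrom`, `pos`, `ratio`, `coverage`.
#' @param assembly A [genome_assembly()] coordinates are validated against.
#' @return An object of class `annotation_track`.
#' @export
annotation_track <- function(attribute_path, kind, data, assembly) {
  kind <- match.arg(kind, c("interval", "categorical-interval",
                            "position-numeric", "gene"))
  check_attribute_path(attribute_path)
  stopifnot(is.data.frame(data), inherits(assembly, "genome_assembly"))
  if (nrow(data) > 0 && !all(data$chrom %in% names(assembly$chromosomes))) {
    stop("track '", attribute_path, "': unknown chromosome(s)")
  }
  lens <- if (nrow(data) > 0) chrom_length(assembly, data$chrom) else numeric()
  if (kind == "position-numeric") {
    stopifnot(all(c("chrom", "pos", "ratio", "coverage") %in% names(data)))
    if (nrow(data) > 0) {
      stopifnot(all(data$pos >= 0 & data$pos < lens),
                all(data$ratio >= 0 & data$ratio <= 1),
                all(data$coverage >= 0 & data$coverage == floor(data$coverage)))
    }
  } else {
    stopifnot(all(c("chrom", "start", "end") %in% names(data)))
    if (nrow(data) > 0) {
      ok <- data$start >= 0 & data$start < data$end & data$end <= lens
      if (!all(ok)) stop("track '", attribute_path, "': invalid interval(s)")
    }
    if (kind == "categorical-interval") {
      stopifnot("category" %in% names(data))
      for (lab in unique(data$category)) check_attribute_path(lab)
    }
    if (kind == "gene") stopifnot("gene_id" %in% names(data))
  }
  structure(list(attribute_path = attribute_path, kind = kind,
                 data = data, assembly_name = assembly$name),
            class = "annotation_track")
}

#' @export
print.annotation_track <- function(x, ...) {
  cat(sprintf("<annotation_track> %s (%s): %d record(s)\n",
              x$attribute_path, x$kind, nrow(x$data)))
  invisible(x)
}

# Reserved characters carry query-grammar meaning; '-' additionally appears
# in the '--' range separator.
check_attribute_path <- function(path) {
  comps <- strsplit(path, ":", fixed = TRUE)[[1]]
  if (length(comps) == 0 || any(!grepl("^[A-Za-z0-9_.]+$", comps))) {
    stop("invalid attribute path '", path,
         "': components must be non-empty and use only [A-Za-z0-9_.]")
  }
  invisible(path)
}

#' Read an interval annotation track from a BED file
#'
#' For `kind = "categorical-interval"` the BED name column supplies the
#' category label; for `kind = "gene"` it supplies the gene id.
#'
#' @inheritParams annotation_track
#' @param path BED file path.
#' @export
read_track_bed <- function(path, assembly, attribute_path,
                           kind = c("interval", "categorical-interval",
                                    "gene")) {
  kind <- match.arg(kind)
  set <- read_bed(path, assembly, set_id = attribute_path)
  df <- set$regions[, c("chrom", "start", "end")]
  if (kind == "categorical-interval") df$category <- set$regions$region_id
  if (kind == "gene") df$gene_id <- set$regions$region_id
  annotation_track(attribute_path, kind, df, assembly)
}

#' Read a position-level numeric track
#'
#' Tab-separated format `chrom<TAB>pos<TAB>ratio<TAB>coverage`, one measured
#' position (e.g. one CpG) per line; `pos` is 0-based, `ratio` in \[0,1\],
#' `coverage` a non-negative integer read count.
#'
#' @inheritParams annotation_track
#' @param path File path.
#' @export
read_position_track <- function(path, assembly, attribute_path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "pos", "ratio", "coverage"),
                          colClasses = c("character", "numeric", "numeric",
                                         "numeric"))
  annotation_track(attribute_path, "position-numeric", df, assembly)
}

#' Write a position-level numeric track
#' @param track A position-numeric [annotation_track()].
#' @param path Output path.
#' @export
write_position_track <- function(track, path) {
  stopifnot(track$kind == "position-numeric")
  d <- track$data
  writeLines(sprintf("%s\t%d\t%s\t%d", d$chrom, as.integer(d$pos),
                     format(d$ratio, trim = TRUE, scientific = FALSE),
                     as.integer(d$coverage)), path)
  invisible(path)
}

#' Gene records with term annotations
#'
#' Reads the gene sidecar format: tab-separated
#' `gene_id<TAB>chrom<TAB>start<TAB>end<TAB>strand<TAB>namespace<TAB>term`,
#' one row per (gene, term); genes without terms use `.` in the namespace
#' and term columns.  Namespaces are typically `go`, `omim` or
#' `description`.
#'
#' @param path File path.
#' @param assembly A [genome_assembly()].
#' @return An object of class `gene_records` with fields `genes` (data.frame
#'   `gene_id`, `chrom`, `start`, `end`, `strand`) and `terms` (data.frame
#'   `gene_id`, `namespace`, `term`).
#' @export
read_gene_table <- function(path, assembly) {
  df <- utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                          col.names = c("gene_id", "chrom", "start", "end",
                                        "strand", "namespace", "term"),
                          colClasses = c("character", "character", "numeric",
                                         "numeric", "character", "character",
                                         "character"))
  genes <- unique(df[, c("gene_id", "chrom", "start", "end", "strand")])
  terms <- df[df$namespace != "." & df$term != ".",
              c("gene_id", "namespace", "term")]
  gene_records(genes, terms, assembly)
}

#' Construct gene records in code
#' @param genes data.frame `gene_id`, `chrom`, `start`, `end`, optional
#'   `strand`.
#' @param terms data.frame `gene_id`, `namespace`, `term` (zero rows allowed).
#' @param assembly A [genome_assembly()].
#' @export
gene_records <- function(genes, terms, assembly) {
  stopifnot(is.data.frame(genes),
            all(c("gene_id", "chrom", "start", "end") %in% names(genes)))
  if (anyDuplicated(genes$gene_id)) stop("gene ids must be unique")
  if (!"strand" %in% names(genes)) genes$strand <- "."
  if (nrow(genes) > 0) {
    lens <- chrom_length(assembly, genes$chrom)
    stopifnot(all(genes$start >= 0 & genes$start < genes$end &
                    genes$end <= lens))
  }
  terms <- terms[, c("gene_id", "namespace", "term")]
  stopifnot(all(terms$gene_id %in% genes$gene_id),
            all(nzchar(terms$term)))
  rownames(genes) <- NULL
  rownames(terms) <- NULL
  structure(list(genes = genes, terms = terms,
                 assembly_name = assembly$name),
            class = "gene_records")
}

#' Write gene records to the sidecar format
#' @param records A [gene_records()] object.
#' @param path Output path.
#' @export
write_gene_table <- function(records, path) {
  g <- records$genes
  t <- records$terms
  rows <- character(0)
  for (i in seq_len(nrow(g))) {
    ti <- t[t$gene_id == g$gene_id[i], , drop = FALSE]
    if (nrow(ti) == 0) {
      rows <- c(rows, sprintf("%s\t%s\t%d\t%d\t%s\t.\t.", g$gene_id[i],
                              g$chrom[i], as.integer(g$start[i]),
                              as.integer(g$end[i]), g$strand[i]))
    } else {
      rows <- c(rows, sprintf("%s\t%s\t%d\t%d\t%s\t%s\t%s", g$gene_id[i],
                              g$chrom[i], as.integer(g$start[i]),
                              as.integer(g$end[i]), g$strand[i],
                              ti$namespace, ti$term))
    }
  }
  writeLines(rows, path)
  invisible(path)
}

#' @export
print.gene_records <- function(x, ...) {
  cat(sprintf("<gene_records> %d gene(s), %d term annotation(s)\n",
              nrow(x$genes), nrow(x$terms)))
  invisible(x)
}
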