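#' Per-region overlap annotation
#'
#' The central annotation concept is overlap: a region carries a track's
#' binary attribute iff it shares at least one base pair with any track
#' interval.  In addition the overlap ratio — the fraction of the region's
#' own length covered by the union of the track's intervals — is computed for
#' filtering on percent overlap.  For categorical tracks (chromatin-state
#' segmentations) a flag is computed per category label as well.
#'
#' @param set A [region_set()].
#' @param track An interval or categorical-interval [annotation_track()].
#' @return A list of class `overlap_annotation`: `path`, `kind`, and
#'   parallel-to-region vectors `flag` (logical), `ratio` (numeric in
#'   \[0,1\]); for categorical tracks also `categories`, a named list of
#'   logical vectors, one per label.
#' @export
annotate_overlap <- function(set, track) {
  stopifnot(inherits(set, "region_set"),
            track$kind %in% c("interval", "categorical-interval"))
  gr_r <- bed_to_granges(set$regions)
  covered <- covered_bp(gr_r, track$data)
  len <- set$regions$end - set$regions$start
  out <- list(path = track$attribute_path, kind = track$kind,
              flag = covered > 0, ratio = covered / len)
  if (track$kind == "categorical-interval") {
    labs <- sort(unique(track$data$category))
    out$categories <- lapply(stats::setNames(labs, labs), function(lab) {
      sub <- track$data[track$data$category == lab, , drop = FALSE]
      covered_bp(gr_r, sub) > 0
    })
  }
  structure(out, class = "overlap_annotation")
}

# bp of each query region covered by the union of intervals in `df`.
covered_bp <- function(gr_r, df) {
  n <- length(gr_r)
  if (nrow(df) == 0) return(numeric(n))
  gr_t <- GenomicRanges::reduce(bed_to_granges(df))
  hits <- GenomicRanges::findOverlaps(gr_r, gr_t)
  if (length(hits) == 0) return(numeric(n))
  pi <- GenomicRanges::pintersect(gr_r[S4Vectors::queryHits(hits)],
                                  gr_t[S4Vectors::subjectHits(hits)])
  w <- tapply(IRanges::width(pi), S4Vectors::queryHits(hits), sum)
  covered <- numeric(n)
  covered[as.integer(names(w))] <- as.numeric(w)
  covered
}

#' Per-region DNA methylation summary
#'
#' Summarizes a position-level methylation track over each region: the number
#' of measured positions (CpGs) falling in the region and the unweighted mean
#' of their methylation ratios.  Regions containing no measured position get
#' `NA` for the mean and are excluded by any downstream methylation filter;
#' read coverage enters only through the position count, not as a weight.
#'
#' @param set A [region_set()].
#' @param track A position-numeric [annotation_track()].
#' @return A data.frame with columns `region_id`, `count` (measured
#'   positions in the region) and `mean_ratio` (`NA` when `count == 0`).
#' @export
annotate_methylation <- function(set, track) {
  stopifnot(inherits(set, "region_set"), track$kind == "position-numeric")
  gr_r <- bed_to_granges(set$regions)
  n <- length(gr_r)
  count <- integer(n)
  mean_ratio <- rep(NA_real_, n)
  if (nrow(track$data) > 0) {
    gr_p <- GenomicRanges::GRanges(
      seqnames = track$data$chrom,
      ranges = IRanges::IRanges(start = track$data$pos + 1, width = 1)
    )
    hits <- GenomicRanges::findOverlaps(gr_r, gr_p)
    if (length(hits) > 0) {
      q <- S4Vectors::queryHits(hits)
      r <- track$data$ratio[S4Vectors::subjectHits(hits)]
      cnt <- tapply(r, q, length)
      mn <- tapply(r, q, mean)
      idx <- as.integer(names(cnt))
      count[idx] <- as.integer(cnt)
      mean_ratio[idx] <- as.numeric(mn)
    }
  }
  data.frame(region_id = set$regions$region_id, count = count,
             mean_ratio = mean_ratio, stringsAsFactors = FALSE)
}

#' Per-region DNA sequence composition
#'
#' CpG frequency is the number of `CG` dinucleotides divided by the number of
#' dinucleotide positions (`length - 1`); G+C frequency is `(#G + #C) /
#' length`.  Matching is case-insensitive and ambiguous bases (`N`) never
#' match.
#'
#' @param set A [region_set()].
#' @param sequences Named character vector (or coercible) of chromosome
#'   sequences; must cover every region (a region extending beyond its
#'   sequence aborts, indicating an assembly/FASTA mismatch).
#' @return A data.frame with columns `region_id`, `cpg_freq`, `gc_freq`.
#' @export
annotate_sequence_composition <- function(set, sequences) {
  stopifnot(inherits(set, "region_set"))
  sequences <- vapply(as.list(sequences), as.character, character(1))
  df <- set$regions
  n <- nrow(df)
  cpg <- numeric(n)
  gc <- numeric(n)
  for (i in seq_len(n)) {
    s <- sequences[[df$chrom[i]]]
    if (is.null(s) || is.na(s)) stop("no sequence for chromosome ",
                                     df$chrom[i])
    if (nchar(s) < df$end[i]) {
      stop("region ", df$region_id[i],
           " extends beyond the sequence of ", df$chrom[i],
           " (assembly/FASTA mismatch)")
    }
    sub <- toupper(substr(s, df$start[i] + 1, df$end[i]))
    len <- nchar(sub)
    m <- gregexpr("CG", sub, fixed = TRUE)[[1]]
    n_cg <- if (m[1] == -1) 0L else length(m)
    cpg[i] <- if (len > 1) n_cg / (len - 1) else 0
    n_gc <- len - nchar(gsub("[GC]", "", sub))
    gc[i] <- n_gc / len
  }
  data.frame(region_id = df$region_id, cpg_freq = cpg, gc_freq = gc,
             stringsAsFactors = FALSE)
}

#' Read chromosome sequences from a FASTA file
#'
#' @param path FASTA path (uncompressed).
#' @return Named character vector of sequences.
#' @export
read_fasta_sequences <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^>", lines)
  if (length(hdr) == 0) stop("no FASTA records in ", path)
  names <- sub("^>\\s*(\\S+).*$", "\\1", lines[hdr])
  starts <- hdr + 1
  ends <- c(hdr[-1] - 1, length(lines))
  seqs <- vapply(seq_along(hdr), function(i) {
    if (starts[i] > ends[i]) "" else {
      paste(lines[starts[i]:ends[i]], collapse = "")
    }
  }, character(1))
  stats::setNames(seqs, names)
}

#' Write chromosome sequences as FASTA
#' @param sequences Named character vector.
#' @param path Output path.
#' @param width Line wrap width.
#' @export
write_fasta_sequences <- function(sequences, path, width = 70) {
  con <- file(path, "wt")
  on.exit(close(con))
  for (nm in names(sequences)) {
    writeLines(paste0(">", nm), con)
    s <- sequences[[nm]]
    n <- nchar(s)
    if (n > 0) {
      starts <- seq(1, n, by = width)
      writeLines(substring(s, starts, pmin(starts + width - 1, n)), con)
    }
  }
  invisible(path)
}

#' Per-region gene links
#'
#' Links every region to each gene whose transcribed interval lies within
#' `proximity_bp` of it (gap in bp between the half-open intervals; an
#' overlapping gene has gap 0), and records the distance to the nearest gene
#' as a numeric attribute.  Links are monotone in `proximity_bp`.
#'
#' @param set A [region_set()].
#' @param genes A [gene_records()] object.
#' @param proximity_bp Maximum gap in bp (default 10 kb).
#' @return A list of class `gene_annotation`: `links` (list of character
#'   vectors of gene ids, parallel to regions) and `nearest` (numeric gap in
#'   bp to the nearest gene on the same chromosome, `NA` when there is
#'   none).
#' @export
annotate_genes <- function(set, genes, proximity_bp = 10000) {
  stopifnot(inherits(set, "region_set"), inherits(genes, "gene_records"),
            proximity_bp >= 0)
  gr_r <- bed_to_granges(set$regions)
  n <- length(gr_r)
  links <- rep(list(character(0)), n)
  nearest <- rep(NA_real_, n)
  if (nrow(genes$genes) > 0) {
    gr_g <- bed_to_granges(genes$genes)
    hits <- GenomicRanges::findOverlaps(gr_r, gr_g,
                                        maxgap = as.integer(proximity_bp))
    if (length(hits) > 0) {
      sp <- split(genes$genes$gene_id[S4Vectors::subjectHits(hits)],
                  S4Vectors::queryHits(hits))
      for (k in names(sp)) links[[as.integer(k)]] <- unique(sp[[k]])
    }
    dn <- GenomicRanges::distanceToNearest(gr_r, gr_g)
    nearest[S4Vectors::queryHits(dn)] <-
      as.numeric(S4Vectors::mcols(dn)$distance)
  }
  structure(list(links = links, nearest = nearest,
                 proximity_bp = proximity_bp),
            class = "gene_annotation")
}

#' Annotation accumulator for a region set
#'
#' Collects the attribute records of all regions in a set across annotation
#' sources; feed the result to [build_region_documents()] to obtain keyword
#' documents.
#'
#' @param set A [region_set()].
#' @return An object of class `region_annotations`.
#' @seealso [add_overlap_track()], [add_methylation_track()],
#'   [add_sequence_composition()], [add_gene_links()]
#' @export
region_annotations <- function(set) {
  stopifnot(inherits(set, "region_set"))
  structure(list(set = set, overlaps = list(), methylation = list(),
                 seqcomp = NULL, genes = NULL),
            class = "region_annotations")
}

#' @rdname region_annotations
#' @param ann A `region_annotations` object.
#' @param track An [annotation_track()].
#' @export
add_overlap_track <- function(ann, track) {
  stopifnot(inherits(ann, "region_annotations"))
  ann$overlaps[[track$attribute_path]] <- annotate_overlap(ann$set, track)
  ann
}

#' @rdname region_annotations
#' @export
add_methylation_track <- function(ann, track) {
  stopifnot(inherits(ann, "region_annotations"),
            track$kind == "position-numeric")
  ann$methylation[[track$attribute_path]] <-
    annotate_methylation(ann$set, track)
  ann
}

#' @rdname region_annotations
#' @param sequences Named character vector of chromosome sequences.
#' @export
add_sequence_composition <- function(ann, sequences) {
  stopifnot(inherits(ann, "region_annotations"))
  ann$seqcomp <- annotate_sequence_composition(ann$set, sequences)
  ann
}

#' @rdname region_annotations
#' @param genes A [gene_records()] object.
#' @param proximity_bp Maximum gap in bp for a gene link.
#' @export
add_gene_links <- function(ann, genes, proximity_bp = 10000) {
  stopifnot(inherits(ann, "region_annotations"))
  ann$genes <- annotate_genes(ann$set, genes, proximity_bp)
  ann
}

#' @export
print.region_annotations <- function(x, ...) {
  cat(sprintf(paste0("<region_annotations> %s: %d overlap track(s), %d",
                     " methylation track(s), seq composition: %s, gene",
                     " links: %s\n"),
              x$set$set_id, length(x$overlaps), length(x$methylation),
              if (is.null(x$seqcomp)) "no" else "yes",
              if (is.null(x$genes)) "no" else "yes"))
  invisible(x)
}
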