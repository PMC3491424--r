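#' Percent-overlap bar summary
#'
#' For each attribute path, the percentage of base regions carrying the
#' corresponding `overlap:` keyword — the bar chart.  With a control set the
#' same percentage is computed over the control (typically a shuffled control
#' set indexed alongside or in its own index), giving the expected-by-chance
#' reference bars.
#'
#' @param index A `search_index`.
#' @param base Non-empty character vector of region doc ids.
#' @param paths Character vector of attribute paths (without the `overlap:`
#'   prefix).
#' @param control Optional doc id set of control regions.
#' @param control_index Index holding the control documents (defaults to
#'   `index`, for controls indexed in the same document collection).
#' @return Data.frame `path`, `overlap_pct` and, when a control is given,
#'   `control_pct`.
#' @export
overlap_summary <- function(index, base, paths, control = NULL,
                            control_index = index) {
  if (length(base) == 0) stop("empty base set: percentage undefined")
  pct <- function(idx, b) {
    vapply(paths, function(p) {
      100 * length(evaluate(idx, q_term(encode_binary(p)), base = b)) /
        length(b)
    }, numeric(1))
  }
  out <- data.frame(path = paths, overlap_pct = unname(pct(index, base)),
                    stringsAsFactors = FALSE)
  if (!is.null(control)) {
    if (length(control) == 0) stop("empty control set: percentage undefined")
    out$control_pct <- unname(pct(control_index, control))
  }
  rownames(out) <- NULL
  out
}

#' Area-chart histogram with optional range selection
#'
#' The histogram of a numeric attribute over the base set, computed through
#' prefix completion, plus — when a value range is given — the doc id subset
#' selected by the equivalent lexicographic range query (the slider
#' refinement).  The selection is consistent with the histogram's bins: it is
#' exactly the regions whose bin code falls between the codes of the range
#' bounds.
#'
#' @param index A `search_index`.
#' @param codec The attribute's [numeric_codec()].
#' @param base Optional region doc id subset.
#' @param value_range Optional numeric `c(lo, hi)`, inclusive at bin
#'   resolution.
#' @return List with `bins` (see [histogram_via_completion()]), `selection`
#'   (doc ids or `NULL`) and `query` (the range query string or `NULL`).
#' @export
area_histogram <- function(index, codec, base = NULL, value_range = NULL) {
  bins <- histogram_via_completion(index, codec, base = base)
  selection <- NULL
  qstr <- NULL
  if (!is.null(value_range)) {
    stopifnot(length(value_range) == 2, value_range[1] <= value_range[2])
    qstr <- range_query(codec, value_range[1], value_range[2])
    selection <- evaluate(index, parse_query(qstr), base = base)
  }
  list(bins = bins, selection = selection, query = qstr)
}

#' Pie-chart partition of a wide-range numeric attribute
#'
#' Partitions the attribute's value range at the given edges into coarse
#' segments, counting the (base) regions per segment; each segment carries
#' the range query that drills down into it (the zoomed-in area chart uses
#' its result as the new base).
#'
#' @param index A `search_index`.
#' @param codec The attribute's [numeric_codec()].
#' @param edges Strictly increasing internal cut points within the codec's
#'   clamp range; `k` edges give `k + 1` segments covering the full range.
#' @param base Optional region doc id subset.
#' @return Data.frame `lo`, `hi`, `count`, `query` (one row per segment;
#'   segment `i` covers values in `[lo, hi)`, the last segment is closed).
#' @export
pie_partition <- function(index, codec, edges, base = NULL) {
  stopifnot(length(edges) >= 1, !is.unsorted(edges, strictly = TRUE))
  if (any(edges <= codec$min) || any(edges >= codec$max)) {
    stop("partition edges must lie strictly inside the codec clamp range [",
         codec$min, ", ", codec$max, "]")
  }
  bins <- histogram_via_completion(index, codec, base = base)
  lo_vals <- c(codec$min, edges)
  hi_vals <- c(edges, codec$max)
  top_code <- 10^codec$width - 1
  out <- lapply(seq_along(lo_vals), function(i) {
    c_lo <- if (i == 1) as.integer(codec_code(codec, codec$min)) else {
      as.integer(ceiling(lo_vals[i] * codec$scale - 1e-9))
    }
    c_hi <- if (i == length(lo_vals)) as.integer(codec_code(codec, codec$max))
            else as.integer(ceiling(hi_vals[i] * codec$scale - 1e-9)) - 1L
    c_hi <- min(c_hi, top_code)
    cnt <- sum(bins$count[bins$code >= c_lo & bins$code <= c_hi])
    qstr <- sprintf("%s:%0*d--%s:%0*d", codec$path, codec$width, c_lo,
                    codec$path, codec$width, c_hi)
    data.frame(lo = lo_vals[i], hi = hi_vals[i], count = cnt, query = qstr,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Genomic neighborhood profile
#'
#' Mean overlap levels of a track in the vicinity of a region set: regions
#' are anchored at their midpoint, the flank on each side is cut into
#' fixed-width bins (`2 * bins_per_side + 1` bins in total, the center bin
#' straddling the anchor), and each bin's value is the fraction of regions
#' whose bin interval shares at least one bp with the track.  Bin intervals
#' are clipped at chromosome edges; a region whose bin falls entirely
#' off-chromosome is excluded from that bin's denominator.
#'
#' @param set A non-empty [region_set()] (typically a filtered subset).
#' @param track An interval-kind [annotation_track()].
#' @param flank_bp Flank on each side of the anchor, in bp.
#' @param bins_per_side Number of bins per side (bin width =
#'   `flank_bp / bins_per_side`).
#' @return An object of class `neighborhood_profile`: data.frame
#'   `offset_bp` (bin center relative to the anchor), `value` (mean overlap
#'   fraction in \[0,1\]), `n` (regions contributing to the bin).
#' @export
neighborhood_profile <- function(set, track, flank_bp = 10000,
                                 bins_per_side = 20) {
  stopifnot(inherits(set, "region_set"),
            track$kind %in% c("interval", "categorical-interval"),
            bins_per_side >= 1, flank_bp >= bins_per_side)
  df <- set$regions
  if (nrow(df) == 0) stop("empty region set: profile undefined")
  w <- flank_bp / bins_per_side
  mid <- floor((df$start + df$end) / 2)
  clen <- chrom_length(set$assembly, df$chrom)
  offsets <- (-bins_per_side):bins_per_side
  value <- numeric(length(offsets))
  nn <- integer(length(offsets))
  for (k in seq_along(offsets)) {
    j <- offsets[k]
    lo <- pmax(0, floor(mid + (j - 0.5) * w))
    hi <- pmin(clen, floor(mid + (j + 0.5) * w))
    keep <- hi > lo
    nn[k] <- sum(keep)
    if (nn[k] == 0) { value[k] <- NA_real_; next }
    bins <- data.frame(chrom = df$chrom[keep], start = lo[keep],
                       end = hi[keep], stringsAsFactors = FALSE)
    hit <- covered_bp(bed_to_granges(bins), track$data) > 0
    value[k] <- mean(hit)
  }
  structure(data.frame(offset_bp = offsets * w, value = value, n = nn),
            class = c("neighborhood_profile", "data.frame"))
}

#' Bubble-chart data
#'
#' For each track: the percentage of base regions overlapping it (y axis)
#' against the track's total genome coverage (x axis, the expected-by-chance
#' baseline); in comparison mode the control set's overlap percentage is the
#' added dimension.
#'
#' @param index A `search_index`.
#' @param base Non-empty region doc id set.
#' @param tracks A list of interval-kind [annotation_track()]s whose
#'   `attribute_path`s were used during annotation.
#' @param assembly A [genome_assembly()].
#' @param control,control_index As in [overlap_summary()].
#' @return Data.frame `path`, `overlap_pct`, `coverage`, and optionally
#'   `control_pct`.
#' @export
bubble_data <- function(index, base, tracks, assembly, control = NULL,
                        control_index = index) {
  paths <- vapply(tracks, function(t) t$attribute_path, character(1))
  out <- overlap_summary(index, base, paths, control = control,
                         control_index = control_index)
  out$coverage <- vapply(tracks, genome_coverage, numeric(1),
                         assembly = assembly)
  out[, c("path", "overlap_pct", "coverage",
          intersect("control_pct", names(out)))]
}

#' Gene-term enrichment against a control set
#'
#' For every annotation term carried by the indexed gene documents, counts
#' the base regions linked (via `gene:<id>` words) to at least one gene
#' carrying the term, compares with the same count over a control set scaled
#' to the base size, and reports the pseudocount-adjusted enrichment ratio
#' `(observed + eps) / (expected + eps)`.  The most general and most specific
#' terms are suppressed by universe size (the number of genes carrying the
#' term), by default more than 5,000 or fewer than 50 genes.  With
#' `base == control` every ratio is exactly 1.
#'
#' @param index A `search_index` with gene documents.
#' @param base Non-empty region doc id set.
#' @param control Doc id set of the control regions (typically from a
#'   shuffled control set).
#' @param control_index Index holding the control documents (defaults to
#'   `index`).
#' @param namespace Optional term namespace filter (e.g. `"go"`).
#' @param min_universe,max_universe Universe-size suppression bounds.
#' @param pseudocount The `eps` regions added to both counts.
#' @param mode Count `"regions"` (default) or `"genes"` — in genes mode
#'   observed/expected are numbers of distinct linked genes carrying the
#'   term.
#' @return Data.frame `term`, `observed`, `expected`, `ratio`, `universe`,
#'   sorted by decreasing ratio.
#' @export
term_enrichment <- function(index, base, control, control_index = index,
                            namespace = NULL, min_universe = 50,
                            max_universe = 5000, pseudocount = 1,
                            mode = c("regions", "genes")) {
  mode <- match.arg(mode)
  if (length(base) == 0) stop("empty base set")
  if (length(control) == 0) stop("empty control set")
  dict <- index$gene$dict
  terms <- dict[startsWith(dict, "geneannot:")]
  if (!is.null(namespace)) {
    terms <- terms[startsWith(terms, paste0("geneannot:", namespace, ":"))]
  }
  if (length(terms) == 0) {
    warning("no gene term annotations indexed; empty enrichment result")
    return(data.frame(term = character(0), observed = numeric(0),
                      expected = numeric(0), ratio = numeric(0),
                      universe = integer(0)))
  }
  universe <- vapply(terms, function(t) {
    length(side_postings(index$gene, t))
  }, integer(1))
  keep <- universe >= min_universe & universe <= max_universe
  terms <- terms[keep]
  universe <- universe[keep]
  obs <- vapply(terms, function(t) {
    length(evaluate(index, q_gene(q_term(t)), base = base))
  }, integer(1))
  ctrl <- vapply(terms, function(t) {
    length(evaluate(control_index, q_gene(q_term(t)), base = control))
  }, integer(1))
  if (mode == "genes") {
    obs <- vapply(terms, function(t) {
      genes <- side_postings(index$gene, t)
      sum(vapply(genes, function(g) {
        length(evaluate(index, q_term(g), base = base)) > 0
      }, logical(1)))
    }, integer(1))
    ctrl <- vapply(terms, function(t) {
      genes <- side_postings(control_index$gene, t)
      sum(vapply(genes, function(g) {
        length(evaluate(control_index, q_term(g), base = control)) > 0
      }, logical(1)))
    }, integer(1))
  }
  expected <- ctrl * length(base) / length(control)
  ratio <- (obs + pseudocount) / (expected + pseudocount)
  out <- data.frame(term = unname(terms), observed = unname(obs),
                    expected = unname(expected), ratio = unname(ratio),
                    universe = unname(universe), stringsAsFactors = FALSE)
  out <- out[order(-out$ratio, out$term, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}
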