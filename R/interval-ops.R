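## Interval arithmetic.  BED half-open [start, end) coordinates are converted
## to 1-based closed IRanges (start+1, end) at the boundary; all overlap
## computations are strand-blind.

bed_to_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1, end = df$end)
  )
}

track_granges <- function(track) {
  stopifnot(track$kind %in% c("interval", "categorical-interval", "gene"))
  bed_to_granges(track$data)
}

#' Base pairs shared by two regions
#'
#' Two regions overlap iff they share at least one base pair; adjacent
#' half-open intervals do not overlap.  Strand is ignored.
#'
#' @param a,b Single regions: lists or one-row data.frames with `chrom`,
#'   `start`, `end` (0-based half-open).
#' @return Integer number of shared base pairs (0 when disjoint or on
#'   different chromosomes).
#' @examples
#' overlap_bp(list(chrom = "c", start = 100, end = 200),
#'            list(chrom = "c", start = 199, end = 300)) # 1
#' @export
overlap_bp <- function(a, b) {
  if (a$chrom != b$chrom) return(0L)
  as.integer(max(0, min(a$end, b$end) - max(a$start, b$start)))
}

#' Distance to the nearest track interval
#'
#' Returns 0 bp when the region overlaps (or is directly adjacent to) a track
#' interval, otherwise the minimal gap in bp to the closest interval on the
#' same chromosome, or `NA` when the chromosome carries no track interval.
#'
#' @param region A single region (list/one-row data.frame with `chrom`,
#'   `start`, `end`).
#' @param track An interval-kind or gene-kind [annotation_track()].
#' @return Non-negative integer gap in bp, or `NA_integer_`.
#' @export
nearest_distance <- function(region, track) {
  stopifnot(track$kind %in% c("interval", "gene"))
  d <- track$data[track$data$chrom == region$chrom, , drop = FALSE]
  if (nrow(d) == 0) return(NA_integer_)
  gap <- pmax(0, pmax(d$start - region$end, region$start - d$end))
  as.integer(min(gap))
}

#' Fraction of the genome covered by a track
#'
#' Base pairs covered by the union of the track's intervals divided by the
#' assembly's total length; duplicated or overlapping intervals count once.
#'
#' @param track An interval-kind [annotation_track()].
#' @param assembly A [genome_assembly()].
#' @return A fraction in \[0, 1\].
#' @export
genome_coverage <- function(track, assembly) {
  stopifnot(track$kind %in% c("interval", "categorical-interval", "gene"))
  if (nrow(track$data) == 0) return(0)
  gr <- GenomicRanges::reduce(track_granges(track))
  sum(as.numeric(IRanges::width(gr))) / assembly$total_length
}

#' Randomized control set by coordinate reshuffling
#'
#' Generates the empirical null used for comparative analysis: the genomic
#' position of every region is reshuffled while the number of regions and the
#' multiset of region lengths are retained exactly.  Each region is placed
#' uniformly at random over all valid (chromosome, start) positions where it
#' fits entirely within a chromosome — the chromosome is chosen with
#' probability proportional to its number of valid start positions.  Shuffled
#' regions may overlap one another.  Deterministic given `seed`.
#'
#' @param set A [region_set()].
#' @param seed Integer seed.
#' @param set_id Label for the control set.
#' @return A [region_set()] whose region ids are the originals prefixed with
#'   `"shuffled:"`; scores and strands carry over.
#' @export
shuffle_regions <- function(set, seed, set_id = paste0(set$set_id, "_shuffled")) {
  stopifnot(inherits(set, "region_set"))
  df <- set$regions
  clen <- set$assembly$chromosomes
  out <- df
  out$region_id <- paste0("shuffled:", df$region_id)
  with_seed(seed, {
    for (i in seq_len(nrow(df))) {
      len <- df$end[i] - df$start[i]
      valid <- pmax(0, clen - len + 1)  # valid start positions per chromosome
      if (sum(valid) == 0) {
        stop("region ", df$region_id[i], " (", len,
             " bp) is longer than every chromosome")
      }
      # uniform over all valid (chrom, start) pairs
      pick <- sample.int(sum(valid), 1)
      cum <- cumsum(valid)
      ci <- which(pick <= cum)[1]
      start <- pick - c(0, cum)[ci] - 1  # 0-based start in [0, clen-len]
      out$chrom[i] <- names(clen)[ci]
      out$start[i] <- start
      out$end[i] <- start + len
    }
  })
  region_set(set_id, set$assembly, out)
}

# Evaluate `code` under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}
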