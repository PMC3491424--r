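#' Genomic region sets
#'
#' A region set is an identified, ordered collection of genomic intervals on
#' one assembly.  Coordinates follow the BED convention: 0-based, half-open
#' `[start, end)`.  Each region carries an id (unique within the set), an
#' optional numeric score, and a strand in `{"+", "-", "."}`; strand is
#' ignored by all overlap computations.
#'
#' @param set_id Label for the set.
#' @param assembly A [genome_assembly()].
#' @param regions A data.frame with columns `chrom`, `start`, `end` and
#'   optionally `region_id`, `score`, `strand`.  Missing ids are generated as
#'   `R1..Rn` in row order; missing strand is `"."`; missing score is `NA`.
#' @return An object of class `region_set` with fields `set_id`, `assembly`
#'   and `regions` (a data.frame with all six columns).
#' @export
region_set <- function(set_id, assembly, regions) {
  stopifnot(inherits(assembly, "genome_assembly"), is.data.frame(regions))
  req <- c("chrom", "start", "end")
  if (!all(req %in% names(regions))) {
    stop("regions needs columns chrom, start, end")
  }
  n <- nrow(regions)
  df <- data.frame(
    region_id = if ("region_id" %in% names(regions)) {
      as.character(regions$region_id)
    } else if (n > 0) paste0("R", seq_len(n)) else character(0),
    chrom  = as.character(regions$chrom),
    start  = as.numeric(regions$start),
    end    = as.numeric(regions$end),
    score  = if ("score" %in% names(regions)) as.numeric(regions$score)
             else rep(NA_real_, n),
    strand = if ("strand" %in% names(regions)) as.character(regions$strand)
             else rep(".", n),
    stringsAsFactors = FALSE
  )
  if (n > 0) {
    if (anyDuplicated(df$region_id)) stop("region ids must be unique")
    if (!all(df$strand %in% c("+", "-", "."))) {
      stop("strand must be one of '+', '-', '.'")
    }
    bad_chrom <- !(df$chrom %in% names(assembly$chromosomes))
    if (any(bad_chrom)) {
      stop("chromosome(s) absent from assembly: ",
           paste(unique(df$chrom[bad_chrom]), collapse = ", "))
    }
    lens <- chrom_length(assembly, df$chrom)
    ok <- df$start >= 0 & df$start < df$end & df$end <= lens &
      df$start == floor(df$start) & df$end == floor(df$end)
    if (!all(ok)) {
      stop("invalid coordinates for region(s): ",
           paste(utils::head(df$region_id[!ok], 5), collapse = ", "))
    }
  }
  rownames(df) <- NULL
  structure(list(set_id = set_id, assembly = assembly, regions = df),
            class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("<region_set> %s: %d region(s) on assembly %s\n",
              x$set_id, nrow(x$regions), x$assembly$name))
  invisible(x)
}

#' Number of regions in a set
#' @param x A `region_set`.
#' @export
n_regions <- function(x) nrow(x$regions)

#' Read a BED file into a region set
#'
#' Accepts BED3 to BED6.  `track`, `browser` and `#` comment lines are
#' skipped.  The name column (if present) becomes the region id; otherwise
#' ids `R1..Rn` are generated in file order.  A numeric 5th column is stored
#' as the score.  By default, malformed lines (non-integer coordinates,
#' `start >= end`, unknown chromosome) are skipped with a warning naming the
#' line; with `strict = TRUE` the first such line aborts the read.
#'
#' @param path BED file path.
#' @param assembly A [genome_assembly()] the coordinates are validated
#'   against.
#' @param set_id Label for the resulting set; defaults to the file name.
#' @param strict Abort on the first malformed line instead of skipping.
#' @return A [region_set()].
#' @export
read_bed <- function(path, assembly, set_id = NULL, strict = FALSE) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  if (is.null(set_id)) set_id <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  lines <- lines[keep]
  n <- length(lines)
  chrom <- character(n); start <- numeric(n); end <- numeric(n)
  id <- rep(NA_character_, n); score <- rep(NA_real_, n)
  strand <- rep(".", n)
  ok <- logical(n)
  complain <- function(i, why) {
    msg <- sprintf("skipping BED line %d (%s)", i, why)
    if (strict) stop(msg) else warning(msg, call. = FALSE)
  }
  for (i in seq_len(n)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) f <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(f) < 3) { complain(i, "fewer than 3 fields"); next }
    s <- suppressWarnings(as.numeric(f[2]))
    e <- suppressWarnings(as.numeric(f[3]))
    if (is.na(s) || is.na(e) || s != floor(s) || e != floor(e)) {
      complain(i, "non-integer coordinates"); next
    }
    if (s < 0 || s >= e) { complain(i, "start >= end"); next }
    if (!(f[1] %in% names(assembly$chromosomes))) {
      complain(i, paste0("unknown chromosome ", f[1])); next
    }
    if (e > chrom_length(assembly, f[1])) {
      complain(i, "end beyond chromosome length"); next
    }
    chrom[i] <- f[1]; start[i] <- s; end[i] <- e
    if (length(f) >= 4 && nzchar(f[4]) && f[4] != ".") id[i] <- f[4]
    if (length(f) >= 5) {
      sc <- suppressWarnings(as.numeric(f[5]))
      if (!is.na(sc)) score[i] <- sc
    }
    if (length(f) >= 6 && f[6] %in% c("+", "-")) strand[i] <- f[6]
    ok[i] <- TRUE
  }
  df <- data.frame(chrom = chrom[ok], start = start[ok], end = end[ok],
                   score = score[ok], strand = strand[ok],
                   stringsAsFactors = FALSE)
  ids <- id[ok]
  if (all(is.na(ids))) {
    if (nrow(df) > 0) df$region_id <- paste0("R", seq_len(nrow(df)))
  } else {
    gen <- paste0("R", seq_len(nrow(df)))
    df$region_id <- ifelse(is.na(ids), gen, ids)
  }
  region_set(set_id, assembly, df)
}

#' Write a region set as a BED file
#'
#' Emits BED6 when any region carries a score or an explicit strand, BED4
#' otherwise.  Optionally prepends a UCSC custom-track line
#' `track name=<label>` for genome-browser visualization.  Coordinates are
#' written unchanged (0-based half-open).
#'
#' @param set A [region_set()].
#' @param path Output path.
#' @param ucsc_track_line Optional track label; when given, a
#'   `track name=...` header line is written first.
#' @return `path`, invisibly.
#' @export
write_bed <- function(set, path, ucsc_track_line = NULL) {
  stopifnot(inherits(set, "region_set"))
  df <- set$regions
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(ucsc_track_line)) {
    writeLines(sprintf("track name=%s", ucsc_track_line), con)
  }
  if (nrow(df) == 0) return(invisible(path))
  bed6 <- any(!is.na(df$score)) || any(df$strand != ".")
  if (bed6) {
    sc <- ifelse(is.na(df$score), "0",
                 sub("\\.0+$", "", format(df$score, trim = TRUE,
                                          scientific = FALSE)))
    out <- sprintf("%s\t%d\t%d\t%s\t%s\t%s", df$chrom, as.integer(df$start),
                   as.integer(df$end), df$region_id, sc, df$strand)
  } else {
    out <- sprintf("%s\t%d\t%d\t%s", df$chrom, as.integer(df$start),
                   as.integer(df$end), df$region_id)
  }
  writeLines(out, con)
  invisible(path)
}
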