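#' Genome assemblies
#'
#' A genome assembly is a named, ordered set of chromosomes with lengths in
#' base pairs.  Its total length is the denominator of all genome-coverage
#' computations (e.g. the bubble-chart x axis).
#'
#' @param name Assembly label (e.g. `"toy1"`).
#' @param chromosomes Named integer/numeric vector of chromosome lengths in
#'   bp, in display order.  Names must be unique, lengths positive.
#' @return An object of class `genome_assembly` with fields `name`,
#'   `chromosomes` (named numeric vector) and `total_length`.
#' @examples
#' asm <- genome_assembly("toy", c(chr1 = 1e6, chr2 = 5e5))
#' asm$total_length
#' @export
genome_assembly <- function(name, chromosomes) {
  if (is.null(names(chromosomes)) || anyNA(names(chromosomes)) ||
      any(names(chromosomes) == "")) {
    stop("chromosome lengths must be a named vector")
  }
  if (anyDuplicated(names(chromosomes))) {
    stop("chromosome names must be unique")
  }
  len <- as.numeric(chromosomes)
  if (any(!is.finite(len)) || any(len <= 0) || any(len != floor(len))) {
    stop("chromosome lengths must be positive integers")
  }
  chrom <- stats::setNames(len, names(chromosomes))
  structure(
    list(name = name, chromosomes = chrom, total_length = sum(len)),
    class = "genome_assembly"
  )
}

#' Read a chromosome-sizes file
#'
#' Parses the UCSC-style two-column tab-separated format
#' `chrom<TAB>length`.
#'
#' @param path File path.
#' @param name Assembly label; defaults to the file name without extension.
#' @return A [genome_assembly()].
#' @export
read_chrom_sizes <- function(path, name = NULL) {
  if (!file.exists(path)) stop("chromosome sizes file not found: ", path)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "length"),
                          colClasses = c("character", "numeric"))
  genome_assembly(name, stats::setNames(df$length, df$chrom))
}

#' Write a chromosome-sizes file
#'
#' @param assembly A [genome_assembly()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chrom_sizes <- function(assembly, path) {
  stopifnot(inherits(assembly, "genome_assembly"))
  writeLines(sprintf("%s\t%d", names(assembly$chromosomes),
                     as.integer(assembly$chromosomes)), path)
  invisible(path)
}

#' @export
print.genome_assembly <- function(x, ...) {
  cat(sprintf("<genome_assembly> %s: %d chromosome(s), %.0f bp total\n",
              x$name, length(x$chromosomes), x$total_length))
  invisible(x)
}

chrom_length <- function(assembly, chrom) {
  len <- assembly$chromosomes[chrom]
  unname(len)
}
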