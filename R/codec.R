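#' Numeric keyword codecs
#'
#' Numeric region attributes are made text-searchable by limiting their
#' precision and binning: a value is clamped to the codec's range, scaled,
#' floored to an integer bin code and zero-padded to a fixed digit width, so
#' that numeric order coincides with lexicographic order of the resulting
#' keywords.  The CpG-frequency codec, for example, maps 0.010 to the keyword
#' `dnaseq:freq:CG:010` and a lexicographic range query over such words is
#' exactly a numeric range filter at bin resolution.
#'
#' @param path Attribute path the codec encodes (e.g. `"dnaseq:freq:CG"`).
#' @param scale Multiplier applied before flooring (bin width is `1/scale`).
#' @param width Digit width of the zero-padded code.
#' @param min,max Clamp range in value units; values outside are clamped so
#'   encoding never fails.
#' @return An object of class `numeric_codec`.
#' @export
numeric_codec <- function(path, scale, width, min = 0,
                          max = (10^width - 1) / scale) {
  check_attribute_path(path)
  stopifnot(scale > 0, width >= 1, width == floor(width), min <= max)
  if (floor(max * scale + 1e-9) > 10^width - 1) {
    stop("codec '", path, "': max does not fit in ", width, " digits")
  }
  structure(list(path = path, scale = scale, width = as.integer(width),
                 min = min, max = max),
            class = "numeric_codec")
}

# Bin code for a value: clamp, scale, floor.  The 1e-9 guard keeps values
# that are exact bin boundaries up to double rounding (0.29 * 100 =
# 28.999...96) in their intended bin.
codec_code <- function(codec, value) {
  v <- pmin(pmax(value, codec$min), codec$max)
  code <- floor(v * codec$scale + 1e-9)
  pmin(pmax(code, 0), 10^codec$width - 1)
}

#' Encode a numeric value as a keyword
#'
#' @param codec A [numeric_codec()].
#' @param value Finite numeric value(s).
#' @return Keyword(s) `<path>:<zero-padded code>`; encoding is monotone
#'   non-decreasing in the value.
#' @examples
#' encode_numeric(numeric_codec("dnaseq:freq:CG", 1000, 3), 0.010)
#' @export
encode_numeric <- function(codec, value) {
  stopifnot(all(is.finite(value)))
  sprintf("%s:%0*d", codec$path, codec$width,
          as.integer(codec_code(codec, value)))
}

#' Decode a keyword back to its value bin
#'
#' @param codec A [numeric_codec()].
#' @param word A keyword produced by [encode_numeric()] (or just its digit
#'   code).
#' @return A list with `code` and the half-open bin `[lo, hi)` that contained
#'   the (clamped) encoded value; bin width is `1/scale`.
#' @export
decode_numeric <- function(codec, word) {
  prefix <- paste0(codec$path, ":")
  tail <- if (startsWith(word, prefix)) {
    substring(word, nchar(prefix) + 1)
  } else {
    word
  }
  if (!grepl("^[0-9]+$", tail)) stop("not a numeric keyword for '",
                                     codec$path, "': ", word)
  code <- as.integer(tail)
  list(code = code, lo = code / codec$scale, hi = (code + 1) / codec$scale)
}

#' Build the keyword for a numeric range query
#'
#' @param codec A [numeric_codec()].
#' @param lo,hi Numeric bounds (inclusive at bin resolution).
#' @return A query string `"<word(lo)>--<word(hi)>"`.
#' @export
range_query <- function(codec, lo, hi) {
  stopifnot(lo <= hi)
  paste0(encode_numeric(codec, lo), "--", encode_numeric(codec, hi))
}

#' Codec registries
#'
#' A codec registry maps attribute paths to their [numeric_codec()]s.  The
#' defaults cover the standard numeric attributes:
#'
#' | attribute | scale | width | meaning |
#' |---|---|---|---|
#' | `dnaseq:freq:CG` / `dnaseq:freq:GC` | 1000 | 3 | per-mille frequency (`0.010` -> `010`) |
#' | `region:length` | 1 | 8 | length in bp |
#' | `region:score` | 1 | 6 | BED score, floored |
#' | `distance:genes` | 1/1000 | 4 | nearest-gene distance in kb, floored |
#' | `dnameth:<t>:ratio` | 100 | 2 | methylation percent, top bin 99 |
#' | `dnameth:<t>:cov` | 1 | 4 | measured CpGs in region |
#' | `overlapratio:<path>` | 100 | 2 | percent of region covered |
#'
#' Percent codecs clamp to \[0, 0.99\] so a ratio of exactly 1 lands in the
#' top bin `99`.
#'
#' @param codecs List of [numeric_codec()]s.
#' @return A named list of codecs keyed by path, class `codec_registry`.
#' @export
codec_registry <- function(codecs = list()) {
  reg <- structure(list(), class = "codec_registry")
  for (cd in codecs) reg <- register_codec(reg, cd)
  reg
}

#' @rdname codec_registry
#' @param registry A `codec_registry`.
#' @param codec A [numeric_codec()] to add (replacing any codec with the same
#'   path).
#' @export
register_codec <- function(registry, codec) {
  stopifnot(inherits(codec, "numeric_codec"))
  registry[[codec$path]] <- codec
  registry
}

# Codec templates keyed by the final path component.
percent_codec <- function(path) numeric_codec(path, 100, 2, 0, 0.99)
count_codec <- function(path, width = 4) numeric_codec(path, 1, width)

#' @rdname codec_registry
#' @export
default_codec_registry <- function() {
  codec_registry(list(
    numeric_codec("dnaseq:freq:CG", 1000, 3, 0, 0.999),
    numeric_codec("dnaseq:freq:GC", 1000, 3, 0, 0.999),
    numeric_codec("region:length", 1, 8),
    numeric_codec("region:score", 1, 6),
    numeric_codec("distance:genes", 1 / 1000, 4)
  ))
}

#' Read / write a codec registry file
#'
#' Flat tab-separated format `path<TAB>scale<TAB>width<TAB>min<TAB>max`, one
#' codec per line, so new numeric attributes need no code change.
#'
#' @param path File path.
#' @export
read_codec_registry <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("path", "scale", "width", "min",
                                        "max"),
                          colClasses = c("character", rep("numeric", 4)))
  codec_registry(lapply(seq_len(nrow(df)), function(i) {
    numeric_codec(df$path[i], df$scale[i], df$width[i], df$min[i], df$max[i])
  }))
}

#' @rdname read_codec_registry
#' @param registry A `codec_registry`.
#' @export
write_codec_registry <- function(registry, path) {
  lines <- vapply(registry, function(cd) {
    sprintf("%s\t%s\t%d\t%s\t%s", cd$path,
            format(cd$scale, scientific = FALSE), cd$width,
            format(cd$min, scientific = FALSE),
            format(cd$max, scientific = FALSE))
  }, character(1))
  writeLines(unname(lines), path)
  invisible(path)
}
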