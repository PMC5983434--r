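# Internal helpers shared across modules.

# Decimal rounding with ties away from zero ("half-up"), as used in the
# printed summary tables. base::round() rounds half to even, which disagrees
# with the tables at some boundaries.
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Exact rational test of missing/n <= rate for a rate given with at most six
# decimal places; avoids binary-float artefacts at the 7% boundary.
rate_le <- function(numerator, denominator, rate) {
  stopifnot(denominator > 0)
  as.numeric(numerator) * 1e6 <= round(rate * 1e6) * as.numeric(denominator)
}

#' Variant key strings
#'
#' Builds the `contig:pos:ref>alt` identity string used to match variants
#' across breeds. Only biallelic records have a well-defined key.
#'
#' @param records A records tibble (see [read_vcf()]) or a tibble with at
#'   least `contig`, `pos`, `ref` columns and either an `alt` character
#'   column or an `alts` list-column of length-1 character vectors.
#' @return A character vector of keys, one per row.
#' @export
variant_key <- function(records) {
  alt <- if (!is.null(records[["alt"]])) {
    records$alt
  } else {
    if (any(lengths(records$alts) != 1L)) {
      abort("variant_key() is defined for biallelic records only")
    }
    vapply(records$alts, `[`, character(1), 1L)
  }
  paste0(records$contig, ":", records$pos, ":", records$ref, ">", alt)
}

#' Split variant keys back into a tibble
#'
#' Inverse of [variant_key()]: parses `contig:pos:ref>alt` strings into a
#' tibble with columns `contig`, `pos`, `ref`, `alt`.
#'
#' @param keys Character vector of key strings.
#' @return A tibble with one row per key.
#' @export
parse_variant_key <- function(keys) {
  m <- regmatches(keys, regexec("^(.+):([0-9]+):([ACGTacgt]+)>([ACGTacgt]+)$", keys))
  bad <- vapply(m, length, integer(1)) != 5L
  if (any(bad)) {
    abort(paste0("malformed variant key: ", keys[which(bad)[1]]))
  }
  tibble(
    contig = vapply(m, `[`, character(1), 2L),
    pos = as.integer(vapply(m, `[`, character(1), 3L)),
    ref = vapply(m, `[`, character(1), 4L),
    alt = vapply(m, `[`, character(1), 5L)
  )
}

is_dna <- function(x) grepl("^[ACGTacgt]+$", x)

`%||%` <- function(a, b) if (is.null(a)) b else a
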