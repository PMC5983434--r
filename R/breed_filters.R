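#' Within-breed fixation filter configuration
#'
#' @param max_missing_rate Maximum fraction of missing genotypes tolerated
#'   at a site, default 0.07 (7%, inclusive: "not higher than").
#' @param require_af_unity If `TRUE` (default) a site must have alternative
#'   allele frequency exactly 1 among non-missing genotypes; if `FALSE`,
#'   `min_af` is used as a lower bound instead.
#' @param min_af Lower AF bound used only when `require_af_unity = FALSE`.
#' @return A list of class `breed_filter_config`.
#' @export
breed_filter_config <- function(max_missing_rate = 0.07, require_af_unity = TRUE,
                                min_af = 1) {
  if (max_missing_rate < 0 || max_missing_rate > 1) {
    abort("max_missing_rate must be in [0, 1]")
  }
  structure(
    list(
      max_missing_rate = max_missing_rate,
      require_af_unity = isTRUE(require_af_unity),
      min_af = min_af
    ),
    class = "breed_filter_config"
  )
}

gt_subset <- function(records, samples) {
  if (length(samples) == 0L) {
    abort("sample subset must be non-empty")
  }
  lapply(records$gt, function(g) {
    missing <- setdiff(samples, rownames(g))
    if (length(missing)) {
      abort(paste0("sample '", missing[1], "' not present in the records"))
    }
    g[samples, , drop = FALSE]
  })
}

#' Per-site genotype missingness
#'
#' Fraction of samples in the subset whose diploid genotype is missing.
#'
#' @param records Records tibble with a `gt` list-column.
#' @param samples Character vector of sample IDs (a breed's cohort).
#' @return Numeric vector in `[0, 1]`, one value per record.
#' @export
missing_rate <- function(records, samples = vcf_samples(records)) {
  gts <- gt_subset(records, samples)
  vapply(gts, function(g) sum(is.na(g[, 1])) / nrow(g), numeric(1))
}

#' Per-site alternative allele frequency
#'
#' The count of alternative alleles among non-missing diploid genotypes
#' divided by twice the number of non-missing genotypes. Defined for
#' biallelic records; sites where every genotype is missing give `NaN`.
#'
#' @inheritParams missing_rate
#' @return Numeric vector in `[0, 1]` (or `NaN` for all-missing sites).
#' @export
alt_allele_frequency <- function(records, samples = vcf_samples(records)) {
  if (nrow(records) > 0L && any(!is_biallelic(records))) {
    abort("alt_allele_frequency() is defined for biallelic records only")
  }
  gts <- gt_subset(records, samples)
  cnt <- alt_counts(gts)
  cnt$alt / (2 * cnt$called)
}

# Integer alt-allele and called-genotype counts per record.
alt_counts <- function(gts) {
  alt <- vapply(gts, function(g) sum(g == 1L, na.rm = TRUE), integer(1))
  called <- vapply(gts, function(g) sum(!is.na(g[, 1])), integer(1))
  list(alt = alt, called = called)
}

#' Sites fixed for the alternative allele within a breed
#'
#' Applies the within-breed criteria to site-filtered records: genotype
#' missingness not higher than `max_missing_rate` (7% by default) and
#' alternative allele frequency equal to one. Both boundaries are tested in
#' integer arithmetic (`missing <= rate * n` as rationals; `alt == 2 *
#' called`), never with a floating tolerance. Only SNP-class records are
#' considered; InDels and MNPs are dropped up front.
#'
#' @param records Site-filtered records tibble.
#' @param samples Sample IDs of the breed.
#' @param config A [breed_filter_config()].
#' @return A tibble of variant keys (`contig`, `pos`, `ref`, `alt`, `key`)
#'   for the fixed sites, sorted by contig and position.
#' @export
fixed_alt_sites <- function(records, samples = vcf_samples(records),
                            config = breed_filter_config()) {
  if (nrow(records) == 0L) {
    return(empty_keys())
  }
  snp <- records[classify_variant(records) %in% "SNP", , drop = FALSE]
  if (nrow(snp) == 0L) {
    return(empty_keys())
  }
  gts <- gt_subset(snp, samples)
  n <- length(samples)
  n_missing <- vapply(gts, function(g) sum(is.na(g[, 1])), integer(1))
  cnt <- alt_counts(gts)
  miss_ok <- rate_le(n_missing, n, config$max_missing_rate)
  af_ok <- if (config$require_af_unity) {
    cnt$called > 0L & cnt$alt == 2L * cnt$called
  } else {
    cnt$called > 0L & cnt$alt >= config$min_af * 2 * cnt$called
  }
  hit <- snp[miss_ok & af_ok, , drop = FALSE]
  out <- tibble(
    contig = hit$contig,
    pos = hit$pos,
    ref = hit$ref,
    alt = vapply(hit$alts, `[`, character(1), 1L)
  )
  out$key <- variant_key(out)
  out[order(out$contig, out$pos, out$alt), , drop = FALSE]
}

empty_keys <- function() {
  tibble(
    contig = character(), pos = integer(), ref = character(),
    alt = character(), key = character()
  )
}
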