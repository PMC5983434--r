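#' Site filter configuration
#'
#' Thresholds for the site-level hard-filter cascade applied to each breed's
#' VCF before any genotype-level filtering.
#'
#' @param min_alt_forward,min_alt_reverse Minimum alternative-allele read
#'   count required on the forward and reverse strand (DP4 components 3 and
#'   4). Default 1 each: a variant never seen on both strands is removed.
#' @param min_qual Minimum site quality (QUAL). Sites below 20 are removed.
#' @param min_mq Minimum RMS mapping quality (INFO/MQ). Sites below 30 are
#'   removed.
#' @param min_dp Minimum pooled site depth (INFO/DP), default 10.
#' @param dp_sigma_mult Multiplier on the depth standard deviation for the
#'   depth ceiling, `median(DP) + dp_sigma_mult * sd(DP)`. Default 3.
#' @param indel_indel_dist An InDel with another InDel closer than this many
#'   base pairs is removed. Default 10.
#' @param snp_snp_dist A SNP with another SNP closer than this is removed.
#'   Default 3.
#' @param snp_indel_dist A SNP with an InDel closer than this is removed.
#'   Default 5.
#' @param strict_missing If `TRUE` (default), records with missing QUAL, MQ,
#'   DP or DP4 fail the corresponding filter; if `FALSE`, a missing
#'   annotation passes it.
#' @return A list of class `site_filter_config`.
#' @export
site_filter_config <- function(min_alt_forward = 1L, min_alt_reverse = 1L,
                               min_qual = 20, min_mq = 30, min_dp = 10L,
                               dp_sigma_mult = 3, indel_indel_dist = 10L,
                               snp_snp_dist = 3L, snp_indel_dist = 5L,
                               strict_missing = TRUE) {
  cfg <- list(
    min_alt_forward = min_alt_forward, min_alt_reverse = min_alt_reverse,
    min_qual = min_qual, min_mq = min_mq, min_dp = min_dp,
    dp_sigma_mult = dp_sigma_mult, indel_indel_dist = indel_indel_dist,
    snp_snp_dist = snp_snp_dist, snp_indel_dist = snp_indel_dist,
    strict_missing = isTRUE(strict_missing)
  )
  num <- unlist(cfg[1:9])
  if (any(num < 0)) {
    abort("all site filter thresholds must be >= 0")
  }
  structure(cfg, class = "site_filter_config")
}

#' Biallelic test
#'
#' A record is biallelic when it has exactly one alternative allele; records
#' with two or more alternative alleles are removed by the cascade.
#'
#' @param records Records tibble.
#' @return Logical vector, one element per record.
#' @export
is_biallelic <- function(records) {
  lengths(records$alts) == 1L
}

#' Classify biallelic variants as SNP, INDEL or OTHER
#'
#' SNP: single-base REF and ALT. INDEL: REF and ALT of different lengths.
#' OTHER: equal lengths greater than one (MNPs), which the cascade removes.
#' Multi-allelic records get `NA`.
#'
#' @param records Records tibble.
#' @return Character vector in `{"SNP","INDEL","OTHER", NA}`.
#' @export
classify_variant <- function(records) {
  alt1 <- vapply(records$alts, function(a) if (length(a) == 1L) a else NA_character_, character(1))
  rl <- nchar(records$ref)
  al <- nchar(alt1)
  dplyr::case_when(
    is.na(alt1) ~ NA_character_,
    rl == 1L & al == 1L ~ "SNP",
    rl != al ~ "INDEL",
    TRUE ~ "OTHER"
  )
}

#' Per-strand alternative read support
#'
#' Requires at least `min_alt_forward` alt reads on the forward strand AND
#' `min_alt_reverse` on the reverse strand (DP4 components 3 and 4), so a
#' variant never observed on both strands fails.
#'
#' @param records Records tibble.
#' @param config A [site_filter_config()].
#' @return Logical vector.
#' @export
passes_strand_support <- function(records, config = site_filter_config()) {
  ok <- records$dp4_alt_fwd >= config$min_alt_forward &
    records$dp4_alt_rev >= config$min_alt_reverse
  ok[is.na(ok)] <- !config$strict_missing
  ok
}

#' Site and mapping quality filter
#'
#' Retains records with QUAL at or above `min_qual` and MQ at or above
#' `min_mq` (sites with quality below 20 or mapping quality below 30 are
#' removed under the defaults).
#'
#' @inheritParams passes_strand_support
#' @return Logical vector.
#' @export
passes_quality <- function(records, config = site_filter_config()) {
  q <- records$qual >= config$min_qual
  m <- records$mq >= config$min_mq
  q[is.na(q)] <- !config$strict_missing
  m[is.na(m)] <- !config$strict_missing
  q & m
}

#' Depth ceiling: median + k standard deviations
#'
#' The maximum admissible site depth is estimated from the depth
#' distribution of the records that survived the multi-allelic, strand and
#' quality steps: `median(DP) + dp_sigma_mult * sd(DP)`, with the sample
#' (n - 1) standard deviation.
#'
#' @inheritParams passes_strand_support
#' @return A single number.
#' @export
compute_depth_ceiling <- function(records, config = site_filter_config()) {
  dp <- records$dp[!is.na(records$dp)]
  if (length(dp) < 2L) {
    abort("compute_depth_ceiling() needs at least 2 records with a DP value")
  }
  median(dp) + config$dp_sigma_mult * sd(dp)
}

#' Depth window filter
#'
#' @inheritParams passes_strand_support
#' @param ceiling Depth ceiling from [compute_depth_ceiling()].
#' @return Logical vector: `min_dp <= DP <= ceiling`.
#' @export
passes_depth <- function(records, ceiling, config = site_filter_config()) {
  ok <- records$dp >= config$min_dp & records$dp <= ceiling
  ok[is.na(ok)] <- !config$strict_missing
  ok
}

#' Remove every record at a duplicated position
#'
#' All members of a (contig, pos) collision group are removed, including the
#' "original": two variants assigned the same base-pair position cannot be
#' trusted apart.
#'
#' @param records Records tibble.
#' @return The records whose (contig, pos) is unique, in input order.
#' @export
remove_duplicate_positions <- function(records) {
  key <- paste(records$contig, records$pos, sep = "\r")
  records[!(duplicated(key) | duplicated(key, fromLast = TRUE)), , drop = FALSE]
}

#' SNP/InDel proximity filter
#'
#' In one pass over the input set (removals do not rescue neighbours): a SNP
#' is removed if any other SNP lies closer than `snp_snp_dist` or any InDel
#' closer than `snp_indel_dist`; an InDel is removed if any other InDel lies
#' closer than `indel_indel_dist`. Distance is `|pos_a - pos_b|` on the same
#' contig, using the VCF anchor position; "closer than" is strict, so a pair
#' at exactly the threshold distance survives.
#'
#' @inheritParams passes_strand_support
#' @return The retained records, sorted by (contig, pos).
#' @export
proximity_filter <- function(records, config = site_filter_config()) {
  if (nrow(records) == 0L) {
    return(records)
  }
  cls <- classify_variant(records)
  keep <- !proximity_flags(records$contig, records$pos, cls, config)$remove
  out <- records[keep, , drop = FALSE]
  out[order(out$contig, out$pos), , drop = FALSE]
}

# Single-pass proximity decisions. Returns remove flag + label per record.
proximity_flags <- function(contig, pos, cls, config) {
  n <- length(pos)
  remove <- logical(n)
  label <- rep(NA_character_, n)
  for (ctg in unique(contig)) {
    idx <- which(contig == ctg)
    p <- pos[idx]
    k <- cls[idx]
    snp_pos <- sort(p[k == "SNP"])
    indel_pos <- sort(p[k == "INDEL"])
    near <- function(x, sorted, d, exclude_self) {
      if (length(sorted) == 0L || d <= 0) {
        return(rep(FALSE, length(x)))
      }
      lo <- findInterval(x - d, sorted) + 1L # first element > x - d
      hi <- findInterval(x + d - 1e-9, sorted) # last element < x + d
      cnt <- pmax(hi - lo + 1L, 0L)
      if (exclude_self) {
        # subtract one occurrence of x itself when present in the window
        self <- findInterval(x, sorted) - findInterval(x - 1e-9, sorted)
        cnt <- cnt - self
      }
      cnt > 0L
    }
    is_snp <- k == "SNP" & !is.na(k)
    is_indel <- k == "INDEL" & !is.na(k)
    if (any(is_snp)) {
      ps <- p[is_snp]
      snp_snp <- near(ps, snp_pos, config$snp_snp_dist, exclude_self = TRUE)
      snp_ind <- near(ps, indel_pos, config$snp_indel_dist, exclude_self = FALSE)
      rm_s <- snp_snp | snp_ind
      remove[idx[is_snp]] <- rm_s
      label[idx[is_snp]][snp_snp] <- "prox_snp_snp"
      label[idx[is_snp]][!snp_snp & snp_ind] <- "prox_snp_indel"
    }
    if (any(is_indel)) {
      pi_ <- p[is_indel]
      ind_ind <- near(pi_, indel_pos, config$indel_indel_dist, exclude_self = TRUE)
      remove[idx[is_indel]] <- ind_ind
      label[idx[is_indel]][ind_ind] <- "prox_indel_indel"
    }
  }
  list(remove = remove, label = label)
}

#' Apply the full site-filter cascade
#'
#' Cascade order: multi-allelic removal, variant-class check (MNPs out),
#' per-strand alt support, site/mapping quality, depth window (ceiling
#' estimated from the survivors of the preceding steps), duplicate-position
#' removal, SNP/InDel proximity rules. Each removed record is labelled with
#' the first filter it failed.
#'
#' @param records One breed's records tibble.
#' @param config A [site_filter_config()].
#' @return An object of class `site_filter`: a list with `kept` (the
#'   surviving records, sorted by contig and position), `trace` (one row per
#'   input record: `contig`, `pos`, `ref`, `alt`, `failed_filter`, `NA` when
#'   retained), `depth_ceiling` and `config`. Use [tidy()] / [glance()] for
#'   the trace and per-filter counts.
#' @export
apply_site_filters <- function(records, config = site_filter_config()) {
  n <- nrow(records)
  fail <- rep(NA_character_, n)
  alt_str <- vapply(records$alts, paste, character(1), collapse = ",")

  bial <- is_biallelic(records)
  fail[!bial] <- "multiallelic"
  cls <- classify_variant(records)
  fail[is.na(fail) & cls == "OTHER"] <- "other_class"

  live <- is.na(fail)
  strand_ok <- passes_strand_support(records, config)
  fail[live & !strand_ok] <- "strand"

  live <- is.na(fail)
  q_ok <- records$qual >= config$min_qual
  q_ok[is.na(q_ok)] <- !config$strict_missing
  m_ok <- records$mq >= config$min_mq
  m_ok[is.na(m_ok)] <- !config$strict_missing
  fail[live & !q_ok] <- "qual"
  fail[live & q_ok & !m_ok] <- "mq"

  live <- is.na(fail)
  ceiling <- NA_real_
  if (any(live)) {
    # with fewer than 2 usable depths no distribution can be estimated:
    # only the lower bound applies
    ceiling <- if (sum(!is.na(records$dp[live])) >= 2L) {
      compute_depth_ceiling(records[live, , drop = FALSE], config)
    } else {
      Inf
    }
    d_ok <- passes_depth(records, ceiling, config)
    low <- is.na(records$dp) | records$dp < config$min_dp
    fail[live & !d_ok & low] <- "depth_low"
    fail[live & !d_ok & !low] <- "depth_high"
  }

  live <- is.na(fail)
  if (any(live)) {
    key <- paste(records$contig, records$pos, sep = "\r")
    key[!live] <- NA
    dup <- (duplicated(key, incomparables = NA) |
      duplicated(key, fromLast = TRUE, incomparables = NA)) & live
    fail[dup] <- "duplicate_pos"
  }

  live <- is.na(fail)
  if (any(live)) {
    pf <- proximity_flags(
      records$contig[live], records$pos[live], cls[live], config
    )
    fail[live][pf$remove] <- pf$label[pf$remove]
  }

  kept <- records[is.na(fail), , drop = FALSE]
  kept <- kept[order(kept$contig, kept$pos), , drop = FALSE]
  attr(kept, "samples") <- attr(records, "samples")
  structure(
    list(
      kept = kept,
      trace = tibble(
        contig = records$contig, pos = records$pos, ref = records$ref,
        alt = alt_str, failed_filter = fail
      ),
      depth_ceiling = ceiling,
      config = config
    ),
    class = "site_filter"
  )
}

#' @export
print.site_filter <- function(x, ...) {
  n <- nrow(x$trace)
  cat("<site_filter> ", n, " records in, ", nrow(x$kept), " kept (depth ceiling ",
    format(x$depth_ceiling, digits = 6), ")\n",
    sep = ""
  )
  rm <- table(x$trace$failed_filter)
  if (length(rm)) {
    for (nm in names(rm)) cat("  removed by ", nm, ": ", rm[[nm]], "\n", sep = "")
  }
  invisible(x)
}

#' @rdname apply_site_filters
#' @param x A `site_filter` object.
#' @param ... Unused.
#' @method tidy site_filter
#' @export
tidy.site_filter <- function(x, ...) {
  x$trace
}

#' @rdname apply_site_filters
#' @method glance site_filter
#' @export
glance.site_filter <- function(x, ...) {
  tr <- x$trace
  tibble(
    n_input = nrow(tr),
    n_kept = sum(is.na(tr$failed_filter)),
    n_removed = sum(!is.na(tr$failed_filter)),
    depth_ceiling = x$depth_ceiling
  )
}
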