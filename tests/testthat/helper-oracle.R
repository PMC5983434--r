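# Independent brute-force reference implementation of the site-filter
# cascade: explicit per-record predicates and an O(n^2) all-pairs proximity
# scan. Deliberately shares no code with the package internals.
oracle_site_keep <- function(rec, cfg = breedsnp::site_filter_config()) {
  n <- nrow(rec)
  n_alts <- lengths(rec$alts)
  alt1 <- vapply(rec$alts, function(a) a[1], character(1))
  cls <- character(n)
  for (i in seq_len(n)) {
    cls[i] <- if (n_alts[i] != 1L) {
      "NA"
    } else if (nchar(rec$ref[i]) == 1L && nchar(alt1[i]) == 1L) {
      "SNP"
    } else if (nchar(rec$ref[i]) != nchar(alt1[i])) {
      "INDEL"
    } else {
      "OTHER"
    }
  }
  s1 <- n_alts == 1L & cls %in% c("SNP", "INDEL")
  strand <- !is.na(rec$dp4_alt_fwd) & !is.na(rec$dp4_alt_rev) &
    rec$dp4_alt_fwd >= cfg$min_alt_forward & rec$dp4_alt_rev >= cfg$min_alt_reverse
  qual <- !is.na(rec$qual) & !is.na(rec$mq) &
    rec$qual >= cfg$min_qual & rec$mq >= cfg$min_mq
  s3 <- s1 & strand & qual

  dpv <- rec$dp[s3 & !is.na(rec$dp)]
  ceil <- if (length(dpv) >= 2) {
    # textbook: median + k * sample SD (n - 1 denominator)
    xbar <- sum(dpv) / length(dpv)
    sdv <- sqrt(sum((dpv - xbar)^2) / (length(dpv) - 1))
    sorted <- sort(dpv)
    m <- length(sorted)
    med <- if (m %% 2 == 1) sorted[(m + 1) / 2] else (sorted[m / 2] + sorted[m / 2 + 1]) / 2
    med + cfg$dp_sigma_mult * sdv
  } else {
    Inf
  }
  s4 <- s3 & !is.na(rec$dp) & rec$dp >= cfg$min_dp & rec$dp <= ceil

  s5 <- s4
  for (i in which(s4)) {
    same <- which(s4 & rec$contig == rec$contig[i] & rec$pos == rec$pos[i])
    if (length(same) > 1L) s5[i] <- FALSE
  }

  s6 <- s5
  for (i in which(s5)) {
    for (j in which(s5)) {
      if (i == j || rec$contig[i] != rec$contig[j]) next
      d <- abs(rec$pos[i] - rec$pos[j])
      if (cls[i] == "SNP" && cls[j] == "SNP" && d < cfg$snp_snp_dist) s6[i] <- FALSE
      if (cls[i] == "SNP" && cls[j] == "INDEL" && d < cfg$snp_indel_dist) s6[i] <- FALSE
      if (cls[i] == "INDEL" && cls[j] == "INDEL" && d < cfg$indel_indel_dist) s6[i] <- FALSE
    }
  }
  s6
}

record_sig <- function(rec) {
  paste(rec$contig, rec$pos, rec$ref,
    vapply(rec$alts, paste, character(1), collapse = ","),
    sep = "|"
  )
}

# Brute-force Venn membership oracle: per-key membership vector.
oracle_venn <- function(sets) {
  union_keys <- unique(unlist(sets, use.names = FALSE))
  cells <- list()
  for (k in union_keys) {
    members <- names(sets)[vapply(sets, function(s) k %in% s, logical(1))]
    lbl <- paste(members, collapse = ",")
    cells[[lbl]] <- c(cells[[lbl]], k)
  }
  cells
}
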