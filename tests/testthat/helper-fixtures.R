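`%||%` <- function(a, b) if (is.null(a)) b else a

# Desk-scale cohort used across tests: 3 breeds x 10 samples.
small_cohort_config <- function(seed = 11, ...) {
  args <- list(
    breeds = c("A", "B", "C"),
    samples_per_breed = c(A = 10L, B = 10L, C = 10L),
    contigs = c(chr1 = 60000L),
    n_breed_specific = 20L, n_shared_all = 15L,
    n_partial = c("A,B" = 8L), n_segregating = 20L,
    n_lowqual = 5L, n_lowmq = 5L, n_strandbias = 5L,
    n_depth_outlier = 5L, n_multiallelic = 5L,
    n_duplicate_pos = 5L, n_snp_cluster = 5L,
    n_snp_near_indel = 5L, n_indel_pair = 5L,
    n_genes = 2L, seed = seed
  )
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(breedsnp::cohort_config, args)
}

# In-memory pipeline: site filters + fixation + specificity, no file I/O.
run_in_memory <- function(cohort) {
  fixed <- lapply(names(cohort$vcfs), function(b) {
    kept <- breedsnp::apply_site_filters(cohort$vcfs[[b]])$kept
    samples <- cohort$panel$sample[cohort$panel$breed == b]
    breedsnp::fixed_alt_sites(kept, samples)
  })
  names(fixed) <- names(cohort$vcfs)
  keys <- dplyr::bind_rows(lapply(names(fixed), function(b) {
    tibble::tibble(breed = b, key = fixed[[b]]$key)
  }))
  list(
    fixed = fixed,
    keys = keys,
    specific = breedsnp::breed_specific_sets(keys, breeds = names(fixed))
  )
}

# Build a records tibble from plain vectors, defaulting every annotation to
# values that pass all site filters, so tests perturb one field at a time.
make_records <- function(contig = "chr1", pos, ref = "A", alt = "G",
                         qual = 100, mq = 50, dp = 12,
                         alt_fwd = 5, alt_rev = 5, ref_fwd = 0, ref_rev = 0,
                         samples = c("s1", "s2"),
                         gt = NULL) {
  n <- length(pos)
  rc <- function(x) rep_len(x, n)
  alts <- lapply(strsplit(rc(alt), ",", fixed = TRUE), identity)
  if (is.null(gt)) {
    gt <- lapply(seq_len(n), function(i) {
      matrix(1L, length(samples), 2, dimnames = list(samples, NULL))
    })
  }
  out <- tibble::tibble(
    contig = rc(contig), pos = as.integer(pos), id = NA_character_,
    ref = rc(ref), alts = alts, qual = as.numeric(rc(qual)),
    filter = ".", mq = as.numeric(rc(mq)), dp = as.integer(rc(dp)),
    dp4_ref_fwd = as.integer(rc(ref_fwd)), dp4_ref_rev = as.integer(rc(ref_rev)),
    dp4_alt_fwd = as.integer(rc(alt_fwd)), dp4_alt_rev = as.integer(rc(alt_rev)),
    format = "GT", gt = gt
  )
  attr(out, "samples") <- samples
  out
}

# Genotype matrix shorthand: strings like "1/1", "0/1", "./."
gt_matrix <- function(...) {
  g <- c(...)
  samples <- sprintf("s%02d", seq_along(g))
  m <- matrix(NA_integer_, length(g), 2, dimnames = list(samples, NULL))
  for (i in seq_along(g)) {
    a <- strsplit(g[i], "/", fixed = TRUE)[[1]]
    if (!any(a == ".")) m[i, ] <- as.integer(a)
  }
  m
}

write_lines_tmp <- function(lines, ext = ".vcf") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

tiny_vcf_lines <- function(body, samples = c("S1", "S2")) {
  c(
    "##fileformat=VCFv4.2",
    paste(c(
      "#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
      "FORMAT", samples
    ), collapse = "\t"),
    body
  )
}

# Random site-filter fixture with collisions, clusters, InDels, MNPs,
# multi-allelic records and missing annotations.
random_site_records <- function(n, pos_max = 400) {
  bases <- c("A", "C", "G", "T")
  contig <- sample(c("c1", "c2"), n, replace = TRUE)
  pos <- sample.int(pos_max, n, replace = TRUE)
  kind <- sample(
    c("snp", "indel", "mnp", "multi"), n,
    replace = TRUE, prob = c(0.6, 0.2, 0.1, 0.1)
  )
  ref <- character(n)
  alt <- character(n)
  for (i in seq_len(n)) {
    r <- sample(bases, 1)
    if (kind[i] == "snp") {
      ref[i] <- r
      alt[i] <- sample(setdiff(bases, r), 1)
    } else if (kind[i] == "indel") {
      if (runif(1) < 0.5) {
        ref[i] <- paste0(r, sample(bases, 1))
        alt[i] <- r
      } else {
        ref[i] <- r
        alt[i] <- paste0(r, sample(bases, 1))
      }
    } else if (kind[i] == "mnp") {
      ref[i] <- paste0(r, sample(bases, 1))
      alt2 <- paste0(sample(setdiff(bases, r), 1), sample(bases, 1))
      alt[i] <- alt2
    } else {
      ref[i] <- r
      others <- setdiff(bases, r)
      alt[i] <- paste(sample(others, 2), collapse = ",")
    }
  }
  rec <- make_records(
    contig = contig, pos = pos, ref = ref, alt = alt,
    qual = round(runif(n, 0, 120), 1),
    mq = round(runif(n, 0, 70), 1),
    dp = sample.int(60, n, replace = TRUE),
    alt_fwd = sample(0:6, n, replace = TRUE),
    alt_rev = sample(0:6, n, replace = TRUE)
  )
  # sprinkle missing annotations
  na_at <- function(x, p = 0.05) {
    x[runif(length(x)) < p] <- NA
    x
  }
  rec$qual <- na_at(rec$qual)
  rec$mq <- na_at(rec$mq)
  rec$dp <- na_at(rec$dp)
  rec
}
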