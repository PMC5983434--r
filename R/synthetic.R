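#' Synthetic cohort configuration
#'
#' Describes a multi-breed cohort with planted variants whose fate under the
#' pipeline is known by construction. Defaults emulate, at desk scale, a
#' seven-breed bull cohort with 10-20 samples per breed: planted
#' breed-specific fixed SNPs, SNPs fixed in all or in a subset of breeds,
#' segregating SNPs, and one decoy category per site filter (low quality,
#' low mapping quality, strand bias, depth outliers, duplicated positions,
#' SNP clusters, SNPs near InDels, InDel pairs, multi-allelic sites).
#'
#' @param breeds Breed names.
#' @param samples_per_breed Named integer vector, samples per breed.
#' @param contigs Named integer vector of contig lengths (bp).
#' @param n_breed_specific Planted breed-specific fixed SNPs per breed.
#' @param n_shared_all SNPs fixed in every breed.
#' @param n_partial Named integer vector: names are comma-joined breed
#'   subsets, values the number of SNPs fixed in exactly those breeds.
#' @param n_segregating Segregating (non-fixed) SNPs per breed.
#' @param n_lowqual,n_lowmq,n_strandbias,n_depth_outlier,n_multiallelic
#'   Single-record decoy counts (distributed round-robin across breeds).
#' @param n_duplicate_pos,n_snp_cluster,n_snp_near_indel,n_indel_pair
#'   Paired-record decoy counts (each unit plants two records).
#' @param missing_rate_range Per-site missing-genotype rate range for
#'   records meant to survive; kept strictly below the 7% threshold.
#' @param depth_mean,depth_sd Site-depth model (negative-binomial-like,
#'   clipped into the admissible window for records meant to survive).
#' @param n_genes Gene models carved into the reference (two-CDS
#'   transcripts, alternating strands) so consequence annotation can run.
#' @param seed Integer seed; all outputs are reproducible given the seed.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(
    breeds = c("ANG", "BSW", "FLV", "HER", "JER", "LIM", "SIM"),
    samples_per_breed = c(
      ANG = 20L, BSW = 16L, FLV = 10L, HER = 12L, JER = 11L,
      LIM = 12L, SIM = 18L
    ),
    contigs = c(chr1 = 700000L, chr2 = 500000L),
    n_breed_specific = 100L,
    n_shared_all = 300L,
    n_partial = c("JER,FLV" = 60L, "JER,BSW" = 50L, "ANG,SIM" = 40L),
    n_segregating = 400L,
    n_lowqual = 60L, n_lowmq = 60L, n_strandbias = 60L,
    n_depth_outlier = 60L, n_multiallelic = 60L,
    n_duplicate_pos = 40L, n_snp_cluster = 40L,
    n_snp_near_indel = 40L, n_indel_pair = 40L,
    missing_rate_range = c(0, 0.05),
    depth_mean = 12, depth_sd = 4,
    n_genes = 6L,
    seed = 1L) {
  if (is.null(names(samples_per_breed))) names(samples_per_breed) <- breeds
  stopifnot(
    all(breeds %in% names(samples_per_breed)),
    all(samples_per_breed >= 1L),
    length(contigs) >= 1L, all(contigs >= 1L),
    missing_rate_range[1] >= 0, missing_rate_range[2] <= 1,
    missing_rate_range[1] <= missing_rate_range[2]
  )
  if (length(n_partial)) {
    for (lbl in names(n_partial)) {
      sub <- strsplit(lbl, ",", fixed = TRUE)[[1]]
      if (!all(sub %in% breeds) || length(sub) < 2L) {
        abort(paste0("partial subset '", lbl, "' is not a valid multi-breed subset"))
      }
    }
  }
  structure(
    list(
      breeds = breeds,
      samples_per_breed = samples_per_breed[breeds],
      contigs = contigs,
      n_breed_specific = n_breed_specific, n_shared_all = n_shared_all,
      n_partial = n_partial, n_segregating = n_segregating,
      n_lowqual = n_lowqual, n_lowmq = n_lowmq, n_strandbias = n_strandbias,
      n_depth_outlier = n_depth_outlier, n_multiallelic = n_multiallelic,
      n_duplicate_pos = n_duplicate_pos, n_snp_cluster = n_snp_cluster,
      n_snp_near_indel = n_snp_near_indel, n_indel_pair = n_indel_pair,
      missing_rate_range = missing_rate_range,
      depth_mean = depth_mean, depth_sd = depth_sd,
      n_genes = n_genes, seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

#' Simulate a random reference genome
#'
#' Uniform A/C/G/T sequences, reproducible for a fixed seed.
#'
#' @param contigs Named integer vector of contig lengths.
#' @param seed Integer seed.
#' @return Named character vector of sequences.
#' @export
write_reference <- function(contigs, seed = 1L) {
  stopifnot(all(contigs >= 1L))
  set.seed(seed)
  vapply(contigs, function(len) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

#' Generate a synthetic multi-breed cohort
#'
#' Builds a random reference, carves gene models into it, plants the
#' configured variant categories at well-spaced positions (25 bp slots, so
#' planted units never interact through the proximity filter unless their
#' category demands it) and emits per-breed record tibbles plus the truth
#' table giving every planted record's category and expected pipeline fate.
#'
#' Category guarantees: breed-specific SNPs are homozygous-alternative in
#' every sample of their target breed (minus injected missingness below the
#' 7% threshold) and absent from all other breeds; shared and partial-subset
#' SNPs are fixed in their carrier breeds; segregating SNPs contain at least
#' one non-homozygous-alternative genotype; each decoy category violates
#' exactly one site filter and is planted in a single breed with fixed
#' genotypes, so a leaky filter would surface as a false breed-specific
#' call.
#'
#' @param config A [cohort_config()].
#' @return A list of class `breed_cohort`: `vcfs` (named list of per-breed
#'   records tibbles), `reference`, `models`, `truth` (tibble: `breed`,
#'   `contig`, `pos`, `ref`, `alt`, `key`, `category`, `expect_site_pass`,
#'   `expect_fixed`, `expect_specific`), `panel` and `config`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  set.seed(config$seed)
  ref <- write_reference(config$contigs, seed = config$seed + 1L)
  models <- carve_genes(ref, config)
  ref <- models$reference
  models <- models$models

  plan <- plant_plan(config)
  slots <- assign_slots(plan, config)
  plan$contig <- slots$contig
  plan$pos <- slots$pos + plan$offset

  tmpl_base <- function(contig, pos) {
    vapply(seq_along(pos), function(i) {
      toupper(substring(ref[[match(contig[i], names(config$contigs))]], pos[i], pos[i]))
    }, character(1))
  }
  plan$ref <- tmpl_base(plan$contig, plan$pos)
  plan <- make_alleles(plan, ref, config)

  samples <- lapply(config$breeds, function(b) {
    sprintf("%s_%02d", b, seq_len(config$samples_per_breed[[b]]))
  })
  names(samples) <- config$breeds
  panel <- tibble(
    breed = rep(config$breeds, lengths(samples)),
    sample = unlist(samples, use.names = FALSE)
  )

  vcfs <- lapply(config$breeds, function(b) {
    build_breed_records(plan, b, samples[[b]], config)
  })
  names(vcfs) <- config$breeds

  truth <- build_truth(plan, config)
  check_depth_separation(vcfs, truth, config)

  structure(
    list(
      vcfs = vcfs, reference = ref, models = models, truth = truth,
      panel = panel, config = config
    ),
    class = "breed_cohort"
  )
}

#' @export
print.breed_cohort <- function(x, ...) {
  cat("<breed_cohort> ", length(x$vcfs), " breeds, ",
    sum(vapply(x$vcfs, nrow, integer(1))), " records, ",
    nrow(x$truth), " truth rows\n",
    sep = ""
  )
  invisible(x)
}

# ---- internals ---------------------------------------------------------

# One row per planted record: category, unit id, carrier breeds, offset
# within the unit's slot, variant class.
plant_plan <- function(config) {
  b <- config$breeds
  rows <- list()
  add <- function(category, carriers, n_units, offsets, classes, fate) {
    if (n_units == 0L) {
      return()
    }
    k <- length(offsets)
    rows[[length(rows) + 1L]] <<- tibble(
      category = category,
      carriers = rep(list(carriers), n_units * k),
      unit = rep(seq_len(n_units), each = k),
      member = rep(seq_len(k), n_units),
      offset = rep(offsets, n_units),
      class = rep(classes, n_units),
      expect_site_pass = rep(fate$site, n_units),
      expect_fixed = rep(fate$fixed, n_units),
      expect_specific = rep(fate$specific, n_units)
    )
  }
  for (breed in b) {
    add(
      paste0("specific_", breed), breed, config$n_breed_specific,
      0L, "SNP", list(site = TRUE, fixed = TRUE, specific = TRUE)
    )
  }
  add(
    "shared_all", b, config$n_shared_all, 0L, "SNP",
    list(site = TRUE, fixed = TRUE, specific = FALSE)
  )
  for (lbl in names(config$n_partial)) {
    add(
      paste0("partial_", lbl), strsplit(lbl, ",", fixed = TRUE)[[1]],
      config$n_partial[[lbl]], 0L, "SNP",
      list(site = TRUE, fixed = TRUE, specific = FALSE)
    )
  }
  for (breed in b) {
    add(
      paste0("segregating_", breed), breed, config$n_segregating,
      0L, "SNP", list(site = TRUE, fixed = FALSE, specific = FALSE)
    )
  }
  # single-record decoys, round-robin over breeds
  decoy1 <- c(
    lowqual = config$n_lowqual, lowmq = config$n_lowmq,
    strandbias = config$n_strandbias, depth_outlier = config$n_depth_outlier,
    multiallelic = config$n_multiallelic
  )
  for (cat in names(decoy1)) {
    n <- decoy1[[cat]]
    if (n == 0L) next
    carrier <- b[(seq_len(n) - 1L) %% length(b) + 1L]
    rows[[length(rows) + 1L]] <- tibble(
      category = cat, carriers = lapply(carrier, identity),
      unit = seq_len(n), member = 1L, offset = 0L, class = "SNP",
      expect_site_pass = FALSE, expect_fixed = FALSE, expect_specific = FALSE
    )
  }
  decoy2 <- list(
    duplicate_pos = list(
      n = config$n_duplicate_pos, offsets = c(0L, 0L),
      classes = c("SNP", "SNP"), site = c(FALSE, FALSE)
    ),
    snp_cluster = list(
      n = config$n_snp_cluster, offsets = c(0L, 2L),
      classes = c("SNP", "SNP"), site = c(FALSE, FALSE)
    ),
    snp_near_indel = list(
      n = config$n_snp_near_indel, offsets = c(0L, 4L),
      classes = c("SNP", "INDEL"), site = c(FALSE, TRUE)
    ),
    indel_pair = list(
      n = config$n_indel_pair, offsets = c(0L, 9L),
      classes = c("INDEL", "INDEL"), site = c(FALSE, FALSE)
    )
  )
  for (cat in names(decoy2)) {
    d <- decoy2[[cat]]
    if (d$n == 0L) next
    carrier <- b[(seq_len(d$n) - 1L + 3L) %% length(b) + 1L]
    for (i in seq_len(d$n)) {
      k <- length(d$offsets)
      rows[[length(rows) + 1L]] <- tibble(
        category = cat, carriers = rep(list(carrier[i]), k),
        unit = i, member = seq_len(k), offset = d$offsets, class = d$classes,
        expect_site_pass = d$site,
        expect_fixed = FALSE, expect_specific = FALSE
      )
    }
  }
  out <- list_rbind(rows)
  out$record_id <- seq_len(nrow(out))
  out
}

# Slot base positions: one 25 bp slot per planted unit, sampled without
# replacement over all contigs so units never sit closer than 16 bp.
slot_positions <- function(config) {
  grid <- list_rbind(lapply(names(config$contigs), function(ctg) {
    len <- config$contigs[[ctg]]
    upper <- len - 30L
    if (upper < 30L) {
      return(tibble(contig = character(), pos = integer()))
    }
    tibble(contig = ctg, pos = seq(30L, upper, by = 25L))
  }))
  grid
}

# Assign each unit a slot, expanding to per-record rows.
assign_slots <- function(plan, config) {
  unit_key <- paste(plan$category, plan$unit)
  units <- unique(unit_key)
  grid <- slot_positions(config)
  if (length(units) > nrow(grid)) {
    abort(paste0(
      "requested planted counts (", length(units),
      " units) exceed contig capacity (", nrow(grid), " slots)"
    ))
  }
  pick <- grid[sample.int(nrow(grid), length(units)), , drop = FALSE]
  idx <- match(unit_key, units)
  list(contig = pick$contig[idx], pos = pick$pos[idx])
}

make_alleles <- function(plan, ref, config) {
  bases <- c("A", "C", "G", "T")
  n <- nrow(plan)
  alt <- character(n)
  for (i in seq_len(n)) {
    alt[i] <- sample(setdiff(bases, plan$ref[i]), 1L)
  }
  plan$alt <- alt
  # second ALT for multi-allelic decoys
  plan$alt2 <- NA_character_
  ma <- plan$category == "multiallelic"
  if (any(ma)) {
    plan$alt2[ma] <- vapply(which(ma), function(i) {
      sample(setdiff(bases, c(plan$ref[i], plan$alt[i])), 1L)
    }, character(1))
  }
  # duplicate-position pairs must differ in ALT
  dup <- which(plan$category == "duplicate_pos" & plan$member == 1L)
  for (i in dup) {
    j <- i + 1L # the paired record follows by construction
    if (plan$alt[j] == plan$alt[i]) {
      plan$alt[j] <- sample(setdiff(bases, c(plan$ref[i], plan$alt[i])), 1L)
    }
  }
  # InDels: 1 bp deletion (ref = base + next base, alt = base)
  ind <- which(plan$class == "INDEL")
  if (length(ind)) {
    nxt <- vapply(ind, function(i) {
      toupper(substring(
        ref[[match(plan$contig[i], names(config$contigs))]],
        plan$pos[i] + 1L, plan$pos[i] + 1L
      ))
    }, character(1))
    plan$alt[ind] <- plan$ref[ind]
    plan$ref[ind] <- paste0(plan$ref[ind], nxt)
  }
  plan
}

draw_depth <- function(n, config, kind = c("survivor", "outlier")) {
  kind <- match.arg(kind)
  mu <- config$depth_mean
  sdv <- config$depth_sd
  if (kind == "outlier") {
    return(rep(as.integer(round(mu + 12 * sdv)), n))
  }
  size <- mu^2 / max(sdv^2 - mu, 0.5)
  d <- rnbinom(n, mu = mu, size = size)
  lo <- 10L
  hi <- as.integer(ceiling(mu + sdv))
  as.integer(pmin(pmax(d, lo), hi))
}

make_gt <- function(n_samples, samples, kind, n_missing = 0L, n_alts = 1L) {
  g <- matrix(1L, nrow = n_samples, ncol = 2, dimnames = list(samples, NULL))
  if (kind == "segregating") {
    pick <- sample(3L, n_samples, replace = TRUE, prob = c(0.3, 0.4, 0.3))
    g[pick == 1L, ] <- 0L
    g[pick == 2L, 1L] <- 0L
    # guarantee at least one non hom-alt genotype
    if (all(pick == 3L)) {
      g[1L, 1L] <- 0L
    }
  } else if (kind == "multiallelic") {
    half <- seq_len(n_samples) %% 2L == 0L
    g[half, ] <- 2L
  }
  if (n_missing > 0L) {
    g[sample.int(n_samples, n_missing), ] <- NA_integer_
  }
  g
}

build_breed_records <- function(plan, breed, samples, config) {
  mine <- plan[vapply(plan$carriers, function(cc) breed %in% cc, logical(1)), ,
    drop = FALSE
  ]
  n <- nrow(mine)
  ns <- length(samples)
  if (n == 0L) {
    return(empty_records(samples))
  }
  qual <- round(runif(n, 60, 200), 1)
  mq <- round(runif(n, 40, 60), 1)
  dp <- draw_depth(n, config)
  is_out <- mine$category == "depth_outlier"
  dp[is_out] <- draw_depth(sum(is_out), config, "outlier")
  qual[mine$category == "lowqual"] <- round(runif(sum(mine$category == "lowqual"), 2, 19.5), 1)
  mq[mine$category == "lowmq"] <- round(runif(sum(mine$category == "lowmq"), 2, 29.5), 1)

  seg <- mine$category %in% paste0("segregating_", config$breeds)
  alt_f <- ifelse(seg, pmax(1L, dp %/% 4L), dp %/% 2L)
  alt_r <- ifelse(seg, pmax(1L, dp %/% 4L), dp - dp %/% 2L)
  ref_f <- ifelse(seg, pmax(0L, (dp - alt_f - alt_r) %/% 2L), 0L)
  ref_r <- ifelse(seg, pmax(0L, dp - alt_f - alt_r - ref_f), 0L)
  sb <- mine$category == "strandbias"
  alt_r[sb] <- alt_r[sb] + alt_f[sb]
  alt_f[sb] <- 0L

  cap <- floor(0.07 * ns)
  lo <- config$missing_rate_range[1]
  hi <- config$missing_rate_range[2]
  miss_n <- pmin(floor(runif(n, lo, hi) * ns), cap)
  miss_n[seg] <- 0L # missingness never masks the segregating guarantee

  gt <- lapply(seq_len(n), function(i) {
    kind <- if (seg[i]) {
      "segregating"
    } else if (mine$category[i] == "multiallelic") {
      "multiallelic"
    } else {
      "fixed"
    }
    make_gt(ns, samples, kind, n_missing = miss_n[i])
  })

  alts <- lapply(seq_len(n), function(i) {
    if (is.na(mine$alt2[i])) mine$alt[i] else c(mine$alt[i], mine$alt2[i])
  })

  out <- tibble(
    contig = mine$contig,
    pos = mine$pos,
    id = NA_character_,
    ref = mine$ref,
    alts = alts,
    qual = qual,
    filter = ".",
    mq = mq,
    dp = dp,
    dp4_ref_fwd = ref_f,
    dp4_ref_rev = ref_r,
    dp4_alt_fwd = alt_f,
    dp4_alt_rev = alt_r,
    format = "GT",
    gt = gt
  )
  out <- out[order(out$contig, out$pos), , drop = FALSE]
  attr(out, "samples") <- samples
  out
}

build_truth <- function(plan, config) {
  rows <- lapply(seq_len(nrow(plan)), function(i) {
    carriers <- plan$carriers[[i]]
    tibble(
      breed = carriers,
      contig = plan$contig[i],
      pos = plan$pos[i],
      ref = plan$ref[i],
      alt = plan$alt[i],
      category = plan$category[i],
      class = plan$class[i],
      expect_site_pass = plan$expect_site_pass[i],
      expect_fixed = plan$expect_fixed[i],
      expect_specific = plan$expect_specific[i]
    )
  })
  out <- list_rbind(rows)
  out$key <- paste0(out$contig, ":", out$pos, ":", out$ref, ">", out$alt)
  out
}

# Internal consistency check: within each breed, the depth ceiling the
# cascade will estimate must separate planted survivors from the planted
# depth outliers.
check_depth_separation <- function(vcfs, truth, config) {
  for (b in names(vcfs)) {
    rec <- vcfs[[b]]
    tr <- truth[truth$breed == b, ]
    m <- match(paste(rec$contig, rec$pos), paste(tr$contig, tr$pos))
    cat_ <- tr$category[m]
    pool <- !(cat_ %in% c("lowqual", "lowmq", "strandbias", "multiallelic"))
    dp <- rec$dp[pool]
    if (length(dp) < 2L) next
    ceiling_ <- median(dp) + config$dp_sigma_mult %||% 3 * sd(dp)
    surv <- rec$dp[pool & cat_ != "depth_outlier"]
    outl <- rec$dp[cat_ == "depth_outlier"]
    if (length(surv) && max(surv) > ceiling_) {
      abort("synthetic cohort: survivor depth exceeds the implied ceiling; lower depth_sd or counts")
    }
    if (length(outl) && min(outl) <= ceiling_) {
      abort("synthetic cohort: depth outliers fall under the implied ceiling; raise their depth")
    }
  }
  invisible(TRUE)
}

#' Write a cohort to disk
#'
#' Emits one VCF per breed, the reference FASTA, the gene models (GFF3), the
#' breed panel TSV, the truth table TSV and a JSON echo of the
#' configuration.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return Named list of file paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  for (b in names(cohort$vcfs)) {
    p <- file.path(dir, paste0(b, ".vcf"))
    write_vcf(cohort$vcfs[[b]], p)
    paths[[paste0("vcf_", b)]] <- p
  }
  paths$reference <- file.path(dir, "reference.fa")
  write_fasta(cohort$reference, paths$reference)
  paths$panel <- file.path(dir, "panel.tsv")
  write_panel(cohort$panel, paths$panel)
  paths$truth <- file.path(dir, "truth.tsv")
  utils::write.table(cohort$truth,
    file = paths$truth, sep = "\t",
    quote = FALSE, row.names = FALSE
  )
  if (!is.null(cohort$models) && nrow(cohort$models) > 0L) {
    paths$gff3 <- file.path(dir, "genes.gff3")
    write_gff3(cohort$models, paths$gff3)
  }
  paths$config <- file.path(dir, "config.json")
  cfg <- cohort$config
  class(cfg) <- NULL
  cfg$n_partial <- as.list(cfg$n_partial)
  jsonlite::write_json(cfg, paths$config, auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

# Overwrite reserved genome windows with valid ORFs so that consequence
# annotation has real coding sequence to work on. Two CDS segments per
# transcript, alternating strands.
carve_genes <- function(ref, config) {
  n_genes <- config$n_genes
  if (n_genes == 0L) {
    return(list(reference = ref, models = gene_model("x", "x", "+", 1, 3)[0, ]))
  }
  ctg <- names(config$contigs)[1]
  len <- config$contigs[[1]]
  l1 <- 300L
  l2 <- 303L
  intron <- 200L
  gene_span <- l1 + intron + l2
  gap <- 400L
  first <- len - n_genes * (gene_span + gap) - 100L
  if (first < 1L) {
    abort("contig 1 too short for the requested gene models")
  }
  models <- vector("list", n_genes)
  s <- ref[[1]]
  codons <- setdiff(names(Biostrings::GENETIC_CODE), c("TAA", "TAG", "TGA"))
  for (g in seq_len(n_genes)) {
    start <- first + (g - 1L) * (gene_span + gap)
    orf <- paste0(
      "ATG",
      paste(sample(codons, (l1 + l2) / 3 - 2L, replace = TRUE), collapse = ""),
      "TAA"
    )
    strand <- if (g %% 2L == 1L) "+" else "-"
    genomic <- if (strand == "+") orf else revcomp(orf)
    substring(s, start, start + l1 - 1L) <- substring(genomic, 1L, l1)
    substring(s, start + l1 + intron, start + gene_span - 1L) <-
      substring(genomic, l1 + 1L, l1 + l2)
    models[[g]] <- gene_model(
      sprintf("tx%02d", g), ctg, strand,
      cds_start = c(start, start + l1 + intron),
      cds_end = c(start + l1 - 1L, start + gene_span - 1L)
    )
  }
  ref[[1]] <- s
  list(reference = ref, models = list_rbind(models))
}
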