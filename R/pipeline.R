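#' Pipeline configuration
#'
#' @param vcfs Named character vector: breed name -> per-breed VCF path.
#' @param panel Path to the breed panel TSV.
#' @param reference Path to the reference FASTA.
#' @param gff3 Optional path to a GFF3 gene model (enables consequence
#'   annotation).
#' @param bed Optional path to a BED feature file (enables feature overlap).
#' @param out_dir Output directory.
#' @param site_config A [site_filter_config()].
#' @param breed_config A [breed_filter_config()].
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(vcfs, panel, reference, out_dir,
                            gff3 = NULL, bed = NULL,
                            site_config = site_filter_config(),
                            breed_config = breed_filter_config()) {
  if (is.null(names(vcfs)) || any(!nzchar(names(vcfs)))) {
    abort("`vcfs` must be a named vector: breed -> VCF path")
  }
  for (p in c(unname(vcfs), panel, reference, gff3, bed)) {
    if (!file.exists(p)) {
      abort(paste0("input path does not exist: ", p))
    }
  }
  structure(
    list(
      vcfs = vcfs, panel = panel, reference = reference, gff3 = gff3,
      bed = bed, out_dir = out_dir, site_config = site_config,
      breed_config = breed_config
    ),
    class = "pipeline_config"
  )
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("stage '", stage, "' failed: ", conditionMessage(e)))
  })
}

write_tsv_plain <- function(df, path) {
  df <- as.data.frame(df)
  list_cols <- vapply(df, is.list, logical(1))
  df <- df[, !list_cols, drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the breed-specific SNP pipeline end to end
#'
#' Stage order: per-breed site-filter cascade; within-breed fixation
#' filtering; cross-breed Venn partition and breed-specific set extraction;
#' consensus reference construction per breed; optional consequence
#' annotation (GFF3) and feature overlap (BED); summary reports. Every
#' artifact is written under `out_dir` and listed in a manifest with an MD5
#' checksum, so reruns on identical inputs are byte-identical.
#'
#' @param config A [pipeline_config()].
#' @return An object of class `breed_pipeline`: `manifest` (tibble
#'   `artifact`, `path`, `md5`), `venn`, `specific`, `fixed`, `filtration`,
#'   `composition`, `consequences` (or `NULL`), `overlaps` (or `NULL`) and
#'   `traces` (named list of per-breed filter traces).
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  panel <- run_stage("read_panel", read_panel(config$panel))
  template <- run_stage("read_reference", read_fasta(config$reference))
  breeds <- names(config$vcfs)
  paths <- character(0)

  emit <- function(name, path) {
    paths[[name]] <<- path
  }

  traces <- list()
  fixed_list <- list()
  raw_snp_counts <- integer(0)
  for (b in breeds) {
    rec <- run_stage(paste0("read_vcf:", b), read_vcf(config$vcfs[[b]]))
    raw_snp_counts[[b]] <- sum(classify_variant(rec) %in% "SNP")
    sf <- run_stage(paste0("site_filter:", b), apply_site_filters(rec, config$site_config))
    traces[[b]] <- sf$trace
    fvcf <- file.path(config$out_dir, paste0(b, ".filtered.vcf"))
    write_vcf(sf$kept, fvcf, samples = vcf_samples(rec))
    emit(paste0("filtered_vcf_", b), fvcf)
    ftr <- file.path(config$out_dir, paste0(b, ".trace.tsv"))
    write_tsv_plain(sf$trace, ftr)
    emit(paste0("trace_", b), ftr)

    breed_samples <- panel$sample[panel$breed == b]
    fixed <- run_stage(
      paste0("breed_filter:", b),
      fixed_alt_sites(sf$kept, breed_samples, config$breed_config)
    )
    fixed_list[[b]] <- fixed
    fks <- file.path(config$out_dir, paste0(b, ".fixed.tsv"))
    write_tsv_plain(fixed, fks)
    emit(paste0("fixed_", b), fks)
  }

  keys <- list_rbind(imap(fixed_list, function(df, b) {
    tibble(breed = b, key = df$key)
  }))
  venn <- run_stage("specificity", venn_partition(keys, breeds = breeds))
  specific <- breed_specific_sets(keys, breeds = breeds)
  vp <- file.path(config$out_dir, "venn.tsv")
  write_tsv_plain(venn, vp)
  emit("venn", vp)

  for (b in breeds) {
    sp_b <- specific[specific$breed == b, , drop = FALSE]
    sp <- file.path(config$out_dir, paste0(b, ".specific.tsv"))
    write_tsv_plain(parse_variant_key(sp_b$key), sp)
    emit(paste0("specific_", b), sp)

    cons <- run_stage(
      paste0("consensus:", b),
      build_breed_reference(parse_variant_key(sp_b$key), template)
    )
    fa <- file.path(config$out_dir, paste0(b, ".reference.fa"))
    write_fasta(cons$sequences, fa)
    emit(paste0("reference_", b), fa)
    lg <- file.path(config$out_dir, paste0(b, ".substitutions.tsv"))
    write_tsv_plain(cons$log, lg)
    emit(paste0("substitutions_", b), lg)
  }

  filtration <- filtration_summary(tibble(
    breed = breeds,
    total_snps = unname(raw_snp_counts[breeds]),
    after_filtration = vapply(fixed_list[breeds], nrow, integer(1))
  ))
  fp <- file.path(config$out_dir, "filtration_summary.tsv")
  write_tsv_plain(filtration, fp)
  emit("filtration_summary", fp)

  composition <- cohort_composition(panel)
  cp <- file.path(config$out_dir, "cohort_composition.tsv")
  write_tsv_plain(composition, cp)
  emit("cohort_composition", cp)

  consequences <- NULL
  if (!is.null(config$gff3)) {
    models <- run_stage("read_gff3", read_gene_models(config$gff3))
    calls <- list_rbind(imap(split(specific, specific$breed), function(df, b) {
      ann <- annotate_snvs(parse_variant_key(df$key), models, template)
      if (nrow(ann)) dplyr::bind_cols(tibble(breed = b), ann) else NULL
    }))
    consequences <- consequence_summary(calls %||% tibble(breed = character(), term = character()))
    qp <- file.path(config$out_dir, "consequence_summary.tsv")
    write_tsv_plain(consequences, qp)
    emit("consequence_summary", qp)
  }

  overlaps <- NULL
  if (!is.null(config$bed)) {
    features <- run_stage("read_bed", read_bed(config$bed))
    overlaps <- overlap_features(parse_variant_key(specific$key), features)
    op <- file.path(config$out_dir, "feature_overlaps.tsv")
    write_tsv_plain(overlaps, op)
    emit("feature_overlaps", op)
  }

  manifest <- tibble(
    artifact = names(paths),
    path = unname(unlist(paths)),
    md5 = unname(tools::md5sum(unlist(paths)))
  )
  mp <- file.path(config$out_dir, "manifest.tsv")
  write_tsv_plain(manifest, mp)

  structure(
    list(
      manifest = manifest, venn = venn, specific = specific,
      fixed = fixed_list, filtration = filtration,
      composition = composition, consequences = consequences,
      overlaps = overlaps, traces = traces
    ),
    class = "breed_pipeline"
  )
}

#' @export
print.breed_pipeline <- function(x, ...) {
  cat("<breed_pipeline> ", nrow(x$filtration), " breeds, ",
    sum(x$venn$count), " fixed keys in union, ",
    nrow(x$specific), " breed-specific\n",
    sep = ""
  )
  invisible(x)
}

#' @rdname run_pipeline
#' @param x A `breed_pipeline` object.
#' @param ... Unused.
#' @method tidy breed_pipeline
#' @export
tidy.breed_pipeline <- function(x, ...) {
  x$specific
}

#' @rdname run_pipeline
#' @method glance breed_pipeline
#' @export
glance.breed_pipeline <- function(x, ...) {
  tibble(
    n_breeds = nrow(x$filtration),
    n_fixed_union = sum(x$venn$count),
    n_specific = nrow(x$specific),
    n_artifacts = nrow(x$manifest)
  )
}
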