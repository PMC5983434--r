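CONSEQUENCE_SEVERITY <- c(
  "start_lost", "stop_gained", "stop_lost", "missense_variant",
  "splice_region_variant", "synonymous_variant", "intron_variant",
  "intergenic_variant"
)

CODING_TERMS <- c(
  "synonymous_variant", "missense_variant", "stop_gained", "stop_lost",
  "start_lost", "splice_region_variant"
)

#' Construct a gene model
#'
#' @param transcript Transcript ID.
#' @param contig Contig name.
#' @param strand `"+"` or `"-"`.
#' @param cds_start,cds_end Integer vectors of 1-based inclusive CDS segment
#'   bounds, in genome order. Segments must be non-overlapping and sorted.
#' @return A one-row tibble with a `cds` list-column, row-bindable into a
#'   gene-model table.
#' @export
gene_model <- function(transcript, contig, strand, cds_start, cds_end) {
  stopifnot(strand %in% c("+", "-"), length(cds_start) == length(cds_end))
  o <- order(cds_start)
  cds_start <- as.integer(cds_start[o])
  cds_end <- as.integer(cds_end[o])
  if (any(cds_end < cds_start)) {
    abort("CDS segment with end < start")
  }
  if (length(cds_start) > 1L && any(cds_start[-1] <= cds_end[-length(cds_end)])) {
    abort("overlapping CDS segments")
  }
  tibble(
    transcript = transcript, contig = contig, strand = strand,
    cds = list(cbind(start = cds_start, end = cds_end))
  )
}

#' Read CDS gene models from a GFF3 file
#'
#' Features of type `CDS` are grouped by their `Parent` attribute into
#' transcripts. Coordinates are GFF3 1-based inclusive.
#'
#' @param path Path to a GFF3 file.
#' @return A gene-model tibble (`transcript`, `contig`, `strand`, `cds`
#'   list-column), one row per transcript.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  cds <- gr[tolower(as.character(gr$type)) == "cds"]
  if (length(cds) == 0L) {
    abort(paste0("no CDS features in ", path))
  }
  parent <- as.character(BiocGenerics::unlist(cds$Parent))
  if (length(parent) != length(cds)) {
    abort("every CDS feature needs exactly one Parent")
  }
  df <- tibble(
    transcript = parent,
    contig = as.character(GenomicRanges::seqnames(cds)),
    strand = as.character(GenomicRanges::strand(cds)),
    start = GenomicRanges::start(cds),
    end = GenomicRanges::end(cds)
  )
  df %>%
    group_by(.data$transcript) %>%
    summarise(
      contig = .data$contig[1],
      strand = .data$strand[1],
      cds = list(cbind(
        start = as.integer(sort(.data$start)),
        end = as.integer(.data$end[order(.data$start)])
      )),
      .groups = "drop"
    )
}

#' Write gene models as GFF3
#'
#' @param models Gene-model tibble as produced by [gene_model()] or
#'   [read_gene_models()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(models, path) {
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(models))) {
    cds <- models$cds[[i]]
    span <- c(min(cds[, "start"]), max(cds[, "end"]))
    lines <- c(
      lines,
      paste(models$contig[i], "breedsnp", "mRNA", span[1], span[2], ".",
        models$strand[i], ".", paste0("ID=", models$transcript[i]),
        sep = "\t"
      ),
      vapply(seq_len(nrow(cds)), function(j) {
        paste(models$contig[i], "breedsnp", "CDS", cds[j, "start"], cds[j, "end"],
          ".", models$strand[i], "0", paste0(
            "ID=", models$transcript[i], ".cds", j,
            ";Parent=", models$transcript[i]
          ),
          sep = "\t"
        )
      }, character(1))
    )
  }
  writeLines(lines, path)
  invisible(path)
}

#' Extract the spliced CDS sequence of a model
#'
#' Concatenates the CDS segments from the template and reverse-complements
#' for minus-strand models, yielding the coding sequence 5' to 3'.
#'
#' @param model One row of a gene-model tibble.
#' @param template Named character vector of reference sequences.
#' @return Uppercase coding sequence string.
#' @export
cds_sequence <- function(model, template) {
  s <- template_seq(template, model$contig)
  cds <- model$cds[[1]]
  parts <- substring(s, cds[, "start"], cds[, "end"])
  out <- toupper(paste(parts, collapse = ""))
  if (model$strand == "-") out <- revcomp(out)
  out
}

template_seq <- function(template, contig) {
  i <- match(contig, fasta_contig_ids(template))
  if (is.na(i)) {
    abort(paste0("contig '", contig, "' not present in the template"))
  }
  template[[i]]
}

revcomp <- function(s) {
  chartr("ACGTacgt", "TGCAtgca", vapply(s, function(x) {
    paste(rev(strsplit(x, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE))
}

translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[toupper(codon)]
  aa[is.na(aa)] <- "X"
  unname(aa)
}

#' Annotate SNVs with coding consequences
#'
#' A simplified single-nucleotide consequence classifier over a CDS gene
#' model. For a SNV inside a CDS the affected codon is rebuilt from the
#' template (reverse-complemented on the minus strand), both codons are
#' translated with the standard genetic code, and the change is classified
#' as `synonymous_variant`, `missense_variant`, `stop_gained`, `stop_lost`
#' or `start_lost`. Variants at a CDS/intron junction — the 1–8 intronic or
#' the 1–3 terminal exonic bases — are `splice_region_variant` (the exonic
#' splice-region label is only reported when no protein-changing consequence
#' applies). Otherwise the call is `intron_variant` inside a transcript span
#' and `intergenic_variant` outside all of them. When several transcripts
#' overlap a variant, the most severe consequence wins (severity:
#' start_lost > stop_gained > stop_lost > missense > splice_region >
#' synonymous > intron > intergenic).
#'
#' @param snps Tibble of SNP keys: columns `contig`, `pos`, `ref`, `alt`
#'   (single bases).
#' @param models Gene-model tibble ([gene_model()] / [read_gene_models()]).
#' @param template Named character vector of reference sequences.
#' @return A tibble: `contig`, `pos`, `ref`, `alt`, `key`, `transcript`
#'   (`NA` for intergenic), `term`, `ref_codon`, `alt_codon` (both `NA`
#'   unless the term is one of the five codon-level terms).
#' @export
annotate_snvs <- function(snps, models, template) {
  if (nrow(snps) == 0L) {
    return(tibble(
      contig = character(), pos = integer(), ref = character(),
      alt = character(), key = character(), transcript = character(),
      term = character(), ref_codon = character(), alt_codon = character()
    ))
  }
  bad <- nchar(snps$ref) != 1L | nchar(snps$alt) != 1L
  if (any(bad)) {
    abort("annotate_snvs() handles single-base substitutions only")
  }
  calls <- lapply(seq_len(nrow(snps)), function(i) {
    annotate_one(
      snps$contig[i], snps$pos[i], toupper(snps$ref[i]), toupper(snps$alt[i]),
      models, template
    )
  })
  out <- list_rbind(calls)
  out$contig <- snps$contig
  out$pos <- snps$pos
  out$ref <- toupper(snps$ref)
  out$alt <- toupper(snps$alt)
  out$key <- variant_key(out)
  out[, c(
    "contig", "pos", "ref", "alt", "key", "transcript", "term",
    "ref_codon", "alt_codon"
  )]
}

annotate_one <- function(contig, pos, ref, alt, models, template) {
  tmpl_base <- toupper(substring(template_seq(template, contig), pos, pos))
  if (nzchar(tmpl_base) && tmpl_base != ref) {
    abort(paste0(
      "reference mismatch at ", contig, ":", pos, ": variant ref ", ref,
      ", template ", tmpl_base
    ))
  }
  best <- tibble(
    transcript = NA_character_, term = "intergenic_variant",
    ref_codon = NA_character_, alt_codon = NA_character_
  )
  best_rank <- match("intergenic_variant", CONSEQUENCE_SEVERITY)
  hits <- models[models$contig == contig, , drop = FALSE]
  for (i in seq_len(nrow(hits))) {
    call <- annotate_in_transcript(hits[i, ], pos, ref, alt, template)
    if (is.null(call)) next
    r <- match(call$term, CONSEQUENCE_SEVERITY)
    if (r < best_rank) {
      best <- call
      best_rank <- r
    }
  }
  best
}

# Consequence of the SNV within one transcript, or NULL when the variant
# lies outside the transcript span.
annotate_in_transcript <- function(model, pos, ref, alt, template) {
  cds <- model$cds[[1]]
  span <- c(min(cds[, "start"]), max(cds[, "end"]))
  if (pos < span[1] - 0L || pos > span[2]) {
    return(NULL)
  }
  seg <- which(pos >= cds[, "start"] & pos <= cds[, "end"])
  out <- function(term, rc = NA_character_, ac = NA_character_) {
    tibble(
      transcript = model$transcript, term = term,
      ref_codon = rc, alt_codon = ac
    )
  }
  if (length(seg) == 1L) {
    cc <- codon_change(model, cds, seg, pos, ref, alt, template)
    term <- classify_codon_change(cc)
    if (term == "synonymous_variant" && exonic_splice_region(cds, pos)) {
      return(out("splice_region_variant"))
    }
    return(out(term, cc$ref_codon, cc$alt_codon))
  }
  # intronic (between CDS segments): splice region within 8 bp of a junction
  if (intronic_splice_region(cds, pos)) {
    return(out("splice_region_variant"))
  }
  out("intron_variant")
}

# TRUE when pos sits in the terminal 1-3 exonic bases of an internal
# CDS/intron junction.
exonic_splice_region <- function(cds, pos) {
  n <- nrow(cds)
  if (n < 2L) {
    return(FALSE)
  }
  donor_ends <- cds[-n, "end"] # junctions after these
  acceptor_starts <- cds[-1, "start"] # junctions before these
  any(pos >= donor_ends - 2L & pos <= donor_ends) ||
    any(pos >= acceptor_starts & pos <= acceptor_starts + 2L)
}

# TRUE when pos is 1-8 intronic bases from an internal junction.
intronic_splice_region <- function(cds, pos) {
  n <- nrow(cds)
  if (n < 2L) {
    return(FALSE)
  }
  donor_ends <- cds[-n, "end"]
  acceptor_starts <- cds[-1, "start"]
  any(pos >= donor_ends + 1L & pos <= donor_ends + 8L) ||
    any(pos >= acceptor_starts - 8L & pos <= acceptor_starts - 1L)
}

# Reconstruct the affected codon (cDNA orientation) and its mutated form.
codon_change <- function(model, cds, seg, pos, ref, alt, template) {
  seg_len <- cds[, "end"] - cds[, "start"] + 1L
  if (model$strand == "+") {
    offset <- sum(seg_len[seq_len(seg - 1L)]) + (pos - cds[seg, "start"])
  } else {
    after <- if (seg < nrow(cds)) sum(seg_len[(seg + 1L):nrow(cds)]) else 0L
    offset <- after + (cds[seg, "end"] - pos)
  }
  codon_idx <- offset %/% 3L # 0-based codon number
  in_codon <- offset %% 3L # 0-based position within codon
  cdna <- cds_sequence(model, template)
  codon_start <- codon_idx * 3L + 1L
  if (codon_start + 2L > nchar(cdna)) {
    # trailing partial codon of an incomplete model: treat as synonymous-safe
    return(list(
      ref_codon = NA_character_, alt_codon = NA_character_,
      codon_idx = codon_idx, partial = TRUE
    ))
  }
  ref_codon <- substring(cdna, codon_start, codon_start + 2L)
  base <- if (model$strand == "+") alt else revcomp(alt)
  alt_codon <- ref_codon
  substring(alt_codon, in_codon + 1L, in_codon + 1L) <- base
  list(
    ref_codon = ref_codon, alt_codon = alt_codon,
    codon_idx = codon_idx, partial = FALSE
  )
}

classify_codon_change <- function(cc) {
  if (isTRUE(cc$partial)) {
    return("synonymous_variant")
  }
  ref_aa <- translate_codon(cc$ref_codon)
  alt_aa <- translate_codon(cc$alt_codon)
  if (cc$codon_idx == 0L && cc$ref_codon == "ATG" && cc$alt_codon != "ATG") {
    return("start_lost")
  }
  if (ref_aa != "*" && alt_aa == "*") {
    return("stop_gained")
  }
  if (ref_aa == "*" && alt_aa != "*") {
    return("stop_lost")
  }
  if (ref_aa == alt_aa) {
    return("synonymous_variant")
  }
  "missense_variant"
}

#' Summarise consequence calls per breed
#'
#' Counts calls per term and expresses each coding-region term (the five
#' codon-level terms plus `splice_region_variant`) as a percentage of the
#' breed's coding-region calls, rounded half-up to one decimal.
#'
#' @param calls A tibble of [annotate_snvs()] output with a `breed` column
#'   (stack per-breed calls with `dplyr::bind_rows(.id = "breed")`).
#' @return A tibble `breed`, `term`, `count`, `pct_coding` (`NA` for
#'   non-coding terms).
#' @export
consequence_summary <- function(calls) {
  if (nrow(calls) == 0L) {
    return(tibble(
      breed = character(), term = character(), count = integer(),
      pct_coding = numeric()
    ))
  }
  if (is.null(calls[["breed"]])) {
    calls$breed <- "all"
  }
  calls %>%
    count(.data$breed, .data$term, name = "count") %>%
    group_by(.data$breed) %>%
    mutate(
      coding_total = sum(.data$count[.data$term %in% CODING_TERMS]),
      pct_coding = ifelse(
        .data$term %in% CODING_TERMS & .data$coding_total > 0L,
        round_half_up(100 * .data$count / .data$coding_total, 1),
        NA_real_
      )
    ) %>%
    ungroup() %>%
    select("breed", "term", "count", "pct_coding")
}

#' Overlap variant keys with BED features
#'
#' BED intervals are 0-based half-open; a variant at 1-based position `p`
#' overlaps `[start, end)` iff `start <= p - 1 < end`.
#'
#' @param snps Tibble of variant keys (`contig`, `pos`, plus any other
#'   columns, carried through).
#' @param features Tibble with columns `contig`, `start`, `end` and
#'   optionally `name` (defaults to `contig:start-end`), e.g. from
#'   [read_bed()].
#' @return A tibble with one row per (feature, overlapping variant):
#'   `feature`, then the columns of `snps`.
#' @export
overlap_features <- function(snps, features) {
  if (any(features$start >= features$end)) {
    i <- which(features$start >= features$end)[1]
    abort(paste0(
      "malformed interval ", features$contig[i], ":[", features$start[i],
      ",", features$end[i], ")"
    ))
  }
  if (is.null(features[["name"]])) {
    features$name <- paste0(
      features$contig, ":", features$start, "-", features$end
    )
  }
  hits <- lapply(seq_len(nrow(features)), function(i) {
    hit <- snps$contig == features$contig[i] &
      snps$pos - 1L >= features$start[i] & snps$pos - 1L < features$end[i]
    if (!any(hit)) {
      return(NULL)
    }
    dplyr::bind_cols(tibble(feature = features$name[i]), snps[hit, , drop = FALSE])
  })
  out <- list_rbind(hits)
  if (is.null(out) || nrow(out) == 0L) {
    return(dplyr::bind_cols(tibble(feature = character()), snps[0, , drop = FALSE]))
  }
  out
}

#' Read a BED file of feature intervals
#'
#' @param path Path to a BED file (0-based half-open intervals).
#' @return A tibble `contig`, `start` (0-based), `end`, `name`.
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  tibble(
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = if (!is.null(gr$name)) as.character(gr$name) else
      paste0(
        as.character(GenomicRanges::seqnames(gr)), ":",
        GenomicRanges::start(gr) - 1L, "-", GenomicRanges::end(gr)
      )
  )
}
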