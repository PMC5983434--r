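#' Read a multi-sample VCF into a records tibble
#'
#' Parses the VCF subset this pipeline consumes: `CHROM`, `POS`, `ID`, `REF`,
#' `ALT`, `QUAL`, `FILTER`, `INFO/DP`, `INFO/MQ`, `INFO/DP4` and `FORMAT/GT`.
#' Any other INFO or FORMAT content is carried along as opaque text (columns
#' `info`, `format`, `sample_data`) so that [write_vcf()] round-trips it, but
#' is never interpreted. Plain and gzip-compressed files are accepted;
#' CRLF line endings are tolerated.
#'
#' Genotypes are read as unphased diploid allele-index pairs: `|` and `/`
#' separate alleles interchangeably, and any genotype containing a missing
#' allele (`./.`, `.|.`, and half-calls such as `./1`) is treated as fully
#' missing (a row of `NA`s in the `gt` matrix).
#'
#' @param path Path to a VCF file (optionally gzipped).
#' @return A tibble with one row per record and columns `contig`, `pos`,
#'   `id`, `ref`, `alts` (list of character vectors), `qual`, `filter`,
#'   `mq`, `dp`, `dp4_ref_fwd`, `dp4_ref_rev`, `dp4_alt_fwd`, `dp4_alt_rev`,
#'   `info`, `format` and `gt` (list of sample-by-2 integer matrices, sample
#'   IDs as rownames) plus `sample_data` (raw per-sample field strings).
#'   The header's sample IDs are attached as attribute `"samples"` and
#'   returned by [vcf_samples()].
#' @seealso [write_vcf()], [vcf_samples()]
#' @export
read_vcf <- function(path) {
  con <- gzfile(path, open = "rt")
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  lines <- sub("\r$", "", lines)

  hdr_idx <- grep("^#CHROM\t", lines)
  if (length(hdr_idx) != 1L) {
    abort(paste0("not a VCF: expected exactly one #CHROM header line in ", path))
  }
  hdr <- strsplit(lines[hdr_idx], "\t", fixed = TRUE)[[1]]
  if (length(hdr) < 10L || hdr[9] != "FORMAT") {
    abort("unsupported file: VCF must contain FORMAT and at least one sample column")
  }
  samples <- hdr[-(1:9)]
  body <- lines[seq_along(lines) > hdr_idx & nzchar(lines)]
  body_lineno <- which(seq_along(lines) > hdr_idx & nzchar(lines))

  n <- length(body)
  if (n == 0L) {
    return(empty_records(samples))
  }

  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != length(hdr))) {
    i <- which(nf != length(hdr))[1]
    abort(paste0(
      "parse error at line ", body_lineno[i], ": expected ",
      length(hdr), " columns, found ", nf[i]
    ))
  }
  m <- matrix(unlist(fields), nrow = n, byrow = TRUE)

  pos <- suppressWarnings(as.integer(m[, 2]))
  bad <- which(is.na(pos) | pos < 1L)
  if (length(bad)) {
    abort(paste0("parse error at line ", body_lineno[bad[1]], ": bad POS '", m[bad[1], 2], "'"))
  }
  ref <- m[, 4]
  alts <- strsplit(m[, 5], ",", fixed = TRUE)
  bad <- which(!is_dna(ref) | !vapply(alts, function(a) all(is_dna(a)), logical(1)))
  if (length(bad)) {
    abort(paste0(
      "parse error at line ", body_lineno[bad[1]],
      ": REF/ALT must be non-empty A/C/G/T strings (got ",
      m[bad[1], 4], " -> ", m[bad[1], 5], ")"
    ))
  }
  qual <- suppressWarnings(as.numeric(ifelse(m[, 6] == ".", NA, m[, 6])))

  info <- m[, 8]
  dp <- as.integer(info_value(info, "DP"))
  mq <- as.numeric(info_value(info, "MQ"))
  dp4_raw <- info_value(info, "DP4")
  dp4 <- matrix(NA_integer_, nrow = n, ncol = 4)
  has4 <- !is.na(dp4_raw)
  if (any(has4)) {
    parts <- strsplit(dp4_raw[has4], ",", fixed = TRUE)
    if (any(lengths(parts) != 4L)) {
      i <- which(has4)[which(lengths(parts) != 4L)[1]]
      abort(paste0("parse error at line ", body_lineno[i], ": DP4 must have 4 components"))
    }
    dp4[has4, ] <- matrix(as.integer(unlist(parts)), ncol = 4, byrow = TRUE)
  }

  format <- m[, 9]
  gt_idx <- vapply(
    strsplit(format, ":", fixed = TRUE),
    function(keys) match("GT", keys),
    integer(1)
  )
  if (anyNA(gt_idx)) {
    i <- which(is.na(gt_idx))[1]
    abort(paste0("unsupported file: FORMAT without GT at line ", body_lineno[i]))
  }

  sample_data <- lapply(seq_len(n), function(i) unname(m[i, -(1:9)]))
  gt <- lapply(seq_len(n), function(i) {
    parse_gt(sample_data[[i]], gt_idx[i], samples,
      n_alt = length(alts[[i]]), lineno = body_lineno[i]
    )
  })

  out <- tibble(
    contig = m[, 1],
    pos = pos,
    id = ifelse(m[, 3] == ".", NA_character_, m[, 3]),
    ref = ref,
    alts = alts,
    qual = qual,
    filter = m[, 7],
    mq = mq,
    dp = dp,
    dp4_ref_fwd = dp4[, 1],
    dp4_ref_rev = dp4[, 2],
    dp4_alt_fwd = dp4[, 3],
    dp4_alt_rev = dp4[, 4],
    info = info,
    format = format,
    sample_data = sample_data,
    gt = gt
  )
  bad <- which(mapply(function(r, a) r %in% a, toupper(ref), lapply(alts, toupper)))
  if (length(bad)) {
    abort(paste0("parse error at line ", body_lineno[bad[1]], ": REF equals an ALT allele"))
  }
  attr(out, "samples") <- samples
  out
}

info_value <- function(info, key) {
  pat <- paste0("(?:^|;)", key, "=([^;]+)")
  m <- regmatches(info, regexec(pat, info))
  vapply(m, function(x) if (length(x) == 2L) x[2] else NA_character_, character(1))
}

parse_gt <- function(sample_fields, gt_idx, samples, n_alt, lineno) {
  out <- matrix(NA_integer_, nrow = length(samples), ncol = 2,
    dimnames = list(samples, NULL)
  )
  for (j in seq_along(sample_fields)) {
    g <- strsplit(sample_fields[j], ":", fixed = TRUE)[[1]][gt_idx]
    alleles <- strsplit(g, "[/|]")[[1]]
    if (length(alleles) != 2L || any(alleles == ".")) next # MISSING (incl. half-calls)
    a <- suppressWarnings(as.integer(alleles))
    if (anyNA(a) || any(a < 0L) || any(a > n_alt)) {
      abort(paste0("parse error at line ", lineno, ": bad genotype '", g, "'"))
    }
    out[j, ] <- a
  }
  out
}

empty_records <- function(samples) {
  out <- tibble(
    contig = character(), pos = integer(), id = character(), ref = character(),
    alts = list(), qual = numeric(), filter = character(), mq = numeric(),
    dp = integer(), dp4_ref_fwd = integer(), dp4_ref_rev = integer(),
    dp4_alt_fwd = integer(), dp4_alt_rev = integer(), info = character(),
    format = character(), sample_data = list(), gt = list()
  )
  attr(out, "samples") <- samples
  out
}

#' Sample IDs of a records tibble
#'
#' @param records A records tibble from [read_vcf()] or the synthetic
#'   cohort generator.
#' @return Character vector of sample IDs, in header order.
#' @export
vcf_samples <- function(records) {
  s <- attr(records, "samples")
  if (!is.null(s)) {
    return(s)
  }
  if (nrow(records) > 0L && !is.null(records$gt[[1]])) {
    return(rownames(records$gt[[1]]))
  }
  abort("cannot determine sample IDs: no 'samples' attribute and no genotypes")
}

#' Write a records tibble as VCF
#'
#' Emits a VCFv4.2 file that, re-read with [read_vcf()], reproduces the
#' records field-by-field on the supported subset. Opaque `info`, `format`
#' and `sample_data` text is written verbatim when present; otherwise the
#' INFO column is composed from `dp`, `mq` and the DP4 counts and the
#' genotype column from the `gt` matrices.
#'
#' @param records Records tibble (see [read_vcf()] for the columns).
#' @param path Output file path.
#' @param samples Sample IDs for the header; defaults to [vcf_samples()].
#' @return `path`, invisibly.
#' @export
write_vcf <- function(records, path, samples = NULL) {
  samples <- samples %||% vcf_samples(records)
  if (nrow(records) > 0L) {
    n_gt <- vapply(records$gt, nrow, integer(1))
    if (any(n_gt != length(samples))) {
      abort(paste0(
        "validation error: record ", which(n_gt != length(samples))[1],
        " has ", n_gt[n_gt != length(samples)][1], " genotypes for ",
        length(samples), " samples"
      ))
    }
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Raw read depth\">",
    "##INFO=<ID=MQ,Number=1,Type=Integer,Description=\"Root-mean-square mapping quality\">",
    "##INFO=<ID=DP4,Number=4,Type=Integer,Description=\"Ref-forward, ref-reverse, alt-forward and alt-reverse bases\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
      "FORMAT", samples), collapse = "\t")
  )
  body <- character(nrow(records))
  if (nrow(records) > 0L) {
    info <- records[["info"]] %||% rep(NA_character_, nrow(records))
    info <- ifelse(is.na(info), compose_info(records), info)
    format <- records[["format"]] %||% rep("GT", nrow(records))
    format[is.na(format)] <- "GT"
    filt <- records[["filter"]] %||% rep(".", nrow(records))
    filt[is.na(filt)] <- "."
    sdata <- records[["sample_data"]] %||% vector("list", nrow(records))
    body <- vapply(seq_len(nrow(records)), function(i) {
      fields <- sdata[[i]]
      if (is.null(fields)) {
        g <- records$gt[[i]]
        fields <- ifelse(is.na(g[, 1]) | is.na(g[, 2]), "./.",
          paste0(g[, 1], "/", g[, 2])
        )
      }
      paste(c(
        records$contig[i], records$pos[i],
        if (is.na(records$id[i])) "." else records$id[i],
        records$ref[i], paste(records$alts[[i]], collapse = ","),
        if (is.na(records$qual[i])) "." else format_num(records$qual[i]),
        filt[i],
        info[i], format[i], fields
      ), collapse = "\t")
    }, character(1))
  }
  writeLines(c(header, body), path)
  invisible(path)
}

compose_info <- function(records) {
  n <- nrow(records)
  parts <- cbind(
    ifelse(is.na(records$dp), NA, paste0("DP=", records$dp)),
    ifelse(is.na(records$mq), NA, paste0("MQ=", format_num(records$mq))),
    ifelse(is.na(records$dp4_ref_fwd), NA, paste0(
      "DP4=", records$dp4_ref_fwd, ",", records$dp4_ref_rev, ",",
      records$dp4_alt_fwd, ",", records$dp4_alt_rev
    ))
  )
  out <- apply(parts, 1, function(p) paste(p[!is.na(p)], collapse = ";"))
  ifelse(nzchar(out), out, ".")
}

format_num <- function(x) {
  ifelse(x == round(x), format(x, scientific = FALSE, trim = TRUE),
    format(x, scientific = FALSE, trim = TRUE, digits = 10)
  )
}

#' Read a breed panel TSV
#'
#' The panel maps each breed to its sample IDs: a two-column tab-separated
#' file (`breed`, `sample`), with or without that header line.
#'
#' @param path Path to the TSV.
#' @return A tibble with columns `breed` and `sample`, rows in file order.
#'   Sample IDs must be globally unique across breeds.
#' @export
read_panel <- function(path) {
  lines <- sub("\r$", "", readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) != 2L)) {
    abort(paste0(
      "panel parse error at line ", which(lengths(fields) != 2L)[1],
      ": expected 2 tab-separated columns"
    ))
  }
  m <- matrix(unlist(fields), ncol = 2, byrow = TRUE)
  if (tolower(m[1, 1]) == "breed") m <- m[-1, , drop = FALSE]
  panel <- tibble(breed = m[, 1], sample = m[, 2])
  validate_panel(panel)
}

validate_panel <- function(panel) {
  dup <- panel$sample[duplicated(panel$sample)]
  if (length(dup)) {
    abort(paste0("validation error: sample '", dup[1], "' listed more than once in the panel"))
  }
  panel
}

#' Write a breed panel TSV
#'
#' @param panel Tibble with columns `breed`, `sample`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  validate_panel(panel)
  writeLines(c("breed\tsample", paste(panel$breed, panel$sample, sep = "\t")), path)
  invisible(path)
}

#' Read a FASTA file into a named character vector
#'
#' Header lines are preserved verbatim (everything after `>` becomes the
#' name); sequence case is preserved so soft-masking survives a round trip.
#'
#' @param path Path to a FASTA file (optionally gzipped).
#' @return Named character vector, one element per contig.
#' @export
read_fasta <- function(path) {
  con <- gzfile(path, open = "rt")
  on.exit(close(con))
  lines <- sub("\r$", "", readLines(con, warn = FALSE))
  lines <- lines[nzchar(lines)]
  hdr <- grepl("^>", lines)
  if (!any(hdr) || !hdr[1]) {
    abort(paste0("not FASTA: ", path))
  }
  grp <- cumsum(hdr)
  names_out <- sub("^>", "", lines[hdr])
  seqs <- vapply(
    split(lines[!hdr], grp[!hdr]),
    paste0, character(1), collapse = ""
  )
  # contigs with no sequence lines become empty strings
  out <- setNames(character(sum(hdr)), names_out)
  out[as.integer(names(seqs))] <- seqs
  names(out) <- names_out
  out
}

#' Write a named character vector as FASTA
#'
#' Sequences wrap at 60 columns; names become header lines verbatim.
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    if (nchar(s) > 0L) {
      starts <- seq(1L, nchar(s), by = 60L)
      writeLines(substring(s, starts, pmin(starts + 59L, nchar(s))), con)
    }
  }
  invisible(path)
}
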