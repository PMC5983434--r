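#' Build a breed-specific consensus reference
#'
#' Substitutes the breed's fixed alternative allele at every breed-specific
#' SNP position of the reference template. Only single-base substitutions
#' are applied; sequence lengths never change. The template base at each
#' position must equal the key's reference allele (case-insensitively); the
#' template's case is preserved, so a soft-masked (lowercase) base is
#' replaced by a lowercase alternative.
#'
#' @param snps A tibble of SNP keys with columns `contig`, `pos`, `ref`,
#'   `alt` (single bases), e.g. from [breed_specific_sets()] keys run
#'   through [parse_variant_key()].
#' @param template Named character vector of reference sequences, as read by
#'   [read_fasta()].
#' @return A list of class `consensus`: `sequences` (modified named
#'   character vector, contig order and headers preserved) and `log` (a
#'   tibble `contig`, `pos`, `ref_base`, `alt_base`, ordered by contig and
#'   position) recording every substitution.
#' @export
build_breed_reference <- function(snps, template) {
  if (nrow(snps) > 0L) {
    bad <- nchar(snps$ref) != 1L | nchar(snps$alt) != 1L
    if (any(bad)) {
      i <- which(bad)[1]
      abort(paste0(
        "non-SNP key at ", snps$contig[i], ":", snps$pos[i],
        " (", snps$ref[i], ">", snps$alt[i], "): only single-base substitutions are applied"
      ))
    }
    dup <- duplicated(paste(snps$contig, snps$pos))
    if (any(dup)) {
      i <- which(dup)[1]
      abort(paste0("duplicated substitution position ", snps$contig[i], ":", snps$pos[i]))
    }
    missing_ctg <- setdiff(unique(snps$contig), fasta_contig_ids(template))
    if (length(missing_ctg)) {
      abort(paste0("contig '", missing_ctg[1], "' not present in the template"))
    }
  }
  ids <- fasta_contig_ids(template)
  out <- template
  log <- snps[order(snps$contig, snps$pos), c("contig", "pos", "ref", "alt"), drop = FALSE]
  for (ctg in unique(log$contig)) {
    i <- match(ctg, ids)
    s <- out[[i]]
    rows <- log[log$contig == ctg, , drop = FALSE]
    if (any(rows$pos < 1L | rows$pos > nchar(s))) {
      bad <- rows[rows$pos < 1L | rows$pos > nchar(s), ][1, ]
      abort(paste0(
        "position out of range: ", ctg, ":", bad$pos,
        " (contig length ", nchar(s), ")"
      ))
    }
    found <- substring(s, rows$pos, rows$pos)
    mism <- toupper(found) != toupper(rows$ref)
    if (any(mism)) {
      b <- which(mism)[1]
      abort(paste0(
        "reference mismatch at ", ctg, ":", rows$pos[b],
        ": expected ", rows$ref[b], ", found ", found[b]
      ))
    }
    sub <- ifelse(found == tolower(found), tolower(rows$alt), toupper(rows$alt))
    for (j in seq_len(nrow(rows))) {
      substring(s, rows$pos[j], rows$pos[j]) <- sub[j]
    }
    out[[i]] <- s
  }
  names(out) <- names(template)
  structure(
    list(
      sequences = out,
      log = tibble(
        contig = log$contig, pos = log$pos,
        ref_base = log$ref, alt_base = log$alt
      )
    ),
    class = "consensus"
  )
}

# FASTA names may be full header lines; the contig ID is the first word.
fasta_contig_ids <- function(seqs) {
  sub("\\s.*$", "", names(seqs))
}

#' @export
print.consensus <- function(x, ...) {
  cat("<consensus> ", length(x$sequences), " contigs, ",
    nrow(x$log), " substitutions\n",
    sep = ""
  )
  invisible(x)
}

#' @rdname build_breed_reference
#' @param x A `consensus` object.
#' @param ... Unused.
#' @method tidy consensus
#' @export
tidy.consensus <- function(x, ...) {
  x$log
}

#' @rdname build_breed_reference
#' @method glance consensus
#' @export
glance.consensus <- function(x, ...) {
  tibble(
    n_contigs = length(x$sequences),
    n_substitutions = nrow(x$log),
    total_bp = sum(nchar(x$sequences))
  )
}

#' Position-by-position difference of two references
#'
#' @param a,b Named character vectors with identical contig IDs and lengths.
#' @return A tibble `contig`, `pos`, `base_a`, `base_b` listing every
#'   1-based position where the sequences differ.
#' @export
diff_references <- function(a, b) {
  ids_a <- fasta_contig_ids(a)
  ids_b <- fasta_contig_ids(b)
  if (!setequal(ids_a, ids_b) || length(ids_a) != length(ids_b)) {
    abort("contig sets differ between the two references")
  }
  out <- lapply(ids_a, function(ctg) {
    sa <- a[[match(ctg, ids_a)]]
    sb <- b[[match(ctg, ids_b)]]
    if (nchar(sa) != nchar(sb)) {
      abort(paste0(
        "length mismatch on ", ctg, ": ", nchar(sa), " vs ", nchar(sb)
      ))
    }
    va <- strsplit(sa, "", fixed = TRUE)[[1]]
    vb <- strsplit(sb, "", fixed = TRUE)[[1]]
    d <- which(va != vb)
    tibble(contig = rep(ctg, length(d)), pos = d, base_a = va[d], base_b = vb[d])
  })
  list_rbind(out)
}
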