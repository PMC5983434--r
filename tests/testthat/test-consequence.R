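# Fixture transcript: ATG AAA TGG | intron | TCA TAC TAA on the plus strand.
# CDS1 = 11-19, intron = 20-39, CDS2 = 40-48.
fixture_gene <- function() {
  tmpl <- paste0(
    strrep("T", 10), "ATGAAATGG", strrep("C", 20), "TCATACTAA", strrep("G", 52)
  )
  list(
    template = c(g1 = tmpl),
    model = gene_model("tx1", "g1", "+", cds_start = c(11, 40), cds_end = c(19, 48))
  )
}

test_that("fixture CDS translates to a complete protein (sanity gate)", {
  fx <- fixture_gene()
  cdna <- cds_sequence(fx$model, fx$template)
  expect_equal(cdna, "ATGAAATGGTCATACTAA")
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(cdna)))
  expect_match(aa, "^M")
  expect_match(aa, "\\*$")
})

annotate1 <- function(pos, ref, alt, fx = fixture_gene()) {
  annotate_snvs(
    tibble::tibble(contig = "g1", pos = pos, ref = ref, alt = alt),
    fx$model, fx$template
  )
}

test_that("codon-level classification covers all five coding terms", {
  expect_equal(annotate1(16, "A", "G")$term, "synonymous_variant") # AAA->AAG
  expect_equal(annotate1(16, "A", "G")$ref_codon, "AAA")
  expect_equal(annotate1(16, "A", "G")$alt_codon, "AAG")
  expect_equal(annotate1(14, "A", "T")$term, "stop_gained") # AAA->TAA
  expect_equal(annotate1(15, "A", "C")$term, "missense_variant") # AAA->ACA
  expect_equal(annotate1(11, "A", "C")$term, "start_lost") # ATG->CTG
  expect_equal(annotate1(46, "T", "C")$term, "stop_lost") # TAA->CAA
  # protein-truncating beats the exonic splice-region label
  expect_equal(annotate1(19, "G", "A")$term, "stop_gained") # TGG->TGA at junction
})

test_that("splice region covers 1-8 intronic and 1-3 terminal exonic bases", {
  # synonymous change in the terminal exonic bases reports splice_region
  sr <- annotate1(42, "A", "G") # TCA->TCG, Ser->Ser, acceptor-side exon
  expect_equal(sr$term, "splice_region_variant")
  expect_true(is.na(sr$ref_codon)) # codon_change only for codon-level terms
  # intronic distances
  expect_equal(annotate1(20, "C", "A")$term, "splice_region_variant") # donor +1
  expect_equal(annotate1(27, "C", "A")$term, "splice_region_variant") # donor +8
  expect_equal(annotate1(28, "C", "A")$term, "intron_variant") # donor +9
  expect_equal(annotate1(32, "C", "A")$term, "splice_region_variant") # acceptor -8
  expect_equal(annotate1(5, "T", "A")$term, "intergenic_variant")
})

test_that("reference disagreement with the template is an error", {
  expect_error(annotate1(16, "C", "G"), "reference mismatch")
})

test_that("the most severe consequence wins across overlapping transcripts", {
  fx <- fixture_gene()
  # a second, intron-only transcript spanning the same locus
  models <- dplyr::bind_rows(
    fx$model,
    gene_model("tx2", "g1", "+", cds_start = c(5, 60), cds_end = c(8, 71))
  )
  call <- annotate_snvs(
    tibble::tibble(contig = "g1", pos = 14, ref = "A", alt = "T"),
    models, fx$template
  )
  expect_equal(call$term, "stop_gained")
  expect_equal(call$transcript, "tx1")
})

test_that("minus-strand annotation equals the mirrored plus-strand gene", {
  fx <- fixture_gene()
  L <- nchar(fx$template[[1]])
  rc <- function(s) as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  mirror_template <- c(g1 = rc(fx$template[[1]]))
  cds <- fx$model$cds[[1]]
  mirror_model <- gene_model(
    "tx1", "g1", "-",
    cds_start = L - cds[, "end"] + 1L,
    cds_end = L - cds[, "start"] + 1L
  )
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  bases <- c("A", "C", "G", "T")
  for (pos in c(11:19, 40:48, 20, 27, 30, 42, 5)) {
    ref <- substring(fx$template[[1]], pos, pos)
    for (alt in setdiff(bases, ref)) {
      fwd <- annotate1(pos, ref, alt, fx)
      rev <- annotate_snvs(
        tibble::tibble(
          contig = "g1", pos = L - pos + 1L,
          ref = comp[[ref]], alt = comp[[alt]]
        ),
        mirror_model, mirror_template
      )
      expect_equal(rev$term, fwd$term)
      expect_equal(rev$ref_codon, fwd$ref_codon)
      expect_equal(rev$alt_codon, fwd$alt_codon)
    }
  }
})

test_that("all nine SNVs of each codon match a translate-both oracle", {
  fx <- fixture_gene()
  cdna <- "ATGAAATGGTCATACTAA"
  cds_genome_pos <- c(11:19, 40:48)
  bases <- c("A", "C", "G", "T")
  translate1 <- function(codon) {
    as.character(Biostrings::translate(Biostrings::DNAString(codon)))
  }
  for (ci in seq_len(nchar(cdna))) {
    pos <- cds_genome_pos[ci]
    ref <- substring(cdna, ci, ci)
    codon_i <- (ci - 1) %/% 3
    within <- (ci - 1) %% 3
    ref_codon <- substring(cdna, codon_i * 3 + 1, codon_i * 3 + 3)
    for (alt in setdiff(bases, ref)) {
      alt_codon <- ref_codon
      substring(alt_codon, within + 1, within + 1) <- alt
      ref_aa <- translate1(ref_codon)
      alt_aa <- translate1(alt_codon)
      expected <- if (codon_i == 0 && alt_codon != "ATG") {
        "start_lost"
      } else if (ref_aa != "*" && alt_aa == "*") {
        "stop_gained"
      } else if (ref_aa == "*" && alt_aa != "*") {
        "stop_lost"
      } else if (ref_aa == alt_aa) {
        "synonymous_variant"
      } else {
        "missense_variant"
      }
      got <- annotate1(pos, ref, alt, fx)
      # the in-package call may upgrade an exonic synonymous to splice_region
      if (expected == "synonymous_variant" && got$term == "splice_region_variant") {
        expect_true(pos %in% c(17:19, 40:42))
      } else {
        expect_equal(got$term, expected)
        expect_equal(got$ref_codon, ref_codon)
        expect_equal(got$alt_codon, alt_codon)
      }
    }
  }
})

test_that("consequence percentages mirror published rounding on coding calls", {
  calls <- tibble::tibble(
    breed = "FLV",
    term = c(rep("missense_variant", 100), rep("synonymous_variant", 81))
  )
  s <- consequence_summary(calls)
  expect_equal(s$pct_coding[s$term == "missense_variant"], 55.2)
  expect_equal(nrow(consequence_summary(calls[0, ])), 0L)
  all_syn <- consequence_summary(tibble::tibble(
    breed = "x", term = rep("synonymous_variant", 4)
  ))
  expect_equal(all_syn$pct_coding, 100)
  # non-coding terms carry counts but no coding percentage
  mixed <- consequence_summary(tibble::tibble(
    breed = "x", term = c("intergenic_variant", "missense_variant")
  ))
  expect_true(is.na(mixed$pct_coding[mixed$term == "intergenic_variant"]))
})

test_that("BED overlap uses 0-based half-open intervals", {
  snp <- function(p) tibble::tibble(contig = "c1", pos = p)
  feat <- function(s, e) tibble::tibble(contig = "c1", start = s, end = e, name = "f")
  expect_equal(nrow(overlap_features(snp(100), feat(99, 100))), 1L)
  expect_equal(nrow(overlap_features(snp(100), feat(100, 200))), 0L)
  expect_equal(nrow(overlap_features(snp(101), feat(100, 200))), 1L)
  expect_error(overlap_features(snp(1), feat(10, 10)), "malformed")

  withr::local_seed(5)
  snps <- tibble::tibble(
    contig = sample(c("c1", "c2"), 60, replace = TRUE),
    pos = sample.int(300, 60, replace = TRUE)
  )
  feats <- tibble::tibble(
    contig = sample(c("c1", "c2"), 12, replace = TRUE),
    start = sample.int(250, 12, replace = TRUE)
  )
  feats$end <- feats$start + sample.int(40, 12, replace = TRUE)
  feats$name <- paste0("f", seq_len(12))
  got <- overlap_features(snps, feats)
  # O(n*m) containment oracle
  expected <- 0L
  for (i in seq_len(nrow(feats))) {
    for (j in seq_len(nrow(snps))) {
      hit <- snps$contig[j] == feats$contig[i] &&
        snps$pos[j] - 1 >= feats$start[i] && snps$pos[j] - 1 < feats$end[i]
      if (hit) {
        expected <- expected + 1L
        expect_true(any(got$feature == feats$name[i] & got$pos == snps$pos[j] &
          got$contig == snps$contig[j]))
      }
    }
  }
  expect_equal(nrow(got), expected)
})

test_that("gene models round trip through GFF3 and BED reads back 0-based", {
  fx <- fixture_gene()
  models <- dplyr::bind_rows(
    fx$model,
    gene_model("tx9", "g1", "-", cds_start = c(60, 80), cds_end = c(65, 90))
  )
  gff <- tempfile(fileext = ".gff3")
  write_gff3(models, gff)
  back <- read_gene_models(gff)
  expect_setequal(back$transcript, models$transcript)
  for (tx in models$transcript) {
    expect_equal(
      back$cds[[match(tx, back$transcript)]],
      models$cds[[match(tx, models$transcript)]]
    )
    expect_equal(
      back$strand[match(tx, back$transcript)],
      models$strand[match(tx, models$transcript)]
    )
  }

  bed <- tempfile(fileext = ".bed")
  writeLines(c("g1\t99\t200\tfeatA", "g1\t0\t10\tfeatB"), bed)
  feats <- read_bed(bed)
  expect_equal(feats$start, c(99L, 0L))
  expect_equal(feats$end, c(200L, 10L))
  expect_equal(feats$name, c("featA", "featB"))
})
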