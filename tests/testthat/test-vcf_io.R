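test_that("a minimal VCF parses: genotypes, missing values, INFO fields", {
  path <- write_lines_tmp(tiny_vcf_lines(
    "chr1\t100\t.\tA\tG\t55.5\t.\tDP=20;MQ=44;DP4=3,4,5,6\tGT\t0/1\t./."
  ))
  rec <- read_vcf(path)
  expect_equal(nrow(rec), 1L)
  expect_equal(vcf_samples(rec), c("S1", "S2"))
  expect_equal(rec$pos, 100L)
  expect_equal(rec$qual, 55.5)
  expect_equal(rec$mq, 44)
  expect_equal(rec$dp, 20L)
  expect_equal(
    c(rec$dp4_ref_fwd, rec$dp4_ref_rev, rec$dp4_alt_fwd, rec$dp4_alt_rev),
    c(3L, 4L, 5L, 6L)
  )
  g <- rec$gt[[1]]
  expect_equal(unname(g["S1", ]), c(0L, 1L))
  expect_true(all(is.na(g["S2", ])))
})

test_that("multi-allelic ALT parses into multiple alleles and matches vcfR", {
  path <- write_lines_tmp(tiny_vcf_lines(
    "chr1\t7\t.\tC\tA,T\t99\t.\tDP=30\tGT\t1/2\t0/0"
  ))
  rec <- read_vcf(path)
  expect_equal(rec$alts[[1]], c("A", "T"))
  expect_equal(unname(rec$gt[[1]]["S1", ]), c(1L, 2L))

  skip_if_not_installed("vcfR")
  v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  expect_equal(unname(v@fix[1, "ALT"]), "A,T")
  expect_equal(unname(v@fix[1, "REF"]), rec$ref)
  expect_equal(as.integer(v@fix[1, "POS"]), rec$pos)
})

test_that("write/read round trip is the identity on the supported subset", {
  path <- write_lines_tmp(tiny_vcf_lines(c(
    "chr1\t10\trs1\tA\tG\t50\tPASS\tDP=15;MQ=40;DP4=1,2,3,4\tGT:PL\t0|1:10,0,5\t1/1:99,9,0",
    "chr1\t20\t.\tC\tCA\t.\t.\tDP=12\tGT\t./1\t.|.",
    "chr2\t5\t.\tT\tA\t33\t.\tXX=opaque;DP=11;MQ=31;DP4=0,0,5,5\tGT\t0/0\t1/1"
  )))
  rec <- read_vcf(path)
  # half-calls and fully missing genotypes are both MISSING
  expect_true(all(is.na(rec$gt[[2]])))
  out <- tempfile(fileext = ".vcf")
  write_vcf(rec, out)
  rec2 <- read_vcf(out)
  expect_equal(rec2, rec, ignore_attr = TRUE)
  # opaque INFO and FORMAT text survives verbatim
  expect_match(rec2$info[3], "XX=opaque", fixed = TRUE)
  expect_equal(rec2$format[1], "GT:PL")
})

test_that("records built in memory round trip through VCF text", {
  rec <- make_records(
    pos = c(10, 25), ref = c("A", "C"), alt = c("G", "T"),
    qual = c(80, NA), gt = list(gt_matrix("1/1", "0/1"), gt_matrix("./.", "1/1"))
  )
  attr(rec, "samples") <- c("s01", "s02")
  out <- tempfile(fileext = ".vcf")
  write_vcf(rec, out)
  lines <- readLines(out)
  # null QUAL is written as "."
  expect_match(lines[length(lines)], "\\t\\.\\t\\.\\tDP=12")
  back <- read_vcf(out)
  expect_equal(back$pos, rec$pos)
  expect_equal(back$qual, rec$qual)
  expect_equal(back$dp, rec$dp)
  expect_equal(unname(back$gt[[1]]), unname(rec$gt[[1]]))
  expect_equal(unname(back$gt[[2]]), unname(rec$gt[[2]]))
})

test_that("empty record list writes a header-only VCF", {
  rec <- make_records(pos = 1)[0, ]
  attr(rec, "samples") <- c("a", "b")
  out <- tempfile(fileext = ".vcf")
  write_vcf(rec, out, samples = c("a", "b"))
  back <- read_vcf(out)
  expect_equal(nrow(back), 0L)
  expect_equal(vcf_samples(back), c("a", "b"))
})

test_that("parsing tolerates CRLF line endings and gzip compression", {
  lines <- tiny_vcf_lines("chr1\t3\t.\tG\tA\t40\t.\tDP=14;MQ=50;DP4=1,1,2,2\tGT\t1/1\t1|1")
  crlf <- tempfile(fileext = ".vcf")
  writeLines(lines, crlf, sep = "\r\n")
  gz <- tempfile(fileext = ".vcf.gz")
  con <- gzfile(gz, "wt")
  writeLines(lines, con)
  close(con)
  plain <- write_lines_tmp(lines)
  a <- read_vcf(plain)
  b <- read_vcf(crlf)
  c3 <- read_vcf(gz)
  expect_equal(b, a, ignore_attr = TRUE)
  expect_equal(c3, a, ignore_attr = TRUE)
  # phased and unphased separators are equivalent
  expect_equal(unname(a$gt[[1]]["S2", ]), c(1L, 1L))
})

test_that("malformed input fails with informative errors", {
  # wrong column count, naming the line
  bad <- write_lines_tmp(tiny_vcf_lines("chr1\t5\t.\tA\tG\t10\t.\tDP=5\tGT\t1/1"))
  expect_error(read_vcf(bad), "line 3")
  # FORMAT without GT
  nogt <- write_lines_tmp(tiny_vcf_lines("chr1\t5\t.\tA\tG\t10\t.\tDP=5\tPL\t1,2\t3,4"))
  expect_error(read_vcf(nogt), "without GT")
  # REF == ALT
  same <- write_lines_tmp(tiny_vcf_lines("chr1\t5\t.\tA\tA\t10\t.\tDP=5\tGT\t1/1\t1/1"))
  expect_error(read_vcf(same), "REF equals an ALT")
  # genotype/sample-count mismatch on write
  rec <- make_records(pos = 1, samples = c("s1", "s2"))
  expect_error(write_vcf(rec, tempfile(), samples = c("only_one")), "validation error")
})

test_that("breed panel reads, validates and reproduces the study cohort size", {
  counts <- c(
    Angus = 287, `Brown Swiss` = 148, Fleckvieh = 53, Hereford = 75,
    Jersey = 66, Limousin = 82, Simmental = 225
  )
  lines <- c("breed\tsample", unlist(lapply(names(counts), function(b) {
    paste0(b, "\t", gsub(" ", "", b), "_", seq_len(counts[[b]]))
  })))
  panel <- read_panel(write_lines_tmp(lines, ".tsv"))
  expect_equal(nrow(panel), 936L)
  expect_equal(length(unique(panel$breed)), 7L)
  expect_equal(sum(panel$breed == "Angus"), 287L)

  single <- read_panel(write_lines_tmp("b1\ts1", ".tsv"))
  expect_equal(nrow(single), 1L)

  dup <- write_lines_tmp(c("b1\tsX", "b2\tsX"), ".tsv")
  expect_error(read_panel(dup), "sX")
})

test_that("FASTA round trip preserves headers, case and wraps at 60 columns", {
  seqs <- c(
    "chr1 assembled from unit test" = paste(rep("ACGTacgtGG", 13), collapse = ""),
    "chr2" = "acgt"
  )
  path <- tempfile(fileext = ".fa")
  write_fasta(seqs, path)
  lines <- readLines(path)
  expect_equal(lines[1], ">chr1 assembled from unit test")
  expect_equal(max(nchar(lines[-grep("^>", lines)])), 60L)
  back <- read_fasta(path)
  expect_equal(back, seqs)
})
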