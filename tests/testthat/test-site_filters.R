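cfg <- site_filter_config()

test_that("biallelic and variant-class predicates follow the VCF allele shapes", {
  rec <- make_records(
    pos = c(1, 10, 20, 30, 40, 50),
    ref = c("A", "A", "A", "A", "AC", "AC"),
    alt = c("T", "T,G", "T,G,C", "AT", "A", "GT")
  )
  expect_equal(is_biallelic(rec), c(TRUE, FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_equal(
    classify_variant(rec),
    c("SNP", NA, NA, "INDEL", "INDEL", "OTHER")
  )
})

test_that("strand support needs at least one alt read on each strand", {
  rec <- make_records(
    pos = c(1, 2, 3),
    alt_fwd = c(0, 1, 7), alt_rev = c(5, 1, 0),
    ref_fwd = c(10, 10, 0), ref_rev = c(12, 12, 0)
  )
  expect_equal(passes_strand_support(rec, cfg), c(FALSE, TRUE, FALSE))
})

test_that("quality filter removes QUAL < 20 or MQ < 30, boundaries retained", {
  rec <- make_records(
    pos = c(1, 2, 3),
    qual = c(19.9, 20, 50), mq = c(60, 30, 29)
  )
  expect_equal(passes_quality(rec, cfg), c(FALSE, TRUE, FALSE))
})

test_that("depth ceiling equals median + 3 sample standard deviations", {
  ceiling_of <- function(dp) {
    compute_depth_ceiling(make_records(pos = seq_along(dp), dp = dp), cfg)
  }
  expect_equal(ceiling_of(rep(10, 5)), 10)
  # independent textbook computation: median 12, SD sqrt(10)
  expect_equal(ceiling_of(c(8, 10, 12, 14, 16)), 12 + 3 * sqrt(10))
  expect_equal(ceiling_of(c(8, 10, 12, 14, 16)), 21.4868330, tolerance = 1e-7)
  # two points: median 52.5, SD = |100 - 5| / sqrt(2)
  expect_equal(ceiling_of(c(5, 100)), 52.5 + 3 * 95 / sqrt(2))
  expect_error(ceiling_of(numeric(0)), "at least 2")
})

test_that("depth window keeps min_dp <= DP <= ceiling", {
  rec <- make_records(pos = 1:4, dp = c(9, 10, 30, 31))
  expect_equal(passes_depth(rec, 30, cfg), c(FALSE, TRUE, TRUE, FALSE))
})

test_that("duplicate positions remove every member of the collision group", {
  rec <- make_records(
    pos = c(100, 100, 200, 300, 300, 300),
    alt = c("G", "T", "G", "G", "T", "C")
  )
  kept <- remove_duplicate_positions(rec)
  expect_equal(kept$pos, 200L)
  uniq <- make_records(pos = c(1, 5, 9))
  expect_equal(remove_duplicate_positions(uniq)$pos, c(1L, 5L, 9L))
})

test_that("proximity removals are single-pass with strict 'closer than'", {
  # two SNPs at distance 2 (< 3): both removed
  pair <- make_records(pos = c(100, 102))
  expect_equal(nrow(proximity_filter(pair, cfg)), 0L)
  # distance exactly 3: both kept
  edge <- make_records(pos = c(100, 103))
  expect_equal(proximity_filter(edge, cfg)$pos, c(100L, 103L))
  # SNP + InDel at 4 (< 5) removes the SNP; InDels at 9 (< 10) remove each other
  trio <- make_records(
    pos = c(100, 104, 113),
    ref = c("A", "AT", "CT"), alt = c("G", "A", "C")
  )
  expect_equal(nrow(proximity_filter(trio, cfg)), 0L)
  # SNP + InDel at exactly 5: both kept, InDel never removed by a SNP
  ok <- make_records(pos = c(100, 105), ref = c("A", "AT"), alt = c("G", "A"))
  expect_equal(nrow(proximity_filter(ok, cfg)), 2L)
})

engineered_fixture <- function() {
  make_records(
    pos = c(
      100, 150, 200, 250, 300, # early failures
      350, 400, # depth low / high
      1000, 1000, # duplicate pair
      2000, 2002, # SNP-SNP cluster
      3000, 3004, # SNP near InDel
      4000, 4009, # InDel pair
      5000, 6000, 7000 # clean survivors
    ),
    ref = c(
      "A", "AC", "A", "A", "A",
      "A", "A",
      "A", "A",
      "A", "C",
      "A", "AT",
      "AG", "CT",
      "A", "C", "G"
    ),
    alt = c(
      "G,T", "GT", "G", "G", "G",
      "G", "G",
      "G", "T",
      "G", "T",
      "G", "A",
      "A", "C",
      "G", "T", "A"
    ),
    qual = c(100, 100, 100, 10, 100, rep(100, 13)),
    mq = c(50, 50, 50, 50, 20, rep(50, 13)),
    dp = c(12, 12, 12, 12, 12, 5, 60, 12, 12, 12, 12, 12, 12, 12, 12, 11, 12, 13),
    alt_fwd = c(5, 5, 0, 5, 5, rep(5, 13))
  )
}

test_that("the cascade assigns each removal its first failing filter", {
  res <- apply_site_filters(engineered_fixture(), cfg)
  expect_s3_class(res, "site_filter")
  expect_equal(sort(res$kept$pos), c(3004L, 5000L, 6000L, 7000L))
  expected <- c(
    multiallelic = 1L, other_class = 1L, strand = 1L, qual = 1L, mq = 1L,
    depth_low = 1L, depth_high = 1L, duplicate_pos = 2L,
    prox_snp_snp = 2L, prox_snp_indel = 1L, prox_indel_indel = 2L
  )
  got <- table(res$trace$failed_filter)
  expect_equal(as.integer(got[names(expected)]), unname(expected))
  # retained records have no failure label; removed ones exactly one
  expect_true(all(is.na(res$trace$failed_filter[res$trace$pos %in% res$kept$pos])))
  expect_equal(sum(is.na(res$trace$failed_filter)), nrow(res$kept))
  # tidy/glance accessors
  expect_equal(tidy(res), res$trace)
  expect_equal(glance(res)$n_kept, 4L)
})

test_that("the cascade equals the brute-force oracle and keeps stated properties", {
  withr::local_seed(424242)
  for (rep in 1:25) {
    rec <- random_site_records(sample(20:120, 1))
    res <- apply_site_filters(rec, cfg)
    keep <- oracle_site_keep(rec, cfg)
    expect_setequal(record_sig(res$kept), record_sig(rec[keep, ]))

    # idempotence under the generator's conditions
    again <- apply_site_filters(res$kept, cfg)
    expect_setequal(record_sig(again$kept), record_sig(res$kept))

    # input-order independence
    perm <- rec[sample.int(nrow(rec)), ]
    expect_setequal(
      record_sig(apply_site_filters(perm, cfg)$kept),
      record_sig(res$kept)
    )

    # dropping the proximity stage can only enlarge the kept set
    no_prox <- site_filter_config(
      snp_snp_dist = 0L, snp_indel_dist = 0L, indel_indel_dist = 0L
    )
    expect_true(all(
      record_sig(res$kept) %in% record_sig(apply_site_filters(rec, no_prox)$kept)
    ))
  }
})

test_that("all-passing and empty inputs pass through unchanged", {
  clean <- make_records(pos = c(100, 200, 300, 400))
  res <- apply_site_filters(clean, cfg)
  expect_equal(nrow(res$kept), 4L)
  expect_true(all(is.na(res$trace$failed_filter)))

  res0 <- apply_site_filters(clean[0, ], cfg)
  expect_equal(nrow(res0$kept), 0L)
  expect_equal(nrow(res0$trace), 0L)
})

test_that("missing annotations fail their filter in strict mode and pass otherwise", {
  rec <- make_records(pos = c(100, 200), qual = c(NA, 100))
  strict <- apply_site_filters(rec, cfg)
  expect_equal(strict$trace$failed_filter[1], "qual")
  lax <- apply_site_filters(rec, site_filter_config(strict_missing = FALSE))
  expect_equal(nrow(lax$kept), 2L)
})
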