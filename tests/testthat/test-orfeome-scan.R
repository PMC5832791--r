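test_that("read_cds_fasta parses pipe headers and skips invalid records", {
  path <- tempfile(fileext = ".fa")
  write_fasta(c("CCDS1.1|GeneA|extra", "CCDS2.1", "CCDS3.1|GeneC"),
              c("ATGGAATAA", "AAACAAGAATAA", "ATGGAAT"),
              path)
  expect_message(cds <- read_cds_fasta(path), "skipped 1 invalid record")
  expect_length(cds, 2)
  expect_identical(cds[[1]]$id, "CCDS1.1")
  expect_identical(cds[[1]]$gene, "GeneA")
  expect_true(is.na(cds[[2]]$gene))
  skipped <- attr(cds, "skipped")
  expect_identical(skipped$id, "CCDS3.1")
  expect_identical(skipped$reason, "LENGTH_NOT_MULTIPLE_OF_3")

  expect_error(read_cds_fasta(tempfile()), class = "FILE_NOT_FOUND")
  empty <- tempfile(fileext = ".fa")
  writeLines(character(0), empty)
  expect_error(read_cds_fasta(empty), class = "wobblebias_error")
})

test_that("scan_orfeome produces one profile row per CDS", {
  cds <- list(validate_cds("AAACAAGAA", id = "a"),
              validate_cds("AAGCAGGAG", id = "b"))
  tab <- scan_orfeome(cds)
  expect_equal(nrow(tab), 2)
  expect_identical(tab$ratio, c(Inf, 0))
  expect_equal(tab$total_codons, c(3L, 3L))

  # order-invariance: the row set does not depend on input order
  tab_rev <- scan_orfeome(rev(cds))
  expect_equal(tab[order(tab$id), ], tab_rev[order(tab_rev$id), ],
               ignore_attr = TRUE)

  expect_error(scan_orfeome(list(validate_cds("ATGTAA", id = "x"),
                                 validate_cds("ATGTAA", id = "x"))),
               class = "DUPLICATE_ID")
})

test_that("collapse = 'longest' keeps one CDS per gene symbol", {
  cds <- list(validate_cds("ATGGAATAA", id = "c1", gene = "GENEA"),
              validate_cds("ATGGAAGAATAA", id = "c2", gene = "genea"),
              validate_cds("ATGTAA", id = "c3", gene = "GENEB"),
              validate_cds("ATGTAA", id = "c4"))
  tab <- scan_orfeome(cds, collapse = "longest")
  expect_equal(nrow(tab), 3)  # longest of GENEA, GENEB, and the anonymous CDS
  expect_true("c2" %in% tab$id)
  expect_false("c1" %in% tab$id)
})

test_that("the bundled AA-biased eGFP scans as a 240-codon infinite-ratio row", {
  tab <- scan_orfeome(list(egfp_aa_sensor()))
  expect_equal(tab$total_codons, 240)
  expect_identical(tab$ratio, Inf)
})

test_that("ratio_distribution bins finite rows and tracks sentinels", {
  tab <- random_orfeome_table(3)
  tab$ratio <- c(0.5, 0.5, 2.0)
  d <- ratio_distribution(tab)
  expect_equal(d$fraction_below_1, 2 / 3)
  expect_equal(sum(d$histogram$count) + d$n_infinite + d$n_undefined, 3)

  tab$ratio <- c(NaN, NaN, NaN)
  d2 <- ratio_distribution(tab)
  expect_true(is.na(d2$fraction_below_1))
  expect_equal(d2$n_undefined, 3)

  expect_error(ratio_distribution(tab[0, ]), class = "EMPTY_TABLE")
  expect_error(ratio_distribution(tab, bin_width = 0),
               class = "INVALID_BIN_WIDTH")
})

test_that("histogram counts plus overflow categories sum to table size", {
  set.seed(3)
  for (i in 1:10) {
    tab <- random_orfeome_table(200)
    # salt in sentinel rows
    tab$ratio[1:5] <- Inf
    tab$ratio[6:8] <- NaN
    d <- ratio_distribution(tab, bin_width = 0.05)
    expect_equal(sum(d$histogram$count) + d$n_infinite + d$n_undefined, 200)
    # infinite ratios count as >= 1 in the below-1 fraction
    fin <- is.finite(tab$ratio)
    expect_equal(d$fraction_below_1,
                 sum(tab$ratio[fin] < 1) / (sum(fin) + 5))
  }
})

test_that("orfeome_summary averages and excludes sentinels from the ratio mean", {
  tab <- random_orfeome_table(1)
  tab$aa_count <- 1L; tab$ag_count <- 2L
  tab$ratio <- 0.5; tab$total_codons <- 300L
  s <- orfeome_summary(tab)
  expect_equal(s$mean_ratio, 0.5)
  expect_equal(s$mean_total_codons, 300)

  tab2 <- rbind(tab, tab)
  tab2$id <- c("a", "b")
  tab2$ratio <- c(0.5, Inf)
  s2 <- orfeome_summary(tab2)
  expect_equal(s2$mean_ratio, 0.5)       # Inf excluded
  expect_equal(s2$mean_total_codons, 300) # but its length still counted
  expect_equal(s2$n_finite_ratio, 1)
})

test_that("prevalence_scan evaluates OR-combined rule clauses", {
  tab <- random_orfeome_table(4)
  tab$total_codons <- c(2000L, 100L, 600L, 200L)
  tab$ratio <- c(1.5, 0.1, 1.5, 0.5)
  res <- prevalence_scan(tab, prevalence_ruleset("stringent"))
  expect_equal(res$n_matched, 2)
  expect_equal(res$fraction, 0.5)
  expect_setequal(res$ids, tab$id[1:2])

  expect_equal(prevalence_scan(tab, list())$n_matched, 0)
  expect_error(prevalence_rule(), class = "EMPTY_RULE")
  expect_error(prevalence_rule(min_codons = 10, max_codons = 20),
               class = "CONFLICTING_BOUNDS")
})

test_that("prevalence rules load from YAML and sentinels behave", {
  yml <- tempfile(fileext = ".yaml")
  writeLines(c("- min_codons: 1755", "  ratio_gt: 1.3",
               "- max_codons: 150", "  ratio_lt: 0.3"), yml)
  tab <- random_orfeome_table(4)
  tab$total_codons <- c(2000L, 100L, 2000L, 100L)
  tab$ratio <- c(Inf, NaN, 1.0, 0.2)
  res <- prevalence_scan(tab, prevalence_ruleset(yml))
  # Inf passes ratio > 1.3; NaN fails ratio < 0.3
  expect_setequal(res$ids, c(tab$id[1], tab$id[4]))
})

test_that("loosening any prevalence bound never shrinks the match set", {
  set.seed(9)
  for (i in 1:20) {
    tab <- random_orfeome_table(100)
    strict <- list(prevalence_rule(min_codons = 600, ratio_gt = 0.8))
    loose_len <- list(prevalence_rule(min_codons = 400, ratio_gt = 0.8))
    loose_ratio <- list(prevalence_rule(min_codons = 600, ratio_gt = 0.6))
    ids_s <- prevalence_scan(tab, strict)$ids
    expect_true(all(ids_s %in% prevalence_scan(tab, loose_len)$ids))
    expect_true(all(ids_s %in% prevalence_scan(tab, loose_ratio)$ids))
  }
})

test_that("TSV round trip preserves ratio sentinels", {
  tab <- random_orfeome_table(5)
  tab$ratio[1] <- Inf
  tab$ratio[2] <- NaN
  path <- tempfile(fileext = ".tsv")
  write_bias_tsv(tab, path)
  line2 <- readLines(path)[2]
  expect_match(line2, "\tinf\t")
  back <- read_bias_tsv(path)
  expect_identical(back$ratio[1], Inf)
  expect_true(is.nan(back$ratio[2]))
  expect_equal(back$ratio[3:5], tab$ratio[3:5])
})
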