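test_that("generator configuration is validated", {
  expect_s3_class(generator_config(), "generator_config")
  expect_error(generator_config(n_genes = 0), class = "INVALID_CONFIG")
  expect_error(generator_config(kqe_fraction = 1.2), class = "INVALID_CONFIG")
  expect_error(generator_config(sigma = -1), class = "INVALID_CONFIG")
})

test_that("the generator is deterministic under its seed", {
  cfg <- generator_config(n_genes = 50, seed = 101)
  a <- gen_study(cfg)
  b <- gen_study(cfg)
  expect_identical(vapply(a$cds, `[[`, character(1), "seq"),
                   vapply(b$cds, `[[`, character(1), "seq"))
  expect_identical(a$manifest, b$manifest)
  expect_identical(a$prot, b$prot)
  expect_false(identical(
    a$manifest$ratio,
    gen_study(generator_config(n_genes = 50, seed = 102))$manifest$ratio))
})

test_that("the manifest is unchanged whether sequences are materialized", {
  cfg <- generator_config(n_genes = 80, seed = 3)
  with_seq <- gen_orfeome(cfg, sequences = TRUE)
  without <- gen_orfeome(cfg, sequences = FALSE)
  expect_identical(with_seq$manifest, without$manifest)
  expect_null(without$cds)
})

test_that("manifest counts agree with scanning the emitted sequences", {
  cfg <- generator_config(n_genes = 60, seed = 19)
  orf <- gen_orfeome(cfg)
  tab <- scan_orfeome(orf$cds)
  expect_equal(nrow(tab), 60)
  expect_equal(tab$aa_count, orf$manifest$aa_count)
  expect_equal(tab$ag_count, orf$manifest$ag_count)
  expect_equal(tab$total_codons, orf$manifest$total_codons)
})

test_that("a degenerate config forces an all-AA ORFeome", {
  cfg <- generator_config(n_genes = 1, seed = 2,
                          length_log_mean = log(100), length_log_sd = 1e-6,
                          ratio_beta_a = 1e8, ratio_beta_b = 1e-8)
  orf <- gen_orfeome(cfg)
  prof <- count_codons(orf$cds[[1]])
  expect_equal(prof$total_codons, 101)  # 100 coding + stop
  expect_equal(prof$ag_count, 0)
  expect_gt(prof$aa_count, 0)
})

test_that("sample mean ratio matches an independent Monte-Carlo oracle", {
  # oracle: simulate the stated generative law directly, without gen_orfeome
  set.seed(77)
  cfg <- generator_config(n_genes = 2000, seed = 55)
  mc <- replicate(4000, {
    L <- max(50, round(stats::rlnorm(1, cfg$length_log_mean, cfg$length_log_sd)))
    k <- stats::rbinom(1, L, cfg$kqe_fraction)
    p <- stats::rbeta(1, cfg$ratio_beta_a, cfg$ratio_beta_b)
    aa <- stats::rbinom(1, k, p)
    if (aa < k) aa / (k - aa) else NA_real_  # finite ratios only
  })
  mc_mean <- mean(mc, na.rm = TRUE)
  mc_se <- stats::sd(mc, na.rm = TRUE) / sqrt(sum(!is.na(mc)))

  man <- gen_orfeome(cfg, sequences = FALSE)$manifest
  fin <- is.finite(man$ratio)
  sample_mean <- mean(man$ratio[fin])
  sample_se <- stats::sd(man$ratio[fin]) / sqrt(sum(fin))
  tol <- 3 * sqrt(mc_se^2 + sample_se^2)
  expect_lt(abs(sample_mean - mc_mean), tol)
})

test_that("with zero couplings the depleted fraction is the Normal tail", {
  cfg <- generator_config(n_genes = 2000, seed = 9, beta_aa = 0, beta_ag = 0)
  man <- gen_orfeome(cfg, sequences = FALSE)$manifest
  om <- gen_omics(man, cfg)
  p_dep <- mean(classify_fc(om$prot$fc) == "DEPLETED")
  p_expect <- stats::pnorm(-1, 0, cfg$sigma)
  se <- sqrt(p_expect * (1 - p_expect) / cfg$n_genes)
  expect_lt(abs(p_dep - p_expect), 3 * se)
  # and the recorded truth has no systematic effect at all
  expect_true(all(om$truth$effect_log2 == 0))
})

test_that("an unbiased gene receives zero systematic effect", {
  man <- data.frame(id = "c1", gene = "g1", total_codons = 500L,
                    kqe_count = 20L, aa_count = 10L, ag_count = 10L,
                    ratio = 1, p_aa = 0.5, stringsAsFactors = FALSE)
  om <- gen_omics(man, generator_config(n_genes = 1, seed = 4))
  expect_equal(om$truth$effect_log2, 0)
  expect_equal(om$truth$x_aa, 0)
  expect_equal(om$truth$x_ag, 0)
})

test_that("truth classes come from the noise-free effect at +/-1 log2", {
  cfg <- generator_config(n_genes = 500, seed = 21, beta_aa = 3, beta_ag = 3)
  man <- gen_orfeome(cfg, sequences = FALSE)$manifest
  om <- gen_omics(man, cfg)
  mu <- om$truth$effect_log2
  expect_identical(as.character(om$truth$truth_class),
                   ifelse(mu <= -1, "DEPLETED", ifelse(mu >= 1, "UP", "NORMAL")))
  expect_true(all(c("DEPLETED", "UP") %in% om$truth$truth_class))
})

test_that("regression on the effect covariates recovers the couplings", {
  cfg <- generator_config(n_genes = 5000, seed = 33)
  man <- gen_orfeome(cfg, sequences = FALSE)$manifest
  om <- gen_omics(man, cfg)
  betas <- recover_betas(man, om$prot)
  expect_lt(abs(betas["beta_aa"] - cfg$beta_aa) / cfg$beta_aa, 0.15)
  expect_lt(abs(betas["beta_ag"] - cfg$beta_ag) / cfg$beta_ag, 0.15)
})

test_that("pipeline closure: no genes drop when all detection flags are true", {
  cfg <- generator_config(n_genes = 150, seed = 13, undetected_fraction = 0)
  study <- gen_study(cfg)
  dir <- tempfile()
  write_study(study, dir)
  expect_true(file.exists(file.path(dir, "orfeome.fa")))

  cds <- read_cds_fasta(file.path(dir, "orfeome.fa"))
  expect_length(cds, 150)
  tab <- scan_orfeome(cds)
  rna <- read_bias_tsv(file.path(dir, "rna.tsv"))
  prot <- read_bias_tsv(file.path(dir, "prot.tsv"))
  rows <- merge_and_filter(rna, prot, tab)
  # the only losses are the normal-transcription filter, applied as stated
  expect_equal(nrow(rows), sum(rna$fc > -1.5 & rna$fc < 1.5))
  bins <- default_grid(rows, "aa")
  expect_true(all(bins$n_genes <= nrow(rows)))
})
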