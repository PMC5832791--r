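# Synthetic study generator: ORFeomes with a realistic length / K-Q-E content
# / AA:AG ratio structure, plus matched transcriptome and proteome fold-change
# tables in which protein depletion is coupled to AA bias scaled by transcript
# length and upregulation to AG bias scaled by shortness. The effect model is
# this package's invention — the study it emulates reports empirical trends,
# not a generative law — and exists so every pipeline stage is testable with
# known ground truth and no external downloads.

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Configuration for the synthetic study generator
#'
#' Defaults emulate mammalian ORFeome-scale facts: lognormal CDS lengths with
#' a mean of ~556 total codons (stop included) and enough spread that ~3% of
#' genes exceed 1,755 codons; a mean K/Q/E codon fraction of 0.16; a per-gene
#' AA fraction among K/Q/E codons drawn from Beta(2, 3.99), giving a mean
#' AA:AG ratio of ~0.67 with the distribution mode below 1, a mean AA-ending
#' count of ~30, and tail occupancies (the fraction of genes simultaneously
#' long and AA-biased, or short and AG-biased) close to those observed in
#' mammalian ORFeomes; and fold-change couplings `beta_aa = beta_ag = 1.2`
#' with protein noise `sigma = 0.6` and transcript noise `rna_sigma = 0.2`
#' (log2 scale), which give non-degenerate class proportions at n = 2,000.
#'
#' @param n_genes number of genes.
#' @param seed RNG seed (integer).
#' @param length_log_mean,length_log_sd lognormal parameters of the CDS
#'   length in non-stop codons.
#' @param kqe_fraction mean fraction of codons encoding Lys/Gln/Glu.
#' @param ratio_beta_a,ratio_beta_b Beta parameters for the per-gene
#'   AA-ending fraction among K/Q/E codons.
#' @param beta_aa,beta_ag coupling strengths of protein log2 fold change to
#'   length-scaled AA bias (depletion) and shortness-scaled AG bias
#'   (upregulation).
#' @param sigma,rna_sigma log2-scale noise SD of the protein and transcript
#'   fold changes.
#' @param undetected_fraction fraction of genes flagged undetected in one
#'   randomly chosen assay/genotype, to exercise the detection filters.
#' @return a `generator_config` list.
#' @export
generator_config <- function(n_genes = 2000L,
                             seed = 1L,
                             length_log_mean = log(555) - 0.8^2 / 2,
                             length_log_sd = 0.8,
                             kqe_fraction = 0.16,
                             ratio_beta_a = 2,
                             ratio_beta_b = 2 / 0.67 + 1,
                             beta_aa = 1.2,
                             beta_ag = 1.2,
                             sigma = 0.6,
                             rna_sigma = 0.2,
                             undetected_fraction = 0.05) {
  cfg <- list(n_genes = as.integer(n_genes), seed = as.integer(seed),
              length_log_mean = length_log_mean, length_log_sd = length_log_sd,
              kqe_fraction = kqe_fraction,
              ratio_beta_a = ratio_beta_a, ratio_beta_b = ratio_beta_b,
              beta_aa = beta_aa, beta_ag = beta_ag,
              sigma = sigma, rna_sigma = rna_sigma,
              undetected_fraction = undetected_fraction)
  ok <- cfg$n_genes >= 1 &&
    is.finite(cfg$length_log_mean) && cfg$length_log_sd > 0 &&
    cfg$kqe_fraction > 0 && cfg$kqe_fraction < 1 &&
    cfg$ratio_beta_a > 0 && cfg$ratio_beta_b > 0 &&
    cfg$beta_aa >= 0 && cfg$beta_ag >= 0 &&
    cfg$sigma > 0 && cfg$rna_sigma > 0 &&
    cfg$undetected_fraction >= 0 && cfg$undetected_fraction < 1
  wb_assert(ok, "INVALID_CONFIG", "invalid generator configuration")
  structure(cfg, class = "generator_config")
}

# sample() without the scalar-x surprise
resample <- function(x, size, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

#' Generate a synthetic ORFeome
#'
#' Per gene: length `L` (non-stop codons) drawn lognormal and rounded with a
#' floor of 50; a binomial number of K/Q/E positions at `kqe_fraction`; a
#' per-gene AA-ending fraction `p ~ Beta(a, b)`; a binomial AA-ending count
#' among the K/Q/E codons at `p`, with the codon identity uniform within
#' {AAA, CAA, GAA} or {AAG, CAG, GAG}; all remaining codons uniform over the
#' 55 non-stop, non-K/Q/E codons; one terminal stop codon appended.
#' Deterministic under `config$seed`. All per-gene quantities are drawn
#' before any sequence is materialized, so the manifest is identical whether
#' or not sequences are built.
#'
#' @param config a [generator_config()].
#' @param sequences build the actual nucleotide sequences (`TRUE`, default)
#'   or only the count manifest (`FALSE`, much faster; sufficient for
#'   [gen_omics()]).
#' @return a list with `cds` (list of `CodingSequence`, or `NULL` when
#'   `sequences = FALSE`) and `manifest` (data frame `id`, `gene`,
#'   `total_codons` (stop included), `kqe_count`, `aa_count`, `ag_count`,
#'   `ratio`, `p_aa`).
#' @export
gen_orfeome <- function(config, sequences = TRUE) {
  wb_assert(inherits(config, "generator_config"), "INVALID_CONFIG",
            "config must come from generator_config()")
  n <- config$n_genes
  set.seed(config$seed)
  len <- pmax(50L, as.integer(round(stats::rlnorm(
    n, config$length_log_mean, config$length_log_sd))))
  kqe_n <- stats::rbinom(n, len, config$kqe_fraction)
  p_aa <- stats::rbeta(n, config$ratio_beta_a, config$ratio_beta_b)
  aa_n <- stats::rbinom(n, kqe_n, p_aa)
  ag_n <- kqe_n - aa_n
  manifest <- data.frame(
    id = sprintf("SYNC%05d.1", seq_len(n)),
    gene = sprintf("SYNG%05d", seq_len(n)),
    total_codons = len + 1L,
    kqe_count = kqe_n,
    aa_count = aa_n,
    ag_count = ag_n,
    ratio = aa_ag_ratio(aa_n, ag_n),
    p_aa = p_aa,
    stringsAsFactors = FALSE
  )
  cds <- NULL
  if (sequences) {
    other <- setdiff(mkAllCodons(), c(AA_CODONS, AG_CODONS, STOP_CODONS))
    cds <- vector("list", n)
    for (i in seq_len(n)) {
      codons <- resample(other, len[i], replace = TRUE)
      if (kqe_n[i] > 0) {
        pos <- resample(seq_len(len[i]), kqe_n[i])
        aa_pos <- resample(pos, aa_n[i])
        codons[aa_pos] <- resample(AA_CODONS, aa_n[i], replace = TRUE)
        codons[setdiff(pos, aa_pos)] <- resample(AG_CODONS, ag_n[i],
                                                 replace = TRUE)
      }
      seq <- paste(c(codons, resample(STOP_CODONS, 1)), collapse = "")
      cds[[i]] <- validate_cds(seq, id = manifest$id[i],
                               gene = manifest$gene[i])
    }
  }
  list(cds = cds, manifest = manifest)
}

mkAllCodons <- function() {
  b <- c("A", "C", "G", "T")
  as.vector(outer(outer(b, b, paste0), b, paste0))
}

# Length-scaled AA-bias and shortness-scaled AG-bias effect covariates. The
# ratio inside the log is smoothed with +0.5 pseudocounts so genes with zero
# AA- or AG-ending codons get a finite, saturating effect.
effect_covariates <- function(manifest) {
  r <- (manifest$aa_count + 0.5) / (manifest$ag_count + 0.5)
  L <- manifest$total_codons
  list(x_aa = pmax(0, log2(r)) * pmin(L / 1755, 1),
       x_ag = pmax(0, -log2(r)) * pmin(150 / L, 1))
}

#' Generate matched transcriptome and proteome fold-change tables
#'
#' Transcript log2 fold change is pure noise, `N(0, rna_sigma)` (the study
#' design conditions on normal transcription). Protein log2 fold change is
#' `-beta_aa * x_aa + beta_ag * x_ag + N(0, sigma)` where `x_aa` is the
#' positive part of the log2 AA:AG ratio scaled by `min(L/1755, 1)` and
#' `x_ag` the positive part of the negative log2 ratio scaled by
#' `min(150/L, 1)`: depletion strengthens with AA bias on long transcripts,
#' upregulation with AG bias on short ones. Fold changes are emitted on the
#' signed scale. A fraction of genes is flagged undetected in one randomly
#' chosen assay/genotype. The truth class is recorded from the noise-free
#' effect at +/-1 on the log2 scale.
#'
#' @param manifest the manifest from [gen_orfeome()].
#' @param config the same [generator_config()].
#' @return a list with `rna` (`gene`, `fc`, `detected_ctrl`,
#'   `detected_cko`), `prot` (the same plus `n_peptides`), and `truth`
#'   (`gene`, `effect_log2`, `truth_class`, `x_aa`, `x_ag`).
#' @export
gen_omics <- function(manifest, config) {
  wb_assert(inherits(config, "generator_config"), "INVALID_CONFIG",
            "config must come from generator_config()")
  wb_assert(is.data.frame(manifest) && nrow(manifest) > 0 &&
              all(c("gene", "total_codons", "aa_count", "ag_count") %in%
                    names(manifest)),
            "INVALID_CONFIG", "manifest must come from gen_orfeome()")
  n <- nrow(manifest)
  set.seed(config$seed + 1L)
  cov <- effect_covariates(manifest)
  mu <- -config$beta_aa * cov$x_aa + config$beta_ag * cov$x_ag
  rna_l2 <- stats::rnorm(n, 0, config$rna_sigma)
  prot_l2 <- mu + stats::rnorm(n, 0, config$sigma)
  n_pep <- stats::rpois(n, 5) + 1L

  flags <- matrix(TRUE, n, 4)
  n_und <- floor(config$undetected_fraction * n)
  if (n_und > 0) {
    genes_und <- resample(seq_len(n), n_und)
    which_flag <- resample(1:4, n_und, replace = TRUE)
    flags[cbind(genes_und, which_flag)] <- FALSE
  }

  truth_class <- factor(
    ifelse(mu <= -1, "DEPLETED", ifelse(mu >= 1, "UP", "NORMAL")),
    levels = c("DEPLETED", "NORMAL", "UP"))

  list(
    rna = data.frame(gene = manifest$gene,
                     fc = signed_fc(2^rna_l2),
                     detected_ctrl = flags[, 1], detected_cko = flags[, 2],
                     stringsAsFactors = FALSE),
    prot = data.frame(gene = manifest$gene,
                      fc = signed_fc(2^prot_l2),
                      detected_ctrl = flags[, 3], detected_cko = flags[, 4],
                      n_peptides = n_pep,
                      stringsAsFactors = FALSE),
    truth = data.frame(gene = manifest$gene,
                       effect_log2 = mu,
                       truth_class = truth_class,
                       x_aa = cov$x_aa, x_ag = cov$x_ag,
                       stringsAsFactors = FALSE)
  )
}

#' Generate a complete synthetic study
#'
#' Convenience wrapper: [gen_orfeome()] then [gen_omics()].
#'
#' @param config a [generator_config()].
#' @param sequences materialize nucleotide sequences (see [gen_orfeome()]).
#' @return a `synthetic_study` list: `cds`, `manifest`, `rna`, `prot`,
#'   `truth`, `config`.
#' @export
gen_study <- function(config = generator_config(), sequences = TRUE) {
  orf <- gen_orfeome(config, sequences = sequences)
  om <- gen_omics(orf$manifest, config)
  structure(c(orf, om, list(config = config)), class = "synthetic_study")
}

#' Write a synthetic study to disk
#'
#' Writes `orfeome.fa` (FASTA, headers `id|gene`), `rna.tsv`, `prot.tsv`,
#' `truth.tsv`, `manifest.tsv` and `manifest.json` (the configuration and
#' row count) into `dir`.
#'
#' @param study from [gen_study()] (with sequences).
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_study <- function(study, dir) {
  wb_assert(inherits(study, "synthetic_study"), "INVALID_ARGUMENT",
            "study must come from gen_study()")
  wb_assert(!is.null(study$cds), "INVALID_ARGUMENT",
            "study was generated without sequences; use gen_study(sequences = TRUE)")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seqs <- Biostrings::DNAStringSet(vapply(study$cds, function(x) x$seq,
                                          character(1)))
  names(seqs) <- vapply(study$cds, function(x) paste(x$id, x$gene, sep = "|"),
                        character(1))
  Biostrings::writeXStringSet(seqs, file.path(dir, "orfeome.fa"))
  utils::write.table(study$rna, file.path(dir, "rna.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(study$prot, file.path(dir, "prot.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(study$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_bias_tsv(study$manifest, file.path(dir, "manifest.tsv"))
  jsonlite::write_json(c(unclass(study$config),
                         list(n_rows = nrow(study$manifest))),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Recover the generator's coupling strengths from a synthetic study
#'
#' Consistency check of the generative model: regresses observed protein
#' log2 fold changes on the effect covariates recomputed from the observed
#' codon counts. With the default noise level the estimates land within a
#' few percent of `beta_aa`/`beta_ag` at n = 5,000.
#'
#' @param manifest manifest from [gen_orfeome()].
#' @param prot proteome table from [gen_omics()].
#' @return named numeric vector `c(beta_aa = ..., beta_ag = ...)`.
#' @export
recover_betas <- function(manifest, prot) {
  cov <- effect_covariates(manifest)
  y <- signed_to_log2(prot$fc[match(manifest$gene, prot$gene)])
  fit <- stats::lm(y ~ 0 + x_aa + x_ag,
                   data = data.frame(y = y, x_aa = -cov$x_aa, x_ag = cov$x_ag))
  c(beta_aa = unname(stats::coef(fit)["x_aa"]),
    beta_ag = unname(stats::coef(fit)["x_ag"]))
}
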