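# Transcriptome x proteome integration: merge gene-level fold-change tables,
# apply the detection and normal-transcription filters, attach per-gene codon
# bias profiles, and classify protein fold changes.

#' Convert an expression ratio to a signed fold change
#'
#' Signed convention: a CKO/control ratio `x >= 1` stays `x` (x-fold up);
#' a ratio `x < 1` becomes `-1/x` (|x|-fold down), so "fold change <= -2"
#' means halved or more and no signed value lies strictly between -1 and 1.
#'
#' @param ratio_value positive expression ratio(s) (CKO / control).
#' @return signed fold change(s).
#' @examples
#' signed_fc(c(2, 0.5, 1))  #  2, -2, 1
#' @export
signed_fc <- function(ratio_value) {
  wb_assert(is.numeric(ratio_value) && all(ratio_value > 0),
            "NONPOSITIVE_RATIO", "expression ratios must be positive")
  ifelse(ratio_value >= 1, ratio_value, -1 / ratio_value)
}

# Signed <-> log2 helpers for averaging and simulation.
signed_to_log2 <- function(fc) sign(fc) * log2(abs(fc))
log2_to_signed <- function(l2) ifelse(l2 >= 0, 2^l2, -2^(-l2))

# Means on the signed scale can fall in the open interval (-1, 1), which no
# signed fold change occupies; snap such means to the nearest valid value.
snap_signed <- function(fc) {
  ifelse(fc >= 1 | fc <= -1, fc, ifelse(fc >= 0, 1, -1))
}

#' Classify a protein fold change
#'
#' `DEPLETED` iff signed fold change <= -2; `UP` iff >= 2; `NORMAL` for
#' values strictly between (boundaries inclusive toward the extreme classes).
#'
#' @param protein_fc signed fold change(s); `|protein_fc| >= 1`.
#' @return factor with levels `DEPLETED`, `NORMAL`, `UP`.
#' @examples
#' classify_fc(c(-2, 1, 2))  # DEPLETED NORMAL UP
#' @export
classify_fc <- function(protein_fc) {
  wb_assert(is.numeric(protein_fc) && all(abs(protein_fc) >= 1),
            "INVALID_SIGNED_FC",
            "signed fold changes have absolute value >= 1")
  factor(ifelse(protein_fc <= -2, "DEPLETED",
         ifelse(protein_fc >= 2, "UP", "NORMAL")),
         levels = c("DEPLETED", "NORMAL", "UP"))
}

# Collapse duplicate RNA probes: average signed fold changes on the signed
# scale ("average fold change values"), AND the detection flags.
collapse_rna <- function(rna) {
  if (!anyDuplicated(rna$gene)) return(rna)
  sp <- split(rna, rna$gene)
  out <- do.call(rbind, lapply(sp, function(d) {
    data.frame(gene = d$gene[1],
               fc = snap_signed(mean(d$fc)),
               detected_ctrl = all(d$detected_ctrl),
               detected_cko = all(d$detected_cko),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

# Collapse duplicate proteome rows: keep the entry with the most peptides,
# else the first as read; log the count collapsed.
collapse_prot <- function(prot) {
  if (!anyDuplicated(prot$gene)) return(prot)
  n_dup <- sum(duplicated(prot$gene))
  if (!"n_peptides" %in% names(prot)) prot$n_peptides <- NA_real_
  ord <- order(match(prot$gene, prot$gene),
               -ifelse(is.na(prot$n_peptides), -Inf, prot$n_peptides))
  prot <- prot[ord, , drop = FALSE]
  prot <- prot[!duplicated(prot$gene), , drop = FALSE]
  message(sprintf("merge_and_filter: collapsed %d duplicate proteome row(s)",
                  n_dup))
  rownames(prot) <- NULL
  prot
}

#' Merge omics tables, filter, and attach bias profiles
#'
#' Reproduces the analysis-set construction: keep genes (a) present in both
#' the transcriptome and proteome tables, (b) detected in both genotypes in
#' both assays (genes detected in only one genotype are dropped, not
#' imputed), and (c) transcribed normally, i.e. with signed transcript fold
#' change strictly between `-rna_fc_bound` and `rna_fc_bound`. Each survivor
#' is annotated with its codon-bias profile by gene symbol (case-insensitive;
#' when the bias table has several CDSs per gene, collapse it first with
#' `scan_orfeome(..., collapse = "longest")`). Genes without a bias profile
#' are dropped with a logged count.
#'
#' @param rna data frame with columns `gene`, `fc` (signed), `detected_ctrl`,
#'   `detected_cko`. Duplicate probes per gene are averaged on the signed
#'   scale before filtering.
#' @param prot data frame with the same columns plus optional `n_peptides`;
#'   duplicate rows are resolved by the entry with the most peptides.
#' @param bias an ORFeome table from [scan_orfeome()].
#' @param rna_fc_bound strict bound on the transcript fold change
#'   (default 1.5; a gene at exactly the bound is excluded).
#' @return a class-row data frame: `gene`, `id`, `total_codons`, `aa_count`,
#'   `ag_count`, `ratio`, `transcript_fc`, `protein_fc`, `fc_class`.
#' @export
merge_and_filter <- function(rna, prot, bias, rna_fc_bound = 1.5) {
  for (nm in c("gene", "fc", "detected_ctrl", "detected_cko")) {
    wb_assert(nm %in% names(rna) && nm %in% names(prot), "MISSING_COLUMN",
              sprintf("rna and prot tables need column '%s'", nm))
  }
  wb_assert(rna_fc_bound >= 1, "INVALID_BOUND", "rna_fc_bound must be >= 1")
  rna <- rna[, intersect(names(rna),
                         c("gene", "fc", "detected_ctrl", "detected_cko"))]
  rna$gene <- toupper(rna$gene)
  prot$gene <- toupper(prot$gene)
  rna <- collapse_rna(rna)
  prot <- collapse_prot(prot)

  m <- merge(rna, prot, by = "gene", suffixes = c("_rna", "_prot"))
  wb_assert(nrow(m) > 0, "EMPTY_JOIN",
            "no genes shared between the rna and prot tables")
  detected <- m$detected_ctrl_rna & m$detected_cko_rna &
    m$detected_ctrl_prot & m$detected_cko_prot
  m <- m[detected, , drop = FALSE]
  m <- m[m$fc_rna > -rna_fc_bound & m$fc_rna < rna_fc_bound, , drop = FALSE]
  wb_assert(nrow(m) > 0, "EMPTY_JOIN",
            "no genes survive the detection and transcription filters")

  b <- bias
  b$gene_key <- toupper(b$gene)
  if (anyDuplicated(b$gene_key[!is.na(b$gene_key)])) {
    wb_stop("DUPLICATE_GENE",
            paste("bias table has several rows per gene symbol;",
                  "collapse it first with scan_orfeome(collapse = 'longest')"))
  }
  idx <- match(m$gene, b$gene_key)
  n_missing <- sum(is.na(idx))
  if (n_missing > 0) {
    message(sprintf(
      "merge_and_filter: dropped %d gene(s) lacking a bias profile", n_missing))
  }
  keep <- !is.na(idx)
  m <- m[keep, , drop = FALSE]
  idx <- idx[keep]
  wb_assert(nrow(m) > 0, "EMPTY_JOIN",
            "no surviving gene has a bias profile")
  out <- data.frame(
    gene = m$gene,
    id = b$id[idx],
    total_codons = b$total_codons[idx],
    aa_count = b$aa_count[idx],
    ag_count = b$ag_count[idx],
    ratio = b$ratio[idx],
    transcript_fc = m$fc_rna,
    protein_fc = m$fc_prot,
    stringsAsFactors = FALSE
  )
  out$fc_class <- classify_fc(out$protein_fc)
  rownames(out) <- NULL
  out
}
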