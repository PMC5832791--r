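# Test fixtures and independent oracles. The oracles here deliberately use
# naive position-by-position loops (or Biostrings' own engines) so they share
# no code path with the implementation they check.

# Random in-frame DNA string of n_codons trinucleotides.
random_cds_string <- function(n_codons, p_n = 0) {
  alphabet <- c("A", "C", "G", "T")
  nt <- sample(alphabet, 3 * n_codons, replace = TRUE)
  if (p_n > 0) {
    mask <- stats::runif(length(nt)) < p_n
    nt[mask] <- "N"
  }
  paste(nt, collapse = "")
}

# Brute-force codon-count oracle: a character-walking for loop.
brute_count <- function(seq) {
  seq <- toupper(seq)
  aa_set <- c("AAA", "CAA", "GAA")
  ag_set <- c("AAG", "CAG", "GAG")
  total <- 0L; aa <- 0L; ag <- 0L; amb <- 0L
  for (i in seq(1L, nchar(seq) - 2L, by = 3L)) {
    codon <- substr(seq, i, i + 2L)
    if (grepl("N", codon, fixed = TRUE)) {
      amb <- amb + 1L
    } else {
      total <- total + 1L
      if (codon %in% aa_set) aa <- aa + 1L
      if (codon %in% ag_set) ag <- ag + 1L
    }
  }
  list(total = total, aa = aa, ag = ag, amb = amb)
}

# Translation oracle via Biostrings' own translation engine.
oracle_translate <- function(seq) {
  as.character(Biostrings::translate(Biostrings::DNAString(seq),
                                     if.fuzzy.codon = "X"))
}

# Build a class-row data frame from parallel vectors.
make_class_rows <- function(ratio, total_codons, protein_fc,
                            aa_count = round(pmax(0, ratio) * 10),
                            gene = sprintf("G%03d", seq_along(ratio))) {
  data.frame(gene = gene, id = gene, total_codons = total_codons,
             aa_count = aa_count,
             ag_count = ifelse(is.finite(ratio) & ratio > 0,
                               round(aa_count / ratio), 0L),
             ratio = ratio, transcript_fc = 1,
             protein_fc = protein_fc,
             fc_class = classify_fc(protein_fc),
             stringsAsFactors = FALSE)
}

# Random ORFeome-like table for property tests.
random_orfeome_table <- function(n) {
  aa <- stats::rpois(n, 20)
  ag <- stats::rpois(n, 30)
  data.frame(id = sprintf("C%04d", seq_len(n)),
             gene = sprintf("G%04d", seq_len(n)),
             total_codons = 50L + stats::rpois(n, 500),
             aa_count = aa, ag_count = ag,
             ratio = aa_ag_ratio(aa, ag),
             n_ambiguous = 0L,
             stringsAsFactors = FALSE)
}

# Minimal single-record FASTA writer for input fixtures.
write_fasta <- function(headers, seqs, path) {
  writeLines(as.vector(rbind(paste0(">", headers), seqs)), path)
  path
}
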