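# Codon-level primitives: CDS validation, in-frame codon counting, and the
# AA:AG wobble-bias statistic for lysine (AAA/AAG), glutamine (CAA/CAG) and
# glutamate (GAA/GAG).
#
# Loss of the Elongator complex abolishes the mcm5s2 modification of the tRNA
# wobble uridine (U34) and impairs decoding of A-ending codons for these three
# amino acids. A transcript's dependence on that modification is summarised by
# the AA:AG ratio: the count of AA-ending codons divided by the count of their
# AG-ending synonymous counterparts. A ratio of 1 means unbiased usage; below
# 1 means AG preference (the genomic norm); above 1 means AA bias.

#' Codons whose third position pairs with the modified wobble uridine
#'
#' `AA_CODONS` are the A-ending codons for Lys/Gln/Glu (AAA, CAA, GAA), whose
#' efficient decoding requires the mcm5s2 U34 tRNA modification.
#' `AG_CODONS` are their G-ending synonymous counterparts (AAG, CAG, GAG).
#'
#' @format Character vectors of length 3.
#' @export
AA_CODONS <- c("AAA", "CAA", "GAA")

#' @rdname AA_CODONS
#' @export
AG_CODONS <- c("AAG", "CAG", "GAG")

#' Validate and normalize a coding sequence
#'
#' Upper-cases the input, checks the alphabet ({A,C,G,T,N}) and that the
#' length is a positive multiple of 3, and returns a `CodingSequence` object.
#' No internal-stop or start-codon check is performed: consensus CDS entries
#' are counted mechanically in frame 0.
#'
#' @param seq a DNA string.
#' @param id identifier for the sequence.
#' @param gene optional gene symbol.
#' @return an object of class `CodingSequence` with fields `id`, `gene`,
#'   `seq` (normalized upper-case DNA).
#' @examples
#' validate_cds("atggaataa")
#' @export
validate_cds <- function(seq, id = "cds", gene = NA_character_) {
  wb_assert(is.character(seq) && length(seq) == 1 && !is.na(seq) && nzchar(seq),
            "EMPTY_SEQUENCE", "seq must be a single non-empty DNA string")
  seq <- unname(toupper(seq))
  if (grepl("[^ACGTN]", seq)) {
    bad <- unique(strsplit(gsub("[ACGTN]", "", seq), "")[[1]])
    wb_stop("INVALID_CHARACTER",
            sprintf("sequence '%s' contains characters outside ACGTN: %s",
                    id, paste(bad, collapse = ", ")))
  }
  if (nchar(seq) %% 3L != 0L) {
    wb_stop("LENGTH_NOT_MULTIPLE_OF_3",
            sprintf("sequence '%s' has length %d, not a multiple of 3",
                    id, nchar(seq)))
  }
  structure(list(id = id, gene = gene, seq = seq), class = "CodingSequence")
}

#' @export
print.CodingSequence <- function(x, ...) {
  cat(sprintf("<CodingSequence %s%s: %d nt / %d codons>\n", x$id,
              if (is.na(x$gene)) "" else paste0(" (", x$gene, ")"),
              nchar(x$seq), nchar(x$seq) %/% 3L))
  invisible(x)
}

# Split a normalized in-frame CDS string into its codon vector.
split_codons <- function(seq) {
  n <- nchar(seq)
  substring(seq, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

#' Count codons and compute the AA:AG bias profile of a CDS
#'
#' Counts every trinucleotide in frame 0, including the terminal stop codon.
#' Codons containing N are excluded from the total and the AA/AG tallies and
#' are counted separately in `n_ambiguous`; a sequence whose ambiguous codons
#' exceed 10% of its trinucleotides is flagged, not dropped.
#'
#' @param cds a `CodingSequence` (from [validate_cds()]) or a DNA string,
#'   which is validated first.
#' @return an object of class `BiasProfile`: a list with `total_codons`,
#'   `aa_count`, `ag_count`, `ratio` (see [aa_ag_ratio()]), `n_ambiguous`,
#'   and `flagged_ambiguous`.
#' @examples
#' count_codons("AAACAAGAA")  # three AA-ending codons
#' @export
count_codons <- function(cds) {
  if (!inherits(cds, "CodingSequence")) cds <- validate_cds(cds)
  codons <- split_codons(cds$seq)
  ambiguous <- grepl("N", codons, fixed = TRUE)
  clean <- codons[!ambiguous]
  aa <- sum(clean %in% AA_CODONS)
  ag <- sum(clean %in% AG_CODONS)
  n_amb <- sum(ambiguous)
  structure(list(
    total_codons = length(clean),
    aa_count = aa,
    ag_count = ag,
    ratio = aa_ag_ratio(aa, ag),
    n_ambiguous = n_amb,
    flagged_ambiguous = n_amb > 0.10 * length(codons)
  ), class = "BiasProfile")
}

#' @export
print.BiasProfile <- function(x, ...) {
  cat(sprintf("<BiasProfile: %d codons, AA=%d, AG=%d, AA:AG=%s%s>\n",
              x$total_codons, x$aa_count, x$ag_count, format_ratio(x$ratio),
              if (x$n_ambiguous > 0) sprintf(", %d ambiguous", x$n_ambiguous) else ""))
  invisible(x)
}

#' The AA:AG codon-bias ratio
#'
#' Ratio of AA-ending to AG-ending Lys/Gln/Glu codon counts. A ratio of 1
#' indicates unbiased usage. When `ag = 0` but `aa > 0` the ratio is the
#' infinite sentinel `Inf`, which compares greater than any finite threshold;
#' when both counts are 0 it is the undefined sentinel `NaN`, which fails
#' every ratio predicate and is reported separately. Values are returned
#' unrounded; presentation-layer rounding is done by [format_ratio()].
#'
#' @param aa,ag non-negative integer codon counts (vectorized).
#' @return numeric vector of ratios.
#' @examples
#' aa_ag_ratio(2, 42)   # the AG-biased eGFP biosensor: reported as 0.05
#' aa_ag_ratio(5, 0)    # Inf
#' aa_ag_ratio(0, 0)    # NaN
#' @export
aa_ag_ratio <- function(aa, ag) {
  wb_assert(all(aa >= 0) && all(ag >= 0), "NEGATIVE_COUNT",
            "codon counts must be non-negative")
  ifelse(ag > 0, aa / ag, ifelse(aa > 0, Inf, NaN))
}

# Translate a CDS using the standard genetic code (Biostrings' table used as a
# lookup, not its translate engine, which serves as an independent oracle in
# the tests). Codons containing N translate to "X"; stops to "*".
translate_codons <- function(codons) {
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"
  aa
}

translate_cds <- function(cds) {
  if (!inherits(cds, "CodingSequence")) cds <- validate_cds(cds)
  paste(translate_codons(split_codons(cds$seq)), collapse = "")
}
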