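# Biosensor design: synonymous recoding of Lys/Gln/Glu codons toward AA- or
# AG-ending wobble forms. Only the AAA<->AAG, CAA<->CAG, GAA<->GAG third
# positions are touched; every other codon is byte-identical, so the protein
# is unchanged and the construct reads out codon-dependent translation only.

kqe_resolutions <- function(codon) {
  # all concrete codons an N-containing trinucleotide could resolve to
  chars <- strsplit(codon, "")[[1]]
  opts <- lapply(chars, function(ch) if (ch == "N") c("A", "C", "G", "T") else ch)
  apply(expand.grid(opts, stringsAsFactors = FALSE), 1, paste, collapse = "")
}

could_be_kqe <- function(codon) {
  if (!grepl("N", codon, fixed = TRUE)) {
    return(codon %in% c(AA_CODONS, AG_CODONS))
  }
  any(kqe_resolutions(codon) %in% c(AA_CODONS, AG_CODONS))
}

#' Synonymously recode Lys/Gln/Glu codons toward AA or AG endings
#'
#' Rewrites the wobble (third) position of every AAA/CAA/GAA and AAG/CAG/GAG
#' codon so that all K/Q/E codons end in the target dinucleotide. With
#' `keep_opposite = k`, the first `k` K/Q/E codons in 5'-to-3' order keep the
#' opposite ending instead, so constructs with an exact AA/AG count split
#' (such as a sensor retaining 2 of 44 AA-ending codons) can be expressed.
#' All other codons are untouched; the translation is preserved.
#'
#' @param cds a `CodingSequence` or DNA string.
#' @param target `"AA"` or `"AG"`.
#' @param keep_opposite number of K/Q/E codons (5' to 3') to set to the
#'   opposite ending (default 0: fully biased).
#' @return a list with `cds` (the recoded `CodingSequence`, id suffixed with
#'   the target) and `report` (class `RecodeReport`: `id`, `target`,
#'   `n_changed`, `before`/`after` bias profiles).
#' @examples
#' recode("AAGTAA", target = "AA")$cds$seq  # "AAATAA"
#' @export
recode <- function(cds, target = c("AA", "AG"), keep_opposite = 0L) {
  target <- match.arg(target)
  if (!inherits(cds, "CodingSequence")) cds <- validate_cds(cds)
  wb_assert(is.numeric(keep_opposite) && length(keep_opposite) == 1 &&
              keep_opposite >= 0, "INVALID_ARGUMENT",
            "keep_opposite must be a non-negative count")
  codons <- split_codons(cds$seq)
  amb_kqe <- grepl("N", codons, fixed = TRUE) &
    vapply(codons, could_be_kqe, logical(1))
  if (any(amb_kqe)) {
    wb_stop("AMBIGUOUS_CODON",
            sprintf("codon(s) at position(s) %s contain N and may encode Lys/Gln/Glu; cannot recode",
                    paste(which(amb_kqe), collapse = ", ")))
  }
  before <- count_codons(cds)
  kqe_pos <- which(codons %in% c(AA_CODONS, AG_CODONS))
  main_end <- if (target == "AA") "A" else "G"
  opp_end <- if (target == "AA") "G" else "A"
  new_codons <- codons
  if (length(kqe_pos) > 0) {
    ends <- rep(main_end, length(kqe_pos))
    k <- min(as.integer(keep_opposite), length(kqe_pos))
    if (k > 0) ends[seq_len(k)] <- opp_end
    new_codons[kqe_pos] <- paste0(substr(codons[kqe_pos], 1, 2), ends)
  }
  out <- validate_cds(paste(new_codons, collapse = ""),
                      id = paste0(cds$id, "_", target), gene = cds$gene)
  report <- structure(list(
    id = cds$id,
    target = target,
    n_changed = sum(new_codons != codons),
    before = before,
    after = count_codons(out)
  ), class = "RecodeReport")
  list(cds = out, report = report)
}

#' @export
print.RecodeReport <- function(x, ...) {
  cat(sprintf("<RecodeReport %s -> %s-biased: %d codon(s) changed; AA:AG %s -> %s>\n",
              x$id, x$target, x$n_changed,
              format_ratio(x$before$ratio), format_ratio(x$after$ratio)))
  invisible(x)
}

#' Check two equal-length CDSs encode the same protein
#'
#' Translates both sequences under the standard genetic code and reports
#' whether the proteins are identical; if not, the first mismatching codon
#' position (1-based codon index) is returned.
#'
#' @param a,b `CodingSequence` objects or DNA strings of equal length.
#' @return a list with `synonymous` (logical) and `first_mismatch` (1-based
#'   codon index of the first differing residue, or `NA` if identical).
#' @export
verify_synonymous <- function(a, b) {
  if (!inherits(a, "CodingSequence")) a <- validate_cds(a, id = "a")
  if (!inherits(b, "CodingSequence")) b <- validate_cds(b, id = "b")
  if (nchar(a$seq) != nchar(b$seq)) {
    wb_stop("LENGTH_MISMATCH",
            sprintf("sequences differ in length (%d vs %d nt)",
                    nchar(a$seq), nchar(b$seq)))
  }
  pa <- translate_codons(split_codons(a$seq))
  pb <- translate_codons(split_codons(b$seq))
  diff <- which(pa != pb)
  list(synonymous = length(diff) == 0,
       first_mismatch = if (length(diff) == 0) NA_integer_ else diff[1])
}

#' The AA-biased eGFP biosensor coding sequence
#'
#' Loads the bundled AA-biased eGFP construct: a 240-codon eGFP CDS in which
#' all 44 Lys/Gln/Glu codons end in AA, used as the modification-dependent
#' biosensor. Its AG-recoded counterpart (the mammalian-optimized sensor
#' keeps 2 of 44 codons AA-ending, AA:AG = 0.05) can be derived with
#' [recode()].
#'
#' @return a `CodingSequence`.
#' @examples
#' count_codons(egfp_aa_sensor())
#' @export
egfp_aa_sensor <- function() {
  path <- system.file("extdata", "egfp_aa_biased.fa", package = "wobblebias",
                      mustWork = TRUE)
  read_cds_fasta(path)[[1]]
}
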