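# ORFeome-scale scanning: read a CDS FASTA collection, compute one bias
# profile per CDS, and summarise the genome-wide AA:AG distribution.

#' Read a CDS FASTA file into validated coding sequences
#'
#' Reads a (plain or gzipped) FASTA of coding sequences and validates each
#' record. Headers in the consensus-CDS pipe-delimited dialect are split on
#' `|`: the first token becomes the id and the second, when present, the gene
#' symbol; otherwise the whole header is the id. Records failing validation
#' (length not a multiple of 3, invalid characters) are skipped with a
#' message, not fatal; the skipped ids and reasons are attached as the
#' `"skipped"` attribute.
#'
#' @param path path to a FASTA file.
#' @return a list of `CodingSequence` objects with attribute `skipped`
#'   (a data frame of id and condition class for each rejected record).
#' @export
read_cds_fasta <- function(path) {
  wb_assert(file.exists(path), "FILE_NOT_FOUND",
            sprintf("FASTA file not found: %s", path))
  set <- Biostrings::readDNAStringSet(path)
  wb_assert(length(set) > 0, "EMPTY_FASTA",
            sprintf("FASTA file contains no records: %s", path))
  headers <- names(set)
  seqs <- as.character(set)
  out <- vector("list", length(set))
  skipped_id <- character(0)
  skipped_why <- character(0)
  for (i in seq_along(seqs)) {
    toks <- strsplit(headers[i], "|", fixed = TRUE)[[1]]
    toks <- trimws(toks)
    id <- if (length(toks) >= 1 && nzchar(toks[1])) toks[1] else headers[i]
    gene <- if (length(toks) >= 2 && nzchar(toks[2])) toks[2] else NA_character_
    cds <- tryCatch(validate_cds(seqs[i], id = id, gene = gene),
                    wobblebias_error = function(e) e)
    if (inherits(cds, "CodingSequence")) {
      out[[i]] <- cds
    } else {
      skipped_id <- c(skipped_id, id)
      skipped_why <- c(skipped_why, class(cds)[1])
    }
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(skipped_id) > 0) {
    message(sprintf("read_cds_fasta: skipped %d invalid record(s): %s",
                    length(skipped_id),
                    paste(skipped_id, skipped_why, sep = " [", collapse = "], ")))
  }
  attr(out, "skipped") <- data.frame(id = skipped_id, reason = skipped_why,
                                     stringsAsFactors = FALSE)
  out
}

#' Compute per-CDS bias profiles for an ORFeome
#'
#' Produces one row per coding sequence with its codon counts and AA:AG
#' ratio. Each CDS record is one analysis unit; use `collapse = "longest"` to
#' keep only the longest CDS per gene symbol for gene-level joins.
#'
#' @param cds_list a list of `CodingSequence` objects.
#' @param collapse `"none"` (default) or `"longest"` (one row per gene symbol,
#'   keeping the longest CDS; records without a gene symbol are kept as-is).
#' @return a data frame (the ORFeome table) with columns `id`, `gene`,
#'   `total_codons`, `aa_count`, `ag_count`, `ratio`, `n_ambiguous`. Ratio
#'   sentinels are `Inf` (no AG-ending codons) and `NaN` (no K/Q/E codons).
#' @export
scan_orfeome <- function(cds_list, collapse = c("none", "longest")) {
  collapse <- match.arg(collapse)
  wb_assert(length(cds_list) > 0, "EMPTY_INPUT", "cds_list is empty")
  profs <- lapply(cds_list, count_codons)
  tab <- data.frame(
    id = vapply(cds_list, function(x) x$id, character(1)),
    gene = vapply(cds_list, function(x) x$gene, character(1)),
    total_codons = vapply(profs, function(p) p$total_codons, integer(1)),
    aa_count = vapply(profs, function(p) p$aa_count, integer(1)),
    ag_count = vapply(profs, function(p) p$ag_count, integer(1)),
    ratio = vapply(profs, function(p) p$ratio, numeric(1)),
    n_ambiguous = vapply(profs, function(p) p$n_ambiguous, integer(1)),
    stringsAsFactors = FALSE
  )
  dup <- duplicated(tab$id)
  if (any(dup)) {
    wb_stop("DUPLICATE_ID",
            sprintf("duplicate CDS ids: %s",
                    paste(unique(tab$id[dup]), collapse = ", ")))
  }
  if (collapse == "longest") {
    has_gene <- !is.na(tab$gene)
    keep <- rep(TRUE, nrow(tab))
    if (any(has_gene)) {
      ord <- order(!has_gene, toupper(tab$gene), -tab$total_codons)
      first_of_gene <- !duplicated(toupper(tab$gene[ord])) | !has_gene[ord]
      keep_ids <- tab$id[ord][first_of_gene]
      keep <- tab$id %in% keep_ids
    }
    tab <- tab[keep, , drop = FALSE]
  }
  rownames(tab) <- NULL
  tab
}

#' Histogram of AA:AG ratios across an ORFeome
#'
#' Bins finite-ratio rows into intervals of width `bin_width` (left-closed,
#' by bin start). Rows with the infinite or undefined sentinel are counted in
#' labelled overflow categories, not binned. `fraction_below_1` is the
#' fraction of rows with ratio < 1 among rows where the comparison is
#' meaningful (finite plus infinite; infinite counts as >= 1); it is `NA`
#' when no such row exists.
#'
#' @param table an ORFeome table from [scan_orfeome()].
#' @param bin_width histogram bin width on the ratio axis (default 0.01;
#'   the distribution is near-continuous at genome scale).
#' @return a list with `histogram` (data frame `bin_start`, `count`),
#'   `n_infinite`, `n_undefined`, `n`, and `fraction_below_1`.
#' @export
ratio_distribution <- function(table, bin_width = 0.01) {
  wb_assert(is.data.frame(table) && nrow(table) > 0, "EMPTY_TABLE",
            "ORFeome table is empty")
  wb_assert(is.numeric(bin_width) && bin_width > 0, "INVALID_BIN_WIDTH",
            "bin_width must be positive")
  r <- table$ratio
  fin <- is.finite(r)
  inf <- is.infinite(r)
  und <- is.nan(r)
  hist_df <- data.frame(bin_start = numeric(0), count = integer(0))
  if (any(fin)) {
    starts <- floor(r[fin] / bin_width) * bin_width
    tb <- table(starts)
    hist_df <- data.frame(bin_start = as.numeric(names(tb)),
                          count = as.integer(tb))
    hist_df <- hist_df[order(hist_df$bin_start), , drop = FALSE]
    rownames(hist_df) <- NULL
  }
  denom <- sum(fin) + sum(inf)
  frac <- if (denom > 0) sum(r[fin] < 1) / denom else NA_real_
  list(histogram = hist_df,
       n_infinite = sum(inf),
       n_undefined = sum(und),
       n = nrow(table),
       fraction_below_1 = frac)
}

#' Summary statistics of an ORFeome table
#'
#' Mean AA:AG ratio over rows with a finite ratio (the infinite and undefined
#' sentinels are excluded from the ratio mean but included in the length and
#' AA-count means), mean CDS length in codons, and mean AA-ending codon
#' count.
#'
#' @param table an ORFeome table from [scan_orfeome()].
#' @return a list with `n`, `n_finite_ratio`, `mean_ratio`,
#'   `mean_total_codons`, `mean_aa_count`.
#' @export
orfeome_summary <- function(table) {
  wb_assert(is.data.frame(table) && nrow(table) > 0, "EMPTY_TABLE",
            "ORFeome table is empty")
  fin <- is.finite(table$ratio)
  list(n = nrow(table),
       n_finite_ratio = sum(fin),
       mean_ratio = if (any(fin)) mean(table$ratio[fin]) else NA_real_,
       mean_total_codons = mean(table$total_codons),
       mean_aa_count = mean(table$aa_count))
}

#' Construct a prevalence rule clause
#'
#' One clause of an Elongator-dependence prevalence rule: bounds on CDS
#' length (in total codons) and on the AA:AG ratio. At least one bound must
#' be set, and `min_codons`/`max_codons` may not both be set in one clause.
#'
#' @param min_codons,max_codons optional integer length bounds (inclusive).
#' @param ratio_gt,ratio_lt optional strict ratio bounds.
#' @return an object of class `prevalence_rule`.
#' @export
prevalence_rule <- function(min_codons = NULL, max_codons = NULL,
                            ratio_gt = NULL, ratio_lt = NULL) {
  set <- !vapply(list(min_codons, max_codons, ratio_gt, ratio_lt),
                 is.null, logical(1))
  wb_assert(any(set), "EMPTY_RULE", "a prevalence rule needs at least one bound")
  wb_assert(!(set[1] && set[2]), "CONFLICTING_BOUNDS",
            "min_codons and max_codons may not both be set in one clause")
  structure(list(min_codons = min_codons, max_codons = max_codons,
                 ratio_gt = ratio_gt, ratio_lt = ratio_lt),
            class = "prevalence_rule")
}

#' Named prevalence rule sets for Elongator-dependence scans
#'
#' The two rule sets used for ORFeome-wide prevalence estimates, OR-combined:
#' * `"stringent"`: (>= 1,755 total codons AND AA:AG > 1.3) OR
#'   (<= 150 total codons AND AA:AG < 0.3)
#' * `"lenient"`: (>= 1,005 AND > 1.3) OR (<= 300 AND < 0.3)
#'
#' A YAML file path may be given instead; it must contain a list of clauses
#' with any of the keys `min_codons`, `max_codons`, `ratio_gt`, `ratio_lt`.
#'
#' @param name `"stringent"`, `"lenient"`, or a path to a YAML rule file.
#' @return a list of [prevalence_rule()] clauses.
#' @export
prevalence_ruleset <- function(name = "stringent") {
  if (identical(name, "stringent")) {
    return(list(prevalence_rule(min_codons = 1755, ratio_gt = 1.3),
                prevalence_rule(max_codons = 150, ratio_lt = 0.3)))
  }
  if (identical(name, "lenient")) {
    return(list(prevalence_rule(min_codons = 1005, ratio_gt = 1.3),
                prevalence_rule(max_codons = 300, ratio_lt = 0.3)))
  }
  wb_assert(file.exists(name), "FILE_NOT_FOUND",
            sprintf("no such ruleset or rule file: %s", name))
  clauses <- yaml::read_yaml(name)
  lapply(clauses, function(cl) do.call(prevalence_rule, cl))
}

rule_matches <- function(table, rule) {
  ok <- rep(TRUE, nrow(table))
  r <- table$ratio
  if (!is.null(rule$min_codons)) ok <- ok & table$total_codons >= rule$min_codons
  if (!is.null(rule$max_codons)) ok <- ok & table$total_codons <= rule$max_codons
  # NaN (undefined ratio) fails every ratio predicate; Inf satisfies any ">".
  if (!is.null(rule$ratio_gt)) ok <- ok & !is.nan(r) & (r > rule$ratio_gt)
  if (!is.null(rule$ratio_lt)) ok <- ok & !is.nan(r) & (r < rule$ratio_lt)
  ok
}

#' Scan an ORFeome table against prevalence rules
#'
#' A CDS matches if all bounds of any one clause hold (clauses are
#' OR-combined). Returns the matching ids and the matched fraction of the
#' table.
#'
#' @param table an ORFeome table from [scan_orfeome()].
#' @param rules a list of [prevalence_rule()] clauses, e.g. from
#'   [prevalence_ruleset()]. An empty list matches nothing.
#' @return a list with `ids`, `n_matched`, `fraction`.
#' @export
prevalence_scan <- function(table, rules) {
  wb_assert(is.data.frame(table) && nrow(table) > 0, "EMPTY_TABLE",
            "ORFeome table is empty")
  if (length(rules) == 0) {
    return(list(ids = character(0), n_matched = 0L, fraction = 0))
  }
  wb_assert(all(vapply(rules, inherits, logical(1), "prevalence_rule")),
            "INVALID_RULE", "rules must be prevalence_rule objects")
  hit <- Reduce(`|`, lapply(rules, rule_matches, table = table))
  list(ids = table$id[hit],
       n_matched = sum(hit),
       fraction = sum(hit) / nrow(table))
}

#' Write / read an ORFeome or class-row table as TSV
#'
#' The `ratio` column is serialized with the sentinel conventions of
#' [format_ratio()] but at full precision for finite values (`"inf"` for the
#' infinite sentinel, `"NA"` for the undefined sentinel); [read_bias_tsv()]
#' restores the numeric sentinels.
#'
#' @param table a data frame with a `ratio` column.
#' @param path output TSV path.
#' @return `write_bias_tsv` returns `path` invisibly; `read_bias_tsv` the
#'   restored data frame.
#' @export
write_bias_tsv <- function(table, path) {
  out <- table
  if ("ratio" %in% names(out)) {
    r <- out$ratio
    s <- as.character(r)
    s[is.infinite(r)] <- "inf"
    s[is.nan(r)] <- "NA"
    out$ratio <- s
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' @rdname write_bias_tsv
#' @export
read_bias_tsv <- function(path) {
  wb_assert(file.exists(path), "FILE_NOT_FOUND",
            sprintf("TSV file not found: %s", path))
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE,
                           colClasses = NA, na.strings = "__none__")
  if ("ratio" %in% names(tab)) tab$ratio <- parse_ratio(as.character(tab$ratio))
  tab
}
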