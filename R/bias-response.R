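# Fold-change-class response to codon bias and transcript length: threshold
# grids over (AA:AG ratio, length-in-codons) cells, the AA-abundance control
# curve, and the named candidate-target filters.

# Class percentages of a set of class rows; NA percentages for empty cells.
cell_summary <- function(classes) {
  n <- length(classes)
  if (n == 0) {
    return(list(n_genes = 0L, pct_depleted = NA_real_, pct_normal = NA_real_,
                pct_up = NA_real_, low_count = TRUE))
  }
  tb <- table(factor(classes, levels = c("DEPLETED", "NORMAL", "UP")))
  pct <- 100 * as.numeric(tb) / n
  list(n_genes = n, pct_depleted = pct[1], pct_normal = pct[2],
       pct_up = pct[3], low_count = n < 5)
}

select_ratio <- function(rows, threshold, dir) {
  r <- rows$ratio
  # the undefined sentinel fails every predicate; Inf satisfies any ">"
  if (dir == ">") !is.nan(r) & r > threshold else !is.nan(r) & r < threshold
}

select_length <- function(rows, threshold, dir) {
  if (dir == ">=") rows$total_codons >= threshold
  else rows$total_codons <= threshold
}

#' Fold-change-class percentages over a bias x length threshold grid
#'
#' For every combination of a ratio threshold and a length threshold, selects
#' the class rows satisfying both bounds and reports the percentage of genes
#' whose protein is depleted (fold change <= -2), normal, or upregulated
#' (>= 2). Cells built from fewer than five proteins are flagged
#' `low_count` (the dashed-line convention); empty cells report `NA`
#' percentages. Rows with an infinite ratio satisfy any `">"` threshold;
#' rows with an undefined ratio are never selected by a ratio bound.
#'
#' @param rows class-row data frame from [merge_and_filter()].
#' @param ratio_thresholds numeric vector of AA:AG thresholds.
#' @param ratio_dir `">"` (AA-bias side) or `"<"` (AG-bias side).
#' @param length_thresholds integer vector of length thresholds (codons).
#' @param length_dir `">="` or `"<="`.
#' @return data frame of bin summaries: one row per (ratio, length) cell with
#'   `ratio_threshold`, `ratio_dir`, `length_threshold`, `length_dir`,
#'   `n_genes`, `pct_depleted`, `pct_normal`, `pct_up`, `low_count`.
#'   Percentages are unrounded; round at presentation with
#'   [format_bin_summary()].
#' @export
threshold_grid <- function(rows, ratio_thresholds, ratio_dir = c(">", "<"),
                           length_thresholds, length_dir = c(">=", "<=")) {
  ratio_dir <- match.arg(ratio_dir)
  length_dir <- match.arg(length_dir)
  wb_assert(is.data.frame(rows) && nrow(rows) > 0, "EMPTY_INPUT",
            "rows is empty")
  wb_assert(length(ratio_thresholds) > 0 && length(length_thresholds) > 0,
            "EMPTY_INPUT", "threshold lists must be non-empty")
  grid <- expand.grid(ratio_threshold = ratio_thresholds,
                      length_threshold = length_thresholds)
  cells <- lapply(seq_len(nrow(grid)), function(i) {
    sel <- select_ratio(rows, grid$ratio_threshold[i], ratio_dir) &
      select_length(rows, grid$length_threshold[i], length_dir)
    cell_summary(rows$fc_class[sel])
  })
  data.frame(
    ratio_threshold = grid$ratio_threshold,
    ratio_dir = ratio_dir,
    length_threshold = grid$length_threshold,
    length_dir = length_dir,
    n_genes = vapply(cells, `[[`, integer(1), "n_genes"),
    pct_depleted = vapply(cells, `[[`, numeric(1), "pct_depleted"),
    pct_normal = vapply(cells, `[[`, numeric(1), "pct_normal"),
    pct_up = vapply(cells, `[[`, numeric(1), "pct_up"),
    low_count = vapply(cells, `[[`, logical(1), "low_count"),
    stringsAsFactors = FALSE
  )
}

#' Default threshold grids for the AA- and AG-biased analyses
#'
#' The AA side scans ratio > {0.5, 0.7, 0.9, 1.1, 1.3, 1.5} against length
#' >= {505, 1005, 1755} codons; the AG side ratio < {0.5, 0.4, 0.3, 0.2,
#' 0.1} against length <= {150, 300, 505}. Only the anchor values quoted in
#' the candidate filters are fixed by the analysis; the remainder are
#' configurable defaults.
#'
#' @param side `"aa"` or `"ag"`.
#' @param rows class-row data frame.
#' @return a bin-summary data frame (see [threshold_grid()]).
#' @export
default_grid <- function(rows, side = c("aa", "ag")) {
  side <- match.arg(side)
  if (side == "aa") {
    threshold_grid(rows, ratio_thresholds = c(0.5, 0.7, 0.9, 1.1, 1.3, 1.5),
                   ratio_dir = ">",
                   length_thresholds = c(505, 1005, 1755), length_dir = ">=")
  } else {
    threshold_grid(rows, ratio_thresholds = c(0.5, 0.4, 0.3, 0.2, 0.1),
                   ratio_dir = "<",
                   length_thresholds = c(150, 300, 505), length_dir = "<=")
  }
}

#' Depletion response to raw AA-ending codon abundance
#'
#' The control analysis: class percentages among genes with
#' `aa_count >= threshold`, irrespective of the AA:AG ratio. If depletion is
#' driven by bias rather than raw AA abundance, this curve is flat.
#'
#' @param rows class-row data frame.
#' @param aa_thresholds ascending integer thresholds on the AA-ending codon
#'   count.
#' @return a bin-summary data frame with column `aa_threshold` in place of
#'   the ratio/length thresholds.
#' @export
aa_abundance_curve <- function(rows, aa_thresholds) {
  wb_assert(is.data.frame(rows) && nrow(rows) > 0, "EMPTY_INPUT",
            "rows is empty")
  wb_assert(length(aa_thresholds) > 0 && !is.unsorted(aa_thresholds),
            "INVALID_THRESHOLDS", "aa_thresholds must be ascending")
  cells <- lapply(aa_thresholds, function(t) {
    cell_summary(rows$fc_class[rows$aa_count >= t])
  })
  data.frame(
    aa_threshold = aa_thresholds,
    n_genes = vapply(cells, `[[`, integer(1), "n_genes"),
    pct_depleted = vapply(cells, `[[`, numeric(1), "pct_depleted"),
    pct_normal = vapply(cells, `[[`, numeric(1), "pct_normal"),
    pct_up = vapply(cells, `[[`, numeric(1), "pct_up"),
    low_count = vapply(cells, `[[`, logical(1), "low_count"),
    stringsAsFactors = FALSE
  )
}

#' Filter class rows for candidate Elongator targets
#'
#' Selects genes by exactly one length bound and one ratio bound (raw,
#' unrounded ratios) and tallies their fold-change classes. Two presets are
#' available through [target_preset()]: `"large-aa"` (>= 1,755 codons, ratio
#' > 1.3) and `"small-ag"` (<= 150 codons, ratio < 0.2).
#'
#' @param rows class-row data frame.
#' @param min_codons,max_codons exactly one inclusive length bound.
#' @param ratio_gt,ratio_lt exactly one strict ratio bound.
#' @return a list with `rows` (the surviving class rows) and `counts`
#'   (named integer vector over DEPLETED/NORMAL/UP).
#' @export
target_filter <- function(rows, min_codons = NULL, max_codons = NULL,
                          ratio_gt = NULL, ratio_lt = NULL) {
  wb_assert(is.null(min_codons) + is.null(max_codons) == 1L,
            "CONFLICTING_BOUNDS", "set exactly one of min_codons/max_codons")
  wb_assert(is.null(ratio_gt) + is.null(ratio_lt) == 1L,
            "CONFLICTING_BOUNDS", "set exactly one of ratio_gt/ratio_lt")
  if (nrow(rows) == 0) {
    return(list(rows = rows,
                counts = c(DEPLETED = 0L, NORMAL = 0L, UP = 0L)))
  }
  sel <- rep(TRUE, nrow(rows))
  if (!is.null(min_codons)) sel <- sel & rows$total_codons >= min_codons
  if (!is.null(max_codons)) sel <- sel & rows$total_codons <= max_codons
  if (!is.null(ratio_gt)) sel <- sel & select_ratio(rows, ratio_gt, ">")
  if (!is.null(ratio_lt)) sel <- sel & select_ratio(rows, ratio_lt, "<")
  kept <- rows[sel, , drop = FALSE]
  counts <- table(factor(kept$fc_class, levels = c("DEPLETED", "NORMAL", "UP")))
  list(rows = kept,
       counts = stats::setNames(as.integer(counts), names(counts)))
}

#' @rdname target_filter
#' @param rows class-row data frame.
#' @param preset `"large-aa"` or `"small-ag"`.
#' @export
target_preset <- function(rows, preset = c("large-aa", "small-ag")) {
  preset <- match.arg(preset)
  if (preset == "large-aa") {
    target_filter(rows, min_codons = 1755, ratio_gt = 1.3)
  } else {
    target_filter(rows, max_codons = 150, ratio_lt = 0.2)
  }
}

#' Round bin-summary percentages for reporting
#'
#' Percentages are reported to one decimal (half-up); the underlying grid
#' keeps full precision for downstream comparisons.
#'
#' @param bins a bin-summary data frame.
#' @return the data frame with percentage columns rounded.
#' @export
format_bin_summary <- function(bins) {
  for (nm in c("pct_depleted", "pct_normal", "pct_up")) {
    if (nm %in% names(bins)) bins[[nm]] <- round_half_up(bins[[nm]], 1)
  }
  bins
}
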