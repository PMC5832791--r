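# End-to-end pipeline: scan -> integrate -> bins -> targets, with artifact
# and provenance output. Each stage error is re-raised with the stage name so
# a failed run names what broke.

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    wb_stop(c("PIPELINE_STAGE_ERROR", class(e)[1]),
            sprintf("stage '%s' failed: %s", stage, conditionMessage(e)))
  })
}

#' Run the codon-bias analysis pipeline on files
#'
#' Executes the full analysis: read and scan the CDS FASTA (collapsing to
#' the longest CDS per gene for the gene-level join), integrate the
#' transcriptome and proteome tables, compute the AA- and AG-side threshold
#' grids and the AA-abundance control curve, and apply both candidate-target
#' presets. All tables are written as TSV, summaries as JSON, and the run
#' configuration is echoed to `config.json` for provenance.
#'
#' @param fasta_path CDS FASTA file.
#' @param rna_path,prot_path TSV fold-change tables (columns `gene`, `fc`,
#'   `detected_ctrl`, `detected_cko`; proteome may add `n_peptides`). Set
#'   `ratio_input = TRUE` if `fc` holds raw expression ratios instead of
#'   signed fold changes.
#' @param out_dir output directory (created if needed).
#' @param rna_fc_bound strict transcript fold-change bound (default 1.5).
#' @param ratio_input convert `fc` columns with [signed_fc()] on ingest.
#' @return invisibly, a list of the in-memory results (`orfeome`,
#'   `class_rows`, `aa_grid`, `ag_grid`, `aa_curve`, `targets_large_aa`,
#'   `targets_small_ag`, `summary`) alongside the written files.
#' @export
run_pipeline <- function(fasta_path, rna_path, prot_path, out_dir,
                         rna_fc_bound = 1.5, ratio_input = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  orfeome <- run_stage("scan", {
    cds <- read_cds_fasta(fasta_path)
    scan_orfeome(cds, collapse = "longest")
  })
  class_rows <- run_stage("integrate", {
    rna <- read_bias_tsv(rna_path)
    prot <- read_bias_tsv(prot_path)
    if (ratio_input) {
      rna$fc <- signed_fc(rna$fc)
      prot$fc <- signed_fc(prot$fc)
    }
    merge_and_filter(rna, prot, orfeome, rna_fc_bound = rna_fc_bound)
  })
  bins <- run_stage("bins", {
    list(aa_grid = default_grid(class_rows, "aa"),
         ag_grid = default_grid(class_rows, "ag"),
         aa_curve = aa_abundance_curve(class_rows,
                                       c(10, 20, 36, 60, 100, 150)))
  })
  targets <- run_stage("targets", {
    list(large_aa = target_preset(class_rows, "large-aa"),
         small_ag = target_preset(class_rows, "small-ag"))
  })

  summ <- orfeome_summary(orfeome)
  dist <- ratio_distribution(orfeome)
  summ$fraction_below_1 <- dist$fraction_below_1
  summ$n_class_rows <- nrow(class_rows)
  summ$class_counts <- as.list(table(class_rows$fc_class))

  write_bias_tsv(orfeome, file.path(out_dir, "orfeome.tsv"))
  write_bias_tsv(class_rows, file.path(out_dir, "class_rows.tsv"))
  utils::write.table(format_bin_summary(bins$aa_grid),
                     file.path(out_dir, "bins_aa.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(format_bin_summary(bins$ag_grid),
                     file.path(out_dir, "bins_ag.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(format_bin_summary(bins$aa_curve),
                     file.path(out_dir, "aa_abundance.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_bias_tsv(targets$large_aa$rows,
                 file.path(out_dir, "targets_large_aa.tsv"))
  write_bias_tsv(targets$small_ag$rows,
                 file.path(out_dir, "targets_small_ag.tsv"))
  # plain gene lists for external enrichment tools
  writeLines(targets$large_aa$rows$gene,
             file.path(out_dir, "targets_large_aa_genes.txt"))
  writeLines(targets$small_ag$rows$gene,
             file.path(out_dir, "targets_small_ag_genes.txt"))
  jsonlite::write_json(summ, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(list(fasta = fasta_path, rna = rna_path,
                            prot = prot_path, rna_fc_bound = rna_fc_bound,
                            ratio_input = ratio_input),
                       file.path(out_dir, "config.json"), auto_unbox = TRUE)
  message(sprintf(
    "pipeline: %d CDS scanned, %d class rows, targets large-aa=%d small-ag=%d",
    nrow(orfeome), nrow(class_rows),
    nrow(targets$large_aa$rows), nrow(targets$small_ag$rows)))

  invisible(list(orfeome = orfeome, class_rows = class_rows,
                 aa_grid = bins$aa_grid, ag_grid = bins$ag_grid,
                 aa_curve = bins$aa_curve,
                 targets_large_aa = targets$large_aa,
                 targets_small_ag = targets$small_ag,
                 summary = summ))
}

#' Simulate a study and analyse it end-to-end
#'
#' Writes a synthetic study to `file.path(out_dir, "sim")` and runs
#' [run_pipeline()] on the written files, exercising the whole pipeline from
#' FASTA and TSV inputs.
#'
#' @param config a [generator_config()].
#' @param out_dir output directory.
#' @return invisibly, the [run_pipeline()] result.
#' @export
run_simulation_pipeline <- function(config = generator_config(), out_dir) {
  sim_dir <- file.path(out_dir, "sim")
  run_stage("simulate", {
    study <- gen_study(config, sequences = TRUE)
    write_study(study, sim_dir)
  })
  run_pipeline(fasta_path = file.path(sim_dir, "orfeome.fa"),
               rna_path = file.path(sim_dir, "rna.tsv"),
               prot_path = file.path(sim_dir, "prot.tsv"),
               out_dir = out_dir)
}
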