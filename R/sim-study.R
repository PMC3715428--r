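#' Simulate a complete synthetic study
#'
#' Convenience orchestrator: annotation, planted truth, expression matrix and
#' ChIP/input reads from one configuration, deterministically under its seed.
#'
#' @param cfg a [sim_config()].
#' @return A list of class `sim_study` with elements `config`, `annotation`,
#'   `truth`, `expression`, `reads`.
#' @examples
#' study <- simulate_study(sim_config(seed = 7, n_genes = 30, noise_sd = 0))
#' study$truth
#' @export
simulate_study <- function(cfg) {
  annotation <- generate_annotation(cfg)
  truth <- generate_truth(annotation, cfg)
  expression <- generate_expression(annotation, cfg, truth)
  reads <- generate_reads(annotation, cfg, truth)
  structure(list(config = cfg, annotation = annotation, truth = truth,
                 expression = expression, reads = reads),
            class = "sim_study")
}

#' @export
print.sim_study <- function(x, ...) {
  print(x$config)
  print(x$annotation)
  print(x$truth)
  invisible(x)
}

#' Write a simulated study to disk in standard formats
#'
#' Writes `annotation.gff3` (1-based inclusive), `reads_ab.bed`,
#' `reads_tumour.bed`, `input.bed` (BED6, 0-based half-open),
#' `expr.tsv`, `peaks_truth.tsv` and `truth.json`.
#'
#' @param study a `sim_study`.
#' @param outdir output directory (created if missing).
#' @return `outdir`, invisibly.
#' @export
write_study <- function(study, outdir) {
  stopifnot(inherits(study, "sim_study"))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_annotation_gff3(study$annotation, file.path(outdir, "annotation.gff3"))
  write_reads_bed(study$reads$ab, file.path(outdir, "reads_ab.bed"))
  write_reads_bed(study$reads$tumour, file.path(outdir, "reads_tumour.bed"))
  write_reads_bed(study$reads$input, file.path(outdir, "input.bed"))
  write_expr_tsv(study$expression, file.path(outdir, "expr.tsv"))
  write.table(study$truth$loci, file.path(outdir, "peaks_truth.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(config = unclass(study$config)[!vapply(study$config, is.null, TRUE)],
         genes = study$truth$genes),
    file.path(outdir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}
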