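#' Run the full integrative target-classification pipeline
#'
#' Differential expression on the array matrix, peak calling per ChIP
#' condition against the input control, promoter/intron peak-to-gene
#' assignment, restriction to the array universe, six-class classification
#' and the Venn bookkeeping report.
#'
#' @param study a `sim_study` (or a list with the same elements:
#'   `annotation`, `expression`, `reads` with `ab`/`tumour`/`input`).
#' @param thresholds a [de_thresholds()].
#' @param caller_cfg a [peak_caller_config()]; its `read_length` is used for
#'   read extension.
#' @param upstream promoter extent in bp.
#' @return List of class `pipeline_result`: `de`, `peaks` (list ab/tumour),
#'   `targets`, `classification`, `venn`.
#' @export
run_pipeline <- function(study, thresholds = de_thresholds(),
                         caller_cfg = peak_caller_config(),
                         upstream = 500L) {
  de <- de_analysis(study$expression, thresholds)
  peaks <- list(
    ab = call_peaks(study$reads$ab, study$reads$input, caller_cfg),
    tumour = call_peaks(study$reads$tumour, study$reads$input, caller_cfg))
  targets <- assign_targets(peaks, study$annotation, upstream = upstream)
  universe <- unique(study$expression$probes$gene_id)
  targets <- filter_to_array_universe(targets, universe)
  classification <- classify_genes(de$genes, targets)
  venn <- venn_report(de$probes, de$genes, targets, classification)
  structure(list(de = de, peaks = peaks, targets = targets,
                 classification = classification, venn = venn),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  print(x$de)
  cat(sprintf("peaks: ab %d, tumour %d\n",
              length(x$peaks$ab), length(x$peaks$tumour)))
  print(x$venn)
  invisible(x)
}
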