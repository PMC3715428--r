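#' Delta-delta-Ct relative expression
#'
#' Livak quantification: technical replicates are averaged on the Ct scale,
#' `dCt = mean Ct(target) - mean Ct(normaliser)` per condition, `ddCt =
#' dCt(condition) - dCt(reference)` and `fold = 2^(-ddCt)` (the reference
#' condition sits at fold 1). Replicate-level fold changes pair biological
#' replicates of the condition and the reference by replicate index.
#'
#' @param ct a `ct_table` data frame (columns assay, target_gene, condition,
#'   replicate, technical_rep, ct).
#' @param target target gene id.
#' @param condition condition to quantify.
#' @param reference_condition baseline condition (default `"control"`).
#' @param normalizer normaliser gene id (default `"CG6044"`).
#' @return List of class `fold_change_result`: target_gene, condition,
#'   fold_change, ddct, replicate_folds, sd.
#' @export
ddct_fold_change <- function(ct, target, condition,
                             reference_condition = "control",
                             normalizer = "CG6044") {
  stop_if(any(ct$ct <= 0), "Ct values must be positive")
  mean_ct <- function(gene, cond) {
    rows <- ct[ct$target_gene == gene & ct$condition == cond, , drop = FALSE]
    if (!nrow(rows)) return(NULL)
    # technical replicates averaged first, then biological replicates
    tapply(rows$ct, rows$replicate, mean)
  }
  tgt_c <- mean_ct(target, condition)
  tgt_r <- mean_ct(target, reference_condition)
  nrm_c <- mean_ct(normalizer, condition)
  nrm_r <- mean_ct(normalizer, reference_condition)
  stop_if(is.null(tgt_c) || is.null(tgt_r),
          "target `", target, "` missing in one of the conditions")
  stop_if(is.null(nrm_c) || is.null(nrm_r),
          "normaliser `", normalizer, "` missing in one of the conditions")
  dct_c <- mean(tgt_c) - mean(nrm_c)
  dct_r <- mean(tgt_r) - mean(nrm_r)
  ddct <- dct_c - dct_r
  reps <- intersect(names(tgt_c), names(tgt_r))
  rep_folds <- if (length(reps)) {
    2^(-((tgt_c[reps] - mean(nrm_c)) - (tgt_r[reps] - mean(nrm_r))))
  } else {
    numeric()
  }
  structure(list(target_gene = target, condition = condition,
                 fold_change = 2^(-ddct), ddct = ddct,
                 replicate_folds = as.numeric(rep_folds),
                 sd = if (length(rep_folds) > 1) sd(rep_folds) else NA_real_),
            class = "fold_change_result")
}

#' ChIP-qPCR fold enrichment over the IgG control
#'
#' The control immunoprecipitation is assigned an enrichment of 1 and the
#' antibody IP is expressed relative to it: `fold = 2^(Ct_controlIP -
#' Ct_antibodyIP)` per biological replicate (technical replicates averaged
#' on the Ct scale first).
#'
#' @param ct a `ct_table` with conditions `"antibody"` and `"igg"`.
#' @param target target region/gene id.
#' @return A `fold_change_result` (condition `"antibody"`).
#' @export
chip_fold_enrichment <- function(ct, target) {
  stop_if(any(ct$ct <= 0), "Ct values must be positive")
  rows <- ct[ct$target_gene == target, , drop = FALSE]
  ab <- rows[rows$condition == "antibody", , drop = FALSE]
  ig <- rows[rows$condition == "igg", , drop = FALSE]
  stop_if(!nrow(ig), "control (IgG) IP missing for target `", target, "`")
  stop_if(!nrow(ab), "antibody IP missing for target `", target, "`")
  ab_ct <- tapply(ab$ct, ab$replicate, mean)
  ig_ct <- tapply(ig$ct, ig$replicate, mean)
  reps <- intersect(names(ab_ct), names(ig_ct))
  rep_folds <- 2^(ig_ct[reps] - ab_ct[reps])
  structure(list(target_gene = target, condition = "antibody",
                 fold_change = 2^(mean(ig_ct) - mean(ab_ct)),
                 ddct = mean(ab_ct) - mean(ig_ct),
                 replicate_folds = as.numeric(rep_folds),
                 sd = if (length(rep_folds) > 1) sd(rep_folds) else NA_real_),
            class = "fold_change_result")
}

#' @export
print.fold_change_result <- function(x, ...) {
  cat(sprintf("%s [%s]: fold change %.3g", x$target_gene, x$condition,
              x$fold_change))
  if (!is.na(x$sd)) cat(sprintf(" (s.d. %.3g across %d replicates)",
                                x$sd, length(x$replicate_folds)))
  cat("\n")
  invisible(x)
}
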