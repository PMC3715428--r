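#' Generate a qPCR Ct table encoding requested fold changes
#'
#' Builds a Ct table that, fed through the delta-delta-Ct arithmetic
#' ([ddct_fold_change()]) or the ChIP enrichment arithmetic
#' ([chip_fold_enrichment()]), recovers the requested fold changes exactly at
#' zero noise. For the expression assay the table carries the normaliser gene
#' (default `CG6044`) at a constant Ct and encodes a fold change F as a
#' target Ct offset of `-log2(F)` cycles relative to the reference condition.
#' For the ChIP assay it encodes F as `Ct(control IP) - Ct(antibody IP) =
#' log2(F)`.
#'
#' @param cfg a [sim_config()] (supplies `n_replicates` and `ct_noise_sd`).
#' @param fold_changes data frame with columns `target_gene`, `condition`,
#'   `fold_change` (> 0). For the expression assay, conditions not listed for
#'   a gene (in particular the reference) sit at fold 1.
#' @param assay `"expression"` or `"chip"`.
#' @param reference_condition reference (fold = 1) condition label for the
#'   expression assay.
#' @param normalizer normaliser gene id for the expression assay.
#' @param n_technical technical replicates per well (default 3).
#' @return A `ct_table` data frame: assay, target_gene, condition, replicate,
#'   technical_rep, ct.
#' @export
generate_ct_table <- function(cfg, fold_changes, assay = c("expression", "chip"),
                              reference_condition = "control",
                              normalizer = "CG6044", n_technical = 3L) {
  stopifnot(inherits(cfg, "sim_config"))
  assay <- match.arg(assay)
  fc <- fold_changes
  stop_if(!is.data.frame(fc) ||
            !all(c("target_gene", "condition", "fold_change") %in% names(fc)),
          "`fold_changes` needs columns target_gene, condition, fold_change")
  stop_if(any(fc$fold_change <= 0), "fold changes must be > 0")
  base_norm <- 20
  base_target <- 24
  with_stream(cfg, 8L, {
    rows <- list()
    add <- function(gene, cond, ct0) {
      grid <- expand.grid(replicate = seq_len(cfg$n_replicates),
                          technical_rep = seq_len(n_technical))
      ct <- rep(ct0, nrow(grid))
      if (cfg$ct_noise_sd > 0) ct <- ct + rnorm(length(ct), 0, cfg$ct_noise_sd)
      rows[[length(rows) + 1L]] <<- data.frame(
        assay = assay, target_gene = gene, condition = cond,
        replicate = grid$replicate, technical_rep = grid$technical_rep,
        ct = ct, stringsAsFactors = FALSE)
    }
    if (assay == "expression") {
      conds <- unique(c(reference_condition, fc$condition))
      for (g in unique(fc$target_gene)) {
        for (cond in conds) {
          f <- fc$fold_change[fc$target_gene == g & fc$condition == cond]
          f <- if (length(f)) f[1L] else 1
          add(g, cond, base_target - log2(f))
          add(normalizer, cond, base_norm)
        }
      }
    } else {
      for (i in seq_len(nrow(fc))) {
        add(fc$target_gene[i], "igg", 25)
        add(fc$target_gene[i], "antibody", 25 - log2(fc$fold_change[i]))
      }
    }
    out <- do.call(rbind, rows)
    out <- out[!duplicated(out[, c("target_gene", "condition", "replicate",
                                   "technical_rep")]), ]
    rownames(out) <- NULL
    class(out) <- c("ct_table", "data.frame")
    out
  })
}
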