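#' Differential-expression thresholds
#'
#' A probe set is called deregulated when |log2 fold change| exceeds
#' `min_abs_log2fc` and the Benjamini-Hochberg adjusted p-value is below
#' `max_adj_p`; both comparisons are strict.
#'
#' @param min_abs_log2fc minimum absolute log2 fold change (default 1).
#' @param max_adj_p maximum BH-adjusted p-value (default 0.05).
#' @export
de_thresholds <- function(min_abs_log2fc = 1.0, max_adj_p = 0.05) {
  assert_positive(min_abs_log2fc, "min_abs_log2fc")
  stop_if(!is.numeric(max_adj_p) || max_adj_p <= 0 || max_adj_p >= 1,
          "`max_adj_p` must be in (0, 1)")
  structure(list(min_abs_log2fc = min_abs_log2fc, max_adj_p = max_adj_p),
            class = "de_thresholds")
}

# Row-wise two-sample t-test (Welch by default) with an explicit
# zero-variance contract: constant groups with equal means give p = 1,
# constant groups with unequal means give p = 0 and a degenerate flag.
rowwise_t <- function(a, b, var_equal = FALSE) {
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- apply(a, 1L, var); vb <- apply(b, 1L, var)
  diff <- ma - mb
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- rep(na + nb - 2, length(diff))
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  tval <- diff / se
  p <- 2 * pt(-abs(tval), df)
  degenerate <- va == 0 & vb == 0
  p[degenerate & diff == 0] <- 1
  p[degenerate & diff != 0] <- 0
  tval[degenerate & diff == 0] <- 0
  if (any(degenerate & diff != 0)) {
    warning(sum(degenerate & diff != 0),
            " probe set(s) with zero variance in both groups but unequal means; p set to 0",
            call. = FALSE)
  }
  data.frame(log2fc = diff, t = tval, df = df, p = p,
             degenerate = degenerate)
}

#' Per-probe contrast statistics
#'
#' Computes, for every probe set, the log2 fold change (mean of the contrast
#' genotype minus mean of control, on log2 values) and a two-sided two-sample
#' t-test p-value. Welch's unequal-variance statistic is the default; a
#' pooled-variance option is available.
#'
#' @param expr an `expr_set`.
#' @param contrast `"ab"` or `"tumour"` (the `scrib_ab` genotype vs control).
#' @param var_equal use the pooled-variance statistic instead of Welch.
#' @return Data frame: probe_set_id, gene_id, log2fc, t, df, p, degenerate.
#' @export
compute_contrast <- function(expr, contrast = c("ab", "tumour"),
                             var_equal = FALSE) {
  stopifnot(inherits(expr, "expr_set"))
  contrast <- match.arg(contrast)
  geno <- contrast_genotype(contrast)
  a_cols <- expr$samples$sample_id[expr$samples$genotype == geno]
  b_cols <- expr$samples$sample_id[expr$samples$genotype == "control"]
  stop_if(length(a_cols) < 2L || length(b_cols) < 2L,
          "need >= 2 replicates per group for contrast `", contrast, "`")
  res <- rowwise_t(expr$log2[, a_cols, drop = FALSE],
                   expr$log2[, b_cols, drop = FALSE], var_equal = var_equal)
  cbind(data.frame(probe_set_id = expr$probes$probe_set_id,
                   gene_id = expr$probes$gene_id,
                   stringsAsFactors = FALSE),
        res)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Order-preserving step-up false-discovery-rate adjustment,
#' `adj_i = min(1, min_{j >= rank(i)} p_(j) * m / j)`.
#'
#' @param pvals numeric vector of raw p-values in \[0, 1\].
#' @return Adjusted p-values in input order.
#' @export
bh_adjust <- function(pvals) {
  stop_if(!is.numeric(pvals), "`pvals` must be numeric")
  stop_if(any(is.na(pvals)) || any(pvals < 0 | pvals > 1),
          "p-values must lie in [0, 1]")
  p.adjust(pvals, method = "BH")
}

#' Call per-probe deregulation directions for both contrasts
#'
#' Runs both contrasts, adjusts p-values per contrast across all probe sets
#' jointly, and assigns a direction code: +1 (up), -1 (down) when
#' |log2FC| > `min_abs_log2fc` and adjusted p < `max_adj_p`, else 0.
#'
#' @param expr an `expr_set`.
#' @param thresholds a [de_thresholds()].
#' @param var_equal passed to [compute_contrast()].
#' @return Data frame with per-contrast columns `log2fc_<c>`, `p_<c>`,
#'   `adj_p_<c>`, `dir_<c>` for c in ab, tumour.
#' @export
call_probes <- function(expr, thresholds = de_thresholds(),
                        var_equal = FALSE) {
  stopifnot(inherits(thresholds, "de_thresholds"))
  out <- NULL
  for (ct in CONTRASTS) {
    res <- compute_contrast(expr, ct, var_equal = var_equal)
    res$adj_p <- bh_adjust(res$p)
    res$dir <- direction_code(res$log2fc, res$adj_p, thresholds)
    res <- res[, c("probe_set_id", "gene_id", "log2fc", "p", "adj_p", "dir")]
    names(res)[3:6] <- paste(c("log2fc", "p", "adj_p", "dir"), ct, sep = "_")
    out <- if (is.null(out)) res else cbind(out, res[, 3:6])
  }
  out
}

# threshold rule: strict inequalities on both sides
direction_code <- function(log2fc, adj_p, thresholds) {
  as.integer(sign(log2fc)) *
    as.integer(abs(log2fc) > thresholds$min_abs_log2fc &
                 adj_p < thresholds$max_adj_p)
}

#' Reconcile multi-probe-set genes into gene-level deregulation calls
#'
#' A gene is deregulated in a contrast if any of its probe sets has a
#' nonzero direction there; a conflict is flagged when both +1 and -1 occur
#' among the gene's probe sets within one contrast. Genotype assignment:
#' `both` if any single probe set is deregulated in both contrasts (or —
#' union semantics, flagged via `mixed_evidence` — when distinct probe sets
#' cover the two contrasts), else `ab_only` / `tumour_only`, else `none`.
#'
#' @param probe_results output of [call_probes()].
#' @return Data frame: gene_id, dereg_ab, dereg_tumour, assignment,
#'   conflict_ab, conflict_tumour, mixed_evidence, n_probes.
#' @export
reconcile_genes <- function(probe_results) {
  pr <- probe_results
  missing_gene <- is.na(pr$gene_id) | pr$gene_id == ""
  if (any(missing_gene)) {
    message(sum(missing_gene), " probe set(s) without gene_id excluded")
    pr <- pr[!missing_gene, , drop = FALSE]
  }
  split_idx <- split(seq_len(nrow(pr)), pr$gene_id)
  rows <- lapply(names(split_idx), function(g) {
    i <- split_idx[[g]]
    d_ab <- pr$dir_ab[i]; d_tm <- pr$dir_tumour[i]
    dereg_ab <- any(d_ab != 0)
    dereg_tm <- any(d_tm != 0)
    same_probe_both <- any(d_ab != 0 & d_tm != 0)
    assignment <- if (same_probe_both) "both"
      else if (dereg_ab && dereg_tm) "both"   # union semantics, flagged below
      else if (dereg_ab) "ab_only"
      else if (dereg_tm) "tumour_only"
      else "none"
    data.frame(
      gene_id = g, dereg_ab = dereg_ab, dereg_tumour = dereg_tm,
      assignment = assignment,
      conflict_ab = any(d_ab == 1L) && any(d_ab == -1L),
      conflict_tumour = any(d_tm == 1L) && any(d_tm == -1L),
      mixed_evidence = !same_probe_both && dereg_ab && dereg_tm,
      n_probes = length(i), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Full differential-expression analysis
#'
#' [call_probes()] followed by [reconcile_genes()].
#'
#' @inheritParams call_probes
#' @return List of class `de_result` with elements `probes` and `genes`.
#' @export
de_analysis <- function(expr, thresholds = de_thresholds(),
                        var_equal = FALSE) {
  probes <- call_probes(expr, thresholds, var_equal = var_equal)
  genes <- reconcile_genes(probes)
  structure(list(probes = probes, genes = genes, thresholds = thresholds),
            class = "de_result")
}

#' @export
print.de_result <- function(x, ...) {
  cat(sprintf("de_result: %d probe sets, %d genes\n",
              nrow(x$probes), nrow(x$genes)))
  cat(sprintf("  deregulated probe sets: ab %d, tumour %d (|log2FC| > %g, adj p < %g)\n",
              sum(x$probes$dir_ab != 0), sum(x$probes$dir_tumour != 0),
              x$thresholds$min_abs_log2fc, x$thresholds$max_adj_p))
  print(table(assignment = x$genes$assignment))
  invisible(x)
}
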