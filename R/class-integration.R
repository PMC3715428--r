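#' Restrict target flags to the expression-array gene universe
#'
#' Genes identified from ChIP-Seq but not represented by any probe set on
#' the array are removed before classification.
#'
#' @param target_flags data frame from [assign_targets()].
#' @param universe character vector of gene ids present on the array.
#' @return The filtered flags.
#' @export
filter_to_array_universe <- function(target_flags, universe) {
  keep <- target_flags$gene_id %in% universe
  stop_if(!any(keep),
          "no target gene is present in the array universe; gene-id namespaces likely mismatched")
  target_flags[keep, , drop = FALSE]
}

#' Classify tumour-deregulated genes into the six target classes
#'
#' The joint deregulation-by-binding scheme over genes deregulated in the
#' tumour contrast (alone or together with the overexpression contrast):
#' \describe{
#'   \item{Class 1}{deregulated in both contrasts, peaks in both conditions}
#'   \item{Class 2}{deregulated in tumour only, peaks in both conditions}
#'   \item{Class 3}{deregulated in both contrasts, peaks in tumour only}
#'   \item{Class 4}{deregulated in tumour only, peaks in tumour only}
#'   \item{Class 5}{tumour-deregulated, no peaks in either condition}
#'   \item{Class 6}{tumour-deregulated, peaks in the overexpression
#'     condition only}
#' }
#' Genes not deregulated in the tumour contrast are `unclassified`.
#'
#' @param gene_calls data frame from [reconcile_genes()].
#' @param target_flags data frame from [assign_targets()] (after
#'   [filter_to_array_universe()]), with `has_peak_ab` / `has_peak_tumour`.
#' @return Data frame: gene_id, dereg_pattern, peak_pattern, class_label.
#' @export
classify_genes <- function(gene_calls, target_flags) {
  idx <- match(gene_calls$gene_id, target_flags$gene_id)
  missing <- is.na(idx)
  if (any(missing)) {
    message(sum(missing),
            " gene(s) absent from the target-flag table treated as peak-free")
  }
  has_ab <- ifelse(missing, FALSE, target_flags$has_peak_ab[idx])
  has_tm <- ifelse(missing, FALSE, target_flags$has_peak_tumour[idx])
  dereg_pattern <- with(gene_calls, ifelse(
    dereg_ab & dereg_tumour, "both",
    ifelse(dereg_tumour, "tumour_only",
           ifelse(dereg_ab, "ab_only", "none"))))
  peak_pattern <- ifelse(has_ab & has_tm, "both",
                  ifelse(has_tm, "tumour_only",
                  ifelse(has_ab, "ab_only", "none")))
  tum <- dereg_pattern %in% c("both", "tumour_only")
  class_label <- rep("unclassified", nrow(gene_calls))
  class_label[tum & peak_pattern == "both" & dereg_pattern == "both"] <- "1"
  class_label[tum & peak_pattern == "both" &
                dereg_pattern == "tumour_only"] <- "2"
  class_label[tum & peak_pattern == "tumour_only" &
                dereg_pattern == "both"] <- "3"
  class_label[tum & peak_pattern == "tumour_only" &
                dereg_pattern == "tumour_only"] <- "4"
  class_label[tum & peak_pattern == "none"] <- "5"
  class_label[tum & peak_pattern == "ab_only"] <- "6"
  data.frame(gene_id = gene_calls$gene_id, dereg_pattern = dereg_pattern,
             peak_pattern = peak_pattern, class_label = class_label,
             stringsAsFactors = FALSE)
}

#' Venn bookkeeping across probes, genes, peaks and classes
#'
#' Collects every additive identity of the integrative analysis: probe-level
#' deregulation patterns per contrast, gene-level deregulation assignments,
#' per-condition ChIP target-gene counts, the six class sizes, and the
#' percentage of deregulated genes associated with peaks in each condition
#' (rounded to the nearest integer).
#'
#' @param probe_results data frame from [call_probes()].
#' @param gene_calls data frame from [reconcile_genes()].
#' @param target_flags data frame from [assign_targets()].
#' @param classification data frame from [classify_genes()].
#' @return A list of class `venn_report`; see the components in the source.
#' @export
venn_report <- function(probe_results, gene_calls, target_flags,
                        classification) {
  pr_ab <- probe_results$dir_ab != 0
  pr_tm <- probe_results$dir_tumour != 0
  probes <- list(
    total = nrow(probe_results),
    unique_ab = sum(pr_ab & !pr_tm),
    unique_tumour = sum(pr_tm & !pr_ab),
    shared = sum(pr_ab & pr_tm),
    none = sum(!pr_ab & !pr_tm),
    dereg_ab = sum(pr_ab),
    dereg_tumour = sum(pr_tm))
  genes <- as.list(table(factor(gene_calls$assignment,
                                levels = c("both", "ab_only", "tumour_only",
                                           "none"))))
  chip <- list(
    unique_ab = sum(target_flags$has_peak_ab & !target_flags$has_peak_tumour),
    unique_tumour = sum(target_flags$has_peak_tumour &
                          !target_flags$has_peak_ab),
    shared = sum(target_flags$has_peak_ab & target_flags$has_peak_tumour))
  chip$total_ab <- chip$unique_ab + chip$shared
  chip$total_tumour <- chip$unique_tumour + chip$shared
  classes <- as.list(table(factor(classification$class_label,
                                  levels = c(as.character(1:6),
                                             "unclassified"))))
  names(classes) <- c(paste0("class", 1:6), "unclassified")

  idx <- match(gene_calls$gene_id, target_flags$gene_id)
  has_ab <- !is.na(idx) & target_flags$has_peak_ab[idx]
  has_tm <- !is.na(idx) & target_flags$has_peak_tumour[idx]
  pct <- list(
    dereg_ab_with_ab_peaks = peak_association_percent(
      sum(gene_calls$dereg_ab & has_ab), sum(gene_calls$dereg_ab)),
    dereg_tumour_with_tumour_peaks = peak_association_percent(
      sum(gene_calls$dereg_tumour & has_tm), sum(gene_calls$dereg_tumour)))
  structure(list(probes = probes, genes = genes, chip = chip,
                 classes = classes, percentages = pct),
            class = "venn_report")
}

#' @export
print.venn_report <- function(x, ...) {
  cat("Probe sets:", x$probes$total, "total;",
      x$probes$unique_ab, "ab-unique,", x$probes$shared, "shared,",
      x$probes$unique_tumour, "tumour-unique\n")
  cat("Gene assignments:",
      paste(names(x$genes), unlist(x$genes), sep = "=", collapse = " "), "\n")
  cat("ChIP target genes:",
      paste(names(x$chip), unlist(x$chip), sep = "=", collapse = " "), "\n")
  cat("Classes:",
      paste(names(x$classes), unlist(x$classes), sep = "=", collapse = " "),
      "\n")
  cat(sprintf("Deregulated genes with peaks: ab %d%%, tumour %d%%\n",
              x$percentages$dereg_ab_with_ab_peaks,
              x$percentages$dereg_tumour_with_tumour_peaks))
  invisible(x)
}

#' Venn arithmetic on printed unique/shared pattern counts
#'
#' Given the unique-to-A, unique-to-B and shared counts of a two-set Venn
#' diagram, returns the per-set totals and the combined union — the additive
#' bookkeeping used throughout the integrative analysis.
#'
#' @param unique_a,unique_b,shared non-negative counts.
#' @return List with `total_a`, `total_b`, `union`.
#' @examples
#' venn_totals(705, 1211, 2323)
#' @export
venn_totals <- function(unique_a, unique_b, shared) {
  assert_count(unique_a, "unique_a", positive = FALSE)
  assert_count(unique_b, "unique_b", positive = FALSE)
  assert_count(shared, "shared", positive = FALSE)
  list(total_a = unique_a + shared, total_b = unique_b + shared,
       union = unique_a + unique_b + shared)
}

#' Percentage of deregulated genes associated with peaks
#'
#' Rounded to the nearest integer percent.
#'
#' @param n_with_peaks,n_deregulated counts.
#' @export
peak_association_percent <- function(n_with_peaks, n_deregulated) {
  stop_if(n_deregulated <= 0, "denominator must be positive")
  as.integer(round(100 * n_with_peaks / n_deregulated))
}

#' Hypergeometric term enrichment
#'
#' One-sided (overrepresentation) hypergeometric test for each term's gene
#' set against a gene universe, with BH adjustment across terms: p =
#' P(X >= observed overlap) for X ~ Hypergeometric(N = |universe|,
#' K = |term|, n = |set|).
#'
#' @param gene_set character vector of genes of interest (subset of
#'   `universe`).
#' @param term_table data frame with columns `term_id`, `gene_id` mapping
#'   terms to member genes (members outside the universe are ignored).
#' @param universe character vector of all considered genes.
#' @return Data frame: term_id, term_size, overlap, p, q, ordered by p.
#' @export
term_enrichment <- function(gene_set, term_table, universe) {
  universe <- unique(universe)
  gene_set <- unique(gene_set)
  stop_if(!all(gene_set %in% universe),
          "`gene_set` must be a subset of `universe`")
  stop_if(!all(c("term_id", "gene_id") %in% names(term_table)),
          "`term_table` needs columns term_id and gene_id")
  tt <- term_table[term_table$gene_id %in% universe, , drop = FALSE]
  terms <- split(unique(tt)$gene_id, unique(tt)$term_id)
  N <- length(universe); n <- length(gene_set)
  rows <- lapply(names(terms), function(tm) {
    K <- length(terms[[tm]])
    k <- length(intersect(terms[[tm]], gene_set))
    p <- phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = tm, term_size = K, overlap = k, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- bh_adjust(out$p)
  out[order(out$p, out$term_id), ]
}
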