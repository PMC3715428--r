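# Expected-class rule used for the planted truth. Kept as its own small
# lookup (rather than calling the classifier) so the end-to-end identity
# between planted labels and classify_genes() output is a real check.
truth_expected_class <- function(dereg_ab, dereg_tumour,
                                 target_ab, target_tumour) {
  dereg_pattern <- ifelse(dereg_ab != 0 & dereg_tumour != 0, "both",
                   ifelse(dereg_tumour != 0, "tumour_only",
                   ifelse(dereg_ab != 0, "ab_only", "none")))
  peak_pattern <- ifelse(target_ab & target_tumour, "both",
                  ifelse(target_tumour, "tumour_only",
                  ifelse(target_ab, "ab_only", "none")))
  cls <- rep("unclassified", length(dereg_ab))
  tum <- dereg_pattern %in% c("both", "tumour_only")
  cls[tum & peak_pattern == "both" & dereg_pattern == "both"] <- "1"
  cls[tum & peak_pattern == "both" & dereg_pattern == "tumour_only"] <- "2"
  cls[tum & peak_pattern == "tumour_only" & dereg_pattern == "both"] <- "3"
  cls[tum & peak_pattern == "tumour_only" &
        dereg_pattern == "tumour_only"] <- "4"
  cls[tum & peak_pattern == "none"] <- "5"
  cls[tum & peak_pattern == "ab_only"] <- "6"
  cls
}

# class id -> (dereg pattern, peak pattern); used when planting an explicit
# class plan. Classes 5 and 6 admit either tumour-deregulation pattern; genes
# are alternated between the two for coverage.
class_patterns <- function(class_id, k) {
  alt <- rep(c("tumour_only", "both"), length.out = k)
  switch(class_id,
         "1" = list(dereg = rep("both", k), peaks = rep("both", k)),
         "2" = list(dereg = rep("tumour_only", k), peaks = rep("both", k)),
         "3" = list(dereg = rep("both", k), peaks = rep("tumour_only", k)),
         "4" = list(dereg = rep("tumour_only", k),
                    peaks = rep("tumour_only", k)),
         "5" = list(dereg = alt, peaks = rep("none", k)),
         "6" = list(dereg = alt, peaks = rep("ab_only", k)))
}

#' Plant the ground truth for a synthetic study
#'
#' Draws, per gene, a true deregulation direction for each expression contrast
#' and a true peak-association flag for each ChIP condition, together with the
#' genomic locus (promoter or an intron midpoint) where reads will be planted,
#' and the target class each gene is therefore expected to receive.
#'
#' With `cfg$class_plan` set, exact per-class gene counts are planted and the
#' two truth tables are derived from the class definitions. Otherwise genes
#' are sampled by the configured per-contrast deregulation fractions (with
#' the configured sharing between contrasts) and per-condition target
#' fractions.
#'
#' @param annotation a `gene_annotation`.
#' @param cfg a [sim_config()].
#' @return An object of class `sim_truth`: list with data frames `genes`
#'   (gene_id, dereg_ab, dereg_tumour in -1/0/+1, conflict_ab,
#'   conflict_tumour, target_ab, target_tumour, expected_class) and `loci`
#'   (gene_id, condition, chrom, center, type).
#' @export
generate_truth <- function(annotation, cfg) {
  stopifnot(inherits(annotation, "gene_annotation"),
            inherits(cfg, "sim_config"))
  n <- nrow(annotation$genes)
  ids <- annotation$genes$gene_id
  with_stream(cfg, 2L, {
    dereg_ab <- dereg_tum <- integer(n)
    target_ab <- target_tum <- logical(n)
    if (!is.null(cfg$class_plan)) {
      plan <- cfg$class_plan[cfg$class_plan > 0]
      picked <- sample(n, sum(plan))
      off <- 0L
      for (cid in names(plan)) {
        k <- plan[[cid]]
        idx <- picked[off + seq_len(k)]
        off <- off + k
        pat <- class_patterns(cid, k)
        sgn <- sample(c(-1L, 1L), k, replace = TRUE)
        dereg_tum[idx] <- sgn
        dereg_ab[idx] <- ifelse(pat$dereg == "both", sgn, 0L)
        target_ab[idx] <- pat$peaks %in% c("both", "ab_only")
        target_tum[idx] <- pat$peaks %in% c("both", "tumour_only")
      }
    } else {
      fr_ab <- cfg$de_fractions$ab
      fr_tm <- cfg$de_fractions$tumour
      n_ab <- round(sum(fr_ab) * n)
      n_tm <- round(sum(fr_tm) * n)
      n_shared <- round(cfg$de_shared_frac * min(n_ab, n_tm))
      shared <- sample(n, n_shared)
      ab_only <- sample(setdiff(seq_len(n), shared), n_ab - n_shared)
      tm_only <- sample(setdiff(seq_len(n), c(shared, ab_only)),
                        n_tm - n_shared)
      sgn_shared <- sample(c(1L, -1L), n_shared, replace = TRUE,
                           prob = fr_ab / sum(fr_ab))
      dereg_ab[shared] <- sgn_shared
      dereg_tum[shared] <- sgn_shared
      dereg_ab[ab_only] <- sample(c(1L, -1L), length(ab_only), replace = TRUE,
                                  prob = fr_ab / sum(fr_ab))
      dereg_tum[tm_only] <- sample(c(1L, -1L), length(tm_only), replace = TRUE,
                                   prob = fr_tm / sum(fr_tm))
      tf <- cfg$planted_target_fractions
      k_ab <- round(tf[["ab"]] * n)
      k_tm <- round(tf[["tumour"]] * n)
      k_shared <- round(cfg$target_shared_frac * min(k_ab, k_tm))
      t_shared <- sample(n, k_shared)
      t_ab <- sample(setdiff(seq_len(n), t_shared), k_ab - k_shared)
      t_tm <- sample(setdiff(seq_len(n), c(t_shared, t_ab)), k_tm - k_shared)
      target_ab[c(t_shared, t_ab)] <- TRUE
      target_tum[c(t_shared, t_tm)] <- TRUE
    }
    # conflicting multi-probe genes: second probe planted with opposite sign
    multi <- ids[ids %in%
                   annotation$probes$gene_id[duplicated(annotation$probes$gene_id)]]
    dereg_any <- dereg_ab != 0 | dereg_tum != 0
    candidates <- which(ids %in% multi & dereg_any)
    n_conf <- round(cfg$frac_conflicting * length(candidates))
    conf <- if (n_conf > 0) sample(candidates, n_conf) else integer()
    conflict_ab <- seq_len(n) %in% conf & dereg_ab != 0
    conflict_tum <- seq_len(n) %in% conf & dereg_tum != 0

    loci <- plant_loci(annotation, ids, target_ab, target_tum)

    genes <- data.frame(
      gene_id = ids, dereg_ab = dereg_ab, dereg_tumour = dereg_tum,
      conflict_ab = conflict_ab, conflict_tumour = conflict_tum,
      target_ab = target_ab, target_tumour = target_tum,
      expected_class = truth_expected_class(dereg_ab, dereg_tum,
                                            target_ab, target_tum),
      stringsAsFactors = FALSE)
    structure(list(genes = genes, loci = loci), class = "sim_truth")
  })
}

# Pick one planted binding locus per target gene: promoter midpoint or the
# midpoint of a random intron. A gene targeted in both conditions gets the
# same locus in both (shared binding), mirroring heavily shared peak sets.
plant_loci <- function(annotation, ids, target_ab, target_tum) {
  any_target <- which(target_ab | target_tum)
  if (!length(any_target)) {
    return(data.frame(gene_id = character(), condition = character(),
                      chrom = character(), center = integer(),
                      type = character(), stringsAsFactors = FALSE))
  }
  rows <- lapply(any_target, function(i) {
    gid <- ids[i]
    g <- annotation$genes[annotation$genes$gene_id == gid, ]
    ex <- annotation$exons[annotation$exons$gene_id == gid, ]
    type <- sample(c("promoter", "intron"), 1L)
    if (type == "promoter") {
      center <- if (g$strand == "+") max(1L, g$start - 250L)
                else min(annotation$seqlengths[[g$chrom]], g$end + 250L)
    } else {
      ex <- ex[order(ex$start), ]
      j <- sample(nrow(ex) - 1L, 1L)
      center <- as.integer(floor((ex$end[j] + ex$start[j + 1L]) / 2))
    }
    conds <- c("ab", "tumour")[c(target_ab[i], target_tum[i])]
    data.frame(gene_id = gid, condition = conds, chrom = g$chrom,
               center = as.integer(center), type = type,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat(sprintf("sim_truth: %d genes (%d dereg ab, %d dereg tumour, %d targets ab, %d targets tumour)\n",
              nrow(x$genes), sum(x$genes$dereg_ab != 0),
              sum(x$genes$dereg_tumour != 0), sum(x$genes$target_ab),
              sum(x$genes$target_tumour)))
  print(table(expected_class = x$genes$expected_class))
  invisible(x)
}
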