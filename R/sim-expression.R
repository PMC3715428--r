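#' Generate a replicated three-genotype expression matrix
#'
#' Builds a probe-set by sample matrix of log2 intensities: a per-probe
#' baseline drawn uniformly in \[6, 12\] log2 units, plus the planted
#' genotype shift of +/- `effect_size` for deregulated genes, plus Gaussian
#' noise with s.d. `noise_sd`. All probe sets of a gene share the gene's
#' shift except in genes planted as "conflicting", where the second probe set
#' receives the opposite sign — emulating genes whose probe sets report
#' opposite regulation.
#'
#' @param annotation a `gene_annotation` (provides the probe-to-gene map).
#' @param cfg a [sim_config()].
#' @param truth a `sim_truth` from [generate_truth()].
#' @return An object of class `expr_set`: list with `log2` (matrix, probe
#'   sets x samples), `probes` (probe_set_id, gene_id) and `samples`
#'   (sample_id, genotype, replicate).
#' @export
generate_expression <- function(annotation, cfg, truth) {
  stopifnot(inherits(annotation, "gene_annotation"),
            inherits(cfg, "sim_config"), inherits(truth, "sim_truth"))
  probes <- annotation$probes
  if (!all(probes$gene_id %in% truth$genes$gene_id)) {
    stop("annotation and truth disagree on gene ids", call. = FALSE)
  }
  samples <- data.frame(
    genotype = rep(GENOTYPES, each = cfg$n_replicates),
    replicate = rep(seq_len(cfg$n_replicates), times = length(GENOTYPES)),
    stringsAsFactors = FALSE)
  samples$sample_id <- paste(samples$genotype, samples$replicate, sep = "_")
  gidx <- match(probes$gene_id, truth$genes$gene_id)
  probe_rank <- stats::ave(seq_len(nrow(probes)), probes$gene_id,
                           FUN = seq_along)
  shift_for <- function(contrast) {
    d <- truth$genes[[paste0("dereg_", contrast)]][gidx]
    conf <- truth$genes[[paste0("conflict_", contrast)]][gidx]
    ifelse(conf & probe_rank == 2L, -d, d) * cfg$effect_size
  }
  shift <- cbind(control = 0, ab = shift_for("ab"),
                 scrib_ab = shift_for("tumour"))
  with_stream(cfg, 3L, {
    baseline <- runif(nrow(probes), 6, 12)
    m <- matrix(NA_real_, nrow(probes), nrow(samples),
                dimnames = list(probes$probe_set_id, samples$sample_id))
    for (j in seq_len(nrow(samples))) {
      mu <- baseline + shift[, samples$genotype[j]]
      m[, j] <- if (cfg$noise_sd > 0) mu + rnorm(length(mu), 0, cfg$noise_sd)
                else mu
    }
    structure(list(log2 = m, probes = probes,
                   samples = samples[, c("sample_id", "genotype", "replicate")]),
              class = "expr_set")
  })
}

#' @export
print.expr_set <- function(x, ...) {
  cat(sprintf("expr_set: %d probe sets (%d genes) x %d samples [%s]\n",
              nrow(x$log2), length(unique(x$probes$gene_id)), ncol(x$log2),
              paste(unique(x$samples$genotype), collapse = ", ")))
  invisible(x)
}

#' Write / read an expression matrix as TSV
#'
#' Layout: `probe_set_id`, `gene_id`, then one column per sample named
#' `<genotype>_<replicate>`.
#'
#' @param expr an `expr_set`.
#' @param path file path.
#' @export
write_expr_tsv <- function(expr, path) {
  df <- data.frame(probe_set_id = expr$probes$probe_set_id,
                   gene_id = expr$probes$gene_id,
                   expr$log2, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expr_tsv
#' @export
read_expr_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  stop_if(!all(c("probe_set_id", "gene_id") %in% names(df)),
          "expression TSV must have probe_set_id and gene_id columns")
  sample_cols <- setdiff(names(df), c("probe_set_id", "gene_id"))
  parts <- regmatches(sample_cols,
                      regexec("^(.*)_([0-9]+)$", sample_cols))
  bad <- vapply(parts, length, 1L) != 3L
  stop_if(any(bad), "sample columns must be named <genotype>_<replicate>: ",
          paste(sample_cols[bad], collapse = ", "))
  genotype <- vapply(parts, `[`, "", 2L)
  stop_if(!all(genotype %in% GENOTYPES),
          "unknown genotype labels: ",
          paste(setdiff(genotype, GENOTYPES), collapse = ", "))
  m <- as.matrix(df[, sample_cols, drop = FALSE])
  rownames(m) <- df$probe_set_id
  structure(list(
    log2 = m,
    probes = df[, c("probe_set_id", "gene_id")],
    samples = data.frame(sample_id = sample_cols, genotype = genotype,
                         replicate = as.integer(vapply(parts, `[`, "", 3L)),
                         stringsAsFactors = FALSE)),
    class = "expr_set")
}
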