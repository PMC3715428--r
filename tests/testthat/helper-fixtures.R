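# shared fixtures, built in code

# a strongly informative non-palindromic PWM (consensus TATAC)
strong_pwm <- function(id = "TATAC", consensus = "TATAC") {
  cons <- strsplit(consensus, "")[[1L]]
  m <- matrix(1, 4, length(cons),
              dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_along(cons)) m[cons[j], j] <- 97
  pwm(id, m)
}

# genome-background sequence set in which the decoy motifs occur commonly
# (the planted motif itself is absent): emulates a genome-wide baseline
# dominated by common motifs
decoy_genome <- function(decoys, seed, n_per_decoy = 8, seq_length = 400) {
  sets <- lapply(seq_along(decoys), function(i) {
    generate_sequences(
      sim_config(seed = seed + i, motif_plant_rate = 1,
                 n_seqs = n_per_decoy, seq_length = seq_length),
      decoys[[i]])$sequences
  })
  out <- do.call(c, sets)
  names(out) <- sprintf("bg%04d", seq_along(out))
  out
}

# a small expr_set built directly from a matrix (bypassing the generator)
make_expr <- function(values, gene_ids = NULL, n_rep = 3) {
  samples <- data.frame(
    genotype = rep(c("control", "ab", "scrib_ab"), each = n_rep),
    replicate = rep(seq_len(n_rep), 3))
  samples$sample_id <- paste(samples$genotype, samples$replicate, sep = "_")
  colnames(values) <- samples$sample_id
  probe_ids <- if (is.null(rownames(values)))
    sprintf("p%03d", seq_len(nrow(values))) else rownames(values)
  if (is.null(gene_ids)) gene_ids <- sub("_p[0-9]+$", "", probe_ids)
  rownames(values) <- probe_ids
  structure(list(log2 = values,
                 probes = data.frame(probe_set_id = probe_ids,
                                     gene_id = gene_ids),
                 samples = samples[, c("sample_id", "genotype", "replicate")]),
            class = "expr_set")
}

# 1 bp stranded 5' anchors on a single toy chromosome
make_reads <- function(pos, strand = "+", chrom = "chr1", chrom_len = 10000) {
  GenomicRanges::GRanges(rep(chrom, length(pos)),
                         IRanges::IRanges(pos, width = rep(1L, length(pos))),
                         strand = rep(strand, length.out = length(pos)),
                         seqlengths = setNames(chrom_len, chrom))
}

# exhaustive step-up definition of the BH adjustment (independent oracle)
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- vapply(seq_len(m), function(k) min(1, min(ps[k:m] * m / (k:m))),
                numeric(1))
  out <- numeric(m)
  out[o] <- adj
  out
}

# brute-force per-window PWM scan on both strands (independent oracle);
# N-containing windows are skipped on both strands
scan_oracle <- function(seq_chr, x, threshold_frac = 0.8) {
  lo <- pwm_logodds(x)
  w <- ncol(lo)
  min_score <- threshold_frac * sum(apply(lo, 2, max))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  hits <- 0L
  L <- nchar(seq_chr)
  if (L < w) return(0L)
  for (i in seq_len(L - w + 1L)) {
    b <- strsplit(substr(seq_chr, i, i + w - 1L), "")[[1L]]
    bi <- match(b, c("A", "C", "G", "T"))
    if (anyNA(bi)) next
    if (sum(lo[cbind(bi, seq_len(w))]) >= min_score) hits <- hits + 1L
    rci <- match(rev(unname(comp[b])), c("A", "C", "G", "T"))
    if (sum(lo[cbind(rci, seq_len(w))]) >= min_score) hits <- hits + 1L
  }
  hits
}
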