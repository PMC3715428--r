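test_that("annotation generation places valid gene models deterministically", {
  cfg <- sim_config(seed = 1, n_genes = 10, frac_multi_probe = 0.2)
  ann <- generate_annotation(cfg)
  expect_equal(nrow(ann$genes), 10)
  # every gene has >= 2 exons, hence >= 1 intron
  expect_true(all(table(ann$exons$gene_id) >= 2))
  introns <- intron_regions(ann)
  expect_setequal(unique(S4Vectors::mcols(introns)$gene_id),
                  ann$genes$gene_id)
  # genes do not overlap within a chromosome
  for (ch in unique(ann$genes$chrom)) {
    g <- ann$genes[ann$genes$chrom == ch, ]
    g <- g[order(g$start), ]
    if (nrow(g) > 1) expect_true(all(g$start[-1] > g$end[-nrow(g)]))
  }
  # exactly 2 of 10 genes carry two probe sets
  expect_equal(sum(table(ann$probes$gene_id) == 2), 2)
  expect_identical(ann, generate_annotation(cfg))
})

test_that("annotation generation errors when genes cannot fit", {
  expect_error(generate_annotation(sim_config(seed = 1, n_genes = 500,
                                              n_chroms = 1,
                                              chrom_length = 10000)),
               "cannot place")
})

test_that("identical configs give byte-identical study files", {
  cfg <- sim_config(seed = 42, n_genes = 20, chrom_length = 100000)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_study(simulate_study(cfg), d1)
  write_study(simulate_study(cfg), d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6),
                     label = paste("bytes of", f))
  }
})

test_that("zero-noise expression matrix carries the planted shifts exactly", {
  cfg <- sim_config(seed = 3, n_genes = 40, noise_sd = 0,
                    frac_multi_probe = 0.5, frac_conflicting = 1,
                    effect_size = 2)
  ann <- generate_annotation(cfg)
  truth <- generate_truth(ann, cfg)
  expr <- generate_expression(ann, cfg, truth)
  ctrl <- expr$samples$sample_id[expr$samples$genotype == "control"]
  tum <- expr$samples$sample_id[expr$samples$genotype == "scrib_ab"]
  ab <- expr$samples$sample_id[expr$samples$genotype == "ab"]
  lfc_tum <- rowMeans(expr$log2[, tum]) - rowMeans(expr$log2[, ctrl])
  lfc_ab <- rowMeans(expr$log2[, ab]) - rowMeans(expr$log2[, ctrl])
  first_probe <- !duplicated(expr$probes$gene_id)
  d_tum <- truth$genes$dereg_tumour[match(expr$probes$gene_id,
                                          truth$genes$gene_id)]
  d_ab <- truth$genes$dereg_ab[match(expr$probes$gene_id,
                                     truth$genes$gene_id)]
  # first probe set of each gene carries the gene's shift exactly
  expect_equal(lfc_tum[first_probe], (2 * d_tum)[first_probe],
               ignore_attr = TRUE)
  expect_equal(lfc_ab[first_probe], (2 * d_ab)[first_probe],
               ignore_attr = TRUE)
  # with frac_conflicting = 1, second probe sets of deregulated multi-probe
  # genes carry the opposite sign
  second <- duplicated(expr$probes$gene_id)
  conf <- truth$genes$conflict_tumour[match(expr$probes$gene_id,
                                            truth$genes$gene_id)]
  sel <- second & conf
  expect_true(any(sel))
  expect_equal(lfc_tum[sel], (-2 * d_tum)[sel], ignore_attr = TRUE)
})

test_that("planted read pileups cover locus centers; empty configs give empty reads", {
  cfg <- sim_config(seed = 5, n_genes = 20, background_read_rate = 0,
                    reads_per_peak = 50)
  ann <- generate_annotation(cfg)
  truth <- generate_truth(ann, cfg)
  reads <- generate_reads(ann, cfg, truth)
  cov <- extend_and_pileup(reads$ab, cfg$read_length)$coverage
  loci <- truth$loci[truth$loci$condition == "ab", ]
  expect_gt(nrow(loci), 0)
  for (i in seq_len(nrow(loci))) {
    depth <- as.integer(cov[[loci$chrom[i]]][loci$center[i]])
    expect_gte(depth, cfg$reads_per_peak / 2)
  }
  # input carries background only -> empty here
  expect_length(reads$input, 0)

  # condition-unique pileups appear only at own planted loci
  ab_only <- truth$genes$gene_id[truth$genes$target_ab &
                                   !truth$genes$target_tumour]
  if (length(ab_only)) {
    cov_tum <- extend_and_pileup(reads$tumour, cfg$read_length)$coverage
    for (g in ab_only) {
      l <- truth$loci[truth$loci$gene_id == g &
                        truth$loci$condition == "ab", ]
      expect_equal(as.integer(cov_tum[[l$chrom]][l$center]), 0)
    }
  }
})

test_that("planted counts in truth match config exactly", {
  plan <- c("1" = 4, "2" = 3, "3" = 2, "4" = 5, "5" = 3, "6" = 2)
  cfg <- sim_config(seed = 11, n_genes = 50, class_plan = plan)
  truth <- generate_truth(generate_annotation(cfg), cfg)
  got <- table(truth$genes$expected_class)
  expect_equal(as.integer(got[names(plan)]), unname(plan),
               ignore_attr = TRUE)
  # class definitions are reflected in the truth tables
  with(truth$genes, {
    expect_equal(sum(dereg_tumour != 0 & dereg_ab != 0 &
                       target_ab & target_tumour), 4)  # class 1
    expect_equal(sum(dereg_tumour != 0 & target_ab & !target_tumour), 2)
  })
})

test_that("sequence generation plants consensus instances at the configured rate", {
  x <- strong_pwm()
  cfg1 <- sim_config(seed = 2, motif_plant_rate = 1, n_seqs = 50,
                     seq_length = 60)
  out <- generate_sequences(cfg1, x)
  expect_equal(nrow(out$planted), 50)
  cons <- "TATAC"
  hits <- vapply(as.character(out$sequences),
                 function(s) grepl(cons, s, fixed = TRUE), TRUE)
  expect_true(all(hits))
  # recorded positions point at actual consensus copies
  for (i in seq_len(nrow(out$planted))) {
    s <- as.character(out$sequences[[out$planted$seq_id[i]]])
    expect_equal(substr(s, out$planted$position[i],
                        out$planted$position[i] + 4), cons)
  }
  expect_identical(generate_sequences(cfg1, x), out)

  # plant rate 0: consensus hit count consistent with the uniform-background
  # binomial expectation (p = 2 * (1/4)^5 per window, both strands)
  cfg0 <- sim_config(seed = 2, motif_plant_rate = 0, n_seqs = 200,
                     seq_length = 100)
  out0 <- generate_sequences(cfg0, strong_pwm())
  expect_equal(nrow(out0$planted), 0)
  hits0 <- nrow(scan_sequences(out0$sequences, strong_pwm(), 0.99))
  n_win <- 200 * (100 - 5 + 1) * 2
  expected <- n_win / 4^5
  expect_lt(abs(hits0 - expected), 5 * sqrt(expected))
})

test_that("generated Ct tables invert the delta-delta-Ct arithmetic", {
  cfg <- sim_config(seed = 1, ct_noise_sd = 0)
  fc <- data.frame(target_gene = "gA", condition = "ab",
                   fold_change = c(2))
  ct <- generate_ct_table(cfg, fc)
  res <- ddct_fold_change(ct, "gA", "ab")
  expect_equal(res$ddct, -1)
  expect_equal(res$fold_change, 2)
  # FC = 1: all dCt equal
  ct1 <- generate_ct_table(cfg, transform(fc, fold_change = 1))
  expect_equal(ddct_fold_change(ct1, "gA", "ab")$fold_change, 1)
  # FC = 0.25 -> ddCt = +2
  ct2 <- generate_ct_table(cfg, transform(fc, fold_change = 0.25))
  expect_equal(ddct_fold_change(ct2, "gA", "ab")$ddct, 2)
})
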