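# minimal hand-built annotation: helper for this file
tiny_annotation <- function(exons, chrom_len = 20000) {
  genes <- do.call(rbind, lapply(split(exons, exons$gene_id), function(d) {
    data.frame(gene_id = d$gene_id[1], chrom = d$chrom[1],
               start = min(d$start), end = max(d$end), strand = d$strand[1])
  }))
  structure(list(genes = genes, exons = exons,
                 probes = data.frame(probe_set_id = paste0(genes$gene_id, "_p1"),
                                     gene_id = genes$gene_id),
                 seqlengths = c(chr1 = chrom_len)),
            class = "gene_annotation")
}

test_that("promoter intervals follow the 500 bp upstream-of-TSS convention", {
  # + strand TSS at 10001 (1-based): promoter [9501, 10000]
  ex <- data.frame(gene_id = "g1", transcript_id = "g1.t1", exon_rank = 1:2,
                   chrom = "chr1", start = c(10001, 11001),
                   end = c(10500, 11500), strand = "+")
  p <- promoter_regions(tiny_annotation(ex))
  expect_equal(GenomicRanges::start(p), 9501)
  expect_equal(GenomicRanges::end(p), 10000)
  # - strand transcript [1001, 2000]: promoter [2001, 2500]
  ex2 <- data.frame(gene_id = "g2", transcript_id = "g2.t1", exon_rank = 1:2,
                    chrom = "chr1", start = c(1001, 1701),
                    end = c(1300, 2000), strand = "-")
  p2 <- promoter_regions(tiny_annotation(ex2))
  expect_equal(c(GenomicRanges::start(p2), GenomicRanges::end(p2)),
               c(2001, 2500))
  # clipping at the chromosome start: + TSS at 301 -> [1, 300]
  ex3 <- data.frame(gene_id = "g3", transcript_id = "g3.t1", exon_rank = 1:2,
                    chrom = "chr1", start = c(301, 801),
                    end = c(500, 1000), strand = "+")
  p3 <- promoter_regions(tiny_annotation(ex3))
  expect_equal(c(GenomicRanges::start(p3), GenomicRanges::end(p3)), c(1, 300))
  # unknown strand errors
  ex4 <- transform(ex3, strand = "*")
  expect_error(promoter_regions(tiny_annotation(ex4)), "strand")
})

test_that("introns are the gaps between consecutive exons", {
  # exons [1,100], [201,300] (1-based closed) -> intron [101, 200]
  ex <- data.frame(gene_id = "g1", transcript_id = "g1.t1", exon_rank = 1:2,
                   chrom = "chr1", start = c(1, 201), end = c(100, 300),
                   strand = "+")
  i1 <- intron_regions(tiny_annotation(ex))
  expect_equal(c(GenomicRanges::start(i1), GenomicRanges::end(i1)),
               c(101, 200))
  ex3 <- data.frame(gene_id = "g1", transcript_id = "g1.t1", exon_rank = 1:3,
                    chrom = "chr1", start = c(1, 201, 401),
                    end = c(100, 300, 500), strand = "+")
  i3 <- intron_regions(tiny_annotation(ex3))
  expect_equal(GenomicRanges::start(i3), c(101, 301))
  expect_equal(GenomicRanges::end(i3), c(200, 400))
  # single-exon transcript contributes no intron (and no error)
  ex1 <- data.frame(gene_id = "g1", transcript_id = "g1.t1", exon_rank = 1,
                    chrom = "chr1", start = 1, end = 100, strand = "+")
  expect_length(intron_regions(tiny_annotation(ex1)), 0)
})

test_that("peaks in promoters or introns flag genes; exon-interior peaks never do", {
  ex <- data.frame(gene_id = "g1", transcript_id = "g1.t1", exon_rank = 1:2,
                   chrom = "chr1", start = c(10001, 12001),
                   end = c(10999, 12500), strand = "+")
  ann <- tiny_annotation(ex)
  flag_for <- function(peak_start, peak_end) {
    peaks <- list(ab = GenomicRanges::GRanges(
      "chr1", IRanges::IRanges(peak_start, peak_end)))
    assign_targets(peaks, ann)$has_peak_ab
  }
  expect_true(flag_for(9601, 9700))     # promoter overlap
  expect_true(flag_for(11100, 11200))   # intron interior
  expect_true(flag_for(9400, 9510))     # 1 bp into the promoter suffices
  expect_false(flag_for(10100, 10200))  # exon interior
  expect_false(flag_for(13000, 13100))  # downstream of the gene
})

test_that("assignment equals a quadratic brute-force overlap oracle", {
  set.seed(31)
  for (rep in 1:6) {
    cfg <- sim_config(seed = 30 + rep, n_genes = 10, n_chroms = 1,
                      chrom_length = 100000)
    ann <- generate_annotation(cfg)
    n_peaks <- sample(5:20, 1)
    starts <- sample(1:99000, n_peaks)
    peaks <- GenomicRanges::GRanges(
      "chr1", IRanges::IRanges(starts, width = sample(20:400, n_peaks,
                                                      replace = TRUE)))
    got <- assign_targets(list(ab = peaks), ann)$has_peak_ab

    # oracle: promoter/intron intervals recomputed by hand from the tables
    expected <- vapply(ann$genes$gene_id, function(g) {
      ge <- ann$genes[ann$genes$gene_id == g, ]
      ex <- ann$exons[ann$exons$gene_id == g, ]
      ex <- ex[order(ex$start), ]
      ivs <- if (ge$strand == "+") {
        rbind(c(max(1, ge$start - 500), ge$start - 1))
      } else {
        rbind(c(ge$end + 1, min(100000, ge$end + 500)))
      }
      if (nrow(ex) > 1) {
        ivs <- rbind(ivs, cbind(ex$end[-nrow(ex)] + 1, ex$start[-1] - 1))
      }
      any(vapply(seq_along(peaks), function(i) {
        ps <- GenomicRanges::start(peaks)[i]
        pe <- GenomicRanges::end(peaks)[i]
        any(ps <= ivs[, 2] & pe >= ivs[, 1])
      }, TRUE))
    }, TRUE)
    expect_equal(got, unname(expected))
  }
})

test_that("mirroring coordinates and flipping strands preserves the flags", {
  cfg <- sim_config(seed = 77, n_genes = 8, n_chroms = 1,
                    chrom_length = 50000)
  ann <- generate_annotation(cfg)
  G <- 50000
  set.seed(5)
  peaks <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(sample(1:49000, 15),
                             width = sample(30:300, 15, replace = TRUE)))
  before <- assign_targets(list(ab = peaks), ann)$has_peak_ab

  mirror <- function(s, e) list(start = G + 1 - e, end = G + 1 - s)
  m_ex <- ann$exons
  m <- mirror(m_ex$start, m_ex$end)
  m_ex$start <- m$start; m_ex$end <- m$end
  m_ex$strand <- ifelse(m_ex$strand == "+", "-", "+")
  m_genes <- ann$genes
  mg <- mirror(m_genes$start, m_genes$end)
  m_genes$start <- mg$start; m_genes$end <- mg$end
  m_genes$strand <- ifelse(m_genes$strand == "+", "-", "+")
  m_ann <- structure(list(genes = m_genes, exons = m_ex, probes = ann$probes,
                          seqlengths = ann$seqlengths),
                     class = "gene_annotation")
  mp <- mirror(GenomicRanges::start(peaks), GenomicRanges::end(peaks))
  m_peaks <- GenomicRanges::GRanges("chr1",
                                    IRanges::IRanges(mp$start, mp$end))
  after <- assign_targets(list(ab = m_peaks), m_ann)$has_peak_ab
  expect_equal(before, after)
})

test_that("peaks on unknown chromosomes are skipped with a warning", {
  ex <- data.frame(gene_id = "g1", transcript_id = "g1.t1", exon_rank = 1:2,
                   chrom = "chr1", start = c(10001, 12001),
                   end = c(10999, 12500), strand = "+")
  ann <- tiny_annotation(ex)
  peaks <- list(ab = GenomicRanges::GRanges(
    c("chrX", "chr1"), IRanges::IRanges(c(9601, 9601), c(9700, 9700))))
  expect_warning(flags <- assign_targets(peaks, ann), "unknown chromosome")
  expect_true(flags$has_peak_ab)
})
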