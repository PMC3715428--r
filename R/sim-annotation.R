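# Deterministic RNG scoping: every generator draws from its own stream derived
# from the config seed, and restores the caller's RNG state afterwards, so a
# given config yields byte-identical outputs no matter the call order.
sim_stream <- function(cfg, stream) {
  (cfg$seed %% 1000000L) * 1009L + stream
}

with_stream <- function(cfg, stream, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(sim_stream(cfg, stream))
  expr
}

#' Generate a toy gene annotation
#'
#' Places `n_genes` non-overlapping genes on a toy genome, alternating
#' chromosomes and strands deterministically under the configuration seed.
#' Every gene has one transcript with 2-4 exons, so every gene has at least
#' one intron, and a configurable fraction of genes is interrogated by two
#' array probe sets (the rest by one).
#'
#' @param cfg a [sim_config()] object.
#' @return An object of class `gene_annotation`: a list with data frames
#'   `genes` (gene_id, chrom, start, end, strand; 1-based inclusive),
#'   `exons` (gene_id, transcript_id, exon_rank, chrom, start, end, strand),
#'   `probes` (probe_set_id, gene_id), and the named `seqlengths` vector.
#' @examples
#' ann <- generate_annotation(sim_config(seed = 1, n_genes = 10))
#' nrow(ann$genes)
#' @export
generate_annotation <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  sl <- sim_seqlengths(cfg)
  per_chrom <- tabulate(rep(seq_len(cfg$n_chroms), length.out = cfg$n_genes),
                        nbins = cfg$n_chroms)
  # worst-case footprint: 4 exons of <=400 bp, 3 introns of <=400 bp, plus
  # promoter headroom and inter-gene gap
  max_span <- 4L * 400L + 3L * 400L
  gap <- cfg$fragment_length + 600L
  if (any(per_chrom * (max_span + gap) + gap > cfg$chrom_length)) {
    stop("cannot place ", cfg$n_genes, " genes without overlap on ",
         cfg$n_chroms, " chromosome(s) of ", cfg$chrom_length,
         " bp; increase chrom_length or n_chroms", call. = FALSE)
  }
  with_stream(cfg, 1L, {
    genes <- vector("list", cfg$n_genes)
    exons <- vector("list", cfg$n_genes)
    gi <- 0L
    for (ci in seq_len(cfg$n_chroms)) {
      cursor <- gap
      for (k in seq_len(per_chrom[ci])) {
        gi <- gi + 1L
        gene_id <- sprintf("gene%04d", gi)
        n_ex <- sample(2:4, 1L)
        ex_len <- sample(150:400, n_ex, replace = TRUE)
        in_len <- sample(150:400, n_ex - 1L, replace = TRUE)
        strand <- sample(c("+", "-"), 1L)
        starts <- cursor + cumsum(c(0L, ex_len[-n_ex] + in_len))
        ends <- starts + ex_len - 1L
        genes[[gi]] <- data.frame(
          gene_id = gene_id, chrom = names(sl)[ci],
          start = starts[1L], end = ends[n_ex], strand = strand,
          stringsAsFactors = FALSE)
        exons[[gi]] <- data.frame(
          gene_id = gene_id, transcript_id = paste0(gene_id, ".t1"),
          exon_rank = seq_len(n_ex), chrom = names(sl)[ci],
          start = starts, end = ends, strand = strand,
          stringsAsFactors = FALSE)
        cursor <- ends[n_ex] + gap + sample(0:200, 1L)
      }
    }
    genes <- do.call(rbind, genes)
    exons <- do.call(rbind, exons)
    n_multi <- round(cfg$frac_multi_probe * cfg$n_genes)
    multi <- if (n_multi > 0) sort(sample(cfg$n_genes, n_multi)) else integer()
    probes <- data.frame(
      probe_set_id = character(), gene_id = character(),
      stringsAsFactors = FALSE)
    rows <- lapply(seq_len(cfg$n_genes), function(i) {
      np <- if (i %in% multi) 2L else 1L
      data.frame(probe_set_id = sprintf("%s_p%d", genes$gene_id[i],
                                        seq_len(np)),
                 gene_id = genes$gene_id[i], stringsAsFactors = FALSE)
    })
    probes <- do.call(rbind, rows)
    structure(list(genes = genes, exons = exons, probes = probes,
                   seqlengths = sl),
              class = "gene_annotation")
  })
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat(sprintf("gene_annotation: %d genes, %d exons, %d probe sets on %d chromosome(s)\n",
              nrow(x$genes), nrow(x$exons), nrow(x$probes),
              length(x$seqlengths)))
  invisible(x)
}

#' Convert a gene annotation to GRanges gene models
#'
#' @param annotation a `gene_annotation` object (or the result of
#'   [read_annotation_gff3()]).
#' @return A named list of per-transcript `GRanges` exon sets is not exposed;
#'   instead this returns a list with `genes` and `exons` as `GRanges`.
#' @keywords internal
annotation_granges <- function(annotation) {
  g <- annotation$genes
  e <- annotation$exons
  list(
    genes = GenomicRanges::GRanges(
      g$chrom, IRanges::IRanges(g$start, g$end), strand = g$strand,
      gene_id = g$gene_id, seqlengths = annotation$seqlengths),
    exons = GenomicRanges::GRanges(
      e$chrom, IRanges::IRanges(e$start, e$end), strand = e$strand,
      gene_id = e$gene_id, transcript_id = e$transcript_id,
      seqlengths = annotation$seqlengths))
}

#' Write / read gene models as GFF3
#'
#' Standard three-level gene/mRNA/exon GFF3 (1-based inclusive), written and
#' parsed with rtracklayer.
#'
#' @param annotation a `gene_annotation` object.
#' @param path output (or input) file path.
#' @return `write_annotation_gff3` returns `path` invisibly;
#'   `read_annotation_gff3` returns a `gene_annotation` (without the `probes`
#'   table, which travels with the expression matrix).
#' @export
write_annotation_gff3 <- function(annotation, path) {
  g <- annotation$genes
  e <- annotation$exons
  tx <- do.call(rbind, lapply(split(e, e$transcript_id), function(d) {
    data.frame(transcript_id = d$transcript_id[1L], gene_id = d$gene_id[1L],
               chrom = d$chrom[1L], start = min(d$start), end = max(d$end),
               strand = d$strand[1L], stringsAsFactors = FALSE)
  }))
  tx <- tx[order(tx$chrom, tx$start), ]
  gr_g <- GenomicRanges::GRanges(g$chrom, IRanges::IRanges(g$start, g$end),
                                 strand = g$strand, type = "gene",
                                 ID = g$gene_id)
  gr_t <- GenomicRanges::GRanges(tx$chrom, IRanges::IRanges(tx$start, tx$end),
                                 strand = tx$strand, type = "mRNA",
                                 ID = tx$transcript_id, Parent = tx$gene_id)
  gr_e <- GenomicRanges::GRanges(e$chrom, IRanges::IRanges(e$start, e$end),
                                 strand = e$strand, type = "exon",
                                 ID = sprintf("%s.e%d", e$transcript_id,
                                              e$exon_rank),
                                 Parent = e$transcript_id)
  all <- c(gr_g, gr_t, gr_e)
  GenomeInfoDb::seqlengths(all) <-
    annotation$seqlengths[GenomeInfoDb::seqlevels(all)]
  rtracklayer::export(sort(all), path, format = "gff3")
  invisible(path)
}

#' @rdname write_annotation_gff3
#' @param seqlengths optional named vector of chromosome lengths; when absent
#'   they are taken from the GFF3 sequence-region pragmas if present, else
#'   from the rightmost feature per chromosome.
#' @export
read_annotation_gff3 <- function(path, seqlengths = NULL) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  if (is.null(seqlengths)) {
    sl <- GenomeInfoDb::seqlengths(gr)
    if (any(is.na(sl))) {
      sl <- tapply(df$end, df$seqnames, max)
      sl <- setNames(as.integer(sl), names(sl))
    }
    seqlengths <- sl
  }
  ex <- df[df$type == "exon", ]
  tx <- df[df$type == "mRNA", ]
  ge <- df[df$type == "gene", ]
  tx2gene <- setNames(as.character(tx$Parent), tx$ID)
  exons <- data.frame(
    gene_id = unname(tx2gene[as.character(unlist(ex$Parent))]),
    transcript_id = as.character(unlist(ex$Parent)),
    exon_rank = NA_integer_, chrom = as.character(ex$seqnames),
    start = ex$start, end = ex$end, strand = as.character(ex$strand),
    stringsAsFactors = FALSE)
  exons <- exons[order(exons$transcript_id, exons$start), ]
  exons$exon_rank <- stats::ave(seq_len(nrow(exons)), exons$transcript_id,
                                FUN = seq_along)
  genes <- data.frame(
    gene_id = ge$ID, chrom = as.character(ge$seqnames),
    start = ge$start, end = ge$end, strand = as.character(ge$strand),
    stringsAsFactors = FALSE)
  structure(list(genes = genes, exons = exons, probes = NULL,
                 seqlengths = seqlengths),
            class = "gene_annotation")
}
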