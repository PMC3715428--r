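#' Generate stranded ChIP and input reads with planted binding loci
#'
#' Emits reads as 1 bp stranded 5'-anchor intervals (extension to the read
#' length happens in the peak caller). Each condition receives a uniform
#' background of `round(background_read_rate * genome_length)` reads plus
#' `reads_per_peak` reads at every planted locus for that condition; the
#' input sample is background only. Planted read anchors are positioned so
#' that every extended read covers the locus center, giving a pileup of
#' `reads_per_peak` at the center.
#'
#' @param annotation a `gene_annotation`.
#' @param cfg a [sim_config()].
#' @param truth a `sim_truth` carrying the planted loci.
#' @return Named list of `GRanges` (`ab`, `tumour`, `input`) of 1 bp stranded
#'   5' anchors, with seqlengths set.
#' @export
generate_reads <- function(annotation, cfg, truth) {
  stopifnot(inherits(annotation, "gene_annotation"),
            inherits(cfg, "sim_config"), inherits(truth, "sim_truth"))
  sl <- annotation$seqlengths
  genome_len <- sum(sl)
  n_bg <- round(cfg$background_read_rate * genome_len)

  background <- function() {
    if (n_bg == 0) {
      return(GenomicRanges::GRanges(seqlengths = sl))
    }
    pos <- sort(sample.int(genome_len, n_bg, replace = TRUE))
    offs <- c(0, cumsum(as.numeric(sl)))
    ci <- findInterval(pos - 1L, offs[-length(offs)], rightmost.closed = FALSE)
    ci <- pmin(pmax(ci, 1L), length(sl))
    local_pos <- pos - offs[ci]
    GenomicRanges::GRanges(names(sl)[ci],
                           IRanges::IRanges(local_pos, width = 1L),
                           strand = sample(c("+", "-"), n_bg, replace = TRUE),
                           seqlengths = sl)
  }

  planted <- function(cond) {
    loci <- truth$loci[truth$loci$condition == cond, , drop = FALSE]
    if (!nrow(loci)) {
      return(GenomicRanges::GRanges(seqlengths = sl))
    }
    L <- cfg$read_length
    per <- lapply(seq_len(nrow(loci)), function(i) {
      center <- loci$center[i]
      str <- sample(c("+", "-"), cfg$reads_per_peak, replace = TRUE)
      # a + read anchored in [center-L+1, center] covers the center once
      # extended; mirrored for - reads
      anchor <- ifelse(str == "+",
                       center - sample.int(L, cfg$reads_per_peak,
                                           replace = TRUE) + 1L,
                       center + sample.int(L, cfg$reads_per_peak,
                                           replace = TRUE) - 1L)
      anchor <- pmin(pmax(anchor, 1L), sl[[loci$chrom[i]]])
      GenomicRanges::GRanges(loci$chrom[i],
                             IRanges::IRanges(anchor, width = 1L),
                             strand = str, seqlengths = sl)
    })
    do.call(c, per)
  }

  reads <- list(
    ab = with_stream(cfg, 4L, sort(c(background(), planted("ab")))),
    tumour = with_stream(cfg, 5L, sort(c(background(), planted("tumour")))),
    input = with_stream(cfg, 6L, sort(background())))
  reads
}

#' Write / read stranded read anchors as BED6
#'
#' BED is 0-based half-open on disk; conversion is handled by rtracklayer.
#'
#' @param reads a `GRanges` of 1 bp stranded anchors.
#' @param path file path.
#' @param seqlengths named chromosome lengths to attach on read.
#' @export
write_reads_bed <- function(reads, path) {
  rtracklayer::export(reads, path, format = "bed")
  invisible(path)
}

#' @rdname write_reads_bed
#' @export
read_reads_bed <- function(path, seqlengths = NULL) {
  gr <- rtracklayer::import(path, format = "bed")
  if (!is.null(seqlengths)) {
    GenomeInfoDb::seqlevels(gr) <- names(seqlengths)
    GenomeInfoDb::seqlengths(gr) <- seqlengths
  }
  gr
}
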