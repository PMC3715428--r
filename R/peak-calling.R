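#' Peak-caller configuration
#'
#' The caller is a deliberately simple input-normalised binomial caller that
#' carries the four conventional PeakSeq-style parameters: reads are
#' extended to `read_length` bp from their 5' anchor, candidate segments are
#' merged across gaps of up to `max_gap` bp, and merged regions are retained
#' when the binomial enrichment p-value is below `pval_thresh` and its BH
#' adjustment is below `min_fdr`.
#'
#' @param read_length extension length in bp (default 40).
#' @param max_gap maximum merge gap in bp (default 40).
#' @param min_fdr BH-adjusted significance cutoff (default 0.01).
#' @param pval_thresh raw binomial p-value cutoff (default 1e-4).
#' @param seed_depth minimum extended-read depth seeding a candidate segment
#'   (default 2).
#' @export
peak_caller_config <- function(read_length = 40L, max_gap = 40L,
                               min_fdr = 0.01, pval_thresh = 1e-4,
                               seed_depth = 2L) {
  assert_count(read_length, "read_length")
  assert_count(max_gap, "max_gap", positive = FALSE)
  assert_count(seed_depth, "seed_depth")
  stop_if(min_fdr <= 0 || min_fdr >= 1, "`min_fdr` must be in (0, 1)")
  stop_if(pval_thresh <= 0 || pval_thresh >= 1,
          "`pval_thresh` must be in (0, 1)")
  structure(list(read_length = as.integer(read_length),
                 max_gap = as.integer(max_gap), min_fdr = min_fdr,
                 pval_thresh = pval_thresh,
                 seed_depth = as.integer(seed_depth)),
            class = "peak_caller_config")
}

#' Extend 5' read anchors and compute per-base coverage
#'
#' Each read contributes 1 to `read_length` consecutive bases starting at its
#' 5' end in strand direction ('+' extends rightwards, '-' leftwards),
#' clipped at chromosome bounds.
#'
#' @param reads `GRanges` of 1 bp stranded 5' anchors with seqlengths set.
#' @param read_length extension length in bp.
#' @return List with `coverage` (an `RleList` over chromosomes) and
#'   `extended` (the clipped extended-read `GRanges`).
#' @export
extend_and_pileup <- function(reads, read_length = 40L) {
  stopifnot(is(reads, "GRanges"))
  stop_if(any(is.na(GenomeInfoDb::seqlengths(reads))),
          "reads must carry seqlengths")
  # resize may momentarily run past chromosome ends; trim() clips right away
  ext <- suppressWarnings(
    GenomicRanges::resize(reads, width = read_length, fix = "start"))
  clipped <- GenomicRanges::trim(ext)
  n_clip <- sum(GenomicRanges::width(clipped) < read_length)
  if (n_clip > 0) {
    message(n_clip, " read(s) clipped at chromosome bounds")
  }
  list(coverage = GenomicRanges::coverage(clipped), extended = clipped)
}

#' Call enriched regions against a scaled input control
#'
#' Candidate segments are maximal runs of sample depth >= `seed_depth`;
#' segments separated by <= `max_gap` bp are merged. Per merged region the
#' caller counts extended sample reads `k_s` and extended input reads scaled
#' by `r = total_sample / total_input`, and computes the upper tail of
#' Binomial(k_s + round(k_i * r), 0.5) at `k_s` — a sign-test comparison of
#' sample vs depth-matched input. BH adjustment is applied across regions and
#' peaks must satisfy both `p < pval_thresh` and `q < min_fdr`. The reported
#' `height` is the maximum extended-read sample depth within the peak.
#'
#' @param sample_reads,input_reads `GRanges` of 1 bp stranded 5' anchors.
#' @param cfg a [peak_caller_config()].
#' @return A `GRanges` of peaks with metadata columns `sample_count`,
#'   `scaled_input_count`, `p`, `q`, `height`, sorted by position, classed as
#'   `peak_set` via its metadata; empty when no candidate survives.
#' @export
call_peaks <- function(sample_reads, input_reads,
                       cfg = peak_caller_config()) {
  stopifnot(inherits(cfg, "peak_caller_config"))
  stop_if(length(input_reads) == 0,
          "empty input sample: input scaling is undefined")
  smp <- extend_and_pileup(sample_reads, cfg$read_length)
  inp <- extend_and_pileup(input_reads, cfg$read_length)
  sl <- GenomeInfoDb::seqlengths(sample_reads)

  segs <- IRanges::slice(smp$coverage, lower = cfg$seed_depth,
                         rangesOnly = TRUE)
  regions <- GenomicRanges::GRanges(
    rep(names(segs), lengths(segs)),
    unlist(segs, use.names = FALSE), seqlengths = sl)
  if (length(regions) == 0) {
    return(empty_peak_set(sl))
  }
  regions <- GenomicRanges::reduce(regions,
                                   min.gapwidth = cfg$max_gap + 1L)

  k_s <- GenomicRanges::countOverlaps(regions, smp$extended,
                                      ignore.strand = TRUE)
  k_i <- GenomicRanges::countOverlaps(regions, inp$extended,
                                      ignore.strand = TRUE)
  r <- length(sample_reads) / length(input_reads)
  k_i_scaled <- round(k_i * r)
  n_trials <- k_s + k_i_scaled
  # upper tail at k_s inclusive
  p <- pbinom(k_s - 1L, n_trials, 0.5, lower.tail = FALSE)
  q <- bh_adjust(p)
  height <- peak_heights(regions, smp$coverage)

  keep <- p < cfg$pval_thresh & q < cfg$min_fdr
  peaks <- regions[keep]
  S4Vectors::mcols(peaks) <- S4Vectors::DataFrame(
    sample_count = k_s[keep], scaled_input_count = k_i_scaled[keep],
    p = p[keep], q = q[keep], height = height[keep])
  names(peaks) <- if (length(peaks)) sprintf("peak%04d", seq_along(peaks))
                  else NULL
  peaks
}

empty_peak_set <- function(sl) {
  gr <- GenomicRanges::GRanges(seqlengths = sl)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    sample_count = integer(), scaled_input_count = numeric(),
    p = numeric(), q = numeric(), height = integer())
  gr
}

# max per-base depth within each region
peak_heights <- function(regions, coverage) {
  if (length(regions) == 0) return(integer())
  out <- integer(length(regions))
  chrom <- as.character(GenomeInfoDb::seqnames(regions))
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    v <- IRanges::Views(coverage[[ch]],
                        start = GenomicRanges::start(regions)[idx],
                        end = GenomicRanges::end(regions)[idx])
    out[idx] <- as.integer(IRanges::viewMaxs(v))
  }
  out
}

#' Pearson correlation between two coverage tracks over genome bins
#'
#' Sums per-base coverage within consecutive fixed-size bins and returns the
#' Pearson correlation of the two binned vectors.
#'
#' @param cov_a,cov_b `RleList` coverages over the same chromosomes.
#' @param bin_size bin width in bp.
#' @return A single correlation coefficient.
#' @export
sample_correlation <- function(cov_a, cov_b, bin_size = 1000L) {
  stop_if(!identical(sort(names(cov_a)), sort(names(cov_b))),
          "coverages must span the same chromosomes")
  binned <- function(cov) {
    unlist(lapply(names(cov), function(ch) {
      x <- cov[[ch]]
      n <- length(x)
      starts <- seq.int(1L, n, by = bin_size)
      ends <- pmin(starts + bin_size - 1L, n)
      IRanges::viewSums(IRanges::Views(x, start = starts, end = ends))
    }), use.names = FALSE)
  }
  a <- binned(cov_a); b <- binned(cov_b)
  stop_if(var(a) == 0 || var(b) == 0,
          "correlation undefined: zero variance in a binned coverage track")
  cor(a, b)
}

#' Retain only the strongest peaks by height
#'
#' Keeps peaks whose height (maximum extended-read depth) is at least
#' `min_height`; the threshold is inclusive and peak order is preserved.
#'
#' @param peaks a peak `GRanges` from [call_peaks()] (or with a `height`
#'   metadata column).
#' @param min_height inclusive height cutoff (default 40 reads).
#' @export
select_top_peaks <- function(peaks, min_height = 40L) {
  stop_if(is.null(S4Vectors::mcols(peaks)$height),
          "peaks must carry a `height` metadata column")
  peaks[S4Vectors::mcols(peaks)$height >= min_height]
}

#' Write / read peaks as BED6+ (name = peak id, score = height, extra
#' columns p and q)
#'
#' @param peaks a peak `GRanges`.
#' @param path file path.
#' @export
write_peaks_bed <- function(peaks, path) {
  df <- data.frame(
    chrom = as.character(GenomeInfoDb::seqnames(peaks)),
    start = GenomicRanges::start(peaks) - 1L,
    end = GenomicRanges::end(peaks),
    name = if (is.null(names(peaks))) sprintf("peak%04d", seq_along(peaks))
           else names(peaks),
    score = S4Vectors::mcols(peaks)$height,
    strand = ".",
    p = S4Vectors::mcols(peaks)$p,
    q = S4Vectors::mcols(peaks)$q)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_peaks_bed
#' @param seqlengths optional named chromosome lengths.
#' @export
read_peaks_bed <- function(path, seqlengths = NULL) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  stop_if(ncol(df) < 3L, "peak BED needs at least 3 columns")
  names(df)[seq_len(min(8L, ncol(df)))] <-
    c("chrom", "start", "end", "name", "score", "strand", "p", "q")[
      seq_len(min(8L, ncol(df)))]
  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$start + 1L, df$end))
  if (!is.null(seqlengths)) {
    GenomeInfoDb::seqlevels(gr) <- names(seqlengths)
    GenomeInfoDb::seqlengths(gr) <- seqlengths
  }
  mc <- S4Vectors::DataFrame(
    height = if ("score" %in% names(df)) df$score else NA_integer_)
  if ("p" %in% names(df)) mc$p <- df$p
  if ("q" %in% names(df)) mc$q <- df$q
  S4Vectors::mcols(gr) <- mc
  if ("name" %in% names(df)) names(gr) <- df$name
  gr
}
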