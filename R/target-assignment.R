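#' Promoter intervals of a gene's transcripts
#'
#' The promoter is the `upstream` bp immediately 5' of each transcript's
#' transcription start site (TSS), excluding the TSS base itself: for a +
#' strand transcript with TSS t (1-based), \[t - upstream, t - 1\]; for a -
#' strand transcript ending at t, \[t + 1, t + upstream\]; clipped at
#' chromosome bounds. One promoter per transcript TSS, deduplicated.
#'
#' @param annotation a `gene_annotation`.
#' @param upstream promoter extent in bp (default 500).
#' @return `GRanges` of promoter intervals with `gene_id` metadata.
#' @export
promoter_regions <- function(annotation, upstream = 500L) {
  assert_count(upstream, "upstream")
  ex <- annotation$exons
  stop_if(!all(ex$strand %in% c("+", "-")), "transcripts with unknown strand")
  tx <- do.call(rbind, lapply(split(ex, ex$transcript_id), function(d) {
    data.frame(gene_id = d$gene_id[1L], chrom = d$chrom[1L],
               start = min(d$start), end = max(d$end),
               strand = d$strand[1L], stringsAsFactors = FALSE)
  }))
  sl <- annotation$seqlengths
  plus <- tx$strand == "+"
  p_start <- ifelse(plus, pmax(1L, tx$start - upstream), tx$end + 1L)
  p_end <- ifelse(plus, tx$start - 1L,
                  pmin(unname(sl[tx$chrom]), tx$end + upstream))
  keep <- p_start <= p_end  # drop promoters fully clipped away
  gr <- GenomicRanges::GRanges(
    tx$chrom[keep], IRanges::IRanges(p_start[keep], p_end[keep]),
    strand = tx$strand[keep], gene_id = tx$gene_id[keep], seqlengths = sl)
  unique(gr)
}

#' Intron intervals of every transcript
#'
#' Introns are the gaps between consecutive exons of a transcript
#' (single-exon transcripts contribute none).
#'
#' @param annotation a `gene_annotation`.
#' @return `GRanges` of introns with `gene_id` metadata.
#' @export
intron_regions <- function(annotation) {
  ex <- annotation$exons
  rows <- lapply(split(ex, ex$transcript_id), function(d) {
    d <- d[order(d$start), ]
    if (nrow(d) < 2L) return(NULL)
    data.frame(gene_id = d$gene_id[1L], chrom = d$chrom[1L],
               start = d$end[-nrow(d)] + 1L, end = d$start[-1L] - 1L,
               strand = d$strand[1L], stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (is.null(df) || !nrow(df)) {
    return(GenomicRanges::GRanges(seqlengths = annotation$seqlengths,
                                  gene_id = character()))
  }
  GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end),
                         strand = df$strand, gene_id = df$gene_id,
                         seqlengths = annotation$seqlengths)
}

#' Flag genes associated with peaks per ChIP condition
#'
#' A gene is flagged for a condition when at least one peak of that
#' condition overlaps (by >= 1 bp by default, or by peak midpoint with
#' `mode = "midpoint"`) any promoter or intron interval of any of its
#' transcripts. One peak may support several genes.
#'
#' @param peak_sets named list of peak `GRanges` (e.g. `ab`, `tumour`).
#' @param annotation a `gene_annotation`.
#' @param upstream promoter extent in bp (default 500).
#' @param mode `"any"` (>= 1 bp overlap) or `"midpoint"` (peak midpoint must
#'   fall inside the interval).
#' @return Data frame: gene_id, then per condition `has_peak_<cond>`
#'   (logical) and `peaks_<cond>` (comma-separated supporting peak names).
#' @export
assign_targets <- function(peak_sets, annotation, upstream = 500L,
                           mode = c("any", "midpoint")) {
  mode <- match.arg(mode)
  stopifnot(is.list(peak_sets), !is.null(names(peak_sets)))
  regions <- c(promoter_regions(annotation, upstream),
               intron_regions(annotation))
  out <- data.frame(gene_id = annotation$genes$gene_id,
                    stringsAsFactors = FALSE)
  for (cond in names(peak_sets)) {
    peaks <- peak_sets[[cond]]
    known <- as.character(GenomeInfoDb::seqnames(peaks)) %in%
      names(annotation$seqlengths)
    if (any(!known)) {
      warning(sum(!known), " peak(s) on unknown chromosomes skipped in `",
              cond, "`", call. = FALSE)
      peaks <- peaks[known]
    }
    query <- if (mode == "midpoint") {
      GenomicRanges::GRanges(
        GenomeInfoDb::seqnames(peaks),
        IRanges::IRanges(floor((GenomicRanges::start(peaks) +
                                  GenomicRanges::end(peaks)) / 2), width = 1L))
    } else {
      peaks
    }
    hits <- GenomicRanges::findOverlaps(query, regions, ignore.strand = TRUE)
    peak_names <- if (is.null(names(peaks))) {
      sprintf("peak%04d", seq_along(peaks))
    } else {
      names(peaks)
    }
    gene_of_hit <- S4Vectors::mcols(regions)$gene_id[S4Vectors::subjectHits(hits)]
    peak_of_hit <- peak_names[S4Vectors::queryHits(hits)]
    support <- tapply(peak_of_hit, gene_of_hit,
                      function(x) paste(sort(unique(x)), collapse = ","))
    has <- out$gene_id %in% names(support)
    out[[paste0("has_peak_", cond)]] <- has
    out[[paste0("peaks_", cond)]] <-
      ifelse(has, unname(support[out$gene_id]), "")
  }
  out
}
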