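#' Position weight matrix
#'
#' A base-count (or probability) matrix over A/C/G/T, one column per motif
#' position, with a pseudocount and background base frequencies used for
#' log-odds scoring.
#'
#' @param matrix_id identifier (used for deterministic rank tie-breaking).
#' @param counts 4 x width numeric matrix, rows named A, C, G, T.
#' @param pseudocount added to every cell before normalisation (default 0.5).
#' @param background named background frequencies (default uniform 0.25).
#' @return An object of class `pwm`.
#' @export
pwm <- function(matrix_id, counts, pseudocount = 0.5,
                background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  counts <- as.matrix(counts)
  stop_if(nrow(counts) != 4L || is.null(rownames(counts)) ||
            !setequal(rownames(counts), c("A", "C", "G", "T")),
          "`counts` must be a 4 x width matrix with rows A, C, G, T")
  stop_if(ncol(counts) < 4L, "PWM width must be >= 4")
  stop_if(any(counts < 0), "counts must be non-negative")
  stop_if(pseudocount < 0, "pseudocount must be >= 0")
  background <- background[c("A", "C", "G", "T")]
  stop_if(any(is.na(background)) || any(background <= 0) ||
            abs(sum(background) - 1) > 1e-8,
          "`background` must be positive A/C/G/T frequencies summing to 1")
  structure(list(matrix_id = as.character(matrix_id),
                 counts = counts[c("A", "C", "G", "T"), , drop = FALSE],
                 pseudocount = pseudocount, background = background),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("pwm %s: width %d, consensus %s\n", x$matrix_id,
              ncol(x$counts), pwm_consensus(x)))
  invisible(x)
}

# highest-count base per column (ties broken alphabetically)
pwm_consensus <- function(pwm) {
  paste(rownames(pwm$counts)[apply(pwm$counts, 2L, which.max)],
        collapse = "")
}

#' Log-odds score matrix of a PWM
#'
#' `score(b, j) = log2(p_bj / background_b)` with
#' `p_bj = (count_bj + pseudocount) / (colsum_j + 4 * pseudocount)`.
#'
#' @param x a [pwm()].
#' @return 4 x width numeric matrix of log2 odds.
#' @export
pwm_logodds <- function(x) {
  stopifnot(inherits(x, "pwm"))
  probs <- sweep(x$counts + x$pseudocount, 2L,
                 colSums(x$counts) + 4 * x$pseudocount, "/")
  log2(sweep(probs, 1L, x$background, "/"))
}

#' Read JASPAR-style count matrices
#'
#' Parses the plain-text JASPAR count-matrix format: a `>` header line with
#' the matrix id, then four lines `A [ 1 2 3 ... ]` (brackets optional) for
#' A, C, G, T. Several matrices per file are allowed.
#'
#' @param path file path.
#' @inheritParams pwm
#' @return A named list of [pwm()] objects.
#' @export
read_jaspar <- function(path, pseudocount = 0.5,
                        background = c(A = 0.25, C = 0.25, G = 0.25,
                                       T = 0.25)) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  stop_if(!length(starts), "no `>` headers found in ", path)
  out <- list()
  for (i in seq_along(starts)) {
    hdr <- sub("^>\\s*", "", lines[starts[i]])
    id <- strsplit(hdr, "\\s+")[[1L]][1L]
    block <- lines[(starts[i] + 1L):(starts[i] + 4L)]
    rows <- lapply(block, function(l) {
      l <- gsub("[][]", " ", l)
      parts <- strsplit(trimws(l), "\\s+")[[1L]]
      list(base = toupper(parts[1L]), counts = as.numeric(parts[-1L]))
    })
    bases <- vapply(rows, `[[`, "", "base")
    stop_if(!setequal(bases, c("A", "C", "G", "T")),
            "matrix ", id, " does not have A/C/G/T rows")
    m <- do.call(rbind, lapply(rows, `[[`, "counts"))
    rownames(m) <- bases
    out[[id]] <- pwm(id, m, pseudocount = pseudocount,
                     background = background)
  }
  out
}

# encode a sequence as row indices into the log-odds matrix (NA for N etc.)
encode_seq <- function(seq_chr) {
  match(strsplit(toupper(seq_chr), "")[[1L]], c("A", "C", "G", "T"))
}

scan_one_strand <- function(idx, lo, min_score) {
  w <- ncol(lo)
  n <- length(idx)
  if (n < w) return(data.frame(position = integer(), score = numeric()))
  n_win <- n - w + 1L
  scores <- numeric(n_win)
  valid <- rep(TRUE, n_win)
  for (j in seq_len(w)) {
    b <- idx[j:(j + n_win - 1L)]
    bad <- is.na(b)
    valid <- valid & !bad
    b[bad] <- 1L
    scores <- scores + lo[cbind(b, j)]
  }
  keep <- valid & scores >= min_score
  data.frame(position = which(keep), score = scores[keep])
}

#' Scan sequences with a PWM on both strands
#'
#' A window is a hit when its log-odds score reaches `threshold_frac` times
#' the maximum achievable score of the matrix. Both strands are scanned (the
#' reverse strand via the reverse complement); windows containing N are
#' skipped. Reported positions are 1-based starts of the window on the
#' forward sequence for both strands.
#'
#' @param seqs a `Biostrings::DNAStringSet` (or named character vector).
#' @param x a [pwm()].
#' @param threshold_frac fraction of the maximum achievable log-odds score
#'   (default 0.8).
#' @return Data frame: seq_id, position, strand, score.
#' @export
scan_sequences <- function(seqs, x, threshold_frac = 0.8) {
  stopifnot(inherits(x, "pwm"))
  assert_fraction(threshold_frac, "threshold_frac")
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  lo <- pwm_logodds(x)
  w <- ncol(lo)
  max_score <- sum(apply(lo, 2L, max))
  min_score <- threshold_frac * max_score
  ids <- if (is.null(names(seqs))) as.character(seq_along(seqs))
         else names(seqs)
  fwd <- as.character(seqs)
  rev <- as.character(Biostrings::reverseComplement(seqs))
  rows <- lapply(seq_along(seqs), function(i) {
    L <- nchar(fwd[i])
    f <- scan_one_strand(encode_seq(fwd[i]), lo, min_score)
    r <- scan_one_strand(encode_seq(rev[i]), lo, min_score)
    res <- rbind(
      if (nrow(f)) data.frame(seq_id = ids[i], position = f$position,
                              strand = "+", score = f$score,
                              stringsAsFactors = FALSE),
      if (nrow(r)) data.frame(seq_id = ids[i],
                              position = L - (r$position + w - 1L) + 1L,
                              strand = "-", score = r$score,
                              stringsAsFactors = FALSE))
    res
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(seq_id = character(), position = integer(),
                      strand = character(), score = numeric(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Rank a PWM collection by normalised hit density in peaks vs genome
#'
#' For every matrix the hit count in the peak-set sequences and in the
#' genome-background sequences is converted to a normalised density
#' `(hits + eps) / total_length` (eps = 0.5 pseudo-hit), matrices are ranked
#' by density within each set (densest = rank 1, ties broken by matrix id),
#' and the rank shift `rank_genome - rank_set` and the log2 density fold
#' change are reported.
#'
#' @param pwms named list of [pwm()] objects.
#' @param peak_seqs,genome_seqs `DNAStringSet`s of the peak-set and
#'   genome-background sequences.
#' @param threshold_frac scan threshold, identical for both sets.
#' @param eps pseudo-hit added to each count (default 0.5).
#' @return Data frame of class `matrix_ranking`: matrix_id, hits_set,
#'   hits_genome, set_length, genome_length, norm_density_set,
#'   norm_density_genome, fold_change, rank_set, rank_genome, rank_shift.
#' @export
rank_matrices <- function(pwms, peak_seqs, genome_seqs,
                          threshold_frac = 0.8, eps = 0.5) {
  stopifnot(is.list(pwms), length(pwms) > 0)
  set_len <- sum(nchar(as.character(peak_seqs)))
  gen_len <- sum(nchar(as.character(genome_seqs)))
  stop_if(set_len == 0 || gen_len == 0,
          "zero total sequence length; nothing to normalise by")
  ids <- vapply(pwms, `[[`, "", "matrix_id")
  hits_set <- vapply(pwms, function(m)
    nrow(scan_sequences(peak_seqs, m, threshold_frac)), 1L)
  hits_gen <- vapply(pwms, function(m)
    nrow(scan_sequences(genome_seqs, m, threshold_frac)), 1L)
  d_set <- (hits_set + eps) / set_len
  d_gen <- (hits_gen + eps) / gen_len
  rank_by <- function(d) {
    ord <- order(-d, ids)
    rk <- integer(length(d))
    rk[ord] <- seq_along(d)
    rk
  }
  out <- data.frame(
    matrix_id = ids, hits_set = hits_set, hits_genome = hits_gen,
    set_length = set_len, genome_length = gen_len,
    norm_density_set = d_set, norm_density_genome = d_gen,
    fold_change = log2(d_set / d_gen),
    rank_set = rank_by(d_set), rank_genome = rank_by(d_gen),
    stringsAsFactors = FALSE)
  out$rank_shift <- out$rank_genome - out$rank_set
  rownames(out) <- NULL
  class(out) <- c("matrix_ranking", "data.frame")
  out
}

#' Select overrepresented matrices by rank shift and fold change
#'
#' A matrix is selected when its genome-to-peak-set rank improvement is at
#' least `min_shift` positions and its normalised fold change is positive —
#' in every supplied ranking (one per ChIP experiment) when more than one is
#' given.
#'
#' @param rankings a `matrix_ranking` data frame, or a list of them (one per
#'   experiment).
#' @param min_shift minimum rank improvement (default 200, calibrated to an
#'   827-matrix collection; scale to the collection in use).
#' @return Character vector of selected matrix ids (sorted by the first
#'   ranking's rank shift, decreasing).
#' @export
select_overrepresented <- function(rankings, min_shift = 200L) {
  if (is.data.frame(rankings)) rankings <- list(rankings)
  n_mat <- nrow(rankings[[1L]])
  if (min_shift >= n_mat) {
    warning("`min_shift` >= number of matrices; empty selection",
            call. = FALSE)
    return(character())
  }
  sel <- Reduce(intersect, lapply(rankings, function(r) {
    r$matrix_id[r$rank_shift >= min_shift & r$fold_change > 0]
  }))
  first <- rankings[[1L]]
  sel[order(-first$rank_shift[match(sel, first$matrix_id)])]
}

#' Column-shuffled decoy PWMs
#'
#' Generates decoy matrices by permuting the column order of a source PWM;
#' used as a null collection for rank-shift analyses. Permutations that
#' reproduce the source matrix (possible when columns repeat) are redrawn, so
#' every decoy differs from the source.
#'
#' @param x a [pwm()].
#' @param n number of decoys.
#' @param seed RNG seed.
#' @return Named list of `pwm` objects (`<id>_shuf01`, ...).
#' @export
shuffle_pwm_columns <- function(x, n, seed = 1L) {
  stopifnot(inherits(x, "pwm"))
  w <- ncol(x$counts)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  out <- list()
  for (i in seq_len(n)) {
    repeat {
      perm <- sample(w)
      if (!identical(x$counts[, perm, drop = FALSE], x$counts)) break
    }
    id <- sprintf("%s_shuf%02d", x$matrix_id, i)
    out[[id]] <- pwm(id, x$counts[, perm, drop = FALSE],
                     pseudocount = x$pseudocount, background = x$background)
  }
  out
}
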