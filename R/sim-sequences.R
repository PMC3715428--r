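#' Generate peak-like sequences with planted motif instances
#'
#' Draws `n_seqs` sequences of `seq_length` bp from a uniform 25% base
#' composition and plants one exact-consensus instance of `pwm` (on the
#' forward strand, at a uniform position) in exactly
#' `round(motif_plant_rate * n_seqs)` of them.
#'
#' @param cfg a [sim_config()].
#' @param pwm a [pwm()] object whose consensus is planted.
#' @return A list with `sequences` (a `Biostrings::DNAStringSet` named
#'   `seq0001`...) and `planted` (data frame seq_id, position (1-based),
#'   strand).
#' @export
generate_sequences <- function(cfg, pwm) {
  stopifnot(inherits(cfg, "sim_config"), inherits(pwm, "pwm"))
  w <- ncol(pwm$counts)
  stop_if(cfg$seq_length < w, "seq_length shorter than the motif width")
  cons <- pwm_consensus(pwm)
  with_stream(cfg, 7L, {
    bases <- c("A", "C", "G", "T")
    seqs <- vapply(seq_len(cfg$n_seqs), function(i) {
      paste(sample(bases, cfg$seq_length, replace = TRUE), collapse = "")
    }, "")
    n_plant <- round(cfg$motif_plant_rate * cfg$n_seqs)
    planted_idx <- if (n_plant > 0) sort(sample(cfg$n_seqs, n_plant))
                   else integer()
    pos <- integer(0)
    if (n_plant > 0) {
      pos <- sample.int(cfg$seq_length - w + 1L, n_plant, replace = TRUE)
      for (k in seq_along(planted_idx)) {
        i <- planted_idx[k]
        substr(seqs[i], pos[k], pos[k] + w - 1L) <- cons
      }
    }
    ids <- sprintf("seq%04d", seq_len(cfg$n_seqs))
    dss <- Biostrings::DNAStringSet(seqs)
    names(dss) <- ids
    list(sequences = dss,
         planted = data.frame(seq_id = ids[planted_idx], position = pos,
                              strand = rep("+", n_plant),
                              stringsAsFactors = FALSE))
  })
}
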