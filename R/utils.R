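#' @importFrom methods is
#' @importFrom stats pt rnorm runif sd var setNames p.adjust pbinom phyper cor
#' @importFrom utils write.table read.delim
NULL

# internal assertion helpers ------------------------------------------------

stop_if <- function(cond, ..., call. = FALSE) {
  if (cond) stop(..., call. = call.)
}

assert_fraction <- function(x, name) {
  stop_if(!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1,
          sprintf("`%s` must be a single number in [0, 1]", name))
}

assert_count <- function(x, name, positive = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) && x == round(x) &&
    (if (positive) x > 0 else x >= 0)
  stop_if(!ok, sprintf("`%s` must be a %s integer", name,
                       if (positive) "positive" else "non-negative"))
}

assert_positive <- function(x, name) {
  stop_if(!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0,
          sprintf("`%s` must be a single positive number", name))
}

#' Condition (genotype) labels used across the pipeline
#'
#' The design has three genotypes: a wild-type control, a transcription-factor
#' overexpression condition (`ab`), and the tumourigenic condition combining
#' overexpression with loss of the polarity gene scribble (`scrib_ab`).
#' Expression contrasts are each non-control genotype against control; the
#' contrast against `scrib_ab` is referred to throughout as the tumour
#' contrast. The two ChIP conditions are named `ab` and `tumour`.
#' @keywords internal
#' @name conditions
NULL

GENOTYPES <- c("control", "ab", "scrib_ab")
CONTRASTS <- c("ab", "tumour")
contrast_genotype <- function(contrast) {
  switch(contrast, ab = "ab", tumour = "scrib_ab",
         stop("unknown contrast: ", contrast))
}
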