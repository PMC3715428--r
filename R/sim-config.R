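#' Simulation configuration for the synthetic study generator
#'
#' Bundles every knob of the synthetic-data generator into a validated
#' configuration object. The defaults emulate the structure of the study this
#' pipeline is designed for: a triplicate three-genotype expression-array
#' design, two ChIP conditions plus an input control, genes that may be
#' interrogated by more than one probe set (a small fraction of which carry
#' probe sets with conflicting directions), and ~500 bp chromatin fragments.
#'
#' @param seed integer seed; the same configuration (including seed) yields
#'   byte-identical outputs.
#' @param n_chroms number of chromosomes in the toy genome.
#' @param chrom_length chromosome length in bp (all chromosomes equal).
#' @param n_genes number of genes to place (non-overlapping).
#' @param frac_multi_probe fraction of genes interrogated by two probe sets.
#' @param n_replicates biological replicates per genotype (default 3,
#'   matching a triplicate array design).
#' @param de_fractions named list with elements `ab` and `tumour`, each a
#'   length-2 numeric `c(up =, down =)` of the fractions of genes planted as
#'   up-/down-regulated in that contrast. Ignored when `class_plan` is given.
#' @param de_shared_frac fraction of the smaller contrast's deregulated genes
#'   drawn from the other contrast's deregulated set, so that the two
#'   contrasts share deregulated genes the way replicated biology does.
#' @param effect_size planted expression shift in log2 units.
#' @param noise_sd Gaussian noise s.d. on log2 intensities.
#' @param frac_conflicting fraction of multi-probe deregulated genes whose
#'   second probe set is planted with the opposite direction, emulating
#'   probe sets that report conflicting expression for one gene.
#' @param planted_target_fractions named numeric `c(ab =, tumour =)`:
#'   per-condition fraction of genes given a planted promoter or intron peak.
#'   Ignored when `class_plan` is given.
#' @param target_shared_frac sharing between the two conditions' planted
#'   target sets, analogous to `de_shared_frac`.
#' @param class_plan optional named integer vector with names among
#'   `"1"`..`"6"`: plant exactly these many genes per target class, deriving
#'   the deregulation and peak truth tables from the class definitions.
#'   Remaining genes are left unplanted. Overrides `de_fractions` and
#'   `planted_target_fractions`.
#' @param background_read_rate background read density, reads per bp per
#'   sample.
#' @param reads_per_peak reads planted at each target locus.
#' @param read_length sequenced read length in bp.
#' @param fragment_length sonication fragment scale in bp (default 500); used
#'   as the minimum spacing kept around planted loci.
#' @param motif_plant_rate fraction of generated peak-like sequences that
#'   carry one exact-consensus motif instance.
#' @param n_seqs number of peak-like sequences to generate.
#' @param seq_length length of each generated sequence in bp.
#' @param ct_noise_sd Gaussian noise s.d. (cycles) on generated Ct values.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(seed = 1, n_genes = 50)
#' cfg$n_replicates
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 2L,
                       chrom_length = 500000L,
                       n_genes = 200L,
                       frac_multi_probe = 0.05,
                       n_replicates = 3L,
                       de_fractions = list(ab = c(up = 0.10, down = 0.06),
                                           tumour = c(up = 0.12, down = 0.08)),
                       de_shared_frac = 0.55,
                       effect_size = 2.0,
                       noise_sd = 0.25,
                       frac_conflicting = 0.3,
                       planted_target_fractions = c(ab = 0.15, tumour = 0.16),
                       target_shared_frac = 0.6,
                       class_plan = NULL,
                       background_read_rate = 0.001,
                       reads_per_peak = 60L,
                       read_length = 40L,
                       fragment_length = 500L,
                       motif_plant_rate = 0.8,
                       n_seqs = 200L,
                       seq_length = 100L,
                       ct_noise_sd = 0) {
  assert_count(seed, "seed", positive = FALSE)
  assert_count(n_chroms, "n_chroms")
  assert_count(chrom_length, "chrom_length")
  assert_count(n_genes, "n_genes")
  assert_count(n_replicates, "n_replicates")
  assert_count(reads_per_peak, "reads_per_peak")
  assert_count(read_length, "read_length")
  assert_count(fragment_length, "fragment_length")
  assert_count(n_seqs, "n_seqs")
  assert_count(seq_length, "seq_length")
  assert_fraction(frac_multi_probe, "frac_multi_probe")
  assert_fraction(de_shared_frac, "de_shared_frac")
  assert_fraction(frac_conflicting, "frac_conflicting")
  assert_fraction(target_shared_frac, "target_shared_frac")
  assert_fraction(motif_plant_rate, "motif_plant_rate")
  stop_if(!is.numeric(background_read_rate) || background_read_rate < 0,
          "`background_read_rate` must be >= 0")
  stop_if(!is.numeric(effect_size) || effect_size < 0,
          "`effect_size` must be >= 0")
  stop_if(!is.numeric(noise_sd) || noise_sd < 0, "`noise_sd` must be >= 0")
  stop_if(!is.numeric(ct_noise_sd) || ct_noise_sd < 0,
          "`ct_noise_sd` must be >= 0")
  stop_if(!is.list(de_fractions) ||
            !all(c("ab", "tumour") %in% names(de_fractions)),
          "`de_fractions` must be a list with elements `ab` and `tumour`")
  for (ct in CONTRASTS) {
    fr <- de_fractions[[ct]]
    stop_if(!is.numeric(fr) || length(fr) != 2L || any(fr < 0) || sum(fr) > 1,
            "each `de_fractions` element must be c(up =, down =) summing to <= 1")
  }
  stop_if(!is.numeric(planted_target_fractions) ||
            !all(c("ab", "tumour") %in% names(planted_target_fractions)) ||
            any(planted_target_fractions < 0 | planted_target_fractions > 1),
          "`planted_target_fractions` must be c(ab =, tumour =) in [0, 1]")
  if (!is.null(class_plan)) {
    stop_if(!is.numeric(class_plan) || is.null(names(class_plan)) ||
              !all(names(class_plan) %in% as.character(1:6)) ||
              any(class_plan < 0) || any(class_plan != round(class_plan)),
            "`class_plan` must be a named non-negative integer vector with names in 1..6")
    stop_if(sum(class_plan) > n_genes,
            "`class_plan` plants more genes than `n_genes`")
  }
  cfg <- list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
              chrom_length = as.integer(chrom_length),
              n_genes = as.integer(n_genes),
              frac_multi_probe = frac_multi_probe,
              n_replicates = as.integer(n_replicates),
              de_fractions = de_fractions, de_shared_frac = de_shared_frac,
              effect_size = effect_size, noise_sd = noise_sd,
              frac_conflicting = frac_conflicting,
              planted_target_fractions = planted_target_fractions,
              target_shared_frac = target_shared_frac,
              class_plan = class_plan,
              background_read_rate = background_read_rate,
              reads_per_peak = as.integer(reads_per_peak),
              read_length = as.integer(read_length),
              fragment_length = as.integer(fragment_length),
              motif_plant_rate = motif_plant_rate,
              n_seqs = as.integer(n_seqs),
              seq_length = as.integer(seq_length),
              ct_noise_sd = ct_noise_sd)
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic study configuration\n")
  cat(sprintf("  genome: %d chromosome(s) x %d bp, %d genes\n",
              x$n_chroms, x$chrom_length, x$n_genes))
  cat(sprintf("  arrays: 3 genotypes x %d replicates, effect %.2g log2, noise sd %.2g\n",
              x$n_replicates, x$effect_size, x$noise_sd))
  if (!is.null(x$class_plan)) {
    cat("  planted classes:",
        paste(sprintf("C%s=%d", names(x$class_plan), x$class_plan),
              collapse = " "), "\n")
  }
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

# Chromosome names and lengths of the toy genome.
sim_seqlengths <- function(cfg) {
  setNames(rep(cfg$chrom_length, cfg$n_chroms),
           paste0("chr", seq_len(cfg$n_chroms)))
}
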