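test_that("log-odds scoring follows the pseudocount-normalised log2 ratio", {
  uni <- pwm("uni", matrix(25, 4, 4,
                           dimnames = list(c("A", "C", "G", "T"), NULL)))
  expect_equal(pwm_logodds(uni), matrix(0, 4, 4,
                                        dimnames = list(c("A", "C", "G", "T"),
                                                        NULL)))
  # hand-computed 4 x 4 example (width >= 4): counts 7/1/1/1, pseudocount 0.5
  m <- matrix(1, 4, 4, dimnames = list(c("A", "C", "G", "T"), NULL))
  m["A", 1] <- 7
  lo <- pwm_logodds(pwm("toy", m))
  expect_equal(unname(lo["A", 1]), log2((7.5 / 12) / 0.25))
  expect_equal(unname(lo["C", 1]), log2((1.5 / 12) / 0.25))
  expect_equal(unname(lo["C", 2]), log2((1.5 / 6) / 0.25))
  # consensus cell positive, others negative
  expect_gt(lo["A", 1], 0)
  expect_lt(lo["T", 1], 0)
  # zero background frequency is rejected
  expect_error(pwm("bad", m, background = c(A = 0, C = 0.5, G = 0.25,
                                            T = 0.25)),
               "background")
})

test_that("scanning finds the unique consensus window on either strand", {
  x <- strong_pwm()
  hits <- scan_sequences(c(s1 = "CCTATACC"), x)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$position, 3)  # 1-based start
  expect_equal(hits$strand, "+")
  # reverse complement sequence: one - strand hit, same count
  rc <- as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet("CCTATACC")))
  hits_rc <- scan_sequences(setNames(rc, "s1rc"), x)
  expect_equal(nrow(hits_rc), 1)
  expect_equal(hits_rc$strand, "-")
  # all-N sequences and sequences shorter than the motif yield nothing
  expect_equal(nrow(scan_sequences(c(n = "NNNNNNNN"), x)), 0)
  expect_equal(nrow(scan_sequences(c(short = "TAT"), x)), 0)
})

test_that("scan hits equal a brute-force window enumeration on random DNA", {
  set.seed(91)
  x <- strong_pwm()
  for (i in 1:8) {
    s <- paste(sample(c("A", "C", "G", "T", "N"), sample(50:400, 1),
                      replace = TRUE, prob = c(.24, .24, .24, .24, .04)),
               collapse = "")
    got <- nrow(scan_sequences(setNames(s, "r"), x, threshold_frac = 0.7))
    expect_equal(got, scan_oracle(s, x, threshold_frac = 0.7))
  }
})

test_that("reverse-complementing every sequence preserves total hit counts", {
  set.seed(14)
  seqs <- Biostrings::DNAStringSet(vapply(1:20, function(i) {
    paste(sample(c("A", "C", "G", "T"), 150, replace = TRUE), collapse = "")
  }, ""))
  names(seqs) <- paste0("s", 1:20)
  x <- strong_pwm()
  n_fwd <- nrow(scan_sequences(seqs, x, 0.7))
  n_rc <- nrow(scan_sequences(Biostrings::reverseComplement(seqs), x, 0.7))
  expect_equal(n_fwd, n_rc)
})

test_that("matrix ranking normalises by length and ranks densities", {
  # arithmetic example: 10 hits / 1000 bp vs 1000 hits / 1,000,000 bp
  d_set <- (10 + 0.5) / 1000
  d_gen <- (1000 + 0.5) / 1e6
  expect_equal(log2(d_set / d_gen), log2(10.4947526), tolerance = 1e-6)
  # on real scans: build one planted and one irrelevant matrix
  cfg <- sim_config(seed = 6, motif_plant_rate = 1, n_seqs = 40,
                    seq_length = 80)
  x <- strong_pwm()
  peak_seqs <- generate_sequences(cfg, x)$sequences
  cfg_bg <- sim_config(seed = 60, motif_plant_rate = 0, n_seqs = 40,
                       seq_length = 400)
  genome_seqs <- generate_sequences(cfg_bg, x)$sequences
  pwms <- c(list(TATAC = x), shuffle_pwm_columns(x, 3, seed = 2))
  rk <- rank_matrices(pwms, peak_seqs, genome_seqs)
  expect_setequal(rk$rank_set, seq_len(nrow(rk)))
  expect_setequal(rk$rank_genome, seq_len(nrow(rk)))
  expect_equal(rk$rank_shift, rk$rank_genome - rk$rank_set)
  expect_equal(rk$rank_set[rk$matrix_id == "TATAC"], 1L)
  # identical densities in both sets give fold change and shift of zero
  rk_same <- rank_matrices(pwms, peak_seqs, peak_seqs)
  expect_equal(rk_same$fold_change, rep(0, nrow(rk_same)))
  expect_equal(rk_same$rank_shift, rep(0L, nrow(rk_same)))
  # deterministic tie-break by matrix id
  expect_identical(rank_matrices(pwms, peak_seqs, genome_seqs), rk)
})

test_that("overrepresentation selection needs shift >= 200 and positive fold change", {
  mk <- function(id, shift, fc, n = 400) {
    data.frame(matrix_id = id, fold_change = fc, rank_shift = shift)
  }
  rk <- rbind(mk("a", 250, 1.2), mk("b", 150, 2.0), mk("c", 400, -0.1))
  rk$rank_set <- seq_len(nrow(rk))  # structure fields used downstream
  attr(rk, "row.names") <- seq_len(nrow(rk))
  # single experiment
  big <- do.call(rbind, replicate(100, rk, simplify = FALSE))
  big$matrix_id <- make.unique(big$matrix_id)
  sel <- select_overrepresented(big, min_shift = 200)
  expect_setequal(sel,
                  big$matrix_id[big$rank_shift >= 200 & big$fold_change > 0])
  expect_true(all(grepl("^a", sel)))   # shift 250, fc +1.2: selected
  expect_false(any(grepl("^b", sel)))  # shift 150, fc +2.0: not selected
  expect_false(any(grepl("^c", sel)))  # shift 400, fc -0.1: not selected
  # two experiments: criterion must hold in each
  rk2 <- rk
  rk2$rank_shift <- c(250, 250, 400)
  big2 <- do.call(rbind, replicate(100, rk2, simplify = FALSE))
  big2$matrix_id <- big$matrix_id
  sel2 <- select_overrepresented(list(big, big2), min_shift = 200)
  expect_identical(sel2, sel)
  # min_shift beyond the collection size warns and selects nothing
  expect_warning(none <- select_overrepresented(rk, min_shift = 200),
                 "min_shift")
  expect_length(none, 0)
})

test_that("JASPAR count matrices round-trip through the reader", {
  path <- withr::local_tempfile(fileext = ".jaspar")
  writeLines(c(
    ">MA0001.1 TOY1",
    "A [ 10  0  0  5 ]",
    "C [  0 10  0  5 ]",
    "G [  0  0 10  0 ]",
    "T [  0  0  0  0 ]",
    ">MA0002.1 TOY2",
    "A 1 2 3 4",
    "C 4 3 2 1",
    "G 0 0 0 0",
    "T 5 5 5 5"), path)
  pwms <- read_jaspar(path)
  expect_named(pwms, c("MA0001.1", "MA0002.1"))
  expect_equal(unname(pwms$MA0001.1$counts["A", ]), c(10, 0, 0, 5))
  expect_equal(unname(pwms$MA0002.1$counts["T", 2]), 5)
  expect_s3_class(pwms$MA0001.1, "pwm")
})
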