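test_that("build_pfm tallies base counts per column", {
  pfm <- build_pfm(c("AC", "AC"), pseudocount = 0)
  expect_equal(pfm$counts["A", 1], 2L, ignore_attr = TRUE)
  expect_equal(pfm$counts["C", 2], 2L, ignore_attr = TRUE)
  expect_equal(sum(pfm$counts[, 1]), 2L)

  # independent tally of the reference high-affinity training columns:
  # position 7 is C in all but one sequence (G), position 8 is G throughout
  seqs <- cre_reference_sequences("high")
  pfm31 <- build_pfm(seqs)
  col7 <- table(factor(substr(seqs, 7, 7), levels = c("A", "C", "G", "T")))
  expect_equal(unname(pfm31$counts[, 7]), as.integer(col7))
  expect_equal(pfm31$counts["C", 7], 30L, ignore_attr = TRUE)
  expect_equal(pfm31$counts["G", 7], 1L, ignore_attr = TRUE)
  expect_equal(pfm31$counts["G", 8], 31L, ignore_attr = TRUE)
})

test_that("pfm columns conserve the training-set size and normalize", {
  set.seed(101)
  for (n in c(1L, 5L, 40L)) {
    pfm <- build_pfm(random_dna(n, 14))
    expect_true(all(colSums(pfm$counts) == n))
    expect_true(all(abs(colSums(pfm$probabilities) - 1) < 1e-9))
  }
})

test_that("build_pfm rejects degenerate alignments with informative errors", {
  expect_error(build_pfm(character(0)), "empty")
  expect_error(build_pfm(c("ACGT", "ACG")), "ragged")
  expect_error(build_pfm(c(ok = "ACGT", bad = "ACUT")),
               "non-ACGT character 'U' in sequence 'bad' at position 3")
  expect_silent(pfm <- build_pfm(c("acgt", "ACGT")))  # lower-case accepted
  expect_equal(pfm$counts["A", 1], 2L, ignore_attr = TRUE)
})

test_that("log-odds follow log2((counts+pc)/(N+4pc)/background)", {
  wm <- tiny_wm()
  expect_equal(wm$log_odds["A", 1], 2, ignore_attr = TRUE)  # log2(1/0.25)
  expect_true(all(wm$log_odds[c("C", "G", "T"), 1] == -Inf))

  pfm <- build_pfm(c("AA", "AA", "CC", "CC"), pseudocount = 0)
  wm2 <- build_weight_matrix(pfm)
  expect_equal(wm2$log_odds["A", 1], 1, ignore_attr = TRUE)  # log2(0.5/0.25)
  expect_equal(wm2$log_odds["G", 1], -Inf, ignore_attr = TRUE)

  # pseudocount 1, N = 4: probabilities (counts+1)/8, re-tallied by hand
  wm3 <- build_weight_matrix(build_pfm(c("AA", "AA", "CC", "CC"),
                                       pseudocount = 1))
  brute <- (rbind(A = c(2, 2), C = c(2, 2), G = c(0, 0), T = c(0, 0)) + 1) / 8
  expect_equal(wm3$probabilities, brute, ignore_attr = TRUE)
  expect_equal(wm3$log_odds, log2(brute / 0.25), ignore_attr = TRUE)

  expect_error(build_weight_matrix(pfm, background = c(0.5, 0.5, 0, 0)),
               "positive")
  expect_error(build_weight_matrix(pfm, pseudocount = -1), "negative")
})

test_that("score_window sums per-position log-odds with guarded extremes", {
  wm <- tiny_wm()
  expect_equal(score_window(wm, "AC"), 4)
  expect_equal(score_window(wm, "AA"), -Inf)   # zero-probability column entry
  expect_true(is.na(score_window(wm, "AN")))   # unscorable sentinel
  expect_error(score_window(wm, "ACG"), "width")
})

test_that("per-column argmax equals exhaustive enumeration at small widths", {
  set.seed(7)
  for (w in c(3L, 5L, 7L)) {
    wm <- build_weight_matrix(build_pfm(random_dna(6, w)))
    all_windows <- do.call(paste0, expand.grid(
      rep(list(c("A", "C", "G", "T")), w), stringsAsFactors = FALSE))
    brute_scores <- vapply(all_windows, function(x) score_window(wm, x),
                           numeric(1L))
    best <- best_window(wm)
    expect_equal(best$score, max(brute_scores))
    expect_true(best$score >= max(brute_scores))  # never beaten
  }
})

test_that("consensus calling reproduces discriminating positions and rules", {
  expect_equal(consensus_call(build_pfm(c("AC", "AC"))), "AC")

  high <- consensus_call(build_pfm(cre_reference_sequences("high")))
  low <- consensus_call(build_pfm(cre_reference_sequences("low")))
  expect_equal(substr(high, 6, 6), "G")   # 22/31 >= 0.70
  expect_equal(substr(low, 6, 6), "R")    # G 19/38 + A 15/38 -> two-base code
  expect_equal(substr(high, 14, 14), "A")
  expect_equal(substr(low, 14, 14), "W")
  # highly conserved central CpG called as single bases in both groups
  expect_equal(substr(high, 7, 8), "CG")
  expect_equal(substr(low, 7, 8), "CG")

  # idempotent under duplication of the alignment (frequency scale invariance)
  seqs <- cre_reference_sequences("low")
  expect_equal(consensus_call(build_pfm(rep(seqs, 3))), low)

  # column below both thresholds gives N; ties break alphabetically
  expect_equal(consensus_call(build_pfm(c("AG", "CG", "GG", "TG"))), "NG")
  expect_equal(consensus_call(build_pfm(c("AA", "AA", "TT", "TT")),
                              theta_pair = 0.9), "WW")
  expect_error(consensus_call(build_pfm(c("AC")), theta_single = 0.5),
               "thresholds")
})

test_that("matrices round-trip exactly through JASPAR and log-odds writers", {
  pfm <- build_pfm(cre_reference_sequences("high"))
  f <- withr::local_tempfile()
  write_pfm_jaspar(pfm, f)
  expect_equal(read_pfm_jaspar(f)$counts, pfm$counts)

  wm <- build_weight_matrix(pfm)
  f2 <- withr::local_tempfile()
  write_weight_matrix(wm, f2)
  wm2 <- read_weight_matrix(f2)
  expect_identical(wm2$log_odds, wm$log_odds)
  expect_identical(wm2$background, wm$background)
})

test_that("alignment reading handles FASTA and line formats", {
  fa <- withr::local_tempfile(lines = c(">a", "ACGT", ">b", "GGTT"))
  aln <- read_motif_alignment(fa)
  expect_equal(unclass(aln), c(a = "ACGT", b = "GGTT"), ignore_attr = TRUE)
  txt <- withr::local_tempfile(lines = c("ACGT", "GGTT", ""))
  expect_equal(as.character(read_motif_alignment(txt)), c("ACGT", "GGTT"))
})

test_that("score distribution matches exhaustive enumeration at small width", {
  set.seed(21)
  wm <- build_weight_matrix(build_pfm(random_dna(5, 3)))
  all_windows <- do.call(paste0, expand.grid(
    rep(list(c("A", "C", "G", "T")), 3), stringsAsFactors = FALSE))
  scores <- vapply(all_windows, function(x) score_window(wm, x), numeric(1L))
  d <- score_distribution(wm, model = "background")
  expect_equal(sum(d$prob), 1, tolerance = 1e-12)
  # background is uniform: each window has mass 4^-3
  for (thr in stats::quantile(scores, c(0.25, 0.5, 0.9))) {
    expect_equal(sum(d$prob[d$score >= thr - 1e-9]),
                 mean(scores >= thr - 1e-9), tolerance = 1e-6)
  }
  # calibrated cutoff retains at least 1 - q of the motif model mass
  cut <- calibrate_cutoff(wm, q = 0.05, model = "motif")
  dm <- score_distribution(wm, model = "motif")
  expect_gte(sum(dm$prob[dm$score >= cut]), 0.95)
})
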