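rec <- function(gene = "g", fc, sig = c(TRUE, TRUE, TRUE)) {
  data.frame(gene_id = gene, fc_low = fc[1], fc_med = fc[2], fc_high = fc[3],
             sig_low = sig[1], sig_med = sig[2], sig_high = sig[3],
             stringsAsFactors = FALSE)
}

test_that("significance requires both the magnitude and the upstream flag", {
  expect_true(is_significant(-4.8, TRUE))        # strongly repressed at low
  expect_false(is_significant(-1.8, FALSE))      # at threshold but unflagged
  expect_false(is_significant(1.7999, TRUE))     # strict magnitude boundary
  expect_true(is_significant(1.8, TRUE))
  expect_error(is_significant(0, TRUE), "0")
  expect_error(is_significant(2, TRUE, threshold = 1), "exceed 1")
})

test_that("the decision tree reproduces the reference classifications", {
  expect_equal(classify_cre(rec(fc = c(-4.8, -18.7, -21.7)))$call,
               "high_affinity")                             # acoR
  expect_equal(classify_cre(rec(fc = c(1.6, 1.0, -2.7),
                                sig = c(FALSE, FALSE, TRUE)))$call,
               "low_affinity")                              # cydA
  expect_equal(classify_cre(rec(fc = c(3.0, 6.2, 2.7)))$call,
               "activating")                                # ilvB
  # no significant regulation at high induction: always unclassified
  expect_equal(classify_cre(rec(fc = c(-5, -5, -1.5)))$call, "unclassified")
  expect_equal(classify_cre(rec(fc = c(-5, -5, -2),
                                sig = c(TRUE, TRUE, FALSE)))$call,
               "unclassified")
  # conflicting directions warn and never classify silently
  expect_warning(out <- classify_cre(rec(fc = c(2.5, -3, -3))),
                 "conflicting")
  expect_equal(out$call, "unclassified")
  # partial activation falls to unclassified with a warning
  expect_warning(out2 <- classify_cre(rec(fc = c(1.2, 1.3, 2.5),
                                          sig = c(FALSE, FALSE, TRUE))),
                 "some induction levels")
  expect_equal(out2$call, "unclassified")
})

test_that("every record maps to exactly one call category", {
  set.seed(43)
  n <- 200
  records <- data.frame(
    gene_id = paste0("g", 1:n),
    fc_low = sample(c(-1, 1), n, TRUE) * stats::runif(n, 1, 8),
    fc_med = sample(c(-1, 1), n, TRUE) * stats::runif(n, 1, 8),
    fc_high = sample(c(-1, 1), n, TRUE) * stats::runif(n, 1, 8),
    sig_low = sample(c(TRUE, FALSE), n, TRUE),
    sig_med = sample(c(TRUE, FALSE), n, TRUE),
    sig_high = sample(c(TRUE, FALSE), n, TRUE))
  calls <- suppressWarnings(classify_cre(records))
  expect_equal(nrow(calls), n)
  expect_true(all(calls$call %in% c("high_affinity", "low_affinity",
                                    "activating", "unclassified")))
})

test_that("raising the threshold never reclassifies an unclassified gene", {
  # direction-coherent records: conflict resolution aside, shrinking the
  # significant set can only move genes toward unclassified
  set.seed(44)
  n <- 200
  sgn <- sample(c(-1, 1), n, TRUE)
  records <- data.frame(
    gene_id = paste0("g", 1:n),
    fc_low = sgn * stats::runif(n, 1, 8),
    fc_med = sgn * stats::runif(n, 1, 8),
    fc_high = sgn * stats::runif(n, 1, 8),
    sig_low = sample(c(TRUE, FALSE), n, TRUE),
    sig_med = sample(c(TRUE, FALSE), n, TRUE),
    sig_high = sample(c(TRUE, FALSE), n, TRUE))
  calls <- suppressWarnings(classify_cre(records))
  strict <- suppressWarnings(classify_cre(records, threshold = 3))
  was_unclassified <- calls$call == "unclassified"
  expect_true(all(strict$call[was_unclassified] == "unclassified"))
})

test_that("operon counts deduplicate multi-cre operons", {
  two_cre <- rbind(rec("op1-cre1", c(-2, -2, -2)), rec("op1-cre2", c(-2, -2, -2)))
  counts <- count_regulated_operons(two_cre,
                                    c("op1-cre1" = "op1", "op1-cre2" = "op1"))
  expect_equal(counts, c(low = 1L, medium = 1L, high = 1L))
  expect_equal(count_regulated_operons(two_cre[0, ]),
               c(low = 0L, medium = 0L, high = 0L))
  # duplicating a cre row within the same operon changes nothing
  ref <- cre_reference_expression()
  map <- cre_reference_operons()
  base_counts <- count_regulated_operons(ref, map)
  dup <- rbind(as.data.frame(ref), as.data.frame(ref)[1, ])
  expect_equal(count_regulated_operons(expression_records(dup), map),
               base_counts)
})

test_that("expression input validates columns and falls back without flags", {
  expect_error(expression_records(data.frame(gene_id = "g")), "fc_low")
  expect_error(expression_records(rec(fc = c(0, 2, 2))), "nonzero")
  expect_message(out <- expression_records(
    data.frame(gene_id = "g", fc_low = -2, fc_med = -2, fc_high = -2)),
    "magnitude criterion")
  expect_true(all(out$sig_low, out$sig_med, out$sig_high))

  f <- withr::local_tempfile(lines = c(
    "gene_id\tfc_low\tfc_med\tfc_high\tsig_low\tsig_med\tsig_high",
    "g1\t-4.8\t-18.7\t-21.7\tTRUE\tTRUE\tTRUE"))
  expect_equal(classify_cre(read_expression(f))$call, "high_affinity")
})

test_that("the report groups calls, flags exclusions and keeps no_data rows", {
  ctx <- data.frame(gene_id = c("gA", "gB", "gC"),
                    operon_id = c("gA", "gB", "gC"), contig = "chr",
                    strand = "+", start_codon = c(1000L, 2000L, 3000L),
                    tss = c(950L, 1950L, NA), stringsAsFactors = FALSE)
  class(ctx) <- c("gene_contexts", "data.frame")
  lit <- data.frame(gene_id = c("gA", "gB", "gC"),
                    sequence = strrep("A", 14), strand = "+",
                    g8_pos = c(960L, 1960L, 2960L))
  sites <- add_known_sites(lit, ctx)
  records <- expression_records(rbind(
    cbind(rec("gA", c(-2, -3, -4)), exclude_flag = FALSE),
    cbind(rec("gB", c(-1.2, -2.5, -2.5), sig = c(FALSE, TRUE, TRUE)),
          exclude_flag = TRUE)))
  calls <- classify_cre(records)
  expect_message(report <- tabulate_report(sites, calls, records), "no_data")
  expect_equal(as.character(report$call),
               c("high_affinity", "low_affinity", "no_data"))
  expect_equal(report$excluded, c(FALSE, TRUE, FALSE))

  f <- withr::local_tempfile()
  write_report(report, f)
  back <- utils::read.delim(f, colClasses = "character")
  expect_equal(back$dist_tss[back$gene_id == "gC"], "ND")
})
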