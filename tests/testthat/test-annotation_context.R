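make_contexts <- function(...) {
  ctx <- data.frame(...)
  class(ctx) <- c("gene_contexts", "data.frame")
  ctx
}

fwd_ctx <- function(start_codon = 1000L, tss = 950L) {
  make_contexts(gene_id = "geneX", operon_id = "opX", contig = "chr",
                strand = "+", start_codon = start_codon, tss = tss,
                stringsAsFactors = FALSE)
}

hit_at <- function(g8, strand = "+") {
  h <- data.frame(contig = "chr", start = g8 - 7L, end = g8 + 6L,
                  strand = strand, site = strrep("A", 14), score = 10,
                  g8_pos = g8, stringsAsFactors = FALSE)
  class(h) <- c("motif_hits", "data.frame")
  h
}

test_that("TSV annotation parses with ND TSS and singleton operons", {
  f <- withr::local_tempfile(lines = c(
    "gene_id\toperon_id\tstrand\tstart_codon\ttss",
    "geneX\topX\t+\t1000\t950",
    "geneY\t\t-\t5000\tND"))
  ctx <- load_annotation(f)
  expect_equal(ctx$tss, c(950L, NA_integer_))
  expect_equal(ctx$operon_id, c("opX", "geneY"))  # singleton default

  bad <- withr::local_tempfile(lines = c("gene_id\tstrand", "g\t+"))
  expect_error(load_annotation(bad), "start_codon")
  dup <- withr::local_tempfile(lines = c(
    "gene_id\tstrand\tstart_codon", "g\t+\t1", "g\t+\t2"))
  expect_error(load_annotation(dup), "duplicate gene_id")
})

test_that("GFF3 minus-strand genes anchor the start codon at the end", {
  f <- withr::local_tempfile(fileext = ".gff3", lines = c(
    "##gff-version 3",
    "chr\ttoy\tgene\t100\t400\t.\t+\t.\tID=gA;operon=op1",
    "chr\ttoy\tgene\t600\t900\t.\t-\t.\tID=gB",
    "chr\ttoy\tgene\t950\t1200\t.\t+\t.\tID=gC;operon=op1"))
  ctx <- load_annotation(f)
  # op1 keeps its most upstream gene (gA); gB is a singleton
  expect_setequal(ctx$gene_id, c("gA", "gB"))
  expect_equal(ctx$start_codon[ctx$gene_id == "gB"], 900L)
  expect_equal(ctx$start_codon[ctx$gene_id == "gA"], 100L)
})

test_that("assign_hits applies the closed [-500, +100] window per strand", {
  ctx <- fwd_ctx()
  expect_equal(assign_hits(hit_at(520L), ctx)$dist_start_codon, -480L)
  expect_equal(nrow(assign_hits(hit_at(499L), ctx)), 0L)  # -501 excluded
  expect_equal(assign_hits(hit_at(500L), ctx)$dist_start_codon, -500L)
  expect_equal(assign_hits(hit_at(1100L), ctx)$dist_start_codon, 100L)
  expect_equal(nrow(assign_hits(hit_at(1101L), ctx)), 0L)

  rev_ctx <- make_contexts(gene_id = "geneR", operon_id = "opR",
                           contig = "chr", strand = "-",
                           start_codon = 1000L, tss = 1030L,
                           stringsAsFactors = FALSE)
  s <- assign_hits(hit_at(1030L), rev_ctx)
  expect_equal(s$dist_start_codon, -30L)  # upstream in reading direction
  expect_equal(s$dist_tss, 0L)
})

test_that("distances follow the gene reading direction, not the cre strand", {
  ctx <- fwd_ctx()
  up <- assign_hits(hit_at(994L, strand = "+"), ctx)
  lo <- assign_hits(hit_at(994L, strand = "-"), ctx)
  expect_equal(up$dist_start_codon, lo$dist_start_codon)
  expect_equal(up$dist_tss, lo$dist_tss)
  expect_equal(up$dist_tss, 44L)  # 44 nt downstream of the TSS
})

test_that("cre_tss_distance is signed, zero at the TSS, absent without TSS", {
  expect_equal(cre_tss_distance(950L, 950L, "+"), 0L)
  expect_equal(cre_tss_distance(994L, 950L, "+"), 44L)
  expect_equal(cre_tss_distance(1027L, 1000L, "-"), -27L)
  expect_true(is.na(cre_tss_distance(994L, NA_integer_, "+")))
})

test_that("literature sites bypass the window and deduplicate predictions", {
  ctx <- fwd_ctx()
  lit <- data.frame(gene_id = "geneX", sequence = "tgaaaacgtTGTCA",
                    strand = "-", g8_pos = 3354L)
  s <- add_known_sites(lit, ctx)
  expect_equal(s$dist_tss, 2404L)       # kept far beyond +100
  expect_equal(s$source, "literature")
  expect_equal(s$site, "TGAAAACGTTGTCA")

  pred <- assign_hits(hit_at(994L), ctx)
  lit2 <- data.frame(gene_id = "geneX", sequence = strrep("A", 14),
                     strand = "+", g8_pos = 994L)
  merged <- add_known_sites(lit2, ctx, cre_sites = pred)
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$source, "literature")

  no_coord <- data.frame(gene_id = "geneX", sequence = strrep("A", 14))
  s3 <- add_known_sites(no_coord, ctx)
  expect_true(is.na(s3$dist_tss) && is.na(s3$dist_start_codon))

  expect_error(add_known_sites(data.frame(gene_id = "nope",
                                          sequence = strrep("A", 14)), ctx),
               "unknown gene_id")
})

test_that("distances are invariant under coordinate translation", {
  set.seed(31)
  for (shift in c(0L, 17L, 1000L)) {
    ctx <- fwd_ctx(start_codon = 1000L + shift, tss = 950L + shift)
    s <- assign_hits(hit_at(994L + shift), ctx)
    expect_equal(s$dist_start_codon, -6L)
    expect_equal(s$dist_tss, 44L)
  }
})

test_that("dist_tss - dist_start_codon is the per-gene leader constant", {
  set.seed(37)
  ctx <- fwd_ctx()                      # leader offset 1000 - 950 = 50
  g8s <- sample(500:1100, 20)
  for (g8 in g8s) {
    s <- assign_hits(hit_at(as.integer(g8)), ctx)
    if (nrow(s)) expect_equal(s$dist_tss - s$dist_start_codon, 50L)
  }
})

test_that("retained predicted sites always satisfy the window bound", {
  set.seed(41)
  spec <- small_spec()
  sim <- generate_genome(spec)
  hits <- scan_genome(sim$scan_matrix, sim$genome, sim$cutoff)
  sites <- assign_hits(hits, sim$annotation)
  expect_true(all(sites$dist_start_codon >= -500 &
                    sites$dist_start_codon <= 100))
})

test_that("cre site writer renders absent distances as ND", {
  ctx <- fwd_ctx()
  s <- add_known_sites(data.frame(gene_id = "geneX",
                                  sequence = strrep("A", 14)), ctx)
  f <- withr::local_tempfile()
  write_cre_sites(s, f)
  tab <- utils::read.delim(f, colClasses = "character")
  expect_equal(tab$dist_tss, "ND")
  expect_equal(tab$dist_start_codon, "ND")
})
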