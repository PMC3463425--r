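#' Reverse complement of DNA strings
#'
#' Standard Watson-Crick reversal over the A/C/G/T/N alphabet (N
#' self-complements); an involution, `reverse_complement(reverse_complement(s))
#' == s`. Vectorized over its input.
#'
#' @param seq character vector of DNA strings.
#' @return character vector of the same length.
#' @examples
#' reverse_complement("TGAAAGCGCTTTCA")  # its own reverse complement
#' @export
reverse_complement <- function(seq) {
  seq <- clean_dna(seq, extra = "N")
  comp <- chartr("ACGTN", "TGCAN", seq)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(x) paste(rev(x), collapse = ""), character(1L))
}

# Score every window of width w on one strand of one contig.
# Returns a numeric vector of length L - w + 1 (NA where the window has N).
scan_strand <- function(lo, codes, w) {
  L <- length(codes)
  n_win <- L - w + 1L
  if (n_win < 1L) return(numeric(0))
  scores <- numeric(n_win)
  has_n <- logical(n_win)
  for (i in seq_len(w)) {
    ci <- codes[i:(i + n_win - 1L)]
    nn <- is.na(ci)
    has_n <- has_n | nn
    ci[nn] <- 1L                     # placeholder, masked below
    scores <- scores + lo[cbind(ci, i)]
  }
  scores[has_n] <- NA_real_
  scores
}

#' Scan a genome on both strands for motif occurrences
#'
#' Slides the weight matrix over every window of both strands and reports
#' each window scoring at least `cutoff` exactly once. Windows containing N
#' are skipped. Overlapping hits are all reported (no masking); a perfectly
#' palindromic site therefore appears once per strand over the same
#' interval.
#'
#' Coordinates are 1-based inclusive. For upper-strand hits the reported
#' `site` is the genomic substring; for lower-strand hits it is the reverse
#' complement (the w-mer in motif orientation). `g8_pos` is the genomic
#' coordinate of motif position 8, the conserved central G of the cre box,
#' used downstream as the positional anchor: `start + 7` on the upper
#' strand, `start + (w - 8)` on the lower strand.
#'
#' @param matrix a `"motif_matrix"` with `log_odds` populated.
#' @param genome a named character vector of contig sequences, a single
#'   string, or a [Biostrings::DNAStringSet].
#' @param cutoff finite score cutoff (use `-Inf` to report every window).
#' @return a data.frame of class `"motif_hits"`: `contig`, `start`, `end`,
#'   `strand` (`"+"` upper / `"-"` lower), `site`, `score`, `g8_pos`,
#'   sorted by contig, start, strand.
#' @export
scan_genome <- function(matrix, genome, cutoff) {
  stopifnot(inherits(matrix, "motif_matrix"))
  if (is.null(matrix$log_odds)) {
    stop("matrix has no log_odds; call build_weight_matrix() first",
         call. = FALSE)
  }
  if (inherits(genome, "DNAStringSet")) genome <- as.character(genome)
  genome <- clean_dna(genome, extra = "N", what = "contig")
  if (length(genome) && is.null(names(genome))) {
    names(genome) <- if (length(genome) == 1L) "genome" else
      paste0("contig", seq_along(genome))
  }
  w <- matrix$width
  lo <- matrix$log_odds
  per_contig <- lapply(names(genome), function(ctg) {
    seq_fwd <- genome[[ctg]]
    L <- nchar(seq_fwd)
    if (L < w) return(NULL)
    code <- function(s) {
      x <- match(dna_chars(s), DNA_BASES)  # N -> NA
      x
    }
    fwd <- scan_strand(lo, code(seq_fwd), w)
    rev_seq <- reverse_complement(seq_fwd)
    rev <- scan_strand(lo, code(rev_seq), w)
    keep_f <- which(!is.na(fwd) & fwd >= cutoff)
    keep_r <- which(!is.na(rev) & rev >= cutoff)
    out <- list()
    if (length(keep_f)) {
      out$f <- data.frame(contig = ctg, start = keep_f,
                          end = keep_f + w - 1L, strand = "+",
                          site = substring(seq_fwd, keep_f, keep_f + w - 1L),
                          score = fwd[keep_f],
                          g8_pos = if (w >= 8L) keep_f + 7L else NA_integer_,
                          stringsAsFactors = FALSE)
    }
    if (length(keep_r)) {
      # position p on the reversed strand starts at genomic L - p - w + 2
      gstart <- L - keep_r - w + 2L
      out$r <- data.frame(contig = ctg, start = gstart,
                          end = gstart + w - 1L, strand = "-",
                          site = substring(rev_seq, keep_r, keep_r + w - 1L),
                          score = rev[keep_r],
                          g8_pos = if (w >= 8L) gstart + w - 8L else NA_integer_,
                          stringsAsFactors = FALSE)
    }
    if (length(out)) do.call(rbind, out) else NULL
  })
  hits <- do.call(rbind, per_contig)
  if (is.null(hits)) {
    hits <- data.frame(contig = character(), start = integer(),
                       end = integer(), strand = character(),
                       site = character(), score = numeric(),
                       g8_pos = integer(), stringsAsFactors = FALSE)
  }
  hits <- hits[order(hits$contig, hits$start, hits$strand), , drop = FALSE]
  rownames(hits) <- NULL
  class(hits) <- c("motif_hits", "data.frame")
  hits
}

#' Write motif hits as BED6
#'
#' Standard BED: 0-based half-open start/end, name = site in motif
#' orientation, score rescaled linearly from `score_range` to the BED
#' 0-1000 integer convention (clamped), strand `+`/`-`. Full-precision
#' scores belong in the TSV companion ([write_hits_tsv()]).
#'
#' @param hits a `"motif_hits"` data.frame.
#' @param path output path.
#' @param score_range numeric length-2 mapped to 0 and 1000.
#' @export
write_hits_bed <- function(hits, path, score_range = NULL) {
  if (is.null(score_range)) {
    score_range <- if (nrow(hits)) range(hits$score) else c(0, 1)
    if (diff(score_range) == 0) score_range[2] <- score_range[1] + 1
  }
  scaled <- round(1000 * (hits$score - score_range[1]) / diff(score_range))
  scaled <- pmax(0L, pmin(1000L, as.integer(scaled)))
  bed <- data.frame(hits$contig, hits$start - 1L, hits$end, hits$site,
                    scaled, hits$strand)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write motif hits as a full-precision TSV
#'
#' 1-based inclusive coordinates with `g8_pos` and the raw score.
#'
#' @inheritParams write_hits_bed
#' @export
write_hits_tsv <- function(hits, path) {
  utils::write.table(as.data.frame(hits), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
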