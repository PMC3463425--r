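#' Palindrome score of fixed-width DNA sequences
#'
#' For an even width `w`, the symmetric pair `(i, w + 1 - i)` is palindromic
#' when the base at `w + 1 - i` is the Watson-Crick complement of the base
#' at `i`; the score is the number of palindromic pairs among `i = 1..w/2`
#' (maximum 7 for a 14-mer). A pair involving an ambiguous base (N) counts
#' as non-palindromic, so genome-scanned sites containing N can still be
#' profiled. Vectorized over sequences.
#'
#' @param seqs character vector of DNA strings of even, equal width.
#' @return integer vector of scores in `[0, w/2]`.
#' @examples
#' palindrome_score("TGAAAGCGCTTTCA")  # 7: a perfect palindrome
#' palindrome_score("TGAAATGAATCGTT")  # 2
#' @export
palindrome_score <- function(seqs) {
  vapply(seqs, function(s) sum(palindrome_mask(s)) %/% 2L, integer(1L),
         USE.NAMES = !is.null(names(seqs)))
}

#' @rdname palindrome_score
#' @param seq a single DNA string.
#' @return `palindrome_mask()`: logical vector of length `w`, `TRUE` at the
#'   positions belonging to a complementary pair; symmetric about the
#'   center.
#' @export
palindrome_mask <- function(seq) {
  seq <- clean_dna(seq, extra = "N", what = "sequence")
  w <- nchar(seq)
  if (w %% 2L != 0L) stop("odd sequence width ", w, call. = FALSE)
  b <- dna_chars(seq)
  half <- seq_len(w %/% 2L)
  paired <- COMPLEMENT[b[half]] == b[w + 1L - half] & b[half] != "N"
  mask <- logical(w)
  mask[half] <- paired
  mask[w + 1L - half] <- paired
  mask
}

#' Palindromicity profile of a sequence group
#'
#' Per-position palindrome percentage (share of sequences whose symmetric
#' pair containing that position is complementary, times 100, rounded half
#' up to an integer) and the group mean score (rounded half up to one
#' decimal). The percentage row is exactly symmetric about the center.
#'
#' @param seqs non-empty character vector of equal-width DNA strings.
#' @return list of class `"palindrome_profile"`: `n`, `width`, `scores`
#'   (integer, per sequence), `percent` (integer, per position),
#'   `mean_score` (1 decimal).
#' @export
group_profile <- function(seqs) {
  if (length(seqs) == 0L) stop("empty sequence set", call. = FALSE)
  w <- unique(nchar(seqs))
  if (length(w) != 1L) {
    stop("ragged sequence widths: ", paste(w, collapse = ", "), call. = FALSE)
  }
  masks <- vapply(seqs, palindrome_mask, logical(w))
  scores <- as.integer(colSums(masks)) %/% 2L
  names(scores) <- names(seqs)
  percent <- as.integer(round_half_up(100 * rowSums(masks) / length(seqs)))
  list2 <- list(n = length(seqs), width = w, scores = scores,
                percent = percent,
                mean_score = round_half_up(mean(scores), 1))
  structure(list2, class = "palindrome_profile")
}

#' @export
print.palindrome_profile <- function(x, ...) {
  cat(sprintf("palindrome profile: %d sequences of width %d\n", x$n, x$width))
  cat("palindrome %:", paste(x$percent, collapse = " "), "\n")
  cat(sprintf("average score = %.1f\n", x$mean_score))
  invisible(x)
}

#' Render the palindromic pair mask of a sequence
#'
#' Wraps every position belonging to a complementary pair in the given
#' markers (mirroring the bold residues of printed cre alignment tables);
#' stripping the markers recovers the plain sequence.
#'
#' @param seq a single DNA string of even width.
#' @param markers length-2 character vector of opening/closing marker.
#' @return a single annotated string.
#' @examples
#' pair_mask_render("TGAAATGAATCGTT")
#' @export
pair_mask_render <- function(seq, markers = c("[", "]")) {
  seq <- toupper(seq)
  mask <- palindrome_mask(seq)
  b <- dna_chars(seq)
  b[mask] <- paste0(markers[1], b[mask], markers[2])
  paste(b, collapse = "")
}

#' Write a palindromicity table mirroring the printed cre alignment tables
#'
#' One row per sequence with its score, then the per-position `%` row and
#' the group mean.
#'
#' @param seqs named character vector of sequences.
#' @param path output TSV path.
#' @export
write_palindrome_table <- function(seqs, path) {
  prof <- group_profile(seqs)
  w <- prof$width
  mat <- t(vapply(seqs, function(s) dna_chars(s), character(w)))
  tab <- data.frame(id = names(seqs) %||% paste0("seq", seq_along(seqs)),
                    mat, score = prof$scores, check.names = FALSE,
                    stringsAsFactors = FALSE)
  names(tab) <- c("id", paste0("p", seq_len(w)), "score")
  pct <- c("palindrome %", as.character(prof$percent),
           sprintf("Average score = %.1f", prof$mean_score))
  con <- file(path, "w")
  on.exit(close(con))
  utils::write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(paste(pct, collapse = "\t"), con)
  invisible(path)
}
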