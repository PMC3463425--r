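#' Construct a validated motif alignment
#'
#' A motif alignment is a set of gap-free DNA sequences of identical width,
#' e.g. the 14-nt cre boxes used to train the scanning matrix. Lower-case
#' input is accepted and upper-cased; any character outside A/C/G/T
#' (including U) is rejected with the offending sequence and position named.
#'
#' @param sequences character vector of DNA strings, all the same width.
#' @param ids optional labels, one per sequence (defaults to names of
#'   `sequences`, else `seq1`, `seq2`, ...).
#' @return a named character vector of class `"motif_alignment"`.
#' @examples
#' motif_alignment(c(acoR = "TGAAAGCGCTTTAT", xynP = "TGAAAGCGCTTTTA"))
#' @export
motif_alignment <- function(sequences, ids = NULL) {
  if (length(sequences) == 0L) stop("empty alignment", call. = FALSE)
  ids <- ids %||% names(sequences) %||% paste0("seq", seq_along(sequences))
  sequences <- toupper(as.character(sequences))
  w <- unique(nchar(sequences))
  if (length(w) != 1L) {
    stop("ragged alignment: sequence widths ", paste(w, collapse = ", "),
         call. = FALSE)
  }
  for (i in seq_along(sequences)) {
    bad <- regexpr("[^ACGT]", sequences[i])
    if (bad > 0L) {
      stop(sprintf("non-ACGT character '%s' in sequence '%s' at position %d",
                   substr(sequences[i], bad, bad), ids[i], bad), call. = FALSE)
    }
  }
  structure(stats::setNames(sequences, ids), class = "motif_alignment")
}

#' Read a motif alignment from FASTA or one-sequence-per-line text
#'
#' @param path file path.
#' @param format `"auto"` sniffs a leading `>`; otherwise `"fasta"` or
#'   `"lines"`.
#' @return a [motif_alignment()].
#' @export
read_motif_alignment <- function(path, format = c("auto", "fasta", "lines")) {
  format <- match.arg(format)
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    format <- if (startsWith(first, ">")) "fasta" else "lines"
  }
  if (format == "fasta") {
    ss <- Biostrings::readDNAStringSet(path)
    motif_alignment(as.character(ss), ids = names(ss))
  } else {
    lines <- trimws(readLines(path))
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    motif_alignment(lines)
  }
}

#' Build a position frequency matrix from an aligned motif set
#'
#' Counts each base per alignment column and converts to per-column
#' probabilities after adding a pseudocount:
#' `p[b,i] = (counts[b,i] + pseudocount) / (N + 4 * pseudocount)`.
#' The default pseudocount 0.5 keeps log-odds finite on the small cre
#' training sets; pass 0 for raw frequencies.
#'
#' @param alignment a [motif_alignment()] or character vector of sequences.
#' @param pseudocount non-negative real added to every count cell.
#' @return an object of class `"motif_matrix"`: a list with `width`, `n`
#'   (training-set size), `counts` and `probabilities` (4 x width matrices,
#'   rows A/C/G/T), `pseudocount`, and (once [build_weight_matrix()] has been
#'   applied) `log_odds` and `background`.
#' @examples
#' pfm <- build_pfm(c("AC", "AC"), pseudocount = 0)
#' pfm$counts
#' @export
build_pfm <- function(alignment, pseudocount = 0.5) {
  if (!inherits(alignment, "motif_alignment")) {
    alignment <- motif_alignment(alignment)
  }
  if (pseudocount < 0) stop("negative pseudocount", call. = FALSE)
  w <- nchar(alignment[[1L]])
  n <- length(alignment)
  mat <- matrix(unlist(strsplit(unclass(alignment), "", fixed = TRUE)),
                nrow = n, ncol = w, byrow = TRUE)
  counts <- vapply(seq_len(w), function(i) {
    tab <- table(factor(mat[, i], levels = DNA_BASES))
    as.integer(tab)
  }, integer(4L))
  dimnames(counts) <- list(DNA_BASES, NULL)
  probs <- (counts + pseudocount) / (n + 4 * pseudocount)
  structure(list(width = w, n = n, counts = counts, probabilities = probs,
                 pseudocount = pseudocount, log_odds = NULL,
                 background = NULL),
            class = "motif_matrix")
}

#' @export
print.motif_matrix <- function(x, ...) {
  cat(sprintf("motif_matrix: width %d, %d training sequences, pseudocount %g\n",
              x$width, x$n, x$pseudocount))
  cat("counts:\n")
  print(x$counts)
  if (!is.null(x$log_odds)) {
    cat("log-odds (base 2):\n")
    print(round(x$log_odds, 2))
  }
  invisible(x)
}

#' Add base-2 log-odds scores to a position frequency matrix
#'
#' `log_odds[b,i] = log2(((counts[b,i] + pseudocount) / (N + 4*pseudocount))
#' / background[b])`. With pseudocount 0, bases absent from a column get
#' `-Inf`; any window containing such a base then scores `-Inf`, which
#' compares below every finite cutoff (the guarded-minimum policy).
#'
#' @param pfm a `"motif_matrix"` from [build_pfm()].
#' @param background length-4 positive base frequencies summing to 1, in
#'   A/C/G/T order. Default uniform.
#' @param pseudocount overrides the pseudocount stored in `pfm` if given.
#' @return the matrix with `log_odds`, `background` (and refreshed
#'   `probabilities`) populated.
#' @export
build_weight_matrix <- function(pfm, background = rep(0.25, 4),
                                pseudocount = NULL) {
  stopifnot(inherits(pfm, "motif_matrix"))
  background <- unname(background)
  if (length(background) != 4L || any(background <= 0)) {
    stop("background must be 4 positive frequencies (A,C,G,T)", call. = FALSE)
  }
  if (abs(sum(background) - 1) > 1e-6) {
    stop("background frequencies must sum to 1", call. = FALSE)
  }
  pc <- pseudocount %||% pfm$pseudocount
  if (pc < 0) stop("negative pseudocount", call. = FALSE)
  probs <- (pfm$counts + pc) / (pfm$n + 4 * pc)
  pfm$pseudocount <- pc
  pfm$probabilities <- probs
  pfm$background <- stats::setNames(background, DNA_BASES)
  pfm$log_odds <- log2(probs / background)
  pfm
}

#' Call a degenerate IUPAC consensus from a position frequency matrix
#'
#' Per column (using raw count frequencies, so the call is invariant under
#' duplication of the alignment): the top base if its frequency reaches
#' `theta_single`; else the two-base IUPAC code (R/Y/W/S/K/M) of the top two
#' bases if their combined frequency reaches `theta_pair`; else `N`. Ties are
#' broken alphabetically on the base letter. The default thresholds (0.70,
#' 0.75) reproduce the discriminating single- vs two-base calls at positions
#' 6 and 14 of the high- and low-affinity cre training sets; they are a
#' heuristic, not a published rule.
#'
#' @param pfm a `"motif_matrix"`.
#' @param theta_single,theta_pair calling thresholds in (0.5, 1].
#' @return a single consensus string of the matrix width.
#' @export
consensus_call <- function(pfm, theta_single = 0.70, theta_pair = 0.75) {
  stopifnot(inherits(pfm, "motif_matrix"))
  if (theta_single <= 0.5 || theta_single > 1 ||
      theta_pair <= 0.5 || theta_pair > 1) {
    stop("consensus thresholds must lie in (0.5, 1]", call. = FALSE)
  }
  freqs <- sweep(pfm$counts, 2, colSums(pfm$counts), "/")
  calls <- vapply(seq_len(pfm$width), function(i) {
    f <- freqs[, i]                      # A,C,G,T order breaks ties
    ord <- order(-f)                     # stable: alphabetical within ties
    if (f[ord[1L]] >= theta_single) return(DNA_BASES[ord[1L]])
    if (f[ord[1L]] + f[ord[2L]] >= theta_pair) {
      pair <- paste(sort(DNA_BASES[ord[1:2]]), collapse = "")
      return(IUPAC_PAIR[[pair]])
    }
    "N"
  }, character(1L))
  paste(calls, collapse = "")
}

#' Score a single window against a weight matrix
#'
#' The score is the sum over positions of the log-odds entries of the
#' window's bases. Windows containing an ambiguous base (N) are unscorable
#' and return `NA_real_`, distinguishable from every real score (including
#' the `-Inf` guard for zero-probability bases).
#'
#' @param matrix a `"motif_matrix"` with `log_odds` (see
#'   [build_weight_matrix()]).
#' @param window DNA string of exactly the matrix width.
#' @return a numeric score, or `NA_real_` for an unscorable window.
#' @export
score_window <- function(matrix, window) {
  stopifnot(inherits(matrix, "motif_matrix"))
  if (is.null(matrix$log_odds)) {
    stop("matrix has no log_odds; call build_weight_matrix() first",
         call. = FALSE)
  }
  window <- clean_dna(window, extra = "N", what = "window")
  if (nchar(window) != matrix$width) {
    stop(sprintf("window width %d does not match matrix width %d",
                 nchar(window), matrix$width), call. = FALSE)
  }
  bases <- dna_chars(window)
  if (any(bases == "N")) return(NA_real_)
  sum(matrix$log_odds[cbind(match(bases, DNA_BASES), seq_len(matrix$width))])
}

#' Best-scoring window of a weight matrix
#'
#' Per-column argmax over the log-odds rows; ties broken alphabetically.
#'
#' @param matrix a `"motif_matrix"` with `log_odds`.
#' @return list with `window` (string) and `score`.
#' @export
best_window <- function(matrix) {
  stopifnot(inherits(matrix, "motif_matrix"), !is.null(matrix$log_odds))
  idx <- apply(matrix$log_odds, 2, which.max)
  window <- paste(DNA_BASES[idx], collapse = "")
  list(window = window, score = score_window(matrix, window))
}

#' Exact score distribution of a weight matrix
#'
#' Convolves the per-column log-odds values under an independent per-column
#' probability model, on a discretized score grid. With `model = "background"`
#' the columns are drawn from the background frequencies (null distribution
#' of a random window); with `model = "motif"` from the matrix's own
#' probabilities (distribution of scores of true motif occurrences); a 4 x w
#' probability matrix may also be supplied for an external model. `-Inf`
#' log-odds cells contribute their mass to a single `-Inf` atom.
#'
#' @param matrix a `"motif_matrix"` with `log_odds`.
#' @param model `"background"`, `"motif"`, or a 4 x width probability matrix.
#' @param resolution score grid step (default 1e-3).
#' @return data.frame with columns `score` (may include `-Inf`) and `prob`,
#'   sorted by score, probabilities summing to 1.
#' @export
score_distribution <- function(matrix, model = c("background", "motif"),
                               resolution = 1e-3) {
  stopifnot(inherits(matrix, "motif_matrix"), !is.null(matrix$log_odds))
  if (is.character(model)) {
    model <- match.arg(model)
    pm <- switch(model,
                 background = matrix(matrix$background, nrow = 4,
                                     ncol = matrix$width,
                                     dimnames = list(DNA_BASES, NULL)),
                 motif = matrix$probabilities)
  } else {
    pm <- model
    stopifnot(is.matrix(pm), nrow(pm) == 4L, ncol(pm) == matrix$width)
  }
  dist <- c(`0` = 1)                    # names are grid indices
  neginf_mass <- 0
  for (i in seq_len(matrix$width)) {
    lo <- matrix$log_odds[, i]
    p <- pm[, i]
    finite <- is.finite(lo)
    neginf_mass <- neginf_mass + sum(dist) * sum(p[!finite])
    steps <- round(lo[finite] / resolution)
    keys <- outer(as.numeric(names(dist)), steps, "+")
    vals <- outer(unname(dist), p[finite], "*")
    agg <- rowsum(as.vector(vals), group = as.vector(keys))
    dist <- stats::setNames(as.vector(agg), rownames(agg))
  }
  out <- data.frame(score = as.numeric(names(dist)) * resolution,
                    prob = unname(dist))
  if (neginf_mass > 0) {
    out <- rbind(data.frame(score = -Inf, prob = neginf_mass), out)
  }
  out[order(out$score), , drop = FALSE]
}

#' Calibrate a scan cutoff from the motif score distribution
#'
#' Returns the largest score `c` such that a window drawn from `model`
#' scores below `c` with probability at most `q` — i.e. the lower `q`
#' quantile of the score distribution. Used to set the genome-scan cutoff so
#' that a stated fraction of true motif occurrences is retained.
#'
#' @inheritParams score_distribution
#' @param q lower tail mass allowed below the cutoff (default 0.001).
#' @return a numeric cutoff.
#' @export
calibrate_cutoff <- function(matrix, q = 0.001, model = "motif",
                             resolution = 1e-3) {
  d <- score_distribution(matrix, model = model, resolution = resolution)
  cum <- cumsum(d$prob)
  i <- which(cum > q)[1L]
  d$score[i]
}

#' Write / read a JASPAR-style position frequency matrix
#'
#' Four `BASE [ counts... ]` lines after a `>` header; integer counts
#' round-trip exactly.
#'
#' @param pfm a `"motif_matrix"`.
#' @param path file path.
#' @param name motif name for the header line.
#' @export
write_pfm_jaspar <- function(pfm, path, name = "motif") {
  stopifnot(inherits(pfm, "motif_matrix"))
  lines <- c(paste0(">", name),
             vapply(DNA_BASES, function(b) {
               sprintf("%s  [ %s ]", b,
                       paste(format(pfm$counts[b, ]), collapse = " "))
             }, character(1L)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_pfm_jaspar
#' @param pseudocount pseudocount for the reconstructed matrix.
#' @export
read_pfm_jaspar <- function(path, pseudocount = 0.5) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, ">") & nzchar(trimws(lines))]
  stopifnot(length(lines) == 4L)
  rows <- lapply(lines, function(ln) {
    nums <- regmatches(ln, gregexpr("[0-9]+", ln))[[1L]]
    base <- trimws(substr(ln, 1, 1))
    list(base = base, counts = as.integer(nums))
  })
  counts <- do.call(rbind, lapply(rows, `[[`, "counts"))
  rownames(counts) <- vapply(rows, `[[`, character(1L), "base")
  counts <- counts[DNA_BASES, , drop = FALSE]
  n <- sum(counts[, 1L])
  out <- structure(list(width = ncol(counts), n = n, counts = counts,
                        probabilities = (counts + pseudocount) /
                          (n + 4 * pseudocount),
                        pseudocount = pseudocount, log_odds = NULL,
                        background = NULL),
                   class = "motif_matrix")
  out
}

#' Write / read a tab-separated 4 x width log-odds table
#'
#' Full-precision (`%.17g`) values; matrices round-trip exactly through
#' write/read.
#'
#' @param matrix a `"motif_matrix"` with `log_odds`.
#' @param path file path.
#' @export
write_weight_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "motif_matrix"), !is.null(matrix$log_odds))
  lo <- matrix$log_odds
  header <- paste(c("base", paste0("pos", seq_len(ncol(lo)))), collapse = "\t")
  body <- vapply(DNA_BASES, function(b) {
    paste(c(b, sprintf("%.17g", lo[b, ])), collapse = "\t")
  }, character(1L))
  meta <- sprintf("# n=%d pseudocount=%.17g background=%s", matrix$n,
                  matrix$pseudocount,
                  paste(sprintf("%.17g", matrix$background), collapse = ","))
  writeLines(c(meta, header, body), path)
  invisible(path)
}

#' @rdname write_weight_matrix
#' @export
read_weight_matrix <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "#")][1L]
  lines <- lines[!startsWith(lines, "#")]
  tab <- utils::read.delim(text = paste(lines, collapse = "\n"),
                           check.names = FALSE)
  lo <- as.matrix(tab[, -1, drop = FALSE])
  rownames(lo) <- tab$base
  lo <- lo[DNA_BASES, , drop = FALSE]
  n <- as.integer(sub(".*n=([0-9]+).*", "\\1", meta))
  pc <- as.numeric(sub(".*pseudocount=([^ ]+).*", "\\1", meta))
  bg <- as.numeric(strsplit(sub(".*background=([^ ]+).*", "\\1", meta),
                            ",")[[1L]])
  probs <- 2^lo * bg
  counts <- probs * (n + 4 * pc) - pc
  structure(list(width = ncol(lo), n = n,
                 counts = round(counts),
                 probabilities = probs,
                 pseudocount = pc, log_odds = unname(lo) ,
                 background = stats::setNames(bg, DNA_BASES)),
            class = "motif_matrix") -> out
  dimnames(out$log_odds) <- list(DNA_BASES, NULL)
  out
}
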