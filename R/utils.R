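#' @keywords internal
"_PACKAGE"

DNA_BASES <- c("A", "C", "G", "T")

# Watson-Crick complement lookup, N self-complements
COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

# IUPAC code for an unordered pair of bases
IUPAC_PAIR <- c(AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K")

# Round half away from zero (paper-style rounding: 30/31 -> 97, 144/31 -> 4.6).
# base::round() rounds half to even, which does not reproduce printed tables.
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

# Uppercase and validate a DNA string vector; returns the cleaned vector.
# `extra` widens the alphabet (e.g. "N" for genome sequence).
clean_dna <- function(x, extra = character(0), what = "sequence") {
  nm <- names(x)
  x <- toupper(as.character(x))
  names(x) <- nm
  alphabet <- c(DNA_BASES, extra)
  bad <- regexpr(sprintf("[^%s]", paste(alphabet, collapse = "")), x)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    stop(sprintf("invalid character '%s' in %s %d at position %d (alphabet %s)",
                 substr(x[i], bad[i], bad[i]), what, i, bad[i],
                 paste(alphabet, collapse = "")), call. = FALSE)
  }
  x
}

# split a single DNA string into a character vector of bases
dna_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

`%||%` <- function(a, b) if (is.null(a)) b else a
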