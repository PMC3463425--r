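#' Load operon first-gene contexts from a TSV or GFF3 annotation
#'
#' Produces one row per operon first gene. For a TSV the mandatory columns
#' are `gene_id`, `strand` and `start_codon`; `operon_id` (defaulting to the
#' gene itself: singleton operons), `tss` (integer or `ND`/empty for
#' unknown) and `contig` are optional. For a GFF3 file, `gene` features are
#' used; the gene id is taken from the `ID`, `locus_tag` or `Name`
#' attribute, the operon from an `operon` attribute when present. For a
#' reverse-strand gene spanning `[s, e]` the first base of the start codon
#' in reading direction is `e`.
#'
#' When an operon has several genes, the first gene is the one whose start
#' codon is most upstream in the operon's reading direction.
#'
#' @param path annotation file.
#' @param format `"auto"` (by extension), `"tsv"` or `"gff3"`.
#' @return a data.frame of class `"gene_contexts"`: `gene_id`, `operon_id`,
#'   `contig`, `strand` (`+`/`-`), `start_codon`, `tss` (NA when unknown).
#' @export
load_annotation <- function(path, format = c("auto", "tsv", "gff3")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3" else "tsv"
  }
  if (format == "tsv") {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                             colClasses = "character")
    mandatory <- c("gene_id", "strand", "start_codon")
    missing_cols <- setdiff(mandatory, names(tab))
    if (length(missing_cols)) {
      stop("annotation is missing mandatory column(s): ",
           paste(missing_cols, collapse = ", "), call. = FALSE)
    }
    ctx <- data.frame(
      gene_id = tab$gene_id,
      operon_id = if ("operon_id" %in% names(tab)) tab$operon_id else tab$gene_id,
      contig = if ("contig" %in% names(tab)) tab$contig else "genome",
      strand = tab$strand,
      start_codon = as.integer(tab$start_codon),
      tss = if ("tss" %in% names(tab)) {
        suppressWarnings(as.integer(ifelse(tab$tss %in% c("ND", "", "NA"),
                                           NA, tab$tss)))
      } else NA_integer_,
      stringsAsFactors = FALSE)
    ctx$operon_id[is.na(ctx$operon_id) | ctx$operon_id == ""] <-
      ctx$gene_id[is.na(ctx$operon_id) | ctx$operon_id == ""]
  } else {
    gr <- rtracklayer::import(path)
    gr <- gr[gr$type == "gene"]
    md <- S4Vectors::mcols(gr)
    pick <- function(...) {
      for (f in c(...)) {
        if (f %in% names(md) && !all(is.na(md[[f]]))) return(as.character(md[[f]]))
      }
      NULL
    }
    ids <- pick("ID", "locus_tag", "Name")
    if (is.null(ids)) stop("GFF3 gene features carry no ID/locus_tag/Name",
                           call. = FALSE)
    operons <- if ("operon" %in% names(md)) as.character(md$operon) else ids
    operons[is.na(operons)] <- ids[is.na(operons)]
    strand <- as.character(BiocGenerics::strand(gr))
    ctx <- data.frame(
      gene_id = ids,
      operon_id = operons,
      contig = as.character(GenomicRanges::seqnames(gr)),
      strand = strand,
      start_codon = ifelse(strand == "-", BiocGenerics::end(gr),
                           BiocGenerics::start(gr)),
      tss = if ("tss" %in% names(md)) as.integer(md$tss) else NA_integer_,
      stringsAsFactors = FALSE)
  }
  if (!all(ctx$strand %in% c("+", "-"))) {
    stop("gene strand must be '+' or '-'", call. = FALSE)
  }
  if (anyDuplicated(ctx$gene_id)) {
    stop("duplicate gene_id in annotation: ",
         paste(unique(ctx$gene_id[duplicated(ctx$gene_id)]), collapse = ", "),
         call. = FALSE)
  }
  # keep the first gene of each operon (most upstream start codon in the
  # operon's reading direction)
  keep <- unlist(lapply(split(seq_len(nrow(ctx)), ctx$operon_id), function(i) {
    if (length(i) == 1L) return(i)
    s <- ctx$strand[i[1L]]
    if (s == "+") i[which.min(ctx$start_codon[i])] else
      i[which.max(ctx$start_codon[i])]
  }))
  ctx <- ctx[sort(keep), , drop = FALSE]
  rownames(ctx) <- NULL
  class(ctx) <- c("gene_contexts", "data.frame")
  ctx
}

# signed offset of a genomic coordinate from an anchor, in the gene's
# reading direction (negative = upstream of the anchor)
reading_offset <- function(pos, anchor, gene_strand) {
  ifelse(gene_strand == "+", pos - anchor, anchor - pos)
}

#' Cre-to-TSS distance
#'
#' Signed offset of the cre box's central G (motif position 8) from the
#' transcription start site, in the regulated gene's reading direction:
#' negative upstream, positive downstream, 0 when the G sits on the TSS.
#' `NA` (never 0) when the TSS is unknown.
#'
#' @param g8_pos genomic coordinate(s) of the central G.
#' @param tss genomic TSS coordinate(s), NA allowed.
#' @param gene_strand `"+"` or `"-"`, recycled.
#' @return integer vector of signed distances with NA for unknown TSS.
#' @export
cre_tss_distance <- function(g8_pos, tss, gene_strand) {
  as.integer(reading_offset(g8_pos, tss, gene_strand))
}

new_cre_sites <- function(df) {
  cols <- c("gene_id", "operon_id", "contig", "gene_strand", "site",
            "cre_strand", "score", "g8_pos", "dist_start_codon", "dist_tss",
            "source")
  df <- df[, cols, drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("cre_sites", "data.frame")
  df
}

#' Attach motif hits to operon first genes via a positional window
#'
#' A hit is attached to every operon first gene for which the signed offset
#' of the hit's central G from the first base of the start codon (in the
#' gene's reading direction) lies inside the closed window, by default
#' `[-500, +100]`. One hit may attach to several genes and one gene may
#' receive several hits. The cre strand is recorded but distance signs
#' follow the regulated gene's reading direction only.
#'
#' @param hits a `"motif_hits"` data.frame from [scan_genome()].
#' @param contexts a `"gene_contexts"` data.frame from [load_annotation()].
#' @param window closed interval of accepted offsets, default `c(-500, 100)`.
#' @return a `"cre_sites"` data.frame with `dist_start_codon`, `dist_tss`
#'   (NA when the TSS is unknown) and `source = "predicted"`.
#' @export
assign_hits <- function(hits, contexts, window = c(-500, 100)) {
  stopifnot(length(window) == 2L, window[1] <= window[2])
  pairs <- merge(as.data.frame(hits), as.data.frame(contexts), by = "contig")
  if (nrow(pairs) == 0L) {
    pairs <- data.frame(gene_id = character(), operon_id = character(),
                        contig = character(), gene_strand = character(),
                        site = character(), cre_strand = character(),
                        score = numeric(), g8_pos = integer(),
                        dist_start_codon = integer(), dist_tss = integer(),
                        source = character(), stringsAsFactors = FALSE)
    return(new_cre_sites(pairs))
  }
  d <- reading_offset(pairs$g8_pos, pairs$start_codon, pairs$strand.y)
  keep <- d >= window[1] & d <= window[2]
  pairs <- pairs[keep, , drop = FALSE]
  out <- if (nrow(pairs) == 0L) data.frame(
    gene_id = character(), operon_id = character(), contig = character(),
    gene_strand = character(), site = character(), cre_strand = character(),
    score = numeric(), g8_pos = integer(), dist_start_codon = integer(),
    dist_tss = integer(), source = character(), stringsAsFactors = FALSE)
  else data.frame(
    gene_id = pairs$gene_id, operon_id = pairs$operon_id,
    contig = pairs$contig, gene_strand = pairs$strand.y,
    site = pairs$site, cre_strand = pairs$strand.x,
    score = pairs$score, g8_pos = pairs$g8_pos,
    dist_start_codon = as.integer(d[keep]),
    dist_tss = cre_tss_distance(pairs$g8_pos, pairs$tss, pairs$strand.y),
    source = "predicted", stringsAsFactors = FALSE)
  out <- out[order(out$gene_id, out$g8_pos), , drop = FALSE]
  new_cre_sites(out)
}

#' Add literature-known cre sites, bypassing the positional window
#'
#' Literature sites name their regulated gene and are attached regardless of
#' the `[-500, +100]` filter (the reference set keeps a site +2404 nt
#' downstream of the TSS). Distances are computed when a `g8_pos` coordinate
#' is given and are `NA` otherwise; sites without coordinates remain
#' classifiable by expression. A literature site duplicating a predicted
#' site at the same central-G coordinate replaces it (one row, `source =
#' "literature"`).
#'
#' @param sites data.frame with columns `gene_id`, `sequence`, `strand`
#'   (cre strand `+`/`-`) and optional `g8_pos`.
#' @param contexts a `"gene_contexts"` data.frame.
#' @param cre_sites optional existing `"cre_sites"` (e.g. from
#'   [assign_hits()]) to merge with.
#' @return a `"cre_sites"` data.frame.
#' @export
add_known_sites <- function(sites, contexts, cre_sites = NULL) {
  unknown <- setdiff(sites$gene_id, contexts$gene_id)
  if (length(unknown)) {
    stop("literature site(s) name unknown gene_id: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  ctx <- as.data.frame(contexts)
  m <- match(sites$gene_id, ctx$gene_id)
  g8 <- if ("g8_pos" %in% names(sites)) {
    suppressWarnings(as.integer(sites$g8_pos))
  } else rep(NA_integer_, nrow(sites))
  lit <- data.frame(
    gene_id = sites$gene_id, operon_id = ctx$operon_id[m],
    contig = ctx$contig[m], gene_strand = ctx$strand[m],
    site = toupper(sites$sequence),
    cre_strand = if ("strand" %in% names(sites)) sites$strand else NA_character_,
    score = NA_real_, g8_pos = g8,
    dist_start_codon = as.integer(
      reading_offset(g8, ctx$start_codon[m], ctx$strand[m])),
    dist_tss = cre_tss_distance(g8, ctx$tss[m], ctx$strand[m]),
    source = "literature", stringsAsFactors = FALSE)
  out <- if (is.null(cre_sites)) lit else {
    pred <- as.data.frame(cre_sites)
    dup <- !is.na(pred$g8_pos) &
      paste(pred$gene_id, pred$g8_pos) %in%
      paste(lit$gene_id[!is.na(lit$g8_pos)], lit$g8_pos[!is.na(lit$g8_pos)])
    rbind(pred[!dup, , drop = FALSE], lit)
  }
  out <- out[order(out$gene_id, out$g8_pos), , drop = FALSE]
  new_cre_sites(out)
}

#' Write cre sites as TSV
#'
#' Absent distances are written as `ND`, matching the notation of the
#' paper-style report tables.
#'
#' @param sites a `"cre_sites"` data.frame.
#' @param path output path.
#' @export
write_cre_sites <- function(sites, path) {
  out <- as.data.frame(sites)
  for (col in c("dist_start_codon", "dist_tss")) {
    out[[col]] <- ifelse(is.na(out[[col]]), "ND", as.character(out[[col]]))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
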