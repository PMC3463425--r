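AFFINITY_LEVELS <- c("high_affinity", "low_affinity", "activating",
                     "unclassified", "no_data")

#' Read a three-condition expression table
#'
#' TSV with columns `gene_id`, `fc_low`, `fc_med`, `fc_high` (signed
#' fold-change ratios, never in (-1, 1)), `sig_low`, `sig_med`, `sig_high`
#' (logical significance flags from upstream testing) and an optional
#' logical `exclude_flag` marking sites to drop from sequence/position
#' analyses (e.g. probes lying upstream of the cre box). When the `sig_*`
#' columns are absent they default to `TRUE`, so that significance reduces
#' to the fold-change magnitude criterion alone (weaker than a proper
#' statistical flag; a message notes the fallback).
#'
#' @param path TSV path.
#' @return a data.frame of class `"expression_records"`.
#' @export
read_expression <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  expression_records(tab)
}

#' @rdname read_expression
#' @param tab a data.frame with the columns described above.
#' @export
expression_records <- function(tab) {
  mandatory <- c("gene_id", "fc_low", "fc_med", "fc_high")
  missing_cols <- setdiff(mandatory, names(tab))
  if (length(missing_cols)) {
    stop("expression table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  sig_cols <- c("sig_low", "sig_med", "sig_high")
  if (!all(sig_cols %in% names(tab))) {
    message("no significance flags supplied; falling back to the ",
            "fold-change magnitude criterion alone")
    for (s in setdiff(sig_cols, names(tab))) tab[[s]] <- TRUE
  }
  for (s in sig_cols) tab[[s]] <- as.logical(tab[[s]])
  if (!"exclude_flag" %in% names(tab)) tab$exclude_flag <- FALSE
  tab$exclude_flag <- as.logical(tab$exclude_flag)
  fc <- as.matrix(tab[, c("fc_low", "fc_med", "fc_high")])
  if (any(fc == 0, na.rm = TRUE)) {
    stop("fold changes must be nonzero signed ratios", call. = FALSE)
  }
  class(tab) <- c("expression_records", "data.frame")
  tab
}

#' Significance of a fold change
#'
#' A condition counts as significantly regulated only when the fold-change
#' magnitude reaches `threshold` AND the upstream significance flag is set:
#' the two criteria are independent (a gene can print -1.8 yet be
#' non-significant). The magnitude comparison is `|fc| >= threshold`
#' (strict at 1.7999...); direction is carried by the sign alone.
#'
#' @param fc signed fold-change ratio(s), nonzero.
#' @param sig logical flag(s) from upstream testing.
#' @param threshold fold-change magnitude cutoff, > 1 (default 1.8).
#' @return logical vector.
#' @examples
#' is_significant(-4.8, TRUE)    # TRUE
#' is_significant(-1.8, FALSE)   # FALSE: flag not set
#' is_significant(1.7999, TRUE)  # FALSE: below magnitude cutoff
#' @export
is_significant <- function(fc, sig, threshold = 1.8) {
  if (threshold <= 1) stop("threshold must exceed 1", call. = FALSE)
  if (any(fc == 0, na.rm = TRUE)) stop("fold change of 0", call. = FALSE)
  abs(fc) >= threshold & as.logical(sig)
}

#' Classify cre sites by regulatory affinity from titrated expression
#'
#' Decision tree over the three regulator-induction levels, mirroring the
#' operational definition of cre affinity by CcpA titration:
#' \enumerate{
#'   \item a gene not significantly regulated (either direction) at the
#'     high induction level is `unclassified` (regulation at least at high
#'     induction is the entry gate);
#'   \item significant repression already at low induction:
#'     `high_affinity`;
#'   \item significant activation at all three levels: `activating`;
#'   \item otherwise, significant repression at medium or high induction:
#'     `low_affinity`;
#'   \item otherwise `unclassified`.
#' }
#' A record showing significant regulation in both directions across
#' conditions is conflicting: it is set to `unclassified` with a warning,
#' never silently.
#'
#' @param records an `"expression_records"` data.frame (or one coercible by
#'   [expression_records()]).
#' @param threshold fold-change magnitude cutoff (default 1.8).
#' @return data.frame of class `"affinity_calls"`: `gene_id`, `call`,
#'   `direction` (`repressed`/`activated`/`none`), and the evidence columns
#'   `fc_low`/`fc_med`/`fc_high` with their significance outcomes
#'   `sig_low`/`sig_med`/`sig_high` (flag AND magnitude).
#' @examples
#' rec <- data.frame(gene_id = "acoR", fc_low = -4.8, fc_med = -18.7,
#'                   fc_high = -21.7, sig_low = TRUE, sig_med = TRUE,
#'                   sig_high = TRUE)
#' classify_cre(rec)$call
#' @export
classify_cre <- function(records, threshold = 1.8) {
  if (!inherits(records, "expression_records")) {
    records <- expression_records(records)
  }
  s_low <- is_significant(records$fc_low, records$sig_low, threshold)
  s_med <- is_significant(records$fc_med, records$sig_med, threshold)
  s_high <- is_significant(records$fc_high, records$sig_high, threshold)
  neg <- cbind(records$fc_low < 0, records$fc_med < 0, records$fc_high < 0)
  sig <- cbind(s_low, s_med, s_high)
  any_neg <- rowSums(sig & neg) > 0L
  any_pos <- rowSums(sig & !neg) > 0L
  conflict <- any_neg & any_pos
  if (any(conflict)) {
    warning("conflicting regulation directions for: ",
            paste(records$gene_id[conflict], collapse = ", "),
            "; set to unclassified", call. = FALSE)
  }
  call <- rep("unclassified", nrow(records))
  gate <- s_high                             # regulated at least at high
  ok <- gate & !conflict
  call[ok & s_low & neg[, 1]] <- "high_affinity"
  act <- ok & call == "unclassified" &
    s_low & s_med & s_high & !neg[, 1] & !neg[, 2] & !neg[, 3]
  call[act] <- "activating"
  lowa <- ok & call == "unclassified" &
    ((s_med & neg[, 2]) | (s_high & neg[, 3]))
  call[lowa] <- "low_affinity"
  part_act <- !conflict & call == "unclassified" & any_pos
  if (any(part_act)) {
    warning("gene(s) activated at only some induction levels, ",
            "left unclassified: ",
            paste(records$gene_id[part_act], collapse = ", "), call. = FALSE)
  }
  direction <- rep("none", nrow(records))
  direction[call %in% c("high_affinity", "low_affinity")] <- "repressed"
  direction[call == "activating"] <- "activated"
  out <- data.frame(gene_id = records$gene_id, call = call,
                    direction = direction,
                    fc_low = records$fc_low, fc_med = records$fc_med,
                    fc_high = records$fc_high,
                    sig_low = s_low, sig_med = s_med, sig_high = s_high,
                    stringsAsFactors = FALSE)
  class(out) <- c("affinity_calls", "data.frame")
  out
}

#' Count distinct operons significantly repressed per induction level
#'
#' For each of the three induction levels, the number of distinct operons
#' whose first gene shows significant repression at that level. Operons
#' carrying several cre boxes (each with its own expression row) are
#' counted once.
#'
#' @param records an `"expression_records"` data.frame.
#' @param operon_map named character vector mapping `gene_id` to
#'   `operon_id`; genes absent from the map are their own operon.
#' @param threshold fold-change magnitude cutoff (default 1.8).
#' @return named integer vector `c(low = , medium = , high = )`.
#' @export
count_regulated_operons <- function(records, operon_map = NULL,
                                    threshold = 1.8) {
  if (nrow(records) == 0L) return(c(low = 0L, medium = 0L, high = 0L))
  if (!inherits(records, "expression_records")) {
    records <- expression_records(records)
  }
  operon <- records$gene_id
  if (!is.null(operon_map)) {
    mapped <- operon_map[records$gene_id]
    operon[!is.na(mapped)] <- mapped[!is.na(mapped)]
  }
  one <- function(fc, sig) {
    repressed <- is_significant(fc, sig, threshold) & fc < 0
    length(unique(operon[repressed]))
  }
  c(low = one(records$fc_low, records$sig_low),
    medium = one(records$fc_med, records$sig_med),
    high = one(records$fc_high, records$sig_high))
}

#' Tabulate the affinity report
#'
#' One row per cre site, grouped high-affinity / low-affinity / activating
#' (then unclassified as a residual section, then sites lacking expression
#' data as `no_data`), ordered by group then gene id. Sites whose
#' expression record carries the probe-orientation `exclude_flag` are kept
#' in the report with `excluded = TRUE` so that sequence/position analyses
#' can drop them.
#'
#' @param sites a `"cre_sites"` data.frame.
#' @param calls an `"affinity_calls"` data.frame from [classify_cre()].
#' @param records optional `"expression_records"` supplying `exclude_flag`.
#' @return data.frame of class `"affinity_report"` with `gene_id`,
#'   `operon_id`, `cre_strand`, `site`, the three fold changes, `call`,
#'   `dist_tss` and `excluded`.
#' @export
tabulate_report <- function(sites, calls, records = NULL) {
  df <- as.data.frame(sites)
  m <- match(df$gene_id, calls$gene_id)
  df$call <- calls$call[m]
  df$fc_low <- calls$fc_low[m]
  df$fc_med <- calls$fc_med[m]
  df$fc_high <- calls$fc_high[m]
  no_data <- is.na(m)
  if (any(no_data)) {
    message(sum(no_data), " cre site(s) without expression record, ",
            "reported as no_data: ",
            paste(unique(df$gene_id[no_data]), collapse = ", "))
    df$call[no_data] <- "no_data"
  }
  df$excluded <- FALSE
  if (!is.null(records) && "exclude_flag" %in% names(records)) {
    mm <- match(df$gene_id, records$gene_id)
    df$excluded <- !is.na(mm) & records$exclude_flag[mm] %in% TRUE
  }
  df$call <- factor(df$call, levels = AFFINITY_LEVELS)
  df <- df[order(df$call, df$gene_id), , drop = FALSE]
  out <- df[, c("gene_id", "operon_id", "cre_strand", "site", "fc_low",
                "fc_med", "fc_high", "call", "dist_tss", "excluded")]
  rownames(out) <- NULL
  class(out) <- c("affinity_report", "data.frame")
  out
}

#' Write the affinity report (and the per-level operon counts)
#'
#' @param report an `"affinity_report"` from [tabulate_report()].
#' @param path output TSV path.
#' @export
write_report <- function(report, path) {
  out <- as.data.frame(report)
  out$dist_tss <- ifelse(is.na(out$dist_tss), "ND", as.character(out$dist_tss))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_report
#' @param counts named vector from [count_regulated_operons()].
#' @export
write_operon_counts <- function(counts, path) {
  utils::write.table(data.frame(level = names(counts),
                                regulated_operons = as.integer(counts)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
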