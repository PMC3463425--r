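#' Published cre-box reference table
#'
#' The packaged reference set of 72 cre boxes of operon first genes from
#' the genome-wide CcpA titration study in *Bacillus subtilis*: 31
#' high-affinity and 38 low-affinity repressing boxes plus 3 activating
#' ones, each with its 14-nt sequence, strand, signed expression fold
#' changes at the low/medium/high CcpA induction levels, significance
#' flags, cre-to-TSS distance (NA where not determined) and the published
#' per-sequence palindrome score (NA for the activating boxes, which were
#' excluded from the sequence analysis).
#'
#' @return data.frame with columns `gene_id`, `operon_id`, `group`
#'   (`high`/`low`/`activating`), `strand` (`upper`/`lower`), `cre_strand`
#'   (`+`/`-`), `cre_sequence`, `fc_low`, `fc_med`, `fc_high`, `sig_low`,
#'   `sig_med`, `sig_high`, `dist_tss`, `score_printed`.
#' @examples
#' tab <- cre_reference_table()
#' table(tab$group)
#' @export
cre_reference_table <- function() {
  path <- system.file("extdata", "cre_reference_sites.tsv", package = "crebox",
                      mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  tab$dist_tss <- suppressWarnings(
    as.integer(ifelse(tab$dist_tss == "ND", NA, tab$dist_tss)))
  tab$cre_strand <- ifelse(tab$strand == "upper", "+", "-")
  tab
}

#' Reference cre sequences by affinity group
#'
#' @param group `"high"` (the 31 high-affinity boxes), `"low"` (the 38
#'   low-affinity boxes), `"repressing"` (both), or `"activating"`.
#' @return named character vector of 14-mers.
#' @export
cre_reference_sequences <- function(group = c("high", "low", "repressing",
                                              "activating")) {
  group <- match.arg(group)
  tab <- cre_reference_table()
  keep <- if (group == "repressing") tab$group %in% c("high", "low") else
    tab$group == group
  stats::setNames(tab$cre_sequence[keep], tab$gene_id[keep])
}

#' Reference expression records and operon map
#'
#' The three-condition fold-change table of the reference set as
#' `"expression_records"`, and the gene-to-operon map merging the
#' two-cre operons (iolA-1/iolA-2 and gntR-1/gntR-2).
#'
#' @return `cre_reference_expression()`: an `"expression_records"`
#'   data.frame; `cre_reference_operons()`: named character vector mapping
#'   gene_id to operon_id.
#' @export
cre_reference_expression <- function() {
  tab <- cre_reference_table()
  expression_records(tab[, c("gene_id", "fc_low", "fc_med", "fc_high",
                             "sig_low", "sig_med", "sig_high")])
}

#' @rdname cre_reference_expression
#' @export
cre_reference_operons <- function() {
  tab <- cre_reference_table()
  stats::setNames(tab$operon_id, tab$gene_id)
}
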