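#' Specification for a synthetic cre-regulon benchmark
#'
#' Defines the study conditions a synthetic dataset emulates: a random
#' genome of given length and GC content hosting one operon per slot, a
#' subset of operon first genes carrying a planted 14-nt cre box of graded
#' affinity, and a three-condition expression table whose effect structure
#' matches the titration design (strong boxes repressed already at low
#' induction, weak ones only at medium/high, a minority activating).
#'
#' Site sequences are sampled column-wise from the packaged high-affinity
#' (strong and activating classes) or low-affinity (weak class) position
#' frequency matrices; decoys are random 14-mers constrained below the scan
#' cutoff. Placement distances from the TSS follow a mixture of a near-TSS
#' Gaussian cluster and a uniform component, mirroring the observed
#' clustering of high-affinity boxes near the TSS. Fold-change effect
#' ranges default to the ranges observed in the published reference table
#' (signed-ratio scale, e.g. strong low-induction magnitudes 1.8-7.4, weak
#' high-induction magnitudes 1.8-12.2).
#'
#' All randomness is driven by `seed`.
#'
#' @param seed integer seed.
#' @param genome_length genome length in nt (default 200000).
#' @param gc_content genomic GC fraction (default 0.435, as in
#'   *B. subtilis*).
#' @param n_operons number of operons (one annotated first gene each).
#' @param n_strong,n_weak,n_activating,n_decoy planted site counts per
#'   class (defaults 20/20/3 plus 10 decoys).
#' @param near_tss_prob probability that a site distance is drawn from the
#'   near-TSS cluster (default 0.7).
#' @param near_tss_sd standard deviation (nt) of the near-TSS cluster.
#' @param uniform_range integer range of the uniform distance component.
#' @param leader_range range of TSS-to-start-codon leader lengths (nt).
#' @param effects per-class list of per-condition fold-change magnitude
#'   ranges on the signed-ratio scale (see Details for defaults).
#' @param noise_sd standard deviation of Gaussian noise added to log2 fold
#'   changes (default 0.25).
#' @param false_flag_rate probability of flipping a significance flag
#'   (default 0).
#' @param threshold fold-change magnitude threshold used for the
#'   significance flags (default 1.8).
#' @param cutoff_q lower tail mass used by [calibrate_cutoff()] when
#'   calibrating the scan cutoff against the planted-site models.
#' @return a validated list of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(seed = 1L,
                           genome_length = 200000L,
                           gc_content = 0.435,
                           n_operons = 50L,
                           n_strong = 20L, n_weak = 20L,
                           n_activating = 3L, n_decoy = 10L,
                           near_tss_prob = 0.7, near_tss_sd = 15,
                           uniform_range = c(-100L, 100L),
                           leader_range = c(20L, 150L),
                           effects = NULL,
                           noise_sd = 0.25, false_flag_rate = 0,
                           threshold = 1.8, cutoff_q = 0.005) {
  n_sites <- n_strong + n_weak + n_activating
  if (n_sites > n_operons) {
    stop("more planted sites than operons", call. = FALSE)
  }
  if (genome_length < n_operons * 800L) {
    stop("genome too short to host ", n_operons,
         " operons without overlap (need >= ", n_operons * 800L, " nt)",
         call. = FALSE)
  }
  if (gc_content <= 0 || gc_content >= 1) stop("gc_content must be in (0,1)")
  effects <- effects %||% list(
    strong     = list(low = c(1.8, 7.4), med = c(1.9, 21.9),
                      high = c(2.1, 35.8), sign = -1),
    weak       = list(low = c(1.0, 1.4), med = c(1.8, 6.6),
                      high = c(1.8, 12.2), sign = -1),
    activating = list(low = c(2.3, 3.0), med = c(2.5, 6.2),
                      high = c(2.3, 2.7), sign = +1),
    none       = list(low = c(1.0, 1.3), med = c(1.0, 1.3),
                      high = c(1.0, 1.3), sign = 0))
  structure(list(seed = as.integer(seed), genome_length = genome_length,
                 gc_content = gc_content, n_operons = n_operons,
                 n_strong = n_strong, n_weak = n_weak,
                 n_activating = n_activating, n_decoy = n_decoy,
                 near_tss_prob = near_tss_prob, near_tss_sd = near_tss_sd,
                 uniform_range = uniform_range, leader_range = leader_range,
                 effects = effects, noise_sd = noise_sd,
                 false_flag_rate = false_flag_rate, threshold = threshold,
                 cutoff_q = cutoff_q),
            class = "synthetic_spec")
}

#' Read a synthetic-data spec from a YAML config file
#'
#' The file may set any argument of [synthetic_spec()] by name (scalars or
#' short lists, e.g. `uniform_range: [-100, 100]`); unset fields keep their
#' defaults.
#'
#' @param path YAML file path.
#' @return a `"synthetic_spec"`.
#' @export
synthetic_spec_from_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- names(formals(synthetic_spec))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    stop("unknown synthetic_spec field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(synthetic_spec, cfg)
}

sample_from_pfm <- function(probs, n) {
  w <- ncol(probs)
  vapply(seq_len(n), function(i) {
    paste(vapply(seq_len(w), function(j) {
      sample(DNA_BASES, 1L, prob = probs[, j])
    }, character(1L)), collapse = "")
  }, character(1L))
}

#' Generate a synthetic genome with planted cre sites
#'
#' Draws an i.i.d. background genome at the requested GC content, lays out
#' `n_operons` operon first genes (random strand, TSS upstream of the start
#' codon by a sampled leader), plants strong/weak/activating cre boxes at
#' sampled TSS distances and strands by overwriting the background, adds
#' below-cutoff decoy 14-mers, and returns everything together with the
#' scan matrix (built from the packaged reference training set), its
#' calibrated cutoff and a truth table. Deterministic under `spec$seed`.
#'
#' @param spec a [synthetic_spec()].
#' @return list of class `"cre_synthetic"`: `genome` (named character,
#'   one contig `"chr"`), `annotation` (`"gene_contexts"`), `truth`
#'   (data.frame: site_id, gene_id, operon_id, class, contig, start, end,
#'   strand, sequence, g8_pos, dist_tss, dist_start_codon), `scan_matrix`,
#'   `cutoff`, `spec`.
#' @export
generate_genome <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  L <- spec$genome_length
  bg <- c(A = (1 - spec$gc_content) / 2, C = spec$gc_content / 2,
          G = spec$gc_content / 2, T = (1 - spec$gc_content) / 2)
  genome_chars <- sample(DNA_BASES, L, replace = TRUE, prob = bg)

  # motif models: strong/activating sites from the high-affinity PFM,
  # weak sites from the low-affinity PFM; scanning uses both sets pooled
  strong_pfm <- build_pfm(cre_reference_sequences("high"))
  weak_pfm <- build_pfm(cre_reference_sequences("low"))
  scan_wm <- build_weight_matrix(build_pfm(cre_reference_sequences("repressing")),
                                 background = unname(bg))
  cutoff <- min(
    calibrate_cutoff(scan_wm, q = spec$cutoff_q,
                     model = strong_pfm$probabilities),
    calibrate_cutoff(scan_wm, q = spec$cutoff_q,
                     model = weak_pfm$probabilities))
  w <- scan_wm$width

  n_op <- spec$n_operons
  slot <- L %/% n_op
  classes <- sample(c(rep("strong", spec$n_strong),
                      rep("weak", spec$n_weak),
                      rep("activating", spec$n_activating),
                      rep("none", n_op - spec$n_strong - spec$n_weak -
                            spec$n_activating)))
  gene_strand <- sample(c("+", "-"), n_op, replace = TRUE)
  leader <- sample(spec$leader_range[1]:spec$leader_range[2], n_op,
                   replace = TRUE)
  tss <- as.integer((seq_len(n_op) - 1L) * slot + slot %/% 2L)
  start_codon <- ifelse(gene_strand == "+", tss + leader, tss - leader)
  gene_id <- sprintf("gene%03d", seq_len(n_op))

  annotation <- data.frame(gene_id = gene_id, operon_id = gene_id,
                           contig = "chr", strand = gene_strand,
                           start_codon = as.integer(start_codon),
                           tss = tss, stringsAsFactors = FALSE)
  class(annotation) <- c("gene_contexts", "data.frame")

  sample_distance <- function() {
    if (stats::runif(1) < spec$near_tss_prob) {
      as.integer(round(stats::rnorm(1, 0, spec$near_tss_sd)))
    } else {
      sample(spec$uniform_range[1]:spec$uniform_range[2], 1L)
    }
  }

  truth <- list()
  occupied <- matrix(integer(0), ncol = 2)   # planted intervals
  overlaps <- function(s, e) {
    nrow(occupied) > 0 && any(s <= occupied[, 2] & e >= occupied[, 1])
  }
  site_no <- 0L
  for (i in seq_len(n_op)) {
    cls <- classes[i]
    if (cls == "none") next
    pfm <- if (cls == "weak") weak_pfm else strong_pfm
    placed <- FALSE
    for (try in 1:100) {
      d <- sample_distance()
      g8 <- if (gene_strand[i] == "+") tss[i] + d else tss[i] - d
      site_strand <- sample(c("+", "-"), 1L)
      start <- if (site_strand == "+") g8 - 7L else g8 - (w - 8L)
      end <- start + w - 1L
      if (start < 1L || end > L || overlaps(start, end)) next
      seq_site <- sample_from_pfm(pfm$probabilities, 1L)
      genomic <- if (site_strand == "+") seq_site else
        reverse_complement(seq_site)
      genome_chars[start:end] <- dna_chars(genomic)
      occupied <- rbind(occupied, c(start, end))
      site_no <- site_no + 1L
      truth[[length(truth) + 1L]] <- data.frame(
        site_id = sprintf("site%03d", site_no), gene_id = gene_id[i],
        operon_id = gene_id[i], class = cls, contig = "chr",
        start = start, end = end, strand = site_strand,
        sequence = seq_site, g8_pos = as.integer(g8),
        dist_tss = as.integer(d),
        dist_start_codon = as.integer(
          reading_offset(g8, start_codon[i], gene_strand[i])),
        stringsAsFactors = FALSE)
      placed <- TRUE
      break
    }
    if (!placed) {
      stop("could not place a ", cls, " site for ", gene_id[i],
           " within genome bounds after 100 attempts", call. = FALSE)
    }
  }

  # decoys: random 14-mers kept below the calibrated cutoff on both strands
  for (k in seq_len(spec$n_decoy)) {
    placed <- FALSE
    for (try in 1:1000) {
      start <- sample.int(L - w + 1L, 1L)
      end <- start + w - 1L
      if (overlaps(start, end)) next
      seq_site <- paste(sample(DNA_BASES, w, replace = TRUE, prob = bg),
                        collapse = "")
      s_f <- score_window(scan_wm, seq_site)
      s_r <- score_window(scan_wm, reverse_complement(seq_site))
      if (s_f >= cutoff || s_r >= cutoff) next
      genome_chars[start:end] <- dna_chars(seq_site)
      occupied <- rbind(occupied, c(start, end))
      site_no <- site_no + 1L
      truth[[length(truth) + 1L]] <- data.frame(
        site_id = sprintf("site%03d", site_no), gene_id = NA_character_,
        operon_id = NA_character_, class = "decoy", contig = "chr",
        start = start, end = end, strand = "+", sequence = seq_site,
        g8_pos = NA_integer_, dist_tss = NA_integer_,
        dist_start_codon = NA_integer_, stringsAsFactors = FALSE)
      placed <- TRUE
      break
    }
    if (!placed) {
      stop("could not place decoy ", k, " below the scan cutoff after ",
           "1000 attempts", call. = FALSE)
    }
  }

  truth <- if (length(truth)) do.call(rbind, truth) else
    data.frame(site_id = character(), gene_id = character(),
               operon_id = character(), class = character(),
               contig = character(), start = integer(), end = integer(),
               strand = character(), sequence = character(),
               g8_pos = integer(), dist_tss = integer(),
               dist_start_codon = integer(), stringsAsFactors = FALSE)

  structure(list(genome = c(chr = paste(genome_chars, collapse = "")),
                 annotation = annotation, truth = truth,
                 scan_matrix = scan_wm, cutoff = cutoff, spec = spec),
            class = "cre_synthetic")
}

#' Generate a three-condition expression table for a synthetic dataset
#'
#' Per gene, log2 fold-change effects are drawn uniformly (on the log2
#' scale) inside the class-specific magnitude ranges of the spec, with the
#' class sign (repression for strong/weak, activation for activating,
#' random sign and sub-threshold magnitude for genes without a site).
#' Gaussian noise of `spec$noise_sd` is added on the log2 scale and the
#' result converted to the signed-ratio convention (never inside (-1, 1)).
#' Significance flags are `|fc| >= spec$threshold`, flipped with
#' probability `spec$false_flag_rate`. Deterministic under `spec$seed`
#' (offset so it is independent of the genome draw).
#'
#' @param sim a `"cre_synthetic"` from [generate_genome()] (or a truth
#'   table plus annotation in the same shape).
#' @param spec the `"synthetic_spec"`; defaults to `sim$spec`.
#' @return list with `records` (an `"expression_records"` data.frame) and
#'   `truth_fc` (per gene: class and noise-free signed log2 fold changes).
#' @export
generate_expression <- function(sim, spec = sim$spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed + 1000003L)
  ann <- sim$annotation
  truth <- sim$truth
  cls <- rep("none", nrow(ann))
  m <- match(ann$gene_id, truth$gene_id)
  cls[!is.na(m)] <- truth$class[m[!is.na(m)]]

  draw <- function(range) stats::runif(1, log2(range[1]), log2(range[2]))
  rows <- lapply(seq_len(nrow(ann)), function(i) {
    eff <- spec$effects[[cls[i]]]
    sgn <- if (eff$sign == 0) sample(c(-1, 1), 3L, replace = TRUE) else
      rep(eff$sign, 3L)
    lfc <- sgn * c(draw(eff$low), draw(eff$med), draw(eff$high))
    noisy <- lfc + stats::rnorm(3L, 0, spec$noise_sd)
    fc <- ifelse(noisy >= 0, 2^noisy, -(2^(-noisy)))
    sig <- abs(fc) >= spec$threshold
    if (spec$false_flag_rate > 0) {
      flip <- stats::runif(3L) < spec$false_flag_rate
      sig <- xor(sig, flip)
    }
    list(rec = data.frame(gene_id = ann$gene_id[i], fc_low = fc[1],
                          fc_med = fc[2], fc_high = fc[3],
                          sig_low = sig[1], sig_med = sig[2],
                          sig_high = sig[3], stringsAsFactors = FALSE),
         tru = data.frame(gene_id = ann$gene_id[i], class = cls[i],
                          lfc_low = lfc[1], lfc_med = lfc[2],
                          lfc_high = lfc[3], stringsAsFactors = FALSE))
  })
  records <- expression_records(do.call(rbind, lapply(rows, `[[`, "rec")))
  truth_fc <- do.call(rbind, lapply(rows, `[[`, "tru"))
  list(records = records, truth_fc = truth_fc)
}

#' Planted-site and affinity-label recovery
#'
#' `site_recovery()` scores a scan result against the truth table: the
#' fraction of planted (non-decoy) sites recovered by a hit at the exact
#' contig/start/strand, plus the count of hits not explained by any
#' planted site (background false positives, reported separately).
#' `label_recovery()` scores affinity calls against planted classes
#' (strong -> high_affinity, weak -> low_affinity, activating ->
#' activating).
#'
#' @param truth truth table from [generate_genome()].
#' @param hits a `"motif_hits"` data.frame.
#' @return `site_recovery()`: list with `recovered`, `n_planted`,
#'   `fraction`, `false_positives`.
#' @export
site_recovery <- function(truth, hits) {
  planted <- truth[truth$class != "decoy", , drop = FALSE]
  key <- function(ctg, s, st) paste(ctg, s, st, sep = ":")
  hit_keys <- key(hits$contig, hits$start, hits$strand)
  found <- key(planted$contig, planted$start, planted$strand) %in% hit_keys
  planted_keys <- key(planted$contig, planted$start, planted$strand)
  list(recovered = sum(found), n_planted = nrow(planted),
       fraction = if (nrow(planted)) sum(found) / nrow(planted) else NA_real_,
       false_positives = sum(!hit_keys %in% planted_keys))
}

#' @rdname site_recovery
#' @param calls an `"affinity_calls"` data.frame from [classify_cre()].
#' @return `label_recovery()`: list with `correct`, `n`, `fraction`, and
#'   the per-gene comparison table.
#' @export
label_recovery <- function(truth, calls) {
  planted <- truth[truth$class != "decoy", , drop = FALSE]
  expected <- c(strong = "high_affinity", weak = "low_affinity",
                activating = "activating")[planted$class]
  got <- calls$call[match(planted$gene_id, calls$gene_id)]
  cmp <- data.frame(gene_id = planted$gene_id, class = planted$class,
                    expected = unname(expected), call = got,
                    stringsAsFactors = FALSE)
  list(correct = sum(cmp$expected == cmp$call, na.rm = TRUE),
       n = nrow(cmp),
       fraction = mean(cmp$expected == cmp$call, na.rm = FALSE),
       table = cmp)
}

#' Write a synthetic dataset to a directory
#'
#' Emits `genome.fasta`, `annotation.tsv`, `annotation.gff3`,
#' `truth.tsv` and, when expression is supplied, `expression.tsv` and
#' `truth_fc.tsv`. Output is byte-identical for identical inputs.
#'
#' @param sim a `"cre_synthetic"`.
#' @param dir output directory (created if needed).
#' @param expression optional result of [generate_expression()].
#' @return the directory, invisibly.
#' @export
write_synthetic <- function(sim, dir, expression = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- Biostrings::DNAStringSet(sim$genome)
  Biostrings::writeXStringSet(fa, file.path(dir, "genome.fasta"))
  tsv <- function(x, name) {
    utils::write.table(x, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  tsv(as.data.frame(sim$annotation), "annotation.tsv")
  ann <- sim$annotation
  glen <- 600L  # nominal gene body length for the emitted features
  L <- nchar(sim$genome[[1L]])
  gff <- sprintf(
    "%s\tcrebox\tgene\t%d\t%d\t.\t%s\t.\tID=%s;operon=%s;tss=%d",
    ann$contig,
    ifelse(ann$strand == "+", ann$start_codon,
           pmax(1L, ann$start_codon - glen)),
    ifelse(ann$strand == "+", pmin(L, ann$start_codon + glen),
           ann$start_codon),
    ann$strand, ann$gene_id, ann$operon_id, ann$tss)
  writeLines(c("##gff-version 3", gff), file.path(dir, "annotation.gff3"))
  tsv(sim$truth, "truth.tsv")
  if (!is.null(expression)) {
    tsv(as.data.frame(expression$records), "expression.tsv")
    tsv(expression$truth_fc, "truth_fc.tsv")
  }
  invisible(dir)
}
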