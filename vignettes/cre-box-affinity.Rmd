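---
title: "Genome-wide cre-box analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genome-wide cre-box analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crebox)
```

## The biological problem

Carbon catabolite control in *Bacillus subtilis* and related low-GC
Gram-positive bacteria is exerted by CcpA, a LacI/GalR-family regulator
that, in complex with HPr-Ser-P, binds 14-nt pseudo-palindromic operators
called catabolite responsive elements (cre boxes). The cre consensus is
weak, and individual boxes differ widely in how strongly they mediate
regulation. A titration design makes those differences measurable:
expressing CcpA at three levels (low, medium, high) and comparing
transcriptomes against a no-CcpA control separates operons that respond
already at low CcpA — operationally *high-affinity* cre boxes — from
operons that respond only when more CcpA is available (*low-affinity*),
with a small third group activated rather than repressed. "Affinity" here
denotes a regulatory hierarchy inferred from titration, not a measured
dissociation constant.

`crebox` implements this analysis end to end: motif-matrix construction
and genome scanning, positional filtering around operon first genes,
three-level affinity classification from fold changes, palindromicity
statistics, per-group consensus calling, cre-to-TSS distance and
helical-phase summaries, and a seeded synthetic-data generator for
end-to-end benchmarking. The published reference set of 72 cre boxes
(31 high-affinity, 38 low-affinity, 3 activating, with fold changes,
significance flags, TSS distances and palindrome scores) ships as a
plain-text fixture and is exposed through `cre_reference_table()`.

## Motif model

An alignment of `w`-nt cre sequences (default `w = 14`) is tallied into a
position frequency matrix. With training-set size \(N\) and pseudocount
\(c\),

\[ p_{b,i} = \frac{n_{b,i} + c}{N + 4c}, \qquad
   \mathrm{lo}_{b,i} = \log_2 \frac{p_{b,i}}{q_b}, \]

where \(q_b\) is the background frequency of base \(b\). A window
\(x_1\ldots x_w\) scores \(\sum_i \mathrm{lo}_{x_i,i}\).

Parameter choices:

* **Pseudocount, default 0.5.** The training sets are small (31–69
  sequences); Laplace-style smoothing keeps log-odds finite. With
  pseudocount 0, a base absent from a column gets \(-\infty\); a window
  containing it scores \(-\infty\), which compares below every finite
  cutoff — the guarded-minimum policy. Windows containing N are
  *unscorable* and return `NA`, a sentinel distinct from any real score.
* **Background, default uniform (0.25 each).** A genome-derived
  mononucleotide background can be passed instead (the synthetic
  benchmark uses the GC content of the simulated genome).
* **Log base 2** throughout; outputs round scores to 2 decimals, internal
  computation keeps full precision.

### Consensus calling

Per column (on raw count frequencies, so the call is invariant under
duplicating the alignment): the top base is emitted if its frequency
reaches `theta_single`; otherwise the IUPAC two-base code of the top two
bases if their combined frequency reaches `theta_pair`; otherwise `N`.
Ties break alphabetically. The defaults (0.70, 0.75) were chosen because
they reproduce the discriminating calls of the published high- and
low-affinity consensus strings — G versus R at position 6 and A versus W
at position 14 — on the reference training sets. They are a documented
heuristic: the tool originally used for the published matrices does not
publish its calling rule, and one printed call (C at position 9 of the
strong consensus, a plurality below any majority threshold) cannot be
reproduced by any deterministic threshold rule, so full-string
reproduction is deliberately not claimed.

```{r consensus}
consensus_call(build_pfm(cre_reference_sequences("high")))
consensus_call(build_pfm(cre_reference_sequences("low")))
```

## Genome scanning

`scan_genome()` slides the weight matrix over both strands and reports
every window scoring at least the cutoff exactly once, sorted by contig,
start and strand. Design choices:

* **Coordinates** are 0-based half-open internally and 1-based inclusive
  in every written output (BED output is 0-based by format definition).
* **Overlaps** are all reported; no greedy masking. A perfectly
  palindromic site appears once per strand over the same interval.
* **The central-G anchor.** Distances are measured from the conserved G
  at motif position 8 (`g8_pos`): `start + 7` (0-based) on the upper
  strand, `start + (w - 8)` on the lower.
* **Cutoff calibration.** The original study used a cutoff of 8.96 on the
  internal scale of an unpublished scoring tool; that number is not
  portable to this implementation's log-odds scale. Instead,
  `calibrate_cutoff()` computes the exact score distribution of the
  matrix under a chosen per-column model (background, the motif model
  itself, or an external probability matrix) by discretized convolution,
  and returns a lower quantile: the cutoff that retains a stated fraction
  of true motif draws. The genome-wide hit counts of the original scan
  (418 sites; 200 upper / 218 lower; 161 genes in window) depend on that
  unpublished scale and an external genome build and are therefore
  treated as context, not as quantities this package reproduces; scanning
  correctness is instead established by properties (strand-mirror
  equivalence, cutoff monotonicity, exhaustive-enumeration agreement at
  small widths, and an independent `Biostrings::matchPWM` cross-check).

## Positional filtering and TSS distances

Motif hits are attached to operon first genes when the signed offset of
the central G from the first base of the start codon, *in the gene's
reading direction*, lies in the closed window `[-500, +100]`. The anchor
on the cre side is the central G for both the start-codon window and the
TSS distance (the published analysis states the G anchor for TSS
distances only; using it for the window too keeps one convention — the
original choice is not stated, so the "161 genes" figure is approximate
under any reading). Signs follow the regulated gene's reading direction,
never the cre strand; `dist = 0` means the anchor coincides with the
first base of the start codon (or with the TSS). Literature-known sites
bypass the window entirely, may lack coordinates (distances become `ND`),
and replace a predicted site at the same central-G coordinate.

## Affinity classification

With signed fold-change ratios (never in \((-1, 1)\)) and upstream
significance flags, a condition is *significant* when `|fc| >= threshold`
**and** its flag is set (default threshold 1.8; the flags encode a
p-value criterion computed upstream — when absent, the package falls back
to the magnitude criterion alone and says so). The decision tree:

1. no significant regulation at high induction → `unclassified` (the
   entry gate: the published gene selection requires regulation at least
   at the high level);
2. significant repression at low → `high_affinity`;
3. significant activation at all three levels → `activating` (all three
   published activating operons satisfy this; partial activation falls to
   `unclassified` with a warning);
4. significant repression at medium or high → `low_affinity`;
5. otherwise `unclassified`. Records significant in both directions are
   conflicting and are unclassified with a warning, never silently.

Operon counts deduplicate multi-cre operons (the reference set merges
iolA-1/iolA-2 and gntR-1/gntR-2).

```{r classify}
calls <- classify_cre(cre_reference_expression())
table(calls$call)
count_regulated_operons(cre_reference_expression(), cre_reference_operons())
```

## Palindromicity

For a 14-mer, pair \((i, 15-i)\) is palindromic when the bases are
Watson-Crick complementary; the score is the number of palindromic pairs
(0–7). Group profiles report the per-position percentage of sequences
whose pair is palindromic and the group mean score. Numerical choices:

* **Rounding is half-up** (not R's default half-to-even): percentages to
  integers, means to one decimal. This reproduces the reference-table
  arithmetic (30/31 → 97, 144/31 → 4.6).
* **Ambiguous bases** void their pair rather than erroring, so scanned
  sites containing N remain profilable.
* Width is a parameter; only evenness is required.

Two printed per-sequence score cells of the published low-affinity table
(yesL and yvdG) are mutually swapped relative to their own sequences and
residue marking, and four cells of its bottom percentage row are off by
one from the printed sequences' arithmetic; the package computes from the
sequences, so those cells differ from print by design. Group means and
every other cell agree.

## Distance and helical phase

`helical_phase()` maps a signed cre-to-TSS distance onto `[0, period)`
with a floored modulo; the default period 10.5 nt is the canonical B-DNA
helical turn (the published description says "10–11 nt"). The phase bin
width defaults to 1.5 nt. `phase_summary()` excludes `ND` distances,
conserves site counts across bins, and reports per bin and affinity group
the site count and the median \(|fc_{high}|\); an optional absolute
distance cap trims only the scatter output (far-downstream outliers are
usually dropped from such plots), the full table always being returned.
The published claim that strongly repressed sites sit at near-multiples
of a helix turn is qualitative — the quoted positions −27, −14 differ by
13 nt — so the module is descriptive and fits no periodicity model.

## Synthetic benchmark

`generate_genome()` plants cre boxes in an i.i.d. random genome and
`generate_expression()` emits a matching three-condition table; the truth
tables let `site_recovery()` and `label_recovery()` score the whole
pipeline. What it emulates, and what not:

* **Genome**: i.i.d. bases at 43.5 % GC (the *B. subtilis* value) — no
  codon structure, repeats or compositional heterogeneity, so background
  motif-like windows are rarer and more uniform than in a real genome.
* **Sites**: strong and activating sequences sampled column-wise from the
  packaged high-affinity PFM, weak from the low-affinity PFM (columns
  independent — real cre boxes may have positional dependencies); decoys
  are random 14-mers constrained below the scan cutoff. One site per
  operon; placement avoids overlaps.
* **Placement**: distance from the TSS is a mixture of a near-TSS
  Gaussian cluster (sd 15 nt, probability 0.7) and a uniform component on
  ±100 nt, mirroring the observed clustering near the TSS; leaders
  (TSS to start codon) are uniform on 20–150 nt.
* **Expression**: per-class log2 effect magnitudes are drawn uniformly
  within the ranges observed in the reference table (strong: 1.8–7.4 at
  low induction; weak: 1.8–12.2 at high, sub-threshold 1.0–1.4 at low;
  activating: the observed 2.3–6.2 band; siteless genes stay below
  threshold). Gaussian noise (default sd 0.25) is added on the log2 scale
  and converted to the signed-ratio convention; significance flags are
  `|fc| >= 1.8` with an optional false-flag rate (default 0). Microarray
  intensities, probes and normalization are not simulated.
* **Determinism**: one seed drives everything; outputs are
  byte-identical across runs.

The default conditions (200 kb genome, 50 operons, 20 strong + 20 weak +
3 activating sites, 10 decoys, noise sd 0.25) are the benchmark the test
suite runs: site recovery at exact coordinates at the calibrated cutoff
(quantile 0.005 of the planted-site score models, taken before any
recovery was measured), label recovery at zero noise and at sd 0.25. A
smaller 60 kb / 12-site configuration backs the faster unit tests; both
fit comfortably in seconds on one CPU. Passing these tests shows the
pipeline is internally consistent under its own generative assumptions —
it does not show that the fixed 1.8-fold threshold or the window bounds
are optimal for real transcriptome data.

```{r synthetic}
spec <- synthetic_spec(seed = 42L)
sim <- generate_genome(spec)
hits <- scan_genome(sim$scan_matrix, sim$genome, sim$cutoff)
site_recovery(sim$truth, hits)$fraction
expr <- generate_expression(sim)
label_recovery(sim$truth, suppressWarnings(classify_cre(expr$records)))$fraction
```

## Known limitations

* The scan cutoff is a calibration parameter, not a reproduction of the
  original tool's 8.96; genome-wide hit counts are therefore not
  comparable across implementations.
* TSS positions are inputs (`ND` allowed); the package performs no
  promoter or TSS prediction.
* Significance flags are inputs; the package performs no microarray
  normalization or hypothesis testing.
* The affinity dichotomy is operational; real cre affinities likely form
  a continuum, and the classification inherits every limitation of the
  1.8-fold + flag criterion.
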