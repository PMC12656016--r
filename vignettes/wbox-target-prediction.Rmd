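---
title: "Predicting WRKY target genes from W-box promoter scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting WRKY target genes from W-box promoter scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wboxscan)
```

## The problem

WRKY transcription factors regulate plant stress responses by binding the
W-box cis-element -- core sequence `TTGAC` followed by `C` or `T` -- in the
promoters of their target genes. Given a genome and annotation (or a
pre-extracted promoter set), `wboxscan` predicts candidate target genes of
a WRKY factor by:

1. extracting the 2000 bp upstream of each gene's transcription start,
   strand-aware (`extract_promoters()`);
2. scanning both strands of every promoter for the W-box core
   (`scan_wbox()`), extending each occurrence to a fixed 17 bp window;
3. ranking windows by occurrence frequency and keeping the 20 most
   frequent as representative W-box motifs (`rank_motifs()`);
4. approximately matching those motifs back against all promoters with a
   mismatch budget and an expectation-value filter (`collect_targets()`);
5. randomly selecting candidates for external structure prediction
   (`select_candidates()`), then gating the final report on the
   interface confidence (ipTM >= 0.8) those predictions return
   (`filter_and_report()`).

The package also implements relative qPCR quantification by the
2^-ddCt (Livak) method (`ddct()`), the standard readout for validating
predicted targets, and a synthetic-data generator
(`simulate_genome()`, `simulate_iptm()`, `simulate_ct()`) that produces
every input the pipeline consumes together with machine-readable ground
truth, so the whole procedure is testable without downloads.

## Promoter extraction

Promoters are defined as the 2000 bp immediately upstream of the
transcription start, on the gene's own strand. The gene feature's 5' end
stands in for the transcription start: `start` for `+` genes, `end` for
`-` genes (GFF3 coordinates, 1-based inclusive). Minus-strand promoters
are reverse-complemented at extraction so that "upstream" always reads
5'->3' toward the TSS; every downstream coordinate (scan offsets, match
spans) then lives in this uniform promoter frame. Genes closer than
2000 bp to a contig edge yield a shorter promoter with `truncated = TRUE`
-- never padded, since padding belongs to window extension where the
sequence context genuinely runs out. Overlapping genes are handled
independently; no masking is applied.

## Window geometry

The scanner reports every core occurrence on either strand (overlapping
occurrences included; `N` never matches) and extends each into a fixed
17 nt window: 4 nt of upstream flank, the 6 nt core, and 7 nt of
downstream flank, with `N` filling positions that fall outside the
promoter. A symmetric 4 bp extension of a 6 nt core would give only
14 nt; the extra 3 nt are placed downstream so that the window length is
exactly 17 while the upstream extension stays at 4 bp. Both flanks are
configurable (`upstream_flank`, `window_len`). For minus-strand sites the
window is taken on the reverse complement of the promoter, so the core
always reads `TTGAC[C/T]` inside the window and windows from the two
strands are directly comparable text.

Ranking counts windows by exact text identity. A window and its reverse
complement are distinct keys -- the two orientations are reported as
separate columns downstream, so canonicalising would lose information.
Ties are broken lexicographically (the choice is arbitrary but must be
deterministic). Windows containing `N` are edge artefacts: they are
counted, but only fill ranks after every `N`-free window.

## Approximate matching and the E-value model

The matcher re-implements a short-query ungapped search with explicit
tolerances: a hit is any placement of a contiguous motif substring on a
promoter (either strand) with at most 2 internal mismatches. Substrings
arise by trimming terminal bases: none, or 2-6 nt in total split freely
between the two ends. We read the "2-6 nt length variation" tolerance as
terminal trimming rather than indels because internal mismatches are
budgeted separately and gapped alignment of an 11-17 nt query is not
meaningful. Trimmed bases are not mismatches; promoter `N` is. The same
promoter interval reachable through different trims is collapsed to its
lowest-mismatch representation.

Each hit carries an E-value: the expected number of chance hits of equal
or better quality in a search of the same size against an i.i.d.
background. With background composition $f$, the probability that a
random background base matches a query base (itself drawn from $f$) is
$p = \sum_b f_b^2$ (0.25 for uniform, ~0.27 for the AT-rich default of
the generator), and

$$E = N \cdot \sum_{j=0}^{k} \binom{L}{j} (1-p)^j p^{L-j}$$

for span $L$, mismatch budget $k$, and $N$ search trials. $N$ counts
every distinct trial for that span class: placements across the promoter
set, times two strands, times the number of distinct motif substrings of
that length ($17 - L + 1$). Including the substring multiplicity matters:
it is what makes the E-value an honest expectation, so that on
background-only sequence the observed mean chance-hit count per motif
stays at or below the cutoff (the calibration test verifies this by
Monte Carlo). Karlin-Altschul statistics are deliberately not used; they
are ill-behaved for ungapped 11-17 nt queries. The default cutoff is
E <= 2, and hits are filtered per class at their own mismatch count.
Best-hit selection per gene orders by E-value, then mismatches, then
span (longer first), then position (leftmost first) -- every tie-break
explicit so results are reproducible.

## Candidate selection and the ipTM gate

Structure prediction of protein-DNA complexes is expensive, so a random
subset of candidate sequences (default 30, sampled uniformly without
replacement under an explicit seed) is sent to an external predictor.
The predictor's interface confidence (ipTM, a [0,1] score for the
modelled protein-DNA interface) is ingested from a two-column TSV and
the report keeps rows with ipTM >= 0.8 (inclusive). The gate is an
explicit, optional stage: passing it is evidence of a plausible binding
interface, not proof of regulation. The package ships a published
29-row TrWRKY41 site table (`trwrky41_sites()`) whose ipTM values span
[0.80, 0.86]; all 29 reverse-complement entries are reproduced exactly
by `reverse_complement()`, which the test suite asserts. Note the
selection default is 30 while the shipped table has 29 rows; the table
is packaged verbatim and the default left at 30.

## Relative expression (2^-ddCt)

`ddct()` implements the plain Livak form: replicate Ct values are
averaged on the Ct scale per (sample, gene); `delta_ct` subtracts the
reference gene within each sample; `ddct` subtracts the calibrator
sample; the fold change is `2^-ddct`, so the calibrator is 1 by
construction. No amplification-efficiency correction is applied. Adding
a constant to every Ct in a sample cancels in `delta_ct`, which the
property tests exercise.

One statistical subtlety: under Gaussian Ct noise the fold estimate is
log-normally distributed, so its arithmetic mean carries a multiplicative
Jensen term $e^{(\sigma_{\Delta\Delta Ct}\ln 2)^2/2}$ (about +1.3% at
sd 0.2 with 3 replicates). The estimator is exactly unbiased on the
log2 scale, and that is where the recovery tests assert unbiasedness;
the arithmetic-scale deviation is checked only to be small.

## What the generator emulates -- and what it does not

`simulate_genome()` builds multi-contig genomes with genes on both
strands, each with a full-length promoter clear of contig edges, over an
i.i.d. background whose default composition is AT-rich
(A = T = 0.32, C = G = 0.18), typical of Arabidopsis intergenic
sequence and deliberately non-uniform so the E-value model is exercised
off the easy case. Planted motif copies are recorded with exact offsets,
strands and mutated positions. Two design rules keep the ground truth
exhaustive:

* mutations are confined to the central zone of the motif (positions
  7-11 of 17 under the default trim margin) that no admissible terminal
  trim can remove, so a copy planted with $k$ mismatches is seen with
  exactly $k$ mismatches at every allowed span;
* accidental W-box cores -- in the background, at splice junctions, or
  created by a mutation -- are scrubbed by bounded rejection/repair
  (this is on by default and can be disabled for realism).

Real promoters are not i.i.d.: they contain repeats, CpG structure,
TATA context, and naturally clustered W-boxes, and real W-box function
depends on chromatin context the sequence alone cannot show. Passing
tests on synthetic data therefore demonstrates the correctness of the
procedure (coordinates, tolerances, statistics, determinism), not the
biological accuracy of any particular prediction.

All randomness flows through explicit integer seeds into R's default
Mersenne-Twister stream, with the caller's RNG state saved and restored,
so outputs are byte-identical across runs and platforms and no function
has hidden global state.

## Numerical and degenerate-input choices

* Coordinates: 1-based inclusive at the GFF3/FASTA interface, 0-based
  half-open internally and in BED output.
* A gene at `tss = 1` on `+` yields a zero-length truncated promoter,
  not an error.
* Fewer distinct windows than `k` in ranking, or fewer candidates than
  `n` in selection: return everything with a warning.
* `evalue()` saturates at `n_positions` when the mismatch allowance
  reaches the span length.
* ipTM values outside [0,1], duplicate gene ids, and missing reference
  genes are hard errors; a report row without an ipTM entry is an error
  unless `allow_missing = TRUE`.

## Problem sizes

The shipped tests and the acceptance script run the full pipeline on
30 genes with 2000 bp promoters (the scale at which every stage's
contract is observable), brute-force oracle comparisons on promoters up
to 500 nt, E-value calibration on 20 replicates of background-only sets,
and 1000 simulation replicates for fold-change recovery. These sizes are
the package's own choice of a thorough desk-scale exercise.

## A worked example

```{r example, eval = FALSE}
plant <- data.frame(motif = "TTGACC", copies = 20L, mismatches = 0L,
                    strand = "random")
sim <- simulate_genome(sim_config(seed = 1, n_genes = 20L,
                                  plant_spec = plant))
promoters <- extract_promoters(sim$genome, sim$genes)
sites <- scan_wbox(promoters)
ranked <- rank_motifs(sites, k = 20L)
params <- match_params(background = c(A = .32, C = .18, G = .18, T = .32))
targets <- collect_targets(ranked, promoters, params)
report <- filter_and_report(
  data.frame(gene_id = targets$gene_id,
             sequence = hit_site_sequence(targets, promoters)),
  setNames(simulate_iptm(targets$gene_id, seed = 2)$iptm, targets$gene_id))
head(report)
```

## Known limitations

* The TSS proxy is the annotated gene 5' end; transcript-level isoforms
  and alternative starts are out of scope.
* Matching is ungapped by design; true indel variants of a site are
  only found if a trimmed exact-length placement survives the budget.
* The E-value background model is i.i.d.; compositional heterogeneity
  along real promoters makes chance-hit rates locally higher or lower
  than the global expectation.
* ipTM scores are ingested, never computed; the package takes no view
  on the structure predictor's reliability.
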