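---
title: "Methods: phase-comparison statistics for the blastogenetic cycle"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phase-comparison statistics for the blastogenetic cycle}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blastodyn)
```

## The problem

Colonies of the ascidian *Botryllus schlosseri* cycle weekly through three
blastogenetic phases: mid-cycle (MC), pre-take-over (preTO) and take-over
(TO), the phase in which the adult zooids are resorbed and replaced by their
buds. The design this package analyses samples five colonies, each split
into three genetically identical subclones, one sequenced per phase —
fifteen libraries in all, with replication supplied by colonies and pairing
supplied by subcloning. The questions are (i) which genes change expression
between consecutive phases, (ii) how whole functional categories (GO terms)
reorganise their regulation across the cycle, and (iii) what to make of
assembled transcripts that do not map to the reference annotation.

## Pairwise differential expression on count pairs

Within one colony, a gene's reads in the two phase libraries are modelled as
Poisson counts proportional to the library totals: `c_A ~ Pois(n_A * lambda_A)`,
`c_B ~ Pois(n_B * lambda_B)`, with the null `lambda_A = lambda_B`. Two tests
are combined:

* **Fisher's exact test** on the 2x2 table
  `[[c_A, n_A - c_A], [c_B, n_B - c_B]]`, two-sided by the probability-mass
  rule — the p-value sums the hypergeometric probabilities of all tables
  with the observed margins whose probability does not exceed the observed
  table's. Ties are resolved with a relative tolerance of `1e-7` (the same
  convention as `stats::fisher.test`, which serves as an independent
  cross-check in the test suite). When the observed table is the modal one
  the sum covers the whole support and the p-value is returned as exactly 1.
* **Likelihood-ratio G-test**: with the pooled rate
  `p = (c_A + c_B) / (n_A + n_B)` and expectations `E_A = n_A p`,
  `E_B = n_B p`,
  `G = 2 [ c_A ln(c_A / E_A) + c_B ln(c_B / E_B) ]` (convention
  `0 ln 0 = 0`), referred to a chi-square distribution with 1 df. This is
  the profile likelihood ratio of the Poisson pair; the suite verifies the
  closed form against numeric maximisation of the Poisson log-likelihoods
  to `1e-8`. The degenerate pair `c_A = c_B = 0` returns `G = 0, p = 1`
  rather than an error.

**Combination rule.** The published analysis "integrates" both tests
without stating how. The default here requires *both* to reject at
`alpha = 0.05` (agreement-based, conservative); `mode` can relax this to
either test alone or their union. P-values are used raw at 0.05, matching
the published threshold; a Benjamini–Hochberg flag exists but is off by
default for the same reason.

**Normalisation** is by library totals only — the assumption of the count
pair tests. No TMM or median-ratio scaling is applied, deliberately: the
implementation reproduces the published method, not an improved one.

## Replicate consensus (minimum clues)

Per-colony calls for a gene and comparison are collapsed by the
minimum-clues rule with default `min_clues = 3` of 5: the consensus is `up`
when at least 3 colonies call `up` *and* strictly more call `up` than
`down`; symmetrically for `down`; otherwise `ns`. Requiring a same-direction
majority (not just any 3 significant replicates) resolves the ambiguity of
"confirmed by at least 3 of 5": a direction-mixed gene is not a coherent
call, and a tie can never be directional. Colonies missing a phase reduce
`n_replicates` for that gene instead of aborting the analysis.

## Category dynamics: GRV and GNV

For a GO category with `D1/U1` down/up genes in the first of two consecutive
comparisons and `D2/U2` in the second:

```
GRV = [ (D1 - D2) + (U2 - U1) ] / [ D1 + D2 + U1 + U2 ]
GNV = [ (D2 + U2) - (D1 + U1) ] / [ D1 + D2 + U1 + U2 ]
```

Both lie in `[-1, 1]`; GRV reaches 1 when a category flips from all-down to
all-up across the transition, GNV measures the change in how many genes are
involved at all. A category absent from both comparisons has a zero
denominator; it is reported with `NA` metrics and `selected = FALSE` rather
than dropped, for auditability.

**Selection rule.** The published criterion "GRV and GNV > |0.9|" cannot be
a conjunction: the publication's own flagship category (ATPase activity,
39/0 then 1/51) has `GRV = 89/91 ≈ 0.978` but `GNV = 13/91 ≈ 0.14`. The
default is therefore `|GRV| > tau OR |GNV| > tau` with `tau = 0.9`,
configurable to AND. "Most represented" categories are ranked by the total
DE-gene count `D1 + U1 + D2 + U2`, descending. Consecutive pairs default to
the temporal succession (preTO vs MC, TO vs preTO) and
(TO vs preTO, MC vs TO); comparison order is preserved through the pipeline
rather than sorted lexically, so the succession survives into the dynamics
table.

## Transcript recovery

**ORF scan.** All three forward-strand reading frames are scanned (reverse
complement optionally); within a frame, candidates are the maximal codon
runs bounded by stop codons or the sequence termini: `complete`
(ATG ... stop), `open3` (ATG, no stop before the 3' end), `open5` (run from
the 5' terminus ending at a stop, no ATG), `open_both` (neither). An
interior start-less run between two stops is not a candidate. Coordinates
are 0-based half-open; the stop codon lies inside the interval but is
excluded from `aa_length`. The transcript's class is that of its best
candidate — longest in amino acids, ties broken by smaller start, then
lower frame index, forward strand first — or `none` when no candidate
reaches `min_aa`.

**Coding-potential proxy.** The published pipeline delegated coding
potential to an external predictor; here the dominant criterion of such
predictors — minimum ORF length — stands in for it, with
`min_aa = 100` codons by default and configurable. Forward-strand-only is
the default because assembled transcripts are orientation-resolved.

**Taxonomy inheritance.** Hits above `evalue_max = 1e-5` are discarded;
each transcript inherits the taxon of its best remaining hit (lowest
e-value, then highest bitscore, then first occurrence). Summaries report
per-taxon counts, proportions, and whole-number percentages; tightening the
threshold can only shrink the assigned set.

## The synthetic-data generator

The generator emulates the study design so every stage is testable without
the deposited sequencing data: 5 colonies x 3 phases, one library each,
expected depth `library_size = 1e6` reads (the real depths are unpublished;
one million reads per library is a plausible scale for this design and the
default is configurable).

Counts for gene `g` in sample `s` are Poisson with mean
`N_s * theta_g * 2^offset(g, phase(s)) * eps(g, colony(s))`:

* `theta_g`: log-normal baseline relative abundance (`sdlog = 1`, a typical
  RNA-seq spread), normalised to sum to 1;
* phase offsets implement *cyclic* differential expression: a DE gene has
  one phase offset by a signed `log2FC` whose magnitude is uniform on
  `log2fc_range` (default 0.5–3). Transition effects are offset
  differences, so the three log2 effects of a gene sum to zero around the
  weekly cycle and each DE gene is non-null on exactly two of the three
  transitions. The per-gene DE probability is `de_fraction * 3/2`, making
  each single transition's expected non-null fraction equal `de_fraction`;
* `eps`: mild log-normal colony effect (`sdlog = 0.05`) shared by the three
  subclones of a colony. Because it is shared within the colony, the
  within-colony conditional tests remain exactly valid under the null —
  the replicate structure adds biological variability between colonies
  without corrupting the paired test.

**Mass balance.** Up/down signs are not assigned independently: within each
phase the signs are chosen by a greedy balancing pass (largest potential
contributions first) so the expected transcriptional mass
`sum_g theta_g * 2^offset` is the same in every phase, while the drawn
`|log2FC|` magnitudes are kept exactly. The proportion-based tests assume a
constant total output per library; with independently random signs the
heavy-tailed abundance distribution lets a handful of abundant DE genes
shift a phase's total by several percent, which biases *every null gene's*
proportion in that phase coherently across colonies and inflates consensus
false calls. Balancing is therefore part of the model the analysis assumes,
not a tuning knob. Real biology may well violate it — a take-over colony
undergoing mass apoptosis plausibly changes total output — and that is one
reason passing tests on synthetic data do not certify the method on real
libraries (see Limitations).

GO annotation: each gene carries 1–4 terms; a configurable fraction of
terms is *coherent* — their members are drawn from genes sharing one
(phase, direction) DE pattern, so all DE members agree in direction in
every comparison (vacuously coherent terms fall back to null genes when a
pattern pool is empty). Toy transcripts are built per completeness class
from a `TAGA`-repeat UTR filler (stop codons in every frame, no ATG) and
`C/G`-only codon interiors (no start or stop can arise in any frame), so
truth labels hold by construction, independently of the classifier. The hit
table plants a strictly best significant hit per assigned transcript, plus
worse decoys, transcripts with only insignificant hits, and transcripts
with none.

Identical seeds give bit-identical datasets; all randomness flows through
`set.seed` on the configured seed (the transcript and hit generators re-seed
deterministically so they are reproducible standalone or within
`simulate_experiment`).

## Numerical and degenerate-input choices

* Fisher tie tolerance `1e-7` relative; modal observed table returns
  exactly 1; empty table (both counts 0) returns 1.
* `0 * log 0 = 0` in the G statistic; `G` clamped at 0 against negative
  rounding at the null.
* Zero-denominator GRV/GNV return `NA` sentinels, never throw.
* Consensus ties (`support_up == support_down`) are always `ns`.
* Taxonomy ties: e-value, then bitscore, then input order.
* ORF ties: length, start position, frame index, strand.
* Sequences shorter than one codon yield no candidates; an empty
  annotation map, an empty call list, and an invalid configuration raise
  immediate errors rather than propagating silently.

## Problem sizes used by the test suite

Unit tests run on 300-gene experiments at depth 1e5. The statistical
guarantees are checked at the design scale: type-I error on 5,000 genes at
depth 1e6 (25,000 per-colony tests per comparison); consensus sensitivity
and false-call rate on 2,000 genes at depth 1e6; the Fisher sweep
enumerates all 2x2 tables with both totals at most 30; the GRV/GNV property
sweep covers all count quadruples with entries at most 20. These sizes make
the whole suite run in well under a minute while keeping the binomial error
of the measured rates small against the asserted bounds.

## Limitations

* The simulator draws Poisson counts with shared colony effects; it does
  not model gene-wise overdispersion beyond that, length bias, GC bias,
  mapping ambiguity, or isoforms — so passing recovery tests bounds the
  method's behaviour under its own assumptions, not under real library
  noise.
* Raw p-values at 0.05 follow the published procedure; with tens of
  thousands of genes the per-comparison false-call control comes from the
  replicate-consensus step, not from multiple-testing correction.
* The minimum-ORF-length proxy for coding potential ignores hexamer
  composition and homology evidence; a transcript with a long spurious ORF
  will be kept.
* Mass balance (above) is an assumption of the analysis, asserted by the
  generator; on real data a global shift in transcriptional output between
  phases would surface as coherent false calls in abundant genes.
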