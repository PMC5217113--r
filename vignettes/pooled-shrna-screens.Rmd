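---
title: "Analysing pooled in vivo shRNA screens with poolscreen"
author: "poolscreen authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing pooled in vivo shRNA screens with poolscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolscreen)
```

## The experiment this package models

A pooled shRNA screen delivers a library of hairpin constructs — typically
3–5 distinct constructs per gene, across positive-control, negative-control
and test genes — into a selective environment: here, germ cells of the living
mouse testis, transfected at low efficiency (1–5%) so that each cell carries
at most one construct. Cells whose construct knocks down a gene required for
survival or differentiation drop out of the population. After selection, the
integrated constructs are PCR-amplified from tissue DNA and sequenced; the
relative abundance of each hairpin, compared with the sequenced input pool,
measures the fitness cost of knocking its target down.

`poolscreen` implements the complete analysis of such a screen, plus a
generative simulator that stands in for deposited raw data so every stage is
testable against known ground truth.

## From reads to counts

Reads are assigned to constructs by **exact substring matching of the
designated unique half of each hairpin sequence**, with no mismatches. The
manifest carries this unique sequence explicitly (column `unique_seq`) rather
than deriving it from the full hairpin, which removes any ambiguity about
which arm is "unique". `build_matcher()` refuses manifests in which one
search sequence is contained in another, in either orientation, because exact
matching would then be ill-defined; `count_reads()` searches both the read
and its reverse complement (amplicons may be sequenced in either
orientation), counts a read for a construct only when exactly *one*
construct matches, and tallies everything else as unmapped or multimapped.
The conservation identity `mapped + unmapped + multimapped = total` holds for
every library. Base qualities are ignored — the matching criterion is the
called sequence only.

Multimapped reads are discarded and reported, never fractionally assigned:
with a collision-free manifest they indicate chimeric amplicons or library
contamination, i.e. a QC signal rather than a quantity.

## Quantification

Each biological sample is sequenced as 3–5 technical libraries from separate
DNA aliquots. These are collapsed by the **per-construct median** (mean of
the two central values for an even number), which is robust against a single
jackpotted library. Counts are then normalized to **reads per million** and
expressed as the **log2 fold change against the sequenced input pool** of the
same pool design — the actual injected material, so that composition noise in
pool preparation cancels. Fold-change matrices from different experiments
that share a pool design may be merged column-wise to gain biological
replicates, each experiment normalized to its own input library.

A **pseudocount of 0.5** (configurable) is added to every construct's count,
in both the sample and the reference, before normalization. The pseudocount
is folded into the RPM denominator, so normalized tables always sum to one
million. This keeps fold changes finite for dropout constructs with minimal
bias and no directional artifact; with pseudocount → 0, RPM and fold changes
are exactly invariant to sequencing depth.

## Hit calling

Each construct's fold changes across biological replicates are compared with
the pooled fold changes of all **negative-control constructs** (hairpins
against genes believed irrelevant to the phenotype) by a **Wilcoxon rank-sum
test**. Pooling the null across constructs and replicates maximizes the null
sample that a small control set can provide; a negative-control construct
under test is excluded from its own null. The test is two-sided by default,
with the direction (depleted/enriched) taken from the sign of the construct's
median fold change relative to the null median; exact zero ties are
`neutral` and never count as depletion.

P-values are exact (by enumeration of the Mann–Whitney null distribution)
when the two samples together hold at most 12 values and there are no ties;
otherwise the normal approximation with tie and continuity corrections is
used — the same regime standard tooling applies at these sample sizes. This
choice has a consequence worth knowing: at nine replicates against a pooled
null of ~130 values the approximation's attainable size at a nominal
`p <= 0.01` is about 0.008–0.01, i.e. slightly conservative, and at one or
two replicates the smallest attainable approximate p-value exceeds 0.01
entirely. The latter is why stringent design curves show *no significant
calls below three biological replicates* — a genuine property of this test
at these sample sizes, reproduced by the package.

Genes are called essential by the **two-hit rule**: at least two distinct
constructs independently significantly depleted (`min_hits = 2`). Enriched
constructs never contribute. Under independence the chance of a spurious
two-hit gene is `alpha^2 = 1e-4` at `alpha = 0.01` in the simple pairwise
reading; `two_hit_null_probability()` also offers the
`binomial_at_least_2` mode, `P(X >= 2), X ~ Bin(k, alpha)` (~9.8e-4 for
k = 5), which accounts for the number of constructs per gene. Both are
provided because the pairwise figure understates the tail for multi-construct
genes by roughly a factor `choose(k, 2)`.

No multiple-testing correction is applied by default — the two-hit rule *is*
the error control in this design — but Benjamini–Hochberg is available
behind `inference_config(p_adjust = "BH")`.

Control genes turn the calls into error-rate estimates:
`control_performance()` reports the false negative rate over positive-control
genes and the false positive rate over negative-control genes (e.g. 14 of 17
positives detected is an FNR of 17.6%, printed as 18% at integer precision;
1 of 8 negatives called is an FPR of 12.5%), plus the fraction of
positive-class constructs showing significant *enrichment*, a normalization
artifact worth monitoring.

## Design analyses

`replicate_subsample_curve()` reruns the construct tests on random subsets of
the replicate columns and records, per significance cutoff, the smallest
`|median log2 fold change|` among significantly depleted constructs — the
*minimum detectable effect size* — summarized as median ± SD across draws
(200 by default; all subsets are enumerated when fewer exist). Because this
is an extreme statistic of one screen, a single realization can jump where
few constructs straddle the detection boundary; averaging the medians over a
handful of simulated screens gives a stable estimate of the design curve.

`downsample_counts()` implements binomial read thinning (every read kept
independently with probability target/current — exactly uniform read
subsampling), and `coverage_power_curve()` reruns the whole pipeline on
thinned technical libraries to trace detection power (the fraction of
positive-control genes called essential) against mean reads per construct.
Thinning at the observed coverage is the identity, so the curve's top end
equals the plain pipeline result exactly.

`screen_capacity()` is the planning arithmetic: with `N` cells, transfection
efficiency `e` and a required `c` independently transfected cells per
construct, the screen supports `floor(N e / c)` constructs — e.g. 10^8 testis
cells at 1% efficiency and 100 cells/construct support 10,000 constructs, or
2,000 genes at five constructs per gene; a 119-construct pilot library then
averages `floor(10^6 / 119) = 8403` cells per construct.

## The simulator

`simulate_screen()` generates a screen from explicit biological mechanism,
per biological replicate:

1. **Transfection** — `Binomial(n_cells_total, efficiency)` cells receive
   exactly one construct each (strict low MOI, as a 1–5% efficiency
   guarantees), assigned multinomially by the input-pool weights.
2. **Selection** — each cell survives with probability
   `min(1, 2^(s + eps))`, where `s` is the construct's log2 selection effect
   and `eps ~ N(0, bio_sd)` is drawn per construct per replicate
   (replicate-level biological noise, default SD 0.3). Selection acts once
   between transfection and harvest; stage structure within spermatogenesis
   is deliberately not modelled, since the readout is a single post-selection
   time point.
3. **Library preparation** — per technical library, every construct's
   surviving lineage count is multiplied by a mean-1
   `Gamma(jackpot_shape, jackpot_shape)` factor modelling PCR jackpotting
   (default shape 2; smaller = stronger jackpotting), then
   `mean_coverage x n_constructs` reads are drawn multinomially.

The input pool is sequenced directly from the pool weights with no jackpot
step: jackpotting is a low-template artifact, and the plasmid pool is
template-rich. All randomness flows from one seed; the same configuration
reproduces the same screen bit for bit.

`make_pilot_like_config()` assembles the standard validation scenario: a
119-construct pool (17 positive-control genes with 83 constructs, 8
negative-control genes with 36, mode five constructs per gene), nine
biological by three technical replicates, 2% transfection efficiency of 10^8
cells, 5000 reads per construct. Each positive-gene construct is an
effective knockdown with probability 0.55; effective constructs draw their
selection effect from a folded normal `-|N(3, 1.25)|`, so knockdown strength
varies continuously — RNAi efficacy does, and a continuum of effect sizes is
precisely what minimum-detectable-effect and coverage–power analyses measure.
The inert fraction (0.45) was set once, from the closed-form two-hit
arithmetic: a per-construct significance probability near 0.52 makes the
expected number of detected positive genes `15 P(Bin(5,.52) >= 2) +
2 P(Bin(4,.52) >= 2) ≈ 14` of 17, an FNR near 18%, matching the
noneffective-RNAi failure mode such screens report.

### What the simulator does and does not capture

Passing tests on simulated screens demonstrate that the pipeline recovers
known ground truth under this generative model: multinomial sequencing noise,
gamma-overdispersed PCR amplification, lognormal replicate noise, low-MOI
transfection sampling. They do not certify behavior under features the
simulator deliberately omits: off-target shRNA effects (inert constructs are
exactly neutral here, never misdirected), cell-type composition and
stage-specific expression in the tissue, transfection-efficiency
heterogeneity between replicates (the source of the positive-construct
*enrichment* artifact observed in real screens, which the simulator does not
reproduce), or cross-contamination between libraries. One visible
consequence: in simulation the coverage–power curve stays flat down to a few
reads per construct and collapses only below ~1 read per construct, whereas
real screens lose power somewhat earlier; the median-of-technical-replicates
plus pseudocount preserve rank information longer than real library noise
does.

## Numerical and degenerate-case choices

- Even-sized medians use the mean of the central pair (the standard sample
  median).
- An all-zero count table with pseudocount 0 is an error; with a positive
  pseudocount it normalizes to the uniform RPM table.
- A fold-change matrix that is identically zero yields `p = 1`, direction
  `neutral`, no calls (degenerate null variance is treated as absence of
  evidence).
- Thinning with target equal to current coverage returns the table unchanged
  (identity, not a resample); a target above current is an error.
- Test problem sizes throughout the package's own suite are chosen desk-scale
  (hundreds of simulated screens, 200 subsample draws) — enough for the
  binomial confidence bounds asserted, small enough to run in minutes.

## Limitations

- The rank-sum approximation is mildly conservative at `alpha = 0.01` with
  nine replicates (attainable size ~0.008–0.010); exact enumeration at these
  null sizes would be calibrated but would also change the low-replicate
  behavior away from what screens of this design actually report.
- The pooled null treats negative-control fold changes as exchangeable
  across constructs and replicates; replicate-matched or construct-stratified
  nulls are not implemented.
- Gene-level inference is the two-hit count rule only — no p-value
  combination, rank aggregation or shrinkage estimators, by design.
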