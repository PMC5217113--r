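# poolscreen

Analysis of pooled shRNA screens with an amplicon-sequencing readout, built
for in vivo screens of germ cell development in mouse testis but applicable
to any pooled knockdown screen of the same design.

## The problem

A pooled screen transfects a library of shRNA constructs (3–5 per gene,
spanning positive-control, negative-control and test genes) into a selective
environment at low efficiency, so each cell carries at most one construct.
Constructs knocking down genes the selected cells need drop out of the
population. Sequencing the integrated hairpins before and after selection
turns gene essentiality into a count comparison — but one buried under PCR
jackpotting, replicate noise, and the small size of the negative-control set
that defines "no effect".

`poolscreen` implements the complete chain:

1. **Counting** — reads are assigned to constructs by exact matching of each
   hairpin's unique half-sequence, both orientations, no mismatches; ambiguous
   reads are tallied as multimapped, never apportioned.
2. **Quantification** — technical replicates collapse to the per-construct
   median; counts become reads per million with a 0.5 pseudocount; each
   biological replicate is expressed as log2 fold change against the
   sequenced input pool: `log2FC = log2(RPM_sample / RPM_input)`.
3. **Inference** — each construct's fold changes across replicates are tested
   against the pooled negative-control fold changes with a Wilcoxon rank-sum
   test; a gene is called essential by the two-hit rule (≥ 2 constructs
   independently depleted at `p ≤ α`, spurious at rate `α² = 10⁻⁴` for
   `α = 0.01` under independence). Control genes yield false negative / false
   positive rate estimates.
4. **Design analysis** — minimum detectable fold change vs number of
   biological replicates (by subsampling), detection power vs read coverage
   (by binomial thinning), and screen-capacity arithmetic.
5. **Simulation** — a generative model of the whole experiment (low-MOI
   transfection, per-construct selection `2^s`, lognormal replicate noise,
   gamma PCR jackpotting, multinomial sequencing) with known ground truth.

## Worked example

Simulate a pilot-scale screen (119 constructs, 17 positive and 8
negative-control genes, nine testes × three sequencing libraries, 5000
reads/construct) and analyse it:

```r
library(poolscreen)
cfg <- make_pilot_like_config(seed = 5)
scr <- simulate_screen(cfg)
res <- analyze_screen(scr, config = inference_config(alpha = 0.01, min_hits = 2))
res$performance
```

```
Screen performance against control genes
  positives: 14/17 called essential  -> FNR 17.6%
  negatives: 0/8 called essential  -> FPR 0.0%
  positive-class constructs enriched: 1/83 (1.2%)
```

14 of 17 positive-control genes are recovered (a false negative rate of
17.6% — the screen design's expected cost of noneffective RNAi) and no
negative-control gene is called. `res$gene_calls` holds the per-gene table:

```
  gene n_constructs n_depleted_significant n_enriched_significant essential_call
   BAX            5                      3                      0           TRUE
   CSF            5                      4                      0           TRUE
   KIT            5                      3                      0           TRUE
  PIN1            5                      3                      0           TRUE
 CPEB1            5                      3                      1           TRUE
  MLH3            5                      3                      0           TRUE
```

Planning arithmetic for scaling the screen up:

```r
screen_capacity(1e8, 0.01, min_cells_per_construct = 100,
                constructs_per_gene = 5, library_size = 119)
```

```
Screen capacity: 1e+06 transfected cells
  mean cells per construct at current library size: 8403
  max constructs: 10000  -> max genes: 2000
```

At 1% transfection of 10⁸ testis cells, a 119-construct pilot averages 8403
cells per construct; requiring 100 cells per construct supports 10,000
constructs, i.e. 2,000 genes at five constructs each.

A command-line front end (`inst/cli/poolscreen.R`) exposes the stages as
subcommands (`simulate`, `count`, `quantify`, `test`, `power`, `run`), and
`run_full_pipeline()` executes the whole analysis from a JSON/YAML
configuration, writing TSV results, a performance JSON and a markdown report.

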