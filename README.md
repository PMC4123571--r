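# macadna

Fuzzy multiple-attractor cellular-automata (MACA) classifiers for DNA
functional regions: promoter, exon, intron and 3′UTR, with sliding-window
boundary calling. The package is aimed at people studying attractor-based
sequence classification — it provides the CA engine, the immune-inspired
trainer, feature encoders, a synthetic benchmark generator, evaluation
metrics and a command-line interface in one place.

## The model in brief

A fuzzy CA is a vector of cells $q_1,\dots,q_n \in [0,1]$ updated
synchronously by three-neighbourhood rules. Each supported rule is a
*bounded sum* of a subset of $(q_{i-1}, q_i, q_{i+1})$:

| rule | next state |
|------|-----------------------------|
| 254  | min(1, q₋ + q + q₊) |
| 252  | min(1, q₋ + q) |
| 238  | min(1, q + q₊) |
| 250  | min(1, q₋ + q₊) |
| 204  | q (identity) |
| 240  | q₋ |
| 170  | q₊ |

plus a complemented variant (1 − bounded sum) of each. A per-cell rule
assignment ⟨r₁,…,rₙ⟩ is a *rule genome*; iterating it drives any state
into an attractor (fixed point or cycle), and the basins of those
attractors act as class regions. Non-complemented genomes have a linear
form: one step is min(1, T·P(t)) for a banded 0/1 matrix T.

Training is by clonal selection: candidate genomes ("antibodies") are
scored on encoded, labelled sequences ("antigens") by basin-majority
classification accuracy, cloned proportionally to rank, mutated inversely
to affinity, and kept in an elitist memory population — with a
reservoir-recycling twist in which high-affinity leftover clones compete
for reservoir slots instead of being discarded. Sequences are encoded as
fixed-length feature states (TATA/CAAT/Inr consensus scores, codon
position asymmetry, hexamer bias, splice-anchored dinucleotides, …),
quantized to a 0.25 grid so basins are shared and finite. See
`vignettes/maca-methods.Rmd` for the full account.

## Worked example

The CA engine, on the engine's reference rule vector ⟨170, 238, 204⟩:

```r
library(macadna)
g <- rule_genome(c(170, 238, 204))
ca_evolve(g, c(0, 0.25, 0.50))
#> P(0) = (0.00, 0.25, 0.50)
#> P(1) = (0.25, 0.75, 0.50)
#> P(2) = (0.75, 1.00, 0.50)
#> P(3) = (1.0, 1.0, 0.5) *
#> attractor: period 1, entered at step 3
transition_matrix(g)
#>      [,1] [,2] [,3]
#> [1,]    0    1    0
#> [2,]    0    1    1
#> [3,]    0    0    1
```

Cell 2's second step is min(1, 1.0 + 0.5) — sums clamp at 1 — and from
step 3 the state (1, 1, 0.5) reproduces itself: a fixed-point attractor.

The full pipeline on synthetic data (40 records per class, 70/30 split):

```r
ds  <- generate_dataset(synth_config(seed = 11))
fit <- fit_pipeline(ds$train,
                    pipeline_config(clonal = clonal_config(seed = 42)))
fit
#> maca_pipeline with stages:
#>   promoter_vs_rest       training affinity 0.973
#>   exon_vs_rest           training affinity 1.000
#>   intron_vs_utr3         training affinity 1.000
#>   coding_vs_noncoding    training affinity 1.000

preds <- predict_pipeline(fit, ds$test)
truth <- setNames(vapply(ds$test, `[[`, "", "label"),
                  vapply(ds$test, `[[`, "", "id"))
compute_metrics(setNames(preds$label, preds$id), truth)
#>     class TP FP TN FN sensitivity specificity precision  accuracy
#>      exon  9  0 36  3   0.7500000   1.0000000 1.0000000 0.9375000
#>    intron 12  1 35  0   1.0000000   0.9722222 0.9230769 0.9791667
#>  promoter 11  1 35  1   0.9166667   0.9722222 0.9166667 0.9583333
#>      utr3 11  3 33  1   0.9166667   0.9166667 0.7857143 0.9166667
#> overall accuracy: 0.8958
```

Training affinity is each stage's basin-majority accuracy on its own
training antigens; the table is one-vs-rest held-out performance
(sensitivity = TP/(TP+FN), specificity = TN/(TN+FP); precision is
reported separately because some of the gene-finding literature calls it
"specificity"). Boundary calls come from `scan_boundaries()` /
`predict_pipeline(..., boundaries = TRUE)` as 0-based half-open intervals.

The same workflow is available from a shell:

```sh
macadna simulate --out data.fa --labels labels.tsv --seed 7
macadna train    --fasta data.fa --model model.json --seed 7
macadna predict  --fasta data.fa --model model.json --out calls.tsv --bed regions.bed
macadna evaluate --predictions calls.tsv --truth labels.tsv
macadna evolve   --rules 170,238,204 --state 0,0.25,0.50
```

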