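---
title: "Fuzzy multiple-attractor cellular automata as DNA region classifiers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fuzzy multiple-attractor cellular automata as DNA region classifiers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(macadna)
```

## The model

A one-dimensional fuzzy cellular automaton (CA) is a vector of cells, each
holding a real value in $[0,1]$, updated synchronously by local rules that
read the three-cell neighbourhood $(q_{i-1}, q_i, q_{i+1})$. The seven rules
this package supports are arithmetic: each names a subset of the
neighbourhood and returns the *bounded sum* of those values,
$\min(1, \sum)$ — the Łukasiewicz t-conorm. Rule 254 sums all three
neighbours, 252 the left neighbour and self, 238 self and right, 250 left
and right, 204 self alone (the identity), 240 left alone, and 170 right
alone. A *complemented* variant of a rule returns one minus the bounded
sum, the fuzzy analogue of the binary-CA complement. Missing neighbours at
the array ends contribute 0 (null boundary), the standard convention in
multiple-attractor CA work; it also keeps the linear form of the update
banded.

Iterating the update from any initial configuration eventually revisits a
configuration, closing an *attractor*: a fixed point or a short cycle. The
set of initial states draining to one attractor is its *basin*. A
multiple-attractor CA (MACA) classifies by basin membership: if the
attractors reached by training examples of one class are labelled with that
class, an unseen example is classified by evolving it and reading off its
attractor's label.

For non-complemented rule vectors the update is linear before clamping:
one step equals $\min(1, T\,P(t))$, where the 0/1 matrix $T$ has a 1 in
row $i$ at every neighbour column rule $i$ reads. `transition_matrix()`
produces $T$ and the package asserts exact agreement between the matrix
form and the per-cell form on the quarter grid. Note the inversion
`genome_from_matrix()` is exact for interior cells only: under the null
boundary a first-cell rule that reads the missing left neighbour leaves no
trace in its row (252 collapses onto 204, 240 onto an empty row), so
boundary rules are recovered only when they reference no missing
neighbour.

### Numerical choices

* **Saturation.** Sums are clamped at 1. This is forced by the dynamics'
  closure requirement (cells must stay in $[0,1]$) and is visible in the
  engine's reference trajectory, where $0.75 + 0.50$ yields $1.0$.
* **Recurrence detection.** States are quantized to 6 decimals before
  hashing. Bounded sums of quarter-grid inputs are exactly representable,
  so this tolerance only guards floating drift for off-grid inputs.
* **Cycle identity.** A cycle is canonicalized by rotating its
  lexicographically smallest serialized state to the front; two
  trajectories entering the same cycle at different phases therefore get
  identical keys.
* **Step cap.** `ca_evolve()` refuses to run past `max_steps` (default
  1000) and raises an error carrying the partial trajectory rather than
  silently truncating. On a grid of multiples of $1/k$ the dynamics are
  closed, so an attractor always exists within $(k+1)^n$ steps; the test
  suite verifies this exhaustively for small $n$ and $k$.

## From DNA to cell values

The raw per-base encoding maps A, C, G, T to 0.25, 0.50, 0.75, 1.00 (N,
missing data, to 0). The values are arbitrary but deliberately nonzero, so
no base is absorbing under bounded sums. Classification, however, runs on
*feature states*: fixed-length vectors of normalized sequence features that
are themselves legal cell values. The features are the ones classical
promoter and coding-region predictors use:

* **Consensus motif scores** — the best fraction of matched positions of
  an IUPAC consensus over a search window. Defaults: TATA box `TATAAA`
  searched around TSS−30, CAAT box `CCAAT` around TSS−75, initiator
  `YYANWYY` spanning the TSS, polyadenylation signal `AATAAA` anywhere.
  These consensus strings are the standard ones; all are configurable.
  Windows may use negative coordinates to anchor at the sequence end,
  which is how the splice-site dinucleotides (GT at the 5′ end, AG at the
  3′ end of an intron) are scored.
* **Codon position asymmetry** — for each base, how unevenly it spreads
  over the three codon positions, rescaled so 0 is uniform and 1 is
  frame-locked. Elevated in coding sequence.
* **Hexamer bias** — mean 6-mer log-odds under an add-one-smoothed
  coding-vs-background model fitted from training data, squashed to
  $[0,1]$ by a logistic. The logistic slope (`hexamer_gain`, default 4 in
  the pipeline encoders) saturates the score for short windows whose mean
  log-odds is reliable but small in magnitude.
* **k-mer composition** and **G+C fraction** for configurable composition
  features.

These three families are a deliberately small subset of the classical
coding-measure battery; the rest of that battery is out of scope here.

### Quantization: why cells snap to a 0.25 grid

Feature values are continuous. If they were fed to the CA unrounded, every
sequence would reach its own private attractor — basins would never be
shared, training accuracy would be trivially perfect, and nothing would
generalize. The encoders therefore snap cells to a 0.25 grid (the
resolution of the engine's reference trajectory) before evolution. On the
grid the dynamics are closed, attractor sets are finite, and similar
sequences genuinely share basins. The grid step is a config knob
(`quantize`), with 0.25 as the package default.

At prediction time a sequence can still reach an attractor no training
example visited. Such an attractor inherits the label of the *nearest*
labelled attractor — smallest $L_1$ distance between representative cycle
states, ties to the earlier attractor — a deterministic nearest-centroid
fallback in attractor space. The training-majority fallback used in an
early design collapsed held-out accuracy and was discarded.

## The clonal-selection trainer

The trainer searches the space of rule assignments ("antibodies") for a
genome whose basins separate the classes of the encoded training
sequences ("antigens"). The *affinity* of an antibody is its training
accuracy: evolve every antigen to its attractor, label each attractor by
the majority class of the antigens reaching it (ties to the earlier class
in the declared class order), and score the fraction classified
correctly. Batch evaluation over all antigens is used throughout — a
single antigen would give a 0/1 affinity that cannot drive proportional
cloning.

Each generation, in order:

1. the top-$m$ antibodies of the whole population are selected;
2. rank $r$ receives $\max(1, \mathrm{round}(\beta (N_m+N_r)/r))$ clones;
3. each clone position mutates with probability
   $p_{\max} e^{-\rho\,a}$ (affinity-inverse mutation), replacements
   drawn uniformly from the 14 rule variants;
4. clones are re-evaluated and sorted;
5. each memory slot keeps the better of its incumbent and the best unused
   clone;
6. the reservoir is refilled with the best of {old reservoir, *leftover
   clones*, fresh random antibodies} — the reservoir-recycling
   modification: in plain clonal selection the leftover clones are
   discarded and the reservoir is simply replaced, which wastes evaluated
   material (`recycle_reservoir = FALSE` restores that behaviour for
   comparison);
7. memory becomes the best $N_m$ of memory ∪ reservoir.

Steps 5 and 7 make elitism provable: the best memory affinity never
decreases, which the tests assert on every run. All randomness flows
through R's RNG seeded from `clonal_config(seed=)`, so training is
bit-reproducible. Defaults ($N_m{=}20$, $N_r{=}30$, $m{=}10$,
$\beta{=}1$, $p_{\max}{=}0.3$, $\rho{=}3$, 50 generations) are classic
clonal-selection settings sized so a stage fit takes seconds at the
package's default data sizes. Identical genomes recur constantly
(unmutated clones, re-selected elites), so evaluations are memoized by
genome within one training run.

## The hierarchical pipeline

Four binary stage models are trained: promoter vs rest, exon vs rest
(non-promoters), intron vs 3′UTR, and a coding-vs-noncoding scanner used
for boundary calling. A sequence is classified by applying the stages in
that order; the first positive stage decides, and a promoter call
short-circuits the rest, so exactly one of the four labels is emitted.

Each stage carries its own feature encoder. This matters: in an early
single-encoder design, cells irrelevant to a stage (splice dinucleotides
in the promoter stage, say) fragmented its basins and measurably hurt
held-out sensitivity. The defaults are: promoter stage — TATA/CAAT/Inr
scores (3 cells); coding stages — position asymmetry and hexamer bias
(5 cells); intron-vs-3′UTR — GT-start, AG-end and poly-A scores (3
cells).

Region boundaries are called by sliding the scanner window (default 54 nt,
the smallest trained coding length; stride one third of the window) along
the sequence, classifying each window, smoothing the calls with a width-3
majority vote (partial neighbourhoods at the ends; ties keep the original
call), and merging runs of positive windows into 0-based half-open
intervals from the first window's start to the last window's end, clipped
to the sequence. Merging is idempotent and intervals never leave the
sequence.

## The synthetic generator

Real promoter/coding corpora are external; the package ships a generator
that emulates the *signal structure* the classifier assumes, so the whole
stack is testable from a seed:

* **Promoters** — 251-nt windows, i.i.d. background at a configurable GC
  (default 0.5), TSS at 0-based position 200, `TATAAA` planted at
  TSS−30±2, `CCAAT` at TSS−75±5, an instantiated `YYANWYY` spanning the
  TSS; every planted base independently corrupted at
  `motif_mutation_rate` (default 0.05, a light corruption so elements are
  present but imperfect).
* **Coding windows** — lengths cycling over 54/108/162/252/354 nt, codons
  i.i.d. from a usage table skewed toward C/G-ending, purine-starting
  codons with no in-frame stops. The skew is what gives the windows
  measurable position asymmetry and hexamer bias.
* **Introns / 3′UTRs** — 300-nt i.i.d. background; introns get the
  canonical GT…AG ends, 3′UTRs one planted `AATAAA`.

Records per class default to 40, split 70/30 train/test within class.
Everything is deterministic given the seed.

What the generator does *not* emulate: realistic base-composition
heterogeneity, CpG islands, splice-site context beyond the GT/AG
dinucleotides, multi-exon gene structure, and the base statistics of any
published corpus. Passing the held-out synthetic benchmark (the test
suite requires ≥ 85% 4-class accuracy at the defaults, and measures ~90%)
therefore demonstrates that the engine, trainer and pipeline work as
designed on data containing the signals they look for — not that these
accuracies transfer to real genomes.

## Problem sizes and known limitations

The shipped tests train on 112 sequences per pipeline fit (28 per class)
with 50-generation stage fits, exhaust all $7^n$ non-complemented genomes
up to length 4 against the matrix form on the full quarter grid, and use
60 planted-basin antigens for the recovery check — sizes chosen so the
whole suite runs in well under five minutes on a laptop core while still
exercising every code path at meaningful scale.

Limitations worth knowing:

* Only the forward strand is scanned; reverse-strand features require
  reverse-complementing the input (a helper is exported).
* The boundary caller's resolution is the scan stride; it reports window
  runs, not base-precise edges, and single-nucleotide TSS calling is out
  of scope.
* The attractor-space nearest-neighbour fallback makes prediction total,
  but sequences far outside the training distribution are still assigned
  *some* label; the per-stage trace exists so such calls can be audited.
* Clonal search is stochastic; different seeds can find different genomes
  of equal affinity. All tie-breaks (equal affinity, basin votes) are
  deterministic, so a fixed seed fixes the model exactly.
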