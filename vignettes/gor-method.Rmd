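---
title: "Windowed information-theoretic secondary structure prediction with GORpred"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Windowed information-theoretic secondary structure prediction with GORpred}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(GORpred)
```

## The problem and the model

GORpred predicts, for each residue of a protein sequence, one of three
secondary-structure states — helix (H), extended/beta strand (E), or coil
(C) — from the sequence alone. It follows the GOR family of methods:
rather than asking what a residue *is*, it asks how much *information*
the residue's local sequence context carries about the state at the
center of a 17-residue window (the target plus eight neighbors on each
side; positions beyond the chain ends read as the boundary symbol `X`,
the 21st symbol of the alphabet).

Training counts, over a database of sequences with known structure, how
often each residue type occurs at each of the 17 window offsets around a
position in state $s$ (the *directional* statistics) and how often each
ordered residue pair occurs at each of the $\binom{17}{2} = 136$
unordered offset pairs (the *pairwise* statistics). Each count is turned
into an information difference

$$ I(\Delta s; e) \;=\; \ln\frac{c_s(e) + \delta}{c_{\bar s}(e) + \delta}, $$

where $c_s(e)$ is the count of evidence $e$ (a singlet or a pair) around
positions in state $s$, $c_{\bar s}(e)$ pools the two competing states,
and $\delta > 0$ is a pseudocount (default 1) that keeps every entry
finite on small training sets. Because raw counts scale with the
per-state totals, each entry equals the log-likelihood ratio of the
evidence under $s$ versus not-$s$ *plus* the log prior odds
$\ln(n_s / n_{\bar s})$ — the prior is deliberately folded into the
table rather than applied separately at decision time.

At prediction time the per-state window score is

$$ I_s \;=\; \frac{2}{17} \sum_{j_1 < j_2} \mathrm{pair}[s, (j_1, j_2), r_{j_1}, r_{j_2}]
 \;-\; \frac{15}{17} \sum_{j} \mathrm{dir}[s, j, r_j]. $$

The $2/17$ and $15/17$ coefficients are fixed by a consistency
condition: if every pair term degenerates to the sum of its two singlet
terms, each singlet appears in 16 of the 136 pairs, so the expression
collapses to the plain singlet sum
($\tfrac{2}{17}\cdot 16 - \tfrac{15}{17} = 1$). The same arithmetic
explains the prior handling: the constant prior term inside every table
entry survives the combination exactly once
($\tfrac{2}{17}\cdot 136 - \tfrac{15}{17}\cdot 17 = 1$), so $I_s$ is the
posterior log odds of state $s$ given the window, and a model trained on
data with *no* sequence signal degenerates gracefully to predicting the
most common state.

The three scores are normalized by a max-shifted softmax,
$p_s = e^{I_s - \max_t I_t} / \sum_t e^{I_t - \max_t I_t}$, which is
overflow-safe and invariant under a common shift of the three inputs.
The predicted state is the argmax, with exact ties broken by the fixed
priority H > E > C (the conventional listing order of the states).

```{r}
db <- generateDataset(generatorConfig(nSequences = 50, seed = 1))
tables <- countsToInformation(accumulateCounts(db))
tables
```

## The streaming engine and lookup accounting

The pairwise table is the large object: one state's block is
$21 \times 21 \times 136 \times 8$ bytes $= 479{,}808$ bytes (468 KB) at
double precision. `segmentPairTable()` splits it into 136 independent
segments, one per offset pair, each serving any `(r1, r2)` query for all
three states without touching another segment — the arrangement that
lets all 136 pair terms of a window be fetched simultaneously from
independent memory banks.

The default prediction engine streams over *ordered* position pairs
$(j, k)$, $j \neq k$, reading one packed 3-state entry per ordered pair
with weight $1/17$; since the entry for $(j,k)$ and $(k,j)$ is the same
address, this is algebraically identical to weight $2/17$ over unordered
pairs, and it issues exactly $17 \times 16 = 272$ pair-table reads per
residue (plus 17 directional reads). A naive unordered-pair engine (136
reads per residue) is retained as an independent reference; the two
agree to better than $10^{-12}$ in probability and exactly in argmax.
`newLookupStats()` counters record the read counts; one "read" is one
table address returning the packed 3-state vector.

```{r}
stats <- newLookupStats()
seq <- db[[1]]$sequence
pred <- predictSequence(seq, tables, stats = stats)
lookupStats(stats)$pair_reads / length(seq)
```

## Correction passes

Two serial scanning passes smooth the preliminary assignment into
physically plausible runs. The literature on the original package
describes the *existence* of two correction scans but not their rules,
so GORpred adopts the standard minimum-run smoothing and documents it as
its own rule set, configurable through `correctionConfig()`:

1. **Pass 1 (helix):** every maximal H run shorter than `minHelixRun`
   (default 4 — one helical turn spans about four residues) is
   dissolved; each residue in it moves to whichever of E or C has the
   higher predicted probability there (ties to C).
2. **Pass 2 (strand):** every maximal E run shorter than `minStrandRun`
   (default 2) becomes C.

Pass 1 never creates an H and pass 2 never creates an H or E, so the
composite terminates in one application and is idempotent — a property
the test suite checks over a thousand random assignments.

## The three-stage pipeline

`runPipeline()` reproduces the task-level architecture: a prediction
stage feeds parallel correction channels through a bounded buffer, and
finished sequences are written back either first-come-first-served
(`"fcfs"`, completion order) or reordered to input order
(`"input_order"`), which yields byte-identical output files for any
channel count. Concurrency is *simulated* by a deterministic
discrete-event schedule — stage costs proportional to sequence length,
sequences assigned dynamically to the first free channel — because the
contract that matters in software is semantic, not temporal: every input
id is delivered exactly once, and the result multiset is identical to
the serial path for every channel count and buffer size. Completion
ordinals (ties broken by input order) are reported so FCFS output is
reproducible run-to-run.

## Quantization

`quantizeTables()` stores each entry as
$\mathrm{round}(v \cdot \mathrm{scale})$ (round half away from zero) in
32-bit integers, halving model storage. The default scale $2^{16}$ keeps
the dequantization error below $2^{-17}$ nats per entry — information
values on real-scale training sets are a few nats at most, so the int32
range is used with ample headroom (an overflow check rejects scales that
would not fit). The per-residue decision margin between the best and
second-best state is, in practice, orders of magnitude larger than the
accumulated rounding error, so float and quantized models select
identical states on the package's synthetic test sets; the acceptance
suite asserts zero argmax flips.

## The synthetic generator

Real training databases of solved structures cannot ship with a package;
`generateDataset()` instead draws data from the minimal process under
which windowed information statistics carry signal — a fixture, not a
biological claim:

* **Structure:** a first-order Markov chain over (H, E, C), started from
  its stationary distribution, with default self-transitions 0.90, 0.85,
  0.80 (mean run lengths 10, ~6.7, 5 residues; the remaining mass is
  split evenly). Run lengths are therefore geometric — real secondary
  structure elements have more regular lengths, and real helices have
  capping signals this process lacks.
* **Emissions:** residues drawn i.i.d. given the state from
  $(1-\kappa)\,\mathrm{Uniform}(20) + \kappa\,\mathrm{pref}_s$, where
  $\mathrm{pref}_s$ gives 3-fold weight to a state's preferred residues
  (helix formers A, E, L, M, Q, K, R, H; beta-branched/aromatic V, I, Y,
  W, F, T, C; turn/coil formers G, N, P, S, D). The contrast
  $\kappa \in [0,1]$ (default 0.8) dials the signal: at $\kappa = 0$ all
  states share one distribution and no predictor can beat the
  majority-state rate.
* **Lengths:** shifted geometric, $17 + \mathrm{Geom}$, mean 150 —
  every sequence spans at least one full window and lengths vary the way
  a real database's do. A `"fixed"` length model is available for
  experiments that need exact residue totals.
* **Defaults:** 300 sequences of mean length 150 (about 45,000 training
  residues), chosen as a realistic desk-scale stand-in for the classical
  few-hundred-chain training databases.

Because emissions are i.i.d. given the state, the pairwise statistics
carry little information *beyond* the singlets here (neighboring
residues are conditionally independent); on real proteins pair
correlations are informative. Passing tests on this generator therefore
validates the machinery — estimation, lookup, normalization, smoothing —
not biological accuracy.

```{r}
test <- generateDataset(generatorConfig(nSequences = 40, seed = 2), prefix = "t")
preds <- lapply(test, function(rec) {
  p <- predictSequence(rec$sequence, tables)
  list(id = seqId(rec$sequence), states = applyCorrections(p$states, p$probs))
})
res <- datasetQ3(preds, test)
c(q3 = res$q3, majority = res$majorityRate)
```

## Numerical and design choices

* **Pseudocount smoothing** ($\delta = 1$ by default) replaces whatever
  zero-count handling the historical implementations used; it bounds
  every table entry and makes training well-defined on arbitrarily small
  databases.
* **Residue coding:** the 20 canonical amino acids map to codes 0–19 in
  alphabetical one-letter order; every other letter (B, J, O, U, Z, X,
  ambiguity codes) collapses to `X` (code 20) rather than erroring, so
  real-world FASTA files pass through. All codes fit in 5 bits.
* **Degenerate inputs:** a length-1 sequence is legal (its window is the
  residue plus 16 pads); empty sequences, empty FASTA records, and
  structure strings of the wrong length or alphabet are rejected with
  positional error messages.
* **Tie-breaks** are all deterministic: argmax ties H > E > C,
  dissolution ties to C, FCFS completion ties to input order.
* **Model file:** a little-endian binary format with magic, version, and
  geometry fields; round-trips are bit-exact and truncation, foreign
  files, and version mismatches produce descriptive errors.
* **Problem sizes in the test and acceptance suites** (training sets of
  300 sequences, held-out sets of 100, 1000-case property loops) were
  chosen so the full suite exercises every code path at desk scale while
  staying fast enough to run routinely.

## Known limitations

* The correction rules are a documented stand-in for the original
  (unpublished) scanning heuristics, not a reproduction of them.
* Single-sequence GOR without evolutionary profiles is a classical
  baseline; modern profile- and deep-learning-based predictors are far
  more accurate on real proteins.
* The generator's i.i.d.-emission Markov process understates pair
  information and contains no long-range structure; Q3 figures on
  synthetic data do not transfer to real proteins.
* Dataset-level Q3 is residue-weighted (pooled over all residues);
  segment-overlap measures such as SOV are not implemented.
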