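---
title: "Methods: promoter-scanning GRN inference and no-replicate DEG calling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: promoter-scanning GRN inference and no-replicate DEG calling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the models it implements, the
parameters that matter, what the synthetic data does and does not emulate,
and the numerical and design choices that were genuinely open.

## 1. The scanning model

A TF's binding preference is a position frequency matrix (PFM): for each of
`w` motif positions, a probability over `A,C,G,T`. A candidate window
`x_1..x_w` in a promoter is scored

$$ S(x) = \sum_{i=1}^{w} \left[ \ln f'(i, x_i) - \ln \pi(x_i) \right], $$

where `f'` is the PFM column smoothed by a pseudo-frequency
(`f' = (f + 0.001)/(1 + 4·0.001)`, so no weight is −∞) and `π` is the
stationary base distribution of the background. The background itself is an
order-`m` Markov chain (default `m = 2`) estimated from the scanned promoter
set, strand-pooled, with pseudo-count 1 on every (context, base) cell.
Promoters are the 1000 bp immediately 5′ of each gene start on the coding
strand (1-based closed coordinates; windows truncated at contig ends are
scanned at their reduced length rather than dropped; windows containing `N`
are skipped rather than penalised; neighbouring genes do not clip the
window).

### Site p-values

A hit is called when `P(S ≥ s)` under the background is at most `1e-5`.
This tail probability is computed *exactly* (up to score discretisation) by
dynamic programming over (motif position, Markov context, discretised
score): letters are generated by the order-`m` chain, starting from the
smoothed marginal context distribution, while scores accumulate the
stationary-background weights above. Weights are floored to multiples of the
granularity (`1e-3` nat), which can only *inflate* a reported p-value (by at
most `w·granularity` in score units), so calls are conservative. The test
suite checks the DP against exhaustive k-mer enumeration (`w ≤ 6`,
`m ≤ 1`) and checks conservativeness against 20,000 chain samples.

Two deliberate approximations, fixed here because the reference scanner's
internals are not published:

* the *score* uses stationary-background weights while the *p-value DP*
  lets the Markov chain govern letter generation. This keeps scores and
  p-values mutually consistent without per-window context bookkeeping; it is
  a documented divergence from scanners that use the full context-dependent
  likelihood ratio in the score itself.
* both strands are scanned (regulatory sites are orientation-ambiguous);
  minus-strand hits are reported in forward coordinates with a strand flag.

### The discrete p-value floor

A width-`w` motif has at most `4^w` distinct words, so the smallest
attainable p-value is approximately `4^{-w}`: at `w = 8` that is
`1.5e-5 > 1e-5`, i.e. **no 8-bp motif can ever be called at p ≤ 1e-5**, and
at `w = 10` only exact-consensus words pass. This floor is asserted by a
regression test. It drives the synthetic-data default of `w = 14` (below)
and is worth remembering when interpreting genome-scale scans of short
eukaryotic motifs at stringent thresholds.

## 2. Network assembly and statistics

Hits collapse to one directed edge per (TF, target) pair regardless of
motif, strand or multiplicity, keeping the site count and best p-value.
Self-loops are retained in the network (and counted separately in the
summary) but never participate in motif triples. Outdegree statistics are
reported over regulators only (nodes with ≥ 1 target), the convention used
for genome-scale TF networks.

* **Betweenness** is computed on the *directed* graph,
  `B(n) = Σ_{i≠j≠n} σ_ij(n)/σ_ij` over ordered pairs with at least one
  path, endpoints excluded, then min–max normalised; when all raw scores tie
  the normalised scores are defined as 0. The directed choice matters: a
  pure source with a huge outdegree has betweenness 0 because no shortest
  path passes *through* it — exactly the pattern seen for dominant hub TFs
  in published tables. It is the one convention here that a cytoscape-style
  undirected treatment would change; the implementation keeps it switchable
  by symmetrising the edge list before calling.
* **Feed-forward loops** are ordered triples (master, intermediate, target)
  of pairwise-distinct nodes with edges m→i, m→t, i→t; 3-cycles and
  fan-outs are not counted. Role counts conserve: each role column sums to
  the number of triples.
* **Greedy unique-coverage ranking** iteratively picks the candidate adding
  the most not-yet-covered out-neighbours. The tie-break (larger total
  outdegree, then lexicographic id) is invented — no published rule exists —
  and makes the ranking a deterministic total order, which the tests verify
  step-by-step against argmax recomputation. Key TFs are the shortest
  ranking prefix whose cumulative unique coverage reaches the threshold
  (default 0.9 of all network nodes).

## 3. No-replicate DEG calling

With one library per condition, biological replication is absent by design;
the caller simulates *technical* replicates instead. Parameters (`pnr = 0.2`
fraction of depth per replicate, `nss = 10` replicates, `v = 0.02` jitter,
uniform — not Gaussian — on the simulated totals) follow the published
operating point. TMM normalization (trim 30 % on M, 5 % on A,
inverse-binomial-variance weights, reference sample by upper-quartile
fraction; verified against edgeR to 1e-10) feeds the multinomial sampling
probabilities, so composition bias propagates into the simulation. Replicates
are scaled to counts-per-million with zeros replaced by 0.5 *after* scaling.

The probability of differential expression is a two-dimensional dominance
rank: `q_g` is the fraction of pooled within-condition noise pairs
`(|M_n|, D_n)` with `|M_g| > |M_n|` **and** `D_g > D_n` (strict
inequalities: ties count against the signal, a conservative choice the
reference description leaves open). Genes with `q ≥ 0.9` are DEGs, signed
by `M = log2(mean_1/mean_2)` with condition 1 = the first-listed condition
(light).

Determinism is imposed by contract: the seed is a required parameter, and
each sample's draws are keyed to its sample *name*, so presenting the
swapped design reproduces the same per-sample replicates and flips `M`
exactly (the label-swap test asserts this at 1e-12, the residual being
reciprocal-rounding in `log2`).

**Known property, not a bug:** when the two libraries are overdispersed
relative to multinomial sampling (any real RNA-seq, and the negative-
binomial fixture), between-condition variability exceeds what technical
replicates can explain and the caller over-calls DEGs. The null-calibration
guarantee (`P(q ≥ 0.9) ≤ 0.05`, observed ≈ 0 in the tests) holds for the
stated null — identical libraries, multinomial noise only. This mirrors the
method's behaviour on the real data it was designed for and is why
downstream network integration (DEG ∩ GRN) is relied on to filter false
positives.

## 4. The synthetic world

`generate_regulatory_fixture()` emulates the scanning inputs: a ground-truth
GRN with a few hub TFs ("global regulators") and a sparse remainder; one
PFM per TF with consensus probability 0.95 per position and the remaining
mass spread evenly; promoters of i.i.d. uniform letters (an order-2 option
exists to exercise the background estimator) with exactly one PFM-sampled
site planted per true edge at a non-overlapping random position and strand.

Defaults were fixed by calculation before any test was run:

* **motif length 14**: with sharpness 0.95 and `p ≤ 1e-5`, words with up to
  two sampling mismatches clear the threshold only from `w = 14`
  (`(1 + 3w + 9\binom{w}{2})/4^w ≤ 10^{-5}`), giving theoretical planted-site
  sensitivity `P(Binom(14, 0.05) ≤ 2) ≈ 0.97`. Anything in the 6–10 bp
  range of typical fungal core motifs is *mathematically incapable* of
  meeting a 90 % recovery requirement at this threshold (§1), so the
  generator trades motif realism for a testable recovery contract.
* **3 hubs at per-node target probability 0.55, 150 genes**: the expected
  accumulated unique coverage is ~0.84 after two hubs and ~0.96 after three
  (never-detected genes drop out of the node denominator), so the 0.9
  key-TF threshold is crossed exactly at the third hub, ~2 standard
  deviations clear on both sides.

What the fixture does **not** emulate: real promoter composition and motif
clustering, TF families sharing binding preferences, multiple sites per
edge (irrelevant after edge collapsing), chromatin context, and annotation
errors. A green end-to-end test therefore establishes algorithmic
correctness of scan → assemble → rank on data satisfying the model's
assumptions — not performance on a real genome.

`generate_counts_fixture()` draws log-normal baselines (sdlog 1) scaled to a
2-million-read library, negative-binomial counts (dispersion 0.1, i.e.
size 10 — a typical technical+biological figure), and plants a 5 % DEG
subset at 8-fold change, half up, half down. The 8-fold/2M operating point
is deliberately easy: it tests that the caller *finds* what it should
(sensitivity ≥ 0.8; observed ≈ 1.0), while specificity under
overdispersion is documented in §3 rather than asserted.

## 5. Numerical choices and degenerate inputs

* Score granularity `1e-3` nat, floored — conservative by construction.
* PFM rows renormalised when within `1e-3` of 1, rejected otherwise;
  anything needing more correction is a malformed file, not data.
* TMM factors rescale to geometric mean exactly 1; a sample equal to a
  scalar multiple of another yields factors (1, 1) exactly.
* Empty networks, empty rankings, genes with zero counts in both
  conditions (q ranks bottom decile by the zero-replacement rule),
  promoters shorter than the motif, and all-N windows all have defined,
  tested behaviour.
* Ortholog filtering applies the inclusive thresholds
  (`evalue ≤ 1e-10`, identity ≥ 60, coverage ≥ 40) to externally produced
  alignment tables; whether "coverage" is query- or subject-side is the
  caller's declaration, since tabular alignment output does not say.

## 6. Limitations

* Published genome-scale hit/interaction counts for the motivating system
  are not reproducible here: they depend on retrieved genome/transcriptome
  data, unpublished scanner internals, and an unseeded stochastic DEG
  simulation. The package instead makes every stage reproducible by
  contract (required seeds, manifests with input checksums).
* The scanner handles backgrounds up to the order the context table can
  hold in memory (`4^m` rows); only `m ≤ 2` is exercised.
* No motif discovery, no binding-site clustering, no replicate-aware DEG
  modes (a design with replicates is rejected with a pointer to standard
  tools), no GO/KEGG annotation.
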