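---
title: "Inference from tree-sequence IBD: models, statistics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inference from tree-sequence IBD: models, statistics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tsabc)
```

## The data structure and the IBD definition

A sample of `m` haploid genome sequences of length $\ell$ sites is encoded
as a *succinct tree sequence*: leaf nodes $1..m$, internal (ancestral)
nodes $m{+}1..n$ ordered backwards in time, a table of inheritance edges
$(c_j, p_j, l_j, r_j)$ meaning that child $c_j$ inherits sites
$[l_j, r_j]$ from parent $p_j$ (1-based closed intervals,
$1 \le l_j \le r_j \le \ell$), and a table of mismatch records
$(c_j, s_j)$ marking sites where a node differs from its parent —
mutations, or sequencing errors when the node is a leaf.  A leaf carries
the derived allele at a site iff an *odd* number of records lie on its
path to the root there, so recurrent mutation on one lineage reverts the
allele.  Because internal ids are time-ordered, `parent id > child id`
on every edge, and the MRCA of two leaves at a site can be found by
always climbing the smaller id; the package's C++ kernel exploits this.

An **IBD segment** of a sequence pair is a maximal interval over which
the pair has a single MRCA *node*.  Two consequences of this definition
drive everything else:

* with no length threshold, the segments of a pair **partition** the
  genome — every site belongs to exactly one segment;
* a recombination need not end a segment: only MRCA-node changes do.
  Conversely a change of node identity breaks a segment even if the new
  node has the same age — the definition is node-based, not time-based.

The **efficient subset** of pairs is $(c, c{+}1)$ for $c = 1..m{-}1$
plus $(1, m)$: $m$ pairs instead of $m(m{-}1)/2$, chosen so that every
edge of the tree sequence lies on a descent path from some segment's
MRCA, hence every mutation remains visible to the statistics
(`edge_coverage_check()` verifies this property).  A length threshold is
a different, information-losing reduction: `extract_ibd()` supports it
(strictly: a segment is kept iff $r-l+1 >$ threshold, so a tie is
excluded), and the standard protocol applies thresholds to *all* pairs.

## Moment estimators when the true tree sequence is known

With node times known, each segment $i$ contributes a TMRCA $g_i$ and a
mismatch count $|M_i|$ over $L_i = r_i - l_i + 1$ sites.  Writing
$\lambda_i = 2\mu g_i$, the per-site mismatch probability under parity
semantics is

$$P_i = (\lambda_i - \lambda_i^2)\,(1 - 4\epsilon(1-\epsilon)) +
  2\epsilon(1-\epsilon),$$

($\lambda-\lambda^2$ is the second-order expansion of the Poisson odd
parity $\tfrac12(1-e^{-2\lambda})$; an error on exactly one of the two
leaves toggles a mismatch).  The genome-wide singleton count has
expectation

$$E[C_1] = \mu X (1 - m\epsilon)
  + (\ell - \mu W)\, m \epsilon\, (1 - (m{-}1)\epsilon),$$

where $X$ is the external branch length integrated over sites (a
mutation is a singleton iff it falls on an edge whose child is a leaf)
and $W$ the total branch length integrated over sites: an error only
*creates* a singleton at a not-already-variant site, destroys an
existing singleton it hits, and two errors at one site make a
doubleton.  `mm_estimate()` solves the two equations (total mismatches
and $C_1$) by fixed-point iteration from the linear solution, truncating
at 0.  The second-order terms matter: at $m = 20$, $\epsilon = 10^{-3}$
the naive linearisation biases $\hat\epsilon$ by $\approx 2\%$ and, via
the $\epsilon$-dominated statistics, $\hat\mu$ by a similar amount;
with the corrections both biases fall below Monte-Carlo error at 50
replicates.  `order = "first"` keeps the pure linearisation, which
exactly inverts a generative model with mismatches placed at rate
$2\mu g$ per site.  Standard errors are not computed analytically; use
replicate simulations (the experiment harness reports mean/SD/SE).

Per-segment TMRCAs are estimated by inverting the mismatch expectation,
$\hat g = \max\{(|M|/L - 2\epsilon)/(2\mu),\ g_{\rm floor}\}$ with
$g_{\rm floor} = 1$ generation to avoid degenerate values for
mismatch-free short segments.  For a sequence pair the coalescence
hazard at $g$ is $1/N(g)$, so `estimate_popsize()` reports
$\hat N(g) = (1 - \hat F(g)) / \hat f(g)$ from a Gaussian kernel density
estimate of the pooled $\hat g_i$ on the log scale (TMRCAs span orders
of magnitude; Silverman bandwidth by default), truncated where
$\hat F > 0.99$.  Segments are pooled unweighted — the estimators treat
the $\hat g_i$ as a sample from the pair-TMRCA distribution; a
length-weighted pooling would target the distribution at a random
*site* instead, a deliberate design choice documented here.

## Summary statistics and the ABC engine

Four statistics drive `tsabc()`:
`total_mismatch` ($\bar M \times I = \sum_i |M_i|$) and `c1` (the
genome-wide singleton count) carry the mutation/error signal;
`mean_len` and `sd_len` of the printed lengths $r_i - l_i$ carry the
demographic signal.  Masks per protocol: $(\bar M{\times}I, C_1)$ for
rate inference, the length pair for demographic parameters, all four
for joint inference.  For the length-*threshold* study we pre-registered
the mismatch statistic alone: $C_1$ is unaffected by a threshold, so
including it would mask exactly the information loss the study
measures; threshold-free runs with both statistics show visibly
smaller spread than the threshold study's zero column, consistent with
that reading.

The engine is plain rejection ABC with a local-linear adjustment:

1. observed data $\to$ backend $\to$ IBD extraction $\to$ statistics;
2. $\eta$ draws from independent uniform priors (default
   $\eta = 2500$); for each, simulate a dataset under the configured
   coalescent model and process it *identically*;
3. distance = Euclidean norm of the component-wise differences scaled
   by the per-component **median absolute deviation across the
   reference table** (no single metric is canonical here; MAD is
   robust to the heavy-tailed mismatch statistic and the choice is
   configurable in code);
4. retain the $\eta \cdot$ `retain_frac` (default $1/20$) smallest
   distances, ties broken by simulation index for reproducibility;
5. per parameter, a weighted linear regression of retained draws on
   their scaled statistics (Epanechnikov weights in the distance, the
   classic regression-adjustment scheme; ridge fallback with a warning
   when statistics are collinear), each draw shifted to its prediction
   at the observed statistics and clipped to the prior support —
   clipping reproduces the prior-boundary pile-up seen in
   high-threshold runs;
6. the reported estimate is the mean of the adjusted retained draws.

Degenerate cases: a zero MAD drops that component with a warning (all
zero falls back to the unscaled norm); datasets with no retained
segments contribute zero-valued statistics rather than `NA`.

A master seed drives everything: parameter draws, one child seed per
inner simulation (kept below $2^{31}$), and one per error-injection
stream, so runs are bit-reproducible and could be parallelised
deterministically.

## The simulator and its stated world

`simulate_treeseq()` delegates the coalescent with recombination to
msprime through a batched Python bridge (one interpreter per batch of
simulations), with mutations placed as binary, possibly recurrent,
records at rate $\mu$ per site per generation.  Defaults are the
conditions of the shipped protocols: $\mu = 1.3\times10^{-8}$, $r = 10^{-8}$ per site per
generation, haploid $N(g)$ models — constant C ($N = 2\times10^4$),
exponential G ($N(g) = N(0)e^{-\tau g}$, capped at $2N(0)$ when
$\tau < 0$), step S ($N(0) = g^* = 4\times10^4$,
$N(g^*) = 10^4$), and piecewise tables.  The shipped
European-American-like table is a labelled *synthetic stand-in*, not an
estimate of any real population's history; it
exercises the piecewise interface and is not used for any quantitative
claim.  Gene conversion (rate $2\times10^{-8}$, tract 300 bp in the
joint-inference challenge) is available in *data generation only* —
the inference model deliberately never includes it.

Sequencing error has two faithful forms: `simulate_error_on_ts()` adds
parity records at leaf nodes (the true-IBD studies), and
`inject_errors()` sets haplotype cells to the derived state at rate
$\epsilon$ (the inferred-IBD studies).  The two differ in semantics
(XOR versus OR) exactly as the two study designs do.  Alternative error
models can be plugged in as any function with the same signature.

What the generator does *not* emulate: real genotyping pipelines
(missingness, phasing error, allele miscalls conditional on depth),
non-uniform mutation rate, selection, or population structure.  A green
test therefore establishes correctness of the machinery and statistical
behaviour *under the stated coalescent world*, not robustness to those
real-data features.

## Tree-sequence inference backend

The field's standard fast tree-sequence inference tool (tsinfer) is
not available to this package, so the backend is shipped as a
*contract* — any function `haplotype_matrix -> rank-ordered tree_seq` —
plus two implementations: `"true-ts"` (observed and simulated data both
processed from the true tree sequence; the protocol of the true-IBD
comparisons) and `"window-upgma"`, a deliberately simple stand-in that
builds an average-linkage tree per fixed genome window from Hamming
distances, sharing node ids across adjacent windows whose inferred
topology coincides.  ABC only requires the backend to be deterministic
and to be applied identically to observed and simulated data —
approximation error then largely cancels — but numerical results that
depend on the specific error structure of sequential inference tools
are out of reach of the stand-in, and the package's rate-recovery
checks use `"true-ts"`.

Two consequences of the backend choice are worth knowing.  First, for
moderate sample sizes adjacent windows essentially never infer an
identical topology, so the stand-in's IBD segments sit at window
resolution and their length statistics are (near-)constant across
datasets; the engine detects the zero spread and drops those components
with a warning.  Second, backend identity matters *scientifically* for
misspecification challenges: with gene conversion present in the data
but absent from the inference model, true-IBD processing resolves every
300 bp tract and pushes the observed length statistics far outside the
simulated reference cloud (the regression adjustment then extrapolates
to the prior boundary), whereas an inference backend cannot resolve
sub-SNP-density tracts and the challenge is survivable — which is why
the joint-inference protocol uses the inference backend.

## Numerical and scale choices

* Coordinates are 1-based closed throughout; the bridge converts the
  0-based half-open convention of the on-disk format.  "A recombination
  at site $s$" means between $s$ and $s{+}1$: the left segment ends at
  $s$.
* Node times are optional everywhere downstream of the simulator; an
  inferred tree sequence carries rank order only.
* The kernel-density $N(g)$ curve defaults to a geometric grid over the
  central sample mass; constant samples are flagged unreliable rather
  than producing spurious curves.
* The test suite runs the desk-scale protocols at their stated sizes
  ($\ell = 10^6$, $\eta = 500$, 10–25 replicates) and the cluster-class
  table replications at an explicitly reduced scale through
  `run_experiment()`'s `scale` argument, asserting scale-invariant
  facts (unbiasedness within 3 SE, orderings of SDs).  Every override
  is logged in the result object, and the harness runs the full-scale
  protocols unchanged when given no overrides.

## Known limitations

* Only independent uniform priors (with an optional rejection
  constraint) are supported; all shipped protocols use them.
* No sequential/adaptive ABC and no likelihood-based TMRCA inference —
  deliberate non-goals.
* The singleton model assumes the ancestral allele is known; folded
  data would need a different $C_1$.
* Multi-chromosome genomes are lists of independent tree sequences;
  no between-chromosome linkage is modelled.
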