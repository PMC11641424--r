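---
title: "Methods: perturbed-input ensemble generation and apo/holo characterization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: perturbed-input ensemble generation and apo/holo characterization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rassemble)
```

## The model

Single-structure predictors approximate the conditional mode of a
structure distribution given a query sequence and its alignment. To
recover more of that distribution without retraining, `rassemble`
perturbs the inputs: alanine-masked sequence replicas weaken the
coevolutionary couplings that pin the prediction to the ground state, and
shallow alignment subsampling raises the variance of the evolutionary
signal the model conditions on. The working assumption — motivated by the
observation that apo and holo forms of allosteric proteins share fold
topology and global soft modes — is that the perturbed predictor falls
into the *functionally relevant* alternative basins rather than into
arbitrary misfolds; the confidence reranker is the guard against the
latter.

### Randomized alanine scanning

For replica $r$ and eligible position $i$, the substitution indicator is a
two-stage Bernoulli: $p_i \sim U(p_\text{low}, p_\text{high})$, then
$X_i \sim \text{Bernoulli}(p_i)$, so the marginal substitution probability
is $(p_\text{low} + p_\text{high})/2 = 0.10$ at the defaults (0.05,
0.15). Design points worth making explicit:

- **Alanine positions stay eligible.** An A$\to$A draw changes nothing in
  the string but is recorded as a substitution event, keeping the
  perturbation intensity uniform across positions regardless of
  composition.
- **`X` is never substituted** — masking an unknown residue would
  fabricate sequence identity.
- **Region-restricted scanning** (a set of eligible positions) supports
  perturbing only a functional region. Positions are 1-based throughout
  the package, including the JSON sidecar — the natural convention in R
  and in the PDB residue numbering the rest of the pipeline uses.
- **Replica $r$ runs on seed $\texttt{seed} + r - 1$** (R's default
  Mersenne-Twister), so any single replica can be regenerated without
  rerunning the others.
- The default of 45 replicas sits in the middle of the 40–50 repetitions
  the protocol typically uses; the replica count is a sampling budget, not
  a statistically critical constant.

### MSA subsampling

`subsample()` draws uniformly without replacement over non-query rows to
fill an attention set of at most `max_seqs` rows and a disjoint extra set
of at most `extra_seqs`. The query is always forced into the attention
set — a prediction without its own query row is meaningless. When the
alignment is no deeper than `max_seqs` the partition degenerates to "all
rows, no extras". The default preset 16:32 is the shallow end that
produces the greatest conformational diversity; deeper presets (up to
512:1024) are a config change. Whether each masked replica should receive
a freshly built alignment or the original alignment with the replica
substituted as the query row is left open by the protocol; both are
supported (`set_query_row()` implements the substitution route, which is
the default in the pipeline since it needs no external alignment builder).

### Prediction contract

A backend receives one replica plus its partition and returns exactly
$\texttt{num\_models} \times \texttt{num\_seeds} \times
(\texttt{num\_recycles} + 2)$ conformers: recycles $0..R$ are each kept as
a conformer and one additional *final refined* structure per model/seed is
flagged separately in provenance (the protocol's "14 structures" per model
at $R = 12$). The final structure is treated as an independent draw, not a
duplicate of recycle $R$ — the protocol does not state they coincide, and
treating them as distinct is the weaker assumption. `run_backend()`
enforces the count contract for every backend.

### The mock predictor and the synthetic hinge system

The mock backend draws each conformer from one of two basin structures
(mixture weight `weight_a`) and adds isotropic Gaussian noise
(`noise_scale`, Å, per coordinate). Its confidence model is
$\text{pLDDT}_i = 100\,e^{-d_i/\sigma}$ clipped to $[30, 100]$, where
$d_i$ is the residue's C$\alpha$ displacement from its basin position and
$\sigma = 2$ Å — chosen so that near-rigid residues score in the high-80s
to 100 while residues displaced by more than ~0.7 Å fall below 70,
mirroring the confidence regimes a reranker must distinguish. Note that at
realistic noise (0.2–0.3 Å per coordinate) most *whole conformers* fall
below the ">70% of residues at pLDDT ≥ 85" bar: the mock emulates the
*shape* of the confidence–displacement relationship, not the absolute
confidence level of a well-converged real prediction.

The synthetic reference system is a two-domain polyalanine backbone whose
C$\alpha$ trace follows an ideal helical curve (radius 2.3 Å, rise 1.5 Å,
100°/residue — canonical 3.8 Å C$\alpha$ spacing); the closed form bends
the second domain about the last C$\alpha$ of the first domain, and
`calibrate_hinge_angle()` solves (by `uniroot`, the RMSD–angle map being
monotone) for the bend that yields a requested inter-basin backbone RMSD
such as 3.5 Å, typical of hinge-type apo/holo pairs. What the generator
*does* emulate: rigid-domain hinge motion, two-basin ensembles,
displacement-correlated confidence, realistic coordinate scales. What it
does *not*: side chains (polyalanine backbone only), stereochemical
realism, partial disorder, crystal-packing artifacts, genuinely
intermediate conformations, or alignment-depth effects on prediction
quality. Passing the synthetic recovery suite therefore demonstrates that
the *analysis machinery* is correct and that the pipeline composes; it
does not by itself certify predictor behaviour on real proteins.

## Metrics

**Kabsch superposition.** SVD of the 3×3 cross-covariance with the
determinant sign correction, so reflections are never returned. Collinear
or planar point sets (second singular value numerically zero) are still
solved but flagged `degenerate`. The transform maps the second point set
onto the first.

**RMSD over atom sets.** The superposition is fitted on the selected atom
set and the RMSD reported on that same set — `backbone` (N, CA, C, O; the
default, matching the protocol's backbone superposition), `ca`, or
`pocket_sidechain_heavy`. Atoms missing on either side are dropped
pairwise and the count used is reported. The binding pocket is defined on
the holo form as every residue with a protein heavy atom within 4.5 Å
(inclusive) of a ligand heavy atom, waters excluded; the protocol never
defines the pocket, so the cutoff is recorded in every report to keep
results auditable.

**TM-score.** $\max (1/L_\text{ref}) \sum_i 1/(1 + (d_i/d_0)^2)$ with
$d_0 = 1.24(L_\text{ref}-15)^{1/3} - 1.8$ floored at 0.5 Å. Residue
equivalency is given (author-numbering correspondence), so only the
superposition is optimized: seeds from the full length, halves, quarters,
eighths and sixteenths (minimum fragment 4) at half-fragment offsets; each
seed is refined by re-fitting on residues within
$\max(d_0, 1.5\,\text{Å})$ of their partner (the cutoff relaxes in 0.5 Å
steps when fewer than 3 residues qualify) until the selected set is
stable, at most 20 iterations; the best score over all evaluated
superpositions is kept. Normalization uses the full residue count of the
reference model — the holo form by default; since the protocol leaves the
normalizing chain unstated, both normalizations are reported by
`characterize_pair()`. The test suite pins the score's invariants: exactly
1 for self-comparison, invariance under rigid motion of either model, and
monotone non-increase under growing coordinate noise.

**Residue correspondence** pairs residues by author numbering (plus
insertion code) within the first protein chain, restricted to residues
with C$\alpha$ resolved in both structures, with an optional declared
numbering offset. Sequence-alignment-based matching is deliberately out of
scope: the intended references are same-construct apo/holo pairs. Fewer
than 30 matched residues is an error — a superposition on fewer is too
easily dominated by noise; the threshold is a parameter for small
synthetic systems.

## Ensemble analysis

- **Reranking** keeps conformers whose fraction of residues at pLDDT ≥ 85
  exceeds 0.70 (threshold configurable; 85 is the lower edge of the 85–90
  confidence band the protocol targets), ordered by fraction then mean
  pLDDT.
- **State classification**: `apo` if
  $\text{RMSD}_\text{apo} + m < \text{RMSD}_\text{holo}$ (margin $m =
  0.5$ Å by default, below typical coordinate noise), `holo` for the
  reverse, `intermediate` otherwise. The protocol never formalizes the
  label; the margin rule is this package's operationalization and is
  reported with its margin.
- **Clustering**: Ward linkage (`ward.D2`) on the all-vs-all superposed
  RMSD matrix. RMSD distances are not an exact Euclidean embedding, so
  Ward is used in its dissimilarity form — a documented caveat, matching
  the stated procedure rather than an embedding detour. $k$ is chosen by
  maximum mean silhouette over `k_range` (default 2–10), ties to the
  smaller $k$ (parsimony). An all-identical ensemble (max distance
  < $10^{-6}$ Å) is a degenerate error advising $k = 1$.
- **Distributions**: histograms on fixed grids anchored at 0 (bin widths:
  RMSD 0.25 Å, TM-score 0.025, pLDDT 2.5) so runs are comparable;
  densities are Gaussian-kernel with Silverman's rule-of-thumb bandwidth
  and are omitted (not faked) for fewer than two distinct values. Box-plot
  summaries use the Tukey 1.5×IQR convention.
- **Confidence/deviation correlation** is Spearman's rank correlation of
  per-conformer mean pLDDT against each RMSD column, reported `NA` when
  either column is constant.

## Pipeline and reproducibility

`run_pipeline()` materializes `masked/`, `subsampled/`, `predictions/`
(PDB with pLDDT in the B-factor column), `analysis/` and `logs/` under one
output directory; completed stages are skipped unless forced, and missing
upstream artifacts raise errors naming the artifact. Seed derivations are
fixed and documented (subsample: `seed + r`; predict: `seed + 65536 + r`),
so identical configurations produce byte-identical analysis tables.
Reference structures are local files by default; fetching by PDB accession
exists but must be explicitly enabled (`allow_download = TRUE`) — the
standard workflow is fully offline.

## Problem sizes

The test suite and the acceptance script run desk-scale configurations
chosen to exercise every code path while keeping the whole suite fast on
one CPU: a 120-residue synthetic hinge pair; 60–70-conformer ensembles
(5 models × 10–12 recycles); 45–50 masking replicas of 200-residue
queries ($10^4$ position draws for the substitution statistics); 100
random point-cloud instances (3–500 points) for the superposition oracle
checks. Full-scale runs (45 replicas × 70 conformers against real
predictors) use the same code with larger configuration values.

## Known limitations

- The external predictor adapter shells out to a `colabfold_batch`-style
  executable and is exercised only for its error paths in the test suite;
  real-predictor integration inherits that tool's file layout.
- Correspondence by author numbering cannot pair renumbered constructs
  beyond a constant offset; alignment-based matching is a non-goal.
- TM-score assumes the given residue equivalency; it is not a structural
  aligner for non-identical proteins.
- The mock's confidence is a one-parameter exponential of local
  displacement; real pLDDT also reflects alignment depth, disorder and
  model uncertainty, none of which are emulated.
- Population weights, free energies, and kinetic ordering of states are
  out of scope: the ensemble is a sample of basins, not a thermodynamic
  ensemble.
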