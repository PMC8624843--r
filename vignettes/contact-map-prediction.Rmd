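---
title: "Predicting residue-base contact maps with a max-margin IP model"
author: "PRIcontact authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting residue-base contact maps with a max-margin IP model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Protein–RNA interactions are mediated by specific spatial contacts
between amino-acid residues and ribonucleotide bases.  Experimental
determination of joint 3D structures is slow and expensive, so
PRIcontact predicts the full residue–base *contact map* — the binary
|P| × |R| matrix z with z~ij~ = 1 when residue i contacts base j —
from sequence alone, plus secondary structure *predicted* from
sequence: an 8-state string for the protein (as an SSpro8-class
predictor emits) and a dot-bracket string for the RNA (as a
CentroidFold-class predictor emits).  No homologs, alignments, PSSMs
or 3D templates are used, so the method applies to any protein–RNA
pair.

## The scoring model

A candidate map z is scored by a sparse linear function

$$ f_\lambda(P, R, z) \;=\; \langle \lambda, \Phi(P,R,z)\rangle
   \;=\; \langle \lambda_p, \Phi_p\rangle +
         \langle \lambda_r, \Phi_r\rangle +
         \langle \lambda_c, \Phi_c\rangle, $$

where Φ counts local features at the binding sites that z induces:

* **Residue features**, one count per *binding* residue (a residue with
  at least one contact): centered k-mers of the amino-acid sequence
  (k = 3, 5), of two reduced alphabets derived from BLOSUM50 clustering
  (10 groups `LVIM C A G ST P FYW EDNQ KR H` and 4 groups
  `LVIMC AGSTP FYW EDNQKRH`, at k = 5, 7), and of the 8-state secondary
  structure string (k = 3, 5).
* **Base features**, one count per binding base: k-mers of the RNA
  sequence and of the 6-state structural profile (both k = 3, 5).
* **Contact features**, one count per contact (i, j): pairs of
  equal-length windows, protein-side × RNA-side, for six track
  combinations (sequence × sequence, SS8 × profile, and each reduced
  alphabet × sequence and × profile) at k = 3 and k = 5.  Note the
  reduced alphabets intentionally use k ∈ {5, 7} as unary features but
  k ∈ {3, 5} inside contact features.

The 6-state RNA profile assigns each base one of: stack (S, paired),
external loop (E), hairpin loop (H), internal loop (I), bulge (B) or
multibranch loop (M).  An unpaired base takes the class of the loop
closed by its innermost enclosing pair: zero inner pairs → H, one inner
pair with both flanking gaps occupied → I, with exactly one occupied →
B, two or more inner pairs → M; no enclosing pair → E, including
unpaired stretches between two separate stems.  Pseudoknots are
rejected — the upstream predictors do not emit them and the profile
taxonomy has no class for them.

### Numerical and representational choices

* **Boundary windows** are padded with the sentinel `^`, so every
  position contributes exactly one feature per configured row and the
  per-position score precomputation below needs no special casing.
  This extends the nominal k-mer spaces by padded contexts.
* **Group representatives** for the reduced alphabets are the first
  letter of each printed group; any injective labeling is equivalent.
* Feature stores are sparse: keys materialize only when observed.  The
  nominal contact spaces (for example 20^5 × 4^5) are never allocated.

## Decoding as integer programming

Because every feature fires at a single binding residue, binding base
or contact, the score is linear in the indicator variables:

$$ f_\lambda = \sum_i u_i x_i + \sum_j v_j y_j + \sum_{ij} w_{ij} z_{ij}, $$

with u, v, w precomputed per position/pair (`computeScoreTerms()`).
`predictContacts()` maximizes this exactly subject to

1. x~i~ + y~j~ ≥ 2 z~ij~ — a contact implies both binding sites;
2. x~i~ ≤ Σ~j~ z~ij~ and y~j~ ≤ Σ~i~ z~ij~ — a binding site implies a
   contact;
3. y~j−1~ + (1 − y~j~) + y~j+1~ ≥ 1 — no isolated binding base;
4. Σ~j~ z~ij~ ≤ X~i~ and Σ~i~ z~ij~ ≤ Y~j~ — contact caps, default
   X = Y = 8 (a calibration adopted from the published cap sweep).

Constraint 3 is enforced with out-of-range neighbors treated as
unbound (the strict reading): a length-1 RNA can never bind, and a
bound terminal base requires its single inward neighbor bound.  The
exhaustive oracle uses the same convention, so the two decoders are
comparable on every instance.

**Backend.**  Any exact 0/1 solver fits the decoder contract; the
default backend is HiGHS branch-and-cut, driven through a small
JSON-in/JSON-out helper (`inst/python/milp_solve.py`, via
`scipy.optimize.milp`) at zero MIP gap, with the interpreter
configurable through `options(PRIcontact.python=)`.  A pure-R
exhaustive decoder (`predictBruteForce()`, |P|·|R| ≤ 20) serves as the
independent verification oracle; it breaks ties by the
lexicographically smallest contact set, while the IP backend's
tie-breaking is solver-dependent — comparisons between the two are
therefore made on objective values, never on contact sets.
`predictContactsBatch()` solves many instances in one backend call,
which amortizes interpreter start-up when problems are known up front.

## Learning

Weights are trained as a structured SVM: minimize over λ

$$ \sum_{(P,R,z)\in D} \Big[ \max_{\hat z} \big( f_\lambda(\hat z) +
   \Delta(z, \hat z) \big) - f_\lambda(z) \Big] + C\,\lVert\lambda\rVert_1 , $$

where the loss Δ counts false negatives and false positives at the
residue, base and contact levels with penalties δ~FN~ = 0.5 and
δ~FP~ = 0.005 (all levels), and C = 10⁻⁵.  The inner maximization is
*loss-augmented decoding*: shifting u~i~ by −δ~FN~ where x~i~ = 1 and
+δ~FP~ where x~i~ = 0 (bases and contacts analogously) and adding the
constant offset δ~FN~ · (#bound residues + #bound bases + #contacts)
makes the augmented objective of every candidate equal its score plus
its loss, so the same IP solves both decoding problems.  The offset is
carried explicitly so the objective value itself is exact, not just
the argmax.

Optimization is stochastic subgradient descent: per visited instance,
one step along φ(ẑ) − φ(z) + C·sgn(λ) with per-coordinate AdaGrad
step sizes η/√(G~k~ + ε).  Choices the published procedure leaves
open, fixed here as package defaults:

| parameter | default | role |
|---|---|---|
| η | 1.0 | base learning rate |
| ε | 10⁻⁸ | AdaGrad stabilizer |
| tol | 10⁻⁶ | stop when the max per-epoch weight change falls below it |
| maxEpochs | 100 | epoch cap |
| shuffling | on, seeded | per-epoch instance order (dataset order available via `shuffle = FALSE`) |

Training additionally stops when an epoch incurs zero hinge — every
instance decoded to its true map with the required margin — at which
point further steps only shrink weights through the regularizer.  The
ℓ1 term follows the plain subgradient with sgn(0) = 0, applied to all
materialized keys (an unbounded dense key space has no meaningful ℓ1
subgradient, so only observed keys regularize); the proximal
forward–backward alternative is deliberately out of scope.  A
consequence worth knowing: with an extreme C the weights oscillate
near zero with AdaGrad-damped amplitude instead of landing exactly on
it, so the model collapses in the sense of uniformly tiny weights and
near-zero optimal objectives, not a literally empty argmax.  Gold maps
are validated against the caps and the isolated-base rule before
training and reported by instance id when infeasible;
`capsInAugment = FALSE` drops the caps inside the loss-augmented max
while keeping them at prediction time.

## Evaluation

`confusionCounts()` compares maps at three levels — contacts (entries
of z), binding residues and binding bases (derived indicators) — and
`ppvSenF()` computes PPV = TP/(TP+FP), SEN = TP/(TP+FN) and their
harmonic mean F, reporting 0 with a flag when a denominator is zero
(required for empty predictions).  Aggregation over a dataset is
**macro** by default (mean of per-pair metrics, excluding pairs that
are vacuous at a level); **micro** (pooled counts) is also provided,
and the mode is recorded in the output, since the published evaluation
does not state which was used.

## Synthetic data: what it emulates and what it does not

`generateSynthetic()` builds fully labeled corpora that stand in for
the PDB-derived training data: uniform random protein sequences with
8-state structure strings from a run-favoring first-order Markov chain
(self-transition 0.75); uniform random RNA sequences with well-formed
dot-brackets from a recursive stem-loop sampler (helices ≥ 3 bp,
hairpins ≥ 3 nt, bulges, internal loops, and multibranch loops when
length permits — the smallest multibranch needs 24 nt, which drives the
default RNA length range of 10–28 so all six profile states occur with
positive probability across a corpus; proteins default to lengths
10–20); sparse planted weights (2% of the feature keys realizable in
the corpus, standard normal scale 1) and labels produced by exact IP
decoding under the planted weights and the configured caps (default
8).  Labels are therefore feasible and perfectly separable by
construction — a linear scorer in the same feature class generated
them.

Passing the learning checks on such corpora demonstrates that the
estimation machinery (loss-augmented decoding, subgradients, AdaGrad,
regularization) recovers a planted model; it does *not* demonstrate
accuracy on real complexes, where contacts are not generated by any
linear model of these features, structure predictions carry errors,
and chains are orders of magnitude longer.  Sign recovery is measured
on the top decile of recovered weights restricted to keys with a
nonzero planted weight: feature rows are heavily correlated by
construction (twelve contact rows fire on the same cell), so the
learner legitimately spreads mass onto correlated unplanted keys,
which have no planted sign to compare against.

Contact maps from coordinates use a single heavy-atom distance
criterion: residue i and base j are in contact when any heavy-atom
pair is within 4.0 Å.  The published extraction also ran a
hydrogen-bond detector with donor–acceptor geometry at 3.5 Å; since
3.5 < 4.0 and the geometric test needs hydrogen positions, the
distance criterion subsumes it here, a documented deviation.
Non-standard residues and nucleotides in PDB input are skipped with a
warning and indices compacted, because every feature alphabet is
canonical-only.

## Problem sizes and runtime

The shipped checks use the corpus conditions above (10 pairs,
proteins 10–20, RNAs 10–28, caps 8): decoding such an instance takes
tens of milliseconds in the backend, a full training run converges to
zero hinge in well under 50 epochs, and oracle comparisons run on
hundreds of random instances with |P|, |R| ≤ 4 where exhaustive
enumeration is exact.  Larger corpora scale linearly in instances per
epoch; decoding cost grows with |P|·|R| as the IP's variable count.

## Known limitations

* The structural profile discards base-pairing partners; stems that
  bind double-stranded readers are represented only as runs of S.
* Decoding cost is superlinear in sequence lengths; there is no
  threshold-cut style pruning because no tractable probability model
  over contact maps is available to rank variables.
* One protein chain × one RNA chain per instance; multi-chain
  complexes must be split upstream.
* The CLI pairs records across files by shared id, one pair per id.
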