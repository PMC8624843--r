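# PRIcontact

Prediction of residue–base contact maps in protein–RNA interactions
from sequence and predicted secondary structure alone.

Protein–RNA interactions drive splicing, transport, localization and
translation, but joint 3D structures exist for only a small fraction of
the pairs of interest.  PRIcontact predicts, for a protein *P* and an
RNA *R*, the full binary contact map **z** (z<sub>ij</sub> = 1 when
residue *i* contacts base *j*), using nothing beyond the two sequences
and secondary structure *predicted from* them: an 8-state string for
the protein (SSpro8-style) and a dot-bracket string for the RNA
(CentroidFold-style).  It is aimed at structural bioinformaticians who
need residue- and base-level interface hypotheses for pairs without
solved structures, homologs or alignments.

## Method

A candidate map is scored by a sparse linear model

> f<sub>λ</sub>(P, R, z) = Σ<sub>i</sub> u<sub>i</sub> x<sub>i</sub> +
> Σ<sub>j</sub> v<sub>j</sub> y<sub>j</sub> +
> Σ<sub>ij</sub> w<sub>ij</sub> z<sub>ij</sub>,

where x, y are the binding-site indicators derived from z, and u, v, w
sum trained weights of local features: k-mers of the amino-acid
sequence, of two BLOSUM-derived reduced alphabets, and of the 8-state
secondary structure on the protein side; k-mers of the sequence and of
a 6-state loop profile (stack, external, hairpin, internal, bulge,
multibranch) on the RNA side; and paired windows for contacts.
Decoding maximizes f exactly as a 0/1 integer program under
consistency constraints — contacts and binding sites imply each other,
no bound base is isolated, and each residue/base has a contact cap
(default X = Y = 8).  Weights are trained as a structured SVM:
stochastic subgradient descent with AdaGrad on

> Σ<sub>k</sub> [ max<sub>ẑ</sub> ( f(ẑ) + Δ(z⁽ᵏ⁾, ẑ) ) − f(z⁽ᵏ⁾) ] + C‖λ‖₁,

with the inner max computed by loss-augmented decoding through the same
IP, loss penalties δ_FN = 0.5 / δ_FP = 0.005 per level and C = 10⁻⁵.
The default IP backend is HiGHS (via a bundled `scipy.optimize.milp`
helper; `python` with scipy must be on the PATH); an exhaustive
enumeration decoder doubles as an independent verification oracle on
small instances.  See the methods vignette
(`vignettes/contact-map-prediction.Rmd`) for the full model and the
design decisions.

## Worked example

```r
library(PRIcontact)

## RNA loop profile from a dot-bracket string
rnaProfile("((.((...))))")
#> [1] "SSBSSHHHSSSS"        # stacks, a bulge, a hairpin loop

## a fully synthetic labeled corpus from planted sparse weights
corpus <- generateSynthetic(syntheticConfig(nPairs = 10, seed = 7))
corpus$instances[[1]]
#> TrainingInstance 'synth001': |P|=19, |R|=28, 50 contacts

## structured-SVM training (stops when an epoch incurs zero hinge)
fit <- trainModel(corpus$instances, h = hyperParams(maxEpochs = 50),
                  seed = 7, verbose = TRUE)
#> epoch   1  hinge 607.228  max|dw| 1  nnz 8674
#> epoch   3  hinge 34.3236  max|dw| 1  nnz 13124
#> epoch   9  hinge 2.84217e-14  max|dw| 1e-05  nnz 13355
fit$model
#> ModelWeights: 13355 nonzero features
#>   contact:protss3xrnass3 | BBB | SSS       -2.408
#>   ...

## decode the contact map of a pair under the trained weights
inst <- corpus$instances[[1]]
pred <- predictContacts(computeScoreTerms(inst@protein, inst@rna, fit$model),
                        Xcap = 8, Ycap = 8)
pred$map
#> ContactMap 19 x 28: 50 contacts, 18 binding residues, 24 binding bases
#>   (1,1) (1,8) (1,9) (2,22) (3,3) (3,11) ...

## three-level evaluation against the true maps
pairs <- lapply(corpus$instances, function(i)
  list(truth = i@map,
       pred = predictContacts(computeScoreTerms(i@protein, i@rna, fit$model))$map))
evaluateDataset(pairs, mode = "macro")
#>     level ppv sen f n_pairs  mode
#> 1 contact   1   1 1      10 macro
#> 2 residue   1   1 1      10 macro
#> 3    base   1   1 1      10 macro
```

The hinge reaching zero means every training pair is decoded to its
true map with the required margin; on this separable planted-weight
corpus the trained model then reproduces all labels exactly (F = 1 at
all three levels).  On real complexes contact maps are not generated by
any linear model of these features, so training-set F is an upper bound
on what the machinery can do, not an accuracy claim.

A command-line interface covering the pipeline
(`train` / `predict` / `evaluate` / `synth` / `profile` / `pdb2map`)
is installed at `inst/scripts/pricontact`; contact maps can also be
derived from PDB complexes by the 4.0 Å heavy-atom criterion
(`pdbToInstances()`).

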