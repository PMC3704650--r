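---
title: "Ranking candidate genes with k-nearest-neighbour phenologs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking candidate genes with k-nearest-neighbour phenologs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenologr)
```

## The model

Two phenotypes in different species are *phenologs* ("orthologous
phenotypes") when the sets of genes underlying them overlap more than
expected by chance, once gene orthology is used to place both gene sets in a
common space. Such correspondences are instances of deep homology — a
conserved ancestral gene module manifesting as superficially unrelated traits
in diverged lineages — and they are predictive: a gene associated with one
phenotype of the pair is a candidate for the other.

phenologr turns this idea into a ranking scheme. For a target phenotype $j$,
it searches all phenotypes of all species for the $k$ whose gene sets most
resemble the target's, and integrates their votes into a per-gene score.
Writing $\Phi_{i\ell} \in \{0, 1\}$ for the incidence of element $i$ in
neighbour phenotype $\ell$, $w_{j\ell}$ for the neighbour's weight, and
$f_{ij\ell}$ for the per-phenolog true-positive fraction, the two supported
classifiers are

* **naive Bayes**:
  $X_{ij} = 1 - \prod_{\ell = 1}^{k} \left(1 - f_{ij\ell}\, w_{j\ell}\right)$,
  a product of independent-evidence terms over the neighbours containing
  gene $i$;
* **additive**: $X_{ij} = \sum_{\ell} w_{j\ell}\, \Phi_{i\ell}$, the
  incidence matrix times the weight vector.

The naive Bayes form is marginally stronger in cross-validation; the
additive form decomposes exactly into per-neighbour contributions
(`decomposeContributions()`), which is why it is preferred when predictions
need to be read and argued about. $f$ is the overlap fraction $v/n$, with
$n$ the target phenotype's cardinality in the shared element space —
empirically a good estimate of the chance that a single phenolog's candidate
is a true positive. The denominator can be switched to the neighbour's
cardinality (`fDenominator = "neighbor"`) for users who prefer the
precision-flavoured variant.

## Two matrix frameworks

Translating annotations between species is where gene-family expansions
bite. phenologr implements both framings:

* **gene-based** (`framework = "gene"`): every annotation of the other
  species is translated to all target-species genes sharing its orthogroup.
  A single mouse association on a family with three human paralogs becomes
  three human associations; overlap statistics then depend on which species
  hosts the expansion, so similarity between the same two phenotypes differs
  with the direction of the search.
* **orthogroup-based** (`framework = "orthogroup"`, the default): both
  phenotypes are projected onto the orthogroups of the species pair, with an
  orthogroup annotated when any member gene on the phenotype's own side is.
  Paralogs collapse to one element, the comparison is symmetric in
  direction, and scores are not inflated by co-occurrence inside a family.

Under strict 1:1 orthology the two framings are provably identical, which
the test suite exercises on seeded synthetic data; under expansions only the
orthogroup framing keeps direction-symmetric scores (also asserted).

Within-species ("paralogous") phenotypes are allowed as neighbours by
default: they are compared in the target species' own annotated-gene space,
the only universe the two columns genuinely share. The universe size $N$ of
each comparison is the orthogroup count of the species pair for
cross-species candidates and the count of target-species genes appearing in
any phenotype for within-species candidates.

## Similarity measures and weights

Six measures are computed from the overlap counts $(v, m, n, N)$: the
hypergeometric tail probability $P(X \ge v)$ (the classical phenolog
significance), Pearson sample correlation of the indicator vectors (equal to
the $\phi$ coefficient of the 2×2 table), cosine $v/\sqrt{mn}$, Tanimoto
$v/(m+n-v)$, and Euclidean / Manhattan distances. Distances are converted to
a common "larger is nearer" ordering for the neighbour search, and ties in
that ordering are broken by phenotype key so results are reproducible.

The measure used to *order* neighbours and the one converted into the
*weight* $w$ may differ; the default pairing — Pearson for distance, the
hypergeometric tail complement for weight — is the configuration that
performed best in cross-validation, and the opposite pairing is available
through `weightingSpec()`. Because the integration treats $w$ as a
probability, raw measures are mapped onto $[0,1]$: $p \mapsto 1-p$ for the
hypergeometric tail, $r \mapsto \max(r, 0)$ for Pearson, identity for cosine
and Tanimoto, and $d \mapsto 1/(1+d)$ for the two distances. No calibration
from similarity to a true probability exists in the method itself, so this
mapping is an explicit design decision of the package; monotonicity is what
matters for rankings.

The default neighbourhood is $k = 40$. Recovery improves sharply from
$k = 1$ to any $k > 1$ and saturates around $k \approx 10$–$40$; larger $k$
mostly reshuffles low ranks.

## Cross-validation

`loocv()` implements orthogroup-aware leave-one-out validation: for each
phenotype with at least two genes, one random known gene is hidden — and
with it *every orthogroup containing it*, in every species pair, so no
annotated paralog can leak the answer back in — the search and scoring are
recomputed, and the hidden gene's rank is recorded. Tied scores share the
mean rank, so the rank sum over $P$ genes is always $P(P+1)/2$, and a gene
with score zero lands mid-way through the zero tie group rather than at an
arbitrary position. The procedure repeats three times per phenotype
(different random hidden genes) and reports the per-phenotype median hidden
rank; `recoveryCurve()` counts phenotypes whose median rank stays at or
below each threshold. An optional audit (`audit = TRUE`) re-derives every
neighbour overlap from the masked column and verifies that no masked
orthogroup contributed.

`nfoldCv()` complements this with fold-based validation and per-phenotype
ROC / precision–recall areas (phenotypes with at least four known genes),
and `randomizeAssociations()` / `randomizeMatrix()` supply the negative
control: gene sets redrawn uniformly with cardinalities preserved. On the
synthetic benchmark the control's mean AUROC sits at 0.5 as it must, while
real (planted) data separates from it by orders of magnitude in a rank-sum
test — the package's analogue of the real-versus-random contrast.
`speciesAblation()` reruns the evaluation with the neighbour pool restricted
to chosen species subsets to apportion credit between data sources.

## The synthetic benchmark

Real gene–phenotype corpora (OMIM, MGI, ZFIN, TAIR, phenomic screens) are
moving targets; the package instead ships a generator whose output has the
structural features the method relies on, so every claim above is testable
offline. `synthConfig()` describes the world:

| parameter | default | meaning |
|---|---|---|
| `species` | 4 names | species in the world |
| `nOrthogroups` | 500 | ancestral orthogroups |
| `expansionMean` | 1.5 | mean paralogs per orthogroup per species (1 + geometric, so family sizes are heavy-tailed as in plant-like expansions) |
| `orthologRetention` | 0.9 | probability an orthogroup survives in a species |
| `nModules` × `moduleSize` | 5 × 20 | disjoint conserved modules |
| `phenotypesPerModule` | 6 | module-linked phenotypes per module per species |
| `signalFraction` | 0.6 | fraction of a phenotype's genes drawn from its module |
| `backgroundPhenotypes` | 10 | unstructured phenotypes per species |
| `phenotypeSizeRange` | 5–15 | genes per phenotype |

Pairwise orthology is derived from the shared ancestral orthogroup id, which
guarantees the one-orthogroup-per-pair invariant and makes per-pair maps
mutually consistent. Two phenotypes planted on the same module overlap in
roughly `signalFraction` of their elements regardless of species — the
planted phenolog — while background phenotypes overlap only by chance.

What the generator deliberately does **not** emulate: phenotype ontologies
and their correlated term structure, literature ascertainment bias (the
mouse–human correlation of discovery effort), species-specific genome sizes,
and inparalog confidence scores. Passing the benchmark therefore
demonstrates that the machinery recovers planted deep-homology signal at
realistic sparsity — not that any particular biological database will
perform at the same level.

The evaluation problem size used throughout the tests and the acceptance
script is the default configuration above over five generator seeds, with
leave-one-out validation on the first species' 40 phenotypes and three
repeats — a size at which the full real-versus-random contrast and the
$k$-benefit comparison complete in well under a minute while leaving the
rank-sum separation unambiguous (p ≈ 1e-14).

## Numerical and degenerate-input choices

* The hypergeometric tail is computed through the survival form of
  `phyper`, with the smaller set passed as the "white ball" count so the
  value is bitwise symmetric in the two phenotypes.
* Pearson similarity is undefined for constant indicator columns (empty or
  universe-covering phenotypes); such candidates are skipped in the search,
  and `binarySimilarity()` raises an explicit error.
* Score ties when converting phenomic profiles to top/bottom-condition
  phenotypes are broken by condition id; the strict "more than" thresholds
  of the expression location/stage expansion are taken literally.
* A masked target column that becomes empty in some comparison space simply
  yields no candidates from that space; if it is empty everywhere the
  prediction is the all-zero score vector and the hidden gene's rank is the
  mean of the zero tie group — the conservative finite convention for
  "unrecoverable".
* All randomness (hidden-gene draws, fold assignment, generator draws,
  randomized controls) flows from explicit seeds recorded in reports and
  run manifests.

## Known limitations

* Orthology is strictly pairwise; multi-species clustered orthogroups and
  inparalog-weighted membership are out of scope (membership is binary).
* Overlap p-values are reported without multiple-testing correction,
  matching the method's use of them as ranking weights rather than as
  hypothesis tests.
* Fusion/blending of classifiers is deliberately absent: the simple
  classifiers' top predictions are too strongly correlated for blending to
  pay for the extra cross-validation layer it would require.
* The package evaluates and predicts; it does not curate. Garbage
  annotation sets (over-collapsed disease entities, broad GO terms) remain
  garbage neighbours, although the per-neighbour decomposition makes them
  visible.

## A worked miniature

```{r example}
syn <- generateSynthData(synthConfig(seed = 7))
spec <- weightingSpec(k = 10, classifier = "additive")
pl <- phenologPredict(syn$dataset, "anolis_ph001", "anolis", spec)
head(predictions(pl))
head(neighbors(pl)[, c("key", "v", "m", "n", "N", "distance", "f", "w")])
```

```{r cv}
rep <- loocv(syn$dataset, "anolis", weightingSpec(k = 5), seed = 11)
head(cvMedians(rep))
sum(cvMedians(rep)$median_rank <= 100)
```
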