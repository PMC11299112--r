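---
title: "Dating the origin of short ORFs with ancestral sequence reconstruction"
author: "orfancestry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dating the origin of short ORFs with ancestral sequence reconstruction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orfancestry)
```

## The problem

A protein-coding gene can arise *de novo* from sequence that was previously
noncoding. The strongest computational evidence for such an event is showing
that the genomic locus did not harbor protein-coding capacity in the past.
`orfancestry` implements a workflow for this inference on short ORFs
(roughly 100–1,000 nt) in a clade of closely related species, with budding
yeast as the motivating system:

1. reconstruct the nucleotide sequence of the locus at every internal node
   of a rooted species phylogeny;
2. scan each reconstructed ancestor for open reading frames;
3. score each ancestral ORF against the extant focal ORF with the *reading
   frame conservation* (RFC) measure;
4. attach a randomization-based empirical P-value to the best score of each
   ancestor; and
5. assign a branch of origin by walking the tree from the root toward the
   focal species, with an ensemble confidence classification when several
   methodological variants are available.

## Ancestral reconstruction

Characters are reconstructed by **marginal maximum likelihood** under a GTR
model using Felsenstein's pruning algorithm: a postorder pass computes the
conditional likelihood of the data below each node, a preorder "outside"
pass the likelihood of everything else, and their product gives the exact
per-site posterior over `A,C,G,T` at every internal node. The reported
state is the posterior argmax (ties broken in the fixed order A < C < G < T),
and the posterior of the chosen state is kept as a per-position confidence.
Branch lengths are taken from the input tree as-is and never re-optimized;
in practice they should come from an ML fit to the same alignment (for
example raxml-ng), so that the divergence the reconstruction assumes
matches the data.

Model parameters: base frequencies default to the empirical proportions of
the alignment with a pseudocount floor of `1e-4` per state (so degenerate
compositions never assign zero probability); the six GTR exchangeabilities
default to 1 (a symmetric, F81-like special case) and are configurable but
not fitted — full ML estimation of the rates belongs to dedicated
phylogenetic software and is out of scope. Discrete-gamma rate
heterogeneity is available (`nCategories = 4` with a supplied shape
reproduces the common four-category setup; category rates use the
quantile-median method normalized to mean 1); the default is rate
homogeneity, which at these sequence lengths changes posteriors very
little but keeps the likelihood surface transparent.

**Indels** are reconstructed separately by Fitch parsimony on the binary
gap/presence character of each alignment column. Parsimony ties are
resolved by the `deletionBias` flag: `TRUE` prefers deletions (ancestrally
present, lost independently — the behavior of tools that produce longer
root sequences), `FALSE` prefers insertions (ancestrally absent), which is
the conservative default here: it never asserts ancestral presence on a
tie, and for origin dating an erroneously long ancestor is the more
damaging mistake. The fraction of tied columns is reported per node as
`ambiguityFraction`, and the two settings differ only at tied columns.
The root node is reconstructed internally but excluded from all origin
calls: without additional outgroups its position along the root branch is
unidentifiable, and its reconstruction leans arbitrarily toward whichever
side it is drawn to.

Ancestors produced by external tools (FastML, PRANK, PREQUEL and the like)
can be imported from FASTA keyed by internal-node label; they join the
ensemble exactly like internal variants, with posteriors recorded as
absent rather than invented.

## RFC and its null distribution

An ancestral ORF is a forward-strand span under one of two definitions:
`ATG` (first ATG of a stop-free in-frame segment to that segment's stop)
or `noATG` (maximal span between consecutive in-frame stops, sequence
edges open). The 3' stop is included in the span, and only spans strictly
longer than 30 nt are kept. A codon containing `N` is neither a stop nor a
start, and `N` scores as a mismatch in alignment — ambiguity never creates
signal.

Each ancestor is aligned **once**, in full, against the extant focal ORF by
global Needleman–Wunsch alignment (match +5 / mismatch −4 by default; gap
open −3 with −0.1 per additional gap position, the penalties of the
published procedure). The traceback preference (diagonal, then gap in the
ancestral row, then gap in the reference row) is fixed, so one canonical
optimal alignment is returned deterministically. ORF coordinates are then
transposed into the alignment, and

> RFC = (number of alignment columns in which both rows are non-gap, the
> column lies inside both ORFs, and the two reading frames agree) /
> (length of the focal ORF),

where the frame of a row at a column is the count of its non-gap characters
since its ORF start, mod 3 — a gap in one row advances only the other
row's frame. RFC = 1 means an ancestral ORF at least as long as the focal
ORF aligns to it in frame without frameshifts. Per ancestor, the ORF with
the maximum RFC is kept (ties to the longer ORF, then the smaller start).

Because spurious ORFs arise in any sequence, the best RFC of an ancestor is
calibrated against chance: the ancestral sequence is shuffled (a uniform
permutation, preserving length and nucleotide composition exactly), the
`noATG` scan + alignment + RFC is repeated on each shuffle, and the
P-value is the fraction of `nReps` shuffles whose best RFC strictly
exceeds the observed one. The published procedure uses 1,000 shuffles and
strictly-greater counting, so P = 0 is possible; a `(k+1)/(n+1)`
pseudocount variant is available behind a flag. Shuffles are drawn from a
per-node random stream derived by hashing the node label into a master
seed, so results do not depend on evaluation order; the characters are
sorted before permutation so the null depends only on the composition of
the ancestor, not its arrangement.

## Branch of origin and the ensemble

Only ancestors on the path from the root to the focal leaf are considered.
Two criteria are implemented, both with strict inequalities:

* **RFC cutoff** — the most ancient path ancestor with best RFC above the
  cutoff (the published analyses scan 0.5, 0.6, 0.7 and 0.9);
* **empirical P-value** — the most ancient path ancestor with P below
  `alpha` (default 0.01).

With no qualifying ancestor the gene is *extant only* (focal-species
specific). `downstreamConsistency` reports the fraction of ancestors more
recent than the called branch that also pass — near 1 when the inferred
ORF presence is stable down to the present. A gene is *robust ancient*
when the most ancient ancestor **and every ancestor below it** exceed RFC
0.9. Across methodology variants, a gene is classified
`high_confidence_ancient` (all variants call the most ancient ancestor),
`high_confidence_de_novo` (all variants call a branch more recent than the
genus ancestor set, including extant-only), `low_confidence_ancient` (one
or two variants, but not all, call the most ancient ancestor), or `other`.
Which label counts as "most ancient" and which labels as "at or before the
genus split" are configurable, because under a free (non-species) topology
the most ancient ancestor may not exist as a node.

Alignment difficulty is summarized by the average gap count per sequence
and the mean pairwise Kimura 2-parameter distance
(`d = -1/2 ln(1 - 2P - Q) - 1/4 ln(1 - 2Q)` over columns where both
sequences have an unambiguous base; saturated pairs are excluded with a
warning).

## The simulator and the recovery experiment

`simulateLocus()` evolves a locus along the tree: a root sequence drawn
i.i.d. at a chosen GC content, substitutions through the GTR transition
matrix per branch, indels as a Poisson process (geometric lengths,
insertions copying stationary bases), with the true alignment tracked
event-by-event through a global column registry. An ORF of chosen length
can be planted on any branch by minimally editing the descendant node
(breaking each in-frame stop with a single substitution); below the
origin the ORF is maintained — arising stops are reverted with probability
`purifyingStrength` (default 1), indels never disrupt the window, and
substitutions inside the window run at `orfRateScale` (default 0.3) times
the neutral rate, modelling purifying selection on conserved coding
sequence relative to the neutral intergenic background.

`recoveryExperiment()` then runs the full pipeline — reconstruction on the
leaf alignment (with branch lengths matching the simulated divergence, as
an ML fit would give), RFC, P-values, branch call — and compares the call
with the planted truth. The acceptance suite uses three scenarios on the
eight-species tree, 20 replicates each, 200 randomizations per P-value:

* *ancient*: ORF planted at the root of a slowly evolving locus
  (`subRateScale = 1`, `indelRate = 0.1`, 300-nt ORF in a 450-nt locus) —
  the easy, conserved-gene case;
* *de novo*: 150-nt ORF planted on the focal terminal branch of a
  fast-evolving, indel-rich locus (`subRateScale = 5`, `indelRate = 0.8`);
* *mid-tree*: the same fast regime with the ORF planted at the third
  ancestor.

The rate split follows the empirical pattern of the system the workflow
was built for: loci whose ORFs date as ancient have visibly lower
pairwise divergence than loci of species-specific ORFs, and de novo
emergence happens in fast-evolving intergenic sequence. GC 0.40
approximates the yeast genome; the simulator treats branch lengths times
`subRateScale` as neutral divergence.

**What the simulator does not emulate.** Real orthologous loci come with
alignment error (the true alignment is handed to the pipeline here),
selection on flanking elements, duplications, translocations and
horizontal transfer; real de novo genes may overlap conserved noncoding
elements. Passing recovery tests therefore shows the inference machinery
is sound under the stated generative model, not that real loci behave
this way.

**A structural limitation worth stating plainly.** Marginal
reconstruction pulls the state of a recent ancestor toward its extant
descendants — including the focal sequence whose ORF is being dated — and
the composition-preserving null is blind to homology: any ancestral locus
that still aligns to the focal ORF with a conserved stop-free in-frame
stretch longer than the null's upper quantile is called significant, even
if it never encoded anything. Both effects push branch-of-origin calls
toward greater age. For a 150-nt focal ORF at yeast-like composition the
null's 99th percentile sits near RFC 0.3, i.e. a conserved in-frame
stretch of roughly 15 codons suffices; stop-free runs of that length occur
in a substantial fraction of noncoding windows. Genuinely recent origins
are therefore systematically over-dated in a non-negligible minority of
replicates, which mirrors the conservatism the method exhibits on real
data. The empirical P-value is best read as an upper bound on the age of
an ORF, not an unbiased estimate.

## Numerical choices and conventions

* All intervals are 0-based, half-open; internal-node auto-labels are
  assigned in postorder (`Anc1`, `Anc2`, ..., root `Root`), fixed so that
  ensemble joins are stable across re-reads.
* Ambiguity codes other than `N` are rejected at read time; `U` maps to
  `T`; zero-length branches are rejected unless explicitly replaced by a
  small epsilon.
* Posteriors are computed in plain (non-log) space, adequate for trees of
  tens of leaves at these divergences; columns where every leaf is gapped
  fall back to the model prior and are in any case reconstructed absent.
* A gap run of length L costs `open + (L - 1) * extend`; the first gap
  position is charged the opening penalty only, matching the convention
  of the alignment routine named in the published procedure.
* The P-value's strictly-greater counting makes 0 an attainable value and
  the statistic conservative near 0 under ties; with `nReps = 200` its
  granularity is 1/200, which is why the calibration check uses a
  Kolmogorov–Smirnov band rather than exact uniformity.
* Problem sizes in the test suite (450-nt loci, 150–300-nt ORFs, 20
  replicates per scenario, 200 randomizations) were chosen as the
  smallest sizes at which the recovery questions are still meaningfully
  posed; the pipeline itself handles the full published geometry
  (1,000-nt ORFs, 500-nt flanks, 1,000 randomizations) unchanged.

## A short example

```{r example, eval = FALSE}
tree <- readTree(system.file("extdata", "saccharomyces_species.nwk",
                             package = "orfancestry"))
st <- simulateLocus(simScenario(tree, locusLen = 450, orfOriginBranch = "Anc3",
                                orfLen = 150, subRateScale = 3,
                                indelRate = 0.4, focalTaxon = "Scer",
                                seed = 42))
msa <- OrthologAlignment(st$trueAlignment[treePhylo(tree)$tip.label], "Scer",
                         focalOrfSpan = st$focalOrfSpan,
                         alignmentMode = "extended")
anc <- reconstructAncestors(msa, tree, fitBaseFreqs(msa))
refOrf <- focalOrfSeq(msa)
perNodeP <- sapply(focalPathAncestors(tree, "Scer"), function(nd)
  empiricalPvalue(ancSequences(anc)[[nd]], refOrf, nReps = 200,
                  seed = deriveSeed(42, nd))$pValue)
assignBranchPvalue(perNodeP, tree, alpha = 0.01, focalTaxon = "Scer")
```
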