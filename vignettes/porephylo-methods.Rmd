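---
title: "Methods: testing the molecular-piracy hypothesis for viral K+ channels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: testing the molecular-piracy hypothesis for viral K+ channels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question

Phycodnaviruses encode the smallest known functional K⁺ channels (e.g. Kcv,
94 residues). If these genes were recently pirated from their algal hosts,
each viral channel should branch inside its own host species' channel
family, close to specific host paralogs. If instead the viral lineage
diverged before host speciation, the viral channels should form a clade of
their own, well separated from every host paralog family. `porephylo`
implements the full desk pipeline for making that contrast quantitative:
candidate screening, pore-module extraction, alignment, four independent
tree methods, and a verdict rule — plus a sequence-evolution simulator that
generates both scenarios with known ground truth, so every stage is
testable without any downloads.

## Screening and the pore module

A K⁺ channel candidate must carry a selectivity-filter motif (one of the
tripeptides GYG, GFG, GLG; the canonical signature is the 8-residue pattern
`TxxTxG[FY]G`) and at least two predicted transmembrane (TM) segments.

TM prediction is a consensus hydropathy method: Kyte–Doolittle sliding
windows at sizes 19 and 21, threshold 1.6 (scale units), segments kept when
both window sizes support them (`min_votes = 2`) and they span ≥ 15
residues. The published analyses this emulates combined seven external
predictors by consensus without reporting settings; our defaults reproduce
the consensus idea with a single auditable core, and every report records
them. Within a window run, candidate intervals are expanded to the full
window extent, so predicted boundaries carry an uncertainty of about half a
window (±10 residues).

The *pore module* runs from the start of the TM before the filter to the
end of the TM after it. Because the filter's neighbourhood is itself partly
hydrophobic, the predicted TM2 usually bleeds across the filter; during
delineation, segments are therefore clipped at the filter boundaries (the
filter is by definition not membrane-spanning) before the flanking pair is
chosen. Canonical filter hits are preferred; ties go to the tightest
TM spacing, then the smallest position. All coordinates in this package are
1-based closed intervals, the R convention.

One caveat surfaced by the generator: the *number* of predicted TM segments
is not monotone in the threshold — raising the threshold can split one
merged segment into two. What is monotone, and what the tests assert, is
the total residue coverage (non-increasing in the threshold) and the vote
rule (relaxing `min_votes` never removes segments).

## Alignment and statistics

Pairwise global alignment is affine-gap Needleman–Wunsch–Gotoh (a gap of
length *k* costs `gap_open + (k-1) * gap_extend`; defaults −10/−1 with the
bundled BLOSUM62). Progressive multiple alignment builds a guide tree by
neighbor joining on 3-mer distances (d = 1 − shared-3-mer fraction over the
smaller set) and merges profiles leaf-to-root with the same affine DP over
profile-pair scores; it is single-pass and deterministic. Identity and
similarity use pairwise deletion (columns with a gap or X in either row are
excluded) and "similarity" counts residue pairs with positive BLOSUM62
score — the conventional reading, since the original analyses never defined
it. Consensus sequences drop columns that are gaps in more than half the
rows, emit the majority residue when it reaches the threshold (default
0.7, a reasonable middle ground for the unreported original setting), and
write X on ties. Local search is Smith–Waterman.

## Four tree methods

All four are implemented in this package and cross-checked in the test
suite against independent oracles (exhaustive enumeration, brute-force
ancestral summation) and, where available, against ape/phangorn:

* **Neighbor joining** — Saitou–Nei Q-criterion; ties broken by the
  lexicographically smallest id pair; negative branch lengths clamped to 0
  with the deficit reported. Distances: p, Poisson (−ln(1−p), capped at
  −ln(1/20) near saturation), or per-pair ML under the model.
* **Fitch parsimony** — bitmask set-intersection scoring with gaps/X as
  missing; heuristic search by random-addition replicas plus NNI
  hill-climbing; exhaustive enumeration available to 7 taxa (945
  topologies) as the oracle.
* **Maximum likelihood** — Felsenstein pruning over site patterns; WAG for
  proteins (bundled exchangeability table), JC69 for nucleotides; optional
  discrete gamma (4 categories, category means, equal weights; shape
  refined by scalar search on [0.05, 10]); NJ start, per-branch scalar
  optimization to 1e-6 substitutions/site, NNI accepted only when the
  log-likelihood improves by > 1e-8.
* **Bayesian MCMC** — Metropolis–Hastings over topologies (uniform NNI
  proposal) and branch lengths (multiplier proposal, exponential prior with
  mean 0.1 substitutions/site, uniform topology prior); two independent
  chains; convergence summarized by the average standard deviation of split
  frequencies, the same diagnostic the original full-scale Bayesian runs
  used. Desk-scale chains (thousands of iterations) replace runs of tens of
  millions; the 4-taxon posterior is validated against a quadrature oracle
  that integrates each topology's likelihood over a grid under the same
  prior.

Bootstrap support resamples columns with replacement and reports, for each
bipartition of the point tree, the percentage of replicate trees containing
it; supports below 50 are retained in data. For parsimony, the verdict
uses a different and older convention that protein-parsimony programs made
standard: support is the consensus over random-addition *search replicas
on the original alignment* (how often independent searches land on trees
containing the split), not over resampled columns; column bootstrap for
parsimony remains available separately. Majority-rule consensus keeps
bipartitions in strictly more than the rule fraction of trees (ties at
exactly one half are excluded).

## The verdict

On an unrooted tree a viral clade exists in *both* scenarios (any subtree
induces a bipartition), so monophyly alone cannot separate them; the
attachment point can. For each viral taxon we find the smallest bipartition
side containing it and at least one non-viral taxon:

* **host-nested** — in at least one method, every such clade is pure host
  *of that viral taxon's own host species*. This is the signature of a
  recent capture.
* **independent-clade** — not host-nested, and every method finds viral
  monophyly with support ≥ `min_support` (default 95).
* **ambiguous** — anything else.

Host-nested takes precedence because a nested viral clade still scores
"monophyletic with high support"; precedence is what makes the two
scenarios mutually exclusive outcomes. The support threshold is a
configurable operationalization — the original claim was visual ("clearly
separate") and came with 100% Bayesian clade support, so 95 is
conservative without being brittle. Host records with ≥ 95% identity to a
viral record are excluded first as proviral copies (the lysogenic-integration
situation in which a viral gene sits verbatim inside a host genome); at
threshold 100 only exact copies would be excluded.

The "own host species" clause needs species identity, which a two-column
id→role map cannot carry; the label-map TSV therefore takes an optional
third column (source species), and the generator always writes it.

## The synthetic generator

Each sequence is head | TM1 | pore-helix linker | filter | TM2 | tail
(defaults 8/21/22/8/21/10 residues ≈ 90 aa, the Kcv size class). TM columns
evolve under WAG restricted to {I, L, V, F, A}; loop columns (head, linker,
tail) under WAG with strongly hydrophobic residues down-weighted to 20% —
loops are solvent-exposed, and without this bias random loops frequently
bridge the two TMs into a single hydrophobic segment, which no real
channel topology does. Filter columns evolve at 5% of the mean rate, and
the core G-x-G signature is held under absolute purifying selection (G
anchors fixed, the middle restricted to Y/F/L): the canonical filter is
present in every known functional K⁺ channel, so a generator that loses it
at appreciable frequency would be emulating pseudogenes, not channels.
Indels (Poisson in number, geometric lengths with mean 3) are confined to
loop regions so the architecture survives. A planted tryptophan in the
pore helix provides the aromatic the extraction step reports.

Trees: the paralog families arise in one ancient duplication burst (a star
radiation with equal stems of twice the species depth — duplications
predate speciation, as in real channel families), and every paralog stem
carries a copy of a pure-birth (Yule) species tree. Equal family stems
matter: a random family tree occasionally produces one extremely deep
lineage whose long-branch attraction corrupts every reconstruction,
confounding the scenario contrast with an artifact. The scenarios differ
only in where the viral crown attaches:

* *independent* — as a sister lineage to the whole host gene tree, with a
  generous stem (0.3 substitutions/site beyond the deeper crown), mirroring
  the long internal edge that separates viral from cellular channels in the
  published trees;
* *piracy* — inside the host lineage with the longest terminal branch, at
  half that branch's depth (both the attachment and the viral crown must
  fit on the branch for the nesting to be identifiable at all).

Default depths (species crown 0.2, viral crown 0.3 independent / 0.05
piracy, in substitutions/site) are the package's strong-signal study
conditions: they were calibrated once so that the generator's own
contracts hold jointly — emitted viral leaves pass the screen in ≥ 95% of
cases, pore-module boundaries are recovered within half a window in ≥ 95%
of leaves, and both verdicts are recovered in ≥ 95% of fixtures — and then
frozen. The species-crown depth also keeps the piracy scenario's
capture-sister identity safely below the proviral-exclusion threshold:
with shallower species trees, a recent capture's host sister is often
nearly identical to the viral clade and gets excluded as a putative
provirus, which erases the very nesting evidence the scenario plants. Divergence is a dial: at a lineage depth of 1.5 substitutions/site
the simulated families fall to 20–30% pairwise identity, the regime of the
real viral channel alignment (~23% identity, 60% similarity); identity
saturates near 30% rather than falling further because the conserved
filter and the restricted TM alphabet set a floor, which is also why real
channel alignments remain alignable at such distances.

## Problem sizes

The default analyses and tests run at desk scale, chosen as the smallest
sizes at which every contrast is statistically clean: benchmark fixtures of
3 host species × 3 paralogs + 5 viral taxa (~90 aa pore modules), 100
bootstrap replicates, parsimony searches with 1–10 random-addition
replicas, MCMC chains of 3,000–12,000 iterations (two chains), verdict
recovery over 50 fixtures per scenario in the acceptance script (20 per
scenario in the test suite), and method agreement over 20 fixtures of 8
taxa. Exhaustive oracles cover ≤ 7 taxa (parsimony), ≤ 5 taxa × 10 sites
(likelihood), and 4 taxa (posterior quadrature).

The method-agreement analysis evolves its sequences on a fixed, fully
balanced 8-taxon tree (a viral and a host clade; internal edges 0.1,
terminals 0.06 substitutions/site) under a Kesv-length architecture
(~126 aa), so that every bipartition carries decisive signal — the regime
in which the real data placed all four approaches on one tree with full
support. On random scenario trees, short
internal edges and saturating TM columns make occasional disagreement a
property of the data, not of the methods: equally parsimonious resolutions
and sub-50% posteriors appear, and the methods then genuinely differ. The
agreement claim is about method concordance when the data decide, and the
fixture is designed to make them decide.

## Known limitations

* The screen operates on user-supplied protein sets; there is no remote
  database search, and the similarity-search role is filled by the local
  Smith–Waterman module.
* TM prediction is a single hydropathy method at two window sizes; it
  predicts neither orientation nor signal peptides, and its boundary
  uncertainty (half a window) propagates into module coordinates.
* The generator's three-class rate scheme (filter/TM/loop) has no further
  site-to-site rate variation; the ML gamma model is therefore exercised on
  its own simulations rather than on generator output.
* Progressive alignment is single-pass without iterative refinement;
  deliberately so, for determinism.
* Formal topology tests (AU/SH) and gene-tree/species-tree reconciliation
  are out of scope; the verdict is a monophyly-plus-attachment rule.
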