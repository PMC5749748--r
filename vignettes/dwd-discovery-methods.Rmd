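---
title: "Methods: discovering and characterizing DDB1-binding WD40 proteins"
author: "dwdmine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discovering and characterizing DDB1-binding WD40 proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dwdmine)
```

## The biological problem

CUL4-RING E3 ubiquitin ligases select their substrates through DWD
proteins: WD40-repeat proteins that dock onto the DDB1 adaptor via a
conserved 16-residue motif (also called the WDxR motif).  Because DWDs
sit at the head of a major ubiquitination pathway, cataloguing them
genome-wide — how many a proteome carries, what fraction of its WD40
repertoire they represent, how their domain architectures vary, and how
they group phylogenetically — is a recurring analysis in plant and algal
genomics.  `dwdmine` implements that analysis as a deterministic,
testable pipeline: WD40 detection, motif scanning, architecture typing,
reference-database characterization, motif phylogenetics, and summary
statistics, plus a simulator that plants known truth so every stage can
be validated quantitatively.

## The motif model

The DWD motif is treated as a hard position-class consensus over 16
residues:

```
[IFVL]-[IFVL]-[AGST]-[AGST]-[AGST]-x-[DE]-x-x-[IFVL]-x-[IFVL]-[WY]-[DE]-[IFVL]-[RK]
```

Twelve positions are constrained (eight classes of size 4, four of size
2); four `x` positions accept any of the 20 amino acids.  There is no
score or threshold: a window either satisfies every class or it does
not, and overlapping hits are all reported.  The unknown residue `X`
matches no position, including `x` positions — a conservative choice
that can only suppress hits on low-quality sequence, never invent them.

Two consequences of the hard-pattern model are used throughout the test
suite.  First, the per-window false-positive probability under a uniform
residue background is exactly

$$ p = \left(\tfrac{4}{20}\right)^{8} \left(\tfrac{2}{20}\right)^{4} = 2.56\times10^{-10}, $$

so ten million random windows are expected to yield `r format(1e7 * 2.56e-10)`
spurious hits — effectively none, which the acceptance checks assert
directly.  Second, under per-site substitution at rate $\mu$ with
uniform replacement among the 19 alternatives, a planted motif survives
scanning with probability

$$ P_{\text{survive}} = \left(1-\mu+\tfrac{3\mu}{19}\right)^{8}
   \left(1-\mu+\tfrac{\mu}{19}\right)^{4}, $$

which the scanner's noise tests verify empirically.

By default the scanner runs over the full sequence of WD40-confirmed
proteins; a `region_only` flag restricts it to the repeat-region hull.
Both behaviours are offered because the field's practice differs on
whether motif searches are confined to annotated repeats.

## WD40 detection

Profile-based homology search (DELTA-BLAST-class tools, structure-aware
repeat predictors) is deliberately out of scope.  The built-in detector
is an explicit sequence heuristic anchored on the one hard property of
the repeat family: units of 40–60 residues ending in the Trp-Asp
dipeptide.  Every `WD` occurrence is an anchor; anchors are chained when
their end-to-end spacing lies in `[min_len, max_len]`, and the longest
chain (found by dynamic programming, ties to the leftmost region start)
is reported when it has at least `min_repeats` units.  `min_repeats`
defaults to 4 rather than the canonical seven blades because annotated
repeats are routinely partial; both bounds and the count are
configurable.  Users with real annotations (WDSP, InterPro) can inject
them as a TSV and bypass the heuristic entirely (`resolve_wd40()` modes
`annotation` / `annotation_else_naive`).

## Architecture types

Records are classified into generic types A–K from three criteria:
motif position, motif count, and presence/topology of non-WD40
accessory domains.  The criteria define the system but not every
boundary, so the default rule table is an explicit reconstruction,
applied with fixed precedence:

1. partial proteins (configurable predicate; default: missing initial
   Met) → `PP`, excluded from type-fraction denominators;
2. accessory domains present: `K` if also ≥ 2 motifs; else `H` (domains
   on both sides of the repeat hull), `J` (≥ 2 distinct names on one
   side), `I` (nested in the hull), `F` (single domain N-terminal),
   `G` (single domain C-terminal), in that order;
3. ≥ 2 motifs → `E`;
4. else `A`/`B`/`C`/`D` by quartile of relative motif position
   (start ÷ protein length, breaks 0.25 / 0.5 / 0.75).

The quartile breaks and the multi-motif threshold are overridable via a
JSON rule table (`load_type_rules()`), so an externally specified rule
set can be matched exactly.  The precedence order within step 2 is a
design choice (domain topology is scored before side-specific single
labels); it is deterministic and order-invariant by construction.

## Homology characterization

Queries are characterized against a reference DWD database by exact
affine-gap global alignment (BLOSUM62, gap open 11, extend 1 — the
BLAST default costs), replacing heuristic local search so that "percent
similarity" is well defined and deterministic: identities plus
positive-scoring substitutions over alignment length (the "positives"
convention; gap columns count in the denominator).  A local-alignment
mode exists for comparison.  Because co-optimal alignments depend on
traceback orientation, the aligner canonicalizes argument order
internally, making identity and similarity symmetric.

A query is assigned the group of its best-similarity reference if the
hit clears `min_similarity` (default 40%) and aligned-column coverage of
the shorter sequence clears `min_coverage` (default 0.5); ties break by
identity, then reference id.  The similarity default was chosen from the
measured null: globally aligned *unrelated* random proteins score a
positives fraction concentrated near 28% (occasionally above 30%), so a
cutoff of 40% separates the null from the homolog regime while distant
true homologs (p-distance ≤ 0.2 in our simulations, similarity ≫ 60%)
are unaffected.  Per-group orthology is then the percentage of reference
members that are the best hit of at least one assigned query.

## Phylogenetics of motif sequences

Motifs are fixed 16-mers, so their multiple alignment is the identity
mapping of columns — no gapped MSA is performed anywhere in the package
(the one deliberate deviation from gap-penalized MSA practice; it is
exact here, not an approximation).  Distances are p-distances (differing
sites over compared sites, `X` sites excluded pairwise).  Trees are
built by the classic neighbor-joining agglomeration with the Q
criterion; ties in Q break on the lexicographically smallest label pair
(internal nodes are represented by the smallest leaf beneath them), so
the topology is independent of input row order.  Negative branch
lengths are clamped to zero with the deficit moved to the sister branch,
preserving the joined pair's summed length.  On additive matrices the
implementation reproduces the generating tree's topology and its full
path-length matrix to ≤ 1e-9, verified against an independent NJ
implementation in the tests.

Bootstrap supports resample the 16 columns with replacement (default
1,000 replicates, seeded) and count, for each internal edge of the
reference tree, the percentage of replicate trees containing the same
bipartition.  A bipartition only counts when its edge length exceeds
1e-12: a zero-length edge is an arbitrary resolution of a polytomy, so
fully degenerate alignments yield support 0 everywhere instead of
spuriously perfect support.

Multi-motif proteins are represented in trees by their `D1` motif (the
first occurrence N→C), configurable via `tree_motif`.  Tree cutting into
`k` groups removes edges in rank order — length descending, then
bootstrap support, then smallest leaf below — accepting only removals
that split a leaf-containing component into two leaf-containing
components, until `k` groups exist.  Ranking over *all* edges (not just
internal ones) is required for the boundary cases `k` near the leaf
count, since an unrooted binary tree has only `n − 3` internal edges.

## The simulator and what it does (not) emulate

`generate_dataset()` builds homolog families along a known species tree:
an ancestral backbone of 4–8 repeats of 40–60 residues (interior
residues uniform over the 20 amino acids — the simplest null, and the
one that makes the closed-form false-positive rate exact), motifs
planted in distinct repeat units with probability mix
`motif_count_probs`, optional accessory domains, and Jukes–Cantor-style
evolution to the leaves (per-branch substitution probability
$1 - e^{-t}$, uniform replacement).  Defaults describe the standard
simulated study: 3 species, 200 families, `dwd_fraction = 0.55` (the
DWD share of WD40 repertoires in green lineages is roughly 53–57%), and
`motif_count_probs = (0.76, 0.21, 0.03)` — midpoints of the observed
72–80% / 17–24% / 0.5–4.7% ranges for one/two/three motifs.
`other_domain_prob = 0.35` roughly matches the combined frequency of
the accessory-domain types (F–K) in surveyed repertoires.

Three protection rules keep the ground truth exact:

* repeat-terminal `WD` anchors are invariant sites, so `is_wd40` labels
  stay detectable at any branch length;
* motifs are planted away from unit-terminal anchors and never overlap
  (one per repeat unit);
* accessory-domain insertion between repeats is only offered when at
  least four units remain on each flank, so the anchor chain still
  qualifies at default thresholds.

Motif degradation is controlled by a single knob: motif windows are
protected during tree evolution and receive one per-leaf round of
substitution at `motif_noise_rate` (and non-motif sites one round at
`noise_rate`, an annotation-noise interpretation).  This makes the
closed-form survival probability above directly applicable.

The simulator does **not** emulate: indels (keeping coordinates stable
and p-distances alignment-free), realistic amino-acid composition or
site-rate heterogeneity, gene duplication/loss, or real accessory-domain
models (the six domain names are synthetic stand-ins with random
content).  Passing tests therefore demonstrate correctness of the
*computations* under a clean substitution-only model — not detector
sensitivity on real, indel-rich, compositionally biased proteomes, where
the naive WD40 heuristic is expected to be the weakest link and
precomputed annotations are recommended.

## Numerical and reproducibility choices

* Coordinates are 0-based half-open everywhere in memory; reports print
  1-based inclusive positions.
* All tie-breaks (NJ pairs, chain starts, best-hit references, edge
  ranking) are lexicographic or leftmost — reruns and row permutations
  give identical results.
* Every entry point with randomness takes a seed; identical configs
  produce byte-identical output files (fixed `\n` line endings).
* Newick output prints branch lengths to 6 decimals and integer
  supports as internal labels; internally NJ carries full double
  precision (additivity to 1e-9 is checked before serialization).
* Problem sizes used by the validation runs: 10^5 + 10^4 windows for
  scanner/oracle agreement, 10^7 windows for the false-positive bound,
  3 × 200 proteins for the end-to-end study, 100 random 8–16-taxon
  trees for NJ, 1,000 bootstrap replicates, 200 short pairs for the
  alignment oracle.

## Known limitations

The WD40 heuristic misses repeats whose terminal dipeptide deviates
from `WD` (real repertoires contain such units) and reports a single
best chain per protein.  Global alignment percent similarity is not
comparable to local-HSP similarity values from heuristic search tools.
The A–D position quartiles and the F–K topology precedence are one
defensible reconstruction of a partially specified typing scheme; use
the JSON rule table to match an external definition.  Bootstrap support
on 16-column alignments saturates quickly and should be read as a
stability indicator, not a posterior probability.
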