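---
title: "Methods: function-structure-adaptability annotation of protein residues"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: function-structure-adaptability annotation of protein residues}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fsannot)
```

## The problem and the idea

Evolutionary conservation flags residues that matter, but it cannot say *why*
they matter: a strictly conserved aspartate may coordinate a cofactor
(functional) or stabilise the fold (structural). Structure-conditioned
sequence design networks such as ProteinMPNN provide a complementary signal.
They generate sequences optimised for the stability of an input backbone, so
positions they conserve are the ones general folding rules demand — while
positions that evolution conserves but the network ignores are candidates for
functional roles that trade stability for activity.

`fsannot` formalises this comparison. Given two sequence sets over the same
reference protein — curated natural homologs on one side, design-network
output on the other — it classifies each reference position as

* **functional** — significantly class-enriched in the natural set only,
* **structural** — significantly class-enriched in both sets,
* **adaptable** — significantly class-enriched in the designed set only,
* **unlabeled** — in neither.

## The statistical procedure

Each branch is reduced to a position-specific scoring matrix (PSSM): the
relative frequency $p_i(a)$ of amino acid $a$ at reference position $i$,
either parsed from an ASCII psiblast-dialect file or computed from the
alignment with a background pseudocount,
$p_i(a) = (n_i(a) + \kappa\,b_a)/(n_i + \kappa)$,
where $n_i$ counts the usable (non-gap, non-X) characters in the column,
$b$ is the background distribution and $\kappa \ge 0$ the pseudocount
(default $\kappa = 1$ with uniform $b$, which keeps every frequency strictly
positive without materially distorting deep alignments). Columns gapped in
the reference are dropped, so coordinates always match the query-anchored
convention of psiblast PSSMs. All downstream statistics use frequencies, not
log-odds, because log-odds scales are dialect-dependent.

Amino acids are grouped into physicochemical classes. The default
six-class scheme is acidic $\{D,E\}$, basic $\{K,R\}$, hydrophilic
$\{S,T,N,Q,H,C,Y\}$, hydrophobic $\{A,V,L,I,M,F,W\}$, glycine $\{G\}$ and
proline $\{P\}$. Histidine sits with the polar class — summing histidine and
glutamine conservation is exactly the kind of signal the class view is meant
to capture — and any one-dimensional grouping is a simplification for
histidine and the aromatics, so the scheme is an ordinary, overridable
configuration object whose membership is echoed into every output.

For position $i$ and class $c$ with members $M_c$, the enrichment test
compares the sample $A = \{p_i(a) : a \in M_c\}$ against the leave-one-out
whole-protein baseline $B = \{p_j(a) : a \in M_c,\ j \ne i\}$ with a
one-sided Mann-Whitney U test ($U$ counts pairs with $A > B$, ties as 1/2).
Significance is a raw $p < \alpha$ with $\alpha = 0.01$; no multiple-testing
correction is applied by default (Benjamini-Hochberg is available). A
`class_sum` mode that compares the summed class frequency $F_i(c)$ against
the other positions' sums is provided as an alternative reading; member mode
is the default because it is the only construction that gives the rank test
more than one observation per multi-residue class.

Positions are then filtered by how much *and* how confidently they deviate
from the protein's average composition: with $F_i$ the class-frequency
vector, $\bar F$ its mean over positions, $d_i = F_i - \bar F$ and
$I_i = \log_2 20 - H(p_i)$ the information content in bits, the score
$s_i = I_i \, \lVert d_i \rVert$ ranks positions, and the top
$\lceil f L \rceil$ are retained (default keep fraction $f = 0.8$).
Enrichment flags on discarded positions are revoked but recorded. Ties are
broken by ascending position, which makes retained sets deterministic and
nested across $f$. Each branch is filtered independently before the two are
compared. The keep fraction is the pipeline's main tunable: it should be
calibrated per protein family — for example against literature-described key
residues — and in practice it mostly moves the count of *adaptable* calls,
which are often borderline natural-enrichment cases.

Finally the two branches are combined by the truth table above. In the
default `any` convergence mode, "significant in both" suffices for a
structural call; the stricter `same_class` mode additionally requires one
enriched class shared by both branches, and positions that are significant
in both branches without a shared class stay unlabeled — the one assignment
that keeps the classification symmetric under swapping the two inputs.
Positions whose natural enrichment does not include the query residue's own
class are flagged `query_deviates`: the homolog family, not the query
sequence, drives such calls, which often mark positions where the query has
wandered from the family consensus.

## Numerical choices

* **Exact versus approximate U test.** The exact conditional permutation
  distribution of $U$ (ties handled exactly) is used whenever
  $\binom{n+m}{n} \le 2\times10^5$; otherwise a tie-corrected normal
  approximation with continuity correction. The enumeration cap, rather than
  a cap on $n+m$, matters for the singleton classes: glycine or proline
  contribute a single observation against $L-1$ baseline values, and a
  normal approximation can never push one observation below $p = 0.01$,
  whereas the exact test gives $p = r/L$ for the value of rank $r$ from the
  top. Closed enumerations are used for samples of size one and two.
* **Degenerate samples.** If all pooled values are identical (e.g. a class
  with zero mass everywhere) the test returns $p = 1$ with a warning, never
  an error.
* **Singleton-class granularity.** The $p = r/L$ floor has a practical
  consequence: at $\alpha = 0.01$ and $L \le 100$, no singleton class can
  ever be significant, and for larger $L$ only the single top-ranked
  position per class can be. Conserved glycines and prolines are therefore
  systematically conservative calls in member mode; `class_sum` mode has the
  same one-observation floor by construction.
* **Gap handling.** Gaps and unknowns are excluded from column counts rather
  than treated as a 21st symbol; columns whose unusable fraction exceeds 50%
  (configurable) are flagged `low_coverage` but still computed. Columns with
  no usable characters are an error naming the positions.
* **Filter boundary cases.** `keep_fraction = 1` is the identity;
  `keep_fraction = 0` revokes everything.

## The synthetic benchmark

Real paired inputs require an external design run and a curated homolog
alignment, so the package ships a generator that emulates the statistical
structure the pipeline assumes: unplanted columns draw residues i.i.d. from
a background distribution in both sets; a planted column draws, with
probability `strength`, a residue uniformly from its target class and
otherwise from the background. Planting in the natural set only yields a
ground-truth *functional* position, designed-only *adaptable*, both
*structural*. The per-column modal residue is prepended as the gap-free
reference row. Generation is a pure function of the spec's seed.

The default benchmark (`default_benchmark_spec()`) uses 120 positions, 200
sequences per set, strength 0.9 and ten planted positions per label —
alignment depths and a signal level typical of a well-curated single-family
study. Plants cycle through the four multi-member classes only: planting the
same singleton class at several positions would measure the $r/L$
granularity floor described above rather than pipeline recovery, since at
most one such position can mathematically be flagged. Under these
conditions the pipeline recovers at least 90% of planted labels (the
residual losses are almost always a false flag in the *opposite* branch
promoting a functional or adaptable plant to structural — an irreducible
consequence of testing ~720 position-class pairs per branch at
$\alpha = 0.01$).

What the generator does *not* emulate: phylogenetic correlation among
natural sequences, backbone-mediated correlation among designed sequences,
gaps, and compositional heterogeneity along the chain. Passing the benchmark
therefore demonstrates the statistical machinery on exchangeable columns —
the assumption the rank test actually uses — and says nothing about
alignment curation quality, which on real data remains the dominant factor.

Null specs (no plants) bound the false-call rate: empirically the per-test
flag rate at $\alpha = 0.01$ is about 0.004 and the fraction of positions
receiving any label stays near 6%, well below the $3\alpha K$ ceiling the
test suite enforces. These quantities are recomputed from scratch by
`scripts/acceptance.R`.

## Design choices that were genuinely open

* **Sample construction for the U test** (member mode with leave-one-out
  baseline) — the only reading that gives multi-residue classes a usable
  sample size; `class_sum` is retained as an option and both are recorded in
  output metadata.
* **Filter-then-compare order**: each branch is filtered independently
  before classification, matching the procedural order of the method
  description; filtering after comparison would preserve more borderline
  structural calls, and users can emulate it with `keep_fraction = 1` plus
  post-hoc filtering on the exported scores.
* **Homodimer design output**: the default `first_chain` policy keeps one
  protomer per record, since multistate dimer designs produce near-identical
  protomers and pooling would double-count; `pool_all_chains` and
  `concatenate` are available.
* **Percentages versus raw frequencies**: file-derived PSSMs use the
  weighted observed percentages (renormalised when rounding makes a row miss
  100); alignment-derived PSSMs use pseudocounted column frequencies. Both
  paths are exposed, and which one fed a run is recorded in the PSSM's
  `source` field.

## Known limitations

One-dimensional classes flatten chemistry (histidine, aromatics); the raw
$p < 0.01$ rule ignores multiplicity by design and should be read as a
screening threshold, not an inferential claim; singleton classes are
conservative as described; and label transfer between homologs with
different numbering is out of scope. The problem sizes used in the test
suite (alignments of tens to a few hundred sequences, 20-120 positions)
reflect the package's intended single-protein scale.
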