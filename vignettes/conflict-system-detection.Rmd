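---
title: "Detecting conserved conflict systems: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting conserved conflict systems: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conflictscan)
```

## The detection model

`conflictscan` identifies conserved, operon-like conflict systems from
three kinds of evidence: protein similarity, gene order, and cross-phylum
conservation.

**Similarity.** Two proteins are linked when their best Smith–Waterman
local alignment (BLOSUM62, affine gaps 11/1) covers at least a fraction
`L` of *both* sequences and its score density — the Karlin–Altschul bit
score $(\lambda r - \ln K)/\ln 2$ divided by the number of aligned
columns — reaches `S` bits per column. Clusters are connected components
of this link graph (single linkage). The defaults `L = 0.9`,
`S = 1.89` are the near-identity culling setting; classification-style
grouping needs lower values, and both are plain parameters of
`scoring_params()`. The neighborhood scanner clusters context proteins
with a looser classification default (`L = 0.6`, `S = 0.8`
bits/column): conserved neighbors from different phyla are homologous
rather than near-identical, and the culling thresholds sit at the
margin of typical within-family densities — two sequences each 5%
diverged from a common consensus average roughly 1.8 bits per aligned
column under BLOSUM62, just below 1.89 — which would make cross-phylum
pooling depend on single-linkage chaining luck. A percent-identity density mode is available for
users who prefer identity thresholds for culling. The two-sided coverage
requirement is deliberate: one-sided coverage would chain multidomain
proteins through shared single domains.

**Gene order.** A system template is an ordered list of required
component domains plus optional accessory domains, an anchor domain, and
an effector-host domain. A neighborhood (±`window` genes around an
anchor, default 5 per side) matches when a run of consecutive genes
carries the required domains in template order, read 5′→3′ on the coding
strand — for minus-strand anchors the genomic order is reversed before
matching. One protein carrying several consecutive required domains in
N→C order satisfies all of those roles, which is how fused components
(for example a vWA–β-propeller fusion) are handled. Three filters apply:

1. every intergenic gap inside the run is at most `max_gap` nucleotides
   (default 70, counted strictly between gene spans, floored at 0 for
   overlapping genes);
2. all run members share one strand;
3. the run's cluster-level signature occurs in at least `min_phyla`
   (default 2) phyla.

**Conservation signatures.** The signature of a matched run is the
ordered tuple of protein-cluster ids of its *required-component context
genes*, together with their strand pattern, both expressed in coding
orientation. Two deliberate exclusions keep signatures stable: the
anchor gene itself (its protein carries a variable effector complement,
so full-length clustering would fragment otherwise identical contexts)
and optional accessory genes (their presence varies between instances of
the same system). This mirrors how neighborhood conservation is judged
in practice — by clustering the neighbors of the query rather than the
query itself. Exact ordered equality of signatures is required; this is
the strict reading of conservation, and a broader shared-core notion can
be emulated by trimming templates.

**Effectors.** The effector complement of an instance is the list of
domains C-terminal to the core domain on the effector-host protein, in
N→C order, from the resolved architecture. Architectures themselves are
the exact maximum-total-score subset of domain hits under a pairwise
overlap tolerance (10 aa by default); exhaustive selection is used up to
15 hits per protein (beyond that a greedy scan, which in practice never
triggers on real domain tables). Greedy selection was rejected because
it can discard two compatible hits in favour of one overlapping
higher-scoring hit, violating the max-score interpretation.

## Statistical layer

**Trait enrichment.** For each system type, `multicell_enrichment`
counts organisms (presence/absence, not instance counts): `k` with the
system, `q` of those flagged multicellular, against `m` multicellular
and `n` non-multicellular organisms overall, and reports the upper tail
$P(X \ge q)$ of the hypergeometric distribution, computed in log space
so that extreme associations (far below 1e-300) stay finite. Organisms
with an `NA` flag carry no information and are excluded from both the
universe and the counts; including them among the negatives would
inflate `n` and bias the test toward significance. A
Benjamini–Hochberg column is emitted for convenience but no conclusion
in this package depends on it.

**Positional clustering.** Normalized anchor positions
(`anchor_stop / replicon_length`; the stop is the gene end on the plus
strand and the gene start on the minus strand) are binned into 20 equal
chromosomal intervals and tested against uniformity with
$\chi^2 = \sum_b (O_b - E)^2/E$, $E = N/20$, on 19 degrees of freedom.
The default is the literal 20-interval reading over $[0,1]$; `fold =
TRUE` maps $x \mapsto \min(x, 1-x)$ first, collapsing a symmetric
two-arm preference into a single mode, for users who want the folded
variant of the same test.

**Entropy screening.** Column entropy is $-\sum_a p_a \log_2 p_a$ over
the 20 standard residues, with gaps and `X` excluded from the
frequencies; columns more than 50% gapped are skipped (common practice
for domain alignments — such columns reflect indel placement more than
substitution). No sequence weighting is applied by default; families
emitted by the generator are unweighted samples, and weighting is a
preprocessing concern for real alignments. Rank-sum comparisons use the
exact two-sided distribution when the pooled sample has at most 12
values and no ties, and the tie- and continuity-corrected normal
approximation otherwise. The corrected approximation tracks the exact
p-value to within about 0.05 in the worst corner of the 6–12 size range
(unbalanced splits, tail statistics) and much closer in the bulk; the
exact branch is used precisely where this matters.

**Tree congruence.** `rf_congruence` consumes externally inferred
newick trees, prunes both to shared leaves, unroots, and reports the
Robinson–Foulds distance normalized by its maximum $2(n-3)$.
Trees are never inferred here.

## The synthetic-data generator

`generate_dataset` emulates the statistical structure each stage
assumes, with every default chosen once as the validation condition:

* 300 genomes over three phyla (0.4/0.3/0.3); 27% of informative
  organisms multicellular, 5% flagged `NA`;
* per-template planting probability 0.3 given multicellular versus 0.02
  otherwise; 36% of system-bearing organisms carry two or more
  paralogous systems;
* 200 genes per chromosome (mean 900 nt), operon-like strand runs
  (flip probability 0.25), geometric intergenic gaps with mean 30 nt in
  the background and mean 15 nt *within* planted systems, truncated at
  the template's `max_gap` — operonic spacing is tighter than
  background spacing, and the truncation guarantees that every planted
  instance satisfies its own template, which is the generator's ground
  truth contract;
* 1–11 effector domains per instance (1 plus a Binomial(10, 0.2) draw;
  mean 3), sampled from a 16-domain weighted pool;
* component families emitted from random consensi at 5% per-site
  divergence (so family members co-cluster at the culling thresholds),
  and a fast/slow alignment pair at 30% versus 5% divergence for the
  entropy contrast;
* anchor positions uniform by default, or a symmetric bimodal mixture
  (modes 0.33/0.67, s.d. 0.05) for positional-power studies;
* decoy neighborhoods, each violating exactly one filter: an internal
  gap of `max_gap + 50`, one flipped strand, or confinement to a single
  phylum (with its own protein families so its signature cannot borrow
  conservation from genuine systems). Gap and strand decoys are spread
  round-robin across phyla so that relaxing *only* the violated filter
  admits them.

Randomness is stage-keyed: metadata, family consensi, planting,
assembly and alignments each draw from a seed derived from the run seed
and a fixed stage index, so extending one stage does not perturb the
others, and a fixed seed reproduces every output file byte for byte.

What the generator does **not** emulate — and what green tests therefore
do not certify about real data: phylogenetic correlation of gene
content, lateral transfer, pseudogenes and annotation errors, domain
hits from actual profile searches (hits are emitted from the planted
layout with ±3 aa jitter), realistic amino-acid composition, and indels
within families. Detection performance on the generator is an upper
bound for performance on real annotations.

## Problem sizes and numerical choices

The shipped validation runs at deliberately modest scale: end-to-end
recovery on 24–36 genomes of 30 genes (≈20–30 planted systems over
three phyla), enrichment calibration on 200 runs of 300-genome planting
simulations, positional calibration on 100 draws of 141 positions, and
entropy contrast on 100 seeded family pairs of 30 sequences × 120
columns. These sizes give stable Monte-Carlo estimates for the
calibration bands while keeping a full check fast on a single CPU;
nothing in the implementation is specific to them.

Tie-breaks are deterministic everywhere: cluster representatives are
the longest member then the lexicographically smallest id; overlapping
instances of one template keep the candidate with more matched optional
components, then the leftmost; equal-score hit selections prefer more
hits, then earlier alignment starts. Degenerate inputs are defined
explicitly: empty instance lists give `NA` means, a rank-sum test on
identical values returns p = 1, an all-gap alignment column is skipped,
and a system absent from the informative universe reports `p = NA`
rather than 0 or 1.

## Known limitations

* All-vs-all alignment is quadratic; the length-ratio prefilter
  (shorter/longer ≥ L) is exact in spirit for two-sided coverage but is
  a heuristic, and can be disabled where exactness matters.
* The multi-phylum filter needs the phylum annotation to be right;
  misassigned phyla convert single-phylum systems into apparent
  cross-phylum ones.
* Signature matching is exact; orthologous neighborhoods whose
  components split into different clusters (fast-evolving components,
  aggressive thresholds) will not be pooled.
* The positional test assumes one linear coordinate per replicon;
  circular chromosomes are treated as linearized at the origin.
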