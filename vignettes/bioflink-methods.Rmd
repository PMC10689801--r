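---
title: "Methods: virus-prokaryote interaction analysis in bioflink"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: virus-prokaryote interaction analysis in bioflink}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`bioflink` reconstructs virus-prokaryote interactions from assembled
metagenomes of surface-attached microbial communities (biofilms) and their
surrounding seawater.  This vignette is the package's own account of the
methods: the rules and models each stage implements, the tunable parameters
and why their defaults are what they are, what the synthetic-data generator
does and does not emulate, and the numerical choices made where the design
was genuinely open.

## Sequence primitives

All coordinates are 0-based half-open; strands are `+`/`-`.  FASTA I/O and
exact pattern matching are delegated to Biostrings; the local aligner and
terminal-repeat detector are implemented in the package (C++ kernel for the
aligner).

**Local alignment** (`local_align()`) is seed-and-extend: exact `seed_k`-mer
anchors (default 13, minimum 11) are hashed on the target, seed hits are
grouped into near-diagonal colinear bands (diagonal drift tolerance 20,
maximum seed gap 500), each band is extended at both ends with an ungapped
X-drop rule (match +1, mismatch -1, drop-off 20), and the resulting region
is re-scored with a unit-cost banded global alignment (band half-width =
indel drift + 16) whose traceback counts matching columns.  `identity` is
matches over alignment columns; `aln_len` is the query span.  Overlapping
alignments are resolved greedily by match count, so the output is a set of
maximal non-overlapping local alignments, each individually satisfying the
identity and length thresholds.  The unit-cost scoring is deliberate: the
linkage rule the aligner serves is a hard threshold (70% identity over
2.5 kb), not a similarity ranking, so affine gap modelling would add
parameters without changing any call.  E-values are not computed: any
2.5 kb alignment at 70% identity is overwhelmingly significant, so the
length and identity thresholds subsume the customary E-value gate.

**Terminal repeats** (`detect_terminal_repeat()`) report the longest exact
prefix that recurs as the suffix, found by anchoring the first
`min_repeat_len` bases (default 20, a common completeness-checking
convention; minimum 10) and testing each anchor occurrence as a suffix
start.  The repeat is annotated with its exact occurrence count in the
scaffold, the fraction of the scaffold covered by the union of occurrences,
whether it contains `N`, and a low-complexity flag.  Low complexity is
defined here as >75% a single base or a perfect 1-3-mer tandem; the
screening literature names low-complexity repeats without defining them,
so the package states its own operational definition.

## Viral triage

A scaffold is a **provirus** only when an external provirus call (supplied
as a table; provirus boundary detection itself is out of scope) coincides
with membership of a quality prokaryotic bin (completeness >= 50,
contamination <= 10).  A scaffold is a **closed genome** when all six rules
hold: DTR present; not a provirus; repeat not low-complexity; repeat free
of `N`; fewer than six repeat copies; repeat copies covering < 20% of the
scaffold.  "Repeat region" is read as the total bases covered by all
occurrences (the union), the stricter of the two readings of a repeat
fraction; a single-copy reading would only loosen the rule.

**Majority-rule taxonomy** assigns a phylum when its summed gene bit scores
strictly exceed half the total (fraction 0.5, configurable); exact ties are
unclassified.  **Bin purity** discards candidate viral bins whose member
scaffolds disagree on phylum (per-scaffold majority rule) or that carry two
or more terminase large subunit (TerL) genes — TerL is effectively
single-copy in phage genomes, so duplicates indicate a mixed bin.
Discarded bins release their scaffolds into the fragment pool; the filter
conserves scaffolds exactly.  A configurable allow-list restricts units to
phyla that infect prokaryotes (Uroviricota, Hofneiviricota,
Preplasmiviricota, Phixviricota, Duplornaviricota, Dividoviricota).

## Virus-host linkage

Four channels, integrated by OR; every reported link is re-verifiable from
the raw sequences:

* **homology** — any viral-scaffold x host-scaffold alignment at identity
  >= 0.70 and span >= 2500 bases.  The length rule is enforced per
  alignment, not summed across alignments, matching the per-HSP convention
  of alignment tools.
* **crispr** — a spacer from a host CRISPR array matches a viral sequence
  exactly, on either strand, with spacers required to exceed 6 bp.  Arrays
  are detected CRT-style but with exact repeat copies (conservative
  relative to fuzzy-repeat detection): duplicated 19-mers at admissible
  periods seed candidate repeats, which are extended to the maximal common
  repeat (19-48 bases) over >= 3 copies with spacers of 19-48 bases;
  candidate arrays are claimed greedily left-to-right, longest repeat
  first.  A tandem repeat extends past its own period and is rejected by
  the spacer-length check rather than truncated into a fake array.
* **trna** — an identical full-length tRNA gene annotated on both sides
  (tRNA prediction itself is out of scope; genes arrive annotated).
  Matching searches both strands, since orientation on assembled scaffolds
  is arbitrary.
* **kmer** — at least `min_shared` distinct canonical 25-mers in common.
  The default `min_shared = 10` is the package's own acceptance bar for
  this alignment-free channel: two random 10 kb sequences share zero
  25-mers with overwhelming probability, so ten distinct shared 25-mers is
  far outside noise while still detecting a single shared 300 bp block
  (276 shared 25-mers).

A provirus unit is never linked to the bin that contains it.  Pairs map to
populations and form a bipartite network whose connected components are the
infection groups; components are computed with igraph and cross-checked
against a union-find oracle in the tests.

## Populations

ANI is fragment-based: the query is cut into consecutive 500 bp fragments,
each aligned to the target; a fragment counts as aligned when its best
alignment covers >= 80% of it, and ANI is the mean identity over aligned
fragments, reported only when the aligned fraction reaches 0.8 for viruses
or 0.5 for host bins (host bins are larger and patchier).  ANI is
directional; clustering uses the larger of the two directed values.
Populations are single-linkage components at ANI >= 95, the standard
dereplication convention; population identifiers are deterministic and
invariant to input order.  An optional k-mer prefilter in `ani_matrix()`
skips genome pairs sharing fewer than a configurable number of canonical
25-mers — genomes anywhere near the 95% threshold share thousands, so a
bar of 100 only removes pairs that could never cluster.

## Quantification

Unit depth is the length-weighted mean of member-scaffold depths; the
canonical input is a per-scaffold depth table, with an optional BAM adapter
(`depth_from_bam()`) producing the same table.  The virus-to-prokaryote
ratio of a host is the *sum* of its paired viruses' depths over its own
depth — multiple infections accumulate — with fragments excluded because
they under-represent whole viral populations; zero-depth hosts are flagged
rather than dividing by zero.  RPKM is `count / (length_kb x
library_millions)`; relative abundance divides each gene's summed RPKM by
the (location, sample-type) group total, so groups sum to one.  TPM is
computed per repeat sample and sums to 1e6 exactly.  A gene is *expressed*
when at least one assembled transcript maps to it in any repeat, or its
read count is positive in all repeats.  Transcript mapping "full coverage"
is read as the transcript aligned over its own full length: a fragment of a
transcript is weak evidence, but a complete transcript need not tile the
whole gene.

## Defensome rules

Defence calls are a conjunction: a PADS-style hit (identity >= 30%,
E < 1e-10) *and* a PFAM conserved-domain confirmation (E < 1e-3, bit score
>= 30) whose accession belongs to the same system in the shipped
system-component-accession map (`inst/extdata/defence_systems.yaml`).
Counter-defence applies the same conjunction to viral genes restricted to
RM accessions, with type I/II/III labels.  AMGs need a passing KEGG hit
(E < 1e-5, score above the per-family threshold carried in the hit table),
a passing PFAM hit, and membership of the curated accession set
(`inst/extdata/amg_accessions.yaml`); genes first or last on their scaffold
are flagged `edge_gene` rather than removed — mechanising a manual
positional screen as a flag keeps the decision visible.  A system is
complete in a container when every required component has at least one
called gene.  The shipped YAML maps are small illustrative defaults (nrdA,
psbA, RM components, cas genes, TA pairs, and one to three components per
named system); completeness of any database's curation is explicitly not
reproduced, and both files are meant to be replaced wholesale by users
with curated sets.  Calls are monotone in every threshold.

## Differential abundance and meta-analysis

Per location, biofilm vs seawater: median-of-ratios size factors
(geometric-mean reference over genes positive in all samples); gene-wise
NB dispersion by method of moments on normalised counts, pooled within
groups, `alpha = max((v - m) / (m + 0.5)^2, 1e-8)` — the half-count
pseudocount stabilises low-mean genes and the floor keeps the GLM family
proper; a log-link negative-binomial GLM with the size factors as offsets;
and a Wald test of the group coefficient.  The Wald statistic is referred
to a t distribution with `n - 2` degrees of freedom rather than a normal:
with eight samples per group and a moments-plugged dispersion, the normal
reference is visibly anticonservative, and the t reference brings the
empirical type-I error at nominal 0.05 to ~0.05 (measured on 2000 null
genes in the tests).  This stage is deliberately a plain NB-Wald fit — no
shrinkage, no independent filtering — and exact numerical agreement with
any particular differential-abundance package is a non-goal; the contract
is parameter recovery on synthetic truth, and a correlation cross-check
against an established NB implementation runs in the test suite.

Genes with BH-adjusted p < 0.05 in at least one location enter the
meta-analysis.  Pooling is classical DerSimonian-Laird: `w_i = 1/se_i^2`,
`Q = sum(w_i (y_i - ybar_w)^2)`,
`tau2 = max(0, (Q - (k-1)) / (sum w - sum w^2 / sum w))`, re-weighting
`w*_i = 1/(se_i^2 + tau2)`, a z test on the pooled effect and a 95%
interval of +/- 1.96 pooled standard errors.  With one location the input
effect is returned exactly.  DL is the classical moment estimator and
matches the reference implementation in the metafor package to 1e-8 in the
tests; a REML variant would be a natural extension.  Sign convention:
positive log2 fold change means seawater-enriched (the seawater group is
the numerator); a flag flips it.  The analysis is per gene with a
system-level rollup of significant genes by direction.

## The synthetic-community generator

The generator is the package's instrument for making every rule testable;
its defaults are the package's reference conditions.  Hosts are bins of
three scaffolds (24 kb total), phages single 10 kb scaffolds (the pipeline
analyses scaffolds >= 5 kb); the default link plan places one pair per
phage, cycling the four channels, plus a second channel on every other
pair — 30 channel-links over 20 pairs for the default 20 phages and 10
hosts.  Planted evidence is literal: homology copies a 3 kb block
phage-to-host with 10% substitutions (comfortably inside the 70% identity
rule while far from trivial identity); crispr builds an array (repeat
25-35 bp, 3-8 spacers of 25-40 bp) with at least one spacer copied exactly
from the phage; trna copies an identical 75 bp gene into both genomes and
records it in the gene table; kmer copies a 300 bp block exactly.  DTR
phages get a clean 40 bp terminal repeat; proviruses are phage blocks
embedded in an extra host-bin scaffold listed in the provirus-call table.
tRNA insertions are planted before any channel copies material *from* a
phage, and host-side insertion points avoid previously planted features,
so one channel can never destroy another's evidence.  Depth profiles are
log-normal (phages around 50x, hosts around 8x).  Count tables are
negative-binomial with gene-wise dispersion 0.1, log-normal library-size
factors (sd 0.25 on the log scale) and log-normal baseline means — the
same family the DA model assumes, which is the point: the DA tests measure
estimator calibration, not robustness to model misspecification.

What the generator does **not** emulate: GC bias and non-uniform base
composition (background is i.i.d. uniform ACGT), sequencing error and
read-level artefacts (depth tables stand in for alignments), assembly
fragmentation and chimerism, fuzzy CRISPR repeats, within-array spacer
turnover, compositional effects in count data, and batch structure.
Passing tests therefore demonstrate that the rules and estimators do what
they claim under their stated assumptions — not that those assumptions
hold in any particular ocean.

## Determinism and problem sizes

Every stochastic step derives from one integer seed; the pipeline writes a
manifest with a configuration hash and per-file checksums, and two runs
with the same configuration are byte-identical (the manifest deliberately
records no wall-clock timestamps, so whole output directories compare
equal).  The test and acceptance workloads use a 20-phage/10-host
community for linkage, 50 scaffolds for the closed-genome rules, 10 kb
genomes in groups of 3/2/2 for population recovery, 2000 null genes for
type-I calibration and 200 genes x 2 locations for effect recovery —
sizes chosen so the planted structure is unambiguous and the whole suite
runs comfortably on a laptop.

## Known limitations

* The aligner's exact-seed design misses homology below ~75% identity when
  no 13-mer survives in a 500 bp window; irrelevant at the 70%/2.5 kb
  linkage rule, but the fragment-ANI floor of usable divergence is ~25%.
* Exact-copy CRISPR detection misses arrays whose repeats have mutated
  between copies.
* The k-mer channel's `min_shared = 10` is a stand-in for a significance
  test of shared k-mer counts; it is configurable, and the channel should
  be treated as supporting evidence rather than proof.
* The defence/AMG YAML maps are illustrative; biological conclusions
  require a curated replacement.
* The DA stage assumes NB counts with library-size offsets; compositional
  (CLR-type) effects are out of scope.
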