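---
title: "Surveying type I PKS ketosynthase domains across biomes"
author: "pksurvey"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surveying type I PKS ketosynthase domains across biomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pksurvey)
```

## The problem

Type I polyketide synthases (T1PKSs) are multidomain enzymes whose products
include many clinically important natural products. Their ketosynthase (KS)
domain — the chain-elongating catalytic domain — is conserved enough to
detect by homology yet variable enough that its phylogeny predicts the PKS
architecture (modular *cis*-AT assembly lines, *trans*-AT systems,
iteratively acting forms) and often the product class (polyunsaturated
fatty acids, enediynes, polycyclic tetramate macrolactams). KS sequence
tags therefore let us survey biosynthetic potential in fragmented
metagenomic assemblies where whole biosynthetic gene clusters rarely
assemble intact.

`pksurvey` implements that survey as a tested pipeline: KS domain
detection and top-hit classification against a labeled reference
collection, full-length domain extraction, clustering into operational
biosynthetic units (OBUs), richness and biome-composition statistics,
in-silico evaluation of degenerate KS PCR primers, and an
amplicon-truncation concordance experiment. A seeded synthetic-data
generator supplies biome-structured inputs with ground-truth labels so
every stage is testable offline.

## Detection and classification model

Query peptides (or six-frame translations of contigs at least 600 nt long;
the boundary is inclusive — a 600-nt contig is kept) are searched against a
labeled reference collection of full KS domains by affine-gap local
alignment (BLOSUM62, gap open 11, extend 1). Raw scores are converted to
bit scores with fixed gapped Karlin–Altschul constants
($\lambda = 0.267$, $K = 0.041$):

$$S' = \frac{\lambda S - \ln K}{\ln 2}, \qquad E = m\,n\,2^{-S'}$$

with $m$ the query length and $n$ the total residue count of the reference
collection. A candidate region's best hit (highest bit score; ties broken
by E-value, identity, then reference id) becomes a domain call if and only
if the alignment spans at least 200 columns and $E \le 10^{-30}$. We read
the published "minimum E-value of $10^{-30}$" in its standard sense of a
maximum allowed E-value. Multiple domains per peptide are accepted when
their query intervals overlap by less than 50% of the shorter interval —
multimodular PKSs carry tandem KS domains, and reference tools do not
document their overlap handling, so the 50% rule is this package's pinned
choice.

The eleven leaf classes (modular *cis*-AT, *cis*-loading module, olefin
synthase, iterative aromatic, iterative PTM, *trans*-AT, hybrid
*trans*-AT, hybrid *cis*-AT, PUFA, enediyne, FAS) aggregate
deterministically into three groups plus FAS and into the five clusters
seen in sequence similarity networks (`map_leaf()`). A phylum is assigned
per domain from the reference with the lowest E-value; matches under 75%
identity are flagged tentative.

For throughput, the search ranks references per query by shared 4-mer
counts — the seeding heuristic word-based protein search tools use — and
fully aligns the top eight. With a reference collection of at most eight
entries the search is exhaustive, which the oracle-equivalence tests
exploit.

## Full-length extraction

A domain is full length when it spans the conserved IAIVG start residues
through the GTNAH end residues. The published rule notes "some degeneracy"
without quantifying it; we default to at most one mismatch per anchor
(configurable 0–2): one mismatch admits conservative substitutions without
admitting noise. When several qualifying windows exist, the longest
spanning pair (leftmost qualifying start, rightmost qualifying end) is
clipped. Genuine full-length domains are ~420 aa.

## OBU clustering and diversity

Full-length domains are clustered greedily: sequences are visited in order
of decreasing length (ties by id) and each joins the first existing
centroid — in founding order — with global identity at or above the
threshold (0.70/0.80/0.90/0.95), else founds a new cluster. Identity is
matches divided by alignment columns under global alignment, gap columns
counted, `X` never matching; full-length domains are homologous end to
end, so global alignment is the appropriate comparison. The published
workflow's clustering tool defaults are not documented, so these choices
are pinned and recorded in run manifests.

Richness per biome is the bias-corrected Chao1 estimate
$S_{\mathrm{obs}} + F_1(F_1-1)/(2(F_2+1))$ averaged over 10 replicate
rarefy–cluster–estimate runs at a fixed depth (580 by convention for this
survey; the depth auto-lowers to the smallest biome with a warning so
desk-scale synthetic runs work unchanged). Shared-OBU analysis rarefies
every biome to a common depth, pools and clusters once per threshold, and
counts, per biome pair, OBUs containing members of both biomes and the
domains inside them. Pooled (rather than per-pair) clustering is the
natural reading of the published comparison and is noted in output
metadata.

## Composition statistics

Per-metagenome KS-type abundance is counts per Gbp of assembly. Rarefied
composition profiles subsample each metagenome's calls to depth 100 and
average the leaf-class count vector over 1,000 permutation draws
(fractional means retained; undersized metagenomes are excluded, not
up-sampled). Profiles feed a Bray–Curtis dissimilarity matrix
($d = \sum_i |x_i - y_i| / \sum_i (x_i + y_i)$, via vegan), principal
coordinates analysis (eigendecomposition of the double-centered squared
distance matrix; negative eigenvalues are reported unadjusted and excluded
from the proportion-explained denominator — no Lingoes/Cailliez correction,
since none is named in the published workflow), and a one-factor PERMANOVA
(vegan's adonis2; 999 free whole-sample label permutations, no strata,
$p = (\#\{F^* \ge F\} + 1)/(P+1)$). Per-class abundances across biomes use
one-way ANOVA with Tukey's HSD, flagged at $\alpha = 0.01$.

## Primer evaluation

Degenerate primers are IUPAC nucleotide strings. Forward primers translate
directly; reverse primers are reverse-complemented first. A trailing
partial codon is padded with N — forced by the fact that both published
23-nt primers translate to 8 amino acid positions. Each degenerate codon
expands to its amino acid set with stop codons removed (forced by the
published (CWRSG) pattern, which omits the TGA stop). Sets render in
alphabetical order; `normalize_pattern_string()` compares renderings
order-insensitively because the published patterns list set members in no
single derivable order.

The primer site on a domain is the sliding window maximizing matched
positions (leftmost tie-break), flagged low-confidence below 50% matched.
Match profiles report, per KS group, the per-position fraction of domains
whose residue falls in the position's set, plus the all-positions
full-match fraction; positions are indexed both N→C and as offsets from
the primer's 3′ end (for a reverse primer, pattern position 1 is
3′-proximal). `apply_modification()` enlarges position sets to quantify
coverage gained by proposed primer changes, e.g. adding H/E alongside
glutamine, or isoleucine alongside valine. Because the published
"all five of the amino acids targeted" phrasing for the reverse primer is
ambiguous (its pattern has six non-degenerate positions), both per-position
and full-match readings are always emitted.

## Amplicon concordance

`trim_to_amplicon()` cuts full-length domains to a next-generation amplicon
length (default 138 aa), anchored at the located forward-primer site with
a centered-window fallback, or centered outright. Trimmed sequences are
re-classified with the match-length floor lowered to 100 aa — the 200-aa
floor cannot apply to a 138-aa query, and the floor used by the original
web tool for its trimmed runs is not documented; the deviation is logged in
run manifests. Concordance is the fraction of domains keeping their leaf
class, per group and overall; trimmed sequences yielding no call count as
discordant. Both the 138-aa window placements are implemented because the
window the original analysis used is unstated.

## Synthetic data: what it emulates, and what it does not

The generator builds, per leaf class, an unrelated random ancestral domain
(420 aa, anchored by IAIVG/GTNAH) and derives reference entries at 90%
identity to it. Ancestors carry controlled primer-site residue
composition at fixed positions (61–68 for the forward site, 355–362 for
the reverse): cis-AT/iterative classes match the KS2F/KS2R consensus,
hybrid and *trans*-AT classes carry histidine at the KS2F glutamine
position and isoleucine at the KS2R 3′ valine, and PUFA/enediyne classes
diverge further — so primer evaluation on generated data reproduces the
qualitative coverage differences between KS types. Biome profiles are mixture weights over leaf classes;
generated sequences mutate a lineage seed to a target identity (default
0.85) with BLOSUM62-weighted substitutions outside the anchor windows, so
full-length status is controlled independently by `full_length_fraction`
(default 0.7). The eight default profiles qualitatively mirror the
surveyed biome structure — marine sediment and seawater enriched in PUFA
and enediyne KSs, forest/agricultural soil and rhizosphere in modular and
hybrid *cis*-AT — with weights that are illustrative choices of this
package, not measurements. `back_translate()` produces contig-like
nucleotide inputs for the six-frame path.

This emulation captures identity structure around labeled seeds, mixture
composition, anchor presence and primer-site composition. It does not
capture real KS phylogeny (sequences within a class share one ancestor,
not a tree), alignment-ambiguous indel patterns, sequencing or assembly
error, chimeras, or database bias. Passing tests therefore demonstrate
that the pipeline's operations implement their contracts and recover
planted structure — not that classification accuracy on real metagenomes
matches the synthetic recovery rates.

## Numerical choices and problem sizes

All randomness flows through explicit seeds; identical configuration and
seed reproduce byte-identical tables. Ties are broken deterministically
everywhere (score, E-value, identity, then lexicographic id; leftmost
windows for start anchors and primer sites, rightmost for end anchors).
Identity computations count `X` as a mismatch always. The test suite and
the acceptance script run the heavy stages at desk scale — a 22- or
44-entry generated reference collection, 200-variant recovery and
concordance sets, 16 synthetic metagenomes of 40 sequences, rarefaction
depths 30–50 — while package defaults keep the survey-scale values
(580/100/1,000 permutations/10 replicates). These sizes were fixed as part
of the test design. Pairwise identities are cached in an identity matrix
when the same sequences are clustered repeatedly; the cache is exact, not
an approximation, and a test asserts cached and uncached clusterings agree.

## Known limitations

- The bundled reference collection is synthetic; absolute domain counts
  are not comparable to searches against curated KS databases, and
  phylum assignments are only as meaningful as the generated labels.
- E-values use fixed Karlin–Altschul constants rather than
  composition-adjusted statistics; externally computed hit tables can be
  supplied where production search statistics are wanted.
- The greedy clusterer reproduces the centroid-clustering idiom but not
  any specific tool's k-mer heuristics; partitions can differ from UCLUST
  on borderline pairs.
- PERMANOVA permutes labels freely; designs needing strata are out of
  scope.
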