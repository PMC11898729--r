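---
title: "Typing and diversity of O-antigen biosynthetic gene clusters: methods"
author: "obctools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Typing and diversity of O-antigen biosynthetic gene clusters: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

In Gram-negative bacteria the O-chain (O-antigen) of the lipopolysaccharide
is encoded by a single genomic island, the O-chain biosynthetic gene cluster
(OBC). The OBC is the canonical *replacement flexible genomic island*: it
occupies a fixed chromosomal position — in Pelagibacterales, between the
16S–ITS–23S rRNA operon and the 5S rRNA gene — while its gene content is
essentially interchangeable between strains. Two genomes that are nearly
identical elsewhere can carry completely unrelated OBCs, and two distantly
related genomes can share one.

`obctools` implements the full analysis chain for this kind of locus:

1. **Extraction** of rRNA-marker-bounded islands from annotated assemblies
   and long reads (`extract_islands()`, `extract_read_islands()`).
2. **Orthology** between island gene sets by reciprocal best hits (RBH) under
   Smith–Waterman/BLOSUM62 alignment, and amino-acid identity (AAI) between
   backbone proteomes (`reciprocal_best_hits()`, `aai_matrix()`).
3. **Typing**: islands sharing ≥ 90% of the genes of the smaller island are
   the same *locus type*; the pairwise relation is closed transitively
   (`cluster_types()`).
4. **Evolution**: locus vs genome distance (100 − AAI), a ≥ 2× rule flagging
   recent horizontal transfers, and a Nei–Gojobori (1986) dN/dS contrast of
   island vs backbone genes (`distance_pair()`, `ng86_dnds()`,
   `aggregate_dnds()`).
5. **Lineage classification** of islands from ITS/23S sequences by
   Jukes–Cantor distance to a labelled reference panel, with neighbor-joining
   trees and column-bootstrap support for inspection (`classify()`,
   `nj_tree()`, `bootstrap_support()`).
6. **Diversity**: locus-type richness by analytic rarefaction, Chao1
   extrapolation and a Chao-style bootstrap confidence band
   (`rarefy()`, `extrapolate()`, `chao_asymptote()`, `bootstrap_ci()`).

A synthetic-population generator (`sim_config()`, `simulate_population()`,
`emit_long_reads()`) produces truth-labelled inputs with the statistical
structure the analysis assumes, so every step is testable against planted
truth.

## Island extraction

A contig's island is the region strictly between the 3′ end of the 23S gene
and the 5′ start of the 5S gene; the markers and the ITS are hallmarks, not
island content. Contigs whose markers lie on the reverse strand are
reverse-complemented first. Completeness classes follow the fragment
anatomy of single-amplified genomes (SAGs): **A** (both markers on one
contig), **B** (both island ends present but on different contigs of the
same genome), **C** (only the 23S-bearing left side), **D** (only the
5S-bearing right side). Island genes are the CDS lying *fully inside* the
span — partial overlaps at fragment edges are excluded so gene counts are
reproducible on fragmented input. When several marker copies occur on one
contig, the tightest pair flanking a CDS-bearing gap is used (leftmost on
ties); a 5S upstream of the 23S with nothing between is degenerate and
skipped with a message. Genome-level screens keep islands strictly longer
than 10 kb; read-level screens keep islands of at least 5 kb (both
configurable; the asymmetry — strict `>` vs `≥` — reflects how the two
screens are conventionally stated). For long reads the island runs from the
23S 3′ end to the read end, truncated at the 5S if the read reaches it so
backbone genes never contaminate a read island.

## Orthology, AAI, and allowed comparisons

Protein pairs are aligned by Smith–Waterman (BLOSUM62, gap open 11 /
extend 1 — BLAST-like defaults). Identity is identical residues over aligned
columns (gap columns count in the length, not the numerator); coverage is
the aligned span over each sequence's full length, and the gate is applied
to **both** sequences (the symmetric choice keeps pair comparisons
symmetric). Island-gene orthology uses 50% identity / 70% coverage; the
genome-level AAI gate uses the community-standard 30% / 70%. RBH ties are
broken by higher score, then lexicographically smaller partner id, making
the matching deterministic.

Two completeness classes can only be compared when their observed fragments
can actually overlap: the allowed unordered combinations are AA, AB, AC,
AD, BC, BD, CC and DD. BB and CD are excluded — a left-only and a
right-only fragment share no sequence at all.

For the batched all-vs-all searches the package calls command-line
`blastp` (single-threaded, masking and composition-based statistics
disabled) when it is on `PATH`, and falls back to the vectorised
Smith–Waterman engine otherwise; both feed the same RBH matcher, and the
test suite pins both engines on the same inputs. Backbone AAI (and the
backbone dN/dS gene set) can be computed from an evenly spaced subsample of
each proteome (`aai_max_genes`, default 16); evenly spaced positions stay
homologous across genomes with conserved gene order, which keeps the
estimate unbiased while making 100+ genome matrices cheap.

## Typing and sharing structure

The ≥ 90% shared-gene relation is not transitive in general; the package
closes it by single linkage (connected components of the sharing graph),
the natural reading of "two **or more** islands of the same type". Type ids
are the lexicographically smallest member id, so typing is deterministic
under permutation of the input. Partial islands join types through any
allowed edge; their gene counts use observed genes only.

On populations built from discrete island repertoires the pooled
shared-fraction histogram is strongly bimodal — pairs either share
essentially everything (> 85%) or essentially nothing (< 5%) — matching the
empirical signature of replacement flexible islands.

**Identifiable truth.** A planted type whose observed members are only
left-side (C) and right-side (D) fragments cannot be reunited by any
gene-sharing method: the fragments share no genes and C–D (like B–B)
comparisons are disallowed. Recovery is therefore scored against the
*identifiable* partition: each planted type refined into connected
components of the allowed-combination graph over its members' fragmentation
classes (`identifiable_types()`, computed from truth labels only). On the
reference simulation the adjusted Rand index against this partition is 1.0.

## Distances, recent HGT, and dN/dS

For genome pairs sharing a locus type, the genome distance is 100 − AAI
over backbone orthologs (the island is excluded from the genome side before
any comparison, so the two axes are independent), and the locus distance is
100 − mean identity over the island's RBH genes. A pair is flagged as a
*recent* horizontal transfer when the genome distance is at least twice the
locus distance; identical genomes (distance 0) are never flagged, and the
false-positive property is asserted on pairs with genome distance ≥ 2
points, where the rule is meaningfully testable.

dN/dS follows Nei–Gojobori (1986): fractional synonymous site counts per
codon (stop-producing single-base changes excluded and the position
renormalised, so N + S = 3 × codons), observed differences averaged with
equal weight over all shortest mutational pathways excluding those
traversing stop codons, and Jukes–Cantor correction
`d = −(3/4)·ln(1 − 4p/3)`. Codon pairs whose pathways are all excluded
contribute nothing. Ortholog codon alignments are obtained by
back-threading the global protein alignment onto the CDS and dropping gap
columns. Counts are pooled per genome pair within each compartment (island
vs backbone) before forming the ratio — per-gene ratios at genomovar-level
divergence have too few synonymous differences to be stable — and the
island-vs-backbone contrast is a paired t-test across genome pairs.
The ML codon-model alternative was deliberately not used: the counting
estimator is fully specifiable and oracle-checkable by exhaustive pathway
enumeration over all sense-codon pairs.

The AAI cladogram treats matrix rows as points, takes Euclidean distances
and clusters by average linkage (UPGMA), giving an ultrametric dendrogram
whose species-level cut reproduces the simulated genomospecies.

## Lineage classification

ITS (preferred) or 23S sequences are compared to a labelled reference panel
by Jukes–Cantor distance over unambiguous aligned columns (global
alignment: match +1, mismatch −1, gap open −2, extend −1). The call is the
nearest label, accepted only if the margin over the runner-up is at least
0.01 substitutions/site and the best distance is at most 0.10; otherwise
"Unclassified". These two defaults are package choices (no numeric rule is
conventional); both are configurable. The NJ tree (with negative branches
clamped to zero and the excess moved to the sister edge) and column
bootstrap supports are emitted for inspection; the multiple alignment
behind the bootstrap is pairwise-to-longest-reference stacking, adequate
for near-globally-alignable rRNA/ITS within an order and documented as a
limitation for anything more divergent.

## Richness

Each sampling unit (SAG or read) carries exactly one typed island, so
incidence- and abundance-based Hill-q = 0 machinery coincide and the
abundance (Chao1) form is implemented. Rarefaction uses the exact
hypergeometric expectation computed in log space (stable to n in the
thousands); extrapolation uses the standard Chao1-based closed form, which
is continuous at the observed sample size and bounded by the asymptote
`S_obs + f1²/(2f2)` (bias-corrected when f2 = 0). Confidence bands come
from a Chao-style bootstrap: the estimated unseen types share the
estimated missing probability mass, `B = 200` multinomial resamples
recompute the curve, and normal-approximation ±1.96·SD intervals are placed
around the point estimate. In the design mirroring a single-species read
sample (158 units from 400 equally common types, where ~130 types are
observed and Chao1 is nearly unbiased), the 95% interval covers the true
richness in ≥ 85% of replicates. Coverage is reported as detected/predicted
richness, with Good–Turing sample coverage (`1 − f1/n`) as an alternative.

## The synthetic population

The generator emulates the features the analysis relies on, with defaults
chosen once as study conditions:

* streamlined AT-rich backbone (GC 29.4%) with a depressed-GC island
  (23.8%); desk-scale backbone 60 kb (the real genomes are ~1.3 Mb — sizes
  are scaled down, not structure);
* one island per genome between the 16S–ITS–23S block and the 5S gene,
  drawn from K discrete repertoires of 8–14 genes (desk scale; real islands
  carry 8–101 genes over 10–90 kb) built from disjoint random gene pools,
  so distinct repertoires share ~no orthologs;
* species structure: genomes diverge by 0.01 substitutions/site within a
  species and 0.15 between (within-species backbone AAI ≈ 99, between ≈ 90;
  the within value is a desk choice balancing genomovar realism against
  having enough substitutions for stable per-pair dN/dS);
* codon evolution with target dN/dS 0.14 (island) and 0.10 (backbone):
  proposals pick a uniform site and base, stops are rejected, synonymous
  changes always accepted, nonsynonymous accepted with probability ω — the
  accepted-substitution count is Poisson(branch × length), so NG86 recovers
  ω without bias (verified on a 10 kb CDS across an ω grid);
* GC control: under uniform (JC) substitution GC relaxes toward 0.5 as
  `GC(b) = 0.5 + (GC₀ − 0.5)e^(−4b/3)`, and rejecting AT-rich stop codons
  skews coding composition upward; root sequences are generated at an
  analytically pre-compensated GC₀ so emitted tips sit within ±1.5 points
  of the targets while the substitution process stays uniform;
* whole-island HGT: with probability `p_hgt` a genome receives a verbatim
  copy of another species' current island (locus distance ≈ 0, genome
  distance unchanged) — exactly the signature the ≥ 2× rule must find;
* fragmentation: classes A/B/C/D drawn per genome (defaults 20/35/23/22%,
  the observed SAG proportions); breakpoints fall in intergenic gaps inside
  the island, never in a marker, and C/D lose only the island-adjacent
  region — the rest of the backbone survives in other contigs, as in real
  SAG assemblies;
* long reads: 5–15 kb, anchored reads contain the complete 23S plus ≥ 5 kb
  of island; a configurable background fraction starts at uniform positions;
  reads are error-free (CCS ≥ Q20 is treated as exact — no error model);
* the reference panel is the per-species ancestral ITS/23S — nearest
  reference classification is well-posed by construction.

What the simulation does **not** emulate: assembly and sequencing error,
rRNA secondary structure, intra-island recombination mosaics, gene gain and
loss within a repertoire, and realistic within-population demography.
Passing the recovery tests therefore shows the pipeline is correct under
its stated assumptions, not that those assumptions hold for any particular
real data set.

## Numerical choices and degenerate inputs

* Alignment tie-breaks come from the engines' deterministic traceback; RBH
  tie-breaks are (score, then id).
* `p ≥ 0.75` saturates the JC correction and is reported missing, as is a
  dN/dS ratio with dS = 0.
* Zero-length islands error; reads without a 23S are skipped; genomes
  without markers yield no island (not an error).
* Problem sizes in the tests: the reference simulation is 3 species × 40
  genomes with 30 repertoires; oracle checks run on all 61 × 61 sense-codon
  pairs, 50 random RBH set pairs, 20 Monte-Carlo rarefaction vectors at
  10,000 subsamples, 100 random additive NJ matrices, and 100 bootstrap
  calibration replicates. These sizes were chosen so each oracle has
  negligible Monte-Carlo error relative to its assertion.

## Known limitations

* Genome AAI from a gene subsample assumes conserved gene order; for
  rearranged genomes set `aai_max_genes = Inf`.
* Single-linkage typing can chain types through intermediate islands; the
  threshold (0.90) is far from the bimodal histogram's valley so chaining
  is not observed in practice, but the behaviour is inherent to the
  transitive closure.
* The relocated-island arrangement (right boundary at a non-5S marker) is
  supported via `extract_islands(right_marker = )` and
  `sim_config(alt_right_marker = )`, both off by default; its exact natural
  right boundary is not modelled beyond a single alternative feature kind.
* The dN/dS estimator is a counting method; for deep divergences or strong
  codon bias an ML codon model would be preferable.
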