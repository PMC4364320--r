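---
title: "Methods: synthetic LMW-GS gene families and their analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic LMW-GS gene families and their analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

Low-molecular-weight glutenin subunits (LMW-GS) are seed-storage proteins
central to bread-making quality. They are encoded by a multigene family at
the *Glu-3* loci; in a diploid wheat such as *Triticum urartu* the single
*Glu-A3* locus already carries on the order of eight genes, each with
several allelic variants. Characterizing such a family in a population
involves a chain of inferences: sizing PCR fragments from conserved primer
sets, calling multilocus genotypes from fragment-size multisets, clustering
cloned sequences into genes and named variants, classifying subunits into
i-, m- and s-types by the first residue of the mature protein, separating
active genes from pseudo-genes interrupted by premature stop codons, and
summarizing allelic and genotypic richness across collection regions.

`lmwgs` implements that chain as tested, reusable code. Because the real
GenBank sequences are not redistributable inside a package, the pipeline is
exercised on two complementary inputs:

* a **packaged fixture** encoding a published 157-accession *T. urartu*
  genotype table — 15 genotypes (U1–U15) over 8 genes and 39 variants, with
  per-region accession counts and per-variant active/pseudo flags — whose
  population statistics are pure arithmetic and therefore exactly
  reproducible; and
* a **synthetic sequence generator** that realizes that table (or any
  configured population) as DNA with full truth labels, so each downstream
  stage can be validated against known ground truth.

## The synthetic gene model

Every generated gene follows the canonical LMW-GS architecture:

* a 20-residue signal peptide (a fixed template constant; typical LMW-GS
  signals are 20 residues, and a fixed length keeps cleavage deterministic);
* a type-diagnostic N-terminal region: absent for i-type (the mature protein
  starts with Ile at the head of the repeats), starting with Met for m-type,
  and carrying `MENSHIPGLEKPS` for s-type, whose `MEN` tripeptide is removed
  with the signal so the mature protein starts with Ser;
* a glutamine/proline-rich repetitive domain built from an 8-residue motif
  (24 coding nucleotides, so repeat indels step by 24 bp, the motif-multiple
  unit seen in real repeat-length polymorphisms);
* C-terminal domains I/II/III of 105/25/55 residues housing 6, 1 and 1
  cysteines: cysteine 1 opens C-terminal I, cysteine 6 closes it, cysteine 7
  ends C-terminal II and cysteine 8 sits inside C-terminal III.

Proteins are back-translated with a single versioned codon table (one fixed
wheat-biased codon per amino acid), which makes theoretical amplicon sizes
and sequence identities exactly reproducible. Each gene is flanked by
gene-specific non-coding sequence; a conserved 68-nt block upstream of the
ATG hosts the three forward marker-primer sites, and two invariant anchor
blocks inside C-terminal I host the reverse sites. With this layout the
LMWGS1 amplicon of a variant of nominal size *S* is exactly *S* bp: the
repeat count supplies the 24-bp steps and a variant-specific non-coding
spacer between the primer block and the ATG absorbs the sub-codon remainder.
The LMWGS2 and LMWGS3 amplicons are S + 117 and S − 28 bp — a package
convention, since the cross-set correspondences printed in the source table
are typographically unreliable; the s-type gene is configured as not
amplified by LMWGS3 so that the "N" (no amplification) path is exercised
end to end.

Divergence between genes is built hierarchically: per-type archetypes of the
C-terminal domains are derived from a common scaffold (the s-type archetype
from the m-type one, so s-type genes fall inside the m-type clade, matching
the observed tree structure), and each gene diverges further from its type
archetype. Repeat motifs are gene-specific. Allelic variants of one gene are
the gene's base sequence plus a variant-specific set of third-position
substitutions (the representative variant is unedited), repeat-count
differences for size variants, and TAG stops at fixed offsets inside their
reported domains for pseudo-gene variants. All generator randomness flows
through an internal multiplicative-congruential generator with one stream
per (seed, label) pair, so output is byte-identical across runs and
independent of generation order and of R's global RNG.

What the generator does **not** emulate: electropherogram signal intensities,
PCR artifacts and stutter, mismatch-tolerant primer binding, real codon usage
variation, and real inter-gene homology levels (synthetic genes are more
diverged from each other than real paralogs, a deliberate margin discussed
below). Passing tests on synthetic populations therefore validate the
*logic* of the pipeline, not its robustness to noisy capillary data.

## Annotation conventions

* **Translation** starts at the first ATG and reads through premature stops
  (reported as `*`), ending at the last in-frame stop; read-through keeps
  pseudo-gene proteins full length so their stop can be localized to a
  domain. Generated 3' flanks are stop-free in all frames so the terminal
  stop of the CDS is that last stop.
* **Cleavage** looks for the earliest type-diagnostic mature-start motif
  (`ISQ`, `MET`, `MEN`) within residues 16–31 and falls back to cleaving
  after residue 20. Real signal-peptide cleavage is not annotated in the
  source material; a motif-anchored rule is deterministic and testable.
* **Domains** follow cysteine ordinals (C-terminal I spans cysteines 1–6,
  C-terminal II ends at cysteine 7, C-terminal III runs to the protein end);
  the N-terminal domain ends at the first `QQ` dipeptide and is absent for
  i-type. Coordinates are 0-based half-open, so the tiling invariant (domain
  widths sum to the mature length) is exact. Where trailing residues follow
  the 8th cysteine they belong to C-terminal III — the ordinal rule is this
  package's convention.
* **Masses** are average (not monoisotopic) residue masses, matching the kDa
  style of storage-protein estimates; **pI** is found by bisection of the
  net-charge curve under the EMBOSS pKa set, to 0.01 pH. The pI is used only
  for relative positioning (2-DE-style ordering), so the choice of pKa set
  is not critical; it is versioned in the package.

## Genotyping and clustering

Primer binding is exact-match (the source treats non-amplification as a
clean "N" category; a mismatch model would be unconstrained). Fragment size
is the full amplicon length including both primers, matching the
"theoretical size" naming of cloned genes. Accessions sharing a fragment
size multiset across all three sets share a provisional genotype;
size-identical groups that differ at the sequence level are split and
flagged SNP-discriminated (in the fixture this is exactly the U5/U6 pair).
Labels are assigned in descending frequency with first-occurrence
tie-breaks after sorting accession IDs, making the calling order-invariant.

Gene clustering is single linkage over global (end-to-end, affine-gap)
nucleotide identity, with gap columns counted in the denominator. Single
linkage is deliberate: allelic series that differ by repeat-domain length
chain into one gene through intermediate sizes. Alignment scoring (match
+2, mismatch −3, gap open 7, gap extend 1) favours one long indel over
scattered gaps for motif-multiple indels.

The gene-membership threshold `t_gene` deserves a note. The function default
is 0.95, consistent with reported within-gene identities above 99% for
SNP-level variants. But with gap columns in the denominator, a repeat-length
difference of *k* bp between two ~1.2 kb variants caps their identity near
(L − k)/L: the large repeat indels that real variants carry (about 150 bp
between the extreme variants of one gene here) push chain-neighbour
identities into the 0.87–0.93 range at realistic gene lengths, below 0.95.
The pipeline therefore runs the fixture at `t_gene = 0.85`, which cleanly
separates the two regimes in this architecture: all within-gene chain links
sit above 0.87 while the maximum cross-gene identity is about 0.75. Both
values are configuration, not code.

Gene and variant names follow the fragment-size convention: a gene is named
for the LMWGS1 size of its most frequent variant (ties broken by smaller
size, then lexicographic sequence ID) and same-size variants get letter
suffixes in descending frequency. Applied mechanically to the fixture
counts, this names two genes by their majority variant (392 and 402) where
the published display names used the 391/400 fragment; the packaged fixture
keeps the published display names, and tests assert partitions and counts
rather than those two labels.

## Diversity tables and phylogeny

Percentages are rounded half-up to two decimals to match printed-table
style. "Active" status comes from ORF annotation of the sequences (or the
fixture's flags), not from any proteomics input: in the source study the
protein-level evidence was consistent with the ORF-based calls. Regional
richness ranks regions by variant then genotype counts; uniqueness is the
complement of presence in any other region, verified by brute force in the
tests. Two printed numbers in the source conflict with their own table (a
"24%" share of minor genotypes where the table implies 29.30%, and "34 vs
35" variants for the top region between two sections); the package reports
the recomputed values (29.30 and 34).

Distances for the tree are p-distances (mismatches over compared columns,
pairwise deletion) from pairwise global alignments — no multiple alignment
is built, a simplification relative to the original ClustalW2+MEGA5
workflow; the distance model used there is unstated, and p-distance is this
package's configurable default. Neighbor-joining is implemented classically
with two determinism rules: Q-matrix ties break to the lexicographically
smallest taxon pair, and negative branch-length estimates are clamped to
zero with the deficit moved to the sibling branch. Tests verify exactness
on additive matrices against both an exhaustive least-squares topology
search (all 105 six-taxon topologies) and an independent reference
implementation. On the fixture population the 39 variants form monophyletic
per-gene clades, the i-type genes form one clade, and the s-type gene falls
with the m-type genes — the clade structure reported for the real family.

## Problem sizes and determinism

The packaged analyses run at the study's own scale: 157 accessions, 39
variant sequences of roughly 1.1–1.4 kb, 741 pairwise alignments per
all-versus-all pass. A full pipeline run takes on the order of two minutes
on one core, dominated by the two alignment passes (identity matrix and
distance matrix); the marker-genotyping path alone takes a few seconds.
Property-style tests use 1000 generated subunits for the domain/cysteine
census, 20 input shuffles for clustering invariance, and random additive
trees with up to six taxa for the NJ oracle. Every stochastic step takes an
explicit integer seed; identical configurations produce byte-identical
outputs.

## Known limitations

* Exact-match primer binding means a single SNP in a landing site reports
  "N" rather than a reduced-efficiency amplicon.
* The identity threshold calibration (0.85) is tied to the synthetic
  architecture's divergence levels; real cross-species data with paralogs at
  90–94% nucleotide identity would need a different threshold or a
  repeat-aware identity measure.
* Signal cleavage is rule-based, not a learned signal-peptide model.
* Haplotype co-segregation reports identical-support variant groups; it does
  not test linkage statistically.
* Cross-species analyses (homolog searches, trees with external sequences)
  are out of scope.

## A minimal run

```{r}
library(lmwgs)
cfg <- pipeline_config(out_dir = "lmwgs-run", seed = 1)
report <- run_pipeline(cfg)
report
```

The report records the recovered gene/variant/genotype counts, the
three-active-i-type share, regional rankings, clade checks, and — because
the generator provides truth labels — exact-recovery indicators for the
zero-mutation population.
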