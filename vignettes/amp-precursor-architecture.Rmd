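---
title: "Methods: multipeptide AMP precursor architecture and evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multipeptide AMP precursor architecture and evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampstruct)
```

## The biological model

Ant hymenoptaecins are glycine-rich antimicrobial peptides (AMPs) translated
as a single *multipeptide precursor*: a signal peptide, a propeptide, one
longer hymenoptaecin-like domain (HLD) and a series of directly repeated
hymenoptaecin domains (HDs). Each repeated unit consists of an `EAEP` spacer,
a 97-aa Q-initial mature domain and a dibasic proprotein-convertase site
(`RR`/`KR`/`RK`); the repeat unit therefore spans
`3 * (4 + 97 + 2) = 309` nt of coding sequence. Release of the mature
peptides is modelled as a three-step enzymatic cascade borrowed from the
yeast alpha-factor pathway:

1. a KEX2-like **endoprotease** cuts C-terminal to each dibasic site;
2. a KEX1-like **carboxypeptidase** removes the two exposed basic residues;
3. a **dipeptidyl aminopeptidase** removes N-terminal E/D–A/P dipeptides,
   consuming the spacer two residues at a time.

Applied after removal of the signal peptide and discarding the
propeptide-derived fragment, the cascade releases one G-initial 108-aa HLD
peptide and one Q-initial 97-aa peptide per repeat. A Q N-terminus can
cyclise to pyroglutamate, which the output flags (`pyroglutamate_capable`).

Around this core the package implements the supporting analyses such a
characterisation needs: exact splice mapping of cDNA onto genomic sequence
with intron phase/interrupted-codon arithmetic, de-novo tandem-repeat
detection, per-domain distance phylogenetics with bootstrap collapse, and
duplication–loss reconciliation of defensin-type gene families.

## The synthetic-locus generator

Because the pipeline must be testable without database access, every stage
runs on seeded synthetic loci whose *dimensions* match the published genes
while their unconstrained residues are random:

* **Default precursor** (`hymenoptaecin_spec()`): 19-aa signal, 26-aa pro,
  108-aa G-initial HLD, six 97-aa Q-initial HDs, `EAEP`/`RR` motifs, one
  820-nt phase-0 intron after codon 39 (pinned to histidine), and UTRs of
  40/168 nt. The UTR total is fixed by the published mRNA and gene sizes
  (2536 and 3356 nt); the 5′/3′ split is not published, and 40/168 is the
  package's own choice.
* **Defensin fixtures**: coding exons 64/229/13 nt over 399/360-nt introns
  (102-aa prepropeptide; phase-1 intron pinned to Glu-22, phase-2 to
  Ala-98), and 97/194 nt over a 1043-nt intron (97 aa; phase-1 at Thr-33).
  Printed exon sizes are treated as CDS *without* the stop codon, because
  their sums match the stated protein lengths exactly; the stop codon and
  UTRs are appended around the CDS.

Three generator properties are load-bearing and deliberate:

* **Exact tandem tiling.** The repeat unit (spacer + HD + cleavage codons)
  is drawn once and tiled, so the undiverged cDNA carries a perfect 309-nt
  array; `diverge_domains()` then mutates each HD independently while
  masking spacer and cleavage codons.
* **No accidental cleavage sites.** Drawn residues never extend a run of
  basic residues and never place R/K immediately before a cleavage motif.
  This makes the dibasic scan find exactly the architectural sites, so the
  parser is a left inverse of the generator over the whole random-spec
  distribution — the central round-trip property the tests rely on.
* **Unambiguous splice junctions.** An intron whose first base equals the
  first base of the following exon can slide without changing the spliced
  product. The generator avoids a G immediately after each intron where the
  encoded residue permits, and `splice_map()` additionally canonicalises any
  remaining slide interval to the leftmost GT..AG placement, the same
  convention spliced aligners use. Together these make exact truth recovery
  well-defined.

Back-translation uses uniform synonymous codon choice (no codon-usage table
is assumed); intron interiors and UTRs are uniform random with GT..AG intron
ends. All randomness in an operation flows from its single integer seed, and
identical seeds give byte-identical bundles.

What the synthetic data does *not* emulate: real codon usage, splice-site
consensus beyond GT..AG, indels, sequencing error, paralogous gene copies
and assembly gaps. Passing tests therefore demonstrate the correctness of
the arithmetic and algorithms under the published dimensions, not robustness
to noisy real-world annotation.

## Gene structure

`splice_map()` performs exact spliced matching (greedy extension to the
first mismatch, then an anchored search for the smallest resumption,
`min_anchor = 20` nt, with backtracking). Mismatch- or indel-tolerant
alignment is explicitly out of scope: gene and cDNA of one clone are
identical where they overlap. Internal exons shorter than the anchor cannot
be resolved and fail loudly; ties between equally small models raise an
"ambiguous splice" error rather than choosing silently.

Intron phase is the number of nucleotides of the interrupted codon already
emitted upstream (`phase = cumulative coding nt mod 3`); a phase-0 intron is
reported as "between codons k|k+1". This convention reproduces all four
published phase/codon pairs (phase 0 after codon 39; phase 1 at codon 22;
phase 2 at codon 98; phase 1 at codon 33).

## Maturation parameters

* `carboxypeptidase_trim()` removes at most 2 trailing basic residues by
  default ("removes both basic residues"); `max_trim = Inf` enables
  unlimited trailing-basic trimming.
* `dipeptidyl_trim()` removes dipeptides from `{EA, EP, DA, DP}` by
  default. The `EANP` spacer variant seen in some relatives is only
  partially removable under this set (`EANPQ` becomes `NPQ`); widening the
  set (e.g. adding `NP`) is a user decision, documented as a limitation.
* Whether the propeptide carries its own dibasic site or the HLD is
  released by a single cut is not settled; the grammar models pro + cleavage
  as separate segments, and the maturation discards the first
  endoprotease fragment (pro plus its site) accordingly.

A residue accounting (`maturation_accounting()`) verifies conservation:
input residues = signal + pro fragment + C-terminal trims + N-terminal
trims + released peptides.

## Tandem-repeat detection

`find_tandem_repeats()` seeds candidate periods with exact 12-mer
self-matches at offsets in `[min_period, max_period]` (defaults 30–600 nt),
chains seeds bridging gaps up to one period, extends base-by-base, and
scores copies against a per-column majority consensus (ties alphabetical).
The copy model is ungapped: the repeats modelled here are exact-length, and
indel-tolerant wraparound alignment is out of scope. Overlapping arrays are
ranked by `copies * period` (larger first), then smaller period — so a
two-unit harmonic of a true array loses to the fundamental. Reported copy
numbers may be fractional; the floor is reported separately.

## Per-domain phylogenetics

Distance methods stand in for the original maximum-likelihood analysis: the
acceptance surface is the qualitative claim (domains of each species form
their own clades), not likelihood values.

* **Alignment**: global affine Gotoh (BLOSUM62 for protein; +1/−1 for
  nucleotide; gap `10 + 0.5L`), with a fixed traceback preference
  (diagonal, then up, then left) so results are deterministic. The same
  engine aligns column-frequency profiles for the progressive MSA, whose
  guide comes from neighbor joining on fractional common k-mer distances
  with lexicographic tie-breaks; shuffling input order does not change the
  result on the domain sets used here.
* **Block cleaning**: keep maximal runs (≥ 5 columns) with gap fraction
  ≤ 0.5 and a most-frequent residue reaching ≥ 0.5 of rows — a simplified,
  documented analogue of conserved-block filtering.
* **Distances**: p-distance or Poisson correction `−ln(1 − p)` with
  pairwise deletion of gapped sites (the simplest defensible default).
* **NJ/BioNJ**: standard Q-criterion agglomeration; BioNJ uses the
  one-parameter variance-weighted update with the variance matrix
  initialised to the distances. Ties in Q break on the lexicographically
  smallest pair of cluster representatives; negative branch lengths are
  clamped to zero with the deficit moved to the sister branch.
* **Bootstrap and collapse**: column resampling with replacement, support =
  percentage of replicates containing each internal bipartition; branches
  below the threshold (default 40) are contracted into polytomies. The
  published analysis does not state how contracted branch lengths were
  handled; here the contracted edge's length is added to its children's
  edges so root-to-tip path lengths are preserved.

## Gene-family simulation and reconciliation

`simulate_gene_family()` runs a birth–death process along a rooted binary
species tree: one gene enters at the root, duplicates and dies with
exponential waiting times on branches, and speciates at internal nodes.
True event counts include events in subtrees that later go extinct, so with
losses the LCA inference is a parsimony lower bound (asserted as a
property), while with `loss_rate = 0` it is exact.

`lca_reconcile()` maps each gene node to the LCA of its children's images;
a node is a duplication iff its image equals a child's image. Losses follow
the standard depth-difference count and are attributed to the species
branch where the lost lineage would have branched off. Species trees with
polytomies are rejected. The bundled nine-taxon defensin fixture (honey bee
plus eight ants, two species carrying two gene copies) is configuration,
not data: the published species tree is shown only graphically, so only
LCA-level claims — the duplication at the bee+ants ancestor and per-species
losses — are asserted against it.

## Problem sizes and numerical notes

The test suite exercises: 200 random architectures for the
generator–parser round trip, 100 random additive 5–8-leaf matrices for
NJ/BioNJ recovery, 50 short pairs against an exhaustive alignment oracle,
100 random gene/species pairs against a brute-force DL minimiser, 200
loss-free simulations for duplication recovery, and a 3-species × 5-domain
end-to-end monophyly check with 100 bootstrap replicates. These sizes keep
the default run to well under a minute on one CPU while leaving each
property statistically meaningful. Floating-point ties in dynamic
programming and Q-selection are compared with a 1e-9/1e-12 tolerance before
the deterministic tie-breaks apply.

Known inconsistencies in the published numbers are resolved as follows and
not targeted: the stated ORF of 2373 bp (781 aa) disagrees with both its own
arithmetic (2373/3 = 791) and the segment sums (775 aa), so segment sums are
ground truth; the smallest repeat-free amplicon is printed as 681 bp where
the ladder arithmetic gives 682, treated as a reporting discrepancy. No
spacer is modelled before the HLD. The 102-aa defensin-1 prepropeptide is
decomposed as 17 + 40 + 44 + 1 (a trailing C-terminal residue), which
reconciles the printed total with the printed segment lengths.
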