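# ampstruct

Structure and evolution of insect antimicrobial peptide (AMP) precursor
genes, modelled on the multipeptide hymenoptaecin and the defensins of
carpenter ants.

Ant hymenoptaecin is translated as a single multipeptide precursor:

```
signal (19 aa) | pro (26 aa) | RR | HLD (108 aa) | RR | 6 x [ EAEP | HD (97 aa) | RR ]
```

Each repeated unit — an `EAEP` spacer, a 97-aa glutamine-initial
hymenoptaecin domain (HD) and a dibasic proprotein-convertase site — spans
3 × (4 + 97 + 2) = **309 nt** of coding sequence, producing a tandem repeat
on the cDNA. Mature peptides are released by a three-step cascade: a
KEX2-like endoprotease cuts C-terminal to each dibasic site, a KEX1-like
carboxypeptidase removes the exposed basic residues, and a dipeptidyl
aminopeptidase trims E/D–A/P dipeptides from the N-terminus. The result is
one glycine-initial 108-aa hymenoptaecin-like peptide plus one Q-initial
97-aa peptide per repeat (the Q can cyclise to pyroglutamate).

The package implements, with seeded synthetic loci carrying the published
dimensions so that every stage is testable offline:

* **Synthetic loci** — `hymenoptaecin_spec()`, `generate_precursor_locus()`,
  `generate_defensin_locus()`, `diverge_domains()`, `simulate_gene_family()`
* **Gene structure** — exact splice mapping (`splice_map()`), intron phase /
  interrupted-codon arithmetic (`intron_report()`, `coding_protein_length()`)
* **Precursor parsing** — dibasic site scanning (`scan_cleavage_sites()`),
  grammar segmentation (`segment_precursor()`), `map_segments_to_cdna()`
* **Maturation** — `endoprotease_cut()`, `carboxypeptidase_trim()`,
  `dipeptidyl_trim()`, `mature_peptides()`
* **Tandem repeats** — `find_tandem_repeats()`, `amplicon_ladder()`
* **Phylogenetics** — affine pairwise/profile alignment, progressive MSA,
  conserved-block cleaning, p/Poisson distances, in-package NJ/BioNJ,
  bootstrap supports and low-support collapse
* **Reconciliation** — LCA duplication–loss mapping (`lca_reconcile()`),
  simulation recovery (`recover_events()`), the bundled defensin scenario
* **Pipeline** — `run_pipeline()` orchestrates everything with one seed and
  writes FASTA/GFF3/TSV/Newick outputs plus a content-hash manifest

## Worked example

```r
library(ampstruct)

spec <- hymenoptaecin_spec()
spec
#> Precursor architecture: signal 19 aa | pro 26 aa | RR | HLD 108 aa | RR | 6 x (EAEP + HD 97 aa + RR)
#> Protein 775 aa; repeat unit 309 nt; 1 intron(s)

bundle <- generate_precursor_locus(spec, seed = 1)
bundle
#> Synthetic locus bundle (seed 1)
#>   genomic 3356 nt; cDNA 2536 nt; protein 775 aa; 1 intron(s)

splice_map(bundle$genomic_seq, bundle$cdna_seq)
#> Gene model: 2 exon(s), 1 intron(s) (820 nt)

mature_peptides(bundle$protein_seq, spec)[, c("length", "n_term")]
#>   length n_term
#> 1    108      G
#> 2     97      Q
#> ...          (six 97-aa Q-initial peptides in total)

find_tandem_repeats(bundle$cdna_seq)[, c("period", "copies_floor", "mean_identity")]
#>   period copies_floor mean_identity
#> 1    309            6             1
```

The 3356-nt gene minus the 2536-nt mRNA is exactly the 820-nt phase-0
intron that splice mapping recovers after codon 39; maturation releases the
108-aa hymenoptaecin-like peptide and six 97-aa Q-initial hymenoptaecins;
and the repeat finder rediscovers the 309-nt unit de novo with six copies
at identity 1.0. The defensin fixtures (`defensin1_fixture()`,
`defensin2_fixture()`) reproduce the 102-aa and 97-aa prepropeptides with
introns at codons 22, 98 and 33, and `defensin_scenario()` reconciles the
bundled defensin gene family, placing one duplication at the bee+ants
ancestor with one loss per single-copy species.

See `vignettes/amp-precursor-architecture.Rmd` for the full model
description, parameter rationale and limitations.

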