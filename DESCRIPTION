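Package: ampstruct
Title: Structure and Evolution of Antimicrobial Peptide Precursor Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing the gene architecture and molecular evolution
    of insect antimicrobial peptide (AMP) precursors, modelled on the
    multipeptide hymenoptaecin and defensin genes of carpenter ants. Provides a
    seeded synthetic-locus generator for multidomain precursor genes, exact
    splice mapping of cDNA onto genomic sequence with intron phase and
    interrupted-codon reports, rule-based segmentation of precursor proteins at
    dibasic proprotein-convertase sites, an in-silico three-step proteolytic
    maturation model (endoprotease, carboxypeptidase, dipeptidyl
    aminopeptidase), de-novo tandem-repeat detection, per-domain phylogenetics
    (progressive alignment, block cleaning, NJ/BioNJ, bootstrap with
    low-support collapse) and duplication-loss reconciliation of gene trees
    against species trees by LCA mapping.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
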