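# Pipeline orchestration: generate -> annotate -> mature -> repeats ->
# genestruct -> phylo -> reconcile from a single validated configuration,
# with per-stage seeds derived from the global seed, a resolved-config
# record and a content-hash manifest beside the outputs.

.STAGES <- c("generate", "annotate", "mature", "repeats", "genestruct",
             "phylo", "reconcile")

#' Default pipeline configuration
#'
#' @return Nested list: `stages` (subset of the seven stage names), global
#'   `seed`, `out_dir`, and one parameter list per stage with the module
#'   defaults.
#' @export
default_run_config <- function() {
  list(
    stages = .STAGES,
    seed = 1L,
    out_dir = "ampstruct_run",
    generate = list(),
    annotate = list(include_rxxr = FALSE),
    mature = list(max_trim = 2L),
    repeats = list(min_period = 30L, max_period = 600L, min_copies = 2L,
                   min_identity = 0.8),
    genestruct = list(min_anchor = 20L),
    phylo = list(subst_rate = 0.05, model = "poisson", variant = "BioNJ",
                 n_boot = 100L, collapse = 40),
    reconcile = list()
  )
}

validate_run_config <- function(config) {
  def <- default_run_config()
  unknown <- setdiff(names(config), names(def))
  if (length(unknown) > 0L) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  if (!is.null(config$stages)) {
    bad <- setdiff(config$stages, .STAGES)
    if (length(bad) > 0L) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  }
  for (st in .STAGES) {
    if (!is.null(config[[st]])) {
      unknown <- setdiff(names(config[[st]]), names(def[[st]]))
      if (length(unknown) > 0L) {
        stop("unknown key(s) in stage '", st, "': ",
             paste(unknown, collapse = ", "))
      }
    }
  }
  merged <- def
  for (nm in names(config)) {
    if (nm %in% .STAGES && is.list(config[[nm]])) {
      merged[[nm]][names(config[[nm]])] <- config[[nm]]
    } else {
      merged[[nm]] <- config[[nm]]
    }
  }
  merged
}

#' Read a plain-text pipeline configuration
#'
#' Lines of the form `key = value` or `stage.key = value`; `stages` is a
#' comma-separated list. Unknown keys are rejected.
#'
#' @param path Config file path.
#' @return A validated configuration list.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  config <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE)) stop("malformed config line: ", ln)
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    val2 <- if (grepl("^-?[0-9.]+$", val)) as.numeric(val)
            else if (val %in% c("TRUE", "FALSE")) as.logical(val)
            else val
    if (grepl(".", key, fixed = TRUE)) {
      st <- sub("\\..*$", "", key)
      k <- sub("^[^.]*\\.", "", key)
      config[[st]][[k]] <- val2
    } else if (key == "stages") {
      config$stages <- trimws(strsplit(val, ",")[[1L]])
    } else {
      config[[key]] <- val2
    }
  }
  validate_run_config(config)
}

# Deterministic per-stage seed offset from the stage name.
.stage_seed <- function(global_seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage))) %% 9973L
  (as.integer(global_seed) + h) %% .Machine$integer.max
}

.write_resolved_config <- function(config, path) {
  # out_dir is deliberately omitted: it is implicit in the file location and
  # would make otherwise-identical runs hash differently.
  lines <- c(paste0("stages = ", paste(config$stages, collapse = ",")),
             paste0("seed = ", config$seed))
  for (st in .STAGES) {
    for (k in names(config[[st]])) {
      lines <- c(lines, paste0(st, ".", k, " = ", config[[st]][[k]]))
    }
  }
  writeLines(lines, path)
}

#' Run the full analysis pipeline
#'
#' Executes the selected stages in dependency order on the bundled default
#' fixtures (hymenoptaecin precursor locus, both defensin loci, defensin
#' gene family), writing FASTA/GFF3/TSV/Newick outputs, the resolved
#' configuration and a manifest of MD5 content hashes to the output
#' directory. Any stage error aborts with an error naming the stage. Runs
#' are deterministic under a fixed global seed.
#'
#' @param config Configuration list (see [default_run_config()]); partial
#'   configs are merged over the defaults, unknown keys rejected.
#' @return Invisibly, a list with `status` (0), `out_dir` and the `manifest`
#'   data frame.
#' @export
run_pipeline <- function(config = list()) {
  config <- validate_run_config(config)
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  produced <- character()
  emit <- function(...) produced <<- c(produced, ...)
  stage <- function(name, fun) {
    if (!name %in% config$stages) return(invisible(NULL))
    tryCatch(fun(), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  spec <- hymenoptaecin_spec()
  bundle <- generate_precursor_locus(spec, .stage_seed(config$seed, "generate"))
  d1 <- defensin1_fixture(.stage_seed(config$seed, "generate") + 1L)
  d2 <- defensin2_fixture(.stage_seed(config$seed, "generate") + 2L)

  stage("generate", function() {
    write_fasta(c(hymenoptaecin_genomic = bundle$genomic_seq),
                file.path(out, "hym_genomic.fa"))
    write_fasta(c(hymenoptaecin_cdna = bundle$cdna_seq),
                file.path(out, "hym_cdna.fa"))
    write_fasta(c(hymenoptaecin_precursor = bundle$protein_seq),
                file.path(out, "hym_protein.fa"))
    write_locus_gff3(bundle, file.path(out, "hym_gene.gff3"),
                     seq_name = "hym_locus", gene_id = "hymenoptaecin")
    write_truth_sidecar(bundle, file.path(out, "hym_truth.txt"))
    write_fasta(c(defensin1_genomic = d1$genomic_seq,
                  defensin2_genomic = d2$genomic_seq),
                file.path(out, "def_genomic.fa"))
    write_fasta(c(defensin1_cdna = d1$cdna_seq, defensin2_cdna = d2$cdna_seq),
                file.path(out, "def_cdna.fa"))
    emit("hym_genomic.fa", "hym_cdna.fa", "hym_protein.fa", "hym_gene.gff3",
         "hym_truth.txt", "def_genomic.fa", "def_cdna.fa")
  })

  ann <- segment_precursor(bundle$protein_seq, spec)
  stage("annotate", function() {
    mapped <- map_segments_to_cdna(ann, bundle$truth_gene_model$cds_start_on_cdna,
                                   nchar(bundle$cdna_seq))
    utils::write.table(as.data.frame(mapped), file.path(out, "annotation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    frags <- substring(bundle$cdna_seq, mapped$nt_start, mapped$nt_end)
    names(frags) <- sprintf("%s_%02d_%d_%d", mapped$role, seq_len(nrow(mapped)),
                            mapped$nt_start, mapped$nt_end)
    write_fasta(frags, file.path(out, "fragments.fna"))
    emit("annotation.tsv", "fragments.fna")
  })

  stage("mature", function() {
    peps <- mature_peptides(bundle$protein_seq, spec,
                            max_trim = config$mature$max_trim)
    seqs <- peps$sequence
    names(seqs) <- sprintf("peptide_%d_len%d_%s", seq_len(nrow(peps)),
                           peps$length, peps$n_term)
    write_fasta(seqs, file.path(out, "peptides.faa"))
    acct <- maturation_accounting(peps)
    utils::write.table(data.frame(component = names(acct), residues = acct),
                       file.path(out, "accounting.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    emit("peptides.faa", "accounting.tsv")
  })

  stage("repeats", function() {
    reps <- find_tandem_repeats(bundle$cdna_seq,
                                min_period = config$repeats$min_period,
                                max_period = config$repeats$max_period,
                                min_copies = config$repeats$min_copies,
                                min_identity = config$repeats$min_identity)
    reps$seq_id <- "hymenoptaecin_cdna"
    utils::write.table(reps[, c("seq_id", "start", "end", "period",
                                "copies_floor", "mean_identity")],
                       file.path(out, "repeats.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    emit("repeats.tsv")
  })

  stage("genestruct", function() {
    rows <- list()
    for (nm in c("hymenoptaecin", "defensin1", "defensin2")) {
      b <- switch(nm, hymenoptaecin = bundle, defensin1 = d1, defensin2 = d2)
      tm <- b$truth_gene_model
      model <- splice_map(b$genomic_seq, b$cdna_seq,
                          min_anchor = config$genestruct$min_anchor,
                          cds_start_on_cdna = tm$cds_start_on_cdna,
                          cds_len_nt = tm$cds_len_nt)
      rep0 <- intron_report(model, protein = b$protein_seq)
      if (nrow(rep0) > 0L) rep0$gene <- nm
      rows[[nm]] <- rep0
    }
    utils::write.table(do.call(rbind, rows), file.path(out, "intron_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    emit("intron_report.tsv")
  })

  stage("phylo", function() {
    sd <- .stage_seed(config$seed, "phylo")
    div <- diverge_domains(bundle, config$phylo$subst_rate, sd)
    m <- div$truth_gene_model
    hd <- ann[ann$role == "HD", , drop = FALSE]
    frags <- substring(div$cdna_seq,
                       m$cds_start_on_cdna + 3L * (hd$start - 1L),
                       m$cds_start_on_cdna + 3L * hd$end - 1L)
    names(frags) <- sprintf("HD%d", seq_along(frags))
    aln <- progressive_msa(frags, kind = "nucleotide")
    aln <- clean_blocks(aln)
    tr <- bootstrap_support(aln, builder = function(a) {
      nj_tree(distance_matrix(a, config$phylo$model), config$phylo$variant)
    }, n_reps = config$phylo$n_boot, seed = sd)
    write_newick(tr, file.path(out, "hd_tree.nwk"))
    write_newick(collapse_low_support(tr, config$phylo$collapse),
                 file.path(out, "hd_tree_collapsed.nwk"))
    emit("hd_tree.nwk", "hd_tree_collapsed.nwk")
  })

  stage("reconcile", function() {
    sc <- defensin_scenario()
    writeLines(sc$narrative, file.path(out, "reconciliation.txt"))
    utils::write.table(sc$losses, file.path(out, "losses.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    emit("reconciliation.txt", "losses.tsv")
  })

  .write_resolved_config(config, file.path(out, "resolved_config.txt"))
  emit("resolved_config.txt")
  files <- file.path(out, produced)
  manifest <- data.frame(file = produced,
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(out, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(list(status = 0L, out_dir = out, manifest = manifest))
}
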