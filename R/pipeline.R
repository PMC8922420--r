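#' Run configuration for the full pipeline
#'
#' One declarative description of a run: libraries (with nucleic-acid
#' flag and at most one control), database paths, per-stage parameters
#' and the master seed. Defaults match the analysis constants where they
#' are fixed (E-value cutoffs 1e-5, Phred threshold 10, dedup window
#' 5-55, ORF minimum 300 nt / ATG / standard code, 50% gap masking).
#'
#' @param libraries `data.frame` with columns `label`, `fastq`,
#'   `nucleic_acid` ("DNA"/"RNA") and `is_control`.
#' @param viral_db,nvnr_db FASTA paths.
#' @param hmm_dir directory of `.hmm` profiles (optional).
#' @param outdir output directory.
#' @param seed master seed.
#' @param qc,assembly,search,annotation named lists of stage-parameter
#'   overrides ([qc_config()], [assembly_config()], [scoring_scheme()]
#'   plus `e_cutoff`/`hmm_bitscore_cutoff`, and `min_orf_size`/
#'   `extend_rounds`).
#' @return object of class `rv_config`.
#' @export
run_config <- function(libraries, viral_db, nvnr_db = NULL, hmm_dir = NULL,
                       outdir = NULL, seed = 1, qc = list(),
                       assembly = list(), search = list(),
                       annotation = list()) {
  stop_if_not(is.data.frame(libraries) && nrow(libraries) >= 1,
              "config error: at least one library is required")
  if (is.null(libraries$nucleic_acid)) libraries$nucleic_acid <- "DNA"
  if (is.null(libraries$is_control)) libraries$is_control <- FALSE
  stop_if_not(!anyDuplicated(libraries$label),
              "config error: library labels must be unique")
  stop_if_not(sum(libraries$is_control) <= 1,
              "config error: at most one control library is permitted")
  structure(list(libraries = libraries, viral_db = viral_db,
                 nvnr_db = nvnr_db, hmm_dir = hmm_dir, outdir = outdir,
                 seed = seed, qc = qc, assembly = assembly, search = search,
                 annotation = annotation),
            class = "rv_config")
}

#' Read a YAML run configuration
#'
#' @param path YAML file with keys `libraries` (list of label/fastq/
#'   nucleic_acid/is_control), `databases` (viral, nvnr, hmm_dir),
#'   `outdir`, `seed` and optional `qc`/`assembly`/`search`/`annotation`
#'   parameter blocks.
#' @return an `rv_config`.
#' @export
read_run_config <- function(path) {
  stop_if_not(file.exists(path), "config error: config file not found")
  y <- yaml::read_yaml(path)
  libs <- do.call(rbind, lapply(y$libraries, function(l) {
    data.frame(label = l$label, fastq = l$fastq,
               nucleic_acid = l$nucleic_acid %||% "DNA",
               is_control = isTRUE(l$is_control), stringsAsFactors = FALSE)
  }))
  run_config(libraries = libs, viral_db = y$databases$viral,
             nvnr_db = y$databases$nvnr, hmm_dir = y$databases$hmm_dir,
             outdir = y$outdir, seed = y$seed %||% 1,
             qc = y$qc %||% list(), assembly = y$assembly %||% list(),
             search = y$search %||% list(),
             annotation = y$annotation %||% list())
}

#' Run the full analysis end-to-end from a configuration
#'
#' Stages run in order QC, assembly, classification, community analysis,
#' annotation/phylogenetics. All randomness flows from the config seed,
#' so re-running the same configuration reproduces every output.
#'
#' @param config an `rv_config` or path to a YAML config.
#' @return an `rv_run` result (see [run_virome_analysis()]).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "rv_config"))
  missing <- !file.exists(config$libraries$fastq)
  stop_if_not(!any(missing),
              paste("config error: missing FASTQ:",
                    paste(config$libraries$fastq[missing], collapse = ", ")))
  stop_if_not(file.exists(config$viral_db),
              "config error: viral database not found")
  reads <- list()
  for (i in seq_len(nrow(config$libraries)))
    reads[[config$libraries$label[i]]] <-
      read_fastq(config$libraries$fastq[i], config$libraries$label[i])
  viral_db <- read_protein_db(config$viral_db, taxonomy = TRUE)
  nvnr_db <- if (!is.null(config$nvnr_db) && file.exists(config$nvnr_db))
    read_protein_db(config$nvnr_db, taxonomy = FALSE) else NULL
  hmms <- NULL
  if (!is.null(config$hmm_dir) && dir.exists(config$hmm_dir)) {
    files <- list.files(config$hmm_dir, pattern = "\\.hmm$",
                        full.names = TRUE)
    hmms <- lapply(files, read_profile_hmm)
    names(hmms) <- vapply(hmms, `[[`, "", "name")
  }
  control <- config$libraries$label[config$libraries$is_control]
  run_virome_analysis(
    reads, viral_db, nvnr_db, hmms,
    control = if (length(control)) control else NULL,
    qc_cfg = do.call(qc_config, config$qc),
    asm_cfg = do.call(assembly_config, config$assembly),
    scheme = do.call(scoring_scheme,
                     config$search[setdiff(names(config$search),
                                           c("e_cutoff",
                                             "hmm_bitscore_cutoff"))]),
    e_cutoff = config$search$e_cutoff %||% 1e-5,
    hmm_bitscore_cutoff = config$search$hmm_bitscore_cutoff %||% 20,
    min_orf_size = config$annotation$min_orf_size %||% 300,
    extend_rounds = config$annotation$extend_rounds %||% 1,
    seed = config$seed, outdir = config$outdir)
}

#' Core end-to-end analysis on in-memory inputs
#'
#' @param reads_by_library named list of read tables (one per library).
#' @param viral_db,nvnr_db protein database tables.
#' @param hmms named list of profile HMMs or `NULL`.
#' @param control label of the control library, or `NULL`.
#' @param qc_cfg,asm_cfg,scheme stage configurations.
#' @param e_cutoff E-value cutoff for both database searches.
#' @param hmm_bitscore_cutoff minimum Viterbi bits for HMM rescue.
#' @param min_orf_size minimum ORF size (nt) for annotation.
#' @param extend_rounds rounds of read-based contig extension before ORF
#'   calling (0 disables).
#' @param seed master seed.
#' @param outdir if non-`NULL`, all result tables/trees are written there.
#' @return object of class `rv_run`: QC/mapping/classification tables,
#'   family and species profiles, ecology results, annotations, hallmark
#'   sets, trees, per-library summary and the control contamination
#'   check.
#' @export
run_virome_analysis <- function(reads_by_library, viral_db, nvnr_db = NULL,
                                hmms = NULL, control = NULL,
                                qc_cfg = qc_config(),
                                asm_cfg = assembly_config(),
                                scheme = scoring_scheme(),
                                e_cutoff = 1e-5, hmm_bitscore_cutoff = 20,
                                min_orf_size = 300, extend_rounds = 1,
                                seed = 1, outdir = NULL) {
  labels <- names(reads_by_library)
  stop_if_not(!is.null(labels) && all(nzchar(labels)),
              "reads_by_library must be a named list")
  sample_labels <- setdiff(labels, control)

  ## stage 1+2: QC, assembly, read-back mapping
  qc_reports <- list()
  clean <- list()
  contigs <- list()
  singlets <- list()
  map_reports <- list()
  per_read_maps <- list()
  for (lib in labels) {
    qc <- qc_library(reads_by_library[[lib]], qc_cfg,
                     seed = op_seed(seed, paste0("qc:", lib)))
    qc_reports[[lib]] <- qc$report
    clean[[lib]] <- qc$reads
    asm <- assemble(qc$reads, asm_cfg)
    mp <- map_reads_back(qc$reads, asm$contigs, asm_cfg,
                         n_raw = qc$report$n_raw)
    if (nrow(asm$contigs)) {
      tally <- table(mp$per_read$contig_id)
      asm$contigs$n_reads_mapped <-
        as.integer(tally[asm$contigs$contig_id])
      asm$contigs$n_reads_mapped[is.na(asm$contigs$n_reads_mapped)] <- 0L
    }
    contigs[[lib]] <- asm$contigs
    singlets[[lib]] <- asm$singlets
    map_reports[[lib]] <- mp$report
    per_read_maps[[lib]] <- mp$per_read
  }
  qc_report <- do.call(rbind, c(qc_reports, list(make.row.names = FALSE)))
  all_contigs <- do.call(rbind, c(contigs, list(make.row.names = FALSE)))
  all_singlets <- do.call(rbind, c(singlets, list(make.row.names = FALSE)))

  ## stage 3: classification
  classifications <- classify_all(all_contigs, all_singlets, viral_db,
                                  nvnr_db, hmms, scheme, e_cutoff,
                                  hmm_bitscore_cutoff)

  ## stage 4: community analysis over the sample libraries
  sample_cls <- classifications[classifications$library %in% sample_labels, ,
                                drop = FALSE]
  prof_fam <- build_profiles(sample_cls, "family", libraries = sample_labels)
  prof_sp <- build_profiles(sample_cls, "species", libraries = sample_labels)
  ecology <- NULL
  if (length(sample_labels) >= 2 && ncol(prof_fam$counts) >= 1 &&
        sum(prof_fam$counts) > 0) {
    bc <- bray_curtis(prof_sp)
    rare <- do.call(rbind, lapply(sample_labels, function(lib) {
      counts <- prof_sp$counts[lib, ]
      counts <- counts[counts > 0]
      if (length(counts) == 0 || sum(counts) < 1) return(NULL)
      depths <- unique(round(seq(0, sum(counts), length.out = 21)))
      cbind(library = lib, rarefaction_curve(counts, depths))
    }))
    ecology <- list(
      bray_curtis = bc,
      pcoa = pcoa_ordination(bc),
      upgma = upgma_tree(bc),
      friedman = if (ncol(prof_fam$counts) >= 2)
        friedman_profile_test(prof_fam) else NULL,
      rarefaction = rare,
      shared = shared_species(prof_sp),
      top10 = top_species(prof_sp, 10))
  }

  ## stage 5: annotation and hallmark phylogenetics on viral contigs
  viral_ids <- classifications$query_id[
    classifications$verdict %in% c("viral", "viral_by_hmm") &
      classifications$query_type == "contig"]
  vc <- all_contigs[all_contigs$contig_id %in% viral_ids, , drop = FALSE]
  if (extend_rounds > 0 && nrow(vc)) {
    vc$seq <- vapply(seq_len(nrow(vc)), function(i) {
      extend_by_mapping(vc$seq[i], clean[[vc$library[i]]],
                        rounds = extend_rounds)
    }, "")
  }
  merge_hits <- classifications[classifications$query_id %in% vc$contig_id &
                                  !is.na(classifications$subject_id), ,
                                drop = FALSE]
  merged <- merge_nonoverlapping_contigs(vc, merge_hits)
  orfs <- do.call(rbind, lapply(seq_len(nrow(merged)), function(i) {
    if (nchar(merged$seq[i]) < min_orf_size) return(NULL)
    predict_orfs(merged$seq[i], merged$record_id[i], min_orf_size)
  }))
  if (is.null(orfs)) orfs <- predict_orfs(strrep("A", 300), "empty")[0, ]
  ann <- annotate_and_extract_hallmarks(orfs, viral_db, scheme, e_cutoff)
  trees <- list()
  for (g in names(ann$hallmark_sets)) {
    mem <- ann$hallmark_sets[[g]]$members
    mem <- mem[mem$complete, , drop = FALSE]
    if (nrow(mem) < 3) next
    peps <- setNames(mem$peptide, mem$orf_id)
    trees[[g]] <- nj_tree(align_and_mask(peps))
  }

  res <- structure(list(
    qc_report = qc_report,
    contigs = all_contigs, singlets = all_singlets,
    map_reports = do.call(rbind, c(map_reports,
                                   list(make.row.names = FALSE))),
    per_read_maps = per_read_maps,
    classifications = classifications,
    profile_family = prof_fam, profile_species = prof_sp,
    ecology = ecology,
    merged_contigs = merged, orf_annotations = ann$annotations,
    hallmark_sets = ann$hallmark_sets, trees = trees,
    control = control, sample_labels = sample_labels,
    seed = seed), class = "rv_run")
  res$summary <- summarize_run(res)
  res$control_check <- if (!is.null(control))
    control_contamination_check(
      res$summary[res$summary$label == control, ],
      res$summary[res$summary$label %in% sample_labels, ]) else NULL
  if (!is.null(outdir)) write_run_outputs(res, outdir)
  res
}

#' @export
print.rv_run <- function(x, ...) {
  cat(sprintf("<rv_run> %d libraries (%s), %d contigs, %d classified viral\n",
              nrow(x$summary), paste(x$summary$label, collapse = ", "),
              nrow(x$contigs),
              sum(x$classifications$verdict %in% c("viral", "viral_by_hmm"))))
  invisible(x)
}

#' Per-library summary table and genome-type family counts
#'
#' @param res an `rv_run` (the `summary` element is computed with this
#'   function; it can be re-derived at any time).
#' @return `data.frame` with one row per library: label, n_raw,
#'   mean_read_length, gc_percent, n_viral_contigs,
#'   pct_reads_mapped_to_viral_contigs, n_viral_reads, n_families,
#'   n_species. The genome-type family-count triple is attached as
#'   attribute `family_triple` (dsDNA, ssDNA, RNA counts of distinct
#'   classified families).
#' @export
summarize_run <- function(res) {
  cls <- res$classifications
  labels <- unique(res$qc_report$library)
  viral_contig_ids <- cls$query_id[cls$query_type == "contig" &
                                     cls$verdict %in% c("viral",
                                                        "viral_by_hmm")]
  rows <- lapply(labels, function(lib) {
    qc <- res$qc_report[res$qc_report$library == lib, ]
    lib_cls <- cls[cls$library == lib, , drop = FALSE]
    viral <- lib_cls[lib_cls$verdict %in% c("viral", "viral_by_hmm"), ,
                     drop = FALSE]
    pm <- res$per_read_maps[[lib]]
    n_viral_mapped <- if (!is.null(pm) && nrow(pm))
      sum(pm$contig_id %in% viral_contig_ids) else 0L
    data.frame(
      label = lib, n_raw = qc$n_raw, mean_read_length = qc$mean_length,
      gc_percent = qc$gc_percent,
      n_viral_contigs = sum(viral$query_type == "contig"),
      pct_reads_mapped_to_viral_contigs =
        100 * n_viral_mapped / max(qc$n_raw, 1),
      n_viral_reads = sum(viral$n_reads),
      n_families = length(unique(stats::na.omit(viral$family))),
      n_species = length(unique(stats::na.omit(viral$species))),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  viral_all <- cls[cls$verdict == "viral", , drop = FALSE]
  fam_type <- unique(viral_all[!is.na(viral_all$family),
                               c("family", "genome_type")])
  triple <- c(dsDNA = sum(fam_type$genome_type == "dsDNA"),
              ssDNA = sum(fam_type$genome_type == "ssDNA"),
              RNA = sum(fam_type$genome_type == "RNA"))
  attr(out, "family_triple") <- triple
  out
}

#' Control-library contamination check
#'
#' Reports the control depth as a percentage of the mean sample depth
#' (two decimals) and the number of control reads classified viral; a
#' warning is raised iff any control read is viral.
#'
#' @param control_summary one-row summary for the control library.
#' @param sample_summaries summary rows for the sample libraries.
#' @return list with `ratio_percent`, `control_viral_reads` and
#'   `warning` (logical).
#' @export
control_contamination_check <- function(control_summary, sample_summaries) {
  stop_if_not(nrow(sample_summaries) >= 1,
              "need at least one sample library")
  ratio <- round(100 * control_summary$n_raw /
                   mean(sample_summaries$n_raw), 2)
  n_viral <- control_summary$n_viral_reads
  if (n_viral > 0)
    warning(sprintf("control library contains %d viral-classified reads",
                    n_viral))
  list(ratio_percent = ratio, control_viral_reads = n_viral,
       warning = n_viral > 0)
}

# write all non-plot outputs of a run
write_run_outputs <- function(res, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(res$qc_report, file.path(outdir, "qc_report.tsv"))
  write_tsv(res$map_reports, file.path(outdir, "mapping_report.tsv"))
  if (nrow(res$contigs))
    write_db_fasta(data.frame(id = res$contigs$contig_id,
                              seq = res$contigs$seq),
                   file.path(outdir, "contigs.fasta"), type = "DNA")
  cls <- res$classifications
  write_tsv(cls, file.path(outdir, "classifications.tsv"))
  write_tsv(profile_to_df(res$profile_family),
            file.path(outdir, "profile_family.tsv"))
  write_tsv(profile_to_df(res$profile_species),
            file.path(outdir, "profile_species.tsv"))
  if (!is.null(res$ecology)) {
    write_tsv(as.data.frame(res$ecology$bray_curtis),
              file.path(outdir, "bray_curtis.tsv"))
    write_tsv(as.data.frame(res$ecology$pcoa$coordinates),
              file.path(outdir, "pcoa_coordinates.tsv"))
    ape::write.tree(res$ecology$upgma, file.path(outdir, "upgma.nwk"))
    if (!is.null(res$ecology$friedman))
      jsonlite::write_json(as.list(res$ecology$friedman),
                           file.path(outdir, "friedman.json"),
                           auto_unbox = TRUE, digits = NA)
    write_tsv(res$ecology$rarefaction, file.path(outdir, "rarefaction.tsv"))
    jsonlite::write_json(
      list(venn_regions = as.list(res$ecology$shared$venn_regions),
           core_species = res$ecology$shared$core_species,
           union_size = res$ecology$shared$union_size),
      file.path(outdir, "shared_species.json"), auto_unbox = TRUE)
    write_tsv(res$ecology$top10, file.path(outdir, "top_species.tsv"))
  }
  write_tsv(res$orf_annotations[, setdiff(names(res$orf_annotations),
                                          "peptide")],
            file.path(outdir, "orf_annotations.tsv"))
  write_orf_gff3(res$orf_annotations, file.path(outdir, "orfs.gff3"))
  if (length(res$hallmark_sets)) {
    dir.create(file.path(outdir, "hallmarks"), showWarnings = FALSE)
    for (g in names(res$hallmark_sets)) {
      mem <- res$hallmark_sets[[g]]$members
      write_db_fasta(data.frame(id = mem$orf_id, seq = mem$peptide),
                     file.path(outdir, "hallmarks", paste0(g, ".fasta")))
    }
  }
  if (length(res$trees)) {
    dir.create(file.path(outdir, "trees"), showWarnings = FALSE)
    for (g in names(res$trees))
      ape::write.tree(res$trees[[g]],
                      file.path(outdir, "trees", paste0(g, ".nwk")))
  }
  write_tsv(res$summary, file.path(outdir, "summary.tsv"))
  report <- list(
    seed = res$seed,
    libraries = res$summary,
    family_triple = as.list(attr(res$summary, "family_triple")),
    control_check = res$control_check,
    n_contigs = nrow(res$contigs),
    n_classified_viral = sum(cls$verdict %in% c("viral", "viral_by_hmm")),
    n_non_viral = sum(cls$verdict == "non_viral"),
    n_unclassified = sum(cls$verdict == "unclassified"))
  jsonlite::write_json(report, file.path(outdir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(outdir)
}

profile_to_df <- function(profile) {
  df <- as.data.frame(profile$counts)
  cbind(library = rownames(profile$counts), df, stringsAsFactors = FALSE)
}

# GFF3 (1-based inclusive) export of ORF records
write_orf_gff3 <- function(orfs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(orfs)) {
    ann <- if (!is.null(orfs$annotation)) orfs$annotation
           else rep("putative protein", nrow(orfs))
    lines <- sprintf("%s\trivervirome\tCDS\t%d\t%d\t.\t%s\t0\tID=%s;product=%s",
                     orfs$contig_id, orfs$start + 1L, orfs$end,
                     orfs$strand, orfs$orf_id, ann)
    writeLines(lines, con)
  }
  invisible(path)
}

#' Generate a complete synthetic input set on disk
#'
#' Writes reference databases, hallmark profile HMMs, per-library FASTQ
#' files and a ready-to-run YAML configuration emulating the six-site
#' survey plus control.
#'
#' @param outdir output directory.
#' @param n_reads nominal reads per sample library.
#' @param n_viral_taxa,n_nvnr_proteins reference-set sizes.
#' @param seed master seed.
#' @return path to the written config YAML, invisibly.
#' @export
simulate_run_inputs <- function(outdir, n_reads = 10000, n_viral_taxa = 34,
                                n_nvnr_proteins = 60, seed = 1) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  refs <- generate_reference_sets(n_viral_taxa, n_nvnr_proteins, seed)
  write_reference_sets(refs, file.path(outdir, "refs"))
  hmms <- build_hallmark_hmms(refs)
  dir.create(file.path(outdir, "hmms"), showWarnings = FALSE)
  for (h in hmms)
    write_profile_hmm(h, file.path(outdir, "hmms", paste0(h$name, ".hmm")))
  designs <- default_designs(refs, n_reads = n_reads, seed = seed)
  libs <- list()
  for (d in designs) {
    reads <- simulate_library(d, refs)
    fq <- file.path(outdir, paste0(d$library_label, ".fastq"))
    write_fastq(reads, fq)
    libs[[length(libs) + 1]] <- list(label = d$library_label, fastq = fq,
                                     nucleic_acid = "DNA",
                                     is_control = d$is_control)
  }
  cfg <- list(seed = seed, outdir = file.path(outdir, "results"),
              libraries = libs,
              databases = list(viral = file.path(outdir, "refs",
                                                 "viral_db.fasta"),
                               nvnr = file.path(outdir, "refs",
                                                "nvnr_db.fasta"),
                               hmm_dir = file.path(outdir, "hmms")))
  path <- file.path(outdir, "config.yaml")
  yaml::write_yaml(cfg, path)
  invisible(path)
}
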