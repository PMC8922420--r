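#' Mock river-water viral community with known ground truth
#'
#' The generator stands in for the sequencer and the public protein
#' databases: it creates a mock community of viral genomes spanning
#' tailed-phage-like dsDNA families, Microviridae/parvovirus/CRESS-like
#' ssDNA families and RNA-virus-like families, plus a non-viral
#' (bacterial/host-like) background, and emits multi-library ~250 bp read
#' sets with PCR duplicates, 3' quality decay and residual adapters.
#' Every emitted record is traceable to its source, so downstream stages
#' can be scored against exact ground truth.
#'
#' @name synthetic_data
NULL

# The 17-family catalogue: nine dsDNA, four ssDNA and four RNA families,
# with host groups and the hallmark gene carried by each group
# (TerL for tailed phages, MCP for Microviridae, NS1 for Parvoviridae,
# Rep for CRESS-DNA families, RdRp for RNA families). Families are ordered
# so that any prefix of length >= 2 spans at least two genome types, and
# base_weight gives the community-wide relative read abundance used by the
# default library designs.
family_catalogue <- function() {
  x <- read.table(header = TRUE, stringsAsFactors = FALSE, text = "
family            genome_type host         hallmark base_weight
Siphoviridae      dsDNA       bacteria     TerL     0.3620
Microviridae      ssDNA       bacteria     MCP      0.0270
Virgaviridae      RNA         plant        RdRp     0.0074
Podoviridae       dsDNA       bacteria     TerL     0.1340
Parvoviridae      ssDNA       invertebrate NS1      0.0020
Dicistroviridae   RNA         invertebrate RdRp     0.0026
Myoviridae        dsDNA       bacteria     TerL     0.0860
Circoviridae      ssDNA       vertebrate   Rep      0.0028
Astroviridae      RNA         vertebrate   RdRp     0.0015
Herelleviridae    dsDNA       bacteria     TerL     0.0500
Genomoviridae     ssDNA       vertebrate   Rep      0.0012
Hepeviridae       RNA         vertebrate   RdRp     0.0004
Ackermannviridae  dsDNA       bacteria     TerL     0.0400
Phycodnaviridae   dsDNA       algae        other    0.0073
Mimiviridae       dsDNA       protist      other    0.0036
Lavidaviridae     dsDNA       protist      other    0.0021
Autographiviridae dsDNA       bacteria     TerL     0.0400
")
  x
}

HALLMARK_GENES <- c("TerL", "MCP", "NS1", "Rep", "RdRp")

# Hallmark gene -> target virus group, fixed by the analysis design.
hallmark_groups <- function() {
  c(TerL = "Caudovirales", MCP = "Microviridae", NS1 = "Parvoviridae",
    Rep = "CRESS-DNA", RdRp = "Riboviria")
}

# point mutations away from a parent peptide; first residue (M) is kept
mutate_peptide <- function(pep, rate) {
  aa <- strsplit(pep, "")[[1]]
  n <- length(aa)
  if (n < 2) return(pep)
  k <- max(1L, round(rate * (n - 1)))
  idx <- sample(2:n, k)
  aa[idx] <- vapply(aa[idx], function(a) sample(setdiff(AA20, a), 1), "")
  paste(aa, collapse = "")
}

# occasional short internal indels so alignments are not trivially gap-free
jitter_indels <- function(pep) {
  aa <- strsplit(pep, "")[[1]]
  if (runif(1) < 0.4 && length(aa) > 20) {
    at <- sample(5:(length(aa) - 5), 1)
    aa <- aa[-(at:min(length(aa), at + sample(0:2, 1)))]
  }
  if (runif(1) < 0.4 && length(aa) > 20) {
    at <- sample(5:(length(aa) - 5), 1)
    aa <- append(aa, sample(AA20, sample(1:3, 1), replace = TRUE), after = at)
  }
  paste(aa, collapse = "")
}

# reverse-translate a peptide with uniformly sampled synonymous codons;
# an M start is encoded as ATG, and a stop codon is appended
encode_orf <- function(pep) {
  aa <- strsplit(pep, "")[[1]]
  codons <- vapply(aa, function(a) {
    cs <- codons_for(a)
    cs[sample.int(length(cs), 1)]
  }, "")
  if (aa[1] == "M") codons[1] <- "ATG"
  paste(c(codons, sample(c("TAA", "TAG", "TGA"), 1)), collapse = "")
}

# lay proteins out on a genome with random intergenic spacers; returns the
# genome string and the exact ORF coordinate table (1-based inclusive)
build_genome <- function(proteins, target_len) {
  segs <- character(0)
  orfs <- list()
  pos <- 0L
  ord <- sample.int(nrow(proteins))
  for (i in ord) {
    gap <- sample(30:120, 1)
    orf_nt <- encode_orf(proteins$peptide[i])
    segs <- c(segs, random_dna(gap), orf_nt)
    start <- pos + gap + 1L
    pos <- pos + gap + nchar(orf_nt)
    orfs[[length(orfs) + 1]] <- data.frame(
      gene = proteins$gene[i], start = start, end = pos, strand = "+",
      peptide = proteins$peptide[i], stringsAsFactors = FALSE)
  }
  tail_gap <- sample(30:120, 1)
  segs <- c(segs, random_dna(max(tail_gap, target_len - pos)))
  list(seq = paste(segs, collapse = ""), orfs = do.call(rbind, orfs))
}

#' Generate paired viral and non-viral reference protein databases
#'
#' Builds a mock community of `n_viral_taxa` viral species distributed over
#' up to 17 families (nine dsDNA, four ssDNA, four RNA), each with a genome
#' carrying implanted ORFs: one family hallmark gene (TerL/MCP/NS1/Rep/RdRp
#' depending on the group) plus accessory proteins, at roughly 85% coding
#' density. Hallmark peptides within a family descend from a family
#' consensus, and families sharing a gene descend from a deeper gene
#' ancestor, so profile construction and phylogenetics see realistic
#' divergence. The non-virus non-redundant (NVNR) side is a set of
#' background (bacterial/host-like) genomes whose implanted proteins form
#' the NVNR database; a `decoy_fraction` of NVNR proteins contain short
#' segments copied from viral proteins so the competitive false-positive
#' filter is actually exercised.
#'
#' @param n_viral_taxa number of viral species (>= 1). With 17, each family
#'   holds exactly one species; beyond 17 extra species are assigned to
#'   families in decreasing abundance order.
#' @param n_nvnr_proteins total NVNR proteins distributed over the
#'   background genomes (0 allowed).
#' @param seed integer seed; identical seeds give byte-identical outputs.
#' @param n_background number of background genomes (ignored when
#'   `n_nvnr_proteins` is 0).
#' @param decoy_fraction fraction of NVNR proteins built as viral-k-mer
#'   decoys.
#' @return list with `taxa` (list of mock taxa: species/family/genome
#'   metadata, genome sequence, implanted ORF table), `viral_db` and
#'   `nvnr_db` protein tables, `background` genome list, and a `truth`
#'   table mapping every database record to its source.
#' @export
generate_reference_sets <- function(n_viral_taxa = 34, n_nvnr_proteins = 60,
                                    seed = 1, n_background = 12,
                                    decoy_fraction = 0.2) {
  stop_if_not(is_count(n_viral_taxa) && n_viral_taxa >= 1,
              "n_viral_taxa must be a positive count")
  stop_if_not(is_count(n_nvnr_proteins), "n_nvnr_proteins must be a count >= 0")
  fam <- family_catalogue()

  with_seed(op_seed(seed, "reference_sets"), {
    # species -> family assignment
    n_fam <- min(n_viral_taxa, nrow(fam))
    fam_idx <- seq_len(n_fam)
    if (n_viral_taxa > nrow(fam)) {
      extra <- order(-fam$base_weight)
      fam_idx <- c(fam_idx, extra[((seq_len(n_viral_taxa - nrow(fam)) - 1) %%
                                     nrow(fam)) + 1])
    }
    fam_of <- fam$family[fam_idx]

    # gene ancestors shared across families, then family consensus copies
    anc_len <- c(TerL = 260, MCP = 240, NS1 = 230, Rep = 220, RdRp = 260,
                 other = 200)
    ancestors <- lapply(anc_len, random_peptide)
    fam_hall <- list()
    for (f in unique(fam_of)) {
      g <- fam$hallmark[fam$family == f]
      fam_hall[[f]] <- mutate_peptide(ancestors[[g]], 0.25)
    }

    taxa <- list()
    viral_rows <- list()
    vid <- 0L
    glen_for <- c(dsDNA = 12000, ssDNA = 5000, RNA = 8000)
    for (i in seq_len(n_viral_taxa)) {
      f <- fam_of[i]
      k <- sum(fam_of[seq_len(i)] == f)
      row <- fam[fam$family == f, ]
      species <- sprintf("Riverine %s %d",
                         tolower(sub("viridae$", "virus", f)), k)
      target <- round(glen_for[[row$genome_type]] * runif(1, 0.9, 1.1))
      hall_gene <- row$hallmark
      hall_pep <- jitter_indels(mutate_peptide(fam_hall[[f]], 0.08))
      prot <- data.frame(gene = hall_gene, peptide = hall_pep,
                         stringsAsFactors = FALSE)
      budget <- round(0.85 * target) - (3 * nchar(hall_pep) + 3)
      while (budget >= 453) {
        len_aa <- sample(150:250, 1)
        if (3 * len_aa + 3 > budget) len_aa <- floor((budget - 3) / 3)
        prot <- rbind(prot, data.frame(gene = "other",
                                       peptide = random_peptide(len_aa),
                                       stringsAsFactors = FALSE))
        budget <- budget - (3 * len_aa + 3)
      }
      g <- build_genome(prot, target)
      taxa[[species]] <- list(
        species_name = species, family = f, genome_type = row$genome_type,
        host = row$host, genome_seq = g$seq, orfs = g$orfs)
      for (j in seq_len(nrow(g$orfs))) {
        vid <- vid + 1L
        viral_rows[[vid]] <- data.frame(
          id = sprintf("VP%05d", vid), species = species, family = f,
          genome_type = row$genome_type, host = row$host,
          gene = g$orfs$gene[j], seq = g$orfs$peptide[j],
          stringsAsFactors = FALSE)
      }
    }
    viral_db <- do.call(rbind, viral_rows)

    # background genomes carrying the NVNR proteins
    background <- list()
    nvnr_rows <- list()
    if (n_nvnr_proteins > 0) {
      n_background <- min(n_background, n_nvnr_proteins)
      split_n <- rep(n_nvnr_proteins %/% n_background, n_background)
      if (n_nvnr_proteins %% n_background > 0)
        split_n[seq_len(n_nvnr_proteins %% n_background)] <-
          split_n[seq_len(n_nvnr_proteins %% n_background)] + 1L
      n_decoy <- round(decoy_fraction * n_nvnr_proteins)
      decoy_flags <- sample(rep(c(TRUE, FALSE),
                                c(n_decoy, n_nvnr_proteins - n_decoy)))
      nid <- 0L
      for (b in seq_len(n_background)) {
        peps <- character(split_n[b])
        dec <- logical(split_n[b])
        for (j in seq_len(split_n[b])) {
          nid <- nid + 1L
          p <- random_peptide(sample(150:250, 1))
          if (decoy_flags[nid]) {
            dec[j] <- TRUE
            aa <- strsplit(p, "")[[1]]
            for (s in 1:3) {
              src <- strsplit(sample(viral_db$seq, 1), "")[[1]]
              if (length(src) < 8 || length(aa) < 10) next
              from <- sample(2:(length(src) - 6), 1)
              at <- sample(2:(length(aa) - 6), 1)
              aa[at:(at + 5)] <- src[from:(from + 5)]
            }
            p <- paste(aa, collapse = "")
          }
          peps[j] <- p
        }
        prot <- data.frame(gene = "other", peptide = peps,
                           stringsAsFactors = FALSE)
        target <- round(sum(3 * nchar(peps) + 3) / 0.85)
        g <- build_genome(prot, target)
        bg_id <- sprintf("BG%02d", b)
        background[[bg_id]] <- list(id = bg_id, genome_seq = g$seq,
                                    orfs = g$orfs)
        for (j in seq_len(nrow(g$orfs))) {
          nvnr_rows[[length(nvnr_rows) + 1]] <- data.frame(
            id = sprintf("NV%05d", length(nvnr_rows) + 1L), source = bg_id,
            decoy = dec[match(g$orfs$peptide[j], peps)],
            seq = g$orfs$peptide[j], stringsAsFactors = FALSE)
        }
      }
    }
    nvnr_db <- if (length(nvnr_rows)) do.call(rbind, nvnr_rows)
               else data.frame(id = character(0), source = character(0),
                               decoy = logical(0), seq = character(0))

    truth <- rbind(
      data.frame(record_id = viral_db$id,
                 kind = rep("viral", nrow(viral_db)),
                 source = viral_db$species, gene = viral_db$gene,
                 decoy = rep(FALSE, nrow(viral_db)),
                 stringsAsFactors = FALSE),
      data.frame(record_id = nvnr_db$id, kind = rep("nvnr", nrow(nvnr_db)),
                 source = nvnr_db$source,
                 gene = rep("other", nrow(nvnr_db)),
                 decoy = nvnr_db$decoy, stringsAsFactors = FALSE))

    structure(list(taxa = taxa, viral_db = viral_db, nvnr_db = nvnr_db,
                   background = background, truth = truth, seed = seed),
              class = "rv_references")
  })
}

#' Describe one simulated sequencing library
#'
#' A community design fixes everything the simulator needs for one library:
#' per-species abundance weights, the non-viral background fraction, depth,
#' PCR duplicate rate, residual-adapter behaviour and the 3' quality decay.
#'
#' @param library_label unique library name.
#' @param weights named non-negative vector of per-species abundance
#'   weights (names must be species in the reference set). May be empty
#'   only when `non_viral_fraction` is 1.
#' @param n_reads number of reads to emit.
#' @param non_viral_fraction fraction of reads drawn from the background
#'   genomes.
#' @param duplicate_rate fraction of reads that are exact re-emissions of
#'   earlier reads (PCR duplicates).
#' @param adapter_seq adapter whose prefix contaminates some 3' ends.
#' @param adapter_fraction fraction of reads carrying a residual adapter.
#' @param quality_decay length-2 vector `(start_q, end_q)`: mean Phred
#'   quality at the first and last base, interpolated linearly.
#' @param read_length maximum read length in nt.
#' @param is_control flag for the blank control library.
#' @param seed integer seed for this library.
#' @return object of class `rv_design`.
#' @export
community_design <- function(library_label, weights = numeric(0),
                             n_reads = 10000, non_viral_fraction = 0.8,
                             duplicate_rate = 0.1,
                             adapter_seq = "AGATCGGAAGAGCACACGTCTGAACTCCAGTCAC",
                             adapter_fraction = 0.1,
                             quality_decay = c(37, 9),
                             read_length = 250,
                             is_control = FALSE, seed = 1) {
  stop_if_not(is_count(n_reads), "n_reads must be a count >= 0")
  stop_if_not(non_viral_fraction >= 0 && non_viral_fraction <= 1,
              "non_viral_fraction must lie in [0, 1]")
  stop_if_not(duplicate_rate >= 0 && duplicate_rate < 1,
              "duplicate_rate must lie in [0, 1)")
  if (non_viral_fraction < 1)
    stop_if_not(length(weights) > 0 && sum(weights) > 0,
                "abundance weights must sum > 0 unless the library is pure background")
  structure(list(library_label = library_label, weights = weights,
                 n_reads = n_reads, non_viral_fraction = non_viral_fraction,
                 duplicate_rate = duplicate_rate, adapter_seq = adapter_seq,
                 adapter_fraction = adapter_fraction,
                 quality_decay = quality_decay, read_length = read_length,
                 is_control = is_control, seed = seed),
            class = "rv_design")
}

#' Simulate one sequencing library from a community design
#'
#' Reads are uniform substrings (or reverse complements) of the source
#' genomes, at most `read_length` nt. A `duplicate_rate` fraction are exact
#' re-emissions of earlier reads; an `adapter_fraction` fraction have their
#' 3' end replaced by a 14-30 nt adapter prefix; per-base qualities decay
#' linearly from `start_q` to `end_q` with small jitter. The FASTQ
#' description line encodes the full ground truth
#' (`src=...;start=...;strand=...;ilen=...;alen=...;dup=...`), recoverable
#' with [read_truth()].
#'
#' @param design an [community_design()] object.
#' @param refs reference set from [generate_reference_sets()].
#' @return read table as in [read_fastq()].
#' @export
simulate_library <- function(design, refs) {
  stopifnot(inherits(design, "rv_design"))
  n <- design$n_reads
  lib <- design$library_label
  empty <- data.frame(read_id = character(0), library = character(0),
                      seq = character(0), qual = character(0),
                      meta = character(0), stringsAsFactors = FALSE)
  if (n == 0) return(empty)
  viral_names <- names(refs$taxa)
  w <- design$weights[design$weights > 0]
  if (design$non_viral_fraction < 1) {
    stop_if_not(all(names(w) %in% viral_names),
                "design references unknown taxa")
  }
  if (design$non_viral_fraction > 0)
    stop_if_not(length(refs$background) > 0,
                "design draws background reads but the reference set has no background genomes")

  with_seed(op_seed(design$seed, paste0("simlib:", lib)), {
    n_dup <- round(n * design$duplicate_rate)
    n_fresh <- n - n_dup
    rl <- design$read_length

    genomes <- c(vapply(refs$taxa, `[[`, "", "genome_seq"),
                 vapply(refs$background, `[[`, "", "genome_seq"))
    src_pool_v <- names(refs$taxa)
    src_pool_b <- names(refs$background)

    is_bg <- runif(n_fresh) < design$non_viral_fraction
    src <- character(n_fresh)
    if (any(!is_bg))
      src[!is_bg] <- sample(names(w), sum(!is_bg), replace = TRUE,
                            prob = w / sum(w))
    if (any(is_bg))
      src[is_bg] <- sample(src_pool_b, sum(is_bg), replace = TRUE)

    glen <- nchar(genomes)[src]
    has_ad <- runif(n_fresh) < design$adapter_fraction
    alen <- integer(n_fresh)
    alen[has_ad] <- sample(14:min(30, nchar(design$adapter_seq)),
                           sum(has_ad), replace = TRUE)
    total_len <- pmin(rl, glen)
    ilen <- pmax(1L, total_len - alen)
    start <- 1L + floor(runif(n_fresh) * (glen - ilen + 1))
    strand <- sample(c("+", "-"), n_fresh, replace = TRUE)

    insert <- substring(genomes[src], start, start + ilen - 1L)
    neg <- strand == "-"
    if (any(neg)) insert[neg] <- revcomp(insert[neg])
    seqs <- ifelse(alen > 0,
                   paste0(insert, substring(design$adapter_seq, 1, alen)),
                   insert)

    # linear quality decay with jitter, encoded Phred+33
    q0 <- design$quality_decay[1]; q1 <- design$quality_decay[2]
    quals <- vapply(nchar(seqs), function(L) {
      base <- if (L == 1) q0 else q0 + (q1 - q0) * (seq_len(L) - 1) / (L - 1)
      phred_encode(pmax(2L, pmin(40L, round(base + rnorm(L, 0, 1.5)))))
    }, "")

    meta <- sprintf("src=%s;start=%d;strand=%s;ilen=%d;alen=%d;dup=.",
                    src, start, strand, ilen, alen)
    ids <- sprintf("%s:r%06d", lib, seq_len(n_fresh))

    if (n_dup > 0) {
      orig <- sample.int(n_fresh, n_dup, replace = TRUE)
      dup_ids <- sprintf("%s:r%06d", lib, n_fresh + seq_len(n_dup))
      dup_meta <- sprintf("%s;dup=%s",
                          sub(";dup=\\.$", "", meta[orig]), ids[orig])
      ids <- c(ids, dup_ids)
      seqs <- c(seqs, seqs[orig])
      quals <- c(quals, quals[orig])
      meta <- c(meta, dup_meta)
    }
    data.frame(read_id = ids, library = lib, seq = seqs, qual = quals,
               meta = meta, stringsAsFactors = FALSE)
  })
}

#' Recover simulation ground truth from read metadata
#'
#' @param reads read table whose `meta` column was written by
#'   [simulate_library()].
#' @return `data.frame` with columns `read_id`, `src`, `start`, `strand`,
#'   `ilen` (insert length), `alen` (adapter length), `dup` (id of the
#'   original read for PCR duplicates, `NA` otherwise).
#' @export
read_truth <- function(reads) {
  pick <- function(key, conv = identity) {
    v <- sub(sprintf(".*%s=([^;]*).*", key), "\\1", reads$meta)
    conv(v)
  }
  data.frame(read_id = reads$read_id,
             src = pick("src"),
             start = as.integer(pick("start")),
             strand = pick("strand"),
             ilen = as.integer(pick("ilen")),
             alen = as.integer(pick("alen")),
             dup = {
               d <- pick("dup"); d[d == "."] <- NA_character_; d
             },
             stringsAsFactors = FALSE)
}

#' Default six-site + control library designs
#'
#' Emulates a six-library river survey: per-library species weights are the
#' community base weights with mild lognormal site-to-site jitter, one site
#' (Nanjing) carries a strong Parvoviridae bloom, and a blank control
#' library holds ~1% of the mean sample depth with background reads only.
#'
#' @param refs reference set from [generate_reference_sets()].
#' @param n_reads nominal reads per sample library.
#' @param seed integer seed.
#' @return named list of [community_design()] objects (last one the control).
#' @export
default_designs <- function(refs, n_reads = 10000, seed = 1) {
  fam <- family_catalogue()
  sites <- c("Anqing", "Wuhu", "Nanjing", "Zhenjiang", "Changzhou", "Nantong")
  species <- names(refs$taxa)
  sp_fam <- vapply(refs$taxa, `[[`, "", "family")
  base_w <- numeric(length(species))
  names(base_w) <- species
  for (f in unique(sp_fam)) {
    members <- species[sp_fam == f]
    split <- 0.5^(seq_along(members) - 1)
    base_w[members] <- fam$base_weight[fam$family == f] * split / sum(split)
  }
  with_seed(op_seed(seed, "designs"), {
    designs <- list()
    for (s in sites) {
      w <- base_w * exp(rnorm(length(base_w), 0, 0.3))
      if (s == "Nanjing" && any(sp_fam == "Parvoviridae")) {
        # Parvoviridae bloom at one site, ~12% of viral reads
        pv <- sp_fam == "Parvoviridae"
        w[pv] <- 0.12 * sum(w[!pv]) / (1 - 0.12) * (base_w[pv] / sum(base_w[pv]))
      }
      designs[[s]] <- community_design(
        library_label = s, weights = w / sum(w),
        n_reads = round(n_reads * runif(1, 0.92, 1.08)),
        seed = op_seed(seed, paste0("lib:", s)))
    }
    designs[["Control"]] <- community_design(
      library_label = "Control", weights = numeric(0),
      n_reads = round(0.01 * n_reads), non_viral_fraction = 1,
      duplicate_rate = 0.05, is_control = TRUE,
      seed = op_seed(seed, "lib:Control"))
    designs
  })
}

#' Write a reference set to disk
#'
#' Emits `viral_db.fasta` and `nvnr_db.fasta` (protein FASTA, the viral one
#' with `id|species|family|genome_type|host|gene` headers), the genome
#' FASTA files and the record-level `truth.tsv`.
#'
#' @param refs reference set from [generate_reference_sets()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_reference_sets <- function(refs, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_db_fasta(refs$viral_db, file.path(dir, "viral_db.fasta"))
  write_db_fasta(refs$nvnr_db[, c("id", "seq")], file.path(dir, "nvnr_db.fasta"))
  vg <- data.frame(id = names(refs$taxa),
                   seq = vapply(refs$taxa, `[[`, "", "genome_seq"))
  write_db_fasta(vg, file.path(dir, "viral_genomes.fasta"), type = "DNA")
  if (length(refs$background)) {
    bg <- data.frame(id = names(refs$background),
                     seq = vapply(refs$background, `[[`, "", "genome_seq"))
    write_db_fasta(bg, file.path(dir, "background_genomes.fasta"), type = "DNA")
  }
  write_tsv(refs$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}
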