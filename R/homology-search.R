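#' Scoring scheme for translated homology search
#'
#' BLOSUM62 with affine gaps and fixed gapped Karlin-Altschul constants
#' (lambda = 0.267, K = 0.041, NCBI's published values for BLOSUM62 with
#' gap costs 11/1), so E-values are deterministic across runs. Seeding and
#' extension parameters control the seed-and-extend heuristic: exact
#' amino-acid k-mer seeds, an ungapped X-drop extension whose score must
#' reach `trigger` before the banded gapped extension runs.
#'
#' @param gap_open,gap_extend affine gap costs (a gap of length k costs
#'   `gap_open + k * gap_extend`).
#' @param lambda,K Karlin-Altschul parameters for `E = K m n exp(-lambda S)`.
#' @param seed_k amino-acid seed length.
#' @param band half-width of the banded gapped extension.
#' @param xdrop X-drop for the ungapped extension.
#' @param trigger minimum ungapped extension score that triggers gapped
#'   extension of a subject.
#' @return object of class `rv_scheme`.
#' @export
scoring_scheme <- function(gap_open = 11, gap_extend = 1, lambda = 0.267,
                           K = 0.041, seed_k = 4, band = 16, xdrop = 20,
                           trigger = 38) {
  stop_if_not(lambda > 0 && K > 0, "lambda and K must be positive")
  m <- blosum62()
  storage.mode(m) <- "integer"
  structure(list(matrix = m, gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend), lambda = lambda,
                 K = K, seed_k = as.integer(seed_k), band = as.integer(band),
                 xdrop = as.integer(xdrop), trigger = as.integer(trigger)),
            class = "rv_scheme")
}

#' Six-frame translation under the standard genetic code
#'
#' Frames +1..+3 read the forward strand with offsets 0..2; frames -1..-3
#' read the reverse complement the same way. Stop codons are rendered as
#' `*`, codons with ambiguous bases as `X`.
#'
#' @param seq one nucleotide string of length >= 3.
#' @return named character vector of six peptides
#'   (`+1`,`+2`,`+3`,`-1`,`-2`,`-3`).
#' @export
six_frame_translate <- function(seq) {
  stop_if_not(is.character(seq) && length(seq) == 1 && nchar(seq) >= 3,
              "seq must be a single nucleotide string of length >= 3")
  frames <- c(1L, 2L, 3L, -1L, -2L, -3L)
  peps <- vapply(frames, function(f) cpp_translate(seq, f), "")
  names(peps) <- c("+1", "+2", "+3", "-1", "-2", "-3")
  peps
}

hit_columns <- c("query_id", "subject_id", "species", "family",
                 "genome_type", "host", "gene", "score", "bitscore",
                 "evalue", "pident", "qstart", "qend", "sstart", "send",
                 "frame")

empty_hits <- function() {
  df <- data.frame(query_id = character(0), subject_id = character(0),
                   species = character(0), family = character(0),
                   genome_type = character(0), host = character(0),
                   gene = character(0), score = integer(0),
                   bitscore = numeric(0), evalue = numeric(0),
                   pident = numeric(0), qstart = integer(0),
                   qend = integer(0), sstart = integer(0), send = integer(0),
                   frame = integer(0), stringsAsFactors = FALSE)
  df
}

finish_hits <- function(raw, queries, query_ids, db, scheme, e_cutoff,
                        peptide = FALSE) {
  if (nrow(raw) == 0) return(empty_hits())
  n_db <- sum(nchar(db$seq))
  m <- if (peptide) nchar(queries)[raw$query]
       else (nchar(queries)[raw$query] - (abs(raw$frame) - 1L)) %/% 3L
  bit <- (scheme$lambda * raw$score - log(scheme$K)) / log(2)
  evalue <- as.numeric(m) * n_db * 2^(-bit)
  df <- data.frame(
    query_id = query_ids[raw$query],
    subject_id = db$id[raw$subject],
    species = if (!is.null(db$species)) db$species[raw$subject] else NA_character_,
    family = if (!is.null(db$family)) db$family[raw$subject] else NA_character_,
    genome_type = if (!is.null(db$genome_type)) db$genome_type[raw$subject] else NA_character_,
    host = if (!is.null(db$host)) db$host[raw$subject] else NA_character_,
    gene = if (!is.null(db$gene)) db$gene[raw$subject] else NA_character_,
    score = raw$score, bitscore = bit, evalue = evalue,
    pident = 100 * raw$matches / pmax(raw$alnlen, 1),
    qstart = raw$qstart, qend = raw$qend, sstart = raw$sstart,
    send = raw$send, frame = raw$frame, stringsAsFactors = FALSE)
  # best local alignment per (query, subject) across frames
  ord <- order(df$query_id, df$subject_id, -df$score, df$evalue)
  df <- df[ord, , drop = FALSE]
  df <- df[!duplicated(df[, c("query_id", "subject_id")]), , drop = FALSE]
  df <- df[df$evalue < e_cutoff, , drop = FALSE]
  df <- df[order(df$evalue, -df$score, df$query_id, df$subject_id), ,
           drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Translated (six-frame) search of nucleotide queries against a protein DB
#'
#' Seed-and-extend local alignment in all six reading frames under the
#' scoring scheme; per (query, subject) the best-scoring local alignment
#' yields the raw score S, converted to a bit score
#' `(lambda S - ln K)/ln 2` and an E-value `E = K m n exp(-lambda S)`
#' with m the query frame peptide length and n the total database
#' residues. Only hits with `E < e_cutoff` are returned, sorted by
#' ascending E then descending score.
#'
#' @param queries character vector of nucleotide sequences.
#' @param db protein database table ([read_protein_db()]); taxonomy
#'   columns, when present, are carried onto the hits.
#' @param scheme a [scoring_scheme()].
#' @param e_cutoff E-value threshold (default 1e-5).
#' @param query_ids identifiers for the queries.
#' @return hit table (one row per query/subject pair); alignment
#'   coordinates are 0-based half-open in frame-peptide and subject
#'   coordinates.
#' @export
translated_search <- function(queries, db, scheme = scoring_scheme(),
                              e_cutoff = 1e-5,
                              query_ids = names(queries) %||%
                                as.character(seq_along(queries))) {
  stop_if_not(!is.null(db) && nrow(db) > 0, "database must be non-empty")
  if (length(queries) == 0) return(empty_hits())
  raw <- cpp_translated_search(queries, db$seq, scheme$matrix, scheme$seed_k,
                               scheme$band, scheme$xdrop, scheme$gap_open,
                               scheme$gap_extend, scheme$trigger)
  finish_hits(raw, queries, query_ids, db, scheme, e_cutoff)
}

#' Peptide-vs-protein-database search
#'
#' Same engine as [translated_search()] but for amino-acid queries (used
#' for ORF annotation); `m` in the E-value is the peptide length.
#'
#' @inheritParams translated_search
#' @param queries character vector of peptides.
#' @export
peptide_search <- function(queries, db, scheme = scoring_scheme(),
                           e_cutoff = 1e-5,
                           query_ids = names(queries) %||%
                             as.character(seq_along(queries))) {
  stop_if_not(!is.null(db) && nrow(db) > 0, "database must be non-empty")
  if (length(queries) == 0) return(empty_hits())
  raw <- cpp_peptide_search(queries, db$seq, scheme$matrix, scheme$seed_k,
                            scheme$band, scheme$xdrop, scheme$gap_open,
                            scheme$gap_extend, scheme$trigger)
  finish_hits(raw, queries, query_ids, db, scheme, e_cutoff, peptide = TRUE)
}

#' Competitive viral / non-viral filtering of one query's hits
#'
#' A query is `viral` iff a viral hit under the E-value cutoff exists and
#' either no NVNR hit under the cutoff exists or the best viral bit score
#' strictly exceeds the best NVNR bit score; it is `non_viral` when an
#' NVNR hit under the cutoff exists and is at least as good as any viral
#' hit (ties are resolved conservatively to non-viral); otherwise it is
#' `unclassified`.
#'
#' @param viral_hits,nvnr_hits hit tables for one query.
#' @param e_cutoff E-value threshold.
#' @return list with `verdict`, `best_viral` (hit row or `NULL`) and
#'   `best_nvnr`.
#' @export
competitive_filter <- function(viral_hits, nvnr_hits, e_cutoff = 1e-5) {
  pick_best <- function(h) {
    if (is.null(h) || nrow(h) == 0) return(NULL)
    h <- h[h$evalue < e_cutoff, , drop = FALSE]
    if (nrow(h) == 0) return(NULL)
    h[order(h$evalue, -h$score)[1], , drop = FALSE]
  }
  bv <- pick_best(viral_hits)
  bn <- pick_best(nvnr_hits)
  verdict <- if (!is.null(bv) && (is.null(bn) || bv$bitscore > bn$bitscore)) {
    "viral"
  } else if (!is.null(bn)) {
    "non_viral"
  } else {
    "unclassified"
  }
  list(verdict = verdict, best_viral = bv, best_nvnr = bn)
}

#' Classify contigs and singlets as viral or non-viral
#'
#' Each query is searched against the viral protein database and the
#' non-virus (NVNR) database; hits are resolved by [competitive_filter()].
#' Contigs with no significant hit in either database are rescued through
#' the profile HMMs: their six-frame translations are fragmented at stop
#' codons and scored against every profile, and a best Viterbi log-odds
#' score at or above `hmm_bitscore_cutoff` yields verdict `viral_by_hmm`.
#' Everything else is `unclassified`. The taxonomy of a `viral` query is
#' that of its best viral hit.
#'
#' @param contigs contig table (columns `contig_id`, `library`, `seq`,
#'   optionally `n_reads_mapped`).
#' @param singlets singlet read table.
#' @param viral_db,nvnr_db protein database tables.
#' @param hmms list of profile HMMs ([build_profile_hmm()]), or `NULL`.
#' @param scheme a [scoring_scheme()].
#' @param e_cutoff E-value threshold for both searches.
#' @param hmm_bitscore_cutoff minimum Viterbi log-odds (bits) for an HMM
#'   rescue.
#' @return classification table: `query_id`, `library`, `query_type`,
#'   `n_reads` (mapped-read weight for contigs, 1 for singlets),
#'   `verdict`, best-viral-hit taxonomy and statistics, best NVNR bit
#'   score, and the HMM name/score for rescued queries.
#' @export
classify_all <- function(contigs, singlets, viral_db, nvnr_db, hmms = NULL,
                         scheme = scoring_scheme(), e_cutoff = 1e-5,
                         hmm_bitscore_cutoff = 20) {
  qids <- c(contigs$contig_id, singlets$read_id)
  seqs <- c(contigs$seq, singlets$seq)
  libs <- c(contigs$library, singlets$library)
  type <- rep(c("contig", "singlet"), c(nrow(contigs), nrow(singlets)))
  weight <- c(
    if ("n_reads_mapped" %in% names(contigs)) contigs$n_reads_mapped
    else contigs$n_members %||% rep(1L, nrow(contigs)),
    rep(1L, nrow(singlets)))
  n <- length(qids)
  if (n == 0) {
    return(data.frame(query_id = character(0), library = character(0),
                      query_type = character(0), n_reads = integer(0),
                      verdict = character(0), stringsAsFactors = FALSE))
  }

  vh <- translated_search(seqs, viral_db, scheme, e_cutoff, query_ids = qids)
  nh <- if (!is.null(nvnr_db) && nrow(nvnr_db) > 0)
    translated_search(seqs, nvnr_db, scheme, e_cutoff, query_ids = qids)
  else empty_hits()

  best_of <- function(h) {
    h <- h[order(h$query_id, h$evalue, -h$score), , drop = FALSE]
    h[!duplicated(h$query_id), , drop = FALSE]
  }
  bv <- best_of(vh)
  bn <- best_of(nh)
  iv <- match(qids, bv$query_id)
  inn <- match(qids, bn$query_id)

  v_bit <- ifelse(is.na(iv), -Inf, bv$bitscore[iv])
  n_bit <- ifelse(is.na(inn), -Inf, bn$bitscore[inn])
  verdict <- ifelse(!is.na(iv) & (is.na(inn) | v_bit > n_bit), "viral",
                    ifelse(!is.na(inn), "non_viral", "unclassified"))

  out <- data.frame(
    query_id = qids, library = libs, query_type = type,
    n_reads = as.integer(weight), verdict = verdict,
    species = bv$species[iv], family = bv$family[iv],
    genome_type = bv$genome_type[iv], host = bv$host[iv],
    gene = bv$gene[iv], subject_id = bv$subject_id[iv],
    evalue = bv$evalue[iv], bitscore = bv$bitscore[iv],
    pident = bv$pident[iv], sstart = bv$sstart[iv], send = bv$send[iv],
    frame = bv$frame[iv],
    nvnr_bitscore = ifelse(is.na(inn), NA, bn$bitscore[inn]),
    hmm_name = NA_character_, hmm_score = NA_real_,
    stringsAsFactors = FALSE)
  # blank the viral taxonomy for non-viral verdicts
  tax_cols <- c("species", "family", "genome_type", "host", "gene",
                "subject_id", "evalue", "bitscore", "pident", "sstart",
                "send", "frame")
  out[out$verdict != "viral", tax_cols] <- NA

  # profile-HMM rescue of contigs with no hit in either database
  if (!is.null(hmms) && length(hmms) > 0) {
    cand <- which(out$verdict == "unclassified" & out$query_type == "contig")
    for (i in cand) {
      frags <- orf_fragments(seqs[i], min_aa = 30)
      if (length(frags) == 0) next
      # hallmark genes are long; the longest frames carry the signal
      frags <- head(frags[order(-nchar(frags))], 6)
      best <- -Inf
      best_h <- NA_character_
      for (h in hmms) {
        sc <- max(vapply(frags, function(p) hmm_score(p, h)$viterbi, 0))
        if (sc > best) {
          best <- sc
          best_h <- h$name
        }
      }
      if (is.finite(best) && best >= hmm_bitscore_cutoff) {
        out$verdict[i] <- "viral_by_hmm"
        out$hmm_name[i] <- best_h
        out$hmm_score[i] <- best
      }
    }
  }
  out
}

# six-frame stop-free peptide fragments of a nucleotide sequence
orf_fragments <- function(seq, min_aa = 30) {
  if (nchar(seq) < 3 * min_aa) return(character(0))
  peps <- six_frame_translate(seq)
  frags <- unlist(strsplit(peps, "*", fixed = TRUE), use.names = FALSE)
  frags[nchar(frags) >= min_aa]
}
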