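#' Merge non-overlapping contigs that hit the same subject protein
#'
#' Two viral contigs are assumed to come from the same genome when their
#' best hits target the same database subject, their subject intervals do
#' not overlap, and their order along the subject is consistent. Such
#' chains are joined with a spacer of 100 `N`s (recorded in provenance so
#' downstream steps can ignore the spacer). Contigs are oriented by the
#' sign of their hit frame before joining.
#'
#' @param contigs contig table (`contig_id`, `seq`).
#' @param hits best-viral-hit table for those contigs (one row per
#'   contig: `query_id`, `subject_id`, `sstart`, `send`, `frame`).
#' @return `data.frame` with `record_id`, `seq`, `members`
#'   (comma-separated contig ids), `subject_id` (`NA` for unmerged
#'   pass-through contigs).
#' @export
merge_nonoverlapping_contigs <- function(contigs, hits) {
  spacer <- strrep("N", 100)
  merged <- list()
  used <- character(0)
  h <- hits[hits$query_id %in% contigs$contig_id, , drop = FALSE]
  for (subj in unique(h$subject_id)) {
    hs <- h[h$subject_id == subj, , drop = FALSE]
    if (nrow(hs) < 2) next
    hs <- hs[order(hs$sstart, hs$send), , drop = FALSE]
    chain <- list(hs[1, ])
    chains <- list()
    for (i in seq_len(nrow(hs))[-1]) {
      prev <- chain[[length(chain)]]
      if (hs$sstart[i] >= prev$send) {
        chain[[length(chain) + 1]] <- hs[i, ]
      } else {
        chains[[length(chains) + 1]] <- chain
        chain <- list(hs[i, ])
      }
    }
    chains[[length(chains) + 1]] <- chain
    for (ch in chains) {
      if (length(ch) < 2) next
      ids <- vapply(ch, function(r) r$query_id, "")
      seqs <- vapply(ids, function(id) {
        s <- contigs$seq[contigs$contig_id == id]
        fr <- h$frame[h$query_id == id]
        if (length(fr) && fr[1] < 0) revcomp(s) else s
      }, "")
      merged[[length(merged) + 1]] <- data.frame(
        record_id = sprintf("merged%03d", length(merged) + 1L),
        seq = paste(seqs, collapse = spacer),
        members = paste(ids, collapse = ","),
        subject_id = subj, stringsAsFactors = FALSE)
      used <- c(used, ids)
    }
  }
  rest <- contigs[!contigs$contig_id %in% used, , drop = FALSE]
  out <- data.frame(record_id = rest$contig_id, seq = rest$seq,
                    members = rest$contig_id,
                    subject_id = rep(NA_character_, nrow(rest)),
                    stringsAsFactors = FALSE)
  if (length(merged)) out <- rbind(do.call(rbind, merged), out)
  rownames(out) <- NULL
  out
}

#' Extend a contig by mapping reads over its ends
#'
#' Iteratively recruits reads that overlap a contig end by at least 20 nt
#' at 95% identity or better and extends the consensus with the majority
#' base over the overhanging reads; stops at a fixpoint or after
#' `rounds`. The output is never shorter than the input.
#'
#' @param contig one contig sequence (character scalar).
#' @param reads read table of the contig's library.
#' @param rounds maximum extension rounds.
#' @param min_overlap,min_identity recruitment thresholds.
#' @return the (possibly longer) contig sequence.
#' @export
extend_by_mapping <- function(contig, reads, rounds = 3,
                              min_overlap = 20, min_identity = 0.95) {
  stop_if_not(rounds >= 1, "rounds must be >= 1")
  for (r in seq_len(rounds)) {
    if (nrow(reads) == 0) break
    m <- cpp_map_reads(reads$seq, contig, min_overlap, min_identity, TRUE)
    if (nrow(m) == 0) break
    clen <- nchar(contig)
    rlen <- nchar(reads$seq)[m$read]
    oriented <- ifelse(m$strand == 0, reads$seq[m$read],
                       revcomp(reads$seq[m$read]))
    left <- m$offset < 0
    right <- m$offset + rlen > clen
    ext_left <- consensus_overhang(oriented[left], -m$offset[left],
                                   side = "left")
    ext_right <- consensus_overhang(oriented[right],
                                    m$offset[right] + rlen[right] - clen,
                                    side = "right",
                                    starts = clen - m$offset[right] + 1L)
    if (!nzchar(ext_left) && !nzchar(ext_right)) break
    contig <- paste0(ext_left, contig, ext_right)
  }
  contig
}

# majority consensus over read overhangs on one side of a contig
consensus_overhang <- function(seqs, overhang, side, starts = NULL) {
  if (length(seqs) == 0) return("")
  W <- max(overhang)
  votes <- matrix(0L, 4, W, dimnames = list(c("A", "C", "G", "T"), NULL))
  for (i in seq_along(seqs)) {
    piece <- if (side == "left") substr(seqs[i], 1, overhang[i])
             else substr(seqs[i], starts[i], nchar(seqs[i]))
    ch <- strsplit(piece, "")[[1]]
    # align pieces at the contig edge
    pos <- if (side == "left") (W - overhang[i]) + seq_along(ch)
           else seq_along(ch)
    ok <- ch %in% rownames(votes)
    for (j in which(ok)) votes[ch[j], pos[j]] <- votes[ch[j], pos[j]] + 1L
  }
  covered <- colSums(votes) > 0
  cons <- rownames(votes)[apply(votes, 2, which.max)]
  paste(cons[covered], collapse = "")
}

#' Predict open reading frames on both strands
#'
#' Standard genetic code, ATG start codons only. An ORF spans ATG..stop
#' with the stop codon included in the coordinates but excluded from the
#' peptide; nested ORFs sharing a stop report the longest (first ATG).
#' ORFs shorter than `min_size` nt are dropped. ORFs running off the
#' contig edge without a stop are reported with `complete = FALSE`.
#' Coordinates are 0-based half-open on the forward strand.
#'
#' @param seq contig sequence.
#' @param contig_id id copied onto the records.
#' @param min_size minimum ORF length in nucleotides (stop included).
#' @return `data.frame` of ORF records: `orf_id`, `contig_id`, `strand`,
#'   `frame`, `start`, `end`, `peptide`, `complete`.
#' @export
predict_orfs <- function(seq, contig_id = "contig", min_size = 300) {
  L <- nchar(seq)
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else revcomp(seq)
    for (off in 0:2) {
      pep <- cpp_translate(s, off + 1L)
      aa <- strsplit(pep, "")[[1]]
      n_aa <- length(aa)
      if (n_aa == 0) next
      stops <- which(aa == "*")
      seg_start <- c(1L, stops + 1L)
      seg_end <- c(stops, n_aa) # segment of codons, stop included at end
      for (k in seq_along(seg_start)) {
        a <- seg_start[k]; b <- seg_end[k]
        if (a > b) next
        has_stop <- k <= length(stops)
        region <- aa[a:b]
        m_at <- which(region == "M")
        if (length(m_at) == 0) next
        first_m <- a + m_at[1] - 1L
        # nt span on strand s (0-based half-open), stop codon included
        nt_start <- off + 3L * (first_m - 1L)
        nt_end <- off + 3L * b
        if (nt_end - nt_start < min_size) next
        pep_out <- paste(aa[first_m:(if (has_stop) b - 1L else b)],
                         collapse = "")
        if (grepl("*", pep_out, fixed = TRUE)) next
        if (strand == "+") {
          fwd_start <- nt_start; fwd_end <- nt_end
        } else {
          fwd_start <- L - nt_end; fwd_end <- L - nt_start
        }
        out[[length(out) + 1]] <- data.frame(
          contig_id = contig_id, strand = strand,
          frame = (off + 1L) * ifelse(strand == "+", 1L, -1L),
          start = fwd_start, end = fwd_end, peptide = pep_out,
          complete = has_stop, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(orf_id = character(0), contig_id = character(0),
                      strand = character(0), frame = integer(0),
                      start = integer(0), end = integer(0),
                      peptide = character(0), complete = logical(0),
                      stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, out)
  df <- df[order(df$start, df$end, df$strand), , drop = FALSE]
  df <- cbind(orf_id = sprintf("%s:orf%03d", contig_id, seq_len(nrow(df))),
              df, stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df
}

#' Annotate ORFs and extract hallmark-gene sets
#'
#' Each ORF peptide is searched against the viral protein database; the
#' best hit under the E-value cutoff becomes its annotation, otherwise
#' the ORF is a "putative protein". ORFs whose best hit is a hallmark
#' gene (MCP, NS1, Rep, TerL, RdRp) are grouped by gene into hallmark
#' sets with their target virus group; only complete ORFs are flagged
#' for phylogenetic use.
#'
#' @param orfs ORF table from [predict_orfs()].
#' @param viral_db viral protein database table.
#' @param scheme a [scoring_scheme()].
#' @param e_cutoff annotation E-value cutoff.
#' @return list with `annotations` (the ORF table plus `annotation`,
#'   `gene`, `subject_id`, `evalue`, `pident`) and `hallmark_sets`
#'   (named list per gene: `gene`, `group`, `members` data.frame).
#' @export
annotate_and_extract_hallmarks <- function(orfs, viral_db,
                                           scheme = scoring_scheme(),
                                           e_cutoff = 1e-5) {
  ann <- orfs
  ann$annotation <- "putative protein"
  ann$gene <- NA_character_
  ann$subject_id <- NA_character_
  ann$evalue <- NA_real_
  ann$pident <- NA_real_
  if (nrow(orfs) > 0) {
    hits <- peptide_search(orfs$peptide, viral_db, scheme, e_cutoff,
                           query_ids = orfs$orf_id)
    if (nrow(hits) > 0) {
      hits <- hits[order(hits$query_id, hits$evalue, -hits$score), ,
                   drop = FALSE]
      best <- hits[!duplicated(hits$query_id), , drop = FALSE]
      i <- match(ann$orf_id, best$query_id)
      hit_rows <- !is.na(i)
      ann$annotation[hit_rows] <- best$subject_id[i[hit_rows]]
      ann$gene[hit_rows] <- best$gene[i[hit_rows]]
      ann$subject_id[hit_rows] <- best$subject_id[i[hit_rows]]
      ann$evalue[hit_rows] <- best$evalue[i[hit_rows]]
      ann$pident[hit_rows] <- best$pident[i[hit_rows]]
    }
  }
  groups <- hallmark_groups()
  sets <- list()
  for (g in HALLMARK_GENES) {
    members <- ann[!is.na(ann$gene) & ann$gene == g, , drop = FALSE]
    if (nrow(members) == 0) next
    sets[[g]] <- list(gene = g, group = unname(groups[g]),
                      members = members[, c("orf_id", "contig_id",
                                            "peptide", "complete")])
  }
  list(annotations = ann, hallmark_sets = sets)
}

# column frequency profile (20 x L, gaps excluded) of alignment rows
profile_freq <- function(rows) {
  L <- ncol(rows)
  f <- matrix(0, 20, L, dimnames = list(AA20, NULL))
  for (j in seq_len(L)) {
    col <- rows[, j]
    col <- col[col != "-"]
    if (length(col)) {
      tb <- table(factor(col, levels = AA20))
      f[, j] <- as.numeric(tb) / length(col)
    }
  }
  f
}

#' Progressive multiple alignment of peptides
#'
#' Pairwise k-mer distances feed a UPGMA guide tree; profiles are merged
#' bottom-up with global affine profile-profile alignment (BLOSUM62,
#' gap open 8, extend 1).
#'
#' @param seqs named character vector of >= 2 peptides.
#' @return named character vector of equal-length gapped rows.
#' @export
align_peptides <- function(seqs) {
  stop_if_not(length(seqs) >= 2, "need at least two sequences")
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  sub20 <- blosum62()[AA20, AA20]
  storage.mode(sub20) <- "double"

  kmer_counts <- lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < 3) return(table(character(0)))
    table(substring(s, 1:(n - 2), 3:n))
  })
  n <- length(seqs)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- c(kmer_counts[[i]]); b <- c(kmer_counts[[j]])
      shared <- intersect(names(a), names(b))
      common <- if (length(shared)) sum(pmin(a[shared], b[shared])) else 0
      tot <- sum(a) + sum(b)
      d[i, j] <- d[j, i] <- if (tot > 0) 1 - 2 * common / tot else 0
    }
  }
  hc <- hclust(as.dist(d), method = "average")

  aln <- lapply(seq_along(seqs),
                function(i) matrix(strsplit(seqs[[i]], "")[[1]], nrow = 1,
                                   dimnames = list(names(seqs)[i], NULL)))
  node <- vector("list", nrow(hc$merge))
  get_aln <- function(id) if (id < 0) aln[[-id]] else node[[id]]
  for (s in seq_len(nrow(hc$merge))) {
    A <- get_aln(hc$merge[s, 1])
    B <- get_aln(hc$merge[s, 2])
    path <- cpp_profile_nw(profile_freq(A), profile_freq(B), sub20, 8, 1)
    La <- ncol(A); Lb <- ncol(B)
    M <- matrix("-", nrow(A) + nrow(B), length(path),
                dimnames = list(c(rownames(A), rownames(B)), NULL))
    ia <- 0L; ib <- 0L
    for (p in seq_along(path)) {
      if (path[p] != 3L) {
        ia <- ia + 1L
        M[seq_len(nrow(A)), p] <- A[, ia]
      }
      if (path[p] != 2L) {
        ib <- ib + 1L
        M[nrow(A) + seq_len(nrow(B)), p] <- B[, ib]
      }
    }
    node[[s]] <- M
  }
  final <- node[[nrow(hc$merge)]]
  final <- final[names(seqs), , drop = FALSE]
  setNames(apply(final, 1, paste, collapse = ""), rownames(final))
}

#' Align peptides and mask gap-rich columns
#'
#' After progressive alignment, columns containing strictly more than
#' 50% gaps are removed.
#'
#' @param seqs named character vector of >= 2 peptides.
#' @param max_gap_frac columns with gap fraction strictly above this are
#'   dropped.
#' @return named character vector of masked alignment rows.
#' @export
align_and_mask <- function(seqs, max_gap_frac = 0.5) {
  aln <- if (length(unique(nchar(seqs))) == 1 &&
               any(grepl("-", seqs, fixed = TRUE))) seqs
         else align_peptides(seqs)
  mask_alignment(aln, max_gap_frac)
}

mask_alignment <- function(aln, max_gap_frac = 0.5) {
  rows <- do.call(rbind, strsplit(aln, ""))
  gap_frac <- colMeans(rows == "-")
  keep <- gap_frac <= max_gap_frac
  setNames(apply(rows[, keep, drop = FALSE], 1, paste, collapse = ""),
           names(aln))
}

#' Neighbor-joining tree from a masked alignment
#'
#' Pairwise p-distances (mismatch fraction over columns where both rows
#' are ungapped) feed Saitou-Nei neighbor joining; negative branch
#' lengths are clamped to zero.
#'
#' @param msa named character vector of aligned rows (>= 3).
#' @return unrooted `phylo` tree.
#' @export
nj_tree <- function(msa) {
  stop_if_not(length(msa) >= 3, "need at least three sequences")
  rows <- do.call(rbind, strsplit(msa, ""))
  n <- nrow(rows)
  d <- matrix(0, n, n, dimnames = list(names(msa), names(msa)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- rows[i, ] != "-" & rows[j, ] != "-"
      d[i, j] <- d[j, i] <- if (any(ok))
        mean(rows[i, ok] != rows[j, ok]) else 0
    }
  }
  tr <- ape::nj(as.dist(d))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}
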