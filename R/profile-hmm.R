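#' Profile hidden Markov models for remote viral homology
#'
#' A minimal profile HMM in the classic match/insert/delete architecture:
#' match states carry per-position emission distributions over the 20
#' amino acids, insert states emit the background distribution, and
#' per-position transition probabilities connect match, insert and delete
#' layers. Scoring is global in the model and local in the sequence
#' (free flanking residues), in log-odds against the background, so
#' scores are directly comparable across profiles.
#'
#' @name profile_hmm
NULL

#' Build a profile HMM from aligned (or identical-length) peptides
#'
#' Columns with more than 50% gaps become insert columns; the rest are
#' match positions. Emissions and transitions are maximum-likelihood
#' counts with Laplace pseudocounts; the background is the overall
#' residue frequency of the input (with pseudocounts).
#'
#' @param seqs character vector of peptides; if unaligned (unequal
#'   lengths), they are first aligned with [align_peptides()].
#' @param name profile name.
#' @param pseudocount added to every emission count.
#' @param trans_pseudocount added to every transition count (kept small so
#'   sparse alignments still favour the match path).
#' @return object of class `rv_hmm` with elements `name`, `length`,
#'   `match_emis` (20 x L), `ins_emis`, `bg`, and transition matrix
#'   `trans` (L x 7: mm, mi, md, im, ii, dm, dd; row j holds transitions
#'   out of position j-1 into position j, row 1 being begin -> 1).
#' @export
build_profile_hmm <- function(seqs, name = "profile", pseudocount = 0.5,
                              trans_pseudocount = 0.05) {
  stop_if_not(length(seqs) >= 1, "need at least one sequence")
  if (length(unique(nchar(seqs))) > 1) {
    stop_if_not(length(seqs) >= 2, "unaligned input needs >= 2 sequences")
    seqs <- align_peptides(seqs)
  }
  rows <- do.call(rbind, strsplit(seqs, ""))
  ncol_aln <- ncol(rows)
  gap_frac <- colMeans(rows == "-")
  is_match <- gap_frac <= 0.5
  L <- sum(is_match)
  stop_if_not(L >= 1, "alignment has no match columns")

  counts_bg <- rep(pseudocount, 20)
  names(counts_bg) <- AA20
  obs <- rows[rows %in% AA20]
  tb <- table(factor(obs, levels = AA20))
  counts_bg <- counts_bg + as.numeric(tb)
  bg <- counts_bg / sum(counts_bg)

  match_emis <- matrix(pseudocount, 20, L, dimnames = list(AA20, NULL))
  mcols <- which(is_match)
  for (j in seq_len(L)) {
    col <- rows[, mcols[j]]
    tb <- table(factor(col[col %in% AA20], levels = AA20))
    match_emis[, j] <- match_emis[, j] + as.numeric(tb)
  }
  match_emis <- sweep(match_emis, 2, colSums(match_emis), "/")

  # transition counts from each sequence's state path through the columns
  tc <- matrix(trans_pseudocount, L, 7,
               dimnames = list(NULL, c("mm", "mi", "md", "im", "ii", "dm", "dd")))
  # row j of the transition table: "im" is I_{j-1} -> M_j, "mm"/"md"/"dm"/
  # "dd" run from position j-1 into j (j-1 = 0 is begin, treated as match),
  # and "mi"/"ii" at row j leave M_j into the insert after it.
  col_state <- ifelse(is_match, "M", "I")
  for (s in seq_len(nrow(rows))) {
    prev <- "M"      # begin behaves like a match state
    prev_pos <- 0L
    pending_ins <- 0L
    for (c in seq_len(ncol_aln)) {
      ch <- rows[s, c]
      if (col_state[c] == "I") {
        if (ch != "-") pending_ins <- pending_ins + 1L
        next
      }
      pos <- prev_pos + 1L
      st <- if (ch == "-") "D" else "M"
      if (pending_ins > 0 && prev_pos >= 1) {
        tc[prev_pos, "mi"] <- tc[prev_pos, "mi"] + 1
        if (pending_ins > 1)
          tc[prev_pos, "ii"] <- tc[prev_pos, "ii"] + pending_ins - 1
        tc[pos, "im"] <- tc[pos, "im"] + 1
      } else {
        # inserts before the first match position are flank, not I states
        key <- paste0(tolower(prev), tolower(st))
        tc[pos, key] <- tc[pos, key] + 1
      }
      prev <- st
      prev_pos <- pos
      pending_ins <- 0L
    }
  }
  trans <- tc
  trans[, c("mm", "mi", "md")] <- tc[, c("mm", "mi", "md")] /
    rowSums(tc[, c("mm", "mi", "md")])
  trans[, c("im", "ii")] <- tc[, c("im", "ii")] / rowSums(tc[, c("im", "ii")])
  trans[, c("dm", "dd")] <- tc[, c("dm", "dd")] / rowSums(tc[, c("dm", "dd")])

  structure(list(name = name, length = L, match_emis = match_emis,
                 ins_emis = bg, bg = bg, trans = trans),
            class = "rv_hmm")
}

#' Score a peptide against a profile HMM
#'
#' Viterbi (max-product) and forward (sum-product) dynamic programming in
#' log2 space, global in the model and local in the sequence: any number
#' of flanking residues before entering match position 1 and after
#' leaving position L are emitted by the background at log-odds zero.
#'
#' @param peptide amino-acid string without `*`.
#' @param hmm an `rv_hmm`.
#' @return list with `viterbi` and `forward` log-odds scores (bits).
#' @export
hmm_score <- function(peptide, hmm) {
  stop_if_not(is.character(peptide) && length(peptide) == 1 &&
                nchar(peptide) >= 1, "peptide must be a non-empty string")
  stop_if_not(!grepl("*", peptide, fixed = TRUE),
              "peptide must not contain stop characters")
  x <- strsplit(peptide, "")[[1]]
  em <- log2(hmm$match_emis / hmm$bg)       # 20 x L match log-odds
  aa_row <- match(x, AA20)                  # NA for unknown residues -> 0
  lt <- log2(hmm$trans[, c("mm", "mi", "md", "im", "ii", "dm", "dd"),
                       drop = FALSE])
  res <- cpp_hmm_score(aa_row, em, lt)
  list(viterbi = res$viterbi, forward = res$forward)
}

#' Write a profile HMM in the package's plain-text format
#'
#' @param hmm an `rv_hmm`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_profile_hmm <- function(hmm, path) {
  con <- file(path, "w")
  on.exit(close(con))
  num <- function(x) paste(formatC(x, digits = 8, format = "g"), collapse = " ")
  writeLines(c(
    paste("HMM", hmm$name),
    paste("LENG", hmm$length),
    paste("ALPH", paste(AA20, collapse = "")),
    paste("BG", num(hmm$bg)),
    paste("INS", num(hmm$ins_emis))), con)
  for (j in seq_len(hmm$length))
    writeLines(paste("MATCH", j, num(hmm$match_emis[, j])), con)
  for (j in seq_len(hmm$length))
    writeLines(paste("TRANS", j, num(hmm$trans[j, ])), con)
  writeLines("END", con)
  invisible(path)
}

#' Read a profile HMM written by [write_profile_hmm()]
#'
#' @param path file path.
#' @return an `rv_hmm`.
#' @export
read_profile_hmm <- function(path) {
  ln <- readLines(path)
  tok <- strsplit(ln, " +")
  tag <- vapply(tok, `[[`, "", 1)
  L <- as.integer(tok[[which(tag == "LENG")]][2])
  nums <- function(v) as.numeric(v[-(1:2)])
  bg <- as.numeric(tok[[which(tag == "BG")]][-1])
  ins <- as.numeric(tok[[which(tag == "INS")]][-1])
  me <- matrix(0, 20, L, dimnames = list(AA20, NULL))
  for (i in which(tag == "MATCH")) me[, as.integer(tok[[i]][2])] <- nums(tok[[i]])
  tr <- matrix(0, L, 7,
               dimnames = list(NULL, c("mm", "mi", "md", "im", "ii", "dm", "dd")))
  for (i in which(tag == "TRANS")) tr[as.integer(tok[[i]][2]), ] <- nums(tok[[i]])
  names(bg) <- AA20
  names(ins) <- AA20
  structure(list(name = tok[[which(tag == "HMM")]][2], length = L,
                 match_emis = me, ins_emis = ins, bg = bg, trans = tr),
            class = "rv_hmm")
}

#' Build hallmark-gene profile HMMs from a reference set
#'
#' One profile per hallmark gene (TerL, MCP, NS1, Rep, RdRp) with at least
#' two member peptides in the viral database.
#'
#' @param refs reference set from [generate_reference_sets()].
#' @return named list of `rv_hmm` objects.
#' @export
build_hallmark_hmms <- function(refs) {
  out <- list()
  for (g in HALLMARK_GENES) {
    peps <- refs$viral_db$seq[refs$viral_db$gene == g]
    if (length(peps) < 2) next
    out[[g]] <- build_profile_hmm(peps, name = g)
  }
  out
}
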