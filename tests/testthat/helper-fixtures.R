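# Shared fixtures (built once per test run) and independent oracles.
# Oracles deliberately re-derive results from first principles (brute-force
# pairwise comparison, full DP, textbook formulas) and never call the code
# paths they check.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

refs17 <- function() fixture("refs17", function() {
  generate_reference_sets(17, 50, seed = 11)
})

refs34 <- function() fixture("refs34", function() {
  generate_reference_sets(34, 60, seed = 1)
})

# the default six-site + control study conditions (~60k reads)
full_run <- function() fixture("full_run", function() {
  refs <- refs34()
  designs <- default_designs(refs, n_reads = 10000, seed = 1)
  reads <- lapply(designs, simulate_library, refs = refs)
  names(reads) <- vapply(designs, `[[`, "", "library_label")
  hmms <- build_hallmark_hmms(refs)
  res <- run_virome_analysis(reads, refs$viral_db, refs$nvnr_db, hmms,
                             control = "Control", seed = 1)
  list(refs = refs, designs = designs, reads = reads, hmms = hmms,
       res = res)
})

random_reads <- function(n, len = 80, lib = "L1", seed = 1,
                         alphabet_runs = FALSE) {
  set.seed(seed)
  seqs <- vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    "")
  data.frame(read_id = sprintf("%s:r%04d", lib, seq_len(n)), library = lib,
             seq = seqs, qual = strrep("I", len), meta = "",
             stringsAsFactors = FALSE)
}

# ---- oracle: window deduplication by all-pairs comparison -----------------
oracle_dedup_groups <- function(seqs, window = c(5, 55)) {
  n <- length(seqs)
  key_equal <- function(i, j) {
    a <- seqs[i]; b <- seqs[j]
    sub <- function(s) if (nchar(s) < window[1]) s
                       else substr(s, window[1], window[2])
    sub(a) == sub(b)
  }
  group <- seq_len(n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (key_equal(i, j)) {
        g <- group[j]
        group[group == g] <- group[i]
      }
    }
  }
  split(seq_len(n), group)
}

# ---- oracle: full (unbanded, seedless) affine Smith-Waterman --------------
oracle_sw <- function(q, s, mat, gap_open = 11, gap_extend = 1) {
  qa <- strsplit(q, "")[[1]]
  sa <- strsplit(s, "")[[1]]
  m <- length(qa); n <- length(sa)
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(-Inf, m + 1, n + 1)
  F <- matrix(-Inf, m + 1, n + 1)
  best <- 0
  for (i in 2:(m + 1)) {
    for (j in 2:(n + 1)) {
      E[i, j] <- max(H[i - 1, j] - gap_open - gap_extend,
                     E[i - 1, j] - gap_extend)
      F[i, j] <- max(H[i, j - 1] - gap_open - gap_extend,
                     F[i, j - 1] - gap_extend)
      H[i, j] <- max(0, H[i - 1, j - 1] + mat[qa[i - 1], sa[j - 1]],
                     E[i, j], F[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

# ---- oracle: best-overlap-first greedy agglomeration ----------------------
# Exact suffix-prefix overlaps only (fixtures are error-free); ids follow
# the documented naming of merged items so tie-breaking is comparable.
oracle_assemble <- function(ids, seqs, min_overlap = 30) {
  items <- data.frame(id = ids, seq = seqs, stringsAsFactors = FALSE)
  exact_overlap <- function(a, b) {
    # longest suffix of a equal to a prefix of b (or containment)
    la <- nchar(a); lb <- nchar(b)
    for (o in min(la, lb):min_overlap) {
      if (lb <= la && o == lb) {
        # containment check anywhere in a
        if (grepl(b, a, fixed = TRUE)) return(o)
      }
      if (substr(a, la - o + 1, la) == substr(b, 1, o)) return(o)
    }
    0L
  }
  counter <- 0L
  repeat {
    n <- nrow(items)
    best <- NULL
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i == j) next
        o <- exact_overlap(items$seq[i], items$seq[j])
        if (o >= min_overlap) {
          pair <- sort(c(items$id[i], items$id[j]))
          cand <- list(o = o, lo = pair[1], hi = pair[2], i = i, j = j)
          if (is.null(best) || cand$o > best$o ||
                (cand$o == best$o && (cand$lo < best$lo ||
                  (cand$lo == best$lo && cand$hi < best$hi))))
            best <- cand
        }
      }
    }
    if (is.null(best)) break
    a <- items$seq[best$i]; b <- items$seq[best$j]
    merged <- if (grepl(b, a, fixed = TRUE)) a
              else paste0(a, substr(b, best$o + 1, nchar(b)))
    counter <- counter + 1L
    items <- items[-c(best$i, best$j), , drop = FALSE]
    items <- rbind(items, data.frame(id = paste0("c", 100000 + counter),
                                     seq = merged, stringsAsFactors = FALSE))
  }
  sort(items$seq)
}

# ---- oracle: UPGMA join-height matrix -------------------------------------
oracle_upgma_cophenetic <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  labels <- rownames(d)
  clusters <- as.list(labels)
  sizes <- rep(1, n)
  coph <- matrix(0, n, n, dimnames = list(labels, labels))
  act <- seq_len(n)
  D <- d
  while (length(act) > 1) {
    k <- length(act)
    bi <- bj <- NA
    bd <- Inf
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      if (D[act[i], act[j]] < bd) {
        bd <- D[act[i], act[j]]; bi <- act[i]; bj <- act[j]
      }
    }
    for (a in clusters[[bi]]) for (b in clusters[[bj]]) {
      coph[a, b] <- coph[b, a] <- bd
    }
    # size-weighted average distances to the new cluster, stored in slot bi
    for (x in setdiff(act, c(bi, bj))) {
      D[bi, x] <- D[x, bi] <- (sizes[bi] * D[bi, x] + sizes[bj] * D[bj, x]) /
        (sizes[bi] + sizes[bj])
    }
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    sizes[bi] <- sizes[bi] + sizes[bj]
    act <- setdiff(act, bj)
  }
  coph
}

# ---- oracle: textbook tie-corrected Friedman statistic --------------------
oracle_friedman <- function(y) {
  # y: blocks in rows, treatments in columns
  b <- nrow(y); k <- ncol(y)
  r <- t(apply(y, 1, rank))
  Rj <- colSums(r)
  stat <- 12 / (b * k * (k + 1)) * sum(Rj^2) - 3 * b * (k + 1)
  ties <- sum(apply(y, 1, function(row) {
    t <- table(row); sum(t^3 - t)
  }))
  C <- 1 - ties / (b * (k^3 - k))
  stat <- stat / C
  list(statistic = stat, df = k - 1,
       p_value = pchisq(stat, k - 1, lower.tail = FALSE))
}

# ---- oracle: exhaustive path enumeration for a 2-position profile HMM -----
# Returns all path log2-odds scores for a query of length 2 or 3 under the
# same architecture: global in model (enter M1 or D1, exit M2), free flanks,
# insert emissions at background (log-odds 0).
oracle_toy_hmm_paths <- function(hmm, query) {
  stopifnot(hmm$length == 2, nchar(query) %in% c(2, 3))
  x <- strsplit(query, "")[[1]]
  e <- function(j, a) log2(hmm$match_emis[a, j] / hmm$bg[a])
  lt <- log2(hmm$trans)
  n <- length(x)
  scores <- c()
  # M1 M2 at consecutive positions (i, i+1)
  for (i in seq_len(n - 1)) {
    scores <- c(scores,
                lt[1, "mm"] + e(1, x[i]) + lt[2, "mm"] + e(2, x[i + 1]))
  }
  # D1 then M2 at any single position
  for (i in seq_len(n)) {
    scores <- c(scores, lt[1, "md"] + lt[2, "dm"] + e(2, x[i]))
  }
  # M1 I1 M2 spanning three consecutive positions
  if (n == 3) {
    scores <- c(scores,
                lt[1, "mm"] + e(1, x[1]) + lt[1, "mi"] + lt[2, "im"] +
                  e(2, x[3]))
  }
  scores
}

logsum2 <- function(v) {
  m <- max(v)
  m + log2(sum(2^(v - m)))
}
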