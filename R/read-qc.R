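#' QC configuration
#'
#' Cleaning rules applied to each raw library: window-based deduplication
#' (reads are duplicates when bases 5-55 are identical; one random copy is
#' kept), Phred-10 low-quality tail trimming, and adapter removal by
#' ungapped suffix-vs-adapter-prefix matching (a VecScreen-style stand-in).
#'
#' @param dedup_window 1-based inclusive base range used as the duplicate
#'   key (default bases 5 to 55). Reads shorter than the window end use
#'   their sequence from the window start; reads shorter than the window
#'   start use their full sequence.
#' @param phred_threshold trim the maximal 3' suffix in which every base
#'   has quality strictly below this Phred score.
#' @param adapters character vector of adapter sequences.
#' @param adapter_min_match minimum aligned bases for an adapter call.
#' @param adapter_max_mismatch_frac maximum mismatch fraction in the
#'   adapter match.
#' @param min_length reads shorter than this after trimming are dropped.
#' @return object of class `rv_qc_config`.
#' @export
qc_config <- function(dedup_window = c(5, 55), phred_threshold = 10,
                      adapters = "AGATCGGAAGAGCACACGTCTGAACTCCAGTCAC",
                      adapter_min_match = 10,
                      adapter_max_mismatch_frac = 0.1,
                      min_length = 50) {
  stop_if_not(dedup_window[1] >= 1 && dedup_window[1] <= dedup_window[2],
              "dedup_window must satisfy 1 <= start <= end")
  stop_if_not(phred_threshold >= 0, "phred_threshold must be >= 0")
  structure(list(dedup_window = as.integer(dedup_window),
                 phred_threshold = as.integer(phred_threshold),
                 adapters = adapters,
                 adapter_min_match = as.integer(adapter_min_match),
                 adapter_max_mismatch_frac = adapter_max_mismatch_frac,
                 min_length = as.integer(min_length)),
            class = "rv_qc_config")
}

dedup_key <- function(seq, window) {
  # reads shorter than the window start keep their full sequence as key
  ifelse(nchar(seq) < window[1], seq, substr(seq, window[1], window[2]))
}

#' Remove PCR duplicates by sequence-window identity
#'
#' Reads are considered duplicates when the bases inside the configured
#' window (default 5-55) are identical; exactly one member of each
#' duplicate group, chosen uniformly at random under the seed, is kept.
#' Output order is input order restricted to the kept reads.
#'
#' @param reads read table (one library).
#' @param cfg a [qc_config()].
#' @param seed integer seed for the random choice of representative.
#' @return list with `kept` (read table) and `n_removed`.
#' @export
deduplicate <- function(reads, cfg = qc_config(), seed = 1) {
  if (nrow(reads) == 0) return(list(kept = reads, n_removed = 0L))
  key <- dedup_key(reads$seq, cfg$dedup_window)
  groups <- split(seq_len(nrow(reads)), key)
  keep <- with_seed(op_seed(seed, "dedup"), {
    vapply(groups, function(ix) ix[sample.int(length(ix), 1)], 0L)
  })
  keep <- sort(unname(keep))
  list(kept = reads[keep, , drop = FALSE],
       n_removed = nrow(reads) - length(keep))
}

#' Trim the low-quality 3' tail of reads
#'
#' Removes the maximal 3' suffix in which every base has Phred quality
#' strictly below the threshold; remaining bases and their qualities are
#' untouched. A fully sub-threshold read becomes empty (dropped later in
#' [qc_library()]).
#'
#' @param reads read table.
#' @param cfg a [qc_config()].
#' @return read table with trimmed `seq`/`qual` and original row order.
#' @export
trim_quality_tail <- function(reads, cfg = qc_config()) {
  if (nrow(reads) == 0) return(reads)
  keep_len <- cpp_qual_keep_len(reads$qual, cfg$phred_threshold)
  reads$seq <- substr(reads$seq, 1L, keep_len)
  reads$qual <- substr(reads$qual, 1L, keep_len)
  reads
}

#' Trim residual 3' adapters
#'
#' If a 3' suffix of the read matches a prefix of any configured adapter
#' with at least `adapter_min_match` aligned bases and at most
#' `adapter_max_mismatch_frac` mismatches, the matching suffix is removed;
#' the longest qualifying match wins.
#'
#' @inheritParams trim_quality_tail
#' @return read table with adapters removed.
#' @export
trim_adapters <- function(reads, cfg = qc_config()) {
  if (nrow(reads) == 0 || length(cfg$adapters) == 0) return(reads)
  keep_len <- cpp_adapter_keep_len(reads$seq, cfg$adapters,
                                   cfg$adapter_min_match,
                                   cfg$adapter_max_mismatch_frac)
  reads$seq <- substr(reads$seq, 1L, keep_len)
  reads$qual <- substr(reads$qual, 1L, keep_len)
  reads
}

#' Clean one library: deduplicate, quality-trim, adapter-trim
#'
#' Stages run in that order; reads shorter than `min_length` after
#' trimming are dropped. The report records counts removed at each stage
#' plus mean length and GC content of the raw input.
#'
#' @inheritParams deduplicate
#' @return list with `reads` (clean read table) and `report` (one-row
#'   `data.frame`: library, n_raw, n_dup_removed, n_qtrimmed,
#'   n_adapter_trimmed, n_short_dropped, n_kept, mean_length, gc_percent).
#' @export
qc_library <- function(reads, cfg = qc_config(), seed = 1) {
  lib <- if (nrow(reads)) reads$library[1] else NA_character_
  n_raw <- nrow(reads)
  raw_mean_len <- if (n_raw) mean(nchar(reads$seq)) else 0
  raw_gc <- if (n_raw) gc_percent(reads$seq) else NA_real_

  dd <- deduplicate(reads, cfg, seed)
  x <- dd$kept
  len0 <- nchar(x$seq)
  x <- trim_quality_tail(x, cfg)
  n_qtrim <- sum(nchar(x$seq) < len0)
  len1 <- nchar(x$seq)
  x <- trim_adapters(x, cfg)
  n_atrim <- sum(nchar(x$seq) < len1)
  short <- nchar(x$seq) < cfg$min_length
  x <- x[!short, , drop = FALSE]

  report <- data.frame(
    library = lib, n_raw = n_raw, n_dup_removed = dd$n_removed,
    n_qtrimmed = n_qtrim, n_adapter_trimmed = n_atrim,
    n_short_dropped = sum(short), n_kept = nrow(x),
    mean_length = raw_mean_len, gc_percent = raw_gc,
    stringsAsFactors = FALSE)
  list(reads = x, report = report)
}
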