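mk_reads <- function(seqs, quals = NULL, lib = "L1") {
  if (is.null(quals)) quals <- strrep("I", nchar(seqs)) # Phred 40
  data.frame(read_id = sprintf("%s:r%03d", lib, seq_along(seqs)),
             library = rep(lib, length(seqs)), seq = seqs, qual = quals,
             meta = rep("", length(seqs)), stringsAsFactors = FALSE)
}

test_that("deduplication keys on bases 5-55 only", {
  base <- paste(rep(c("A", "C", "G", "T"), length.out = 250), collapse = "")
  mutate_at <- function(s, i) {
    substr(s, i, i) <- ifelse(substr(s, i, i) == "A", "C", "A")
    s
  }
  # byte-identical reads collapse
  r <- deduplicate(mk_reads(c(base, base)), seed = 1)
  expect_equal(nrow(r$kept), 1)
  expect_equal(r$n_removed, 1)
  # difference at base 3 (outside the window) still collapses
  r <- deduplicate(mk_reads(c(base, mutate_at(base, 3))), seed = 1)
  expect_equal(nrow(r$kept), 1)
  # difference at base 30 (inside) keeps both
  r <- deduplicate(mk_reads(c(base, mutate_at(base, 30))), seed = 1)
  expect_equal(nrow(r$kept), 2)
  # empty input
  empty <- mk_reads(character(0))
  expect_equal(nrow(deduplicate(empty)$kept), 0)
})

test_that("dedup kept-groups match the brute-force all-pairs oracle", {
  set.seed(202)
  # 200 reads over few distinct window keys to force collisions
  pool <- vapply(1:40, function(i)
    paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE), collapse = ""), "")
  seqs <- sample(pool, 200, replace = TRUE)
  # randomize bases outside the window: prefix 4 and suffix beyond 55
  seqs <- vapply(seqs, function(s) {
    paste0(paste(sample(c("A", "C", "G", "T"), 4, replace = TRUE),
                 collapse = ""), substr(s, 5, 55),
           paste(sample(c("A", "C", "G", "T"), 5, replace = TRUE),
                 collapse = ""))
  }, "", USE.NAMES = FALSE)
  reads <- mk_reads(seqs)
  res <- deduplicate(reads, qc_config(), seed = 7)
  oracle <- oracle_dedup_groups(seqs)
  expect_equal(res$n_removed, length(seqs) - length(oracle))
  # exactly one representative kept per oracle group
  kept_idx <- match(res$kept$read_id, reads$read_id)
  for (g in oracle) expect_equal(sum(kept_idx %in% g), 1)
  # idempotence: kept set is stable under re-deduplication
  res2 <- deduplicate(res$kept, qc_config(), seed = 99)
  expect_equal(res2$n_removed, 0)
  expect_identical(res2$kept$read_id, res$kept$read_id)
})

test_that("quality tail trimming removes the maximal sub-threshold suffix", {
  q <- function(v) rivervirome:::phred_encode(v)
  rd <- mk_reads("ACGTA", q(c(30, 30, 30, 2, 2)))
  out <- trim_quality_tail(rd, qc_config())
  expect_equal(out$seq, "ACG")
  expect_equal(nchar(out$qual), 3)
  # untouched when no sub-threshold tail
  rd <- mk_reads("ACGTA", q(rep(30, 5)))
  expect_equal(trim_quality_tail(rd)$seq, "ACGTA")
  # fully trimmed read becomes empty
  rd <- mk_reads("ACGTA", q(rep(2, 5)))
  expect_equal(trim_quality_tail(rd)$seq, "")
  # a low-quality base inside a good tail is kept (suffix rule only)
  rd <- mk_reads("ACGTA", q(c(30, 2, 30, 30, 30)))
  expect_equal(trim_quality_tail(rd)$seq, "ACGTA")
})

test_that("adapter trimming removes qualifying 3' suffix matches", {
  adapter <- "AGATCGGAAGAGCACACGTCTGAACTCCAGTCAC"
  cfg <- qc_config(adapters = adapter)
  insert <- strrep("ACGT", 20)
  # exact full adapter appended: whole adapter removed
  rd <- mk_reads(paste0(insert, adapter))
  expect_equal(trim_adapters(rd, cfg)$seq, insert)
  # 12 nt adapter prefix with one mismatch (<= 10%) removed
  pre12 <- substr(adapter, 1, 12)
  substr(pre12, 6, 6) <- "T" # AGATCG G->T
  rd <- mk_reads(paste0(insert, pre12))
  expect_equal(trim_adapters(rd, cfg)$seq, insert)
  # no >= 10 nt match: unchanged
  rd <- mk_reads(paste0(insert, substr(adapter, 1, 8)))
  expect_equal(trim_adapters(rd, cfg)$seq, paste0(insert, substr(adapter, 1, 8)))
})

test_that("qc_library composes the stages and reports exact counts", {
  # empty library
  out <- qc_library(mk_reads(character(0)))
  expect_equal(out$report$n_raw, 0)
  expect_equal(out$report$n_kept, 0)

  # all-perfect distinct reads, no adapters: identity pipeline
  set.seed(31)
  seqs <- vapply(1:20, function(i)
    paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE), collapse = ""), "")
  rd <- mk_reads(seqs)
  out <- qc_library(rd, qc_config(), seed = 1)
  expect_identical(out$reads$seq, rd$seq)
  expect_equal(out$report$n_dup_removed, 0)
  expect_equal(out$report$n_adapter_trimmed, 0)

  # synthetic library with known duplicate structure: removals match the
  # header-derived ground truth (source genome, strand and 5'-end position
  # determine the dedup window content exactly)
  refs <- refs17()
  d <- community_design("Ld", weights = setNames(rep(1, 4),
                                                 names(refs$taxa)[1:4]),
                        n_reads = 1500, non_viral_fraction = 0.4,
                        duplicate_rate = 0.5, seed = 21)
  rd <- simulate_library(d, refs)
  tr <- read_truth(rd)
  end5 <- ifelse(tr$strand == "+", tr$start, tr$start + tr$ilen - 1L)
  truth_groups <- paste(tr$src, tr$strand, end5)
  out <- qc_library(rd, qc_config(), seed = 3)
  expect_equal(out$report$n_dup_removed,
               nrow(rd) - length(unique(truth_groups)))
})

test_that("trimming is monotone and never edits surviving bases", {
  refs <- refs17()
  d <- community_design("Lm", weights = setNames(1, names(refs$taxa)[1]),
                        n_reads = 200, non_viral_fraction = 0.5,
                        adapter_fraction = 0.3, seed = 8)
  rd <- simulate_library(d, refs)
  s1 <- trim_quality_tail(rd)
  expect_true(all(nchar(s1$seq) <= nchar(rd$seq)))
  expect_true(all(substr(rd$seq, 1, nchar(s1$seq)) == s1$seq))
  s2 <- trim_adapters(s1)
  expect_true(all(nchar(s2$seq) <= nchar(s1$seq)))
  expect_true(all(substr(s1$seq, 1, nchar(s2$seq)) == s2$seq))
})
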