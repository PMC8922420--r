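test_that("six-frame translation follows the standard code", {
  expect_equal(six_frame_translate("ATGAAATAG")[["+1"]], "MK*")
  # a frame +1 ORF appears in frame -1 of the reverse complement
  s <- "ATGGCCTTTAAATAG"
  rc <- rivervirome:::revcomp(s)
  expect_equal(six_frame_translate(rc)[["-1"]],
               six_frame_translate(s)[["+1"]])
  expect_error(six_frame_translate("AT"), "length >= 3")
  # random 300-mer: every frame matches the Biostrings codon-table oracle
  set.seed(13)
  s <- paste(sample(c("A", "C", "G", "T"), 300, replace = TRUE), collapse = "")
  fr <- six_frame_translate(s)
  for (off in 0:2) {
    fwd <- substr(s, off + 1, off + 3 * ((300 - off) %/% 3))
    oracle <- as.character(Biostrings::translate(Biostrings::DNAString(fwd), no.init.codon = TRUE))
    expect_equal(fr[[paste0("+", off + 1)]], oracle)
    rcs <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    rcf <- substr(rcs, off + 1, off + 3 * ((300 - off) %/% 3))
    expect_equal(fr[[paste0("-", off + 1)]],
                 as.character(Biostrings::translate(Biostrings::DNAString(rcf),
                                                    no.init.codon = TRUE)))
  }
})

test_that("self-match hits score the BLOSUM62 diagonal with 100% identity", {
  refs <- refs17()
  pep <- refs$viral_db$seq[3]
  nt <- paste(vapply(strsplit(pep, "")[[1]], function(a)
    rivervirome:::codons_for(a)[1], ""), collapse = "")
  h <- translated_search(nt, refs$viral_db, query_ids = "q")
  top <- h[1, ]
  expect_equal(top$subject_id, refs$viral_db$id[3])
  expect_equal(top$pident, 100)
  aa <- strsplit(pep, "")[[1]]
  expect_equal(top$score, sum(diag(rivervirome:::blosum62()[aa, aa])))
  expect_equal(top$frame, 1)
  # bit score definition and E-value closed form
  sch <- scoring_scheme()
  expect_equal(top$bitscore,
               (sch$lambda * top$score - log(sch$K)) / log(2))
  m <- nchar(pep); n <- sum(nchar(refs$viral_db$seq))
  expect_equal(top$evalue, m * n * 2^(-top$bitscore), tolerance = 1e-12)
  # search is invariant under reverse complement, with mirrored frame
  h2 <- translated_search(rivervirome:::revcomp(nt), refs$viral_db,
                          query_ids = "q")
  expect_equal(h2$subject_id[1], top$subject_id)
  expect_equal(h2$score[1], top$score)
  expect_equal(h2$frame[1], -1)
})

test_that("E = K m n exp(-lambda S) and the cutoff excludes weak hits", {
  # closed form: bit score 20, m = 100, n = 1000 -> E = 100 * 1000 * 2^-20
  expect_equal(100 * 1000 * 2^(-20), 0.095367431640625)
  sch <- scoring_scheme()
  S <- (20 * log(2) + log(sch$K)) / sch$lambda
  expect_equal(sch$K * 100 * 1000 * exp(-sch$lambda * S), 100 * 1000 * 2^-20,
               tolerance = 1e-12)
  # monotonicity: for fixed m, n the E-value strictly decreases in S
  E <- function(S) sch$K * 100 * 1000 * exp(-sch$lambda * S)
  expect_true(all(diff(E(seq(10, 200, by = 5))) < 0))

  # hits with E in [1e-5, 1e-4) are excluded at the default cutoff
  refs <- refs17()
  pep <- refs$viral_db$seq[1]
  nt <- paste(vapply(strsplit(pep, "")[[1]], function(a)
    rivervirome:::codons_for(a)[1], ""), collapse = "")
  loose <- translated_search(nt, refs$viral_db, e_cutoff = 1e-4,
                             query_ids = "q")
  strict <- translated_search(nt, refs$viral_db, e_cutoff = 1e-5,
                              query_ids = "q")
  expect_true(all(strict$evalue < 1e-5))
  dropped <- setdiff(loose$subject_id, strict$subject_id)
  if (length(dropped))
    expect_true(all(loose$evalue[loose$subject_id %in% dropped] >= 1e-5))
})

test_that("seeded banded search equals full Smith-Waterman on small inputs", {
  set.seed(300)
  mat <- rivervirome:::blosum62()
  sch <- scoring_scheme()
  mutate <- function(p, k) {
    aa <- strsplit(p, "")[[1]]
    idx <- sample(seq_along(aa), k)
    aa[idx] <- vapply(aa[idx], function(a)
      sample(setdiff(rivervirome:::AA20, a), 1), "")
    paste(aa, collapse = "")
  }
  for (rep in 1:8) {
    base <- rivervirome:::random_peptide(sample(20:30, 1), first_m = FALSE)
    db <- data.frame(id = paste0("p", 1:5),
                     seq = c(base,
                             vapply(1:2, function(i) mutate(base, 3), ""),
                             vapply(1:2, function(i)
                               rivervirome:::random_peptide(25, FALSE), "")),
                     stringsAsFactors = FALSE)
    query <- mutate(base, 2)
    hits <- peptide_search(query, db, sch, e_cutoff = Inf, query_ids = "q")
    for (d in seq_len(nrow(db))) {
      oracle <- oracle_sw(query, db$seq[d], mat, sch$gap_open, sch$gap_extend)
      got <- hits$score[hits$subject_id == db$id[d]]
      if (length(got)) {
        expect_equal(got, oracle)
      } else {
        # unreported subjects must be below the ungapped trigger score
        expect_lt(oracle, 2 * sch$trigger)
      }
    }
  }
})

test_that("competitive filtering resolves viral vs NVNR evidence", {
  hit <- function(bit, e) data.frame(query_id = "q", subject_id = "s",
                                     score = 1, bitscore = bit, evalue = e,
                                     stringsAsFactors = FALSE)
  # viral under cutoff, NVNR over cutoff -> viral
  r <- competitive_filter(hit(60, 1e-8), hit(80, 1e-3))
  expect_equal(r$verdict, "viral")
  # both under cutoff, NVNR better -> non-viral
  r <- competitive_filter(hit(60, 1e-8), hit(80, 1e-12))
  expect_equal(r$verdict, "non_viral")
  # exact bit-score tie -> conservative non-viral
  r <- competitive_filter(hit(60, 1e-8), hit(60, 1e-8))
  expect_equal(r$verdict, "non_viral")
  # nothing under cutoff -> unclassified
  r <- competitive_filter(hit(60, 1e-3), hit(60, 1e-2))
  expect_equal(r$verdict, "unclassified")
  # NVNR only -> non-viral
  r <- competitive_filter(hit(60, 1), hit(80, 1e-9))
  expect_equal(r$verdict, "non_viral")
})

test_that("classification recovers ground truth on constructed queries", {
  refs <- refs17()
  hmms <- build_hallmark_hmms(refs)
  tx <- refs$taxa[[1]]
  viral_contig <- substring(tx$genome_seq, 1, 1500)
  bg <- refs$background[[1]]
  bg_contig <- substring(bg$genome_seq, 1, 1500)
  set.seed(5)
  random_contig <- paste(sample(c("A", "C", "G", "T"), 800, replace = TRUE),
                         collapse = "")
  contigs <- data.frame(
    contig_id = c("v1", "b1", "x1"), library = "L1",
    seq = c(viral_contig, bg_contig, random_contig),
    n_members = 2L, n_reads_mapped = c(10L, 5L, 2L),
    stringsAsFactors = FALSE)
  singlets <- data.frame(read_id = character(0), library = character(0),
                         seq = character(0), qual = character(0),
                         stringsAsFactors = FALSE)
  cls <- classify_all(contigs, singlets, refs$viral_db, refs$nvnr_db, hmms)
  expect_equal(cls$verdict[cls$query_id == "v1"], "viral")
  expect_equal(cls$species[cls$query_id == "v1"], tx$species_name)
  expect_equal(cls$family[cls$query_id == "v1"], tx$family)
  expect_equal(cls$verdict[cls$query_id == "b1"], "non_viral")
  expect_equal(cls$verdict[cls$query_id == "x1"], "unclassified")
  # n_reads weight comes from the mapped-read totals for contigs
  expect_equal(cls$n_reads[cls$query_id == "v1"], 10L)
})

test_that("profile HMMs rescue remote homologs absent from the database", {
  refs <- refs17()
  hmms <- build_hallmark_hmms(refs)
  # a novel tailed phage: TerL-like gene diverged from the family consensus,
  # not present in the database
  set.seed(41)
  with_seed <- rivervirome:::with_seed
  novel <- with_seed(77, {
    anc <- refs$viral_db$seq[refs$viral_db$gene == "TerL"][1]
    aa <- strsplit(anc, "")[[1]]
    idx <- sample(2:length(aa), round(0.35 * length(aa)))
    aa[idx] <- vapply(aa[idx], function(a)
      sample(setdiff(rivervirome:::AA20, a), 1), "")
    paste(aa, collapse = "")
  })
  orf_nt <- paste(vapply(strsplit(novel, "")[[1]], function(a)
    rivervirome:::codons_for(a)[1], ""), collapse = "")
  contig <- paste0(strrep("C", 60), orf_nt, "TAA", strrep("G", 60))
  contigs <- data.frame(contig_id = "n1", library = "L1", seq = contig,
                        n_members = 2L, n_reads_mapped = 4L,
                        stringsAsFactors = FALSE)
  empty <- data.frame(read_id = character(0), library = character(0),
                      seq = character(0), qual = character(0))
  # against an unrelated viral db subset (no TerL records), the contig has
  # no direct hit but the TerL profile recognises it
  small_db <- refs$viral_db[refs$viral_db$gene == "other", ][1:10, ]
  cls <- classify_all(contigs, empty, small_db, refs$nvnr_db, hmms,
                      hmm_bitscore_cutoff = 20)
  expect_equal(cls$verdict, "viral_by_hmm")
  expect_equal(cls$hmm_name, "TerL")
  expect_gte(cls$hmm_score, 20)
})
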