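encode_pep <- function(pep) {
  paste(vapply(strsplit(pep, "")[[1]], function(a)
    rivervirome:::codons_for(a)[1], ""), collapse = "")
}

test_that("ORF prediction honours size, start codon and strand symmetry", {
  # 9 nt ORF is far below the 300 nt minimum
  expect_equal(nrow(predict_orfs("ATGAAATAA", "c", 300)), 0)

  # ATG + 98 sense codons + TAA: exactly one complete ORF, 99-aa peptide
  set.seed(6)
  pep <- rivervirome:::random_peptide(99)
  orf_nt <- paste0(encode_pep(pep), "TAA")
  contig <- paste0(strrep("C", 30), orf_nt, strrep("C", 30))
  orfs <- predict_orfs(contig, "c", 300)
  fwd <- orfs[orfs$strand == "+", ]
  expect_equal(nrow(fwd), 1)
  expect_equal(fwd$peptide, pep)
  expect_true(fwd$complete)
  expect_equal(fwd$end - fwd$start, 300) # stop codon included
  expect_equal(substr(contig, fwd$start + 1, fwd$start + 3), "ATG")

  # the reverse complement carries the same ORF on the minus strand with
  # mirrored coordinates
  rc <- rivervirome:::revcomp(contig)
  orfs_rc <- predict_orfs(rc, "c", 300)
  rev <- orfs_rc[orfs_rc$strand == "-", ]
  expect_equal(nrow(rev), 1)
  expect_equal(rev$peptide, pep)
  expect_equal(rev$start, nchar(contig) - fwd$end)
  expect_equal(rev$end, nchar(contig) - fwd$start)

  # every reported peptide re-translates exactly from its coordinates
  all_orfs <- rbind(orfs, orfs_rc)
  for (i in seq_len(nrow(all_orfs))) {
    r <- all_orfs[i, ]
    src <- if (r$strand == "+") contig else rc
    nt <- substr(src, r$start + 1, r$end)
    if (r$strand == "-") nt <- rivervirome:::revcomp(nt)
    pep_back <- six_frame_translate(nt)[["+1"]]
    expect_equal(sub("\\*$", "", pep_back), r$peptide)
  }

  # an ORF running off the contig edge is reported incomplete
  open_contig <- paste0(strrep("C", 21), encode_pep(
    rivervirome:::random_peptide(120)))
  op <- predict_orfs(open_contig, "c", 300)
  op <- op[op$strand == "+" & op$start == 21, ]
  expect_equal(nrow(op), 1)
  expect_false(op$complete)
})

test_that("ORF annotation labels hallmarks and putative proteins", {
  refs <- refs17()
  terl_row <- which(refs$viral_db$gene == "TerL")[1]
  orfs <- data.frame(
    orf_id = c("o1", "o2"), contig_id = c("c1", "c2"), strand = "+",
    frame = 1L, start = 0L, end = 30L,
    peptide = c(refs$viral_db$seq[terl_row],
                rivervirome:::random_peptide(150)),
    complete = c(TRUE, TRUE), stringsAsFactors = FALSE)
  out <- annotate_and_extract_hallmarks(orfs, refs$viral_db)
  ann <- out$annotations
  expect_equal(ann$gene[1], "TerL")
  expect_equal(ann$annotation[2], "putative protein")
  expect_equal(names(out$hallmark_sets), "TerL")
  expect_equal(out$hallmark_sets$TerL$group, "Caudovirales")
  expect_equal(out$hallmark_sets$TerL$members$orf_id, "o1")

  # an implanted Rep lands in the CRESS-DNA set
  rep_row <- which(refs$viral_db$gene == "Rep")[1]
  orfs$peptide[2] <- refs$viral_db$seq[rep_row]
  out2 <- annotate_and_extract_hallmarks(orfs, refs$viral_db)
  expect_true("Rep" %in% names(out2$hallmark_sets))
  expect_equal(out2$hallmark_sets$Rep$group, "CRESS-DNA")
})

test_that("contigs hitting disjoint regions of one subject merge with an N spacer", {
  set.seed(10)
  c1 <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE), collapse = "")
  c2 <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE), collapse = "")
  contigs <- data.frame(contig_id = c("a", "b"), seq = c(c1, c2),
                        stringsAsFactors = FALSE)
  hits <- data.frame(query_id = c("a", "b"), subject_id = "P1",
                     sstart = c(0, 150), send = c(120, 300), frame = c(1, 1),
                     stringsAsFactors = FALSE)
  out <- merge_nonoverlapping_contigs(contigs, hits)
  expect_equal(nrow(out), 1)
  expect_equal(out$seq, paste0(c1, strrep("N", 100), c2))
  expect_equal(out$members, "a,b")

  # different subjects: no merge
  hits2 <- within(hits, subject_id <- c("P1", "P2"))
  out2 <- merge_nonoverlapping_contigs(contigs, hits2)
  expect_equal(nrow(out2), 2)
  expect_true(all(is.na(out2$subject_id)))

  # overlapping subject intervals: no merge
  hits3 <- within(hits, {sstart <- c(0, 100); send <- c(120, 300)})
  out3 <- merge_nonoverlapping_contigs(contigs, hits3)
  expect_equal(nrow(out3), 2)
})

test_that("contig extension grows into read overhangs and reaches a fixpoint", {
  set.seed(18)
  genome <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
                  collapse = "")
  contig <- substr(genome, 101, 300)
  reads <- data.frame(
    read_id = c("r1", "r2"), library = "L1",
    seq = c(substr(genome, 61, 140), substr(genome, 261, 340)),
    qual = strrep("I", 80), stringsAsFactors = FALSE)
  out <- extend_by_mapping(contig, reads, rounds = 3)
  expect_equal(out, substr(genome, 61, 340))
  # idempotent at the fixpoint
  expect_equal(extend_by_mapping(out, reads, rounds = 2), out)
  # no overlapping reads: unchanged
  expect_equal(extend_by_mapping(contig, reads[0, ], rounds = 1), contig)
  # one read overhanging the 3' end by 40 nt grows the contig by 40
  r40 <- data.frame(read_id = "r3", library = "L1",
                    seq = substr(genome, 241, 340), qual = strrep("I", 100),
                    stringsAsFactors = FALSE)
  expect_equal(extend_by_mapping(contig, r40, rounds = 1),
               substr(genome, 101, 340))
})

test_that("progressive alignment and gap masking follow the column rule", {
  set.seed(26)
  base <- rivervirome:::random_peptide(60)
  # identical sequences: gap-free alignment, nothing masked
  ident <- setNames(c(base, base, base), paste0("s", 1:3))
  aln <- align_and_mask(ident)
  expect_false(any(grepl("-", aln, fixed = TRUE)))
  expect_equal(unname(gsub("-", "", aln)), unname(ident))

  # pre-aligned rows: a 75%-gap column is dropped, a 50%-gap column kept
  rows <- c(a = "AC-D", b = "A--D", c = "AC-D", d = "-C-D")
  masked <- rivervirome:::mask_alignment(rows)
  expect_equal(unname(masked), c("ACD", "A-D", "ACD", "-CD"))
  expect_length(masked, 4) # masking never changes the row count
  # idempotence
  expect_equal(rivervirome:::mask_alignment(masked), masked)

  # divergent-but-related sequences recover their residues after degapping
  vars <- vapply(1:4, function(i) {
    aa <- strsplit(base, "")[[1]]
    idx <- sample(2:60, 8)
    aa[idx] <- vapply(aa[idx], function(a)
      sample(setdiff(rivervirome:::AA20, a), 1), "")
    paste(aa[-sample(10:50, 2)], collapse = "")
  }, "")
  names(vars) <- paste0("v", 1:4)
  aln2 <- align_peptides(vars)
  expect_equal(length(unique(nchar(aln2))), 1)
  expect_equal(unname(gsub("-", "", aln2[names(vars)])), unname(vars))
})

test_that("neighbor joining recovers known branch lengths and topologies", {
  # three taxa with d = (3, 4, 5): branches 1, 2, 3
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- ape::nj(as.dist(d))
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(bl[c("A", "B", "C")]), c(1, 2, 3))

  # an additive 4-taxon matrix from a known tree is recovered exactly
  true_tree <- ape::read.tree(text = "((A:2,B:3):1,(C:4,D:5):2);")
  dm <- ape::cophenetic.phylo(true_tree)
  rec <- ape::nj(as.dist(dm))
  expect_equal(unname(ape::cophenetic.phylo(rec)[rownames(dm), rownames(dm)]),
               unname(dm), tolerance = 1e-9)

  # nj_tree on an alignment: identical rows give zero branch lengths
  msa <- setNames(rep("ACDEFGHIKL", 4), paste0("t", 1:4))
  tr0 <- nj_tree(msa)
  expect_true(all(tr0$edge.length < 1e-12))
  expect_error(nj_tree(msa[1:2]), "three")

  # p-distances feed NJ: two identical rows coalesce at zero distance
  msa2 <- setNames(c("AAAA", "AAAA", "CCCC", "CCGG"), paste0("u", 1:4))
  tru <- nj_tree(msa2)
  coph <- ape::cophenetic.phylo(tru)
  expect_equal(coph["u1", "u2"], 0)
  expect_gt(coph["u1", "u3"], 0.5)
})
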