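mk_cls <- function(lib, species, family, type, n, verdict = "viral") {
  data.frame(query_id = paste0(lib, ":", species, ":", seq_along(species)),
             library = lib, query_type = "singlet", n_reads = n,
             verdict = verdict, species = species, family = family,
             genome_type = type, host = "bacteria", gene = "other",
             stringsAsFactors = FALSE)
}

test_that("profiles count reads by taxon, weighted by mapped reads", {
  cls <- data.frame(query_id = "s1", library = "L1", query_type = "singlet",
                    n_reads = 1L, verdict = "viral", species = "SpA",
                    family = "FamA", genome_type = "dsDNA", host = "bacteria",
                    gene = "TerL", stringsAsFactors = FALSE)
  p <- build_profiles(cls, "species")
  expect_equal(dim(p$counts), c(1, 1))
  expect_equal(unname(p$counts[1, 1]), 1)

  # contigs contribute their mapped-read totals
  cls2 <- rbind(cls, within(cls, {
    query_id <- "c1"; query_type <- "contig"; n_reads <- 25L
  }))
  p2 <- build_profiles(cls2, "species")
  expect_equal(unname(p2$counts["L1", "SpA"]), 26)

  # unclassified-by-taxonomy viral reads are tracked as a reserved taxon
  cls3 <- rbind(cls, within(cls, {
    query_id <- "h1"; verdict <- "viral_by_hmm"; species <- NA; family <- NA
  }))
  p3 <- build_profiles(cls3, "family")
  expect_true("unclassified virus" %in% colnames(p3$counts))
  expect_error(build_profiles(cls, "genus"))
})

test_that("family counts by genome type reproduce the fixture triple", {
  refs <- refs17()
  db <- refs$viral_db
  cls <- mk_cls("L1", db$species, db$family, db$genome_type,
                rep(1L, nrow(db)))
  cls$genome_type <- db$genome_type
  p <- build_profiles(cls, "family")
  meta <- p$taxon_meta
  triple <- table(meta$genome_type)[c("dsDNA", "ssDNA", "RNA")]
  expect_equal(as.vector(triple), c(9L, 4L, 4L))
  expect_equal(sum(triple), 17L)
})

test_that("analytic rarefaction matches the hypergeometric closed form", {
  # counts {A:4, B:2}, n = 2 -> 23/15
  out <- rarefaction_curve(c(A = 4, B = 2), c(0, 2, 6))
  expect_equal(out$expected_taxa, c(0, 23 / 15, 2), tolerance = 1e-9)
  expect_error(rarefaction_curve(c(A = 4), 10), "exceed")
  # strictly increasing and concave, reaching S at full depth
  counts <- c(a = 50, b = 20, c = 10, d = 5, e = 1)
  depths <- 0:sum(counts)
  es <- rarefaction_curve(counts, depths)$expected_taxa
  expect_true(all(diff(es) > 0))
  expect_true(all(diff(diff(es)) < 1e-9))
  expect_equal(es[length(es)], 5)
})

test_that("Bray-Curtis follows its definition and metric axioms", {
  m <- rbind(L1 = c(6, 2), L2 = c(2, 2))
  d <- bray_curtis(m)
  expect_equal(d["L1", "L2"], 1 / 3)
  # identical rows -> 0; disjoint supports -> 1
  expect_equal(bray_curtis(rbind(A = c(3, 1), B = c(3, 1)))["A", "B"], 0)
  expect_equal(bray_curtis(rbind(A = c(3, 0), B = c(0, 7)))["A", "B"], 1)
  # two all-zero libraries are at distance 0 by convention
  expect_equal(bray_curtis(rbind(A = c(0, 0), B = c(0, 0)))["A", "B"], 0)
  # randomized: symmetry, zero diagonal, range
  set.seed(8)
  mm <- matrix(rpois(50, 4), 5, dimnames = list(paste0("S", 1:5), NULL))
  dd <- bray_curtis(mm)
  expect_equal(dd, t(dd))
  expect_true(all(diag(dd) == 0))
  expect_true(all(dd >= 0 & dd <= 1))
})

test_that("PCoA reproduces classical scaling", {
  # two points at distance 0.5: coordinates +/- 0.25, eigenvalue 0.125
  dm <- matrix(c(0, 0.5, 0.5, 0), 2, dimnames = list(c("a", "b"),
                                                     c("a", "b")))
  p <- pcoa_ordination(dm)
  expect_equal(unname(sort(p$coordinates[, 1])), c(-0.25, 0.25))
  expect_equal(p$eigenvalues[1], 0.125)
  # all-zero distances -> no positive axes / all-zero coordinates
  z <- pcoa_ordination(matrix(0, 3, 3, dimnames = list(letters[1:3],
                                                       letters[1:3])))
  expect_true(ncol(z$coordinates) == 0 || all(abs(z$coordinates) < 1e-12))
  # Euclidean-embeddable: round-trip distances, no negative eigenvalues,
  # variance fractions sum to 1
  set.seed(21)
  pts <- matrix(rnorm(12), 4, 3)
  dm <- as.matrix(dist(pts))
  p <- pcoa_ordination(dm)
  rec <- as.matrix(dist(p$coordinates))
  expect_equal(unname(rec), unname(dm), tolerance = 1e-9)
  expect_true(all(p$eigenvalues > -1e-9))
  expect_equal(sum(p$variance_explained), 1, tolerance = 1e-9)
  expect_error(pcoa_ordination(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("UPGMA is ultrametric and matches hand/oracle agglomeration", {
  # two labels at distance 2: both leaves at height 1
  d2 <- matrix(c(0, 2, 2, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  t2 <- upgma_tree(d2)
  expect_equal(sort(t2$edge.length), c(1, 1))
  # d(A,B)=2, d(A,C)=d(B,C)=4 -> ((A:1,B:1):1,C:2)
  d3 <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t3 <- upgma_tree(d3)
  coph <- ape::cophenetic.phylo(t3)
  expect_equal(coph["A", "B"], 2)
  expect_equal(coph["A", "C"], 4)
  expect_equal(coph["B", "C"], 4)
  # random 5x5: join heights equal the brute-force oracle's
  set.seed(31)
  x <- matrix(runif(25), 5)
  d5 <- as.matrix(dist(x))
  dimnames(d5) <- list(paste0("t", 1:5), paste0("t", 1:5))
  t5 <- upgma_tree(d5)
  expect_equal(ape::cophenetic.phylo(t5)[rownames(d5), rownames(d5)],
               oracle_upgma_cophenetic(d5), tolerance = 1e-9)
  # ultrametric: root equidistant from every leaf
  depths <- ape::node.depth.edgelength(t5)[seq_along(t5$tip.label)]
  expect_true(max(depths) - min(depths) < 1e-9)
})

test_that("Friedman test matches the textbook tie-corrected formula", {
  # worked 3x3 example: every block ranks the treatments 1,2,3
  m <- t(rbind(c(1, 2, 3), c(2, 4, 6), c(1, 3, 5))) # libraries x taxa
  out <- friedman_profile_test(m)
  expect_equal(out$statistic, 6, tolerance = 1e-9)
  expect_equal(out$df, 2)
  expect_equal(out$p_value, pchisq(6, 2, lower.tail = FALSE),
               tolerance = 1e-9)
  # all values equal: no discrimination
  flat <- friedman_profile_test(matrix(5, 3, 4))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p_value, 1)
  # random 10x4 with ties: equals the independently coded formula
  set.seed(14)
  y <- matrix(sample(1:6, 40, replace = TRUE), 10, 4) # blocks x treatments
  out <- friedman_profile_test(t(y))
  oracle <- oracle_friedman(y)
  expect_equal(out$statistic, oracle$statistic, tolerance = 1e-9)
  expect_equal(out$p_value, oracle$p_value, tolerance = 1e-9)
  expect_error(friedman_profile_test(matrix(1, 1, 3)))
})

test_that("shared and top species bookkeeping is exact", {
  m <- rbind(L1 = c(A = 1, B = 2, C = 0),
             L2 = c(A = 0, B = 5, C = 3))
  sh <- shared_species(m)
  expect_equal(sort(sh$core_species), "B")
  expect_equal(sh$union_size, 3)
  expect_equal(sh$per_library$core_fraction, c(0.5, 0.5))
  expect_equal(sh$per_library$n_unique, c(1L, 1L))
  expect_equal(sum(sh$venn_regions), 3)
  # identical sets: core = union, fractions 1
  m2 <- rbind(L1 = c(A = 1, B = 2), L2 = c(A = 3, B = 1))
  sh2 <- shared_species(m2)
  expect_equal(sh2$per_library$core_fraction, c(1, 1))
  # disjoint sets: empty core
  m3 <- rbind(L1 = c(A = 1, B = 0), L2 = c(A = 0, B = 2))
  expect_length(shared_species(m3)$core_species, 0)

  top <- top_species(rbind(L1 = c(X = 30, Y = 10)), k = 10)
  expect_equal(top$relative_abundance, c(0.75, 0.25))
  expect_equal(top$species, c("X", "Y"))
  top2 <- top_species(m, k = 1)
  expect_equal(top2$species, c("B", "B"))
  expect_true(all(top2$shared))
  expect_error(top_species(m, k = 0), "positive")
})
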