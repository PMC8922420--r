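#' Build a libraries-by-taxa abundance profile from classifications
#'
#' Counts are reads assigned to each taxon per library: singlets
#' contribute 1 read, contigs contribute their mapped-read total.
#' Queries with verdict `viral` are tallied under their best-hit taxon;
#' `viral_by_hmm` queries have no taxonomy and are tracked under the
#' reserved taxon `"unclassified virus"` (excluded from none of the
#' ecology, mirroring how unclassified viral reads are reported alongside
#' named families).
#'
#' @param classifications table from [classify_all()].
#' @param rank `"family"` or `"species"`.
#' @param libraries optional library ordering (defaults to order of
#'   appearance).
#' @return object of class `rv_profile`: list with `rank`, `counts`
#'   (libraries x taxa integer matrix) and `taxon_meta` (`data.frame`
#'   with `taxon`, `genome_type`, `host`).
#' @export
build_profiles <- function(classifications, rank = c("family", "species"),
                           libraries = NULL) {
  rank <- match.arg(rank)
  cl <- classifications
  keep <- cl$verdict %in% c("viral", "viral_by_hmm")
  cl <- cl[keep, , drop = FALSE]
  taxon <- if (rank == "family") cl$family else cl$species
  taxon[cl$verdict == "viral_by_hmm" | is.na(taxon)] <- "unclassified virus"
  libs <- libraries %||% unique(classifications$library)
  taxa <- sort(unique(taxon))
  counts <- matrix(0L, length(libs), length(taxa),
                   dimnames = list(libs, taxa))
  if (nrow(cl)) {
    agg <- aggregate(cl$n_reads,
                     by = list(library = cl$library, taxon = taxon), FUN = sum)
    for (r in seq_len(nrow(agg)))
      counts[agg$library[r], agg$taxon[r]] <- as.integer(agg$x[r])
  }
  meta <- data.frame(taxon = taxa,
                     genome_type = NA_character_, host = NA_character_,
                     stringsAsFactors = FALSE)
  for (i in seq_along(taxa)) {
    rows <- which(taxon == taxa[i])
    if (length(rows)) {
      meta$genome_type[i] <- cl$genome_type[rows[1]]
      meta$host[i] <- cl$host[rows[1]]
    }
  }
  structure(list(rank = rank, counts = counts, taxon_meta = meta),
            class = "rv_profile")
}

#' @export
print.rv_profile <- function(x, ...) {
  cat(sprintf("<rv_profile> rank=%s, %d libraries x %d taxa, %d reads\n",
              x$rank, nrow(x$counts), ncol(x$counts), sum(x$counts)))
  invisible(x)
}

#' Analytic (hypergeometric) rarefaction
#'
#' Expected number of distinct taxa in a random subsample of n reads:
#' `E[S_n] = sum_i (1 - choose(N - N_i, n) / choose(N, n))`.
#'
#' @param counts named vector of per-taxon counts (one library).
#' @param depths subsample sizes; all must be `<= sum(counts)`.
#' @return `data.frame` with `depth` and `expected_taxa`.
#' @export
rarefaction_curve <- function(counts, depths) {
  counts <- counts[counts > 0]
  N <- sum(counts)
  stop_if_not(all(depths >= 0), "depths must be non-negative")
  stop_if_not(all(depths <= N), "depths must not exceed the total count")
  es <- vapply(depths, function(n) {
    if (n == 0) return(0)
    as.numeric(suppressWarnings(vegan::rarefy(counts, sample = n)))
  }, 0)
  data.frame(depth = depths, expected_taxa = es)
}

#' Bray-Curtis dissimilarity between library profiles
#'
#' `d(x, y) = sum |x_i - y_i| / sum (x_i + y_i)` over taxa. Two all-zero
#' libraries are at distance 0 by convention.
#'
#' @param profile an `rv_profile` (or a libraries x taxa count matrix).
#' @return a symmetric `dist`-convertible matrix with zero diagonal.
#' @export
bray_curtis <- function(profile) {
  m <- if (inherits(profile, "rv_profile")) profile$counts else profile
  stop_if_not(nrow(m) >= 2, "need at least two libraries")
  d <- as.matrix(suppressWarnings(vegan::vegdist(m, method = "bray")))
  # vegdist yields NaN for a pair of all-zero rows; define it as 0
  d[is.nan(d)] <- 0
  diag(d) <- 0
  d
}

#' Principal coordinates analysis (classical metric scaling)
#'
#' Gower-centres -D^2/2, eigendecomposes, and scales eigenvectors by the
#' square root of their (positive) eigenvalues. Negative eigenvalues are
#' reported, not corrected.
#'
#' @param dm symmetric distance matrix with labels.
#' @return list with `coordinates` (labels x axes), `eigenvalues`, and
#'   `variance_explained` (fractions over positive eigenvalues).
#' @export
pcoa_ordination <- function(dm) {
  dm <- as.matrix(dm)
  stop_if_not(isTRUE(all.equal(dm, t(dm), tolerance = 1e-8)),
              "distance matrix must be symmetric")
  n <- nrow(dm)
  # cmdscale warns whenever trailing eigenvalues are <= 0, which is the
  # normal situation for semi-metric ecological distances
  fit <- suppressWarnings(cmdscale(as.dist(dm), k = max(n - 1, 1),
                                   eig = TRUE))
  eig <- fit$eig
  pos <- eig > 1e-12
  coords <- fit$points
  if (ncol(coords) > 0)
    colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  ve <- if (any(pos)) eig[pos] / sum(eig[pos]) else numeric(0)
  list(coordinates = coords, eigenvalues = eig,
       variance_explained = ve)
}

#' UPGMA clustering of a distance matrix
#'
#' Iteratively merges the closest pair under size-weighted average
#' linkage; leaf heights are half the merge distance, so the tree is
#' ultrametric.
#'
#' @param dm symmetric distance matrix with labels.
#' @return rooted ultrametric `phylo` tree (ape).
#' @export
upgma_tree <- function(dm) {
  dm <- as.matrix(dm)
  stop_if_not(nrow(dm) >= 2, "need at least two labels")
  # lexicographic label order makes hclust's tie-breaking reproducible
  ord <- order(rownames(dm))
  phangorn::upgma(as.dist(dm[ord, ord]))
}

#' Friedman rank-sum test across libraries
#'
#' Taxa are the blocks and libraries the treatments: within every taxon
#' the library counts are mid-ranked, and the tie-corrected Friedman
#' chi-square is referred to a chi-square distribution with k - 1 degrees
#' of freedom (k = number of libraries).
#'
#' @param profile an `rv_profile` or a libraries x taxa count matrix.
#' @return `data.frame` with `statistic`, `df`, `p_value`, `tie_corrected`.
#' @export
friedman_profile_test <- function(profile) {
  m <- if (inherits(profile, "rv_profile")) profile$counts else profile
  stop_if_not(nrow(m) >= 2 && ncol(m) >= 2,
              "need >= 2 libraries and >= 2 taxa")
  y <- t(m) # blocks (taxa) in rows, treatments (libraries) in columns
  if (all(apply(y, 1, function(r) length(unique(r)) == 1))) {
    # every block fully tied: no discrimination at all
    return(data.frame(statistic = 0, df = ncol(y) - 1, p_value = 1,
                      tie_corrected = TRUE))
  }
  ft <- friedman.test(y)
  ties <- any(apply(y, 1, function(r) anyDuplicated(r) > 0))
  data.frame(statistic = unname(ft$statistic), df = unname(ft$parameter),
             p_value = ft$p.value, tie_corrected = ties)
}

#' Shared and unique species across libraries
#'
#' Exact region counts of the presence/absence set system (a Venn
#' breakdown), the core (species present in all libraries), and each
#' library's core fraction.
#'
#' @param profile a species-rank `rv_profile` (or presence matrix).
#' @return list with `venn_regions` (named counts, names are
#'   `+`/`-` membership patterns in library order), `core_species`,
#'   `union_size`, `per_library` (`data.frame`: library, n_species,
#'   core_fraction, n_unique).
#' @export
shared_species <- function(profile) {
  m <- if (inherits(profile, "rv_profile")) profile$counts else profile
  stop_if_not(nrow(m) >= 2, "need at least two libraries")
  pres <- m > 0
  libs <- rownames(pres)
  present_any <- colSums(pres) > 0
  pres <- pres[, present_any, drop = FALSE]
  pattern <- apply(pres, 2, function(col) paste(ifelse(col, "+", "-"),
                                                collapse = ""))
  venn <- table(pattern)
  core <- colnames(pres)[colSums(pres) == nrow(pres)]
  per_lib <- data.frame(
    library = libs,
    n_species = rowSums(pres),
    core_fraction = ifelse(rowSums(pres) > 0,
                           length(core) / rowSums(pres), NA_real_),
    n_unique = vapply(seq_along(libs), function(i) {
      sum(pres[i, ] & colSums(pres) == 1)
    }, 0L),
    stringsAsFactors = FALSE)
  list(venn_regions = venn, core_species = core,
       union_size = ncol(pres), per_library = per_lib)
}

#' Top-k most abundant species per library
#'
#' Species ranked by descending count (ties broken lexicographically);
#' relative abundance is the count over the library's viral-assigned
#' total; species present in every library are flagged as shared.
#'
#' @param profile a species-rank `rv_profile`.
#' @param k number of species per library.
#' @return `data.frame`: library, rank, species, count,
#'   relative_abundance, shared.
#' @export
top_species <- function(profile, k = 10) {
  stop_if_not(is_count(k) && k >= 1, "k must be a positive count")
  m <- if (inherits(profile, "rv_profile")) profile$counts else profile
  shared_set <- colnames(m)[colSums(m > 0) == nrow(m)]
  out <- list()
  for (lib in rownames(m)) {
    x <- m[lib, ]
    x <- x[x > 0]
    if (length(x) == 0) next
    ord <- order(-x, names(x))
    top <- head(ord, k)
    out[[lib]] <- data.frame(
      library = lib, rank = seq_along(top), species = names(x)[top],
      count = unname(x[top]),
      relative_abundance = unname(x[top]) / sum(x),
      shared = names(x)[top] %in% shared_set,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
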