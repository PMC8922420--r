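#' Assembly configuration
#'
#' Parameters for the per-library greedy overlap-layout-consensus
#' assembler and for the read-back mapping statistic.
#'
#' @param min_overlap minimum suffix-prefix overlap (nt) for a merge.
#' @param min_overlap_identity minimum identity inside the overlap.
#' @param min_contig_len contigs shorter than this are demoted to their
#'   member reads (the length-based chimera filter).
#' @param map_min_identity,map_min_aligned thresholds for counting a read
#'   as mapped to a contig (ungapped, either strand).
#' @return object of class `rv_assembly_config`.
#' @export
assembly_config <- function(min_overlap = 30, min_overlap_identity = 0.98,
                            min_contig_len = 250, map_min_identity = 0.95,
                            map_min_aligned = 50) {
  stop_if_not(min_overlap_identity > 0 && min_overlap_identity <= 1 &&
                map_min_identity > 0 && map_min_identity <= 1,
              "identities must lie in (0, 1]")
  structure(list(min_overlap = as.integer(min_overlap),
                 min_overlap_identity = min_overlap_identity,
                 min_contig_len = as.integer(min_contig_len),
                 map_min_identity = map_min_identity,
                 map_min_aligned = as.integer(map_min_aligned)),
            class = "rv_assembly_config")
}

#' Greedy overlap assembly of one cleaned library
#'
#' Repeatedly merges the pair of sequences (read or growing contig) with
#' the longest suffix-prefix overlap of at least `min_overlap` nt at
#' `min_overlap_identity` or better, ties broken by the lexicographically
#' smallest id pair, taking the per-position majority base (quality-sum
#' tie-break) as consensus, until no merge qualifies. Reverse-complement
#' overlaps are considered. Merged items shorter than `min_contig_len`
#' are demoted back to their member reads as singlets.
#'
#' @param reads cleaned read table (one library).
#' @param cfg an [assembly_config()].
#' @return list with `contigs` (data.frame: contig_id, library, seq,
#'   n_members, member_read_ids list-column) and `singlets` (read table).
#' @export
assemble <- function(reads, cfg = assembly_config()) {
  lib <- if (nrow(reads)) reads$library[1] else NA_character_
  if (nrow(reads) == 0) {
    return(list(contigs = data.frame(contig_id = character(0),
                                     library = character(0),
                                     seq = character(0),
                                     n_members = integer(0)),
                singlets = reads))
  }
  res <- cpp_assemble(reads$read_id, reads$seq, reads$qual,
                      cfg$min_overlap, cfg$min_overlap_identity)
  n_members <- lengths(res$members)
  is_contig <- n_members >= 2 & nchar(res$seq) >= cfg$min_contig_len
  singlet_idx <- sort(unlist(res$members[!is_contig]))
  contigs <- data.frame(
    contig_id = sprintf("%s:ctg%04d", lib, seq_len(sum(is_contig))),
    library = rep(lib, sum(is_contig)),
    seq = res$seq[is_contig],
    n_members = n_members[is_contig],
    stringsAsFactors = FALSE)
  contigs$member_read_ids <- lapply(res$members[is_contig],
                                    function(ix) reads$read_id[ix])
  list(contigs = contigs,
       singlets = reads[singlet_idx, , drop = FALSE])
}

#' Map reads back to contigs and report the mapped percentage
#'
#' A read maps when it has an ungapped alignment to some contig of at
#' least `map_min_aligned` bases at `map_min_identity` or better, on
#' either strand. The percentage is taken over `n_raw` (the raw read count
#' of the library before QC) when given, else over the supplied reads.
#'
#' @param reads read table to map (typically the cleaned reads).
#' @param contigs contig table from [assemble()].
#' @param cfg an [assembly_config()].
#' @param n_raw raw read count used as the percentage denominator.
#' @return list with `per_read` (data.frame read_id, contig_id, mapped
#'   placement details) and `report` (one-row data.frame: library,
#'   n_mapped, n_raw, pct_mapped).
#' @export
map_reads_back <- function(reads, contigs, cfg = assembly_config(),
                           n_raw = nrow(reads)) {
  lib <- if (nrow(reads)) reads$library[1] else NA_character_
  if (nrow(contigs) == 0 || nrow(reads) == 0) {
    return(list(per_read = data.frame(read_id = character(0),
                                      contig_id = character(0)),
                report = data.frame(library = lib, n_mapped = 0L,
                                    n_raw = n_raw, pct_mapped = 0)))
  }
  m <- cpp_map_reads(reads$seq, contigs$seq, cfg$map_min_aligned,
                     cfg$map_min_identity, FALSE)
  per_read <- data.frame(
    read_id = reads$read_id[m$read],
    contig_id = contigs$contig_id[m$contig],
    offset = m$offset, strand = ifelse(m$strand == 0, "+", "-"),
    aligned = m$aligned, matches = m$matches,
    stringsAsFactors = FALSE)
  list(per_read = per_read,
       report = data.frame(library = lib, n_mapped = nrow(per_read),
                           n_raw = n_raw,
                           pct_mapped = 100 * nrow(per_read) / max(n_raw, 1)))
}
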