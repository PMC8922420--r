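#' Read a FASTQ file into a read table
#'
#' Reads are returned as a plain `data.frame`, the unit that flows through
#' QC and assembly: one row per read with the sequence and its Phred+33
#' quality string kept in lockstep.
#'
#' @param path path to an (uncompressed or gzipped) FASTQ file.
#' @param library library label to attach to every read; defaults to the
#'   file name without extension.
#' @return `data.frame` with columns `read_id`, `library`, `seq`, `qual`,
#'   `meta` (the FASTQ description after the first space, possibly empty).
#' @export
read_fastq <- function(path, library = NULL) {
  library <- library %||% sub("\\.(fastq|fq)(\\.gz)?$", "", basename(path))
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  nm <- names(x)
  id <- sub(" .*$", "", nm)
  meta <- ifelse(grepl(" ", nm), sub("^[^ ]+ ", "", nm), "")
  data.frame(
    read_id = id,
    library = library,
    seq = as.character(x),
    qual = as.character(S4Vectors::mcols(x)$qualities),
    meta = meta,
    stringsAsFactors = FALSE
  )
}

#' Write a read table to FASTQ (Phred+33)
#'
#' @param reads read table as returned by [read_fastq()] or
#'   [simulate_library()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  keep <- nchar(reads$seq) > 0
  reads <- reads[keep, , drop = FALSE]
  x <- Biostrings::DNAStringSet(reads$seq)
  nm <- reads$read_id
  if (!is.null(reads$meta)) {
    has <- !is.na(reads$meta) & nzchar(reads$meta)
    nm[has] <- paste(nm[has], reads$meta[has])
  }
  names(x) <- nm
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qual))
  invisible(path)
}

#' Read a protein database FASTA with structured taxonomy headers
#'
#' Viral database headers use the dialect
#' `>id|species|family|genome_type|host|gene`; non-virus (NVNR) databases
#' carry plain identifiers.
#'
#' @param path FASTA path.
#' @param taxonomy if `TRUE`, parse the pipe-delimited taxonomy fields.
#' @return `data.frame` with columns `id`, `seq` and, when `taxonomy`,
#'   `species`, `family`, `genome_type`, `host`, `gene`.
#' @export
read_protein_db <- function(path, taxonomy = TRUE) {
  x <- Biostrings::readAAStringSet(path)
  # the taxonomy dialect allows spaces inside fields, so the full header
  # line is parsed; plain databases keep only the first word as the id
  nm <- if (taxonomy) trimws(names(x)) else sub(" .*$", "", names(x))
  if (taxonomy) {
    parts <- strsplit(nm, "|", fixed = TRUE)
    stop_if_not(all(lengths(parts) == 6),
                "viral database headers must be id|species|family|genome_type|host|gene")
    m <- do.call(rbind, parts)
    data.frame(id = m[, 1], species = m[, 2], family = m[, 3],
               genome_type = m[, 4], host = m[, 5], gene = m[, 6],
               seq = as.character(x), stringsAsFactors = FALSE)
  } else {
    data.frame(id = nm, seq = as.character(x), stringsAsFactors = FALSE)
  }
}

#' Write a protein or nucleotide database to FASTA
#'
#' For tables carrying taxonomy columns the structured header dialect
#' `id|species|family|genome_type|host|gene` is emitted.
#'
#' @param db `data.frame` with at least `id` and `seq`.
#' @param path output FASTA path.
#' @param type `"AA"` or `"DNA"`.
#' @return `path`, invisibly.
#' @export
write_db_fasta <- function(db, path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  nm <- db$id
  if (all(c("species", "family", "genome_type", "host", "gene") %in% names(db))) {
    nm <- paste(db$id, db$species, db$family, db$genome_type, db$host, db$gene,
                sep = "|")
  }
  x <- if (type == "AA") Biostrings::AAStringSet(db$seq)
       else Biostrings::DNAStringSet(db$seq)
  names(x) <- nm
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path) {
  read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}
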