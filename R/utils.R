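#' Internal helpers: seeding, sequence utilities, Phred codecs
#'
#' All randomness in the package flows from one user-visible integer seed.
#' Each stochastic operation derives its own stream with `op_seed(seed, tag)`
#' so that, e.g., regenerating one library does not disturb another.
#' @noRd
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic sub-seed derivation: distinct tags give decorrelated streams,
# results stay inside 32-bit integer range.
op_seed <- function(seed, tag) {
  h <- 0
  for (ch in utf8ToInt(as.character(tag))) h <- (h * 131 + ch) %% 1000003
  v <- ((as.numeric(seed) %% 2147483647) * 48271 + h * 9349) %% 2147483629
  as.integer(v)
}

# Evaluate expr under a temporary RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

DNA_BASES <- c("A", "C", "G", "T")
AA20 <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")

random_dna <- function(len) {
  paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
}

random_peptide <- function(len, first_m = TRUE) {
  p <- sample(AA20, len, replace = TRUE)
  if (first_m) p[1] <- "M"
  paste(p, collapse = "")
}

revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  out <- chartr("ACGTNacgtn", "TGCANtgcan", x)
  vapply(out, function(s) intToUtf8(rev(utf8ToInt(s))), "", USE.NAMES = FALSE)
}

phred_decode <- function(qual) {
  if (nchar(qual) == 0) return(integer(0))
  utf8ToInt(qual) - 33L
}

phred_encode <- function(q) {
  if (length(q) == 0) return("")
  intToUtf8(pmin(q, 60L) + 33L)
}

gc_percent <- function(seqs) {
  seqs <- seqs[nchar(seqs) > 0]
  if (length(seqs) == 0) return(NA_real_)
  x <- Biostrings::DNAStringSet(seqs)
  af <- Biostrings::alphabetFrequency(x)[, c("A", "C", "G", "T"), drop = FALSE]
  100 * sum(af[, c("C", "G")]) / sum(af)
}

# Standard genetic code keyed by codon, derived from the Biostrings table.
genetic_code <- function() {
  gc <- .rv_cache$genetic_code
  if (is.null(gc)) {
    gc <- Biostrings::GENETIC_CODE
    .rv_cache$genetic_code <- gc
  }
  gc
}

# Codons for one amino acid (standard code).
codons_for <- function(aa) {
  tab <- .rv_cache$codon_table
  if (is.null(tab)) {
    gc <- genetic_code()
    tab <- split(names(gc), unname(gc))
    .rv_cache$codon_table <- tab
  }
  tab[[aa]]
}

blosum62 <- function() {
  m <- .rv_cache$blosum62
  if (is.null(m)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    m <- e$BLOSUM62
    .rv_cache$blosum62 <- m
  }
  m
}

is_count <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) &&
  x >= 0 && x == floor(x)

stop_if_not <- function(cond, msg) if (!cond) stop(msg, call. = FALSE)
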