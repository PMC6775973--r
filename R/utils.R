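# shared internal helpers: sequence coercion, alphabet checks, seeded RNG

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#'
#' Thin character-in/character-out wrapper around
#' [Biostrings::reverseComplement()].
#'
#' @param x single DNA string (IUPAC codes allowed).
#' @return reverse-complemented string.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# GC fraction of a DNA string
gc_fraction <- function(x) {
  b <- strsplit(x, "", fixed = TRUE)[[1]]
  mean(b == "G" | b == "C")
}

# Accept an annotated_genome, a 1-row sequence data.frame, or a plain string,
# and return the uppercase sequence.
as_genome_seq <- function(genome) {
  if (inherits(genome, "annotated_genome")) return(genome$seq)
  if (is.data.frame(genome)) {
    stopifnot(nrow(genome) == 1L, "seq" %in% names(genome))
    return(toupper(genome$seq[[1]]))
  }
  if (is.character(genome) && length(genome) == 1L) return(toupper(genome))
  stop("cannot interpret `genome` as a single nucleotide sequence")
}

genome_id_of <- function(genome, default = "genome") {
  if (inherits(genome, "annotated_genome")) return(genome$id)
  if (is.data.frame(genome) && "id" %in% names(genome)) return(genome$id[[1]])
  nm <- names(genome)
  if (!is.null(nm) && nzchar(nm[1])) return(nm[1])
  default
}

# Normalize a genome database (list of annotated_genome, data.frame with
# id/seq, or named character vector) to a named character vector of
# uppercase sequences.
as_genome_db <- function(genomes) {
  if (inherits(genomes, "annotated_genome")) genomes <- list(genomes)
  if (is.list(genomes) && !is.data.frame(genomes)) {
    out <- vapply(genomes, as_genome_seq, character(1))
    nm <- names(genomes)
    ids <- vapply(seq_along(genomes), function(i) {
      if (!is.null(nm) && nzchar(nm[i])) nm[i]
      else genome_id_of(genomes[[i]], default = paste0("genome", i))
    }, character(1))
    names(out) <- ids
    return(out)
  }
  if (is.data.frame(genomes)) {
    stopifnot(all(c("id", "seq") %in% names(genomes)))
    return(setNames(toupper(genomes$seq), genomes$id))
  }
  if (is.character(genomes)) {
    if (length(genomes) &&
        (is.null(names(genomes)) || any(!nzchar(names(genomes)))))
      names(genomes) <- paste0("genome", seq_along(genomes))
    return(toupper(genomes))
  }
  stop("cannot interpret `genomes` as a genome database")
}

assert_dna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGTRYSWKMBDHVN]", toupper(x))
  if (any(bad))
    stop(sprintf("%s contains non-IUPAC nucleotide characters", what))
  invisible(TRUE)
}

assert_aa <- function(x, what = "protein sequence") {
  bad <- grepl("[^ACDEFGHIKLMNPQRSTVWYX*]", toupper(x))
  if (any(bad))
    stop(sprintf("%s contains non-amino-acid characters", what))
  invisible(TRUE)
}

# Run `expr` under a dedicated seeded RNG stream, restoring the caller's RNG
# state afterwards (one seeded generator per operation call).
with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

# Phred+33 helpers
phred_decode <- function(qual) utf8ToInt(qual) - 33L
phred_encode <- function(q) intToUtf8(as.integer(q) + 33L)

# random DNA of length n at a target GC content
random_dna <- function(n, gc) {
  paste(sample(DNA_BASES, n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}
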