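# io_formats: FASTA/FASTQ/SAM readers, TSV reports, GFF3 feature export.
# All internal coordinates are 0-based half-open; SAM (1-based) is converted
# at this boundary and GFF3 output is 1-based inclusive.

#' Read sequences from FASTA or FASTQ
#'
#' Returns records in file order as a data frame with one row per record.
#' Lowercase (soft-masked) bases are uppercased on read; FASTQ qualities are
#' kept as Phred+33 strings (decode with [phred_scores()]).
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"fasta"` or `"fastq"`.
#' @return data.frame with columns `id`, `desc`, `seq`, `qual`
#'   (`qual` is `NA` for FASTA).
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file does not exist: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.f(ast)?q(\\.gz)?$", path, ignore.case = TRUE))
      "fastq" else "fasta"
  }
  empty <- data.frame(id = character(), desc = character(),
                      seq = character(), qual = character(),
                      stringsAsFactors = FALSE)
  if (file.size(path) == 0) return(empty)
  if (format == "fasta") {
    x <- Biostrings::readBStringSet(path, format = "fasta")
    hdr <- names(x)
    seqs <- toupper(as.character(x))
    qual <- rep(NA_character_, length(x))
  } else {
    x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                      with.qualities = TRUE)
    hdr <- names(x)
    seqs <- toupper(as.character(x))
    qual <- as.character(S4Vectors::mcols(x)$qualities)
  }
  id <- sub("\\s.*$", "", hdr)
  desc <- ifelse(grepl("\\s", hdr), sub("^\\S+\\s+", "", hdr), "")
  data.frame(id = id, desc = desc, seq = unname(seqs), qual = unname(qual),
             stringsAsFactors = FALSE)
}

#' Write sequences to FASTA or FASTQ
#'
#' @param records data.frame as returned by [read_sequences()].
#' @param path output file.
#' @param format `"fasta"` or `"fastq"` (FASTQ requires a `qual` column).
#' @return `path`, invisibly.
#' @export
write_sequences <- function(records, path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  hdr <- ifelse(is.na(records$desc) | records$desc == "",
                records$id, paste(records$id, records$desc))
  if (format == "fasta") {
    x <- Biostrings::BStringSet(setNames(records$seq, hdr))
    Biostrings::writeXStringSet(x, path, format = "fasta", width = 70L)
  } else {
    if (is.null(records$qual) || anyNA(records$qual))
      stop("FASTQ output requires qualities for every record")
    x <- Biostrings::DNAStringSet(setNames(records$seq, hdr))
    q <- Biostrings::BStringSet(records$qual)
    Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  }
  invisible(path)
}

#' Decode Phred+33 quality strings
#'
#' @param qual character vector of Phred+33 quality strings.
#' @return list of integer vectors of per-base Phred scores.
#' @export
phred_scores <- function(qual) lapply(qual, phred_decode)

#' Construct a table of read-to-genome alignment records
#'
#' The alignment record is the package-wide currency for identity
#' computations: `ref_start`/`ref_end` are 0-based half-open reference
#' coordinates, and the edit decomposition obeys
#' `ref_end - ref_start = matches + mismatches + deletions` and
#' `aligned_read_bases = matches + mismatches + insertions`.
#'
#' @param read_id,genome_id character vectors.
#' @param ref_start,ref_end 0-based half-open reference interval.
#' @param strand `"+"` or `"-"`.
#' @param matches,mismatches,insertions,deletions edit counts (bases).
#' @return validated data.frame of alignment records.
#' @export
alignment_records <- function(read_id, genome_id, ref_start, ref_end, strand,
                              matches, mismatches, insertions, deletions) {
  out <- data.frame(read_id = as.character(read_id),
                    genome_id = as.character(genome_id),
                    ref_start = as.integer(ref_start),
                    ref_end = as.integer(ref_end),
                    strand = as.character(strand),
                    matches = as.integer(matches),
                    mismatches = as.integer(mismatches),
                    insertions = as.integer(insertions),
                    deletions = as.integer(deletions),
                    stringsAsFactors = FALSE)
  out$aligned_read_bases <- out$matches + out$mismatches + out$insertions
  validate_alignments(out)
  out
}

validate_alignments <- function(a) {
  cnt <- c(a$matches, a$mismatches, a$insertions, a$deletions)
  if (any(cnt < 0)) stop("negative edit counts in alignment records")
  if (any(a$ref_end - a$ref_start != a$matches + a$mismatches + a$deletions))
    stop("reference span inconsistent with edit counts")
  if (!all(a$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  invisible(a)
}

#' Read alignments from a SAM file
#'
#' Ingests mapped primary alignments produced by an external mapper.  The
#' `NM` tag is required: mismatches are recovered as
#' `NM - insertions - deletions` (MD parsing is not attempted).  1-based SAM
#' `POS` is converted to 0-based `ref_start`; unmapped, secondary and
#' supplementary records are skipped.
#'
#' @param path SAM file.
#' @return data.frame of alignment records (see [alignment_records()]).
#' @export
read_alignments <- function(path) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  bam <- Rsamtools::asBam(path, destination = tempfile(),
                          overwrite = TRUE, indexDestination = FALSE)
  on.exit(unlink(bam), add = TRUE)
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "rname", "pos", "strand", "cigar", "flag"),
    tag = "NM")
  x <- Rsamtools::scanBam(bam, param = param)[[1]]
  flag <- x$flag
  keep <- bitwAnd(flag, 4L) == 0L &      # mapped
          bitwAnd(flag, 256L) == 0L &    # primary
          bitwAnd(flag, 2048L) == 0L     # not supplementary
  if (!any(keep)) {
    return(alignment_records(character(), character(), integer(), integer(),
                             character(), integer(), integer(), integer(),
                             integer()))
  }
  cigar <- x$cigar[keep]
  nm <- x$tag$NM
  if (is.null(nm)) nm <- rep(NA_integer_, length(keep))
  nm <- nm[keep]
  if (anyNA(nm))
    stop("mapped SAM record lacks the NM tag; identity is not computable")
  opt <- GenomicAlignments::cigarOpTable(cigar)
  m_tot <- opt[, "M"] + opt[, "="] + opt[, "X"]
  ins <- opt[, "I"]
  del <- opt[, "D"]
  if (any(nm < ins + del))
    stop("NM smaller than indel bases in SAM record")
  mism <- nm - ins - del
  if (any(mism > m_tot))
    stop("NM implies more mismatches than aligned columns")
  pos0 <- x$pos[keep] - 1L
  alignment_records(
    read_id = x$qname[keep],
    genome_id = as.character(x$rname[keep]),
    ref_start = pos0,
    ref_end = pos0 + m_tot + del,
    strand = ifelse(bitwAnd(flag[keep], 16L) != 0L, "-", "+"),
    matches = m_tot - mism,
    mismatches = mism,
    insertions = ins,
    deletions = del)
}

#' Write a recruitment (or other tabular) report as TSV
#'
#' Rows are sorted by `(sample_id, genome_id)` (and `identity_cutoff` when
#' present); floating-point columns are written at fixed 6-decimal precision
#' so that re-runs produce byte-identical files.
#'
#' @param reports data.frame sharing one schema.
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_report <- function(reports, path) {
  df <- as.data.frame(reports, stringsAsFactors = FALSE)
  keys <- intersect(c("sample_id", "genome_id", "identity_cutoff"), names(df))
  if (length(keys) && nrow(df))
    df <- df[do.call(order, df[keys]), , drop = FALSE]
  isnum <- vapply(df, is.double, logical(1))
  df[isnum] <- lapply(df[isnum], function(v) sprintf("%.6f", v))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a TSV report written by [write_report()]
#' @param path TSV file.
#' @return data.frame.
#' @export
read_report <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}

#' Export genome feature annotations as GFF3
#'
#' Converts the 0-based half-open internal feature table of an
#' [annotated genome][simulate_genome] to 1-based inclusive GFF3.
#'
#' @param genome an `annotated_genome`.
#' @param path output GFF3 file.
#' @return `path`, invisibly.
#' @export
write_features_gff3 <- function(genome, path) {
  stopifnot(inherits(genome, "annotated_genome"))
  ft <- genome$features
  if (is.null(ft) || nrow(ft) == 0) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = genome$id,
    ranges = IRanges::IRanges(start = ft$start + 1L, end = ft$end),
    strand = ifelse(ft$strand %in% c("+", "-"), ft$strand, "*"),
    type = ft$type)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
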