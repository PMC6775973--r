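# recruitment: read cleaning, seed-and-extend alignment, identity filtering,
# breadth-of-coverage presence calls and per-Gb relative abundance.

#' Read-cleaning parameters
#'
#' Defaults implement the standard metagenome preprocessing rule: low-quality
#' (Phred < 20) bases trimmed from both read ends, then reads with mean
#' quality < 20 or length < 30 discarded.
#'
#' @param end_quality Phred threshold for end trimming.
#' @param min_avg_quality minimum mean Phred after trimming.
#' @param min_length minimum read length after trimming (bp).
#' @return a `clean_params` list.
#' @export
clean_params <- function(end_quality = 20L, min_avg_quality = 20L,
                         min_length = 30L) {
  stopifnot(end_quality >= 0, min_avg_quality >= 0, min_length >= 0)
  structure(list(end_quality = end_quality,
                 min_avg_quality = min_avg_quality,
                 min_length = min_length),
            class = "clean_params")
}

#' Recruitment parameters
#'
#' The presence rule: a genome is present in a sample when at least
#' `min_breadth` of its positions are covered by reads of at least
#' `min_identity` percent identity (both thresholds inclusive).
#' `alt_identities` adds further cutoffs (e.g. 0.95 and 1.00 for enrichment
#' profiling) to [profile_sample()].
#'
#' @param min_identity identity cutoff in (0,1].
#' @param min_breadth breadth cutoff in (0,1].
#' @param alt_identities optional numeric vector of additional cutoffs.
#' @return a `recruit_params` list.
#' @export
recruit_params <- function(min_identity = 0.90, min_breadth = 0.75,
                           alt_identities = NULL) {
  stopifnot(min_identity > 0, min_identity <= 1,
            min_breadth > 0, min_breadth <= 1)
  structure(list(min_identity = min_identity, min_breadth = min_breadth,
                 alt_identities = alt_identities),
            class = "recruit_params")
}

#' Quality-trim and filter reads
#'
#' Bases are trimmed from each read end up to the first base with quality
#' `>= end_quality`; reads whose trimmed mean quality falls below
#' `min_avg_quality` or whose trimmed length falls below `min_length` are
#' dropped.
#'
#' @param reads data.frame with `seq` and `qual` (Phred+33) columns.
#' @param params a [clean_params()] object.
#' @return list with `reads` (cleaned data.frame) and `stats`
#'   (`reads_in/out`, `bases_in/out`).
#' @export
clean_reads <- function(reads, params = clean_params()) {
  if (is.null(reads$qual) || anyNA(reads$qual))
    stop("reads lack qualities; disable cleaning to align raw reads")
  n <- nrow(reads)
  bases_in <- sum(nchar(reads$seq))
  first <- integer(n); last <- integer(n); keep <- logical(n)
  for (i in seq_len(n)) {
    q <- phred_decode(reads$qual[i])
    ok <- q >= params$end_quality
    if (!any(ok)) { keep[i] <- FALSE; next }
    f <- which.max(ok)
    l <- length(q) - which.max(rev(ok)) + 1L
    len <- l - f + 1L
    if (len < params$min_length ||
        mean(q[f:l]) < params$min_avg_quality) {
      keep[i] <- FALSE
    } else {
      keep[i] <- TRUE; first[i] <- f; last[i] <- l
    }
  }
  out <- reads[keep, , drop = FALSE]
  out$seq <- substring(out$seq, first[keep], last[keep])
  out$qual <- substring(out$qual, first[keep], last[keep])
  rownames(out) <- NULL
  list(reads = out,
       stats = list(reads_in = n, reads_out = nrow(out),
                    bases_in = bases_in, bases_out = sum(nchar(out$seq))))
}

# k-mer index over the forward strand of every genome: data.table
# (kmer, genome, pos0) with pos0 the 0-based k-mer start
build_kmer_index <- function(db, k) {
  parts <- lapply(names(db), function(g) {
    s <- db[[g]]
    n <- nchar(s)
    if (n < k) return(NULL)
    data.table::data.table(
      kmer = substring(s, 1:(n - k + 1L), k:n),
      genome = g, pos0 = 0:(n - k))
  })
  idx <- data.table::rbindlist(parts)
  data.table::setkey(idx, kmer)
  idx
}

#' Align reads to a genome database by seed-and-extend
#'
#' Exact k-mer seeds are looked up against both strands; for each read the
#' most seed-supported candidate diagonals are extended by banded semi-global
#' alignment (the whole read against a genome window of slack `band`), and
#' the best-scoring location is reported as the read's single primary
#' alignment.  Multi-mapping ties are broken by lexicographic genome id,
#' then leftmost position, then `+` strand, for determinism.
#'
#' @param reads data.frame with `id` and `seq` columns.
#' @param genomes genome database (list of `annotated_genome`, data.frame
#'   `id`/`seq`, or named character vector).
#' @param k seed k-mer length.
#' @param band extension window slack (bp).
#' @param max_candidates candidate loci extended per read.
#' @return data.frame of alignment records; reads without a seeded candidate
#'   are simply absent.
#' @export
align_reads <- function(reads, genomes, k = 15L, band = 16L,
                        max_candidates = 4L) {
  db <- as_genome_db(genomes)
  glen <- nchar(db)
  empty <- alignment_records(character(), character(), integer(), integer(),
                             character(), integer(), integer(), integer(),
                             integer())
  if (nrow(reads) == 0) return(empty)
  idx <- build_kmer_index(db, k)
  if (nrow(idx) == 0) return(empty)

  seqs_fw <- toupper(reads$seq)
  seqs_rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(seqs_fw)))
  rl <- nchar(seqs_fw)

  # seed query table over both orientations
  qparts <- lapply(c("+", "-"), function(orient) {
    qs <- if (orient == "+") seqs_fw else seqs_rc
    per <- lapply(seq_along(qs), function(i) {
      n <- rl[i]
      if (n < k) return(NULL)
      offs <- unique(c(seq(0L, n - k, by = k), n - k))
      data.table::data.table(ridx = i, orient = orient, off = offs,
                             kmer = substring(qs[i], offs + 1L, offs + k))
    })
    data.table::rbindlist(per)
  })
  q <- data.table::rbindlist(qparts)
  hits <- idx[q, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
  if (nrow(hits) == 0) return(empty)
  hits[, diag0 := pos0 - off]
  hits[, dgroup := diag0 %/% band]
  cand <- hits[, .(support = .N, diag0 = as.integer(round(stats::median(diag0)))),
               by = .(ridx, orient, genome, dgroup)]
  data.table::setorder(cand, ridx, -support, genome, diag0, orient)
  cand <- cand[, head(.SD, max_candidates), by = ridx]

  res <- vector("list", nrow(reads))
  cand_split <- split(seq_len(nrow(cand)), cand$ridx)
  for (ri_chr in names(cand_split)) {
    ri <- as.integer(ri_chr)
    best <- NULL
    for (ci in cand_split[[ri_chr]]) {
      g <- cand$genome[ci]
      d <- cand$diag0[ci]
      L <- glen[[g]]
      m <- rl[ri]
      w0 <- max(0L, d - band)
      w1 <- min(L, d + m + band)
      if (w1 - w0 < max(k, m %/% 2L)) next
      rseq <- if (cand$orient[ci] == "+") seqs_fw[ri] else seqs_rc[ri]
      al <- semiglobal_align(rseq, substr(db[[g]], w0 + 1L, w1))
      score <- al$score
      rec <- list(score = score, genome = g, strand = cand$orient[ci],
                  ref_start = w0 + al$ref_start, ref_end = w0 + al$ref_end,
                  matches = al$matches, mismatches = al$mismatches,
                  insertions = al$insertions, deletions = al$deletions)
      if (is.null(best) ||
          score > best$score ||
          (score == best$score &&
           (rec$genome < best$genome ||
            (rec$genome == best$genome &&
             (rec$ref_start < best$ref_start ||
              (rec$ref_start == best$ref_start && rec$strand == "+")))))) {
        best <- rec
      }
    }
    if (!is.null(best)) res[[ri]] <- best
  }
  got <- which(!vapply(res, is.null, logical(1)))
  if (!length(got)) return(empty)
  b <- res[got]
  alignment_records(
    read_id = reads$id[got],
    genome_id = vapply(b, `[[`, character(1), "genome"),
    ref_start = vapply(b, `[[`, numeric(1), "ref_start"),
    ref_end = vapply(b, `[[`, numeric(1), "ref_end"),
    strand = vapply(b, `[[`, character(1), "strand"),
    matches = vapply(b, `[[`, numeric(1), "matches"),
    mismatches = vapply(b, `[[`, numeric(1), "mismatches"),
    insertions = vapply(b, `[[`, numeric(1), "insertions"),
    deletions = vapply(b, `[[`, numeric(1), "deletions"))
}

#' Percent identity of alignment records
#'
#' `identity = matches / (matches + mismatches + insertions + deletions)`;
#' the denominator counts indel columns (conservative, as common mappers
#' do).  A read at exactly the cutoff passes the inclusive `>=` filter.
#'
#' @param a data.frame of alignment records.
#' @return numeric vector of identities in \[0,1\].
#' @export
alignment_identity <- function(a) {
  denom <- a$matches + a$mismatches + a$insertions + a$deletions
  if (any(denom == 0)) stop("alignment with zero columns")
  a$matches / denom
}

#' Per-genome coverage profiles from identity-filtered alignments
#'
#' Alignments below `min_identity` are discarded entirely; passing
#' alignments increment per-position depth over `[ref_start, ref_end)`.
#' `aligned_bases` counts reference bases covered with multiplicity
#' (`sum(depth)`).
#'
#' @param alignments data.frame of alignment records.
#' @param genome_lengths named vector of genome lengths (bp); every genome
#'   gets a profile even without alignments.
#' @param params a [recruit_params()] object.
#' @return named list of `coverage_profile` objects (`genome_id`, `depth`,
#'   `aligned_bases`, `passing_reads`).
#' @export
recruit <- function(alignments, genome_lengths, params = recruit_params()) {
  if (nrow(alignments)) {
    unknown <- setdiff(alignments$genome_id, names(genome_lengths))
    if (length(unknown))
      stop("alignments reference unknown genomes: ",
           paste(unknown, collapse = ", "))
    pass <- alignment_identity(alignments) >= params$min_identity
    alignments <- alignments[pass, , drop = FALSE]
  }
  out <- lapply(names(genome_lengths), function(g) {
    L <- as.integer(genome_lengths[[g]])
    a <- alignments[alignments$genome_id == g, , drop = FALSE]
    if (nrow(a) && (any(a$ref_start < 0) || any(a$ref_end > L)))
      stop("alignment beyond genome bounds for ", g)
    depth <- if (nrow(a)) {
      delta <- tabulate(a$ref_start + 1L, nbins = L + 1L) -
               tabulate(a$ref_end + 1L, nbins = L + 1L)
      cumsum(delta)[seq_len(L)]
    } else integer(L)
    structure(list(genome_id = g, depth = depth,
                   aligned_bases = sum(depth), passing_reads = nrow(a)),
              class = "coverage_profile")
  })
  setNames(out, names(genome_lengths))
}

#' Breadth of coverage
#'
#' Fraction of genome positions covered by at least one passing read.
#'
#' @param profile a `coverage_profile` from [recruit()].
#' @return fraction in \[0,1\].
#' @export
breadth <- function(profile) {
  stopifnot(inherits(profile, "coverage_profile"))
  mean(profile$depth >= 1L)
}

#' Presence call for a genome in a sample
#'
#' Present if and only if breadth is at least `params$min_breadth`
#' (inclusive), with breadth computed from alignments already filtered at
#' `params$min_identity`.
#'
#' @param profile a `coverage_profile`.
#' @param params a [recruit_params()] object.
#' @return logical.
#' @export
call_presence <- function(profile, params = recruit_params()) {
  breadth(profile) >= params$min_breadth
}

#' Relative abundance per gigabase of library
#'
#' `abundance = aligned_bases / genome_length / (library_bases / 1e9)`:
#' a depth-like statistic normalized by library size, invariant under
#' duplicating the sample.
#'
#' @param profile a `coverage_profile`, or a plain number of aligned bases.
#' @param genome_length genome length (bp, > 0).
#' @param library_bases total bases in the (cleaned) library (> 0).
#' @return abundance per Gb.
#' @export
relative_abundance <- function(profile, genome_length, library_bases) {
  aligned <- if (inherits(profile, "coverage_profile"))
    profile$aligned_bases else as.numeric(profile)
  if (genome_length <= 0) stop("genome_length must be positive")
  if (library_bases <= 0) stop("library_bases must be positive")
  aligned / genome_length / (library_bases / 1e9)
}

#' Full per-sample recruitment profile
#'
#' Runs clean, align, recruit and the presence/abundance statistics for
#' every genome and every identity cutoff in
#' `{min_identity} U alt_identities`.  Library size is the total bases after
#' cleaning (the denominator consistent with what was mapped).  The
#' `percent_of_library` column reports the same aligned bases as a percent
#' of total library bases, the normalization used alongside per-Gb abundance
#' in enrichment profiling.
#'
#' @param sample_reads data.frame of reads (`id`, `seq`, `qual`).
#' @param genome_db genome database (see [align_reads()]).
#' @param clean_params a [clean_params()] object, or `NULL` to skip
#'   cleaning (e.g. for reads without qualities).
#' @param recruit_params a [recruit_params()] object.
#' @param sample_id label for the report.
#' @param k,band aligner tuning (see [align_reads()]).
#' @return data.frame with one row per (genome, identity cutoff):
#'   `sample_id`, `genome_id`, `identity_cutoff`, `breadth`, `mean_depth`,
#'   `abundance_per_gb`, `percent_of_library`, `present`, `library_bases`.
#' @export
profile_sample <- function(sample_reads, genome_db,
                           clean_params = cobascan::clean_params(),
                           recruit_params = cobascan::recruit_params(),
                           sample_id = "sample", k = 15L, band = 16L) {
  db <- as_genome_db(genome_db)
  glen <- nchar(db)
  if (!is.null(clean_params)) {
    cleaned <- clean_reads(sample_reads, clean_params)
    sample_reads <- cleaned$reads
  }
  library_bases <- sum(nchar(sample_reads$seq))
  aln <- align_reads(sample_reads, db, k = k, band = band)
  cutoffs <- sort(unique(c(recruit_params$min_identity,
                           recruit_params$alt_identities)))
  rows <- lapply(cutoffs, function(cut) {
    p <- recruit_params
    p$min_identity <- cut
    profs <- recruit(aln, glen, p)
    do.call(rbind, lapply(profs, function(pr) {
      br <- breadth(pr)
      data.frame(
        sample_id = sample_id, genome_id = pr$genome_id,
        identity_cutoff = cut, breadth = br,
        mean_depth = pr$aligned_bases / glen[[pr$genome_id]],
        abundance_per_gb = relative_abundance(pr, glen[[pr$genome_id]],
                                              library_bases),
        percent_of_library = 100 * pr$aligned_bases / library_bases,
        present = br >= p$min_breadth,
        library_bases = library_bases,
        stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
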