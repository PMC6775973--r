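# termini: direct terminal repeat detection, reference-DTR anchoring,
# genome reorientation to the DTR 5' end, and read-start pileup evidence.

#' Find the direct (or inverted) terminal repeat of a genome
#'
#' Compares the length-L prefix against the length-L suffix for every
#' candidate L, end-anchored and substitutions-only (indels are disallowed in
#' the repeat: DTR copies arise by replication of identical ends, and indel
#' tolerance would inflate false repeats).  The longest candidate with
#' mismatch fraction `<= max_mismatch_frac` is reported.  `mode =
#' "inverted"` compares the prefix against the reverse-complemented suffix;
#' this diagnostic variant is reported but never used for reorientation.
#'
#' @param genome `annotated_genome` or sequence string.
#' @param min_len minimum repeat length considered (bp).
#' @param max_mismatch_frac maximum tolerated mismatch fraction.
#' @param max_len maximum repeat length considered; defaults to a quarter of
#'   the genome (terminal repeats of linear phages are short relative to the
#'   genome), capped at half the genome length.
#' @param mode `"direct"` or `"inverted"`.
#' @return one-row data.frame (`genome_id`, `length`, `mismatches`, `seq`,
#'   `five_start`, `five_end`, `three_start`, `three_end`, `mode`), or
#'   `NULL` when no repeat satisfies the tolerance.
#' @export
find_terminal_repeat <- function(genome, min_len = 30L,
                                 max_mismatch_frac = 0.02,
                                 max_len = NULL,
                                 mode = c("direct", "inverted")) {
  mode <- match.arg(mode)
  seq <- as_genome_seq(genome)
  n <- nchar(seq)
  if (n <= 2L * min_len)
    stop("genome shorter than twice min_len")
  if (is.null(max_len)) max_len <- min(n %/% 2L, n %/% 4L + min_len)
  max_len <- min(max_len, n %/% 2L)
  mm <- terminal_mismatch_scan(seq, min_len, max_len,
                               inverted = (mode == "inverted"))
  lens <- min_len:max_len
  ok <- mm <= floor(max_mismatch_frac * lens)
  if (!any(ok)) return(NULL)
  L <- max(lens[ok])
  data.frame(genome_id = genome_id_of(genome), length = L,
             mismatches = mm[L - min_len + 1L],
             seq = substr(seq, 1L, L),
             five_start = 0L, five_end = L,
             three_start = n - L, three_end = n,
             mode = mode, stringsAsFactors = FALSE)
}

# cluster integer values into groups whose consecutive sorted members are
# within `gap`; returns a list of index vectors into the original order
cluster_within <- function(x, gap) {
  o <- order(x)
  xs <- x[o]
  grp <- cumsum(c(1L, diff(xs) > gap))
  split(o, grp)
}

#' Locate a reference DTR within a target genome
#'
#' Seed-and-extend search for local hits of a known DTR (e.g. from a close
#' relative) inside `target_genome`, on both strands.  Each seeded candidate
#' locus is re-aligned semi-globally (the full reference against a window of
#' the target), so hits cover the whole reference; hits are kept at identity
#' `>= min_identity` where identity = matches / alignment columns.  Related
#' phages carry DTRs at 70-100% nucleotide identity, hence the permissive
#' default.
#'
#' @param target_genome `annotated_genome` or sequence string.
#' @param reference_dtr DTR sequence (string, length >= 30).
#' @param min_identity minimum alignment identity.
#' @param k seed k-mer length.
#' @param band extension window slack (bp).
#' @return data.frame of hits (`start`, `end` 0-based half-open, `strand`,
#'   `identity`) sorted by position; zero rows when nothing matches.
#' @export
locate_dtr_by_reference <- function(target_genome, reference_dtr,
                                    min_identity = 0.70, k = 12L,
                                    band = 16L) {
  tseq <- as_genome_seq(target_genome)
  rseq <- toupper(reference_dtr)
  if (nchar(rseq) < 30L) stop("reference DTR must be at least 30 bp")
  rlen <- nchar(rseq)
  n <- nchar(tseq)
  hits <- list()
  for (strand in c("+", "-")) {
    q <- if (strand == "+") rseq else revcomp(rseq)
    offs <- seq(0L, rlen - k, by = max(1L, k %/% 2L))
    seeds <- substring(q, offs + 1L, offs + k)
    diags <- integer(0)
    for (i in seq_along(seeds)) {
      m <- Biostrings::matchPattern(seeds[i], Biostrings::DNAString(tseq))
      if (length(m))
        diags <- c(diags, BiocGenerics::start(m) - 1L - offs[i])
    }
    if (!length(diags)) next
    for (idx in cluster_within(diags, band)) {
      d <- as.integer(round(stats::median(diags[idx])))
      w0 <- max(0L, d - band)
      w1 <- min(n, d + rlen + band)
      if (w1 - w0 < rlen %/% 2L) next
      al <- semiglobal_align(q, substr(tseq, w0 + 1L, w1))
      cols <- al$matches + al$mismatches + al$insertions + al$deletions
      ident <- al$matches / cols
      if (ident >= min_identity) {
        hits[[length(hits) + 1L]] <- data.frame(
          start = w0 + al$ref_start, end = w0 + al$ref_end,
          strand = strand, identity = ident, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), identity = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  # de-duplicate overlapping hits: best identity wins, leftmost on ties
  out <- out[order(-out$identity, out$start), , drop = FALSE]
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))[-1]) {
    for (j in which(keep[seq_len(i - 1L)])) {
      if (out$start[i] < out$end[j] && out$end[i] > out$start[j]) {
        keep[i] <- FALSE; break
      }
    }
  }
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Reorient a genome so the DTR 5' end defines position zero
#'
#' Treats the genome as a circular permutation: the sequence is first
#' circularized (a detected terminal repeat copy at the 3' end is collapsed),
#' rotated so that the 5' end of the DTR hit becomes position 0, and the
#' leading DTR copy is then re-appended at the 3' end so that both termini
#' carry the repeat -- the convention used to rearrange mis-ordered phage
#' assemblies around their true termini.
#'
#' @param genome `annotated_genome` or sequence string.
#' @param dtr_hit_interval 0-based half-open interval `c(start, end)` of the
#'   DTR hit (e.g. a row of [locate_dtr_by_reference()]).
#' @return an `annotated_genome` whose provenance records the rotation
#'   amount and the collapsed terminal-repeat length; features are remapped
#'   modulo the circular length (features crossing the new origin carry
#'   `wraps_origin = TRUE`).
#' @export
reorient_to_dtr <- function(genome, dtr_hit_interval) {
  seq <- as_genome_seq(genome)
  n <- nchar(seq)
  if (is.data.frame(dtr_hit_interval))
    dtr_hit_interval <- c(dtr_hit_interval$start[1], dtr_hit_interval$end[1])
  s0 <- as.integer(dtr_hit_interval[1]); e0 <- as.integer(dtr_hit_interval[2])
  if (s0 < 0 || e0 > n || e0 <= s0)
    stop("DTR hit interval out of genome bounds")
  dtr_len <- e0 - s0
  tr <- find_terminal_repeat(seq)
  collapsed <- if (!is.null(tr)) tr$length else 0L
  circ <- if (collapsed > 0) substr(seq, 1L, n - collapsed) else seq
  Lc <- nchar(circ)
  rot <- s0 %% Lc
  rotated <- if (rot == 0) circ else
    paste0(substr(circ, rot + 1L, Lc), substr(circ, 1L, rot))
  out_seq <- paste0(rotated, substr(rotated, 1L, min(dtr_len, Lc)))
  ft <- if (inherits(genome, "annotated_genome")) genome$features
        else empty_features()
  if (nrow(ft)) {
    w <- ft$end - ft$start
    ns <- (ft$start %% Lc - rot) %% Lc
    ft <- data.frame(type = ft$type, start = ns, end = ns + w,
                     strand = ft$strand,
                     wraps_origin = ns + w > Lc + min(dtr_len, Lc),
                     stringsAsFactors = FALSE)
  }
  new_annotated_genome(
    id = paste0(genome_id_of(genome), "_reoriented"),
    seq = out_seq, features = ft,
    provenance = list(generator = "reorient_to_dtr", rotation = rot,
                      collapsed_terminal_repeat = collapsed,
                      appended_dtr = min(dtr_len, Lc)))
}

#' Circularized sequence of a genome
#'
#' Drops the trailing copy of a detected terminal repeat, yielding the
#' sequence of the underlying circular (concatemer-junction) form.  Rotation
#' and reorientation are bijections on this circular sequence.
#'
#' @param genome `annotated_genome` or sequence string.
#' @return sequence string without the 3' terminal-repeat copy.
#' @export
circularize <- function(genome) {
  seq <- as_genome_seq(genome)
  tr <- find_terminal_repeat(seq)
  if (is.null(tr)) seq else substr(seq, 1L, nchar(seq) - tr$length)
}

#' Terminus evidence from alignment-start pileups
#'
#' On a linear genome every read that spans a terminus must start exactly at
#' it, so alignment starts pile up at the true end; under a circular
#' (randomly rotated) model starts are uniform.  Positions whose start count
#' exceeds the uniform-start null (mean `N/L`) by at least `z_threshold`
#' standard deviations are reported, merged within 5 bp.
#'
#' @param genome `annotated_genome` or sequence string (defines the length).
#' @param alignments alignment records (>= 100 required).
#' @param z_threshold minimum z-score against the uniform null.
#' @return data.frame (`position`, `start_pileup`, `zscore`), strongest
#'   position per 5 bp cluster, sorted by position.
#' @export
termini_from_alignments <- function(genome, alignments, z_threshold = 6) {
  L <- nchar(as_genome_seq(genome))
  N <- nrow(alignments)
  if (N < 100L) stop("need at least 100 alignments for pileup evidence")
  counts <- tabulate(alignments$ref_start + 1L, nbins = L)
  mu <- N / L
  sdv <- sqrt(N * (1 / L) * (1 - 1 / L))
  z <- (counts - mu) / sdv
  idx <- which(z >= z_threshold)
  if (!length(idx)) {
    return(data.frame(position = integer(), start_pileup = integer(),
                      zscore = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, lapply(cluster_within(idx, 5L), function(grp) {
    p <- idx[grp]
    best <- p[which.max(counts[p])]
    data.frame(position = best - 1L, start_pileup = counts[best],
               zscore = z[best], stringsAsFactors = FALSE)
  }))
  out <- out[order(out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Positional G+C profile across a set of DTRs
#'
#' Tiles windows from the 5' end (step 1) and averages per-window G+C across
#' all DTRs, exposing the conserved G+C-rich region at the 5' end of
#' cobavirus-like DTRs.
#'
#' @param dtrs data.frame with a `seq` column (e.g. rows of
#'   [find_terminal_repeat()]) or a character vector of DTR sequences.
#' @param window window width (bp); all DTRs must be at least this long.
#' @return list with `profile` (data.frame `start` 0-based, `gc`) and
#'   `max_window_start` (argmax window).
#' @export
dtr_gc_profile <- function(dtrs, window = 20L) {
  seqs <- if (is.data.frame(dtrs)) dtrs$seq else as.character(dtrs)
  seqs <- toupper(seqs)
  if (any(nchar(seqs) < window)) stop("all DTRs must be at least `window` bp")
  nw <- min(nchar(seqs)) - window + 1L
  per_dtr <- vapply(seqs, function(s) {
    b <- strsplit(s, "", fixed = TRUE)[[1]] %in% c("G", "C")
    cs <- cumsum(c(0L, as.integer(b)))
    (cs[(window + 1L):(window + nw)] - cs[1:nw]) / window
  }, numeric(nw))
  gc <- if (nw == 1L) mean(per_dtr) else rowMeans(as.matrix(per_dtr))
  profile <- data.frame(start = 0:(nw - 1L), gc = gc)
  list(profile = profile, max_window_start = profile$start[which.max(gc)])
}
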