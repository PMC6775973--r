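# synthetic_data: phage genomes with planted DTRs and bidirectional
# terminators, diverged relatives, and mixed-community read libraries with
# ground-truth alignments.  Every generator takes an explicit seed and is
# bit-reproducible.

TERM_STEM <- 12L   # planted hairpin stem (bp, all G/C)
TERM_LOOP <- 4L    # planted loop (bp)
TERM_TRACT <- 6L   # planted poly-T / poly-A tract length (bp)

#' Specification of a synthetic phage genome
#'
#' Defaults mirror a typical cobavirus-like genome: ~40 kb linear genome at
#' G+C 0.47 carrying a ~170 bp direct terminal repeat and a bidirectional
#' terminator between the two genomic arms.
#'
#' @param length genome length (bp).
#' @param gc G+C content in (0,1).
#' @param dtr_length direct terminal repeat length (bp, 0 disables; must be
#'   `< length/4`).
#' @param terminator_offset position of the planted hairpin as a fraction of
#'   genome length in (0,1).
#' @param seed integer RNG seed.
#' @return a `genome_spec` list.
#' @export
genome_spec <- function(length = 40000L, gc = 0.47, dtr_length = 170L,
                        terminator_offset = 0.5, seed = 1L) {
  stopifnot(length > 0, gc > 0, gc < 1,
            terminator_offset > 0, terminator_offset < 1)
  if (dtr_length < 0 || dtr_length >= length / 4)
    stop("dtr_length must satisfy 0 <= dtr_length < length/4")
  structure(list(length = as.integer(length), gc = gc,
                 dtr_length = as.integer(dtr_length),
                 terminator_offset = terminator_offset,
                 seed = as.integer(seed)),
            class = "genome_spec")
}

new_annotated_genome <- function(id, seq, features, provenance) {
  structure(list(id = id, seq = seq, features = features,
                 provenance = provenance),
            class = "annotated_genome")
}

#' @export
print.annotated_genome <- function(x, ...) {
  cat(sprintf("<annotated_genome> %s: %d bp, GC %.3f, %d feature(s)\n",
              x$id, nchar(x$seq), gc_fraction(x$seq),
              if (is.null(x$features)) 0L else nrow(x$features)))
  invisible(x)
}

#' @export
as.character.annotated_genome <- function(x, ...) x$seq

#' Length of an annotated genome (bp)
#' @param genome an `annotated_genome`.
#' @return integer length.
#' @export
genome_length <- function(genome) nchar(as_genome_seq(genome))

empty_features <- function() {
  data.frame(type = character(), start = integer(), end = integer(),
             strand = character(), stringsAsFactors = FALSE)
}

# build the planted bidirectional terminator cassette:
#   A-tract | left stem (G/C) | loop | revcomp(left stem) | T-tract
# so that each strand sees a hairpin followed downstream by a T-tract.
make_terminator_cassette <- function() {
  stem <- paste(sample(c("G", "C"), TERM_STEM, replace = TRUE), collapse = "")
  loop <- paste(sample(DNA_BASES, TERM_LOOP, replace = TRUE), collapse = "")
  paste0(strrep("A", TERM_TRACT), stem, loop, revcomp(stem),
         strrep("T", TERM_TRACT))
}

#' Simulate a linear phage genome with planted DTR and terminator
#'
#' The generated sequence starts and ends with an identical direct terminal
#' repeat whose first 30 bp are drawn at elevated G+C (`gc + 0.15`, capped at
#' 0.9), emulating the conserved G+C-rich 5' region of cobaviral DTRs.  A
#' palindromic hairpin cassette (12 bp all-G/C stem, 4 bp loop, 6 bp A/T
#' tracts flanking so that both strands carry a downstream T-tract) is
#' written at `terminator_offset * length`, marking the boundary between the
#' two genomic arms.  Annotations record the DTR copies, the terminator
#' hairpin and the arm boundary in 0-based half-open coordinates.
#'
#' @param spec a [genome_spec()].
#' @return an `annotated_genome` (fields `id`, `seq`, `features`,
#'   `provenance`); identical spec (including seed) gives identical output.
#' @export
simulate_genome <- function(spec = genome_spec()) {
  stopifnot(inherits(spec, "genome_spec"))
  L <- spec$length; dtr <- spec$dtr_length
  hp_len <- 2L * TERM_STEM + TERM_LOOP
  t0 <- as.integer(round(spec$terminator_offset * L))
  if (t0 - TERM_TRACT <= dtr || t0 + hp_len + TERM_TRACT >= L - dtr)
    stop("terminator_offset places the cassette inside the terminal repeat")
  with_seed(spec$seed, {
    dtr_seq <- if (dtr > 0) {
      gc_head <- min(spec$gc + 0.15, 0.9)
      nh <- min(30L, dtr)
      paste0(random_dna(nh, gc_head), random_dna(dtr - nh, spec$gc))
    } else ""
    body <- random_dna(L - 2L * dtr, spec$gc)
    seq <- paste0(dtr_seq, body, dtr_seq)
    cassette <- make_terminator_cassette()
    c0 <- t0 - TERM_TRACT              # 0-based cassette start
    seq <- paste0(substr(seq, 1L, c0),
                  cassette,
                  substr(seq, c0 + nchar(cassette) + 1L, L))
    stopifnot(nchar(seq) == L)
    ft <- data.frame(
      type = c("terminator_hairpin", "arm_boundary"),
      start = c(t0, t0 + hp_len %/% 2L),
      end = c(t0 + hp_len, t0 + hp_len %/% 2L + 1L),
      strand = c("*", "*"), stringsAsFactors = FALSE)
    if (dtr > 0) {
      ft <- rbind(data.frame(type = c("dtr_5p", "dtr_3p"),
                             start = c(0L, L - dtr), end = c(dtr, L),
                             strand = c("*", "*"), stringsAsFactors = FALSE),
                  ft)
    }
    new_annotated_genome(
      id = sprintf("simphage_%d", spec$seed),
      seq = seq, features = ft,
      provenance = list(generator = "simulate_genome", spec = unclass(spec)))
  })
}

#' Introduce i.i.d. substitutions into a genome
#'
#' Each base is substituted with probability `subst_rate`, uniformly over the
#' three alternative bases, so the expected nucleotide identity to the parent
#' is `1 - subst_rate`.  Annotations are carried over with unchanged
#' coordinates.
#'
#' @param genome `annotated_genome` or sequence string.
#' @param subst_rate per-base substitution probability in \[0, 0.5).
#' @param seed integer RNG seed.
#' @return an `annotated_genome`.
#' @export
diverge_genome <- function(genome, subst_rate, seed = 1L) {
  stopifnot(subst_rate >= 0, subst_rate < 0.5)
  seq <- as_genome_seq(genome)
  id <- genome_id_of(genome)
  with_seed(seed, {
    b <- strsplit(seq, "", fixed = TRUE)[[1]]
    hit <- which(runif(length(b)) < subst_rate)
    if (length(hit)) {
      b[hit] <- vapply(b[hit], function(x) {
        sample(setdiff(DNA_BASES, x), 1L)
      }, character(1), USE.NAMES = FALSE)
    }
    new_annotated_genome(
      id = paste0(id, "_div"),
      seq = paste(b, collapse = ""),
      features = if (inherits(genome, "annotated_genome"))
        genome$features else empty_features(),
      provenance = list(generator = "diverge_genome", parent = id,
                        subst_rate = subst_rate, seed = seed,
                        n_substituted = length(hit)))
  })
}

# internal read simulator core; n_reads overrides the depth-derived count
simulate_reads_core <- function(seq, gid, n_reads, read_length, subst_rate,
                                indel_rate, base_quality, decay_to,
                                id_prefix = "read") {
  L <- nchar(seq); rl <- as.integer(read_length)
  starts <- sample.int(L - rl + 1L, n_reads, replace = TRUE) - 1L
  strands <- sample(c("+", "-"), n_reads, replace = TRUE)
  templates <- substring(seq, starts + 1L, starts + rl)

  # substitutions, vectorized over the concatenated template bases
  big <- strsplit(paste(templates, collapse = ""), "", fixed = TRUE)[[1]]
  n_sub_per <- integer(n_reads)
  if (subst_rate > 0) {
    hit <- which(runif(length(big)) < subst_rate)
    if (length(hit)) {
      big[hit] <- vapply(big[hit], function(x)
        sample(setdiff(DNA_BASES, x), 1L), character(1), USE.NAMES = FALSE)
      n_sub_per <- tabulate((hit - 1L) %/% rl + 1L, nbins = n_reads)
    }
  }
  reads <- substring(paste(big, collapse = ""),
                     (seq_len(n_reads) - 1L) * rl + 1L,
                     seq_len(n_reads) * rl)

  n_ins_per <- integer(n_reads); n_del_per <- integer(n_reads)
  if (indel_rate > 0) {
    # single-base indels, insertion and deletion equiprobable; applied
    # per read only where drawn (rare at realistic rates)
    n_events <- rbinom(n_reads, rl, indel_rate)
    for (i in which(n_events > 0)) {
      b <- strsplit(reads[i], "", fixed = TRUE)[[1]]
      for (e in seq_len(n_events[i])) {
        p <- sample.int(length(b), 1L)
        if (runif(1) < 0.5) {          # insertion after p
          b <- append(b, sample(DNA_BASES, 1L), after = p)
          n_ins_per[i] <- n_ins_per[i] + 1L
        } else {                        # deletion of p
          b <- b[-p]
          n_del_per[i] <- n_del_per[i] + 1L
        }
      }
      reads[i] <- paste(b, collapse = "")
    }
  }

  flip <- strands == "-"
  if (any(flip)) {
    reads[flip] <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(reads[flip])))
  }

  qual_for_len <- function(len) {
    q <- if (is.null(decay_to)) rep(base_quality, len)
         else round(seq(base_quality, decay_to, length.out = len))
    phred_encode(q)
  }
  lens <- nchar(reads)
  qtab <- vapply(sort(unique(lens)), qual_for_len, character(1))
  names(qtab) <- sort(unique(lens))
  quals <- qtab[as.character(lens)]

  ids <- sprintf("%s_%06d", id_prefix, seq_len(n_reads))
  matches <- rl - n_sub_per - n_del_per
  truth <- alignment_records(
    read_id = ids, genome_id = gid,
    ref_start = starts, ref_end = starts + rl,
    strand = strands,
    matches = matches, mismatches = n_sub_per,
    insertions = n_ins_per, deletions = n_del_per)
  reads_df <- data.frame(
    id = ids,
    desc = sprintf("pos=%d strand=%s", starts, strands),
    seq = reads, qual = unname(quals), stringsAsFactors = FALSE)
  list(reads = reads_df, truth = truth)
}

#' Simulate shotgun reads from a single genome
#'
#' Read start positions are uniform over the linear genome (no circular
#' wrap), about half the reads are reverse-complemented, and per-base errors
#' are i.i.d.: substitutions uniform over the three alternatives, single-base
#' indels with equiprobable insertion/deletion.  The returned truth table
#' records each read's error-free placement and edit counts as alignment
#' records.
#'
#' @param genome `annotated_genome` or sequence string.
#' @param depth target mean coverage (x-fold); `round(depth*L/read_length)`
#'   reads are generated.
#' @param read_length read length before indels (bp).
#' @param subst_rate,indel_rate per-base error probabilities.
#' @param seed integer RNG seed.
#' @param base_quality constant Phred score assigned to read bases.
#' @param decay_to if non-NULL, per-read qualities decay linearly from
#'   `base_quality` at the 5' end to `decay_to` at the 3' end (for testing
#'   quality trimming).
#' @return list with `reads` (data.frame `id`, `desc`, `seq`, `qual`) and
#'   `truth` (alignment records of the planted placements).
#' @export
simulate_reads <- function(genome, depth, read_length = 150L,
                           subst_rate = 0, indel_rate = 0, seed = 1L,
                           base_quality = 37L, decay_to = NULL) {
  seq <- as_genome_seq(genome)
  stopifnot(read_length < nchar(seq), depth > 0)
  n_reads <- max(1L, as.integer(round(depth * nchar(seq) / read_length)))
  with_seed(seed,
    simulate_reads_core(seq, genome_id_of(genome), n_reads, read_length,
                        subst_rate, indel_rate, base_quality, decay_to))
}

#' Specification of a mixed phage community
#'
#' @param members list of `annotated_genome` objects (or sequence strings).
#' @param weights per-member relative abundance weights (summing to 1).
#' @param total_bases total read bases to generate across the community.
#' @param read_length read length (bp).
#' @param subst_rate,indel_rate per-base error probabilities.
#' @param seed integer RNG seed.
#' @return a `community_spec` list.
#' @export
community_spec <- function(members, weights, total_bases,
                           read_length = 150L, subst_rate = 0,
                           indel_rate = 0, seed = 1L) {
  stopifnot(length(members) == length(weights), all(weights > 0))
  if (abs(sum(weights) - 1) > 1e-8)
    stop("community weights must sum to 1")
  structure(list(members = members, weights = weights,
                 total_bases = total_bases, read_length = as.integer(read_length),
                 subst_rate = subst_rate, indel_rate = indel_rate,
                 seed = as.integer(seed)),
            class = "community_spec")
}

#' Simulate a mixed-community read library with planted truth
#'
#' Genome g receives `weight_g * total_bases` read bases in expectation
#' (multinomial read allocation).  The truth table reports, per genome, the
#' planted aligned bases and the implied per-Gb abundance
#' `planted_bases / genome_length / (library_bases / 1e9)`, which the
#' recruitment module should recover.
#'
#' @param spec a [community_spec()].
#' @return list with `reads` (all members, shuffled order), `truth`
#'   (per-genome table: `genome_id`, `genome_length`, `n_reads`,
#'   `planted_bases`, `planted_abundance`), and `alignments` (planted
#'   alignment records).
#' @export
simulate_community <- function(spec) {
  stopifnot(inherits(spec, "community_spec"))
  with_seed(spec$seed, {
    n_total <- max(1L, as.integer(round(spec$total_bases / spec$read_length)))
    counts <- as.integer(rmultinom(1, n_total, spec$weights))
    gids <- vapply(seq_along(spec$members), function(i)
      genome_id_of(spec$members[[i]], default = paste0("member", i)),
      character(1))
    parts <- lapply(seq_along(spec$members), function(i) {
      if (counts[i] == 0L) return(NULL)
      simulate_reads_core(as_genome_seq(spec$members[[i]]), gids[i],
                          counts[i], spec$read_length, spec$subst_rate,
                          spec$indel_rate, base_quality = 37L,
                          decay_to = NULL, id_prefix = paste0(gids[i], "_r"))
    })
    reads <- do.call(rbind, lapply(parts, `[[`, "reads"))
    truth_aln <- do.call(rbind, lapply(parts, `[[`, "truth"))
    ord <- sample.int(nrow(reads))
    reads <- reads[ord, , drop = FALSE]
    rownames(reads) <- NULL
    library_bases <- sum(nchar(reads$seq))
    glens <- vapply(spec$members, function(g) nchar(as_genome_seq(g)),
                    numeric(1))
    planted <- counts * spec$read_length
    truth <- data.frame(
      genome_id = gids, genome_length = glens, n_reads = counts,
      planted_bases = planted,
      planted_abundance = planted / glens / (library_bases / 1e9),
      stringsAsFactors = FALSE)
    list(reads = reads, truth = truth, alignments = truth_aln,
         library_bases = library_bases)
  })
}

#' Shuffle a genome preserving dinucleotide composition
#'
#' Resamples the sequence from its own first-order Markov (dinucleotide
#' transition) model, preserving mono- and dinucleotide composition in
#' expectation while destroying all longer-range structure.  Used as the
#' negative control for hairpin/terminator scanning.
#'
#' @param genome `annotated_genome` or sequence string.
#' @param seed integer RNG seed.
#' @return shuffled sequence string of the same length.
#' @export
shuffle_genome <- function(genome, seed = 1L) {
  seq <- as_genome_seq(genome)
  b <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(b)
  idx <- match(b, DNA_BASES)
  trans <- matrix(0, 4, 4, dimnames = list(DNA_BASES, DNA_BASES))
  tab <- table(factor(idx[-n], levels = 1:4), factor(idx[-1], levels = 1:4))
  trans[] <- as.numeric(tab)
  trans <- trans + 1e-9          # guard empty rows
  trans <- trans / rowSums(trans)
  with_seed(seed, {
    out <- integer(n)
    out[1] <- idx[1]
    u <- runif(n - 1L)
    cum <- t(apply(trans, 1, cumsum))
    for (i in 2:n) {
      out[i] <- findInterval(u[i - 1L], cum[out[i - 1L], ]) + 1L
    }
    paste(DNA_BASES[out], collapse = "")
  })
}
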