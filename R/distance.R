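# distance: completeness length filter, fragment-based nucleotide identity
# (an ANI surrogate for genome-BLAST distances), and OPTSIL-style F-linkage
# threshold clustering for species/genus delineation.

#' Completeness filter on contig length
#'
#' Contigs smaller than `min_len` (default 34 kb, ~85% of a complete
#' cobavirus-like genome) are considered incomplete; the boundary is
#' inclusive (`>= min_len` retained).
#'
#' @param contigs genome database (data.frame `id`/`seq`, named character
#'   vector, or list of `annotated_genome`).
#' @param min_len minimum retained length (bp).
#' @return list with `retained` and `discarded` named character vectors,
#'   input order preserved.
#' @export
length_filter <- function(contigs, min_len = 34000L) {
  db <- as_genome_db(contigs)
  keep <- nchar(db) >= min_len
  list(retained = db[keep], discarded = db[!keep])
}

# one direction of the fragment comparison: tile `query` and align each
# fragment to `subject` (both strands, seed-and-extend)
fragment_identity_dir <- function(query, subject, frag_len,
                                  min_frag_identity, k, band) {
  nf <- nchar(query) %/% frag_len
  if (nf == 0) stop("genome shorter than one fragment")
  starts <- (seq_len(nf) - 1L) * frag_len
  frags <- data.frame(
    id = sprintf("frag_%04d", seq_len(nf)),
    seq = substring(query, starts + 1L, starts + frag_len),
    stringsAsFactors = FALSE)
  aln <- align_reads(frags, c(subject_genome = subject), k = k, band = band)
  if (nrow(aln) == 0) return(c(identity = NA_real_, aligned_fraction = 0))
  ident <- alignment_identity(aln)
  ok <- ident >= min_frag_identity
  if (!any(ok)) return(c(identity = NA_real_, aligned_fraction = 0))
  c(identity = mean(ident[ok]), aligned_fraction = sum(ok) / nf)
}

#' Fragment-based nucleotide identity between two genomes
#'
#' Tiles each genome into non-overlapping `frag_len` windows, aligns every
#' fragment to the other genome (both strands, seed-and-extend), and
#' averages the identity of aligned fragments; symmetrized by averaging the
#' two directions.  This is a fragment-ANI surrogate for genome-BLAST
#' intergenomic distances: close relatives diverged by substitutions at rate
#' r recover identity `1 - r`.
#'
#' @param g1,g2 `annotated_genome` or sequence strings (each >= `frag_len`).
#' @param frag_len fragment length (bp).
#' @param min_frag_identity minimum identity for a fragment to count as
#'   aligned.
#' @param k,band aligner tuning (see [align_reads()]).
#' @return named vector `c(identity, aligned_fraction)`; identity is `NA`
#'   when no fragment aligns in either direction.
#' @export
fragment_identity <- function(g1, g2, frag_len = 1020L,
                              min_frag_identity = 0.3, k = 15L,
                              band = 16L) {
  s1 <- as_genome_seq(g1); s2 <- as_genome_seq(g2)
  stopifnot(nchar(s1) >= frag_len, nchar(s2) >= frag_len)
  d12 <- fragment_identity_dir(s1, s2, frag_len, min_frag_identity, k, band)
  d21 <- fragment_identity_dir(s2, s1, frag_len, min_frag_identity, k, band)
  ids <- c(d12["identity"], d21["identity"])
  identity <- if (all(is.na(ids))) NA_real_ else mean(ids, na.rm = TRUE)
  c(identity = unname(identity),
    aligned_fraction = unname(mean(c(d12["aligned_fraction"],
                                     d21["aligned_fraction"]))))
}

#' Pairwise intergenomic distance matrix
#'
#' `d = 1 - identity` from [fragment_identity()] for every pair (point
#' estimates, no replicates); pairs with no alignable fragments get
#' distance 1.
#'
#' @param genomes genome database of at least two genomes.
#' @param frag_len,min_frag_identity,k,band passed to [fragment_identity()].
#' @return a `distance_matrix`: list with `ids`, `d` (symmetric, zero
#'   diagonal) and `aligned_fraction` (companion symmetric matrix).
#' @export
distance_matrix <- function(genomes, frag_len = 1020L,
                            min_frag_identity = 0.3, k = 15L, band = 16L) {
  db <- as_genome_db(genomes)
  n <- length(db)
  if (n < 2) stop("need at least two genomes")
  ids <- names(db)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  af <- matrix(1, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    fi <- fragment_identity(db[[i]], db[[j]], frag_len, min_frag_identity,
                            k, band)
    dij <- if (is.na(fi["identity"])) 1 else 1 - fi[["identity"]]
    d[i, j] <- d[j, i] <- dij
    af[i, j] <- af[j, i] <- fi[["aligned_fraction"]]
  }
  structure(list(ids = ids, d = d, aligned_fraction = af),
            class = "distance_matrix")
}

#' Threshold-clustering parameters
#'
#' @param threshold distance cutoff in \[0,1\] below which a pair counts as
#'   linked.
#' @param f_link fraction of inter-cluster links required for cluster
#'   fusion, in (0,1\] (OPTSIL's F parameter; 0.5 by convention).
#' @return a `cluster_params` list.
#' @export
cluster_params <- function(threshold, f_link = 0.5) {
  stopifnot(threshold >= 0, threshold <= 1, f_link > 0, f_link <= 1)
  structure(list(threshold = threshold, f_link = f_link),
            class = "cluster_params")
}

#' F-linkage (OPTSIL-style) agglomerative clustering
#'
#' Starting from singletons, repeatedly merges the pair of clusters with the
#' highest link fraction -- the fraction of inter-cluster pairs at distance
#' `<= threshold` -- while that fraction is at least `f_link`.  Ties are
#' broken first by the smallest maximum inter-cluster distance and then by
#' the lexicographically smallest member ids, which makes `f_link = 1`
#' coincide exactly with a complete-linkage cut at `threshold` (complete
#' linkage is monotone, so every sub-threshold merge precedes all others in
#' height order); as `f_link` approaches 0 the result approaches
#' single-linkage (connected components of the threshold graph).
#'
#' @param dm a `distance_matrix` from [distance_matrix()], or a plain
#'   symmetric numeric matrix with dimnames.
#' @param params a [cluster_params()] object.
#' @return a `cluster_set` (see [markov_cluster()] for the structure).
#' @export
f_link_cluster <- function(dm, params) {
  stopifnot(inherits(params, "cluster_params"))
  d <- if (inherits(dm, "distance_matrix")) dm$d else as.matrix(dm)
  ids <- rownames(d)
  if (is.null(ids)) ids <- colnames(d)
  if (is.null(ids)) ids <- paste0("g", seq_len(nrow(d)))
  if (!isSymmetric(unname(d), tol = 1e-9))
    stop("distance matrix must be symmetric")
  n <- nrow(d)
  clusters <- lapply(seq_len(n), identity)
  repeat {
    if (length(clusters) < 2) break
    best <- NULL
    for (a in seq_len(length(clusters) - 1L)) {
      for (b in (a + 1L):length(clusters)) {
        cross <- d[clusters[[a]], clusters[[b]], drop = FALSE]
        frac <- mean(cross <= params$threshold)
        if (frac < params$f_link) next
        maxd <- max(cross)
        key <- sort(ids[c(clusters[[a]], clusters[[b]])])
        cand <- list(a = a, b = b, frac = frac, maxd = maxd, key = key)
        if (is.null(best) || frac > best$frac ||
            (frac == best$frac &&
             (maxd < best$maxd ||
              (maxd == best$maxd && key_less(key, best$key))))) {
          best <- cand
        }
      }
    }
    if (is.null(best)) break
    clusters[[best$a]] <- c(clusters[[best$a]], clusters[[best$b]])
    clusters[[best$b]] <- NULL
  }
  clusters <- lapply(clusters, function(ix) sort(ids[ix]))
  clusters <- clusters[order(vapply(clusters, `[`, character(1), 1L))]
  new_cluster_set(clusters,
                  list(threshold = params$threshold, f_link = params$f_link))
}

# lexicographic comparison of two sorted character vectors
key_less <- function(x, y) {
  m <- min(length(x), length(y))
  for (i in seq_len(m)) {
    if (x[i] < y[i]) return(TRUE)
    if (x[i] > y[i]) return(FALSE)
  }
  length(x) < length(y)
}
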