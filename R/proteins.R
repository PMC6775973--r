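# protein_clustering: all-vs-all Smith-Waterman similarity graph with
# BLAST-like bitscore/e-value statistics and an implemented Markov
# clustering (mcl "-I 2 --abc" semantics).

#' All-versus-all protein similarity scores
#'
#' Smith-Waterman local alignment (BLOSUM62, gap open 11 / extend 1) over
#' every unordered pair; scores are symmetric so each pair is computed once.
#' Bitscores and e-values follow Karlin-Altschul statistics with the
#' standard gapped BLOSUM62/11-1 constants (`lambda = 0.267`, `K = 0.041`),
#' with the raw `m x n` search space (no length adjustment):
#' `bits = (lambda*S - ln K)/ln 2`, `E = K*m*n*exp(-lambda*S)`.
#'
#' @param proteins named character vector of amino-acid sequences, or a
#'   data.frame with `id` and `seq` columns.
#' @param lambda,K Karlin-Altschul constants.
#' @param gap_open,gap_extend gap penalties (positive costs).
#' @return data.frame of similarity edges (`a`, `b`, `raw_score`,
#'   `bitscore`, `evalue`).
#' @export
pairwise_protein_scores <- function(proteins, lambda = 0.267, K = 0.041,
                                    gap_open = 11, gap_extend = 1) {
  if (is.data.frame(proteins)) proteins <- setNames(proteins$seq, proteins$id)
  seqs <- toupper(proteins)
  assert_aa(seqs)
  if (any(nchar(seqs) < 10L))
    stop("all protein sequences must be at least 10 aa")
  ids <- names(seqs)
  n <- length(seqs)
  if (n < 2L) {
    return(data.frame(a = character(), b = character(), raw_score = numeric(),
                      bitscore = numeric(), evalue = numeric(),
                      stringsAsFactors = FALSE))
  }
  blosum <- local({
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    e$BLOSUM62
  })
  lens <- nchar(seqs)
  out <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    js <- (i + 1L):n
    sc <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::AAStringSet(seqs[js]),
      subject = Biostrings::AAString(seqs[[i]]),
      type = "local", substitutionMatrix = blosum,
      gapOpening = gap_open, gapExtension = gap_extend,
      scoreOnly = TRUE)
    out[[i]] <- data.frame(
      a = ids[i], b = ids[js], raw_score = sc,
      bitscore = (lambda * sc - log(K)) / log(2),
      evalue = K * lens[i] * lens[js] * exp(-lambda * sc),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Build the thresholded protein similarity graph
#'
#' Keeps edges passing both the e-value and bitscore thresholds
#' (`evalue <= max_evalue` and `bitscore >= min_bitscore`); edge weight is
#' the bitscore.  Proteins left without any passing edge are retained as
#' singleton nodes.
#'
#' @param edges data.frame from [pairwise_protein_scores()].
#' @param nodes character vector of all protein ids (defaults to every id
#'   appearing in `edges`, including filtered ones).
#' @param max_evalue,min_bitscore thresholds.
#' @return weighted undirected [igraph][igraph::graph_from_data_frame] graph.
#' @export
build_graph <- function(edges, nodes = NULL, max_evalue = 1e-5,
                        min_bitscore = 50) {
  if (is.null(nodes)) nodes <- unique(c(edges$a, edges$b))
  keep <- edges$evalue <= max_evalue & edges$bitscore >= min_bitscore
  kept <- edges[keep, , drop = FALSE]
  g <- igraph::graph_from_data_frame(
    kept[, c("a", "b")], directed = FALSE, vertices = data.frame(name = nodes))
  igraph::E(g)$weight <- kept$bitscore
  g
}

#' Markov clustering of a weighted graph
#'
#' Implementation of the MCL process on the column-stochastic transition
#' matrix of the graph: self-loops are added with weight equal to each
#' node's maximum incident edge weight, then expansion (matrix squaring) and
#' inflation (elementwise power, column renormalization) alternate until the
#' maximum elementwise change drops below `tol`.  Clusters are read off the
#' limit matrix attractor-wise (rows with positive diagonal attract their
#' positive-mass columns; overlapping attractor systems are merged), which
#' reproduces mcl's interpretation of the equilibrium state.  Inflation 2.0
#' corresponds to the canonical `mcl -I 2` granularity.
#'
#' @param graph weighted undirected igraph (non-negative weights).
#' @param inflation inflation exponent.
#' @param max_iter iteration cap; non-convergence returns the current
#'   clustering with `converged = FALSE` and a warning.
#' @param tol convergence tolerance on the max elementwise change.
#' @return a `cluster_set`: list with `clusters` (list of id vectors),
#'   `params`, `converged`, `iterations`.
#' @export
markov_cluster <- function(graph, inflation = 2.0, max_iter = 100L,
                           tol = 1e-6) {
  ids <- igraph::V(graph)$name
  n <- length(ids)
  if (n == 0)
    return(new_cluster_set(list(), list(inflation = inflation), TRUE, 0L))
  A <- igraph::as_adjacency_matrix(graph, attr =
    if (is.null(igraph::E(graph)$weight) || igraph::ecount(graph) == 0)
      NULL else "weight", sparse = FALSE)
  if (any(A < 0)) stop("negative edge weights")
  mode(A) <- "double"
  diag(A) <- 0
  loop <- apply(A, 1L, max)
  loop[loop == 0] <- 1
  diag(A) <- loop
  normalize_cols <- function(M) {
    cs <- colSums(M)
    zero <- cs == 0
    if (any(zero)) { M[cbind(which(zero), which(zero))] <- 1; cs[zero] <- 1 }
    sweep(M, 2L, cs, "/")
  }
  M <- normalize_cols(A)
  converged <- FALSE; it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    M2 <- M %*% M
    M2 <- M2 ^ inflation
    M2[M2 < 1e-12] <- 0
    M2 <- normalize_cols(M2)
    delta <- max(abs(M2 - M))
    M <- M2
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("Markov clustering did not converge within max_iter")
  eps <- 1e-6
  attractors <- which(diag(M) > eps)
  if (!length(attractors)) attractors <- seq_len(n)
  member_sets <- lapply(attractors, function(i) which(M[i, ] > eps))
  # merge attractor systems sharing members (union-find)
  parent <- seq_along(attractors)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  owner <- integer(n)
  for (s in seq_along(member_sets)) {
    for (v in member_sets[[s]]) {
      if (owner[v] == 0L) owner[v] <- s
      else {
        a <- find(owner[v]); b <- find(s)
        if (a != b) parent[b] <- a
      }
    }
  }
  grp <- vapply(seq_along(attractors), function(s) find(s), integer(1))
  clusters <- list()
  seen <- integer(0)
  for (s in seq_along(member_sets)) {
    gkey <- grp[s]
    hit <- match(gkey, seen)
    if (is.na(hit)) {
      seen <- c(seen, gkey)
      clusters[[length(clusters) + 1L]] <- member_sets[[s]]
    } else {
      clusters[[hit]] <- union(clusters[[hit]], member_sets[[s]])
    }
  }
  assigned <- unlist(clusters)
  lost <- setdiff(seq_len(n), assigned)
  for (v in lost) clusters[[length(clusters) + 1L]] <- v
  clusters <- lapply(clusters, function(ix) sort(ids[sort(ix)]))
  clusters <- clusters[order(vapply(clusters, `[`, character(1), 1L))]
  new_cluster_set(clusters,
                  list(inflation = inflation, tol = tol,
                       self_loops = "max incident weight"),
                  converged, it)
}

new_cluster_set <- function(clusters, params, converged = TRUE,
                            iterations = NA_integer_) {
  structure(list(clusters = clusters, params = params,
                 converged = converged, iterations = iterations),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  sizes <- lengths(x$clusters)
  cat(sprintf("<cluster_set> %d cluster(s) over %d item(s)%s\n",
              length(sizes), sum(sizes),
              if (isTRUE(x$converged)) "" else " [not converged]"))
  invisible(x)
}

#' Cluster membership as a data frame
#' @param x a `cluster_set`.
#' @param ... unused.
#' @return data.frame with `item` and `cluster` (1-based index, clusters
#'   ordered by their lexicographically smallest member).
#' @export
membership_table <- function(x, ...) {
  stopifnot(inherits(x, "cluster_set"))
  data.frame(
    item = unlist(x$clusters),
    cluster = rep(seq_along(x$clusters), lengths(x$clusters)),
    stringsAsFactors = FALSE, row.names = NULL)
}
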