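# protein_clustering: similarity graph thresholds and Markov clustering

test_that("self-similar and unrelated proteins score as expected", {
  set.seed(301)
  p <- random_protein(100)
  edges <- pairwise_protein_scores(c(a = p, b = p))
  expect_equal(nrow(edges), 1L)
  expect_lt(edges$evalue, 1e-5)
  expect_gt(edges$bitscore, 50)
  # bitscore/e-value follow Karlin-Altschul from the raw score
  expect_equal(edges$bitscore,
               (0.267 * edges$raw_score - log(0.041)) / log(2))
  expect_equal(edges$evalue,
               0.041 * 100 * 100 * exp(-0.267 * edges$raw_score))

  # random unrelated pairs sit below the bitscore threshold
  rnd <- setNames(replicate(8, random_protein(100)), paste0("u", 1:8))
  redges <- pairwise_protein_scores(rnd)
  expect_true(all(redges$bitscore < 50))

  expect_error(pairwise_protein_scores(c(x = "MKV1LA*ZZZ?", y = p)), "amino")
  expect_error(pairwise_protein_scores(c(x = "MKVLA", y = p)), "10 aa")
})

test_that("protein scores are symmetric under input order", {
  set.seed(302)
  prots <- setNames(c(random_protein(80), mutate_protein(random_protein(80), 0),
                      random_protein(120)), c("p1", "p2", "p3"))
  e1 <- pairwise_protein_scores(prots)
  e2 <- pairwise_protein_scores(rev(prots))
  key <- function(e) {
    k <- apply(cbind(pmin(e$a, e$b), pmax(e$a, e$b)), 1, paste, collapse = "|")
    e$raw_score[order(k)]
  }
  expect_equal(key(e1), key(e2))
})

test_that("graph thresholds are conjunctive with exact boundaries", {
  edges <- data.frame(
    a = c("p1", "p1", "p2"), b = c("p2", "p3", "p3"),
    raw_score = c(200, 200, 200),
    bitscore = c(49.9, 60, 55),
    evalue = c(1e-9, 1e-4, 1e-6))
  g <- build_graph(edges, nodes = c("p1", "p2", "p3", "lonely"))
  expect_equal(igraph::vcount(g), 4L)         # singleton retained
  expect_equal(igraph::ecount(g), 1L)         # 49.9 and 1e-4 both dropped
  expect_true(igraph::are_adjacent(g, "p2", "p3"))

  clique_edges <- do.call(rbind, lapply(combn(5, 2, simplify = FALSE),
    function(ij) data.frame(a = paste0("c", ij[1]), b = paste0("c", ij[2]),
                            raw_score = 300, bitscore = 80, evalue = 1e-20)))
  gc <- build_graph(clique_edges)
  expect_equal(igraph::ecount(gc), 10L)
})

test_that("Markov clustering resolves disconnected cliques and singletons", {
  mk_clique <- function(ids, w = 60) do.call(rbind, lapply(
    combn(length(ids), 2, simplify = FALSE),
    function(ij) data.frame(a = ids[ij[1]], b = ids[ij[2]],
                            raw_score = w, bitscore = w, evalue = 1e-20)))
  edges <- rbind(mk_clique(paste0("x", 1:4)), mk_clique(paste0("y", 1:4)))
  g <- build_graph(edges, nodes = c(paste0("x", 1:4), paste0("y", 1:4), "solo"))
  cs <- markov_cluster(g)
  expect_true(cs$converged)
  part <- canonical_partition(cs$clusters)
  expect_equal(part, canonical_partition(list(paste0("x", 1:4),
                                              paste0("y", 1:4), "solo")))
})

test_that("planted 3-block graphs match the connected-components oracle", {
  set.seed(303)
  blocks <- split(sprintf("n%02d", 1:20), rep(1:3, c(7, 7, 6)))
  edges <- do.call(rbind, lapply(blocks, function(ids) do.call(rbind, lapply(
    combn(length(ids), 2, simplify = FALSE),
    function(ij) data.frame(a = ids[ij[1]], b = ids[ij[2]],
                            raw_score = 60, bitscore = 60, evalue = 1e-20)))))
  g <- build_graph(edges)
  cs <- markov_cluster(g)
  comp <- igraph::components(g)
  expect_equal(canonical_partition(cs$clusters),
               partition_from_membership(comp$membership))
})

test_that("clustering is invariant under protein id relabeling", {
  set.seed(304)
  fam <- function(tag) {
    anc <- random_protein(110)
    setNames(replicate(4, mutate_protein(anc, 0.2)), paste0(tag, 1:4))
  }
  prots <- c(fam("a"), fam("b"))
  cs1 <- markov_cluster(build_graph(pairwise_protein_scores(prots),
                                    nodes = names(prots)))
  relabel <- setNames(sprintf("z%02d", sample(8)), names(prots))
  prots2 <- setNames(prots, relabel[names(prots)])
  cs2 <- markov_cluster(build_graph(pairwise_protein_scores(prots2),
                                    nodes = names(prots2)))
  mapped <- canonical_partition(lapply(cs1$clusters,
                                       function(cl) unname(relabel[cl])))
  expect_equal(mapped, canonical_partition(cs2$clusters))
})

test_that("synthetic protein families are recovered exactly", {
  set.seed(305)
  fams <- lapply(1:4, function(f) {
    anc <- random_protein(sample(90:150, 1))
    setNames(replicate(4, mutate_protein(anc, 0.25)),
             sprintf("fam%d_m%d", f, 1:4))
  })
  prots <- unlist(fams)
  edges <- pairwise_protein_scores(prots)
  cs <- markov_cluster(build_graph(edges, nodes = names(prots)))
  expect_equal(canonical_partition(cs$clusters),
               canonical_partition(lapply(fams, names)))
})
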