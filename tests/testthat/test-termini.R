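# termini: DTR detection, reference anchoring, reorientation, pileups

test_that("planted terminal repeats are recovered exactly", {
  set.seed(201)
  R <- random_dna_str(170)
  g <- paste0(R, random_dna_str(9660), R)
  tr <- find_terminal_repeat(g)
  expect_equal(tr$length, 170L)
  expect_equal(tr$mismatches, 0L)
  expect_identical(tr$seq, R)
  expect_equal(c(tr$five_start, tr$five_end), c(0L, 170L))
  expect_equal(c(tr$three_start, tr$three_end), c(10000L - 170L, 10000L))
})

test_that("mismatch tolerance admits slightly diverged repeat copies", {
  set.seed(202)
  R <- random_dna_str(170)
  b <- strsplit(R, "")[[1]]
  for (p in c(40, 120)) b[p] <- setdiff(c("A", "C", "G", "T"), b[p])[1]
  g <- paste0(R, random_dna_str(6000), paste(b, collapse = ""))
  tr <- find_terminal_repeat(g)           # 2/170 = 0.012 <= 0.02
  expect_equal(tr$length, 170L)
  expect_equal(tr$mismatches, 2L)

  for (p in c(10, 60, 90, 150)) b[p] <- setdiff(c("A", "C", "G", "T"), b[p])[1]
  g6 <- paste0(R, random_dna_str(6000), paste(b, collapse = ""))
  tr6 <- find_terminal_repeat(g6)         # 6/170 = 0.035 > 0.02
  expect_true(is.null(tr6) || tr6$length < 170)
})

test_that("random sequence yields no repeat; detection is strand-invariant", {
  set.seed(203)
  g <- random_dna_str(10000)
  expect_null(find_terminal_repeat(g))

  gp <- paste0(substr(g, 1, 160), substr(g, 161, 9840), substr(g, 1, 160))
  fwd <- find_terminal_repeat(gp)
  rev <- find_terminal_repeat(revcomp(gp))
  expect_equal(fwd$length, rev$length)
})

test_that("inverted-repeat mode diagnoses inverted termini separately", {
  set.seed(204)
  R <- random_dna_str(200)
  # inner flanks are forced non-complementary so the repeat cannot extend
  core <- paste0("A", random_dna_str(7998), "A")
  g <- paste0(R, core, revcomp(R))
  expect_null(find_terminal_repeat(g))
  inv <- find_terminal_repeat(g, max_mismatch_frac = 0, mode = "inverted")
  expect_equal(inv$length, 200L)
  expect_equal(inv$mismatches, 0L)
  # under the default tolerance the repeat may over-extend slightly, but
  # its first 200 bases are still the planted copy
  tol <- find_terminal_repeat(g, mode = "inverted")
  expect_gte(tol$length, 200L)
  expect_identical(substr(tol$seq, 1, 200), R)
})

test_that("a reference DTR locates exact and diverged copies, not noise", {
  set.seed(205)
  dtr <- random_dna_str(170)
  target <- paste0(random_dna_str(3000), dtr, random_dna_str(3000))
  hits <- locate_dtr_by_reference(target, dtr)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$identity, 1.0)
  expect_equal(c(hits$start, hits$end), c(3000L, 3170L))

  # 20% substitution divergence: cross-genome DTRs sit in the 70-100% band
  b <- strsplit(dtr, "")[[1]]
  mut <- which(runif(170) < 0.20)
  b[mut] <- vapply(b[mut], function(x)
    sample(setdiff(c("A", "C", "G", "T"), x), 1), character(1))
  target2 <- paste0(random_dna_str(2000), paste(b, collapse = ""),
                    random_dna_str(2000))
  hits2 <- locate_dtr_by_reference(target2, dtr)
  expect_equal(nrow(hits2), 1L)
  expect_lt(abs(hits2$identity - (1 - length(mut) / 170)), 0.05)

  expect_equal(nrow(locate_dtr_by_reference(random_dna_str(5000), dtr)), 0L)
})

test_that("reorientation is the identity on DTR-first genomes", {
  set.seed(206)
  R <- random_dna_str(170)
  g <- paste0(R, random_dna_str(7660), R)
  out <- reorient_to_dtr(g, c(0L, 170L))
  expect_identical(out$seq, g)
  expect_equal(out$provenance$rotation, 0L)
})

test_that("reorientation inverts an arbitrary rotation exactly", {
  g <- simulate_genome(genome_spec(length = 12000, dtr_length = 165,
                                   seed = 11))
  circ <- circularize(g)
  expect_equal(nchar(circ), 12000L - 165L)
  for (r in c(1000L, 5000L, 11000L)) {
    rotated <- paste0(substr(circ, r + 1, nchar(circ)), substr(circ, 1, r))
    hit <- locate_dtr_by_reference(rotated, substr(g$seq, 1, 165))
    expect_equal(nrow(hit), 1L)
    out <- reorient_to_dtr(rotated, hit[1, ])
    expect_identical(out$seq, g$seq)
    # rotation never changes the circular 21-mer multiset
    expect_identical(circular_kmer_multiset(circularize(out)),
                     circular_kmer_multiset(circ))
  }
})

test_that("alignment-start pileups flag linear termini but not circular ones", {
  set.seed(207)
  L <- 4000L; rl <- 150L; N <- 2000L
  # linear model: reads overhanging the left end clip to position 0
  starts <- pmax(0L, sample((-rl + 1L):(L - rl), N, replace = TRUE))
  lin <- alignment_records(
    read_id = sprintf("r%04d", 1:N), genome_id = "g",
    ref_start = starts, ref_end = pmin(starts + rl, L), strand = "+",
    matches = pmin(starts + rl, L) - starts, mismatches = 0L,
    insertions = 0L, deletions = 0L)
  ev <- termini_from_alignments(random_dna_str(L), lin)
  expect_true(0L %in% ev$position)
  expect_gte(max(ev$zscore), 6)

  # circular model: uniformly rotated starts, no pileup anywhere
  circ_starts <- sample(0:(L - 1L), N, replace = TRUE)
  circ <- alignment_records(
    read_id = sprintf("c%04d", 1:N), genome_id = "g",
    ref_start = circ_starts, ref_end = pmin(circ_starts + 1L, L),
    strand = "+", matches = 1L, mismatches = 0L,
    insertions = 0L, deletions = 0L)
  ev2 <- termini_from_alignments(random_dna_str(L), circ)
  expect_equal(nrow(ev2), 0L)

  expect_error(termini_from_alignments(random_dna_str(L), lin[1:50, ]),
               "100")
})

test_that("DTR GC profiles expose a GC-rich 5' region", {
  expect_equal(dtr_gc_profile(strrep("GC", 60))$profile$gc,
               rep(1, 120 - 20 + 1))

  set.seed(208)
  dtrs <- replicate(20, paste0(random_dna_str(30, gc = 0.85),
                               random_dna_str(140, gc = 0.45)))
  prof <- dtr_gc_profile(dtrs)
  expect_lte(prof$max_window_start, 10L)

  single <- random_dna_str(100)
  p1 <- dtr_gc_profile(single)
  b <- strsplit(single, "")[[1]] %in% c("G", "C")
  own <- vapply(1:81, function(i) mean(b[i:(i + 19)]), numeric(1))
  expect_equal(p1$profile$gc, own)
})
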