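# recruitment: cleaning, alignment, identity filtering, breadth/presence,
# per-Gb abundance

test_that("quality trimming applies the end/average/length rules", {
  q37 <- strrep(rawToChar(as.raw(37 + 33)), 50)
  reads <- data.frame(id = "a", desc = "", seq = random_dna_str(50),
                      qual = q37, stringsAsFactors = FALSE)
  out <- clean_reads(reads)
  expect_identical(out$reads$seq, reads$seq)

  # 5 terminal Q10 bases at each end are trimmed (10 bases total)
  q <- paste0(strrep(rawToChar(as.raw(10 + 33)), 5),
              strrep(rawToChar(as.raw(37 + 33)), 40),
              strrep(rawToChar(as.raw(10 + 33)), 5))
  reads2 <- data.frame(id = "b", desc = "", seq = random_dna_str(50),
                       qual = q, stringsAsFactors = FALSE)
  out2 <- clean_reads(reads2)
  expect_equal(nchar(out2$reads$seq), 40L)
  expect_identical(out2$reads$seq, substr(reads2$seq, 6, 45))
  expect_equal(out2$stats$bases_out, 40L)

  expect_error(clean_reads(data.frame(id = "c", seq = "ACGT",
                                      qual = NA_character_)), "qualit")
})

test_that("cleaning of a 3'-decay library matches a per-read recount", {
  g <- simulate_genome(genome_spec(length = 5000, seed = 21))
  sim <- simulate_reads(g, depth = 3, read_length = 100, seed = 22,
                        base_quality = 37, decay_to = 5)
  out <- clean_reads(sim$reads)
  # independent per-read oracle
  survived <- 0L
  for (i in seq_len(nrow(sim$reads))) {
    q <- utf8ToInt(sim$reads$qual[i]) - 33L
    ok <- q >= 20L
    if (!any(ok)) next
    f <- which(ok)[1]; l <- rev(which(ok))[1]
    if (l - f + 1 >= 30 && mean(q[f:l]) >= 20) survived <- survived + 1L
  }
  expect_equal(out$stats$reads_out, survived)
  expect_gt(survived, 0L)
  expect_lt(survived, nrow(sim$reads) + 1L)
})

test_that("seed-and-extend places perfect and reverse-complement reads", {
  set.seed(210)
  g <- c(phageA = random_dna_str(4000))
  read <- substr(g, 1001, 1150)
  aln <- align_reads(data.frame(id = c("fw", "rc"),
                                seq = c(read, revcomp(read))), g)
  expect_equal(nrow(aln), 2L)
  expect_equal(aln$ref_start, c(1000L, 1000L))
  expect_equal(aln$strand, c("+", "-"))
  expect_true(all(alignment_identity(aln) == 1))
})

test_that("aligner identities agree with a full DP oracle at 2% error", {
  g <- c(oracleG = random_dna_str(2000))
  sim <- simulate_reads(g[[1]], depth = 40, read_length = 150,
                        subst_rate = 0.02, indel_rate = 0.002, seed = 23)
  keep <- seq_len(min(250, nrow(sim$reads)))
  reads <- sim$reads[keep, ]
  aln <- align_reads(reads, g)
  expect_gt(nrow(aln), 0.99 * length(keep))   # >= 99% aligned
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2,
                                                 baseOnly = TRUE)
  idx <- match(aln$read_id, reads$id)
  for (i in sample.int(nrow(aln), 40)) {
    rseq <- reads$seq[idx[i]]
    if (aln$strand[i] == "-") rseq <- revcomp(rseq)
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(rseq), Biostrings::DNAString(g[[1]]),
      type = "global-local", substitutionMatrix = sm,
      gapOpening = 0, gapExtension = 3)
    score_mine <- aln$matches[i] - 2 * aln$mismatches[i] -
      3 * (aln$insertions[i] + aln$deletions[i])
    expect_equal(score_mine, Biostrings::score(pa))
    oracle_ident <- Biostrings::nmatch(pa) /
      (Biostrings::nmatch(pa) + Biostrings::nmismatch(pa) +
         sum(Biostrings::width(unlist(Biostrings::insertion(pa)))) +
         sum(Biostrings::width(unlist(Biostrings::deletion(pa)))))
    expect_equal(alignment_identity(aln[i, ]), oracle_ident,
                 tolerance = 0.02)
  }
})

test_that("built-in aligner and SAM ingestion produce identical records", {
  set.seed(211)
  g <- c(refG = random_dna_str(1000))
  read <- substr(g, 201, 320)
  b <- strsplit(read, "")[[1]]; b[30] <- setdiff(c("A","C","G","T"), b[30])[1]
  read <- paste(b, collapse = "")
  internal <- align_reads(data.frame(id = "r1", seq = read), g)
  sam <- withr::local_tempfile(fileext = ".sam")
  write_sam(sam, g, sprintf("r1\t0\trefG\t201\t60\t120M\t*\t0\t0\t%s\t%s\tNM:i:1",
                            read, strrep("I", 120)))
  external <- read_alignments(sam)
  cols <- c("read_id", "genome_id", "ref_start", "ref_end", "strand",
            "matches", "mismatches", "insertions", "deletions")
  expect_equal(internal[cols], external[cols], ignore_attr = TRUE)
})

test_that("identity follows the column formula with inclusive boundary", {
  a <- alignment_records("r", "g", 0, 100, "+", 100, 0, 0, 0)
  expect_equal(alignment_identity(a), 1.0)
  a2 <- alignment_records("r", "g", 0, 100, "+", 90, 10, 0, 0)
  expect_equal(alignment_identity(a2), 0.90)
  p <- recruit(a2, c(g = 200), recruit_params(min_identity = 0.90))
  expect_equal(p$g$passing_reads, 1L)       # "at least 90%" is inclusive
  a3 <- alignment_records("r", "g", 0, 100, "+", 95, 0, 5, 5)
  expect_equal(alignment_identity(a3), 95 / 105)
})

test_that("recruitment accumulates depth and excludes sub-cutoff reads", {
  a <- alignment_records(c("r1", "r2"), "g", c(0, 500), c(150, 650), "+",
                         150, 0, 0, 0)
  p <- recruit(a, c(g = 1000))
  expect_equal(p$g$aligned_bases, 300)
  expect_equal(breadth(p$g), 300 / 1000)

  low <- alignment_records("r3", "g", 0, 100, "+", 89, 11, 0, 0)  # 0.89
  p2 <- recruit(low, c(g = 1000))
  expect_equal(p2$g$aligned_bases, 0)
  expect_equal(p2$g$passing_reads, 0L)

  bad <- alignment_records("r4", "g", 950, 1100, "+", 150, 0, 0, 0)
  expect_error(recruit(bad, c(g = 1000)), "bounds")
})

test_that("recruited aligned bases match simulation truth within 1%", {
  g <- simulate_genome(genome_spec(length = 5000, seed = 24))
  sim <- simulate_reads(g, depth = 20, read_length = 150,
                        subst_rate = 0.01, seed = 25)
  aln <- align_reads(sim$reads, list(g))
  p <- recruit(aln, setNames(5000, g$id))
  planted <- nrow(sim$reads) * 150
  expect_lt(abs(p[[g$id]]$aligned_bases / planted - 1), 0.01)
})

test_that("breadth follows the random-occupancy formula", {
  set.seed(212)
  L <- 10000L; m <- 100L; R <- 300L
  starts <- sample(0:(L - m), R, replace = TRUE)
  a <- alignment_records(sprintf("r%03d", 1:R), "g", starts, starts + m,
                         "+", m, 0, 0, 0)
  p <- recruit(a, c(g = L))
  expect_equal(breadth(p$g), 1 - (1 - m / L)^R, tolerance = 0.02)
})

test_that("presence calls are inclusive at the breadth boundary", {
  mk <- function(covered, L = 40000L) {
    a <- alignment_records("r", "g", 0, covered, "+", covered, 0, 0, 0)
    if (covered == 0) a <- a[0, , drop = FALSE]
    recruit(a, c(g = L))$g
  }
  expect_true(call_presence(mk(30000L)))       # breadth exactly 0.75
  expect_false(call_presence(mk(29996L)))      # 0.7499
  expect_true(call_presence(mk(40000L)))
  expect_false(call_presence(mk(0L)))
})

test_that("per-Gb abundance follows its formula and scaling laws", {
  expect_equal(relative_abundance(8e5, 40000, 1e9), 20.0)
  expect_equal(relative_abundance(0, 40000, 1e9), 0)
  expect_equal(relative_abundance(8e5, 40000, 2e9),
               relative_abundance(8e5, 40000, 1e9) / 2)
  expect_error(relative_abundance(1, 0, 1e9), "genome_length")
  expect_error(relative_abundance(1, 100, 0), "library_bases")

  # invariant under duplicating the sample
  a <- alignment_records(c("r1", "r2"), "g", c(0, 0), c(100, 100), "+",
                         100, 0, 0, 0)
  one <- recruit(a[1, ], c(g = 1000))$g
  two <- recruit(a, c(g = 1000))$g
  expect_equal(relative_abundance(one, 1000, 1e6),
               relative_abundance(two, 1000, 2e6))
})

test_that("raising the identity cutoff never increases breadth or abundance", {
  g <- simulate_genome(genome_spec(length = 4000, seed = 26))
  sim <- simulate_reads(g, depth = 8, read_length = 150,
                        subst_rate = 0.02, seed = 27)
  rep <- profile_sample(sim$reads, list(g), clean_params = NULL,
                        recruit_params = recruit_params(
                          alt_identities = c(0.95, 1.0)))
  rep <- rep[order(rep$identity_cutoff), ]
  expect_true(all(diff(rep$breadth) <= 1e-12))
  expect_true(all(diff(rep$abundance_per_gb) <= 1e-9))
})

test_that("divergent relatives drop out at 90% but reappear at 80% identity", {
  ref <- simulate_genome(genome_spec(length = 4000, seed = 28))
  far <- diverge_genome(ref, 0.15, seed = 29)
  sim <- simulate_reads(far, depth = 10, read_length = 150, seed = 30)
  rep90 <- profile_sample(sim$reads, list(ref), clean_params = NULL)
  expect_false(rep90$present)
  rep80 <- profile_sample(sim$reads, list(ref), clean_params = NULL,
                          recruit_params = recruit_params(min_identity = 0.80))
  expect_true(rep80$present)
})
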