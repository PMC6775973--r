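# shared fixture builders; everything is generated in code under fixed seeds

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "V", "W", "Y")

random_dna_str <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

random_protein <- function(n) paste(sample(AA20, n, replace = TRUE),
                                    collapse = "")

mutate_protein <- function(s, rate) {
  b <- strsplit(s, "", fixed = TRUE)[[1]]
  i <- which(runif(length(b)) < rate)
  if (length(i)) b[i] <- sample(AA20, length(i), replace = TRUE)
  paste(b, collapse = "")
}

# k-mer multiset of the circular form of a sequence
circular_kmer_multiset <- function(circ_seq, k = 21L) {
  ext <- paste0(circ_seq, substr(circ_seq, 1L, k - 1L))
  sort(substring(ext, seq_len(nchar(circ_seq)),
                 seq_len(nchar(circ_seq)) + k - 1L))
}

# canonical labelling of a partition (list of member vectors) for comparison
canonical_partition <- function(clusters) {
  cl <- lapply(clusters, function(x) sort(unname(as.character(x))))
  unname(cl[order(vapply(cl, `[`, character(1), 1L))])
}

# partition from an integer membership vector named by item
partition_from_membership <- function(memb) {
  canonical_partition(split(names(memb), memb))
}

# rebuild the pairwise alignment implied by a SAM record and recount the
# per-column edit decomposition (independent oracle for read_alignments)
recount_from_cigar <- function(ref, read, pos1, cigar) {
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDSH=X]", cigar))[[1]]
  n <- as.integer(sub("[A-Z=]", "", ops))
  op <- sub("[0-9]+", "", ops)
  ri <- pos1; qi <- 1L
  matches <- 0L; mism <- 0L; ins <- 0L; del <- 0L
  for (i in seq_along(op)) {
    if (op[i] %in% c("M", "=", "X")) {
      for (j in seq_len(n[i])) {
        if (substr(ref, ri, ri) == substr(read, qi, qi))
          matches <- matches + 1L else mism <- mism + 1L
        ri <- ri + 1L; qi <- qi + 1L
      }
    } else if (op[i] == "I") { ins <- ins + n[i]; qi <- qi + n[i]
    } else if (op[i] == "D") { del <- del + n[i]; ri <- ri + n[i]
    } else if (op[i] %in% c("S", "H")) { if (op[i] == "S") qi <- qi + n[i] }
  }
  list(matches = matches, mismatches = mism, insertions = ins,
       deletions = del, ref_start = pos1 - 1L, ref_end = ri - 1L)
}

write_sam <- function(path, refs, records) {
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(refs), nchar(refs)))
  writeLines(c(hdr, records), path)
}
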