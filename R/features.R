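# features: rho-independent terminator scanning with a transparent
# stem-loop stability model, and pairing of opposite-strand calls into
# bidirectional terminators.

#' Scan a genome for rho-independent terminator hairpins
#'
#' Enumerates candidate hairpins (stem 4-20 bp with at most one mismatch,
#' loop 4-12 bp, G:T wobble allowed as a pair) on both strands and scores
#' them with a simplified nearest-neighbour stability model:
#' `-3.3` kcal/mol per G:C stem pair, `-2.0` per A:T or G:T pair, `+4.0`
#' loop initiation, `+1.0` per loop base beyond 4, and `+3.0` per stem
#' mismatch.  A call additionally requires a run of at least `min_u_tract`
#' T's starting within 8 bp downstream of the stem on the call's strand (the
#' poly-U tract of the terminated transcript), and a stability magnitude
#' `|dG| >= min_abs_delta_g` (terminator dG values are conventionally
#' negative; the threshold applies to the magnitude).  Overlapping calls on
#' one strand are reduced to the most stable call.
#'
#' @param genome `annotated_genome` or sequence string.
#' @param min_abs_delta_g minimum stability magnitude (kcal/mol).
#' @param min_u_tract minimum downstream T-run (bases).
#' @param min_stem,max_stem,min_loop,max_loop,max_stem_mismatch,u_window
#'   enumeration bounds.
#' @param dg_gc,dg_at,dg_loop_init,dg_loop_base,dg_mismatch stability model
#'   parameters (kcal/mol, magnitudes).
#' @return data.frame of terminator calls sorted by position: `position`
#'   (0-based leftmost genome coordinate of the hairpin), `strand`,
#'   `stem_len`, `loop_len`, `mismatches_in_stem`, `delta_g` (negative),
#'   `u_tract_len`, `bidirectional` (always `FALSE` here; see
#'   [pair_bidirectional()]).
#' @export
find_terminators <- function(genome, min_abs_delta_g = 10.5,
                             min_u_tract = 3L, min_stem = 4L,
                             max_stem = 20L, min_loop = 4L, max_loop = 12L,
                             max_stem_mismatch = 1L, u_window = 8L,
                             dg_gc = 3.3, dg_at = 2.0, dg_loop_init = 4.0,
                             dg_loop_base = 1.0, dg_mismatch = 3.0) {
  seq <- as_genome_seq(genome)
  n <- nchar(seq)
  scan1 <- function(s, strand) {
    df <- scan_hairpins(s, min_stem, max_stem, min_loop, max_loop,
                        max_stem_mismatch, min_abs_delta_g, min_u_tract,
                        u_window, dg_gc, dg_at, dg_loop_init, dg_loop_base,
                        dg_mismatch)
    if (nrow(df) == 0) return(df)
    ext <- 2L * df$stem_len + df$loop_len
    if (strand == "-") df$position <- n - (df$position + ext)
    df$strand <- strand
    df
  }
  calls <- rbind(scan1(seq, "+"), scan1(revcomp(seq), "-"))
  if (nrow(calls) == 0) {
    return(data.frame(position = integer(), strand = character(),
                      stem_len = integer(), loop_len = integer(),
                      mismatches_in_stem = integer(), delta_g = numeric(),
                      u_tract_len = integer(), bidirectional = logical(),
                      stringsAsFactors = FALSE))
  }
  # per-strand overlap reduction: most stable call wins
  reduce <- function(df) {
    if (nrow(df) <= 1) return(df)
    df <- df[order(-df$abs_delta_g, df$position), , drop = FALSE]
    s <- df$position
    e <- df$position + 2L * df$stem_len + df$loop_len
    keep <- logical(nrow(df))
    for (i in seq_len(nrow(df))) {
      sel <- which(keep)
      keep[i] <- !any(s[i] < e[sel] & e[i] > s[sel])
    }
    df[keep, , drop = FALSE]
  }
  calls <- do.call(rbind, lapply(split(calls, calls$strand), reduce))
  out <- data.frame(position = calls$position, strand = calls$strand,
                    stem_len = calls$stem_len, loop_len = calls$loop_len,
                    mismatches_in_stem = calls$mismatches_in_stem,
                    delta_g = -calls$abs_delta_g,
                    u_tract_len = calls$u_tract_len,
                    bidirectional = FALSE, stringsAsFactors = FALSE)
  out <- out[order(out$position, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pair opposite-strand terminator calls into bidirectional terminators
#'
#' A `+` and a `-` call whose hairpin extents overlap or lie within
#' `max_gap` bp are merged into a single bidirectional call positioned at
#' the midpoint of their combined extent (keeping the geometry of the more
#' stable partner and the more stable `delta_g`).  Unpaired calls are
#' returned unchanged.  A bidirectional rho-independent terminator between
#' two divergently transcribed genome arms is the hallmark configuration
#' this detects.
#'
#' @param calls data.frame from [find_terminators()] (one genome).
#' @param max_gap maximum gap between the two hairpin extents (bp).
#' @return data.frame of calls with merged rows flagged
#'   `bidirectional = TRUE`, sorted by position.
#' @export
pair_bidirectional <- function(calls, max_gap = 60L) {
  if (nrow(calls) == 0) return(calls)
  ext_end <- calls$position + 2L * calls$stem_len + calls$loop_len
  plus <- which(calls$strand == "+")
  minus <- which(calls$strand == "-")
  pairs <- list()
  for (i in plus) for (j in minus) {
    gap <- max(calls$position[j] - ext_end[i],
               calls$position[i] - ext_end[j])
    if (gap <= max_gap)
      pairs[[length(pairs) + 1L]] <-
        c(i = i, j = j, stab = -(calls$delta_g[i] + calls$delta_g[j]))
  }
  if (!length(pairs)) {
    out <- calls[order(calls$position), , drop = FALSE]
    rownames(out) <- NULL
    return(out)
  }
  pm <- do.call(rbind, pairs)
  pm <- pm[order(-pm[, "stab"]), , drop = FALSE]
  used <- logical(nrow(calls))
  merged <- list()
  for (r in seq_len(nrow(pm))) {
    i <- pm[r, "i"]; j <- pm[r, "j"]
    if (used[i] || used[j]) next
    used[i] <- used[j] <- TRUE
    strong <- if (calls$delta_g[i] <= calls$delta_g[j]) i else j
    lo <- min(calls$position[i], calls$position[j])
    hi <- max(ext_end[i], ext_end[j])
    row <- calls[strong, , drop = FALSE]
    row$position <- as.integer((lo + hi) %/% 2L)
    row$delta_g <- min(calls$delta_g[i], calls$delta_g[j])
    row$u_tract_len <- max(calls$u_tract_len[i], calls$u_tract_len[j])
    row$bidirectional <- TRUE
    merged[[length(merged) + 1L]] <- row
  }
  out <- rbind(calls[!used, , drop = FALSE], do.call(rbind, merged))
  out <- out[order(out$position), , drop = FALSE]
  rownames(out) <- NULL
  out
}
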