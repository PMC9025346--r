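# Independent oracles kept deliberately naive: they re-derive results by
# brute force and never share code with the implementation paths they check.

# affine-gap Smith-Waterman score by full dynamic programming
# (gap of length L costs gap_open + gap_extend * L)
sw_oracle <- function(a, b, reward = 2, mismatch = -3,
                      gap_open = 5, gap_extend = 2) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  FF <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in seq(2, n + 1)) {
    for (j in seq(2, m + 1)) {
      E[i, j] <- max(H[i, j - 1] - gap_open - gap_extend,
                     E[i, j - 1] - gap_extend)
      FF[i, j] <- max(H[i - 1, j] - gap_open - gap_extend,
                      FF[i - 1, j] - gap_extend)
      s <- if (A[i - 1] == B[j - 1]) reward else mismatch
      H[i, j] <- max(0, H[i - 1, j - 1] + s, E[i, j], FF[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# brute-force non-redundancy scan over an interval table
dedup_oracle <- function(df) {
  keep <- rep(TRUE, nrow(df))
  for (i in seq_len(nrow(df))) {
    for (j in seq_len(nrow(df))) {
      if (i == j || df$contig_id[i] != df$contig_id[j]) next
      if (df$start[i] == df$start[j] && df$end[i] == df$end[j]) {
        better_j <- (df$period[j] < df$period[i]) ||
          (df$period[j] == df$period[i] && df$score[j] > df$score[i]) ||
          (df$period[j] == df$period[i] && df$score[j] == df$score[i] &&
             df$consensus[j] < df$consensus[i])
        if (better_j) keep[i] <- FALSE
      } else if (df$start[j] <= df$start[i] && df$end[j] >= df$end[i]) {
        keep[i] <- FALSE
      }
    }
  }
  df[keep, , drop = FALSE]
}

# brute-force connected components (transitive closure by iteration)
components_oracle <- function(nodes, edges) {
  comp <- seq_along(nodes)
  names(comp) <- nodes
  repeat {
    changed <- FALSE
    for (k in seq_len(nrow(edges))) {
      a <- edges$from[k]; b <- edges$to[k]
      if (comp[a] != comp[b]) {
        comp[comp == max(comp[a], comp[b])] <- min(comp[a], comp[b])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  comp
}

# canonical form of a partition for comparison: sorted member groups
partition_canon <- function(membership) {
  groups <- split(names(membership), membership)
  groups <- lapply(groups, sort)
  unname(groups[order(vapply(groups, `[`, character(1), 1))])
}

# a minimal TRArray table for clustering/naming tests (sequence content
# irrelevant, topology supplied via a match table)
fake_arrays <- function(n, periods = rep(50L, n), assembly = "asmX") {
  data.frame(
    array_id = sprintf("a%02d", seq_len(n)), assembly_id = assembly,
    contig_id = "c1", start = seq_len(n) * 1000L,
    end = seq_len(n) * 1000L + 500L,
    period = periods, copies = 10, percent_match = 95, percent_indel = 0,
    score = 500, consensus = strrep("ACGTG", 10),
    array_seq = strrep("ACGTG", 100), stringsAsFactors = FALSE)
}

rand_dna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste0(sample(c("A", "C", "G", "T"), n, TRUE, prob = p), collapse = "")
}
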