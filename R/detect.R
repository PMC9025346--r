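#' Detector parameters
#'
#' Scoring and filtering parameters of the tandem-array detector. Defaults
#' are the classic Tandem Repeats Finder parameterization used for satellite
#' discovery in rodent genomes: match +2, mismatch 5, indel 7, matching
#' probability 80, indel probability 10, minimum score 50, maximum monomer
#' 2000 bp.
#'
#' @param match_weight reward for a matching base.
#' @param mismatch_penalty penalty for a mismatching base (positive).
#' @param indel_penalty penalty per inserted/deleted base (positive).
#' @param pm assumed percent match probability between adjacent copies;
#'   controls how tolerant the candidate-window gate is.
#' @param pi assumed percent indel probability; reserved for the same gate.
#' @param minscore minimum wraparound alignment score for an emitted array.
#' @param maxperiod maximum monomer length considered, in bp.
#' @return an object of class `detector_params`.
#' @export
detector_params <- function(match_weight = 2, mismatch_penalty = 5,
                            indel_penalty = 7, pm = 80, pi = 10,
                            minscore = 50, maxperiod = 2000) {
  p <- list(match_weight = match_weight, mismatch_penalty = mismatch_penalty,
            indel_penalty = indel_penalty, pm = pm, pi = pi,
            minscore = minscore, maxperiod = maxperiod)
  stopifnot(all(unlist(p) > 0), maxperiod >= 1, minscore >= 1)
  structure(p, class = "detector_params")
}

#' Majority-vote consensus monomer of a tandem array
#'
#' The array is sliced into period-length phases and each column takes the
#' most frequent base; ties break by the fixed order A < C < G < T. N bases
#' cast no vote.
#'
#' @param array_seq the array sequence.
#' @param period monomer length in bp.
#' @return consensus monomer of length `period`.
#' @export
consensus_of <- function(array_seq, period) {
  array_seq <- clean_seq(array_seq)
  n <- nchar(array_seq)
  if (period < 1) stop("period must be >= 1")
  if (n < period) stop("array (", n, " bp) shorter than one period (", period, ")")
  chars <- strsplit(array_seq, "")[[1]]
  col <- ((seq_len(n) - 1L) %% period) + 1L
  cons <- vapply(seq_len(period), function(j) {
    votes <- chars[col == j]
    votes <- votes[votes != "N"]
    if (length(votes) == 0) return("N")
    counts <- table(factor(votes, levels = BASES))
    BASES[which.max(counts)]  # which.max takes the first max: A < C < G < T
  }, character(1))
  paste0(cons, collapse = "")
}

# candidate monomer lengths from k-mer recurrence distances.
# Spaced re-occurrences of an exact k-mer at distance d vote for period d;
# k = 5 covers short monomers (<= 29 bp), k = 7 the rest, mirroring the
# two-regime tuple sizes of probabilistic tandem detectors.
candidate_lags <- function(s, maxperiod, min_votes = 3L) {
  lags <- integer(0)
  for (spec in list(c(5L, min(29L, maxperiod)), c(7L, maxperiod))) {
    k <- spec[1]; lagmax <- spec[2]
    km <- kmers_of(s, k)
    if (length(km) == 0) next
    km[grepl("N", km, fixed = TRUE)] <- NA
    pos <- split(seq_along(km), km)
    pos <- pos[lengths(pos) >= 2]
    if (length(pos) == 0) next
    d <- unlist(lapply(pos, function(p) diff(p)), use.names = FALSE)
    d <- d[d >= 1 & d <= lagmax]
    if (length(d) == 0) next
    tab <- table(d)
    lags <- c(lags, as.integer(names(tab)[tab >= min_votes]))
  }
  sort(unique(lags))
}

# contiguous candidate windows at one lag: runs of self-matches merged when
# the gap between them is small, gated on the within-window match fraction
lag_windows <- function(m, d, min_frac) {
  r <- rle(m)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= 4L
  if (!any(keep)) return(NULL)
  ws <- starts[keep]; we <- ends[keep]
  gap <- max(d, 10L)
  merged_s <- ws[1]; merged_e <- we[1]
  out <- list()
  for (i in seq_along(ws)[-1]) {
    if (ws[i] - merged_e - 1L <= gap) {
      merged_e <- we[i]
    } else {
      out[[length(out) + 1L]] <- c(merged_s, merged_e)
      merged_s <- ws[i]; merged_e <- we[i]
    }
  }
  out[[length(out) + 1L]] <- c(merged_s, merged_e)
  cm <- cumsum(m)
  res <- do.call(rbind, out)
  frac <- (cm[res[, 2]] - c(0, cm)[res[, 1]]) / (res[, 2] - res[, 1] + 1L)
  len <- res[, 2] - res[, 1] + 1L
  res <- res[frac >= min_frac & (len + d) >= max(2L * d, 12L), , drop = FALSE]
  if (nrow(res) == 0) return(NULL)
  res
}

# verify one candidate window by wraparound alignment against its own
# phase consensus; two refinement passes (trim, re-derive consensus, re-align)
refine_candidate <- function(s, n, a, b, d, par) {
  lo <- max(1L, a - d); hi <- min(n, b + 2L * d)
  region <- substr(s, lo, hi)
  if (nchar(region) < d) return(NULL)
  best <- NULL
  for (pass in 1:2) {
    cons <- tryCatch(consensus_of(region, d), error = function(e) NULL)
    if (is.null(cons)) break
    al <- wrap_align(region, cons, par$match_weight, par$mismatch_penalty,
                     par$indel_penalty)
    if (al$score <= 0) break
    abs_s <- lo - 1L + al$start      # 0-based
    abs_e <- lo - 1L + al$end
    cur <- list(start = abs_s, end = abs_e, period = d, score = al$score,
                matches = al$matches, mismatches = al$mismatches,
                indels = al$indels, consensus = cons)
    if (is.null(best) || cur$score >= best$score) best <- cur
    lo2 <- max(1L, abs_s + 1L - d); hi2 <- min(n, abs_e + d)
    if (lo2 == lo && hi2 == hi) break
    lo <- lo2; hi <- hi2
    region <- substr(s, lo, hi)
  }
  best
}

# collapse a verified period to the smallest divisor whose score stays
# within 95% of the best, so near-primitive monomers are reported
collapse_period <- function(s, hit, par) {
  p <- hit$period
  divs <- which(p %% seq_len(p) == 0)
  if (length(divs) <= 1) return(hit)
  arr <- substr(s, hit$start + 1L, hit$end)
  cands <- lapply(divs, function(d2) {
    cons <- tryCatch(consensus_of(arr, d2), error = function(e) NULL)
    if (is.null(cons)) return(NULL)
    al <- wrap_align(arr, cons, par$match_weight, par$mismatch_penalty,
                     par$indel_penalty)
    list(period = d2, score = al$score, matches = al$matches,
         mismatches = al$mismatches, indels = al$indels, consensus = cons,
         start = hit$start + al$start, end = hit$start + al$end)
  })
  cands <- Filter(Negate(is.null), cands)
  scores <- vapply(cands, `[[`, numeric(1), "score")
  ok <- which(scores >= 0.95 * max(scores))
  cands[[min(ok)]]
}

#' Detect tandem arrays in sequence
#'
#' Native tandem-array detection: candidate monomer lengths are proposed
#' from the distances at which exact k-mers re-occur, each candidate window
#' is verified by wraparound dynamic programming against its own phase
#' consensus (match `+match_weight`, mismatch `-mismatch_penalty`, indel
#' `-indel_penalty`), verified periods collapse to the smallest
#' near-equivalent divisor, and arrays below `minscore` are dropped last so
#' the emitted set is monotone in `minscore`.
#'
#' Detection is strand-symmetric by construction (self-match lags are
#' invariant under reverse complement); arrays carry no strand.
#'
#' @param x a sequence-record data.frame from [read_fasta()], a named
#'   character vector, or a single sequence string.
#' @param params a [detector_params()] object.
#' @param assembly_id assembly label stored on each array.
#' @return a TRArray table: one row per array with columns `array_id`,
#'   `assembly_id`, `contig_id`, `start`, `end` (0-based half-open),
#'   `period`, `copies`, `percent_match`, `percent_indel`, `score`,
#'   `consensus`, `array_seq`.
#' @export
detect_arrays <- function(x, params = detector_params(),
                          assembly_id = NA_character_) {
  if (is.character(x) && is.null(names(x)) && length(x) == 1) {
    x <- data.frame(id = "seq", sequence = x, stringsAsFactors = FALSE)
  } else if (is.character(x)) {
    x <- data.frame(id = names(x), sequence = unname(x), stringsAsFactors = FALSE)
  }
  out <- lapply(seq_len(nrow(x)), function(i)
    detect_one(clean_seq(x$sequence[i]), x$id[i], params, assembly_id))
  res <- do.call(rbind, c(list(empty_arrays()), out))
  rownames(res) <- NULL
  res
}

detect_one <- function(s, contig_id, par, assembly_id) {
  n <- nchar(s)
  if (n < 2) return(empty_arrays())
  min_frac <- max(0.45, (par$pm / 100)^2 - 0.10)
  hits <- list()
  for (d in candidate_lags(s, min(par$maxperiod, n - 1L))) {
    m <- as.logical(lag_matches(s, d))
    win <- lag_windows(m, d, min_frac)
    if (is.null(win)) next
    for (w in seq_len(nrow(win))) {
      hit <- refine_candidate(s, n, win[w, 1], win[w, 2] + d, d, par)
      if (is.null(hit)) next
      if (hit$end - hit$start < 2L * hit$period) next
      hit <- collapse_period(s, hit, par)
      if (hit$end - hit$start < 2L * hit$period) next
      hits[[length(hits) + 1L]] <- hit
    }
  }
  if (length(hits) == 0) return(empty_arrays())
  df <- do.call(rbind, lapply(hits, function(h) {
    aln <- h$matches + h$mismatches + h$indels
    data.frame(
      array_id = NA_character_, assembly_id = assembly_id,
      contig_id = contig_id, start = h$start, end = h$end,
      period = h$period, copies = round((h$end - h$start) / h$period, 1),
      percent_match = round(100 * h$matches / max(1, h$matches + h$mismatches), 1),
      percent_indel = round(100 * h$indels / max(1, aln), 1),
      score = h$score, consensus = h$consensus,
      array_seq = substr(s, h$start + 1L, h$end),
      stringsAsFactors = FALSE)
  }))
  df <- dedupe_detections(df)
  df <- df[df$score >= par$minscore, , drop = FALSE]
  if (nrow(df)) df$array_id <- sprintf("%s:%d-%d", df$contig_id, df$start, df$end)
  rownames(df) <- NULL
  df
}

# near-duplicate windows found at several lags collapse to the best-scoring
# one; distinct overlapping structures survive for the catalog stage to judge
dedupe_detections <- function(df) {
  df <- df[order(-df$score, df$start, df$period), , drop = FALSE]
  keep <- rep(TRUE, nrow(df))
  for (i in seq_len(nrow(df))[-1]) {
    for (j in which(keep[seq_len(i - 1)])) {
      ov <- min(df$end[i], df$end[j]) - max(df$start[i], df$start[j])
      un <- max(df$end[i], df$end[j]) - min(df$start[i], df$start[j])
      same_p <- df$period[i] == df$period[j] ||
        df$period[i] %% df$period[j] == 0 || df$period[j] %% df$period[i] == 0
      if (ov > 0 && same_p && ov / un >= 0.8) { keep[i] <- FALSE; break }
    }
  }
  df[keep, , drop = FALSE]
}
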