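#' @useDynLib satfam, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats uniroot runif rbinom setNames
#' @importFrom utils read.delim write.table head
NULL

BASES <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#'
#' N is its own complement; any non-ACGTN character is mapped to N first.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    chars <- rev(strsplit(clean_seq(s), "")[[1]])
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    paste0(comp[chars], collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' GC content of a DNA string, in percent
#'
#' N bases are excluded from the denominator.
#'
#' @param x character vector of DNA sequences.
#' @return numeric vector, 0-100.
#' @export
gc_percent <- function(x) {
  vapply(x, function(s) {
    chars <- strsplit(toupper(s), "")[[1]]
    acgt <- chars[chars %in% BASES]
    if (length(acgt) == 0) return(NA_real_)
    100 * sum(acgt %in% c("G", "C")) / length(acgt)
  }, numeric(1), USE.NAMES = FALSE)
}

# uppercase and map everything outside {A,C,G,T,N} to N
clean_seq <- function(s) {
  s <- toupper(s)
  gsub("[^ACGTN]", "N", s)
}

# Shannon entropy (bits) of non-overlapping dinucleotides, the monomer
# read cyclically, so a pure dinucleotide repeat scores exactly 0.
dinucleotide_entropy <- function(s) {
  s <- clean_seq(s)
  n <- nchar(s)
  if (n < 2) return(0)
  s2 <- paste0(s, s)
  idx <- seq(1L, n, by = 2L)
  dinucs <- substring(s2, idx, idx + 1L)
  p <- table(dinucs) / length(dinucs)
  -sum(p * log2(p))
}

# longest homopolymer run length
max_homopolymer <- function(s) {
  r <- rle(strsplit(toupper(s), "")[[1]])
  max(r$lengths)
}

# all k-mers of a string (character vector); empty if too short
kmers_of <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  substring(s, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
}

# deterministic derived seed for a pipeline stage, kept below 2^31
split_seed <- function(seed, offset) {
  ((as.numeric(seed) %% 2147483647) * 48271 + offset) %% 2147483647
}

# run code under a temporary RNG state
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed %% 2147483647))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# empty TRArray table with the canonical column set
empty_arrays <- function() {
  data.frame(
    array_id = character(0), assembly_id = character(0),
    contig_id = character(0), start = integer(0), end = integer(0),
    period = integer(0), copies = numeric(0),
    percent_match = numeric(0), percent_indel = numeric(0),
    score = numeric(0), consensus = character(0), array_seq = character(0),
    stringsAsFactors = FALSE
  )
}

assert_arrays <- function(arrays) {
  need <- c("contig_id", "start", "end", "period", "score")
  miss <- setdiff(need, names(arrays))
  if (length(miss))
    stop("array table is missing columns: ", paste(miss, collapse = ", "))
  invisible(arrays)
}
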