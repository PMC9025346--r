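# Local-alignment scoring shared by pair scoring, library annotation and
# cross-assembly matching. Scoring follows blastn defaults (reward +2,
# mismatch -3, gap open 5, gap extend 2); N aligns as a mismatch.

sub_matrix <- function(reward = 2, mismatch = -3) {
  letters <- c(BASES, "N")
  m <- matrix(mismatch, 5, 5, dimnames = list(letters, letters))
  diag(m)[1:4] <- reward
  m["N", "N"] <- mismatch
  m
}

#' Best local alignment score of two sequences
#'
#' Smith-Waterman score under blastn-default scoring. Used for array pair
#' scoring, repeat-library annotation and cross-assembly family matching.
#'
#' @param a,b DNA sequences (character).
#' @param reward match reward.
#' @param mismatch mismatch score (negative).
#' @param gap_open,gap_extend affine gap parameters (positive); a gap of
#'   length L costs `gap_open + gap_extend * L`.
#' @return integer score (0 if nothing aligns).
#' @export
local_score <- function(a, b, reward = 2, mismatch = -3,
                        gap_open = 5, gap_extend = 2) {
  if (nchar(a) == 0 || nchar(b) == 0) return(0)
  as.numeric(Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    type = "local", substitutionMatrix = sub_matrix(reward, mismatch),
    gapOpening = gap_open, gapExtension = gap_extend, scoreOnly = TRUE))
}

# Karlin-Altschul lambda for match/mismatch scoring at uniform base
# composition: solves sum_ij p_i p_j exp(lambda * s_ij) = 1
ka_lambda <- function(reward = 2, mismatch = -3) {
  f <- function(l) 0.25 * exp(l * reward) + 0.75 * exp(l * mismatch) - 1
  uniroot(f, c(1e-6, 5))$root
}

# E-value of a local score for one m x n comparison; K is the standard
# Karlin-Altschul prefactor, fixed at 0.3 (ungapped approximation)
ka_evalue <- function(score, m, n, lambda, K = 0.3) {
  K * m * n * exp(-lambda * score)
}
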