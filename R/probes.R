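#' Probe-family selection criteria
#'
#' @param require_te_free exclude families with transposable-element
#'   similarity (gene-fragment or satellite library hits are allowed).
#' @param min_monomer minimum family monomer length, bp.
#' @param min_assemblies minimum number of assemblies a family must occur in.
#' @param long_array_bp array length considered "long" in the report; long
#'   two-assembly families are worth rescuing for probe design even at low
#'   abundance, so the length is reported alongside the selection rather
#'   than used as a hard gate.
#' @return an object of class `selection_criteria`.
#' @export
selection_criteria <- function(require_te_free = TRUE, min_monomer = 10,
                               min_assemblies = 2, long_array_bp = 20000) {
  stopifnot(min_monomer > 0, min_assemblies > 0, long_array_bp > 0)
  structure(list(require_te_free = require_te_free, min_monomer = min_monomer,
                 min_assemblies = min_assemblies, long_array_bp = long_array_bp),
            class = "selection_criteria")
}

# numeral part of a family name ("CG33A" / "33A" -> 33)
name_numeral <- function(name) {
  as.integer(sub("^[A-Za-z]*([0-9]+)[A-Z]+$", "\\1", name))
}

#' Select probe-worthy families
#'
#' Keeps families with no transposable-element similarity (library hits
#' classed as satellite or gene fragment, e.g. "Zn-finger", pass), monomer
#' length at least `min_monomer`, and presence in at least `min_assemblies`
#' assemblies per the co-occurrence table. The result is ranked by genome
#' abundance; maximum array length is reported so long low-abundance
#' families remain visible.
#'
#' @param family_table data.frame with columns `name`, `te_similarity`
#'   (empty/NA for none) and either `is_te` or `similarity_class`
#'   (transposable-element classes: SINE, LINE, LTR, DNA, RC);
#'   `min_monomer` is taken from the column of that name or parsed from
#'   the name numeral. An `abundance_percent` column is used for ranking.
#' @param cooccurrence data.frame with columns `name` and `n_assemblies`
#'   (see [cooccurrence_counts()] for deriving it from a class table).
#' @param criteria a [selection_criteria()] object.
#' @return the selected subset of `family_table`, ranked by abundance.
#' @export
select_probe_families <- function(family_table, cooccurrence,
                                  criteria = selection_criteria()) {
  if (nrow(family_table) == 0) return(family_table)
  tab <- family_table
  if (is.null(tab$min_monomer)) tab$min_monomer <- name_numeral(tab$name)
  if (is.null(tab$is_te)) {
    if (!is.null(tab$similarity_class)) {
      tab$is_te <- tab$similarity_class %in% TE_CLASSES
    } else {
      stop("family_table needs an is_te or similarity_class column")
    }
  }
  n_asm <- cooccurrence$n_assemblies[match(tab$name, cooccurrence$name)]
  n_asm[is.na(n_asm)] <- 1L
  keep <- tab$min_monomer >= criteria$min_monomer &
    n_asm >= criteria$min_assemblies
  if (criteria$require_te_free) keep <- keep & !tab$is_te
  out <- family_table[keep, , drop = FALSE]
  out$n_assemblies <- n_asm[keep]
  if (!is.null(out$abundance_percent))
    out <- out[order(-out$abundance_percent), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rank a family's arrays by sequence homogeneity
#'
#' Descending percent match (the array's internal copy-to-copy identity),
#' ties broken by longer array, then genomic coordinate. The top-ranked
#' array is the probe-design template.
#'
#' @param fams a `tr_families` object or a TRArray table.
#' @param name family name (required for a `tr_families`).
#' @return the member TRArray table in rank order.
#' @export
rank_arrays_by_homogeneity <- function(fams, name = NULL) {
  if (inherits(fams, "tr_families")) {
    if (is.null(name)) stop("give the family name")
    f <- fams$families$family_id[fams$families$name == name]
    if (length(f) != 1) stop("unknown family: ", name)
    ids <- fams$membership$array_id[fams$membership$family_id == f]
    arrays <- fams$arrays[fams$arrays$array_id %in% ids, , drop = FALSE]
  } else {
    arrays <- fams
  }
  if (nrow(arrays) == 0) stop("family has no members")
  out <- arrays[homogeneity_order(arrays), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# best ungapped antiparallel self-alignment score (+1 match / -1 mismatch):
# how strongly the oligo can fold back on itself or dimerize
selfcomp_score <- function(s) {
  p <- strsplit(toupper(s), "")[[1]]
  q <- strsplit(revcomp(s), "")[[1]]
  n <- length(p)
  best <- 0
  for (off in (-(n - 1)):(n - 1)) {
    i <- max(1, 1 + off):min(n, n + off)
    j <- i - off
    sc <- sum(ifelse(p[i] == q[j] & p[i] != "N", 1, -1))
    if (sc > best) best <- sc
  }
  best
}

# does the pattern (or its reverse complement) hit the subject with at most
# max_mm mismatches, no indels?
mismatch_hit <- function(pattern, subject, max_mm = 2) {
  subj <- Biostrings::DNAString(subject)
  hit <- Biostrings::countPattern(pattern, subj, max.mismatch = max_mm,
                                  with.indels = FALSE, fixed = TRUE) > 0
  if (hit) return(TRUE)
  Biostrings::countPattern(revcomp(pattern), subj, max.mismatch = max_mm,
                           with.indels = FALSE, fixed = TRUE) > 0
}

#' Design a FISH oligonucleotide probe for a family
#'
#' Enumerates every window of `length_range` nucleotides over the consensus
#' monomer of the family's most homogeneous array (windows may wrap across
#' the monomer junction; monomers shorter than the window use the
#' tandem-doubled sequence). Windows must pass: GC within `gc_range`,
#' longest homopolymer at most `max_homopolymer`, ungapped antiparallel
#' self-complementarity score at most `max_selfcomp` (+1/-1 scoring), and
#' no occurrence within 2 mismatches in any other family's representative.
#' Among passing windows the one hitting the largest fraction of the
#' family's arrays (within 2 mismatches, either strand) wins; ties resolve
#' by monomer position, then window length, making the search deterministic.
#'
#' @param fams a `tr_families` object.
#' @param name family to design for.
#' @param length_range allowed probe lengths, inclusive.
#' @param gc_range allowed GC percent range.
#' @param max_homopolymer longest allowed single-base run.
#' @param max_selfcomp maximum self-complementarity score.
#' @param max_mm mismatches tolerated when counting array hits and
#'   cross-family hits.
#' @return one-row data.frame: `name`, `sequence`, `length`, `position`
#'   (0-based start on the monomer), `gc_percent`, `max_homopolymer`,
#'   `selfcomp_score`, `cross_family_hit`, `array_coverage`.
#' @export
design_probe <- function(fams, name, length_range = c(18, 27),
                         gc_range = c(35, 65), max_homopolymer = 4,
                         max_selfcomp = 8, max_mm = 2) {
  members <- rank_arrays_by_homogeneity(fams, name)
  top <- members[1, ]
  monomer <- consensus_of(top$array_seq, top$period)
  template <- monomer
  while (nchar(template) < length_range[2])  # short monomers: tandem-double
    template <- paste0(template, monomer)
  doubled <- paste0(template, substr(template, 1, length_range[2] - 1))
  others <- fams$families[fams$families$name != name, , drop = FALSE]
  other_reps <- if (nrow(others))
    paste0(others$representative, others$representative) else character(0)

  fail <- c(gc = 0L, homopolymer = 0L, selfcomp = 0L, cross_family = 0L)
  best <- NULL
  for (pos in seq_len(nchar(template))) {
    for (len in seq(length_range[1], length_range[2])) {
      w <- substr(doubled, pos, pos + len - 1L)
      if (grepl("N", w, fixed = TRUE)) next
      gc <- gc_percent(w)
      if (gc < gc_range[1] || gc > gc_range[2]) { fail["gc"] <- fail["gc"] + 1L; next }
      hp <- max_homopolymer(w)
      if (hp > max_homopolymer) { fail["homopolymer"] <- fail["homopolymer"] + 1L; next }
      scs <- selfcomp_score(w)
      if (scs > max_selfcomp) { fail["selfcomp"] <- fail["selfcomp"] + 1L; next }
      cross <- any(vapply(other_reps, mismatch_hit, logical(1),
                          pattern = w, max_mm = max_mm))
      if (cross) { fail["cross_family"] <- fail["cross_family"] + 1L; next }
      cov <- mean(vapply(members$array_seq, mismatch_hit, logical(1),
                         pattern = w, max_mm = max_mm))
      if (is.null(best) || cov > best$array_coverage) {
        best <- data.frame(name = name, sequence = w, length = len,
                           position = pos - 1L, gc_percent = round(gc, 1),
                           max_homopolymer = hp, selfcomp_score = scs,
                           cross_family_hit = FALSE, array_coverage = cov,
                           stringsAsFactors = FALSE)
      }
    }
  }
  if (is.null(best))
    stop("no probe window passes the filters for family ", name,
         " (rejected: ", paste(names(fail), fail, sep = "=", collapse = ", "),
         ")")
  best
}

#' Re-validate a probe against the design filters
#'
#' Independent checker for a designed (or externally supplied) probe:
#' recomputes every gate from the sequence alone.
#'
#' @param sequence probe sequence.
#' @param other_representatives representative monomers of the other
#'   families (cross-hybridization check); optional.
#' @inheritParams design_probe
#' @return named logical vector: `length_ok`, `gc_ok`, `homopolymer_ok`,
#'   `selfcomp_ok`, `unique_ok`, `all_ok`.
#' @export
validate_probe <- function(sequence, other_representatives = character(0),
                           length_range = c(18, 27), gc_range = c(35, 65),
                           max_homopolymer = 4, max_selfcomp = 8, max_mm = 2) {
  len_ok <- nchar(sequence) >= length_range[1] &&
    nchar(sequence) <= length_range[2]
  gc <- gc_percent(sequence)
  gc_ok <- !is.na(gc) && gc >= gc_range[1] && gc <= gc_range[2]
  hp_ok <- max_homopolymer(sequence) <= max_homopolymer
  sc_ok <- selfcomp_score(sequence) <= max_selfcomp
  uniq_ok <- !any(vapply(other_representatives, function(r)
    mismatch_hit(sequence, paste0(r, r), max_mm), logical(1)))
  out <- c(length_ok = len_ok, gc_ok = gc_ok, homopolymer_ok = hp_ok,
           selfcomp_ok = sc_ok, unique_ok = uniq_ok)
  c(out, all_ok = all(out))
}
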