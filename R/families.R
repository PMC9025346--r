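#' Score all array pairs of a catalog by local alignment
#'
#' Every pair of catalog arrays is compared by Smith-Waterman local
#' alignment under blastn-default scoring (reward +2, mismatch -3, gap
#' open 5, gap extend 2) with no low-complexity masking; a pair is emitted
#' when the score is positive and its Karlin-Altschul E-value is at most
#' `evalue_max`.
#'
#' @param catalog a `tr_catalog` or TRArray table with `array_id` and
#'   `array_seq` columns.
#' @param evalue_max E-value cutoff for emitting a pair.
#' @param reward,mismatch,gap_open,gap_extend alignment scoring.
#' @return data.frame with columns `array_a`, `array_b`, `score`, `evalue`;
#'   each unordered pair appears once.
#' @export
score_pairs <- function(catalog, evalue_max = 1e-15, reward = 2,
                        mismatch = -3, gap_open = 5, gap_extend = 2) {
  arrays <- if (inherits(catalog, "tr_catalog")) catalog$arrays else catalog
  n <- nrow(arrays)
  if (n < 2)
    return(data.frame(array_a = character(0), array_b = character(0),
                      score = numeric(0), evalue = numeric(0)))
  lambda <- ka_lambda(reward, mismatch)
  out <- vector("list", n * (n - 1) / 2)
  k <- 0L
  for (i in seq_len(n - 1)) {
    for (j in seq((i + 1), n)) {
      s <- local_score(arrays$array_seq[i], arrays$array_seq[j],
                       reward, mismatch, gap_open, gap_extend)
      if (s <= 0) next
      ev <- ka_evalue(s, nchar(arrays$array_seq[i]),
                      nchar(arrays$array_seq[j]), lambda)
      if (ev > evalue_max) next
      k <- k + 1L
      out[[k]] <- data.frame(array_a = arrays$array_id[i],
                             array_b = arrays$array_id[j],
                             score = s, evalue = ev,
                             stringsAsFactors = FALSE)
    }
  }
  if (k == 0)
    return(data.frame(array_a = character(0), array_b = character(0),
                      score = numeric(0), evalue = numeric(0)))
  do.call(rbind, out[seq_len(k)])
}

# homogeneity ordering shared with probe design: best percent_match first,
# ties by longer array, then by genomic coordinate
homogeneity_order <- function(arrays) {
  order(-arrays$percent_match, -(arrays$end - arrays$start),
        arrays$assembly_id, arrays$contig_id, arrays$start)
}

#' Cluster catalog arrays into families by single linkage
#'
#' Two arrays belong to the same family when they are connected (possibly
#' transitively) by pair matches with score strictly greater than
#' `score_threshold`; arrays with no such match become singleton families.
#' The partition is independent of input order and of duplicated symmetric
#' matches.
#'
#' @param catalog a `tr_catalog` or TRArray table.
#' @param matches pair table from [score_pairs()].
#' @param score_threshold minimum (exclusive) pair score linking two arrays.
#' @return an object of class `tr_families`: list with `families` (one row
#'   per family: `family_id`, `name`, `min_monomer`, `representative`
#'   consensus monomer, `rep_array` sequence of the most homogeneous member,
#'   `max_array_len`, `gc_percent`, `n_members`, `te_similarity`, `te_class`,
#'   `is_te`, `chromosomes`), `membership` (`array_id` -> `family_id`) and
#'   the member `arrays`.
#' @export
cluster_families <- function(catalog, matches, score_threshold = 200) {
  arrays <- if (inherits(catalog, "tr_catalog")) catalog$arrays else catalog
  if (nrow(arrays) == 0) stop("empty catalog")
  ids <- arrays$array_id
  strong <- matches[matches$score > score_threshold &
                      matches$array_a %in% ids & matches$array_b %in% ids, ,
                    drop = FALSE]
  g <- igraph::graph_from_data_frame(
    strong[, c("array_a", "array_b")], directed = FALSE,
    vertices = data.frame(name = ids))
  comp <- igraph::components(g)$membership[ids]
  # stable family ids: number components by first member in coordinate order
  ord <- order(arrays$assembly_id, arrays$contig_id, arrays$start)
  fid <- match(comp, unique(comp[ord]))
  membership <- data.frame(array_id = ids, family_id = fid,
                           stringsAsFactors = FALSE)
  fams <- do.call(rbind, lapply(sort(unique(fid)), function(f) {
    mem <- arrays[fid == f, , drop = FALSE]
    rep_row <- mem[homogeneity_order(mem)[1], ]
    data.frame(
      family_id = f, name = NA_character_,
      min_monomer = min(mem$period),
      representative = rep_row$consensus,
      rep_array = rep_row$array_seq,
      max_array_len = max(mem$end - mem$start),
      gc_percent = round(gc_percent(paste0(mem$array_seq, collapse = "")), 1),
      n_members = nrow(mem),
      te_similarity = NA_character_, te_class = NA_character_, is_te = FALSE,
      chromosomes = NA_character_,
      stringsAsFactors = FALSE)
  }))
  structure(list(families = fams, membership = membership, arrays = arrays),
            class = "tr_families")
}

#' @export
print.tr_families <- function(x, ...) {
  cat("Tandem-repeat families: ", nrow(x$families), " families over ",
      nrow(x$membership), " arrays\n", sep = "")
  invisible(x)
}

# letter suffix: A..Z, then AA, AB, ...
letter_suffix <- function(i) {
  if (i <= 26) return(LETTERS[i])
  paste0(LETTERS[(i - 1) %/% 26], LETTERS[(i - 1) %% 26 + 1])
}

#' Name families by minimum monomer length
#'
#' A family name is `<prefix><numeral><letter>`: the numeral is the minimum
#' monomer length (bp) among the family's arrays and the letter
#' disambiguates families sharing a numeral. Letters are assigned in order
#' of first genomic occurrence (assembly id, contig id, start of the
#' earliest member), which makes naming deterministic and independent of
#' input order. The species prefix (e.g. "CG") may be empty when only one
#' species is analysed.
#'
#' @param fams a `tr_families` object.
#' @param species_prefix prefix prepended to every name; default none.
#' @return the `tr_families` object with `name` filled in.
#' @export
assign_names <- function(fams, species_prefix = "") {
  arrays <- fams$arrays
  fid <- fams$membership$family_id[match(arrays$array_id,
                                         fams$membership$array_id)]
  first_idx <- vapply(fams$families$family_id, function(f) {
    mem <- which(fid == f)
    mem[order(arrays$assembly_id[mem], arrays$contig_id[mem],
              arrays$start[mem])][1]
  }, integer(1))
  occ <- order(arrays$assembly_id[first_idx], arrays$contig_id[first_idx],
               arrays$start[first_idx])
  names_out <- character(nrow(fams$families))
  for (mono in unique(fams$families$min_monomer)) {
    idx <- which(fams$families$min_monomer == mono)
    idx <- idx[order(match(idx, occ))]
    for (r in seq_along(idx))
      names_out[idx[r]] <- paste0(species_prefix, mono, letter_suffix(r))
  }
  fams$families$name <- names_out
  fams
}

#' Annotate families against a repeat library
#'
#' Each family member array is tiled and every tile locally aligned against
#' each library entry; an entry "covers" an array when at least
#' `coverage_threshold` of its tiles reach a near-identity local score.
#' The family is annotated with the best covering entry; entries whose
#' library class is not a transposable-element class (satellites, gene
#' fragments such as Zn-finger) are recorded but flagged `is_te = FALSE`,
#' so they do not disqualify a family from probe design.
#'
#' @param fams a `tr_families` object.
#' @param repeat_library data.frame from [read_repeat_library()].
#' @param coverage_threshold minimum covered fraction of a member array.
#' @param tile_bp tile width used to measure coverage.
#' @return the `tr_families` object with `te_similarity`, `te_class`,
#'   `is_te` filled in.
#' @export
annotate_library <- function(fams, repeat_library, coverage_threshold = 0.80,
                             tile_bp = 50) {
  if (nrow(repeat_library) == 0) stop("empty repeat library")
  arrays <- fams$arrays
  fid <- fams$membership$family_id[match(arrays$array_id,
                                         fams$membership$array_id)]
  for (r in seq_len(nrow(fams$families))) {
    f <- fams$families$family_id[r]
    mem <- arrays[fid == f, , drop = FALSE]
    best_name <- NA_character_; best_cov <- 0; best_class <- NA_character_
    for (e in seq_len(nrow(repeat_library))) {
      for (m in seq_len(nrow(mem))) {
        cov <- tile_coverage(mem$array_seq[m], repeat_library$sequence[e],
                             tile_bp)
        if (cov > best_cov) {
          best_cov <- cov
          best_name <- repeat_library$name[e]
          best_class <- repeat_library$class[e]
        }
      }
    }
    if (best_cov >= coverage_threshold) {
      fams$families$te_similarity[r] <- best_name
      fams$families$te_class[r] <- best_class
      fams$families$is_te[r] <- best_class %in% TE_CLASSES
    }
  }
  fams
}

# fraction of an array's tiles that align to the library entry: a tile
# counts as covered when its best local score reaches half the perfect
# score (breakeven ~80% identity over the full tile under +2/-3 scoring,
# or higher identity over a shorter span); random 50 bp tiles against a
# few-hundred-bp entry stay far below this. Both strands tried.
tile_coverage <- function(array_seq, entry_seq, tile_bp = 50) {
  n <- nchar(array_seq)
  if (n < tile_bp) {
    starts <- 1L; widths <- n
  } else {
    starts <- seq(1L, n - tile_bp + 1L, by = tile_bp)
    widths <- rep(tile_bp, length(starts))
  }
  entry_rc <- revcomp(entry_seq)
  covered <- vapply(seq_along(starts), function(i) {
    tile <- substr(array_seq, starts[i], starts[i] + widths[i] - 1L)
    thr <- nchar(tile)   # half of the maximum score 2 * tile length
    if (local_score(tile, entry_seq) >= thr) return(TRUE)
    local_score(tile, entry_rc) >= thr
  }, logical(1))
  mean(covered)
}

#' Flag simple-sequence families
#'
#' A family is "simple" (unsuitable for a specific probe) when its minimum
#' monomer is shorter than `min_complex_monomer` or the dinucleotide
#' entropy of its representative monomer is below 1 bit — e.g. a pure
#' (AT)n repeat reported with a degenerate longer period.
#'
#' @param fams a `tr_families` object, or a family table with
#'   `min_monomer` and `representative` columns.
#' @param min_complex_monomer minimum monomer length for a complex family.
#' @return logical vector, one element per family.
#' @export
flag_simple <- function(fams, min_complex_monomer = 10) {
  tab <- if (inherits(fams, "tr_families")) fams$families else fams
  vapply(seq_len(nrow(tab)), function(i) {
    tab$min_monomer[i] < min_complex_monomer ||
      dinucleotide_entropy(tab$representative[i]) < 1.0
  }, logical(1))
}

#' Per-family diagnostics replacing a manual error check
#'
#' Flags families whose members' pairwise identity spread exceeds
#' `max_spread` percentage points — heterogeneous clusters that a curator
#' would inspect. No silent edits are made.
#'
#' @param fams a `tr_families` object.
#' @param max_spread maximum tolerated identity spread, percentage points.
#' @return data.frame with `family_id`, `name`, `identity_min`,
#'   `identity_max`, `flagged`.
#' @export
family_diagnostics <- function(fams, max_spread = 30) {
  arrays <- fams$arrays
  fid <- fams$membership$family_id[match(arrays$array_id,
                                         fams$membership$array_id)]
  out <- lapply(seq_len(nrow(fams$families)), function(r) {
    f <- fams$families$family_id[r]
    mem <- arrays[fid == f, , drop = FALSE]
    if (nrow(mem) < 2)
      return(data.frame(family_id = f, name = fams$families$name[r],
                        identity_min = NA_real_, identity_max = NA_real_,
                        flagged = FALSE))
    pids <- c()
    for (i in seq_len(nrow(mem) - 1)) {
      for (j in seq(i + 1, nrow(mem))) {
        al <- Biostrings::pairwiseAlignment(
          Biostrings::DNAString(mem$array_seq[i]),
          Biostrings::DNAString(mem$array_seq[j]),
          type = "local", substitutionMatrix = sub_matrix(),
          gapOpening = 5, gapExtension = 2)
        pids <- c(pids, Biostrings::pid(al))
      }
    }
    data.frame(family_id = f, name = fams$families$name[r],
               identity_min = min(pids), identity_max = max(pids),
               flagged = (max(pids) - min(pids)) > max_spread)
  })
  do.call(rbind, out)
}

#' Family summary table
#'
#' One row per family with the standard reporting columns: name, maximum
#' array length, GC percent, abundance percent (if estimated), assembly of
#' maximum content, chromosomes in silico, repeat-library similarity.
#'
#' @param fams a `tr_families` object.
#' @param abundance optional data.frame from [estimate_abundance()] rows
#'   (`name`, `percent`) to merge in.
#' @return data.frame in reporting column order.
#' @export
family_table <- function(fams, abundance = NULL) {
  f <- fams$families
  arrays <- fams$arrays
  fid <- fams$membership$family_id[match(arrays$array_id,
                                         fams$membership$array_id)]
  max_asm <- vapply(f$family_id, function(ff) {
    mem <- arrays[fid == ff, , drop = FALSE]
    bp <- tapply(mem$end - mem$start, mem$assembly_id, sum)
    names(bp)[which.max(bp)] %||% NA_character_
  }, character(1))
  out <- data.frame(
    name = f$name, max_array_len = f$max_array_len,
    gc_percent = f$gc_percent,
    abundance_percent = NA_real_,
    assembly = max_asm,
    chromosomes = f$chromosomes,
    te_similarity = ifelse(is.na(f$te_similarity), "", f$te_similarity),
    stringsAsFactors = FALSE)
  if (!is.null(abundance))
    out$abundance_percent <- abundance$percent[match(out$name, abundance$name)]
  out[order(-out$max_array_len), ]
}
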