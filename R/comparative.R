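#' Match families across assemblies
#'
#' Families from different assemblies are declared equivalent when their
#' representative arrays (the array sequence of each family's most
#' homogeneous member) reach a local-alignment score strictly above
#' `score_threshold` — the same criterion that links arrays within an
#' assembly. Each family keeps at most one link per other assembly: the
#' best-scoring reciprocal match.
#'
#' @param sets named list (assembly id -> `tr_families` object), two or
#'   more assemblies.
#' @param score_threshold minimum (exclusive) representative-pair score.
#' @return data.frame of cross-links: `assembly_a`, `family_a`,
#'   `assembly_b`, `family_b`, `score`.
#' @export
match_families_across <- function(sets, score_threshold = 200) {
  if (length(sets) < 2) stop("need at least two assemblies")
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("sets must be a named list of assemblies")
  links <- list()
  asm <- names(sets)
  for (i in seq_len(length(asm) - 1)) {
    for (j in seq(i + 1, length(asm))) {
      fa <- sets[[i]]$families; fb <- sets[[j]]$families
      sc <- matrix(0, nrow(fa), nrow(fb))
      for (a in seq_len(nrow(fa))) {
        for (b in seq_len(nrow(fb))) {
          s <- max(local_score(fa$rep_array[a], fb$rep_array[b]),
                   local_score(fa$rep_array[a], revcomp(fb$rep_array[b])))
          sc[a, b] <- s
        }
      }
      sc[sc <= score_threshold] <- 0
      # best reciprocal links only
      while (any(sc > 0)) {
        best <- which(sc == max(sc), arr.ind = TRUE)[1, ]
        links[[length(links) + 1L]] <- data.frame(
          assembly_a = asm[i], family_a = fa$name[best[1]],
          assembly_b = asm[j], family_b = fb$name[best[2]],
          score = sc[best[1], best[2]], stringsAsFactors = FALSE)
        sc[best[1], ] <- 0
        sc[, best[2]] <- 0
      }
    }
  }
  if (length(links) == 0)
    return(data.frame(assembly_a = character(0), family_a = character(0),
                      assembly_b = character(0), family_b = character(0),
                      score = numeric(0)))
  do.call(rbind, links)
}

#' Assembly co-occurrence classes of cross-linked families
#'
#' Cross-linked families are merged into equivalence groups (connected
#' components over the link graph); each group's class is the set of
#' assemblies it occurs in. Classes are disjoint and exhaustive over the
#' union of families.
#'
#' @param sets named list (assembly id -> `tr_families`).
#' @param links cross-link table from [match_families_across()].
#' @return data.frame with one row per family group: `group_id`, `class`
#'   (assembly ids joined by "+"), `n_assemblies`, `families` (assembly:name
#'   pairs joined by ","), `label` (name of the member from the first
#'   assembly present).
#' @export
intersection_classes <- function(sets, links) {
  nodes <- unlist(lapply(names(sets), function(a)
    paste0(a, ":", sets[[a]]$families$name)))
  edges <- if (nrow(links)) {
    data.frame(from = paste0(links$assembly_a, ":", links$family_a),
               to = paste0(links$assembly_b, ":", links$family_b))
  } else {
    data.frame(from = character(0), to = character(0))
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = nodes))
  comp <- igraph::components(g)$membership
  out <- lapply(sort(unique(comp)), function(cc) {
    mem <- names(comp)[comp == cc]
    asms <- sub(":.*$", "", mem)
    fam <- sub("^[^:]*:", "", mem)
    first <- order(match(asms, names(sets)))[1]
    data.frame(group_id = cc,
               class = paste(sort(unique(asms)), collapse = "+"),
               n_assemblies = length(unique(asms)),
               families = paste(mem, collapse = ","),
               label = fam[first], stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Assign in-silico chromosomes to families
#'
#' Union of the chromosome labels of the contigs bearing each family's
#' arrays. Group labels (e.g. "9-10" for chromosomes that could not be
#' separated during flow sorting) are preserved verbatim. Contigs absent
#' from the map, or a missing map, yield "NA".
#'
#' @param fams a `tr_families` object.
#' @param chrom_map named character vector from [read_chrom_map()], or NULL.
#' @return the `tr_families` object with the `chromosomes` column filled.
#' @export
assign_chromosomes <- function(fams, chrom_map = NULL) {
  arrays <- fams$arrays
  fid <- fams$membership$family_id[match(arrays$array_id,
                                         fams$membership$array_id)]
  fams$families$chromosomes <- vapply(fams$families$family_id, function(f) {
    if (is.null(chrom_map)) return("NA")
    ctgs <- unique(arrays$contig_id[fid == f])
    labs <- chrom_map[ctgs]
    labs[is.na(labs)] <- "NA"
    paste(sort(unique(labs)), collapse = ", ")
  }, character(1))
  fams
}

#' Estimate genome abundance of a family from raw reads
#'
#' A read counts as aligned to the family when at least
#' `min_kmer_fraction` of its k-mers (on either strand) occur in the k-mer
#' set of the family's member arrays; the family's genome abundance is the
#' percentage of aligned reads. This mirrors a sensitive-local read
#' alignment (most of the read must be covered by family sequence) without
#' an external aligner; counts from such an aligner can be supplied to
#' [abundance_from_counts()] instead.
#'
#' @param family_seqs character vector of the family's array sequences, or
#'   a `tr_families` object plus `name`.
#' @param reads character vector of read sequences, or a data.frame with a
#'   `sequence` column.
#' @param min_kmer_fraction minimum fraction of read k-mers that must be
#'   family k-mers.
#' @param k k-mer length.
#' @param name family name carried into the result.
#' @return data.frame row: `name`, `reads_aligned`, `reads_total`, `percent`.
#' @export
estimate_abundance <- function(family_seqs, reads, min_kmer_fraction = 0.5,
                               k = 21, name = NA_character_) {
  if (inherits(family_seqs, "tr_families")) {
    fams <- family_seqs
    if (is.na(name)) stop("give the family name when passing a tr_families")
    f <- fams$families$family_id[fams$families$name == name]
    ids <- fams$membership$array_id[fams$membership$family_id == f]
    family_seqs <- fams$arrays$array_seq[fams$arrays$array_id %in% ids]
  }
  if (is.data.frame(reads)) reads <- reads$sequence
  if (length(reads) == 0) stop("no reads")
  long_enough <- nchar(reads) >= k
  if (!all(long_enough)) {
    warning(sum(!long_enough), " reads shorter than k = ", k,
            " excluded from the denominator")
    reads <- reads[long_enough]
  }
  fam_kmers <- unique(unlist(lapply(c(family_seqs, revcomp(family_seqs)),
                                    kmers_of, k = k), use.names = FALSE))
  aligned <- vapply(reads, function(r) {
    km <- kmers_of(r, k)
    mean(km %in% fam_kmers) >= min_kmer_fraction
  }, logical(1), USE.NAMES = FALSE)
  data.frame(name = name, reads_aligned = sum(aligned),
             reads_total = length(reads),
             percent = 100 * sum(aligned) / length(reads),
             stringsAsFactors = FALSE)
}

#' Abundance from externally computed alignment counts
#'
#' Seam for substituting a sensitive-local read aligner: supply the aligned
#' and total read counts and get the same `AbundanceEstimate` row.
#'
#' @param name family name.
#' @param reads_aligned,reads_total counts.
#' @return data.frame row as in [estimate_abundance()].
#' @export
abundance_from_counts <- function(name, reads_aligned, reads_total) {
  stopifnot(reads_total > 0, reads_aligned >= 0, reads_aligned <= reads_total)
  data.frame(name = name, reads_aligned = reads_aligned,
             reads_total = reads_total,
             percent = 100 * reads_aligned / reads_total,
             stringsAsFactors = FALSE)
}
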