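#' Specification of one implanted repeat family
#'
#' Describes a ground-truth tandem-repeat family for the synthetic-genome
#' generator: the monomer (given, or drawn with a length and GC), how many
#' arrays to implant per assembly, copy number and per-copy divergence, and
#' which assemblies carry the family.
#'
#' @param name family label used in the truth tables.
#' @param monomer explicit monomer sequence; if NULL one is drawn.
#' @param monomer_length,gc length (bp) and GC fraction used to draw a
#'   monomer when `monomer` is NULL.
#' @param copies copies per array: a single number or a `c(min, max)` range.
#' @param sub_rate per-base substitution rate applied to each copy.
#' @param indel_rate per-base indel rate applied to each copy (half
#'   insertions, half deletions).
#' @param n_arrays arrays implanted per assembly carrying the family.
#' @param assemblies_present assembly ids carrying the family; NULL = all.
#' @param te_entry optional repeat-library entry sequence; when given the
#'   monomer is a fragment of it and the family is flagged TE-derived.
#' @return an object of class `implant_spec`.
#' @export
implant_spec <- function(name, monomer = NULL, monomer_length = 50, gc = 0.5,
                         copies = 30, sub_rate = 0.05, indel_rate = 0,
                         n_arrays = 2, assemblies_present = NULL,
                         te_entry = NULL) {
  stopifnot(sub_rate >= 0, sub_rate <= 0.3, indel_rate >= 0, indel_rate <= 0.3,
            all(copies >= 2))
  structure(list(name = name, monomer = monomer,
                 monomer_length = monomer_length, gc = gc, copies = copies,
                 sub_rate = sub_rate, indel_rate = indel_rate,
                 n_arrays = n_arrays, assemblies_present = assemblies_present,
                 te_entry = te_entry),
            class = "implant_spec")
}

# iid random sequence at a given GC fraction
random_seq <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste0(sample(BASES, n, replace = TRUE, prob = p), collapse = "")
}

# random monomer honoring the requested GC exactly (short monomers pin the
# composition of every probe window, so the draw must not drift)
random_monomer <- function(n, gc = 0.5) {
  n_gc <- round(gc * n)
  chars <- c(sample(c("G", "C"), n_gc, replace = TRUE),
             sample(c("A", "T"), n - n_gc, replace = TRUE))
  paste0(sample(chars), collapse = "")
}

# one diverged copy of a monomer: substitutions then indels, per base
mutate_copy <- function(monomer, sub_rate, indel_rate) {
  chars <- strsplit(monomer, "")[[1]]
  n <- length(chars)
  if (sub_rate > 0) {
    hit <- runif(n) < sub_rate
    if (any(hit)) {
      chars[hit] <- vapply(chars[hit], function(b)
        sample(setdiff(BASES, b), 1), character(1))
    }
  }
  if (indel_rate > 0) {
    out <- character(0)
    for (i in seq_len(n)) {
      u <- runif(1)
      if (u < indel_rate / 2) next                      # deletion
      out <- c(out, chars[i])
      if (u >= 1 - indel_rate / 2) out <- c(out, sample(BASES, 1))  # insertion
    }
    chars <- out
  }
  paste0(chars, collapse = "")
}

# a full array: tandem of diverged copies
build_array <- function(monomer, copies, sub_rate, indel_rate) {
  paste0(vapply(seq_len(copies), function(i)
    mutate_copy(monomer, sub_rate, indel_rate), character(1)), collapse = "")
}

#' Generate synthetic assemblies with implanted tandem arrays
#'
#' Builds `n_assemblies` genomes of iid background sequence, implants each
#' family's arrays at non-overlapping uniform positions in the assemblies
#' that carry it (replacing background segments, so the stated contig
#' lengths — and hence the truth fractions — are exact), and returns the
#' ground truth (monomers, intervals, per-assembly genomic fractions). Fully reproducible from the seed; the
#' per-assembly, per-family random streams are derived from it so stages
#' can be regenerated independently.
#'
#' @param specs list of [implant_spec()] objects.
#' @param n_assemblies number of assemblies to emit.
#' @param contig_lengths integer vector of contig lengths used for every
#'   assembly.
#' @param background_gc GC fraction of the background sequence.
#' @param seed integer seed.
#' @param assembly_ids optional assembly names; default "asm1", "asm2", ...
#' @return list with `assemblies` (named list of sequence-record
#'   data.frames), and `truth`: `families` (name, monomer, te_derived),
#'   `arrays` (family, assembly_id, contig_id, start, end; 0-based
#'   half-open), `fractions` (family, assembly_id, fraction in percent).
#' @export
make_assemblies <- function(specs, n_assemblies = 3,
                            contig_lengths = c(50000, 30000),
                            background_gc = 0.42, seed = 1,
                            assembly_ids = NULL) {
  if (inherits(specs, "implant_spec")) specs <- list(specs)
  asm_ids <- assembly_ids %||% paste0("asm", seq_len(n_assemblies))
  # monomers are family properties shared across assemblies
  monomers <- lapply(seq_along(specs), function(i) {
    sp <- specs[[i]]
    if (!is.null(sp$monomer)) return(clean_seq(sp$monomer))
    if (!is.null(sp$te_entry)) {
      with_seed(split_seed(seed, 1000 + i), {
        frag_len <- min(nchar(sp$te_entry), sp$monomer_length)
        s0 <- sample(nchar(sp$te_entry) - frag_len + 1L, 1)
        substr(clean_seq(sp$te_entry), s0, s0 + frag_len - 1L)
      })
    } else {
      with_seed(split_seed(seed, 1000 + i),
                random_monomer(sp$monomer_length, sp$gc))
    }
  })
  total_bp <- sum(contig_lengths)
  est_implant <- sum(vapply(seq_along(specs), function(i) {
    sp <- specs[[i]]
    mean(sp$copies) * nchar(monomers[[i]]) * sp$n_arrays
  }, numeric(1)))
  if (est_implant >= 0.5 * total_bp)
    stop("infeasible packing: implants would exceed half the genome")

  assemblies <- list()
  truth_arrays <- list()
  for (a in seq_len(n_assemblies)) {
    contigs <- lapply(seq_along(contig_lengths), function(ci)
      with_seed(split_seed(seed, a * 100 + ci),
                random_seq(contig_lengths[ci], background_gc)))
    names(contigs) <- paste0(asm_ids[a], "_c", seq_along(contig_lengths))
    occupied <- lapply(contigs, function(x) NULL)
    for (i in seq_along(specs)) {
      sp <- specs[[i]]
      present <- sp$assemblies_present %||% asm_ids
      if (!(asm_ids[a] %in% present)) next
      with_seed(split_seed(seed, a * 100000 + i), {
        for (ar in seq_len(sp$n_arrays)) {
          cp <- if (length(sp$copies) == 2) sample(sp$copies[1]:sp$copies[2], 1)
                else sp$copies
          arr <- build_array(monomers[[i]], cp, sp$sub_rate, sp$indel_rate)
          placed <- FALSE
          for (try in 1:500) {
            ci <- sample(seq_along(contigs), 1,
                         prob = vapply(contigs, nchar, numeric(1)))
            L <- nchar(contigs[[ci]])
            if (L < nchar(arr) + 2) next
            # replace a background segment so contig lengths (and truth
            # fractions over them) stay exactly as specified
            s0 <- sample(L - nchar(arr), 1)        # 1-based segment start
            iv <- c(s0 - 1L, s0 - 1L + nchar(arr)) # 0-based half-open
            occ <- occupied[[ci]]
            clash <- !is.null(occ) &&
              any(pmin(occ[, 2], iv[2]) > pmax(occ[, 1], iv[1]))
            if (clash) next
            contigs[[ci]] <- paste0(substr(contigs[[ci]], 1, s0 - 1L),
                                    arr,
                                    substr(contigs[[ci]], s0 + nchar(arr), L))
            occupied[[ci]] <- rbind(occ, iv)
            truth_arrays[[length(truth_arrays) + 1L]] <- data.frame(
              family = sp$name, assembly_id = asm_ids[a],
              contig_id = names(contigs)[ci],
              start = iv[1], end = iv[2], stringsAsFactors = FALSE)
            placed <- TRUE
            break
          }
          if (!placed) stop("infeasible packing: could not place an array of ",
                            sp$name, " in ", asm_ids[a])
        }
      })
    }
    assemblies[[asm_ids[a]]] <- data.frame(
      id = names(contigs), sequence = unlist(contigs, use.names = FALSE),
      source = paste0("generator:seed=", seed), stringsAsFactors = FALSE)
  }
  tarr <- do.call(rbind, truth_arrays)
  tfam <- data.frame(
    family = vapply(specs, `[[`, character(1), "name"),
    monomer = unlist(monomers),
    te_derived = vapply(specs, function(s) !is.null(s$te_entry), logical(1)),
    stringsAsFactors = FALSE)
  fr <- do.call(rbind, lapply(names(assemblies), function(aid) {
    gsize <- sum(nchar(assemblies[[aid]]$sequence))
    sub <- tarr[tarr$assembly_id == aid, , drop = FALSE]
    if (nrow(sub) == 0) return(NULL)
    bp <- tapply(sub$end - sub$start, sub$family, sum)
    data.frame(family = names(bp), assembly_id = aid,
               fraction = 100 * as.numeric(bp) / gsize,
               stringsAsFactors = FALSE)
  }))
  list(assemblies = assemblies,
       truth = list(families = tfam, arrays = tarr, fractions = fr))
}

#' Simulate raw reads from an assembly
#'
#' Uniform start positions over contigs, both strands equally likely,
#' iid per-base substitution errors. The read count is
#' `round(coverage * genome_bp / read_length)`. When ground-truth array
#' intervals are supplied, each read is labelled with whether at least half
#' of it lies inside an implanted array.
#'
#' @param records assembly sequence-record data.frame.
#' @param read_length read length, bp.
#' @param coverage mean genome coverage.
#' @param error_rate per-base substitution error rate.
#' @param seed integer seed.
#' @param truth_arrays optional truth interval table from
#'   [make_assemblies()] (columns `family`, `contig_id`, `start`, `end`).
#' @return data.frame of reads: `id`, `sequence`, `contig_id`, `start`,
#'   `end`, `strand`, and `in_array` / `array_family` when truth was given.
#' @export
make_reads <- function(records, read_length = 100, coverage = 20,
                       error_rate = 0, seed = 1, truth_arrays = NULL) {
  lens <- nchar(records$sequence)
  if (read_length > min(lens))
    stop("read_length exceeds the shortest contig")
  n_reads <- round(coverage * sum(lens) / read_length)
  with_seed(split_seed(seed, 77), {
    ci <- sample(seq_len(nrow(records)), n_reads, replace = TRUE,
                 prob = lens - read_length + 1)
    s0 <- vapply(ci, function(x)
      sample(lens[x] - read_length + 1L, 1), integer(1))
    strand <- sample(c("+", "-"), n_reads, replace = TRUE)
    seqs <- substring(records$sequence[ci], s0, s0 + read_length - 1L)
    seqs[strand == "-"] <- revcomp(seqs[strand == "-"])
    if (error_rate > 0) {
      seqs <- vapply(seqs, function(s) {
        ch <- strsplit(s, "")[[1]]
        hit <- runif(length(ch)) < error_rate
        if (any(hit))
          ch[hit] <- vapply(ch[hit], function(b)
            sample(setdiff(BASES, b), 1), character(1))
        paste0(ch, collapse = "")
      }, character(1), USE.NAMES = FALSE)
    }
    out <- data.frame(id = sprintf("read%06d", seq_len(n_reads)),
                      sequence = seqs, contig_id = records$id[ci],
                      start = s0 - 1L, end = s0 - 1L + read_length,
                      strand = strand, stringsAsFactors = FALSE)
    if (!is.null(truth_arrays)) {
      out$in_array <- FALSE
      out$array_family <- NA_character_
      for (i in seq_len(nrow(truth_arrays))) {
        t <- truth_arrays[i, ]
        ov <- pmin(out$end, t$end) - pmax(out$start, t$start)
        hit <- out$contig_id == t$contig_id & ov >= read_length / 2
        out$in_array[hit] <- TRUE
        out$array_family[hit] <- t$family
      }
    }
    out
  })
}

#' Write reads as FASTQ
#'
#' Constant quality ("I") placeholder scores; the pipeline does not use
#' qualities.
#'
#' @param reads read table from [make_reads()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_fastq <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", reads$id, "\n", reads$sequence, "\n+\n",
                    vapply(nchar(reads$sequence), function(n)
                      strrep("I", n), character(1))), con)
  invisible(path)
}

#' Reference synthetic scenario
#'
#' A three-assembly benchmark with five implanted families spanning the
#' monomer-length and divergence ranges typical of rodent satellites:
#' monomers 20-120 bp, per-copy divergence 2-10%, four families in all
#' three assemblies (one of them a tandemized fragment of a repeat-library
#' LTR entry, i.e. TE-derived), and one family restricted to the first two
#' assemblies. Returns the implant specs plus the toy repeat library used
#' for annotation.
#'
#' @param seed integer seed used to draw the library entry.
#' @return list with `specs` (list of [implant_spec()]), `library`
#'   (repeat-library data.frame), `n_assemblies`, `contig_lengths`.
#' @export
reference_scenario <- function(seed = 1) {
  te_seq <- with_seed(split_seed(seed, 999), random_seq(300, 0.45))
  library_df <- data.frame(name = "ERVtoy", class = "LTR", subclass = "ERV2",
                           sequence = te_seq, stringsAsFactors = FALSE)
  specs <- list(
    implant_spec("famA", monomer_length = 40, gc = 0.45, copies = 30,
                 sub_rate = 0.02, n_arrays = 2),
    implant_spec("famB", monomer_length = 20, gc = 0.50, copies = 40,
                 sub_rate = 0.05, n_arrays = 2),
    implant_spec("famC", monomer_length = 120, gc = 0.40, copies = 12,
                 sub_rate = 0.10, n_arrays = 2),
    implant_spec("famD", monomer_length = 60, gc = 0.55, copies = 20,
                 sub_rate = 0.05, n_arrays = 2,
                 assemblies_present = c("asm1", "asm2")),
    implant_spec("famTE", monomer_length = 80, copies = 15, sub_rate = 0.05,
                 n_arrays = 2, te_entry = te_seq))
  list(specs = specs, library = library_df, n_assemblies = 3,
       contig_lengths = c(30000, 20000))
}
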