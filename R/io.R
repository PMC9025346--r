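#' Read a FASTA file into a sequence-record table
#'
#' Sequences are case-folded to uppercase and any character outside
#' \{A,C,G,T,N\} is mapped to N. Duplicate record ids are an error because
#' downstream stages key arrays by contig id.
#'
#' @param path path to a FASTA file.
#' @return a data.frame with columns `id`, `sequence`, `source`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file does not exist: ", path)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || !any(nzchar(lines)))
    stop("format error in ", path, ": empty file (line 1)")
  first <- which(nzchar(lines))[1]
  if (!startsWith(lines[first], ">"))
    stop("format error in ", path, ": expected '>' header (line ", first, ")")
  x <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  if (any(ids == ""))
    stop("format error in ", path, ": empty record id")
  if (anyDuplicated(ids))
    stop("duplicate record ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- clean_seq(as.character(x))
  if (any(nchar(seqs) < 1))
    stop("format error in ", path, ": zero-length sequence for ",
         ids[nchar(seqs) < 1][1])
  data.frame(id = ids, sequence = unname(seqs), source = path,
             stringsAsFactors = FALSE)
}

#' Write sequence records to FASTA
#'
#' @param records data.frame with `id` and `sequence` columns, or a named
#'   character vector.
#' @param path output path.
#' @param width line width for wrapping.
#' @return the path, invisibly.
#' @export
write_fasta <- function(records, path, width = 70) {
  if (is.character(records)) {
    records <- data.frame(id = names(records), sequence = unname(records),
                          stringsAsFactors = FALSE)
  }
  x <- Biostrings::DNAStringSet(records$sequence)
  names(x) <- records$id
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Read a FASTQ file into a sequence-record table
#'
#' Quality strings are dropped; the pipeline's abundance estimator works on
#' bases only.
#'
#' @param path path to a FASTQ file.
#' @return a data.frame with columns `id`, `sequence`, `source`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file does not exist: ", path)
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  data.frame(id = sub("\\s.*$", "", names(x)),
             sequence = clean_seq(as.character(x)),
             source = path, stringsAsFactors = FALSE)
}

# TRF .dat data records carry 15 whitespace-separated fields:
# start end period copies consensus_size pct_match pct_indel score
# pctA pctC pctG pctT entropy consensus array_sequence
TRF_NCOL <- 15L

#' Parse Tandem Repeats Finder `.dat` output
#'
#' Supports the plain `.dat` dialect: optional header/parameter lines,
#' optional `Sequence: <id>` lines, and one whitespace-separated data record
#' per detected array. TRF coordinates are 1-based inclusive; they are
#' converted to the package's 0-based half-open convention at this boundary.
#'
#' @param path path to a `.dat` file.
#' @param contig_id contig id to assign to records when the file carries no
#'   `Sequence:` lines.
#' @param assembly_id assembly label stored on each array.
#' @return a TRArray table (see [detect_arrays()] for the column set).
#' @export
parse_trf_dat <- function(path, contig_id = NA_character_,
                          assembly_id = NA_character_) {
  if (!file.exists(path)) stop(".dat file does not exist: ", path)
  lines <- readLines(path, warn = FALSE)
  out <- list()
  cur <- contig_id
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    if (startsWith(ln, "Sequence:")) {
      cur <- trimws(sub("^Sequence:", "", ln))
      cur <- sub("\\s.*$", "", cur)
      next
    }
    if (!grepl("^[0-9]", ln)) next  # header / parameter lines
    f <- strsplit(ln, "\\s+")[[1]]
    if (length(f) != TRF_NCOL)
      stop("format error in ", path, " (line ", i, "): expected ",
           TRF_NCOL, " fields, got ", length(f))
    if (is.na(cur))
      stop("no contig id for record at line ", i,
           " (pass contig_id= or use 'Sequence:' lines)")
    start1 <- as.integer(f[1]); end1 <- as.integer(f[2])
    out[[length(out) + 1L]] <- data.frame(
      array_id = NA_character_, assembly_id = assembly_id, contig_id = cur,
      start = start1 - 1L, end = end1,
      period = as.integer(f[3]), copies = as.numeric(f[4]),
      percent_match = as.numeric(f[6]), percent_indel = as.numeric(f[7]),
      score = as.numeric(f[8]),
      consensus = clean_seq(f[14]), array_seq = clean_seq(f[15]),
      stringsAsFactors = FALSE
    )
  }
  if (length(out) == 0) return(empty_arrays())
  res <- do.call(rbind, out)
  res$array_id <- sprintf("%s:%d-%d", res$contig_id, res$start, res$end)
  res
}

#' Write a TRArray table in the TRF `.dat` dialect
#'
#' Inverse of [parse_trf_dat()]: internal 0-based half-open coordinates are
#' converted back to TRF's 1-based inclusive convention.
#'
#' @param arrays TRArray table.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_trf_dat <- function(arrays, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (ctg in unique(arrays$contig_id)) {
    writeLines(paste("Sequence:", ctg), con)
    sub <- arrays[arrays$contig_id == ctg, , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      a <- sub[i, ]
      comp <- sapply(BASES, function(b)
        round(100 * lengths(regmatches(a$array_seq, gregexpr(b, a$array_seq))) /
                max(1L, nchar(a$array_seq))))
      writeLines(paste(a$start + 1L, a$end, a$period,
                       format(a$copies, nsmall = 1), nchar(a$consensus),
                       round(a$percent_match), round(a$percent_indel),
                       round(a$score), comp[1], comp[2], comp[3], comp[4],
                       sprintf("%.2f", dinucleotide_entropy(a$array_seq)),
                       a$consensus, a$array_seq), con)
    }
  }
  invisible(path)
}

#' Read a contig-to-chromosome map
#'
#' Two-column tab-separated file (`contig_id`, `chromosome`), no comment
#' lines. Chromosome labels are kept verbatim, so group labels such as
#' "9-10" (chromosomes that could not be separated during flow sorting)
#' survive the round trip.
#'
#' @param path path to the TSV.
#' @return named character vector mapping contig id to chromosome label.
#' @export
read_chrom_map <- function(path) {
  df <- read.delim(path, header = FALSE, colClasses = "character")
  if (ncol(df) < 2) stop("chromosome map needs two columns: ", path)
  setNames(df[[2]], df[[1]])
}

#' Read a repeat library FASTA (RepeatMasker header dialect)
#'
#' Headers of the form `name#class/subclass` are split into entry name and
#' class; headers without `#` get class "Unknown". The class string decides
#' whether a library hit counts as a transposable element during probe
#' selection (see [annotate_library()]).
#'
#' @param path path to the library FASTA.
#' @return data.frame with columns `name`, `class`, `subclass`, `sequence`.
#' @export
read_repeat_library <- function(path) {
  recs <- read_fasta(path)
  full <- recs$id
  name <- sub("#.*$", "", full)
  cls <- ifelse(grepl("#", full), sub("^[^#]*#", "", full), "Unknown")
  class1 <- sub("/.*$", "", cls)
  subclass <- ifelse(grepl("/", cls), sub("^[^/]*/", "", cls), "")
  data.frame(name = name, class = class1, subclass = subclass,
             sequence = recs$sequence, stringsAsFactors = FALSE)
}

# repeat-library classes treated as transposable elements (probe exclusion);
# satellites, simple repeats, multicopy genes pass through
TE_CLASSES <- c("SINE", "LINE", "LTR", "DNA", "RC", "Retroposon", "TE")

#' Write arrays, families or probes to standard formats
#'
#' `format = "bed"` writes 0-based half-open intervals; `"tsv"` writes the
#' full table; `"fasta"` writes consensus monomers (arrays/families) or probe
#' sequences; `"json"` writes the object as a JSON report.
#'
#' @param x a TRArray table, family table or probe table.
#' @param path output path.
#' @param format one of "bed", "tsv", "fasta", "json".
#' @return the path, invisibly.
#' @export
write_catalog <- function(x, path, format = c("tsv", "bed", "fasta", "json")) {
  format <- match.arg(format)
  if (format == "bed") {
    assert_arrays(x)
    bed <- data.frame(x$contig_id, x$start, x$end,
                      x$array_id %||% ".",
                      round(x$score), ".")
    write.table(bed, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  } else if (format == "tsv") {
    write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else if (format == "fasta") {
    if (!is.null(x$sequence)) {
      write_fasta(data.frame(id = x$name %||% x$family, sequence = x$sequence),
                  path)
    } else {
      idcol <- x$name %||% x$array_id
      write_fasta(data.frame(id = idcol, sequence = x$consensus %||% x$representative),
                  path)
    }
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}
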