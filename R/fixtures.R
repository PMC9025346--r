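# Packaged reference data: the Chinese hamster (Cricetulus griseus)
# tandem-repeat family catalog, the assembly co-occurrence classes of those
# families across the AFTD / APMK / AMDS whole-genome assemblies, and the
# validated FISH oligo probe set. Used as desk-scale worked examples and to
# regression-test the selection rules.

fixture_path <- function(f) {
  system.file("extdata", f, package = "satfam", mustWork = TRUE)
}

#' Reference FISH probe set for C. griseus tandem-repeat families
#'
#' @return data.frame: `no`, `name` (family), `sequence`.
#' @export
cgriseus_probe_set <- function() {
  read.delim(fixture_path("cgriseus_probes.tsv"), colClasses = "character")
}

#' Reference assembly co-occurrence classes for C. griseus families
#'
#' Which named families are shared by which of the three genome assemblies
#' (AFTD, AMDS, APMK).
#'
#' @return data.frame: `class` (assembly ids joined by "+"), `families`
#'   (comma-separated names), `count`.
#' @export
cgriseus_cooccurrence <- function() {
  df <- read.delim(fixture_path("cgriseus_cooccurrence.tsv"),
                   colClasses = c("character", "character", "integer"))
  df
}

#' Reference tandem-repeat family catalog for C. griseus
#'
#' One row per family: maximum array length, GC, genome abundance, the
#' assembly of maximum content, in-silico chromosomes, and repeat-library
#' similarity with its class (TE classes versus satellite / gene fragment).
#'
#' @return data.frame with the reporting column set.
#' @export
cgriseus_family_catalog <- function() {
  df <- read.delim(fixture_path("cgriseus_families.tsv"), fill = TRUE,
                   stringsAsFactors = FALSE)
  df$te_similarity[is.na(df$te_similarity)] <- ""
  df$similarity_class[is.na(df$similarity_class)] <- ""
  df
}

#' Per-family assembly counts from a co-occurrence class table
#'
#' Expands a class table (one row per assembly combination with its family
#' list) into per-family assembly counts, the form
#' [select_probe_families()] consumes.
#'
#' @param cooc a class table as returned by [cgriseus_cooccurrence()] or
#'   [table3_report()].
#' @return data.frame: `name`, `n_assemblies`.
#' @export
cooccurrence_counts <- function(cooc) {
  out <- lapply(seq_len(nrow(cooc)), function(i) {
    fams <- trimws(strsplit(cooc$families[i], ",")[[1]])
    fams <- sub("^[^:]*:", "", fams)   # tolerate assembly:name entries
    data.frame(name = unique(fams),
               n_assemblies = length(strsplit(cooc$class[i], "+",
                                              fixed = TRUE)[[1]]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  # a family may appear via several groups; keep its maximum class size
  out <- out[order(out$name, -out$n_assemblies), ]
  out[!duplicated(out$name), ]
}
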