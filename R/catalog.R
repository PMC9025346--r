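#' Remove redundant arrays from raw detections
#'
#' Applies the non-redundancy rules that turn raw detector output into the
#' array catalog ("TR fields"): among arrays with identical coordinates only
#' the smallest monomer survives (ties: higher score, then lexicographically
#' smaller consensus); any array whose interval is contained within another
#' array's interval on the same contig is discarded; partially overlapping
#' arrays are kept as independent fields.
#'
#' The two rules are applied in that order, which makes them disjoint and
#' the result independent of input order. The operation is idempotent.
#'
#' @param arrays a TRArray table from one assembly.
#' @param assembly_id assembly label; defaults to the one on the arrays.
#' @return an object of class `tr_catalog`: list with `assembly_id`,
#'   `arrays` (the non-redundant table) and `provenance`.
#' @export
remove_redundant <- function(arrays, assembly_id = NULL) {
  assert_arrays(arrays)
  asm <- unique(stats::na.omit(arrays$assembly_id))
  if (length(asm) > 1)
    stop("arrays come from multiple assemblies: ", paste(asm, collapse = ", "))
  assembly_id <- assembly_id %||% (if (length(asm)) asm else NA_character_)
  n_input <- nrow(arrays)

  if (nrow(arrays) > 0) {
    # identical-coordinate rule first: keep smallest period
    key <- paste(arrays$contig_id, arrays$start, arrays$end)
    ord <- order(key, arrays$period, -arrays$score, arrays$consensus)
    arrays <- arrays[ord, , drop = FALSE]
    arrays <- arrays[!duplicated(paste(arrays$contig_id, arrays$start,
                                       arrays$end)), , drop = FALSE]
    # containment rule: drop intervals inside a strictly larger interval
    keep <- rep(TRUE, nrow(arrays))
    for (ctg in unique(arrays$contig_id)) {
      idx <- which(arrays$contig_id == ctg)
      s <- arrays$start[idx]; e <- arrays$end[idx]
      for (ii in seq_along(idx)) {
        contained <- s <= s[ii] & e >= e[ii] &
          (e - s) > (e[ii] - s[ii])
        if (any(contained)) keep[idx[ii]] <- FALSE
      }
    }
    arrays <- arrays[keep, , drop = FALSE]
    arrays <- arrays[order(arrays$contig_id, arrays$start, arrays$end), ,
                     drop = FALSE]
    rownames(arrays) <- NULL
  }
  structure(list(assembly_id = assembly_id, arrays = arrays,
                 provenance = list(n_input = n_input)),
            class = "tr_catalog")
}

#' @export
print.tr_catalog <- function(x, ...) {
  cat("Tandem-repeat array catalog (", x$assembly_id, "): ",
      nrow(x$arrays), " fields\n", sep = "")
  invisible(x)
}

#' Summary statistics of an array catalog
#'
#' Field count, total array bp (each field counted once; overlapping fields
#' are independent and may double-cover genomic bases) and a monomer-length
#' histogram.
#'
#' @param catalog a `tr_catalog` or a TRArray table.
#' @return list with `n_fields`, `total_bp`, `period_hist`.
#' @export
catalog_stats <- function(catalog) {
  arrays <- if (inherits(catalog, "tr_catalog")) catalog$arrays else catalog
  list(n_fields = nrow(arrays),
       total_bp = sum(arrays$end - arrays$start),
       period_hist = table(arrays$period))
}
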