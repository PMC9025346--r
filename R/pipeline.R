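#' Run the discovery pipeline end to end
#'
#' Composes the stages detect -> dedup -> cluster -> name -> annotate ->
#' compare -> abundance -> probes over one or more assemblies. Any prefix
#' of the stages runs when later inputs (repeat library, reads) are absent.
#' Every stage product is a plain data.frame so external tools can be
#' interposed at any seam (e.g. arrays parsed from a Tandem Repeats Finder
#' `.dat` file via [parse_trf_dat()] instead of the native detector).
#'
#' @param config list with entries:
#'   \describe{
#'     \item{assemblies}{named list of sequence-record data.frames (see
#'       [read_fasta()]), or a named character vector of FASTA paths.}
#'     \item{simulate}{alternatively, arguments for [make_assemblies()];
#'       ground truth is echoed in the report.}
#'     \item{params}{[detector_params()]; default paper-standard values.}
#'     \item{score_threshold}{family linkage score, default 200.}
#'     \item{evalue_max}{pair E-value cutoff, default 1e-15.}
#'     \item{repeat_library}{library data.frame from
#'       [read_repeat_library()], or NULL to skip annotation.}
#'     \item{coverage_threshold}{library coverage for a TE call, default 0.8.}
#'     \item{chrom_maps}{named list (assembly -> chromosome map) or NULL.}
#'     \item{reads}{read table or sequences for abundance, or NULL.}
#'     \item{abundance_k, abundance_min_fraction}{k-mer abundance knobs.}
#'     \item{design_probes}{logical, default TRUE when >= 2 assemblies.}
#'     \item{species_prefix}{family-name prefix, default "".}
#'     \item{seed}{integer seed for simulation.}
#'   }
#' @param verbose print per-stage progress lines with timings.
#' @return a report list: `config` echo, `counts` per stage, per-assembly
#'   `families` objects, `links`, `classes`, `table3`, `abundance`,
#'   `probes`, `diagnostics`, and `truth` when simulated.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  t0 <- Sys.time()
  report <- list(config = config[setdiff(names(config), "assemblies")],
                 counts = list(), timings = list())
  stage <- function(name, expr) {
    ts <- Sys.time()
    r <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    report$timings[[name]] <<- round(as.numeric(Sys.time() - ts, units = "secs"), 2)
    if (verbose) message(sprintf("[%s] %.2fs", name,
                                 report$timings[[name]]))
    r
  }

  ingested <- stage("ingest", {
    if (!is.null(config$simulate)) {
      do.call(make_assemblies,
              c(config$simulate, list(seed = config$seed %||% 1)))
    } else if (!is.null(config$assemblies)) {
      a <- config$assemblies
      if (is.character(a)) a <- lapply(a, read_fasta)
      if (is.null(names(a)) || any(!nzchar(names(a))))
        stop("assemblies must be named")
      if (length(a) == 0) stop("no assemblies given")
      a
    } else stop("no assemblies given")
  })
  if (!is.null(ingested$truth)) {
    report$truth <- ingested$truth
    assemblies <- ingested$assemblies
  } else {
    assemblies <- ingested
  }

  params <- config$params %||% detector_params()
  sets <- list()
  for (aid in names(assemblies)) {
    arrays <- stage(paste0("detect:", aid),
                    detect_arrays(assemblies[[aid]], params, assembly_id = aid))
    catalog <- stage(paste0("dedup:", aid), remove_redundant(arrays, aid))
    report$counts[[paste0("fields_", aid)]] <- nrow(catalog$arrays)
    matches <- stage(paste0("pairs:", aid),
                     score_pairs(catalog, config$evalue_max %||% 1e-15))
    fams <- stage(paste0("cluster:", aid),
                  cluster_families(catalog, matches,
                                   config$score_threshold %||% 200))
    fams <- stage(paste0("name:", aid),
                  assign_names(fams, config$species_prefix %||% ""))
    if (!is.null(config$repeat_library))
      fams <- stage(paste0("annotate:", aid),
                    annotate_library(fams, config$repeat_library,
                                     config$coverage_threshold %||% 0.80))
    fams <- assign_chromosomes(fams, config$chrom_maps[[aid]])
    report$counts[[paste0("families_", aid)]] <- nrow(fams$families)
    sets[[aid]] <- fams
  }
  report$families <- sets

  if (length(sets) >= 2) {
    report$links <- stage("compare",
                          match_families_across(sets,
                                                config$score_threshold %||% 200))
    report$classes <- intersection_classes(sets, report$links)
    report$table3 <- table3_report(report$classes)
  }

  if (!is.null(config$reads)) {
    report$abundance <- stage("abundance", {
      aid <- names(sets)[1]
      fams <- sets[[aid]]
      do.call(rbind, lapply(fams$families$name, function(nm)
        estimate_abundance(fams, config$reads,
                           config$abundance_min_fraction %||% 0.5,
                           config$abundance_k %||% 21, name = nm)))
    })
  }

  design <- config$design_probes %||% (length(sets) >= 2)
  if (isTRUE(design)) {
    report$probes <- stage("probes", {
      crit <- config$criteria %||% selection_criteria()
      aid <- names(sets)[1]
      fams <- sets[[aid]]
      ft <- fams$families
      ft$abundance_percent <-
        if (!is.null(report$abundance))
          report$abundance$percent[match(ft$name, report$abundance$name)]
        else NA_real_
      cooc <- if (length(sets) >= 2) cooccurrence_counts(
        data.frame(class = report$classes$class,
                   families = report$classes$families))
        else data.frame(name = ft$name, n_assemblies = 1L)
      simple <- flag_simple(fams, crit$min_monomer)
      sel <- select_probe_families(ft[!simple, , drop = FALSE], cooc, crit)
      probes <- lapply(sel$name, function(nm)
        tryCatch(design_probe(fams, nm), error = function(e) NULL))
      do.call(rbind, Filter(Negate(is.null), probes))
    })
    report$counts$probes <- if (is.null(report$probes)) 0L else nrow(report$probes)
  }

  report$diagnostics <- lapply(sets, family_diagnostics)
  report$elapsed <- round(as.numeric(Sys.time() - t0, units = "secs"), 2)
  report
}

#' Co-occurrence class report
#'
#' Formats intersection classes the standard way: the all-assemblies class
#' first, then each pair-only class, each with its family list and count,
#' plus a grand "at least two assemblies" total row labelled "All".
#'
#' @param classes data.frame from [intersection_classes()].
#' @return data.frame: `class`, `families`, `count`, with the total row last.
#' @export
table3_report <- function(classes) {
  multi <- classes[classes$n_assemblies >= 2, , drop = FALSE]
  rows <- lapply(split(multi, multi$class), function(g) {
    data.frame(class = g$class[1],
               families = paste(sort(g$label), collapse = ", "),
               count = nrow(g), stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows))
    rows <- data.frame(class = character(0), families = character(0),
                       count = integer(0))
  rows <- rows[order(-nchar(rows$class), rows$class), , drop = FALSE]
  total <- data.frame(class = "All", families = "", count = sum(rows$count),
                      stringsAsFactors = FALSE)
  out <- rbind(rows, total)
  rownames(out) <- NULL
  out
}

#' Write a JSON run report
#'
#' Serializes the scalar parts of a [run_pipeline()] report (config echo,
#' per-stage counts, timings) for reproducibility records.
#'
#' @param report a report list.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_run_report <- function(report, path) {
  keep <- list(config = report$config, counts = report$counts,
               timings = report$timings, elapsed = report$elapsed)
  jsonlite::write_json(keep, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}
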