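test_that("truth fractions are exact arithmetic over stated genome sizes", {
  sim <- make_assemblies(list(implant_spec("f", monomer_length = 21,
                                           copies = 30, sub_rate = 0,
                                           n_arrays = 1)),
                         n_assemblies = 1, contig_lengths = 10000, seed = 3)
  expect_equal(sum(nchar(sim$assemblies[[1]]$sequence)), 10000)
  expect_equal(sim$truth$fractions$fraction, 100 * 630 / 10000)
  # recount from the emitted sequence agrees exactly
  tr <- sim$truth$arrays
  expect_equal(sum(tr$end - tr$start), 630)
  arr_seq <- substr(sim$assemblies[[1]]$sequence[
    sim$assemblies[[1]]$id == tr$contig_id], tr$start + 1, tr$end)
  expect_equal(arr_seq, strrep(sim$truth$families$monomer, 30))
})

test_that("generation is reproducible from the seed and varies across seeds", {
  spec <- list(implant_spec("f", monomer_length = 30, copies = 10,
                            sub_rate = 0.05, n_arrays = 2))
  a <- make_assemblies(spec, n_assemblies = 2, contig_lengths = 5000, seed = 10)
  b <- make_assemblies(spec, n_assemblies = 2, contig_lengths = 5000, seed = 10)
  c <- make_assemblies(spec, n_assemblies = 2, contig_lengths = 5000, seed = 11)
  expect_identical(a, b)
  expect_false(identical(a$assemblies, c$assemblies))
})

test_that("families appear only in their declared assemblies", {
  sim <- make_assemblies(
    list(implant_spec("everywhere", monomer_length = 30, copies = 10,
                      n_arrays = 1),
         implant_spec("only2", monomer_length = 40, copies = 10, n_arrays = 1,
                      assemblies_present = c("asm1", "asm2"))),
    n_assemblies = 3, contig_lengths = 8000, seed = 12)
  tr <- sim$truth$arrays
  expect_setequal(unique(tr$assembly_id[tr$family == "everywhere"]),
                  c("asm1", "asm2", "asm3"))
  expect_setequal(unique(tr$assembly_id[tr$family == "only2"]),
                  c("asm1", "asm2"))
})

test_that("the divergence knob is calibrated against the monomer", {
  for (r in c(0.02, 0.10)) {
    sim <- make_assemblies(list(implant_spec("d", monomer_length = 50,
                                             copies = 40, sub_rate = r,
                                             n_arrays = 1)),
                           n_assemblies = 1, contig_lengths = 5000,
                           seed = 100 + round(100 * r))
    tr <- sim$truth$arrays
    arr <- substr(sim$assemblies[[1]]$sequence[
      sim$assemblies[[1]]$id == tr$contig_id], tr$start + 1, tr$end)
    mono <- sim$truth$families$monomer
    copies <- substring(arr, seq(1, nchar(arr), 50), seq(50, nchar(arr), 50))
    ident <- mean(vapply(copies, function(cp)
      mean(strsplit(cp, "")[[1]] == strsplit(mono, "")[[1]]), numeric(1)))
    expect_lt(abs(ident - (1 - r)), 0.01)
  }
})

test_that("infeasible packing is refused", {
  expect_error(make_assemblies(list(implant_spec("big", monomer_length = 100,
                                                 copies = 30, n_arrays = 10)),
                               n_assemblies = 1, contig_lengths = 5000,
                               seed = 1),
               "infeasible")
})

test_that("read simulation honours coverage, strands and error-free identity", {
  sim <- make_assemblies(list(implant_spec("f", monomer_length = 30,
                                           copies = 15, n_arrays = 1)),
                         n_assemblies = 1, contig_lengths = 10000, seed = 15)
  reads <- make_reads(sim$assemblies[[1]], read_length = 100, coverage = 20,
                      error_rate = 0, seed = 16,
                      truth_arrays = sim$truth$arrays)
  expect_equal(nrow(reads), 2000)  # 20x over 10 kb at 100 bp
  genome <- sim$assemblies[[1]]$sequence
  idx <- sample(nrow(reads), 25)
  for (i in idx) {
    r <- reads[i, ]
    expect_true(grepl(r$sequence, genome, fixed = TRUE) ||
                  grepl(revcomp(r$sequence), genome, fixed = TRUE))
  }
  expect_true(all(c("+", "-") %in% reads$strand))
  # in-array labelling requires >= half of the read inside an implant
  tr <- sim$truth$arrays
  lab <- reads$in_array
  ov <- pmin(reads$end, tr$end) - pmax(reads$start, tr$start)
  expect_equal(lab, reads$contig_id == tr$contig_id & ov >= 50)
})

test_that("read errors appear at the requested rate", {
  sim <- make_assemblies(list(implant_spec("f", monomer_length = 30,
                                           copies = 10, n_arrays = 1)),
                         n_assemblies = 1, contig_lengths = 20000, seed = 17)
  reads <- make_reads(sim$assemblies[[1]], 100, 5, error_rate = 0.02, seed = 18)
  genome <- sim$assemblies[[1]]$sequence
  mism <- vapply(seq_len(200), function(i) {
    r <- reads[i, ]
    orig <- substr(genome, r$start + 1, r$end)
    if (r$strand == "-") orig <- revcomp(orig)
    mean(strsplit(r$sequence, "")[[1]] != strsplit(orig, "")[[1]])
  }, numeric(1))
  expect_equal(mean(mism), 0.02, tolerance = 0.15)
})
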