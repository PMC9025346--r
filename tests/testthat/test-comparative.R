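# a tr_families with one synthetic family per monomer, arrays long enough
# to clear the 200-score linkage when monomers agree
toy_set <- function(monomers, assembly) {
  arr <- fake_arrays(length(monomers), assembly = assembly)
  arr$array_seq <- vapply(monomers, function(m)
    strrep(m, ceiling(400 / nchar(m))), character(1))
  arr$consensus <- monomers
  arr$period <- nchar(monomers)
  no_m <- data.frame(array_a = character(0), array_b = character(0),
                     score = numeric(0), evalue = numeric(0))
  assign_names(cluster_families(arr, no_m, 200))
}

test_that("cross-assembly matching recovers a constructed sharing pattern", {
  set.seed(71)
  f1 <- rand_dna(40); f2 <- rand_dna(40); f3 <- rand_dna(40)
  sets <- list(P = toy_set(c(f1, f2), "P"),
               Q = toy_set(c(f1), "Q"),
               R = toy_set(c(f1, f3), "R"))
  links <- match_families_across(sets)
  cls <- intersection_classes(sets, links)
  expect_equal(sum(cls$n_assemblies == 3), 1)   # f1 in all three
  expect_equal(sum(cls$n_assemblies == 1), 2)   # f2, f3 private
  # disjoint and exhaustive over the union of families
  expect_equal(sum(lengths(strsplit(cls$families, ","))),
               sum(vapply(sets, function(s) nrow(s$families), numeric(1))))
  # symmetric in assembly order
  links_rev <- match_families_across(rev(sets))
  canon <- function(l) sort(paste(pmin(paste0(l$assembly_a, ":", l$family_a),
                                       paste0(l$assembly_b, ":", l$family_b)),
                                  pmax(paste0(l$assembly_a, ":", l$family_a),
                                       paste0(l$assembly_b, ":", l$family_b))))
  expect_equal(canon(links_rev), canon(links))
})

test_that("co-occurrence report sums classes into the at-least-two total", {
  cls <- data.frame(group_id = 1:5,
                    class = c("P+Q+R", "P+Q", "P+Q", "P", "R"),
                    n_assemblies = c(3, 2, 2, 1, 1),
                    families = c("P:33A,Q:33A,R:33A", "P:24A,Q:24A",
                                 "P:24B,Q:24B", "P:9A", "R:7A"),
                    label = c("33A", "24A", "24B", "9A", "7A"))
  t3 <- table3_report(cls)
  expect_equal(t3$count[t3$class == "All"], 3)
  expect_equal(t3$count[t3$class == "P+Q+R"], 1)
  expect_false(any(t3$class %in% c("P", "R")))
  # a single all-assembly group alone totals 1
  t3b <- table3_report(cls[1, ])
  expect_equal(t3b$count[t3b$class == "All"], 1)
})

test_that("chromosome assignment takes the union of verbatim labels", {
  arr <- fake_arrays(3)
  arr$contig_id <- c("ctgA", "ctgB", "ctgC")
  m <- data.frame(array_a = c("a01", "a02"), array_b = c("a02", "a03"),
                  score = 500, evalue = 1e-30)
  fams <- assign_names(cluster_families(arr, m, 200))
  cm <- c(ctgA = "5", ctgB = "9-10", ctgC = "5")
  fams <- assign_chromosomes(fams, cm)
  expect_equal(fams$families$chromosomes, "5, 9-10")
  # no map -> NA; unmapped contig -> explicit NA label
  expect_equal(assign_chromosomes(fams, NULL)$families$chromosomes, "NA")
  fams2 <- assign_chromosomes(fams, c(ctgA = "5"))
  expect_equal(fams2$families$chromosomes, "5, NA")
})

test_that("abundance is the percentage of reads aligned", {
  est <- abundance_from_counts("33A", 50, 10000)
  expect_equal(est$percent, 0.5)
  expect_error(abundance_from_counts("x", 5, 0))
})

test_that("k-mer containment counts reads from the family and not others", {
  set.seed(81)
  fam_seq <- strrep(rand_dna(40), 10)
  reads_in <- vapply(1:50, function(i) {
    s0 <- sample(nchar(fam_seq) - 99, 1)
    substr(fam_seq, s0, s0 + 99)
  }, character(1))
  reads_out <- vapply(1:50, function(i) rand_dna(100), character(1))
  est <- estimate_abundance(fam_seq, c(reads_in, reads_out), name = "f")
  expect_equal(est$reads_aligned, 50)
  expect_equal(est$percent, 50)
  # reverse-complement reads count too
  est_rc <- estimate_abundance(fam_seq, revcomp(reads_in), name = "f")
  expect_equal(est_rc$reads_aligned, 50)
})

test_that("reads shorter than k drop from the denominator with a warning", {
  fam_seq <- strrep("ACGTGACTGTTAGCCGTGAAT", 20)
  reads <- c(substr(fam_seq, 1, 100), "ACGT")
  expect_warning(est <- estimate_abundance(fam_seq, reads, name = "f"),
                 "shorter than k")
  expect_equal(est$reads_total, 1)
})

test_that("abundance of disjoint families is additive without double counting", {
  set.seed(83)
  sim <- make_assemblies(
    list(implant_spec("fx", monomer_length = 40, copies = 25, sub_rate = 0.02,
                      n_arrays = 2),
         implant_spec("fy", monomer_length = 70, copies = 15, sub_rate = 0.02,
                      n_arrays = 2)),
    n_assemblies = 1, contig_lengths = 30000, seed = 83)
  reads <- make_reads(sim$assemblies[[1]], 100, 4, 0, seed = 9,
                      truth_arrays = sim$truth$arrays)
  tr <- sim$truth$arrays
  seqs_for <- function(fam) {
    rows <- tr[tr$family == fam, ]
    vapply(seq_len(nrow(rows)), function(i)
      substr(sim$assemblies[[1]]$sequence[
        sim$assemblies[[1]]$id == rows$contig_id[i]],
        rows$start[i] + 1, rows$end[i]), character(1))
  }
  ex <- estimate_abundance(seqs_for("fx"), reads, name = "fx")
  ey <- estimate_abundance(seqs_for("fy"), reads, name = "fy")
  both <- estimate_abundance(c(seqs_for("fx"), seqs_for("fy")), reads,
                             name = "joint")
  expect_lte(abs(both$reads_aligned - (ex$reads_aligned + ey$reads_aligned)), 2)
})

test_that("abundance recovers implanted fractions across a fraction sweep", {
  # families spanning ~0.5% to ~7% of the genome; error-bearing reads
  errs <- c()
  for (seed in 1:5) {
    sim <- make_assemblies(
      list(implant_spec("lo", monomer_length = 25, copies = 5, sub_rate = 0.02,
                        n_arrays = 1),
           implant_spec("hi", monomer_length = 50, copies = 35, sub_rate = 0.02,
                        n_arrays = 2)),
      n_assemblies = 1, contig_lengths = 25000, seed = seed)
    reads <- make_reads(sim$assemblies[[1]], 100, 4, 0.002, seed = seed)
    tr <- sim$truth$arrays
    for (fam in c("lo", "hi")) {
      rows <- tr[tr$family == fam, ]
      seqs <- vapply(seq_len(nrow(rows)), function(i)
        substr(sim$assemblies[[1]]$sequence[
          sim$assemblies[[1]]$id == rows$contig_id[i]],
          rows$start[i] + 1, rows$end[i]), character(1))
      est <- estimate_abundance(seqs, reads, name = fam)
      truth <- sim$truth$fractions$fraction[sim$truth$fractions$family == fam]
      errs <- c(errs, abs(est$percent - truth) /
                  (100 * sqrt(truth / 100 * (1 - truth / 100) /
                                est$reads_total)))
    }
  }
  # mean deviation within ~1 binomial sigma, max within 3 (plus edge effects)
  expect_lt(mean(errs), 2)
  expect_lt(max(errs), 4)
})
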