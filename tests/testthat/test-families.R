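test_that("identical arrays score the perfect-alignment bound", {
  set.seed(31)
  s <- rand_dna(500)
  arr <- fake_arrays(2)
  arr$array_seq <- c(s, s)
  m <- score_pairs(arr)
  expect_equal(nrow(m), 1)
  expect_equal(m$score, 2 * 500)  # 500 matches at +2, no gaps
  expect_lt(m$evalue, 1e-15)
})

test_that("unrelated random sequences never pass the E-value gate", {
  set.seed(32)
  emitted <- 0
  for (i in 1:100) {
    arr <- fake_arrays(2)
    arr$array_seq <- c(rand_dna(200), rand_dna(200))
    emitted <- emitted + nrow(score_pairs(arr))
  }
  expect_equal(emitted, 0)
})

test_that("pair scores equal an independent Smith-Waterman dynamic program", {
  set.seed(33)
  for (i in 1:20) {
    la <- sample(60:300, 1); lb <- sample(60:300, 1)
    a <- rand_dna(la); b <- rand_dna(lb)
    # seed some shared sequence so scores are non-trivial in half the cases
    if (i %% 2 == 0) {
      frag <- substr(a, 1, sample(30:min(100, la), 1))
      b <- paste0(substr(b, 1, lb - nchar(frag)), frag)
    }
    expect_equal(local_score(a, b), sw_oracle(a, b),
                 info = paste("pair", i))
  }
})

test_that("single-linkage clustering follows score > threshold transitively", {
  arr <- fake_arrays(3)
  m <- data.frame(array_a = c("a01", "a02", "a01"),
                  array_b = c("a02", "a03", "a03"),
                  score = c(250, 210, 150), evalue = 1e-20)
  fams <- cluster_families(arr, m, 200)
  expect_equal(nrow(fams$families), 1)   # 250 and 210 chain all three

  m2 <- m[m$score == 150, ]
  fams2 <- cluster_families(arr[1:2, ], m2[0, ], 200)
  expect_equal(nrow(fams2$families), 2)  # no link above threshold
})

test_that("clustering matches brute-force connected components", {
  set.seed(44)
  for (rep in 1:150) {
    n <- sample(4:30, 1)
    arr <- fake_arrays(n)
    npair <- sample(0:(2 * n), 1)
    if (npair > 0) {
      pairs <- t(replicate(npair, sample(arr$array_id, 2)))
      m <- data.frame(array_a = pairs[, 1], array_b = pairs[, 2],
                      score = sample(c(100, 150, 201, 300, 500), npair, TRUE),
                      evalue = 1e-20)
    } else {
      m <- data.frame(array_a = character(0), array_b = character(0),
                      score = numeric(0), evalue = numeric(0))
    }
    fams <- cluster_families(arr, m, 200)
    got <- setNames(fams$membership$family_id, fams$membership$array_id)
    strong <- m[m$score > 200, , drop = FALSE]
    want <- components_oracle(arr$array_id,
                              data.frame(from = strong$array_a,
                                         to = strong$array_b))
    expect_equal(partition_canon(got), partition_canon(want))
  }
})

test_that("clustering is invariant to input order and duplicate matches", {
  arr <- fake_arrays(6)
  m <- data.frame(array_a = c("a01", "a03", "a05"),
                  array_b = c("a02", "a04", "a06"),
                  score = c(300, 201, 199), evalue = 1e-20)
  base <- cluster_families(arr, m, 200)
  dup <- rbind(m, data.frame(array_a = m$array_b, array_b = m$array_a,
                             score = m$score, evalue = m$evalue))
  perm <- cluster_families(arr[sample(6), ], dup[sample(6), ], 200)
  canon <- function(f) partition_canon(setNames(f$membership$family_id,
                                                f$membership$array_id))
  expect_equal(canon(base), canon(perm))
})

test_that("family names combine min monomer and occurrence-ordered letters", {
  arr <- fake_arrays(3, periods = c(24L, 24L, 13L))
  arr$start <- c(5000L, 1000L, 3000L)
  no_m <- data.frame(array_a = character(0), array_b = character(0),
                     score = numeric(0), evalue = numeric(0))
  fams <- assign_names(cluster_families(arr, no_m, 200))
  got <- setNames(fams$families$name[fams$membership$family_id],
                  fams$membership$array_id)
  expect_equal(unname(got["a02"]), "24A")  # earliest 24-mer family
  expect_equal(unname(got["a01"]), "24B")
  expect_equal(unname(got["a03"]), "13A")
  # prefix supported
  pf <- assign_names(cluster_families(arr, no_m, 200), "CG")
  expect_true(all(grepl("^CG", pf$families$name)))
  # permutation invariance
  perm <- assign_names(cluster_families(arr[c(3, 1, 2), ], no_m, 200))
  got_p <- setNames(perm$families$name[perm$membership$family_id],
                    perm$membership$array_id)
  expect_equal(got_p[names(got)], got)
  # numerals always equal min monomer
  num <- as.integer(sub("^([0-9]+).*$", "\\1", fams$families$name))
  expect_equal(num, fams$families$min_monomer)
})

test_that("distinct monomers stay apart; re-implanted monomers merge", {
  for (seed in 1:3) {
    sim <- make_assemblies(
      list(implant_spec("m1", monomer_length = 40, copies = 15,
                        sub_rate = 0.05, n_arrays = 2),
           implant_spec("m2", monomer_length = 55, copies = 12,
                        sub_rate = 0.05, n_arrays = 2)),
      n_assemblies = 1, contig_lengths = 20000, seed = seed)
    cat0 <- remove_redundant(detect_arrays(sim$assemblies[[1]],
                                           assembly_id = "asm1"))
    fams <- cluster_families(cat0, score_pairs(cat0))
    # two random monomers are far below 60% identity: never merged;
    # arrays of the same monomer (>= 150 bp at 5% divergence): always merged
    expect_equal(nrow(fams$families), 2)
  }
})

test_that("TE-derived tandems are annotated, half-covered arrays are not", {
  set.seed(61)
  te <- rand_dna(200, gc = 0.45)
  lib <- data.frame(name = "TEtoy", class = "LTR", subclass = "",
                    sequence = te, stringsAsFactors = FALSE)
  # array = 10 tandem copies of a 60 bp library fragment -> full coverage
  frag <- substr(te, 50, 109)
  arr <- fake_arrays(1)
  arr$array_seq <- strrep(frag, 10)
  arr$period <- 60L
  arr$consensus <- frag
  fams <- cluster_families(arr, data.frame(array_a = character(0),
                                           array_b = character(0),
                                           score = numeric(0),
                                           evalue = numeric(0)))
  ann <- annotate_library(fams, lib, 0.80)
  expect_equal(ann$families$te_similarity, "TEtoy")
  expect_true(ann$families$is_te)
  # only half the array is library-derived -> coverage < 80%, no call
  arr2 <- arr
  arr2$array_seq <- paste0(strrep(frag, 5), rand_dna(300))
  fams2 <- cluster_families(arr2, data.frame(array_a = character(0),
                                             array_b = character(0),
                                             score = numeric(0),
                                             evalue = numeric(0)))
  ann2 <- annotate_library(fams2, lib, 0.80)
  expect_true(is.na(ann2$families$te_similarity))
  # non-TE library classes are recorded but not flagged
  lib_gene <- data.frame(name = "Znf", class = "Gene", subclass = "",
                         sequence = te, stringsAsFactors = FALSE)
  ann3 <- annotate_library(fams, lib_gene, 0.80)
  expect_equal(ann3$families$te_similarity, "Znf")
  expect_false(ann3$families$is_te)
})

test_that("simple-sequence families are flagged by monomer length or entropy", {
  tab <- data.frame(min_monomer = c(6L, 33L, 12L),
                    representative = c("ACACAC",
                                       "GTGATGTCACCTGAAGGGTCTGTGATGTCACCT",
                                       "ATATATATATAT"))
  expect_equal(flag_simple(tab), c(TRUE, FALSE, TRUE))
})
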