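test_that("k-mer counts match brute-force enumeration across parameter grid", {
  set.seed(21)
  cases <- expand.grid(L = c(2L, 3L, 10L, 17L, 40L),
                       k_min = c(1L, 3L), k_max = c(3L, 8L, 15L),
                       step = c(1L, 2L, 3L))
  cases <- cases[cases$k_max >= cases$k_min, ]
  for (i in seq_len(nrow(cases))) {
    cs <- cases[i, ]
    a <- antigen("g", random_peptide(cs$L))
    got <- generate_kmers(a, cs$k_min, cs$k_max, cs$step)
    oracle <- enumerate_kmers_oracle(a$sequence, cs$k_min, cs$k_max, cs$step)
    expect_identical(nrow(got), length(oracle),
                     info = paste(unlist(cs), collapse = "/"))
    if (length(oracle)) {
      om <- do.call(rbind, oracle)
      expect_identical(got$start, unname(om[, "start"]))
      expect_identical(got$k, unname(om[, "k"]))
    }
  }
  # the 17-residue worked example, all k-mers of length 3..15
  expect_identical(nrow(generate_kmers(antigen("f", "SYVDLFIRETDFLSLDE"))),
                   117L)
  expect_identical(nrow(generate_kmers(antigen("s", "ACD"))), 1L)
  expect_identical(nrow(generate_kmers(antigen("s2", "AC"))), 0L)
  # substrings really are the claimed slices
  a <- antigen("sub", random_peptide(20))
  km <- generate_kmers(a, 3, 6)
  expect_identical(km$sequence,
                   substring(a$sequence, km$start, km$start + km$k - 1L))
})

test_that("overlap labeling implements the three rules with tie-inclusive majority", {
  a <- antigen("lab", random_peptide(20),
               regions(c(7, 1, 13), c(12, 6, 20),
                       c("epitope", "nonepitope", "nonepitope")))
  km6 <- data.frame(antigen_id = "lab", start = c(10L, 12L, 7L),
                    k = 6L,
                    sequence = substring(a$sequence, c(10, 12, 7),
                                         c(15, 17, 12)))
  maj <- label_kmers(km6, a, "majority")
  any <- label_kmers(km6, a, "any_overlap")
  full <- label_kmers(km6, a, "full_containment")
  # 3/6 residues epitopic: ties go to the epitope class
  expect_identical(maj$label[1], "epitope")
  expect_equal(maj$overlap_fraction[1], 0.5)
  # 1/6: positive only under any_overlap; majority sees 5/6 nonepitope
  expect_identical(any$label[2], "epitope")
  expect_identical(maj$label[2], "nonepitope")
  # fully inside the epitope: positive under all three rules
  expect_identical(maj$label[3], "epitope")
  expect_identical(any$label[3], "epitope")
  expect_identical(full$label[3], "epitope")
  # 3/6 epitope + 3/6 nonepitope: neither class fully contains it
  expect_identical(full$label[1], "unassigned")
})

test_that("unassigned residues count toward neither class but stay in k", {
  a <- antigen("ua", random_peptide(12), regions(1, 4, "epitope"))
  km <- data.frame(antigen_id = "ua", start = 3L, k = 6L,
                   sequence = substring(a$sequence, 3, 8))
  lab <- label_kmers(km, a, "majority")
  expect_equal(lab$overlap_fraction, 2 / 6)
  expect_equal(lab$nonepitope_fraction, 0)
  expect_identical(lab$label, "unassigned")
})

test_that("rule positives are nested: full ⊆ majority ⊆ any_overlap", {
  set.seed(31)
  for (rep in 1:20) {
    a <- toy_antigen(paste0("mono", rep), L = sample(25:60, 1),
                     epi = sort(sample(5:20, 2)) + c(0L, 3L))
    km <- generate_kmers(a, 3, 9)
    key <- function(rule) {
      l <- label_kmers(km, a, rule)
      paste(l$start, l$k)[l$label == "epitope"]
    }
    expect_true(all(key("full_containment") %in% key("majority")))
    expect_true(all(key("majority") %in% key("any_overlap")))
  }
})

test_that("majority labeling yields no more residue-level false positives than any_overlap", {
  set.seed(32)
  for (rep in 1:15) {
    a <- toy_antigen(paste0("fp", rep), L = 50L, epi = c(20L, 31L))
    km <- generate_kmers(a, 3, 15)
    truth <- 20:31
    fp_of <- function(rule)
      length(setdiff(positive_residues(label_kmers(km, a, rule)), truth))
    expect_lte(fp_of("majority"), fp_of("any_overlap"))
    expect_lte(fp_of("full_containment"), fp_of("majority"))
  }
})

test_that("build_labeled_set concatenates panels and validates input", {
  allepi <- antigen("all", random_peptide(20), regions(1, 20, "epitope"))
  km <- build_labeled_set(list(allepi), "majority", 3, 15)
  expect_true(all(km$label == "epitope"))
  expect_identical(nrow(km), 156L)  # L=20: sum over k=3..15 of L-k+1
  bare <- antigen("bare", random_peptide(20))
  expect_error(build_labeled_set(list(bare)), "no annotated regions")
  two <- list(toy_antigen("p1"), toy_antigen("p2"))
  km2 <- build_labeled_set(two, drop_unassigned = TRUE)
  expect_setequal(unique(km2$antigen_id), c("p1", "p2"))
  expect_true(all(km2$label %in% c("epitope", "nonepitope")))
})
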