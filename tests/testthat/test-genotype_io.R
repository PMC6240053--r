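test_that("GenePop round-trip is the identity on genotypes and metadata", {
  for (seed in c(1, 2, 3)) {
    ds <- random_dataset(n_ind = 12, n_loci = 4, seed = seed)
    f <- withr::local_tempfile(fileext = ".gen")
    write_genepop(ds, f)
    back <- read_genepop(f, motif_bp = 2L, encoding = "repeat_units")
    expect_identical(unname(back$allele1), unname(ds$allele1))
    expect_identical(unname(back$allele2), unname(ds$allele2))
    expect_identical(back$individuals, ds$individuals)
    expect_identical(back$loci$id, ds$loci$id)
    expect_identical(back$species_id, ds$species_id)
  }
})

test_that("GenePop parsing follows the format conventions", {
  f <- withr::local_tempfile(fileext = ".gen")
  writeLines(c("toy", "locA", "Pop",
               "i1 , 010010", "i2 , 010012"), f)
  ds <- read_genepop(f)
  expect_equal(dim(ds$allele1), c(2L, 1L))
  expect_equal(unname(ds$allele1[, 1]), c(10L, 10L))
  expect_equal(unname(ds$allele2[, 1]), c(10L, 12L))

  # "000000" is a missing call, not allele 0; 3-digit codes auto-detected
  f2 <- withr::local_tempfile(fileext = ".gen")
  writeLines(c("toy", "locA", "locB", "Pop",
               "i1 , 102104 000000", "i2 , 102102 098100"), f2)
  ds2 <- read_genepop(f2)
  expect_true(is.na(ds2$allele1[1, 2]) && is.na(ds2$allele2[1, 2]))
  expect_equal(unname(ds2$allele1[2, ]), c(102L, 98L))
})

test_that("malformed GenePop input gives parse errors naming the line", {
  f <- withr::local_tempfile(fileext = ".gen")
  writeLines(c("toy", "locA", "locB", "Pop",
               "i1 , 102104"), f)  # ragged row: 1 genotype for 2 loci
  expect_error(read_genepop(f), "line 5")
  f2 <- withr::local_tempfile(fileext = ".gen")
  writeLines(c("toy", "locA", "Pop",
               "i1 , 0101", "i2 , 010101"), f2)  # width switch
  expect_error(read_genepop(f2), "line 5")
  f3 <- withr::local_tempfile(fileext = ".gen")
  writeLines(c("toy"), f3)
  expect_error(read_genepop(f3), "malformed")
})

test_that("write_genepop rejects alleles exceeding the code width and emits
           missing codes", {
  ds <- random_dataset(n_ind = 5, n_loci = 2, seed = 4, alleles = 995:1005)
  f <- withr::local_tempfile(fileext = ".gen")
  expect_error(write_genepop(ds, f), "exceeds")
  ds2 <- random_dataset(n_ind = 5, n_loci = 2, seed = 4)
  ds2$allele1[2, 1] <- NA_integer_; ds2$allele2[2, 1] <- NA_integer_
  write_genepop(ds2, f)
  expect_true(any(grepl("000000", readLines(f))))
  # monomorphic dataset -> one repeated code
  mono <- generate_fixture("monomorphic")
  write_genepop(mono, f)
  lines <- readLines(f)
  expect_true(all(grepl("100100 100100", lines[grepl(",", lines)])))
})

test_that("to_repeat_units maps bp alleles onto the modal-gap lattice", {
  mk <- function(sizes1, sizes2) {
    genotype_dataset("bp", matrix(sizes1), matrix(sizes2),
                     data.frame(id = "L1", motif_bp = 2L), encoding = "bp")
  }
  # exact dinucleotide lattice {150,152,154}: consecutive units
  ds <- mk(c(150L, 152L, 154L), c(150L, 152L, 154L))
  ru <- to_repeat_units(ds)
  u <- sort(unique(ru$allele1[, 1]))
  expect_equal(diff(u), c(1L, 1L))
  expect_identical(ru$encoding, "repeat_units")

  # {150,152,155}: modal gap 2 (tie broken to the smaller), 155 -> unit
  # round(5/2) = 2 above the minimum (approximate off-lattice mapping)
  ds2 <- mk(c(150L, 152L, 155L), c(150L, 152L, 155L))
  ru2 <- to_repeat_units(ds2)
  u2 <- unname(ru2$allele1[, 1]) - min(ru2$allele1[, 1])
  expect_equal(u2, c(0L, 1L, 2L))

  # already repeat units: identity
  ds3 <- random_dataset(seed = 5)
  expect_identical(to_repeat_units(ds3), ds3)

  # monomorphic locus: declared motif fallback, and motif 0 errors
  mono <- generate_fixture("monomorphic")
  mono$encoding <- "bp"; mono$loci$encoding <- "bp"
  expect_silent(to_repeat_units(mono))
  mono$loci$motif_bp <- 0L
  expect_error(to_repeat_units(mono), "motif")
})

test_that("subset preserves order, enforces invariants, and is idempotent", {
  ds <- random_dataset(n_ind = 10, n_loci = 4, seed = 6)
  expect_identical(subset(ds), ds)
  sub <- subset(ds, individuals = ds$individuals[c(2, 5)],
                loci = c("L1", "L3"))
  expect_identical(sub$loci$id, c("L1", "L3"))
  expect_identical(sub$individuals, ds$individuals[c(2, 5)])
  expect_identical(subset(sub, individuals = sub$individuals), sub)
  # disjoint individual/locus selections commute
  a <- subset(subset(ds, individuals = ds$individuals[1:5]), loci = c("L2"))
  b <- subset(subset(ds, loci = c("L2")), individuals = ds$individuals[1:5])
  expect_identical(a, b)
  expect_error(subset(ds, individuals = character(0)), "empty")
  expect_error(subset(ds, loci = "nope"), "unknown")
  # an individual typed nowhere at a locus breaks the invariant
  ds$allele1[1, 2] <- NA_integer_; ds$allele2[1, 2] <- NA_integer_
  expect_error(subset(ds, individuals = ds$individuals[1]),
               "non-missing")
})

test_that("chi-square HWE test matches hand-computed genotype expectations", {
  # exact Hardy-Weinberg proportions 25/50/25: statistic 0, p = 1
  hw <- hwe_tests(generate_fixture("two_allele_hwe"), n_mc = 1000, seed = 1)
  expect_equal(hw$chi2_stat[1], 0)
  expect_equal(hw$chi2_p[1], 1)
  expect_false(hw$flagged[1])

  # all 100 individuals heterozygous: chi2 = 25+50+25 = 100 on 1 df
  a1 <- matrix(rep(10L, 100)); a2 <- matrix(rep(12L, 100))
  ds <- genotype_dataset("het", a1, a2, data.frame(id = "L1", motif_bp = 2L),
                        encoding = "repeat_units")
  hw2 <- hwe_tests(ds, n_mc = 2000, seed = 2)
  expect_equal(hw2$chi2_stat[1], 100)
  expect_equal(hw2$chi2_df[1], 1)
  expect_lt(hw2$chi2_p[1], 1e-3)
  expect_lt(hw2$exact_p[1], 0.01)
  expect_true(hw2$flagged[1])
})

test_that("monomorphic loci are untestable and excluded from the Bonferroni
           denominator", {
  ds <- random_dataset(n_ind = 40, n_loci = 2, seed = 7)
  ds$allele1[, 2] <- 10L; ds$allele2[, 2] <- 10L
  hw <- hwe_tests(ds, n_mc = 1000, alpha = 0.05,
                  correction = "bonferroni_per_dataset", seed = 3)
  expect_false(hw$testable[2])
  expect_true(is.na(hw$chi2_p[2]))
  expect_equal(attr(hw, "corrected_alpha"), 0.05 / 1)  # one testable locus
})

test_that("Monte-Carlo exact p converges to the chi-square p for a large
           2-allele locus", {
  set.seed(11)
  n <- 300
  # genotypes drawn from HW with p = 0.6, mild random deviation
  g <- sample(c("aa", "ab", "bb"), n, TRUE, prob = c(0.42, 0.42, 0.16))
  a1 <- ifelse(g == "bb", 12L, 10L)
  a2 <- ifelse(g == "aa", 10L, 12L)
  ds <- genotype_dataset("conv", matrix(a1), matrix(a2),
                        data.frame(id = "L1", motif_bp = 2L),
                        encoding = "repeat_units")
  hw <- hwe_tests(ds, n_mc = 10000, seed = 4)
  # the two statistics order outcomes slightly differently, so agreement is
  # approximate even asymptotically
  mc_se <- sqrt(hw$exact_p[1] * (1 - hw$exact_p[1]) / 10000)
  expect_lt(abs(hw$exact_p[1] - hw$chi2_p[1]), 2 * mc_se + 0.05)
})
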