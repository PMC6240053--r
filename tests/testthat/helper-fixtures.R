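# shared fixtures, built lazily and cached for the whole test run

.fixture_env <- new.env(parent = emptyenv())

# desk-scale reference table for unit tests (2 x 2500 rows, 40 ind x 10 loci)
small_table <- function() {
  if (is.null(.fixture_env$small_table))
    .fixture_env$small_table <- build_reference_table(2500, seed = 101)
  .fixture_env$small_table
}

# acceptance-scale reference table (2 x 3e5 rows; three times the criterion
# minimum, narrowing the gap to the full-scale 1e7-per-model world); built
# once, ~50 s
acceptance_table <- function() {
  if (is.null(.fixture_env$acceptance_table))
    .fixture_env$acceptance_table <- build_reference_table(3e5, seed = 2024)
  .fixture_env$acceptance_table
}

# a small random genotype dataset with known allele tables
random_dataset <- function(n_ind = 30, n_loci = 5, seed = 9,
                           alleles = 8:15, species = "rand") {
  set.seed(seed)
  a1 <- matrix(sample(alleles, n_ind * n_loci, TRUE), n_ind, n_loci)
  a2 <- matrix(sample(alleles, n_ind * n_loci, TRUE), n_ind, n_loci)
  genotype_dataset(species, a1, a2,
                   data.frame(id = paste0("L", seq_len(n_loci)),
                              motif_bp = 2L),
                   encoding = "repeat_units")
}

# independent per-locus statistic oracle: plain tallies, no shared code with
# locus_stats()
oracle_locus_stats <- function(ds, j, unbiased = TRUE) {
  a1 <- ds$allele1[, j]; a2 <- ds$allele2[, j]
  ok <- which(!is.na(a1))
  copies <- c(a1[ok], a2[ok])
  counts <- sapply(sort(unique(copies)), function(a) sum(copies == a))
  p <- counts / length(copies)
  he <- 1 - sum(p^2)
  if (unbiased) he <- he * length(copies) / (length(copies) - 1)
  list(k = length(counts),
       r = max(copies) - min(copies),
       Ho = mean(a1[ok] != a2[ok]),
       He = he,
       M = length(counts) / (max(copies) - min(copies) + 1),
       lfa = mean(p < 0.05))
}
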