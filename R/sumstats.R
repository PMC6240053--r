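#' Per-locus diversity statistics
#'
#' Computes, for one locus: the allele count `k`, the allele size range `r`,
#' observed heterozygosity `Ho` (proportion of heterozygous individuals among
#' those typed), Nei's gene diversity `He`, the M-ratio `M = k/(r+1)` and the
#' proportion of low-frequency alleles `lfa` (alleles at sample frequency
#' strictly below 5%). Individuals with a missing genotype are excluded from
#' this locus only (pairwise deletion). The M-ratio is meaningful on the
#' repeat-unit lattice; convert with [to_repeat_units()] first for bp data.
#'
#' @param ds a [genotype_dataset()].
#' @param locus a locus id present in `ds`.
#' @param unbiased if `TRUE` (default) `He` is the sample-size corrected Nei
#'   estimator `2n/(2n-1) * (1 - sum(p^2))` on gene copies; otherwise the
#'   plug-in `1 - sum(p^2)`.
#' @return A named list of class `locus_stats` with elements `k`, `r`, `Ho`,
#'   `He`, `M`, `lfa`, `n_typed`.
#' @export
locus_stats <- function(ds, locus, unbiased = TRUE) {
  j <- match(locus, ds$loci$id)
  if (is.na(j)) stop("unknown locus: ", locus)
  a1 <- ds$allele1[, j]; a2 <- ds$allele2[, j]
  keep <- !is.na(a1)
  a1 <- a1[keep]; a2 <- a2[keep]
  n <- length(a1)
  if (n == 0) stop("locus ", locus, " has no non-missing genotypes")
  copies <- c(a1, a2)
  tab <- table(copies)
  k <- length(tab)
  p <- as.numeric(tab) / (2 * n)
  r <- max(copies) - min(copies)
  he <- 1 - sum(p^2)
  if (unbiased && n > 0) he <- he * 2 * n / (2 * n - 1)
  structure(list(k = k, r = r,
                 Ho = mean(a1 != a2),
                 He = he,
                 M = k / (r + 1),
                 lfa = sum(p < 0.05) / k,
                 n_typed = n),
            class = "locus_stats")
}

#' Dataset-level ABC summary statistics
#'
#' The five summary statistics used for ABC inference, each the arithmetic
#' mean across loci of the per-locus value: allele count `k`, allele size
#' range `r`, Nei gene diversity `He`, M-ratio `M` and low-frequency-allele
#' proportion `lfa`.
#'
#' @inheritParams locus_stats
#' @return A named numeric vector of length 5 (`k`, `r`, `He`, `M`, `lfa`).
#' @export
mean_sumstats <- function(ds, unbiased = TRUE) {
  per <- vapply(ds$loci$id, function(l) {
    s <- locus_stats(ds, l, unbiased = unbiased)
    c(s$k, s$r, s$He, s$M, s$lfa)
  }, numeric(5))
  out <- rowMeans(per)
  names(out) <- c("k", "r", "He", "M", "lfa")
  out
}

#' Resampling-standardised statistics
#'
#' Standardises statistics across datasets of different sample size by
#' repeatedly resampling a fixed number of individuals with replacement.
#' Two uses: `what = "diversity"` reports mean and 95% CI (2.5/97.5
#' percentiles over resamples) of observed heterozygosity, allelic richness,
#' gene diversity and the low-frequency-allele proportion, averaged over loci
#' (the cross-species diversity standardisation, default 10 individuals);
#' `what = "abc"` returns the mean over resamples of the five ABC summary
#' statistics (default 40 individuals). Datasets smaller than `n_ind` are
#' used whole, unsampled.
#'
#' @param ds a [genotype_dataset()].
#' @param n_ind individuals per resample.
#' @param n_reps number of resamples.
#' @param what `"diversity"` or `"abc"`.
#' @param unbiased passed to [locus_stats()].
#' @param seed optional integer seed.
#' @return For `"abc"`, a named numeric vector of length 5. For
#'   `"diversity"`, an object of class `standardized_diversity`: a data.frame
#'   with rows `Ho`, `Ar`, `He`, `lfa` and columns `mean`, `lower`, `upper`,
#'   plus attributes `n_ind_resampled`, `n_reps`.
#' @export
resampled_stats <- function(ds, n_ind = 10, n_reps = 1000,
                            what = c("diversity", "abc"),
                            unbiased = TRUE, seed = NULL) {
  what <- match.arg(what)
  if (n_ind < 1) stop("n_ind must be >= 1")
  if (n_reps < 1) stop("n_reps must be >= 1")
  full <- n_individuals(ds) < n_ind
  # per-locus stats straight from the allele matrices; loci with no typed
  # individual in a given resample are skipped (mean over remaining loci)
  one_rep <- function(idx) {
    per <- vapply(seq_len(n_loci(ds)), function(j) {
      a1 <- ds$allele1[idx, j]; a2 <- ds$allele2[idx, j]
      keep <- !is.na(a1)
      a1 <- a1[keep]; a2 <- a2[keep]
      n <- length(a1)
      if (n == 0) return(rep(NA_real_, 5))
      copies <- c(a1, a2)
      tab <- table(copies)
      p <- as.numeric(tab) / (2 * n)
      k <- length(tab)
      r <- max(copies) - min(copies)
      he <- 1 - sum(p^2)
      if (unbiased) he <- he * 2 * n / (2 * n - 1)
      if (what == "abc") c(k, r, he, k / (r + 1), sum(p < 0.05) / k)
      else c(mean(a1 != a2), k, he, sum(p < 0.05) / k, NA_real_)
    }, numeric(5))
    rowMeans(per, na.rm = TRUE)[seq_len(if (what == "abc") 5 else 4)]
  }
  draws <- with_seed(seed, {
    if (full) {
      matrix(one_rep(seq_len(n_individuals(ds))), nrow = 1)
    } else {
      t(vapply(seq_len(n_reps), function(i) {
        one_rep(sample.int(n_individuals(ds), n_ind, replace = TRUE))
      }, numeric(if (what == "abc") 5 else 4)))
    }
  })
  if (what == "abc") {
    out <- colMeans(draws)
    names(out) <- c("k", "r", "He", "M", "lfa")
    return(out)
  }
  stats <- c("Ho", "Ar", "He", "lfa")
  out <- data.frame(
    mean = colMeans(draws),
    lower = apply(draws, 2, stats::quantile, 0.025),
    upper = apply(draws, 2, stats::quantile, 0.975),
    row.names = stats)
  structure(out, n_ind_resampled = if (full) n_individuals(ds) else n_ind,
            n_reps = if (full) 1L else n_reps, full_dataset = full,
            class = c("standardized_diversity", "data.frame"))
}

#' @export
print.standardized_diversity <- function(x, ...) {
  cat("Diversity standardised to", attr(x, "n_ind_resampled"),
      "individuals over", attr(x, "n_reps"), "resamples",
      if (isTRUE(attr(x, "full_dataset"))) "(full dataset, unsampled)", "\n")
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' Export per-locus and summary statistics as CSV
#' @param ds a [genotype_dataset()].
#' @param path output CSV path.
#' @param unbiased passed to [locus_stats()].
#' @return `path`, invisibly.
#' @export
write_sumstats_csv <- function(ds, path, unbiased = TRUE) {
  per <- summary(ds)
  mean_row <- cbind(locus = "MEAN_ACROSS_LOCI",
                    as.data.frame(as.list(colMeans(per[-1]))))
  utils::write.csv(rbind(per, mean_row), path, row.names = FALSE)
  invisible(path)
}
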