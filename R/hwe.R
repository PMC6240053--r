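#' Hardy-Weinberg equilibrium tests per locus
#'
#' For every polymorphic locus, compares observed genotype counts to their
#' Hardy-Weinberg expectation from the sample allele frequencies with (i) a
#' chi-square test over all genotype classes (no pooling of rare classes; see
#' Details) and (ii) a Monte-Carlo exact test that permutes gene copies among
#' individuals within the locus and uses the Levene conditional probability of
#' the genotype configuration as the test statistic. A locus is flagged as
#' deviating only when *both* tests are significant after the chosen
#' Bonferroni correction, mirroring the conservative convention of pooled
#' multi-study panels.
#'
#' @details The chi-square statistic is `sum((O-E)^2/E)` over all genotype
#' classes with `E_ii = n p_i^2`, `E_ij = 2 n p_i p_j` and
#' `df = k(k+1)/2 - k`. Rare genotype classes are not pooled; the Monte-Carlo
#' exact test is the robust companion where expected counts are small. The
#' exact p-value is `(1 + #(perm <= obs)) / (n_mc + 1)` on the log conditional
#' probability, so it is never exactly zero.
#'
#' @param ds a [genotype_dataset()].
#' @param n_mc number of Monte-Carlo permutations for the exact test.
#' @param alpha nominal significance level before correction.
#' @param correction `"bonferroni_table_wide"` (divide alpha by `m_total`,
#'   the number of testable loci across the whole analysis run),
#'   `"bonferroni_per_dataset"` (divide by this dataset's testable loci) or
#'   `"none"`.
#' @param m_total total testable loci for table-wide correction; defaults to
#'   this dataset's testable locus count.
#' @param seed optional integer seed for the permutations.
#' @return An object of class `hwe_result`: a data.frame with one row per
#'   locus (columns `locus`, `k`, `n_typed`, `chi2_stat`, `chi2_df`,
#'   `chi2_p`, `exact_p`, `testable`, `flagged`) plus attributes
#'   `corrected_alpha` and `correction`.
#' @export
hwe_tests <- function(ds, n_mc = 10000, alpha = 0.05,
                      correction = c("bonferroni_table_wide",
                                     "bonferroni_per_dataset", "none"),
                      m_total = NULL, seed = NULL) {
  correction <- match.arg(correction)
  if (n_mc < 1000) stop("n_mc must be >= 1000 for the exact test")
  res <- with_seed(seed, {
    lapply(seq_len(n_loci(ds)), function(j) {
      a1 <- ds$allele1[, j]; a2 <- ds$allele2[, j]
      keep <- !is.na(a1)
      a1 <- a1[keep]; a2 <- a2[keep]
      n <- length(a1)
      alleles <- sort(unique(c(a1, a2)))
      k <- length(alleles)
      if (n == 0 || k < 2) {
        return(data.frame(locus = ds$loci$id[j], k = k, n_typed = n,
                          chi2_stat = NA_real_, chi2_df = NA_real_,
                          chi2_p = NA_real_, exact_p = NA_real_,
                          testable = FALSE))
      }
      i1 <- match(a1, alleles); i2 <- match(a2, alleles)
      counts <- matrix(0, k, k)  # upper-triangular genotype counts
      for (g in seq_len(n)) {
        lo <- min(i1[g], i2[g]); hi <- max(i1[g], i2[g])
        counts[lo, hi] <- counts[lo, hi] + 1
      }
      p <- tabulate(c(i1, i2), k) / (2 * n)
      expect <- outer(p, p) * n
      expect <- 2 * expect
      diag(expect) <- diag(expect) / 2
      ut <- upper.tri(expect, diag = TRUE)
      chi2 <- sum((counts[ut] - expect[ut])^2 / expect[ut])
      df <- k * (k + 1) / 2 - k
      chi2_p <- stats::pchisq(chi2, df, lower.tail = FALSE)
      # exact test: log Levene probability up to configuration-independent
      # constants: h*log(2) - sum(log(n_ij!))
      log_stat <- function(i1, i2) {
        het <- sum(i1 != i2)
        tab <- table(pmin(i1, i2) * (k + 1L) + pmax(i1, i2))
        het * log(2) - sum(lgamma(tab + 1))
      }
      obs <- log_stat(i1, i2)
      copies <- c(i1, i2)
      hits <- 0L
      for (r in seq_len(n_mc)) {
        perm <- sample(copies)
        b1 <- perm[seq_len(n)]; b2 <- perm[n + seq_len(n)]
        if (log_stat(b1, b2) <= obs + 1e-12) hits <- hits + 1L
      }
      exact_p <- (1 + hits) / (n_mc + 1)
      data.frame(locus = ds$loci$id[j], k = k, n_typed = n,
                 chi2_stat = chi2, chi2_df = df, chi2_p = chi2_p,
                 exact_p = exact_p, testable = TRUE)
    })
  })
  res <- do.call(rbind, res)
  m <- switch(correction,
              bonferroni_table_wide = m_total %||% sum(res$testable),
              bonferroni_per_dataset = sum(res$testable),
              none = 1L)
  m <- max(m, 1L)
  corrected_alpha <- alpha / m
  res$flagged <- res$testable & !is.na(res$chi2_p) &
    res$chi2_p < corrected_alpha & res$exact_p < corrected_alpha
  structure(res, corrected_alpha = corrected_alpha, correction = correction,
            class = c("hwe_result", "data.frame"))
}

#' @export
print.hwe_result <- function(x, ...) {
  cat("Hardy-Weinberg tests:", sum(x$testable), "testable of", nrow(x),
      "loci; corrected alpha =",
      format(attr(x, "corrected_alpha"), digits = 3),
      paste0("(", attr(x, "correction"), ")"), "\n")
  cat("  flagged (significant in both tests):", sum(x$flagged), "\n")
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Export HWE results as CSV
#' @param x an `hwe_result`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_hwe_csv <- function(x, path) {
  out <- data.frame(locus = x$locus, chi2_stat = x$chi2_stat,
                    chi2_p = x$chi2_p, exact_p = x$exact_p,
                    corrected_alpha = attr(x, "corrected_alpha"),
                    flagged = x$flagged)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
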