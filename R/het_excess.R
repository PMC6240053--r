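#' Simulate equilibrium heterozygosity conditional on allele number
#'
#' Draws the distribution of gene diversity expected at mutation-drift
#' equilibrium in a constant-size population, conditional on observing
#' exactly `k` alleles in a sample of `n_copies` gene copies. The scaled
#' mutation rate theta is first calibrated by stochastic bisection so that
#' the mean simulated allele count matches `k`; loci are then simulated at
#' that theta (constant-size coalescent plus the mutation model) and
#' replicates with exactly `k` alleles are retained by rejection, which
#' samples the stationary distribution of gene diversity given the allele
#' count (up to its weak residual dependence on theta). The unbiased Nei
#' gene diversity of each retained configuration is recorded.
#'
#' @param n_copies sample size in gene copies (`2 x` typed individuals).
#' @param k observed allele count, `2 <= k <= n_copies`.
#' @param model a `mutation_model` (see [smm_model()]).
#' @param n_sims number of retained simulations.
#' @param pilot_sims simulations per bisection step of the theta
#'   calibration.
#' @param max_attempt_factor cap on total attempts, as a multiple of
#'   `n_sims`; exceeding it (allele count unreachable) is an error.
#' @param seed optional integer seed.
#' @return Numeric vector of `n_sims` equilibrium heterozygosity draws.
#' @export
heq_simulate <- function(n_copies, k, model = tpm_model(), n_sims = 10000,
                         pilot_sims = 200, max_attempt_factor = 500,
                         seed = NULL) {
  if (k < 2 || k > n_copies) stop("need 2 <= k <= n_copies")
  stopifnot(inherits(model, "mutation_model"))
  with_seed(seed,
            cpp_heq_simulate(as.integer(n_copies), as.integer(k),
                             model$p_single, model$q_mult,
                             as.integer(n_sims), as.integer(pilot_sims),
                             max_attempt_factor))
}

#' Heterozygosity-excess test
#'
#' Cornuet-Luikart style test for recent bottlenecks: for every polymorphic
#' locus, the observed gene diversity `He` is compared with the
#' equilibrium heterozygosity `H_eq` expected in a stable population with
#' the same sample size and allele count under the given mutation model
#' (simulated with [heq_simulate()]). The dataset-level statistic
#' `prop_het_exc` is the fraction of polymorphic loci whose `He` exceeds the
#' mean (default; optionally median) of the `H_eq` draws: 0.5 is the
#' expectation for a stable population, values above 0.5 indicate a recent
#' decline and values below 0.5 a recent expansion.
#'
#' @param ds a [genotype_dataset()].
#' @param model a `mutation_model` (see [smm_model()], [tpm_model()]).
#' @param n_sims equilibrium simulations per locus.
#' @param center `"mean"` (default) or `"median"` of the `H_eq` draws used
#'   for the per-locus excess decision.
#' @param seed optional integer seed.
#' @return An object of class `het_excess`: a per-locus data.frame (columns
#'   `locus`, `n_copies`, `k`, `He_obs`, `Heq_mean`, `Heq_sd`, `excess`)
#'   with attributes `prop_het_exc`, `model`, `n_sims`, `n_polymorphic`.
#' @export
prop_het_excess <- function(ds, model = tpm_model(), n_sims = 10000,
                            center = c("mean", "median"), seed = NULL) {
  center <- match.arg(center)
  stopifnot(inherits(model, "mutation_model"))
  with_seed(seed, {
    rows <- lapply(ds$loci$id, function(l) {
      s <- locus_stats(ds, l)
      if (s$k < 2)
        return(data.frame(locus = l, n_copies = 2 * s$n_typed, k = s$k,
                          He_obs = s$He, Heq_mean = NA_real_,
                          Heq_sd = NA_real_, excess = NA))
      heq <- cpp_heq_simulate(as.integer(2 * s$n_typed), as.integer(s$k),
                              model$p_single, model$q_mult,
                              as.integer(n_sims), 200L, 500)
      ctr <- if (center == "mean") mean(heq) else stats::median(heq)
      data.frame(locus = l, n_copies = 2 * s$n_typed, k = s$k,
                 He_obs = s$He, Heq_mean = mean(heq), Heq_sd = stats::sd(heq),
                 excess = s$He > ctr)
    })
    res <- do.call(rbind, rows)
    n_poly <- sum(!is.na(res$excess))
    if (n_poly == 0) stop("all loci are monomorphic")
    structure(res,
              prop_het_exc = mean(res$excess, na.rm = TRUE),
              model = model, n_sims = n_sims, n_polymorphic = n_poly,
              center = center,
              class = c("het_excess", "data.frame"))
  })
}

#' @export
print.het_excess <- function(x, ...) {
  m <- attr(x, "model")
  cat("Heterozygosity-excess test (", m$kind,
      if (m$kind == "TPM") sprintf(", %d%% single-step", round(100 * m$p_single)),
      "; ", attr(x, "n_sims"), " simulations/locus)\n", sep = "")
  cat(sprintf("  prop_het_exc = %.3f over %d polymorphic loci (0.5 = stable)\n",
              attr(x, "prop_het_exc"), attr(x, "n_polymorphic")))
  invisible(x)
}

#' Heterozygosity-excess across standard mutation models
#'
#' Runs [prop_het_excess()] under the SMM, TPM70, TPM80 and TPM90 presets
#' and collects the dataset-level proportions.
#'
#' @inheritParams prop_het_excess
#' @param models named list of `mutation_model`s (default
#'   [het_excess_presets()]).
#' @return A named list of `het_excess` objects with attribute `summary`, a
#'   data.frame of `model` and `prop_het_exc`.
#' @export
het_excess_panel <- function(ds, models = het_excess_presets(),
                             n_sims = 10000, seed = NULL) {
  with_seed(seed, {
    res <- lapply(models, function(m) prop_het_excess(ds, m, n_sims = n_sims))
    structure(res,
              summary = data.frame(
                model = names(models),
                prop_het_exc = vapply(res, attr, numeric(1), "prop_het_exc")),
              class = "het_excess_panel")
  })
}

#' @export
print.het_excess_panel <- function(x, ...) {
  cat("Heterozygosity-excess across mutation models:\n")
  print(attr(x, "summary"), row.names = FALSE, digits = 3)
  invisible(x)
}

#' Export a heterozygosity-excess panel as CSV
#' @param x a [het_excess_panel()] result.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_het_excess_csv <- function(x, path) {
  per_locus <- do.call(rbind, lapply(names(x), function(nm) {
    cbind(model = nm, as.data.frame(x[[nm]]))
  }))
  utils::write.csv(per_locus, path, row.names = FALSE)
  invisible(path)
}
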