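#' Analyse one species end-to-end
#'
#' Runs the full per-species inference chain against a prebuilt reference
#' table: conversion to repeat units, HWE quality tests (reported, and
#' optionally used to drop deviating loci), resampling-standardised
#' diversity (10 individuals) and ABC observables (40 individuals), ABC
#' model choice, parameter estimation under the preferred model with
#' local-linear adjustment, point estimates, prior-predictive goodness of
#' fit, posterior predictive simulation, and the heterozygosity-excess test
#' under the standard mutation-model presets. Parameters are reported only
#' for the preferred model.
#'
#' @param ds a [genotype_dataset()].
#' @param table a [build_reference_table()] built at matching simulation
#'   dimensions (its `n_ind`/`n_loci` attributes drive the resampling and
#'   posterior predictive sizes).
#' @param tolerance ABC tolerance; automatically raised so that at least
#'   `min_accepted` rows are retained on desk-scale tables (logged via
#'   message).
#' @param min_accepted floor on accepted rows.
#' @param drop_hwe_loci if `TRUE`, loci flagged by [hwe_tests()] are removed
#'   before inference (sensitivity rerun).
#' @param hwe_n_mc,het_n_sims,n_resamples,ppc_draws stage sizes.
#' @param het_models mutation models for the heterozygosity-excess stage.
#' @param seed integer seed stamping every stochastic stage.
#' @return An object of class `species_report`: list with elements
#'   `species_id`, `diversity`, `obs_stats`, `hwe`, `model_choice`, `p_bot`,
#'   `preferred_model`, `posterior`, `estimates`, `gof`, `ppc`,
#'   `het_excess` (summary data.frame), `provenance`.
#' @export
analyze_species <- function(ds, table, tolerance = 5e-4, min_accepted = 500,
                            drop_hwe_loci = FALSE, hwe_n_mc = 2000,
                            het_n_sims = 1000, n_resamples = 1000,
                            ppc_draws = 1000,
                            het_models = het_excess_presets(), seed = 1) {
  stopifnot(inherits(ds, "genotype_dataset"),
            inherits(table, "reference_table"))
  n_ind_sim <- attr(table, "n_ind")
  n_loci_sim <- attr(table, "n_loci")
  stage <- function(name, code) {
    tryCatch(code, error = function(e)
      stop("stage '", name, "' failed for ", ds$species_id, ": ",
           conditionMessage(e), call. = FALSE))
  }
  ds <- stage("to_repeat_units", to_repeat_units(ds))
  hwe <- stage("hwe_tests",
               hwe_tests(ds, n_mc = hwe_n_mc, seed = seed + 1L))
  if (drop_hwe_loci && any(hwe$flagged)) {
    keep <- ds$loci$id[!ds$loci$id %in% hwe$locus[hwe$flagged]]
    if (length(keep) == 0) stop("all loci flagged by HWE filter")
    ds <- subset(ds, loci = keep)
  }
  diversity <- stage("resampled_diversity",
                     resampled_stats(ds, n_ind = 10, n_reps = n_resamples,
                                     what = "diversity", seed = seed + 2L))
  obs <- stage("resampled_abc_stats",
               resampled_stats(ds, n_ind = n_ind_sim, n_reps = n_resamples,
                               what = "abc", seed = seed + 3L))
  tol_eff <- max(tolerance, min(1, min_accepted / nrow(table)))
  if (tol_eff > tolerance)
    message("tolerance raised to ", format(tol_eff),
            " to retain >= ", min_accepted, " rows")
  mc <- stage("model_posterior",
              model_posterior(obs, table, tolerance = tol_eff))
  preferred <- names(which.max(mc$prob))
  post <- stage("param_posterior",
                param_posterior(obs, table, model = preferred,
                                tolerance = tol_eff,
                                min_accepted = min(min_accepted / 2, 50)))
  est <- point_estimates(post)
  gof <- stage("goodness_of_fit",
               goodness_of_fit(obs, table, model = preferred,
                               tolerance = tol_eff, seed = seed + 4L))
  ppc <- stage("posterior_predictive",
               posterior_predictive(post, n_draws = ppc_draws,
                                    n_ind = n_ind_sim, n_loci = n_loci_sim,
                                    seed = seed + 5L))
  ppc_summary <- data.frame(
    stat = stat_cols,
    obs = unname(unlist(obs[stat_cols])),
    pred_lower = vapply(stat_cols, function(cn)
      stats::quantile(ppc[[cn]], 0.025), numeric(1)),
    pred_upper = vapply(stat_cols, function(cn)
      stats::quantile(ppc[[cn]], 0.975), numeric(1)))
  ppc_summary$inside <- ppc_summary$obs >= ppc_summary$pred_lower &
    ppc_summary$obs <= ppc_summary$pred_upper
  het <- stage("het_excess",
               het_excess_panel(ds, models = het_models,
                                n_sims = het_n_sims, seed = seed + 6L))
  structure(list(
    species_id = ds$species_id,
    diversity = diversity,
    obs_stats = obs,
    hwe = hwe,
    model_choice = mc,
    p_bot = mc$p_bot,
    preferred_model = preferred,
    posterior = post,
    estimates = est,
    gof = gof,
    ppc = ppc_summary,
    het_excess = attr(het, "summary"),
    provenance = list(seed = seed, tolerance = tol_eff,
                      table_rows = nrow(table),
                      table_dims = c(n_ind = n_ind_sim, n_loci = n_loci_sim),
                      table_seed = attr(table, "seed"))),
    class = "species_report")
}

#' @export
print.species_report <- function(x, ...) {
  cat("Species report:", x$species_id, "\n")
  cat(sprintf("  p_bot = %.3f -> preferred model: %s\n",
              x$p_bot, x$preferred_model))
  tpm80 <- x$het_excess$prop_het_exc[x$het_excess$model == "TPM80"]
  if (length(tpm80))
    cat(sprintf("  prop_het_exc (TPM80) = %.3f\n", tpm80))
  cat(sprintf("  goodness of fit p = %.3f; obs stats inside 95%% ppc: %d/5\n",
              x$gof$p_value, sum(x$ppc$inside)))
  cat("  parameter estimates (", x$preferred_model, " model):\n", sep = "")
  print(x$estimates, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Cross-species panel report
#'
#' Combines per-species reports into one table (one row per species) and
#' computes cross-species summaries: Pearson correlations among the
#' standardised diversity measures and the count of species supporting the
#' bottleneck model (`p_bot > 0.5`).
#'
#' @param reports list of [analyze_species()] results (>= 2).
#' @return An object of class `panel_report`: list with `table` (data.frame)
#'   and `summary` (list with `cor_Ho_Ar`, `n_bottleneck_supported`,
#'   `n_species`).
#' @export
panel_report <- function(reports) {
  if (length(reports) < 2) stop("need >= 2 species reports")
  rows <- lapply(reports, function(r) {
    div <- r$diversity
    est <- r$estimates
    pick <- function(p, col) {
      v <- est[[col]][est$parameter == p]
      if (length(v)) v else NA_real_
    }
    het <- r$het_excess
    data.frame(
      species_id = r$species_id,
      n_hwe_flagged = sum(r$hwe$flagged),
      Ho_10 = div["Ho", "mean"], Ar_10 = div["Ar", "mean"],
      He_10 = div["He", "mean"], lfa_10 = div["lfa", "mean"],
      prop_het_exc_SMM = het$prop_het_exc[het$model == "SMM"][1],
      prop_het_exc_TPM70 = het$prop_het_exc[het$model == "TPM70"][1],
      prop_het_exc_TPM80 = het$prop_het_exc[het$model == "TPM80"][1],
      prop_het_exc_TPM90 = het$prop_het_exc[het$model == "TPM90"][1],
      p_bot = r$p_bot,
      preferred_model = r$preferred_model,
      Ne_bot_mode = pick("Ne_bot", "mode"),
      Ne_bot_lower = pick("Ne_bot", "lower"),
      Ne_bot_upper = pick("Ne_bot", "upper"),
      mu_mode = pick("mu", "mode"),
      gsm_par_mode = pick("gsm_par", "mode"),
      gof_p = r$gof$p_value)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  cor_Ho_Ar <- if (stats::sd(tab$Ho_10) == 0 || stats::sd(tab$Ar_10) == 0) {
    warning("diversity correlation undefined (zero variance)")
    NA_real_
  } else {
    stats::cor(tab$Ho_10, tab$Ar_10)
  }
  structure(list(table = tab,
                 summary = list(cor_Ho_Ar = cor_Ho_Ar,
                                n_bottleneck_supported = sum(tab$p_bot > 0.5),
                                n_species = nrow(tab))),
            class = "panel_report")
}

#' @export
print.panel_report <- function(x, ...) {
  cat("Panel report:", x$summary$n_species, "species;",
      x$summary$n_bottleneck_supported, "support the bottleneck model",
      "(p_bot > 0.5)\n")
  cat(sprintf("  Pearson r(Ho, Ar) = %s\n",
              format(x$summary$cor_Ho_Ar, digits = 3)))
  invisible(x)
}

#' Export a panel report as CSV
#' @param x a [panel_report()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_panel_csv <- function(x, path) {
  utils::write.csv(x$table, path, row.names = FALSE)
  invisible(path)
}
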