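#' Leave-one-out cross-validation of ABC model choice
#'
#' Repeatedly treats a random reference-table row as a pseudo-observation,
#' classifies it against all remaining rows with [model_posterior()], and
#' averages the posterior probabilities per true model. The diagonal of the
#' resulting confusion summary is the mean posterior probability assigned to
#' the correct model.
#'
#' @param table a [build_reference_table()] object.
#' @param n_reps pseudo-observations per true model.
#' @param tolerance ABC tolerance (proportion of remaining rows retained).
#' @param method passed to [model_posterior()].
#' @param seed optional integer seed.
#' @return An object of class `abc_cv_model`: list with `confusion` (2x2
#'   matrix of mean posterior probabilities, rows = true model), `rates`
#'   (2x2 matrix of assignment frequencies by posterior argmax; its diagonal
#'   is the correct-classification rate), `mean_correct` and `correct_rate`
#'   (named vectors), `n_reps`, `tolerance`.
#' @export
cv_model_choice <- function(table, n_reps = 100, tolerance = 5e-4,
                            method = "mnlogistic", seed = NULL) {
  if (n_reps < 1) stop("n_reps must be >= 1")
  models <- c("bottleneck", "non_bottleneck")
  # precompute the scaled statistic matrix once; each rep excludes its
  # pseudo-observation by an infinite distance instead of copying the table
  S <- as.matrix(table[, stat_cols])
  scales <- stat_scales(table)
  Ssc <- sweep(S, 2, scales, "/")
  labels <- table$model
  n_accept <- ceiling(tolerance * (nrow(table) - 1))
  with_seed(seed, {
    conf <- matrix(0, 2, 2, dimnames = list(true = models, assigned = models))
    rates <- conf
    for (m in models) {
      rows <- which(labels == m)
      picks <- sample(rows, n_reps, replace = n_reps > length(rows))
      acc <- c(bottleneck = 0, non_bottleneck = 0)
      hit <- acc
      for (i in picks) {
        obs <- S[i, ]
        d <- sqrt(colSums((t(Ssc) - Ssc[i, ])^2))
        d[i] <- Inf
        ord <- order(d, seq_along(d))[seq_len(n_accept)]
        mp <- suppressWarnings(
          model_choice_core(obs, S[ord, , drop = FALSE], labels[ord],
                            scales, d[ord], tolerance, method))
        acc <- acc + mp$prob
        hit[which.max(mp$prob)] <- hit[which.max(mp$prob)] + 1
      }
      conf[m, ] <- acc / n_reps
      rates[m, ] <- hit / n_reps
    }
    structure(list(confusion = conf, rates = rates,
                   mean_correct = c(bottleneck = conf[1, 1],
                                    non_bottleneck = conf[2, 2]),
                   correct_rate = c(bottleneck = rates[1, 1],
                                    non_bottleneck = rates[2, 2]),
                   n_reps = n_reps, tolerance = tolerance),
              class = "abc_cv_model")
  })
}

#' @export
print.abc_cv_model <- function(x, ...) {
  cat("ABC model-choice cross-validation (", x$n_reps,
      " pseudo-observations per model, tolerance ", format(x$tolerance),
      ")\n", sep = "")
  cat("Mean posterior probability assigned (rows = true model):\n")
  print(round(x$confusion, 3))
  cat("Assignment frequency by highest posterior probability:\n")
  print(round(x$rates, 3))
  invisible(x)
}

#' Cross-validated prediction error of ABC parameter estimates
#'
#' For each of `n_reps` pseudo-observed rows of one model, estimates every
#' parameter as the posterior median of the *rejection* sample (no
#' regression adjustment) computed against the remaining rows, and reports
#' the prediction error
#' `E_pred = sum((est - true)^2) / (n_reps * var(true))`
#' per parameter: 0 is perfect estimation and values near 1 mean the
#' posterior carries no information beyond the prior.
#'
#' @inheritParams cv_model_choice
#' @param model which demographic model's rows to cross-validate.
#' @return An object of class `abc_cv_param`: list with `errors` (named
#'   numeric per parameter), `estimates` and `truth` (data.frames),
#'   `n_reps`, `tolerance`, `model`.
#' @export
cv_param_error <- function(table, model = "bottleneck", n_reps = 100,
                           tolerance = 5e-4, seed = NULL) {
  if (n_reps < 1) stop("n_reps must be >= 1")
  pars <- model_param_cols(model)
  sub_all <- table[table$model == model, , drop = FALSE]
  S <- as.matrix(sub_all[, stat_cols])
  scales <- suppressWarnings(stat_scales(sub_all))
  Ssc <- sweep(S, 2, scales, "/")
  pmat <- as.matrix(sub_all[, pars])
  n_accept <- ceiling(tolerance * (nrow(sub_all) - 1))
  with_seed(seed, {
    picks <- sample(nrow(sub_all), n_reps, replace = n_reps > nrow(sub_all))
    est <- matrix(NA_real_, n_reps, length(pars),
                  dimnames = list(NULL, pars))
    tru <- pmat[picks, , drop = FALSE]
    for (ri in seq_len(n_reps)) {
      i <- picks[ri]
      d <- sqrt(colSums((t(Ssc) - Ssc[i, ])^2))
      d[i] <- Inf
      idx <- order(d, seq_along(d))[seq_len(n_accept)]
      for (pn in pars) est[ri, pn] <- stats::median(pmat[idx, pn])
    }
    v <- apply(tru, 2, stats::var)
    if (any(v == 0)) stop("zero variance among true parameter values")
    errors <- colSums((est - tru)^2) / (n_reps * v)
    structure(list(errors = errors, estimates = as.data.frame(est),
                   truth = as.data.frame(tru), n_reps = n_reps,
                   tolerance = tolerance, model = model),
              class = "abc_cv_param")
  })
}

#' @export
print.abc_cv_param <- function(x, ...) {
  cat("ABC parameter-estimation cross-validation (", x$model, " model, ",
      x$n_reps, " reps, rejection algorithm)\n", sep = "")
  cat("Prediction error (0 = perfect, ~1 = uninformative):\n")
  print(round(x$errors, 3))
  invisible(x)
}

#' Prior-predictive goodness-of-fit test
#'
#' Tests whether the preferred model can plausibly generate the observed
#' summary statistics. The test statistic is the median MAD-scaled distance
#' between the observation and its accepted simulations (within the model's
#' rows); the null distribution is built by recomputing the same statistic
#' for `n_null` pseudo-observations drawn from the model's own rows. The
#' p-value is the fraction of null statistics at least as large as the
#' observed one; small values indicate poor fit.
#'
#' @inheritParams cv_model_choice
#' @param obs observed summary statistics (named numeric of length 5).
#' @param model which demographic model to assess.
#' @param n_null null-distribution size (>= 100).
#' @return An object of class `abc_gof`: list with `stat`, `null`,
#'   `p_value`, `model`, `tolerance`.
#' @export
goodness_of_fit <- function(obs, table, model = "bottleneck", n_null = 200,
                            tolerance = 5e-4, seed = NULL) {
  if (n_null < 100) stop("n_null must be >= 100")
  sub <- table[table$model == model, , drop = FALSE]
  median_acc_dist <- function(o, tab) {
    rej <- suppressWarnings(abc_reject(o, tab, tolerance))
    stats::median(rej$distance)
  }
  with_seed(seed, {
    stat <- median_acc_dist(obs, sub)
    picks <- sample(nrow(sub), n_null, replace = n_null > nrow(sub))
    null <- vapply(picks, function(i) {
      median_acc_dist(unlist(sub[i, stat_cols]), sub[-i, , drop = FALSE])
    }, numeric(1))
    structure(list(stat = stat, null = null,
                   p_value = mean(null >= stat), model = model,
                   tolerance = tolerance),
              class = "abc_gof")
  })
}

#' @export
print.abc_gof <- function(x, ...) {
  cat("Prior-predictive goodness of fit (", x$model, " model)\n", sep = "")
  cat(sprintf("  median accepted distance = %.4f, p = %.3f\n",
              x$stat, x$p_value))
  invisible(x)
}

#' Posterior predictive simulation
#'
#' Samples `n_draws` joint parameter vectors from the adjusted posterior
#' (whole rows, preserving cross-parameter dependence, with the ABC kernel
#' weights), simulates one dataset per draw under the posterior's model, and
#' returns the simulated summary statistics for comparison with the
#' observation (e.g. histogram overlays).
#'
#' @param posterior an [param_posterior()] object.
#' @param n_draws number of posterior draws / simulated datasets.
#' @param n_ind,n_loci dimensions of each simulated dataset.
#' @param seed optional integer seed.
#' @return An object of class `posterior_predictive`: a data.frame of
#'   `n_draws` rows with the five statistic columns, with attribute `obs`.
#' @export
posterior_predictive <- function(posterior, n_draws = 1000, n_ind = 40,
                                 n_loci = 10, seed = NULL) {
  stopifnot(inherits(posterior, "abc_posterior"))
  if (nrow(posterior$adjusted) == 0) stop("empty posterior")
  with_seed(seed, {
    picks <- sample.int(nrow(posterior$adjusted), n_draws, replace = TRUE,
                        prob = posterior$weights)
    draws <- posterior$adjusted[picks, , drop = FALSE]
    draws$model <- posterior$model
    ep <- epochs_matrix(draws)
    stats <- cpp_batch_sumstats(as.integer(n_ind), as.integer(n_loci),
                                ep$start, ep$N, draws$mu,
                                rep(0, n_draws), 1 - draws$gsm_par, 100L)
    out <- as.data.frame(stats)
    structure(out, obs = posterior$obs,
              class = c("posterior_predictive", "data.frame"))
  })
}

#' @export
plot.posterior_predictive <- function(x, ...) {
  obs <- attr(x, "obs")
  old <- graphics::par(mfrow = c(2, 3))
  on.exit(graphics::par(old))
  for (cn in stat_cols) {
    graphics::hist(x[[cn]], main = cn, xlab = cn, col = "grey85",
                   border = "grey60", ...)
    if (!is.null(obs)) graphics::abline(v = obs[[cn]], col = 2, lwd = 2)
  }
  invisible(x)
}
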