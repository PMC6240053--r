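#' Build an ABC reference table
#'
#' Draws `n_per_model` parameter vectors from the priors of each demographic
#' model, simulates a dataset of `n_ind` individuals and `n_loci`
#' microsatellite loci for every draw, and records the five mean summary
#' statistics per row. Simulation runs in chunks so that very large tables
#' can be built with bounded memory.
#'
#' @param n_per_model simulations per demographic model.
#' @param n_ind,n_loci dimensions of every simulated dataset (default 40
#'   individuals, 10 loci).
#' @param priors_bot,priors_nonbot prior sets for the two models; defaults
#'   are [default_priors()].
#' @param seed optional integer seed (fully determines the table).
#' @param chunk_size simulations per C++ call.
#' @return An object of class `reference_table`: a data.frame with columns
#'   `model`, the parameter columns (`Ne`, `Ne_hist`, `Ne_bot`,
#'   `t_bot_start`, `t_bot_end`, `t_hist`, `mu`, `gsm_par`; unused ones are
#'   `NA`) and the statistic columns `k`, `r`, `He`, `M`, `lfa`, with
#'   attributes `n_ind`, `n_loci`, `n_per_model`, `seed`.
#' @export
build_reference_table <- function(n_per_model, n_ind = 40, n_loci = 10,
                                  priors_bot = default_priors("bottleneck"),
                                  priors_nonbot = default_priors("non_bottleneck"),
                                  seed = NULL, chunk_size = 20000L) {
  if (n_per_model < 1) stop("n_per_model must be >= 1")
  with_seed(seed, {
    draws <- rbind_fill(sample_priors(priors_bot, n_per_model),
                        sample_priors(priors_nonbot, n_per_model))
    n <- nrow(draws)
    stats <- matrix(NA_real_, n, 5)
    for (from in seq(1, n, by = chunk_size)) {
      to <- min(from + chunk_size - 1, n)
      idx <- from:to
      ep <- epochs_matrix(draws[idx, , drop = FALSE])
      stats[idx, ] <- cpp_batch_sumstats(
        as.integer(n_ind), as.integer(n_loci), ep$start, ep$N,
        draws$mu[idx], rep(0, length(idx)), 1 - draws$gsm_par[idx], 100L)
    }
    colnames(stats) <- c("k", "r", "He", "M", "lfa")
    tab <- cbind(draws, as.data.frame(stats))
    structure(tab, n_ind = n_ind, n_loci = n_loci,
              n_per_model = n_per_model, seed = seed,
              class = c("reference_table", "data.frame"))
  })
}

# rbind data.frames with different columns, padding with NA
rbind_fill <- function(a, b) {
  cols <- union(names(a), names(b))
  for (nm in setdiff(cols, names(a))) a[[nm]] <- NA_real_
  for (nm in setdiff(cols, names(b))) b[[nm]] <- NA_real_
  rbind(a[cols], b[cols])
}

stat_cols <- c("k", "r", "He", "M", "lfa")

#' @export
print.reference_table <- function(x, ...) {
  cat("ABC reference table:", nrow(x), "simulations (",
      paste(names(table(x$model)), table(x$model), collapse = ", "), ")\n")
  cat("  simulated datasets:", attr(x, "n_ind"), "individuals x",
      attr(x, "n_loci"), "loci\n")
  invisible(x)
}

# MAD scaling over the whole table; zero-MAD statistics are dropped from the
# distance with a warning
stat_scales <- function(table) {
  s <- vapply(stat_cols, function(cn) stats::mad(table[[cn]]), numeric(1))
  if (any(s == 0)) {
    warning("statistic(s) with zero MAD dropped from distance: ",
            paste(stat_cols[s == 0], collapse = ", "))
    s[s == 0] <- Inf  # scaled column becomes 0 everywhere
  }
  s
}

scaled_distances <- function(obs, table, scales) {
  d2 <- 0
  for (i in seq_along(stat_cols)) {
    cn <- stat_cols[i]
    d2 <- d2 + ((table[[cn]] - obs[[cn]]) / scales[i])^2
  }
  sqrt(d2)
}

#' ABC rejection step
#'
#' Computes Euclidean distances between the observed summary statistics and
#' every table row, each statistic scaled by its median absolute deviation
#' over the whole table, and accepts the `ceiling(tolerance * nrow)` closest
#' rows (ties broken deterministically by row index).
#'
#' @param obs named numeric vector of the five observed summary statistics
#'   (as from [mean_sumstats()] or [resampled_stats()]).
#' @param table a [build_reference_table()] object.
#' @param tolerance proportion of rows to retain, in `(0, 1]`.
#' @return A list of class `abc_rejection` with `accepted` (integer row
#'   indices, in increasing distance order), `distance` (their distances),
#'   `all_distance` (distances for every row), `tolerance`, `n_accept`.
#' @export
abc_reject <- function(obs, table, tolerance = 5e-4) {
  if (tolerance <= 0 || tolerance > 1) stop("tolerance must be in (0, 1]")
  scales <- stat_scales(table)
  d <- scaled_distances(as.list(obs), table, scales)
  n_accept <- ceiling(tolerance * nrow(table))
  ord <- order(d, seq_along(d))  # deterministic tie-break by row index
  acc <- ord[seq_len(n_accept)]
  structure(list(accepted = acc, distance = d[acc], all_distance = d,
                 tolerance = tolerance, n_accept = n_accept,
                 scales = scales),
            class = "abc_rejection")
}

# Epanechnikov weights on accepted rows
epanechnikov <- function(d) {
  dmax <- max(d)
  if (dmax == 0) return(rep(1, length(d)))
  w <- 1 - (d / dmax)^2
  w[w < 0] <- 0
  w
}

#' ABC model choice
#'
#' Posterior model probabilities for the bottleneck versus non-bottleneck
#' model given the observed summary statistics. The rejection estimate is the
#' label proportion among accepted rows; the regression estimate ("multinomial
#' regression" method, here a weighted binomial logistic regression since
#' there are two models) regresses the model indicator on the MAD-scaled
#' statistics over the accepted rows with Epanechnikov weights in distance
#' and evaluates the fitted probability at the observation. On regression
#' failure (non-convergence or separation) the rejection proportions are
#' returned with `method = "rejection"` and a warning.
#'
#' @inheritParams abc_reject
#' @param method `"mnlogistic"` (default) or `"rejection"`.
#' @return An object of class `abc_model_choice` with `p_bot`,
#'   `prob` (named probabilities for both models), `rejection_prob`,
#'   `method`, `tolerance`, `n_accepted` (per model).
#' @export
model_posterior <- function(obs, table, tolerance = 5e-4,
                            method = c("mnlogistic", "rejection")) {
  method <- match.arg(method)
  rej <- abc_reject(obs, table, tolerance)
  Xacc <- as.matrix(table[rej$accepted, stat_cols])
  model_choice_core(obs, Xacc, table$model[rej$accepted], rej$scales,
                    rej$distance, tolerance, method)
}

# shared core: classify from the accepted rows (statistics matrix, labels,
# distances). Used by model_posterior and the fast CV loop.
model_choice_core <- function(obs, Xacc, lab, scales, dist, tolerance,
                              method) {
  models <- c("bottleneck", "non_bottleneck")
  rej_prob <- vapply(models, function(m) mean(lab == m), numeric(1))
  prob <- rej_prob
  used <- "rejection"
  if (method == "mnlogistic" && all(rej_prob > 0)) {
    y <- as.integer(lab == "bottleneck")
    # centre at the observation and scale: the fitted intercept is then the
    # logit of p_bot at the observed statistics
    X <- sweep(Xacc, 2, unlist(obs[stat_cols]))
    X <- sweep(X, 2, scales, "/")
    keep <- is.finite(colSums(X)) & apply(X, 2, function(v) stats::var(v) > 0)
    w <- epanechnikov(dist)
    fit <- tryCatch(
      suppressWarnings(stats::glm.fit(cbind(1, X[, keep, drop = FALSE]), y,
                                      weights = w,
                                      family = stats::binomial())),
      error = function(e) NULL)
    if (!is.null(fit) && fit$converged && all(is.finite(fit$coefficients))) {
      p_bot <- stats::plogis(fit$coefficients[1])
      prob <- c(bottleneck = unname(p_bot),
                non_bottleneck = unname(1 - p_bot))
      used <- "mnlogistic"
    } else {
      warning("logistic model-choice regression failed; ",
              "falling back to rejection proportions")
    }
  } else if (method == "mnlogistic") {
    warning("one model absent among accepted rows; ",
            "using rejection proportions")
  }
  structure(list(p_bot = unname(prob["bottleneck"]), prob = prob,
                 rejection_prob = rej_prob, method = used,
                 tolerance = tolerance,
                 n_accepted = table(factor(lab, levels = models))),
            class = "abc_model_choice")
}

#' @export
print.abc_model_choice <- function(x, ...) {
  cat("ABC model choice (", x$method, ", tolerance ",
      format(x$tolerance), ")\n", sep = "")
  cat(sprintf("  p(bottleneck)     = %.4f\n", x$prob["bottleneck"]))
  cat(sprintf("  p(non-bottleneck) = %.4f\n", x$prob["non_bottleneck"]))
  invisible(x)
}

# parameters estimated per model and their transforms
model_param_cols <- function(model) {
  if (model == "bottleneck")
    c("Ne", "Ne_hist", "Ne_bot", "t_bot_start", "t_bot_end", "mu", "gsm_par")
  else
    c("Ne", "Ne_hist", "t_hist", "mu", "gsm_par")
}

# log for the lognormal sizes, logit-on-prior-support for bounded-uniform
# parameters (guarantees adjusted draws respect the prior support)
param_transform <- function(name, priors) {
  p <- priors$priors[[name]]
  if (p$dist == "lnorm")
    list(fw = log, bw = exp)
  else
    list(fw = function(x) logit(x, p$min, p$max),
         bw = function(y) inv_logit(y, p$min, p$max))
}

#' ABC parameter estimation with local-linear adjustment
#'
#' Constructs a posterior sample for the parameters of one demographic model:
#' rows of that model among the accepted simulations form the raw rejection
#' sample; the regression adjustment fits a weighted least-squares regression
#' of each transformed parameter on the MAD-scaled statistics (Epanechnikov
#' weights) and replaces every draw by the fit at the observation plus its
#' residual. Lognormally distributed sizes are log-transformed;
#' bounded-uniform parameters are logit-transformed to their prior support,
#' so adjusted draws always respect the support after back-transformation.
#' A singular design falls back to a small ridge penalty (flagged).
#'
#' @inheritParams abc_reject
#' @param model `"bottleneck"` or `"non_bottleneck"`; the rejection step and
#'   the tolerance proportion operate on that model's rows only.
#' @param priors the prior set of that model (for transform supports).
#' @param min_accepted minimum accepted rows of the model required.
#' @return An object of class `abc_posterior` with `model`, `raw`
#'   (data.frame of accepted raw draws), `adjusted` (regression-adjusted
#'   draws), `weights` (normalised Epanechnikov weights), `obs`,
#'   `tolerance`, `ridge` (logical flag).
#' @export
param_posterior <- function(obs, table, model = "bottleneck",
                            tolerance = 5e-4,
                            priors = default_priors(model),
                            min_accepted = 50) {
  table <- table[table$model == model, , drop = FALSE]
  if (nrow(table) == 0) stop("no rows for model '", model, "'")
  rej <- abc_reject(obs, table, tolerance)
  idx <- rej$accepted
  if (length(idx) < min_accepted)
    stop("only ", length(idx), " accepted rows for model '", model,
         "' (need >= ", min_accepted, "); increase tolerance")
  d <- rej$distance
  w <- epanechnikov(d)
  if (sum(w) == 0) w <- rep(1, length(w))
  pars <- model_param_cols(model)
  raw <- table[idx, pars, drop = FALSE]
  X <- as.matrix(table[idx, stat_cols])
  X <- sweep(X, 2, unlist(obs[stat_cols]))
  X <- sweep(X, 2, rej$scales, "/")
  keep <- apply(X, 2, function(v) is.finite(sum(v)) && stats::var(v) > 0)
  X <- cbind(1, X[, keep, drop = FALSE])
  ridge_used <- FALSE
  adjusted <- raw
  for (pn in pars) {
    tr <- param_transform(pn, priors)
    th <- tr$fw(raw[[pn]])
    if (stats::var(th) == 0) { adjusted[[pn]] <- raw[[pn]]; next }
    WX <- X * w
    XtX <- crossprod(X, WX)
    co <- tryCatch(solve(XtX, crossprod(WX, th)), error = function(e) NULL)
    if (is.null(co)) {
      ridge_used <- TRUE
      co <- solve(XtX + diag(1e-8, ncol(X)), crossprod(WX, th))
    }
    fitted <- drop(X %*% co)
    # fit at the observation is the intercept (statistics centred at obs)
    adjusted[[pn]] <- tr$bw(co[1] + (th - fitted))
  }
  structure(list(model = model, raw = raw, adjusted = adjusted,
                 weights = w / sum(w), obs = obs, tolerance = tolerance,
                 distance = d, ridge = ridge_used),
            class = "abc_posterior")
}

#' Posterior point estimates
#'
#' Mode (argmax of a Gaussian kernel density with Silverman bandwidth,
#' weighted by the ABC kernel weights), weighted median and central 95%
#' credible interval (2.5/97.5 weighted percentiles) per parameter of the
#' adjusted posterior sample. A degenerate (constant) sample returns that
#' constant with a zero-width interval.
#'
#' @param p an [param_posterior()] object.
#' @param use `"adjusted"` (default) or `"raw"` draws.
#' @return A data.frame with one row per parameter and columns `mode`,
#'   `median`, `lower`, `upper`.
#' @export
point_estimates <- function(p, use = c("adjusted", "raw")) {
  use <- match.arg(use)
  draws <- p[[use]]
  w <- p$weights
  out <- lapply(names(draws), function(pn) {
    x <- draws[[pn]]
    if (length(unique(x)) == 1)
      return(data.frame(parameter = pn, mode = x[1], median = x[1],
                        lower = x[1], upper = x[1]))
    dens <- stats::density(x, weights = w, bw = stats::bw.nrd0(x))
    data.frame(parameter = pn,
               mode = dens$x[which.max(dens$y)],
               median = weighted_median(x, w),
               lower = weighted_quantile(x, w, 0.025),
               upper = weighted_quantile(x, w, 0.975))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' @export
print.abc_posterior <- function(x, ...) {
  cat("ABC posterior sample (", x$model, " model): ",
      nrow(x$adjusted), " draws, tolerance ", format(x$tolerance),
      if (x$ridge) ", ridge fallback used", "\n", sep = "")
  print(point_estimates(x), digits = 4, row.names = FALSE)
  invisible(x)
}

#' @export
summary.abc_posterior <- function(object, ...) point_estimates(object)

#' Plot posterior densities
#' @param x an [param_posterior()] object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.abc_posterior <- function(x, ...) {
  pars <- names(x$adjusted)
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(pars)))
  on.exit(graphics::par(old))
  for (pn in pars) {
    v <- x$adjusted[[pn]]
    if (length(unique(v)) == 1) next
    dens <- stats::density(v, weights = x$weights, bw = stats::bw.nrd0(v))
    graphics::plot(dens, main = pn, xlab = pn, ...)
  }
  invisible(x)
}
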