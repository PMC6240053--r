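#' Prior distributions for the two demographic models
#'
#' The bottleneck model has seven parameters: present and historical diploid
#' effective sizes `Ne` and `Ne_hist` (lognormal, meanlog 10.5, sdlog 1,
#' concentrating mass between thousands and tens of thousands), the
#' bottleneck size `Ne_bot ~ U[1, 500]`, bottleneck start and end times
#' `t_bot_start ~ U[10, 70]` and `t_bot_end ~ U[1, 30]` generations before
#' present (jointly constrained to `t_bot_end < t_bot_start` by rejection),
#' the per-locus mutation rate `mu ~ U[1e-5, 1e-4]` and the generalized
#' stepwise mutation parameter `gsm_par ~ U[0, 0.3]` (the proportion of
#' multistep mutations). The non-bottleneck model drops `Ne_bot` and the
#' bottleneck times and instead switches from `Ne` to `Ne_hist` at
#' `t_hist ~ U[10, 70]`. All priors are independent.
#'
#' @param model `"bottleneck"` or `"non_bottleneck"`.
#' @return An object of class `prior_set`: a named list of distribution
#'   specifications, each `list(dist=, ...)` with `dist` one of `"lnorm"`,
#'   `"unif"`.
#' @export
default_priors <- function(model = c("bottleneck", "non_bottleneck")) {
  model <- match.arg(model)
  size <- list(dist = "lnorm", meanlog = 10.5, sdlog = 1)
  pri <- list(
    Ne = size,
    Ne_hist = size,
    mu = list(dist = "unif", min = 1e-5, max = 1e-4),
    gsm_par = list(dist = "unif", min = 0, max = 0.3))
  if (model == "bottleneck") {
    pri$Ne_bot <- list(dist = "unif", min = 1, max = 500)
    pri$t_bot_start <- list(dist = "unif", min = 10, max = 70)
    pri$t_bot_end <- list(dist = "unif", min = 1, max = 30)
  } else {
    pri$t_hist <- list(dist = "unif", min = 10, max = 70)
  }
  structure(list(model = model, priors = pri), class = "prior_set")
}

#' @export
print.prior_set <- function(x, ...) {
  cat("Priors for the", x$model, "demographic model:\n")
  for (nm in names(x$priors)) {
    p <- x$priors[[nm]]
    cat(" ", format(nm, width = 12),
        if (p$dist == "lnorm") sprintf("lognormal(meanlog=%g, sdlog=%g)",
                                       p$meanlog, p$sdlog)
        else sprintf("uniform[%g, %g]", p$min, p$max), "\n")
  }
  invisible(x)
}

# prior support [lo, hi] per parameter (Inf for lognormal sizes)
prior_support <- function(priors, name) {
  p <- priors$priors[[name]]
  if (p$dist == "unif") c(p$min, p$max) else c(0, Inf)
}

draw_one <- function(p, n) {
  switch(p$dist,
         lnorm = stats::rlnorm(n, p$meanlog, p$sdlog),
         unif = stats::runif(n, p$min, p$max),
         stop("unknown prior distribution: ", p$dist))
}

#' Sample demographic parameters from their priors
#'
#' Draws `n` independent parameter vectors. For the bottleneck model, joint
#' draws violating `t_bot_end < t_bot_start` are rejected and redrawn as a
#' pair, which preserves the marginal supports while excluding meaningless
#' inverted bottlenecks.
#'
#' @param priors a [default_priors()] object (or one with modified entries).
#' @param n number of draws.
#' @param seed optional integer seed.
#' @return A data.frame of `n` rows with one column per parameter plus a
#'   `model` column. With `n = 1` the single row can be passed to
#'   [demographic_params()] via `as_params()`.
#' @export
sample_priors <- function(priors, n = 1, seed = NULL) {
  stopifnot(inherits(priors, "prior_set"))
  with_seed(seed, {
    d <- as.data.frame(lapply(priors$priors, draw_one, n = n))
    if (priors$model == "bottleneck") {
      bad <- which(d$t_bot_end >= d$t_bot_start)
      while (length(bad)) {
        d$t_bot_start[bad] <- draw_one(priors$priors$t_bot_start, length(bad))
        d$t_bot_end[bad] <- draw_one(priors$priors$t_bot_end, length(bad))
        bad <- bad[d$t_bot_end[bad] >= d$t_bot_start[bad]]
      }
    }
    d$model <- priors$model
    d
  })
}

#' Demographic parameter set
#'
#' A validated single parameter vector for the piecewise-constant coalescent:
#' looking backwards in time the diploid size is `Ne` from the present,
#' `Ne_bot` between `t_bot_end` and `t_bot_start` (bottleneck model only) and
#' `Ne_hist` older than `t_bot_start` (or than `t_hist` in the
#' non-bottleneck model). All size changes are instantaneous.
#'
#' @param model `"bottleneck"` or `"non_bottleneck"`.
#' @param Ne,Ne_hist present and historical diploid effective sizes.
#' @param Ne_bot bottleneck size (bottleneck model).
#' @param t_bot_start,t_bot_end bottleneck epoch bounds in generations before
#'   present, `1 <= t_bot_end < t_bot_start`.
#' @param t_hist size-change time (non-bottleneck model).
#' @param mu mutation rate per locus per generation.
#' @param gsm_par proportion of multistep mutations, in `[0, 1)`.
#' @param size_units `"diploid"` (sizes count diploid individuals; pairwise
#'   coalescence rate `1/(2N)` per generation, so for two gene copies
#'   `E[TMRCA] = 2N`) or `"gene_copies"` (sizes count gene copies, rate
#'   `1/N`; the convention of the coalescent simulator family these priors
#'   were calibrated in, used for all prior-derived parameter sets).
#' @return An object of class `demographic_params`.
#' @export
demographic_params <- function(model = c("bottleneck", "non_bottleneck"),
                               Ne, Ne_hist, Ne_bot = NULL,
                               t_bot_start = NULL, t_bot_end = NULL,
                               t_hist = NULL, mu, gsm_par = 0,
                               size_units = c("diploid", "gene_copies")) {
  model <- match.arg(model)
  size_units <- match.arg(size_units)
  if (any(c(Ne, Ne_hist) < 1)) stop("effective sizes must be >= 1")
  if (mu < 0) stop("mu must be >= 0")
  if (gsm_par < 0 || gsm_par >= 1) stop("gsm_par must be in [0, 1)")
  if (model == "bottleneck") {
    if (is.null(Ne_bot) || is.null(t_bot_start) || is.null(t_bot_end))
      stop("bottleneck model needs Ne_bot, t_bot_start, t_bot_end")
    if (Ne_bot < 1) stop("Ne_bot must be >= 1")
    if (!(t_bot_end >= 1 && t_bot_end < t_bot_start))
      stop("need 1 <= t_bot_end < t_bot_start")
  } else {
    if (is.null(t_hist)) stop("non-bottleneck model needs t_hist")
  }
  structure(list(model = model, Ne = Ne, Ne_hist = Ne_hist, Ne_bot = Ne_bot,
                 t_bot_start = t_bot_start, t_bot_end = t_bot_end,
                 t_hist = t_hist, mu = mu, gsm_par = gsm_par,
                 size_units = size_units),
            class = "demographic_params")
}

#' @rdname demographic_params
#' @param row a one-row data.frame as produced by [sample_priors()].
#' @export
as_params <- function(row) {
  stopifnot(nrow(row) == 1)
  if (row$model == "bottleneck")
    demographic_params("bottleneck", Ne = row$Ne, Ne_hist = row$Ne_hist,
                       Ne_bot = row$Ne_bot, t_bot_start = row$t_bot_start,
                       t_bot_end = row$t_bot_end, mu = row$mu,
                       gsm_par = row$gsm_par, size_units = "gene_copies")
  else
    demographic_params("non_bottleneck", Ne = row$Ne, Ne_hist = row$Ne_hist,
                       t_hist = row$t_hist, mu = row$mu,
                       gsm_par = row$gsm_par, size_units = "gene_copies")
}

#' @export
print.demographic_params <- function(x, ...) {
  cat("Demographic parameters (", x$model, " model)\n", sep = "")
  flds <- x[!vapply(x, is.null, logical(1))]
  for (nm in setdiff(names(flds), "model"))
    cat(" ", format(nm, width = 12), format(flds[[nm]], digits = 4), "\n")
  invisible(x)
}

# epoch representation for the C++ simulator: start times (ascending, first
# 0) and *diploid* sizes (the C++ uses pairwise rate 1/(2N)); gene-copy
# sizes are halved here. Always 3 epochs, degenerate ones have zero length.
epochs_of <- function(p) {
  h <- if (identical(p$size_units, "gene_copies")) 0.5 else 1
  if (p$model == "bottleneck")
    list(start = c(0, p$t_bot_end, p$t_bot_start),
         N = h * c(p$Ne, p$Ne_bot, p$Ne_hist))
  else
    list(start = c(0, p$t_hist, p$t_hist),
         N = h * c(p$Ne, p$Ne_hist, p$Ne_hist))
}

# vectorized over a data.frame of prior draws (always gene-copy units)
epochs_matrix <- function(d, size_units = "gene_copies") {
  n <- nrow(d)
  start <- matrix(0, n, 3)
  N <- matrix(0, n, 3)
  bot <- d$model == "bottleneck"
  N[, 1] <- d$Ne
  if (any(bot)) {
    # guard against inverted epochs (possible for regression-adjusted draws)
    start[bot, 2] <- pmin(d$t_bot_end[bot], d$t_bot_start[bot])
    start[bot, 3] <- pmax(d$t_bot_end[bot], d$t_bot_start[bot])
    N[bot, 2] <- d$Ne_bot[bot]
    N[bot, 3] <- d$Ne_hist[bot]
  }
  if (any(!bot)) {
    start[!bot, 2] <- d$t_hist[!bot]
    start[!bot, 3] <- d$t_hist[!bot]
    N[!bot, 2] <- d$Ne_hist[!bot]
    N[!bot, 3] <- d$Ne_hist[!bot]
  }
  if (size_units == "gene_copies") N <- N / 2
  list(start = start, N = N)
}
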