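# internal helpers

# Run code with a temporarily seeded RNG, restoring the caller's RNG state.
# seed = NULL leaves the global stream untouched (draws advance it).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# weighted quantiles of type 7-ish linear interpolation on the weighted ECDF
weighted_quantile <- function(x, w, probs) {
  stopifnot(length(x) == length(w), all(w >= 0))
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  vapply(probs, function(p) {
    i <- which(cw >= p)[1L]
    x[i]
  }, numeric(1))
}

weighted_median <- function(x, w) weighted_quantile(x, w, 0.5)

logit <- function(x, lo, hi) {
  z <- (x - lo) / (hi - lo)
  eps <- 1e-9
  z <- pmin(pmax(z, eps), 1 - eps)
  log(z / (1 - z))
}

inv_logit <- function(y, lo, hi) lo + (hi - lo) / (1 + exp(-y))

`%||%` <- function(a, b) if (is.null(a)) b else a
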