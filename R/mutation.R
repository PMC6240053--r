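#' Microsatellite mutation model specifications
#'
#' All three models draw a signed step in repeat units for every mutation.
#' `smm_model()`: strict stepwise, every step is +-1. `tpm_model()`: two-phase
#' model; with probability `p_single` the step is exactly one unit, otherwise
#' its magnitude is geometric on \{1, 2, ...\} with the parameter `q` solving
#' `(1-q)/q^2 = variance` (the conventional "variance of the geometric
#' distribution" parameterisation, default 0.30). `gsm_model()`: generalized
#' stepwise; step magnitude geometric with `P(S = s) = (1-g) g^(s-1)`, so
#' `gsm_par = g` is literally the proportion of multistep (`S >= 2`)
#' mutations. Step direction is equiprobable in all models.
#'
#' @param p_single probability that a mutation is single-step (TPM).
#' @param variance variance of the geometric multistep magnitude (TPM).
#' @param gsm_par proportion of multistep mutations (GSM), in `[0, 1)`.
#' @return An object of class `mutation_model` with fields `kind`,
#'   `p_single`, `q_mult` (the internal geometric success probability) and
#'   the constructor arguments.
#' @export
smm_model <- function() {
  structure(list(kind = "SMM", p_single = 1, q_mult = 1),
            class = "mutation_model")
}

#' @rdname smm_model
#' @export
tpm_model <- function(p_single = 0.8, variance = 0.30) {
  if (p_single < 0 || p_single > 1) stop("p_single must be in [0, 1]")
  if (variance < 0) stop("variance must be >= 0")
  q <- if (variance == 0) 1 else (-1 + sqrt(1 + 4 * variance)) / (2 * variance)
  structure(list(kind = "TPM", p_single = p_single, q_mult = q,
                 variance = variance),
            class = "mutation_model")
}

#' @rdname smm_model
#' @export
gsm_model <- function(gsm_par) {
  if (gsm_par < 0 || gsm_par >= 1) stop("gsm_par must be in [0, 1)")
  structure(list(kind = "GSM", p_single = 0, q_mult = 1 - gsm_par,
                 gsm_par = gsm_par),
            class = "mutation_model")
}

#' @export
print.mutation_model <- function(x, ...) {
  cat("Mutation model:", x$kind)
  if (x$kind == "TPM")
    cat(sprintf(" (p_single = %.2f, geometric variance = %.2f, q = %.4f)",
                x$p_single, x$variance, x$q_mult))
  if (x$kind == "GSM") cat(sprintf(" (gsm_par = %.3f)", x$gsm_par))
  cat("\n")
  invisible(x)
}

#' @rdname smm_model
#' @details `het_excess_presets()` returns the four models conventionally
#'   evaluated in heterozygosity-excess analyses: strict SMM and two-phase
#'   models with 70%, 80% and 90% single-step mutations at geometric
#'   variance 0.30.
#' @export
het_excess_presets <- function() {
  list(SMM = smm_model(),
       TPM70 = tpm_model(0.70),
       TPM80 = tpm_model(0.80),
       TPM90 = tpm_model(0.90))
}
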