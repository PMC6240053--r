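#' Simulate a coalescent genealogy
#'
#' Kingman coalescent for `n_copies` gene copies in a single population with
#' piecewise-constant diploid effective size: pairwise coalescence rate
#' `1/(2*N(t))` per generation, with `N(t)` taken from the demographic model
#' (present to `t_bot_end`: `Ne`; `t_bot_end` to `t_bot_start`: `Ne_bot`;
#' older: `Ne_hist`; non-bottleneck: `Ne` then `Ne_hist` after `t_hist`).
#' Epoch boundaries are handled by exponential time-rescaling within epochs.
#'
#' @param n_copies number of gene copies (>= 2).
#' @param params a [demographic_params()] object.
#' @param seed optional integer seed.
#' @return An object of class `genealogy`: list with `n` (tip count),
#'   `parent` (1-based parent index per node, `NA` for the root), `time`
#'   (node ages in generations; tips are nodes `1..n` at age 0, internal
#'   nodes follow in coalescence order).
#' @export
simulate_genealogy <- function(n_copies, params, seed = NULL) {
  if (n_copies < 2) stop("n_copies must be >= 2")
  ep <- epochs_of(params)
  if (any(ep$N <= 0)) stop("non-positive effective size in an epoch")
  g <- with_seed(seed, cpp_sim_genealogy(n_copies, ep$start, ep$N))
  parent <- g$parent + 1L
  parent[parent == 0L] <- NA_integer_
  structure(list(n = n_copies, parent = parent, time = g$time),
            class = "genealogy")
}

#' @export
print.genealogy <- function(x, ...) {
  cat("Coalescent genealogy:", x$n, "gene copies,",
      x$n - 1, "coalescences; TMRCA =",
      format(tmrca(x), digits = 4), "generations\n")
  invisible(x)
}

#' Genealogy summaries
#' @param g a [simulate_genealogy()] object.
#' @return time to the most recent common ancestor / total branch length, in
#'   generations.
#' @export
tmrca <- function(g) max(g$time)

#' @rdname tmrca
#' @export
total_branch_length <- function(g) {
  has_parent <- !is.na(g$parent)
  sum(g$time[g$parent[has_parent]] - g$time[has_parent])
}

#' Drop stepwise mutations on a genealogy
#'
#' Mutations occur as a Poisson process with intensity `mu` per generation on
#' every branch. Each mutation applies a signed step drawn from the mutation
#' model (see [smm_model()]); allele states are propagated from a fixed root
#' state down to the tips and floored at one repeat unit.
#'
#' @param g a [simulate_genealogy()] genealogy.
#' @param mu mutation rate per locus per generation.
#' @param model a `mutation_model`, or a number interpreted as `gsm_par` of a
#'   generalized stepwise model.
#' @param root_state ancestral allele size in repeat units.
#' @param seed optional integer seed.
#' @return Integer vector of allele sizes, one per gene copy (tip).
#' @export
mutate_gsm <- function(g, mu, model = 0, root_state = 100L, seed = NULL) {
  if (mu < 0) stop("mu must be >= 0")
  if (is.numeric(model)) model <- gsm_model(model)
  stopifnot(inherits(model, "mutation_model"))
  parent0 <- g$parent - 1L
  parent0[is.na(parent0)] <- -1L
  st <- with_seed(seed, cpp_mutate_tree(parent0, g$time, mu,
                                        model$p_single, model$q_mult,
                                        as.integer(root_state)))
  st[seq_len(g$n)]
}

#' Simulate a genotype dataset under a demographic model
#'
#' Simulates `n_loci` independent genealogies of `2*n_ind` gene copies under
#' the demographic model, mutates each under the mutation model implied by
#' `params$gsm_par` (or an explicit `model`), and pairs consecutive gene
#' copies into diploid individuals (copies are exchangeable, so this equals
#' random pairing). No missing data are produced.
#'
#' @param params a [demographic_params()] object.
#' @param n_ind number of diploid individuals.
#' @param n_loci number of loci.
#' @param model optional `mutation_model` overriding `params$gsm_par`.
#' @param species_id dataset label.
#' @param root_state ancestral allele size in repeat units.
#' @param seed optional integer seed.
#' @return A [genotype_dataset()] in repeat-unit encoding.
#' @export
simulate_dataset <- function(params, n_ind = 40, n_loci = 10, model = NULL,
                             species_id = "sim", root_state = 100L,
                             seed = NULL) {
  if (n_ind < 1 || n_loci < 1) stop("n_ind and n_loci must be >= 1")
  if (is.null(model)) model <- gsm_model(params$gsm_par)
  ep <- epochs_of(params)
  with_seed(seed, {
    a1 <- matrix(NA_integer_, n_ind, n_loci)
    a2 <- matrix(NA_integer_, n_ind, n_loci)
    for (j in seq_len(n_loci)) {
      copies <- cpp_sim_locus(2L * n_ind, ep$start, ep$N, params$mu,
                              model$p_single, model$q_mult,
                              as.integer(root_state))
      a1[, j] <- copies[seq(1, 2 * n_ind, by = 2)]
      a2[, j] <- copies[seq(2, 2 * n_ind, by = 2)]
    }
    genotype_dataset(species_id, a1, a2,
                     data.frame(id = paste0("L", seq_len(n_loci)),
                                motif_bp = 2L),
                     encoding = "repeat_units")
  })
}

#' Equilibrium heterozygosity under strict stepwise mutation
#'
#' Closed-form expected gene diversity at mutation-drift equilibrium for a
#' constant-size population under the single-step mutation model:
#' `1 - 1/sqrt(1 + 2*theta)` with `theta = 4*Ne*mu`. Used as an independent
#' oracle for the simulator.
#'
#' @param Ne diploid effective size.
#' @param mu mutation rate per locus per generation.
#' @return Expected heterozygosity in `[0, 1)`.
#' @export
equilibrium_het_smm <- function(Ne, mu) {
  if (any(Ne <= 0)) stop("Ne must be > 0")
  if (any(mu < 0)) stop("mu must be >= 0")
  1 - 1 / sqrt(1 + 2 * (4 * Ne * mu))
}
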