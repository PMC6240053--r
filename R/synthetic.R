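#' Configuration for a synthetic multi-species panel
#'
#' Describes a panel of study-like microsatellite datasets with known
#' demographic ground truth. Per-species dimensions are drawn from
#' truncated log-normal samplers centred on the empirical medians of pooled
#' pinniped panels (individuals: range 16--2386, median 253; loci: range
#' 5--35, median 14). A configurable fraction of species (default 11/30) is
#' generated under the bottleneck demography, the rest under the
#' non-bottleneck demography, with parameters drawn from [default_priors()]
#' unless fixed parameters are supplied.
#'
#' @param n_species number of species datasets.
#' @param bottleneck_fraction expected fraction of bottlenecked species.
#' @param n_ind_range,n_loci_range inclusive dimension ranges.
#' @param n_ind_median,n_loci_median medians targeted by the samplers.
#' @param missing_rate per-genotype missing probability (0--0.2).
#' @param params_bot,params_nonbot optional fixed [demographic_params()]
#'   used for every species of that kind instead of prior draws.
#' @return An object of class `panel_config`.
#' @export
panel_config <- function(n_species = 30, bottleneck_fraction = 11 / 30,
                         n_ind_range = c(16, 2386), n_ind_median = 253,
                         n_loci_range = c(5, 35), n_loci_median = 14,
                         missing_rate = 0,
                         params_bot = NULL, params_nonbot = NULL) {
  if (missing_rate < 0 || missing_rate > 0.2)
    stop("missing_rate must be in [0, 0.2]")
  if (bottleneck_fraction < 0 || bottleneck_fraction > 1)
    stop("bottleneck_fraction must be in [0, 1]")
  structure(list(n_species = n_species,
                 bottleneck_fraction = bottleneck_fraction,
                 n_ind_range = n_ind_range, n_ind_median = n_ind_median,
                 n_loci_range = n_loci_range, n_loci_median = n_loci_median,
                 missing_rate = missing_rate,
                 params_bot = params_bot, params_nonbot = params_nonbot),
            class = "panel_config")
}

# truncated log-normal integer sampler centred on the target median
sample_dim <- function(n, range, median) {
  sdlog <- diff(log(range)) / 4  # ~95% of the untruncated mass inside range
  out <- integer(n)
  need <- seq_len(n)
  while (length(need)) {
    x <- round(stats::rlnorm(length(need), log(median), sdlog))
    ok <- x >= range[1] & x <= range[2]
    out[need[ok]] <- as.integer(x[ok])
    need <- need[!ok]
  }
  out
}

#' Generate a synthetic multi-species panel
#'
#' Simulates every species of the configuration, optionally writes one
#' GenePop file per species, and returns the datasets together with a truth
#' manifest recording the generating parameters and per-species seeds. The
#' master seed fully determines the output.
#'
#' @param config a [panel_config()].
#' @param dir optional directory for GenePop files (created if needed);
#'   `NULL` keeps the datasets in memory only.
#' @param seed master seed.
#' @return An object of class `synthetic_panel`: list with `datasets` (named
#'   list of [genotype_dataset()]), `manifest` (data.frame: `species_id`,
#'   `model`, parameter columns, `n_ind`, `n_loci`, `seed`, `file`).
#' @export
generate_panel <- function(config = panel_config(), dir = NULL, seed = 1) {
  stopifnot(inherits(config, "panel_config"))
  with_seed(seed, {
    n <- config$n_species
    n_bot <- round(config$bottleneck_fraction * n)
    kinds <- sample(c(rep("bottleneck", n_bot),
                      rep("non_bottleneck", n - n_bot)))
    n_ind <- sample_dim(n, config$n_ind_range, config$n_ind_median)
    n_loci <- sample_dim(n, config$n_loci_range, config$n_loci_median)
    species_seeds <- sample.int(2^31 - 2, n)
    datasets <- vector("list", n)
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      sp <- sprintf("species_%02d", i)
      fixed <- if (kinds[i] == "bottleneck") config$params_bot
               else config$params_nonbot
      params <- if (!is.null(fixed)) fixed
                else as_params(with_seed(species_seeds[i],
                                         sample_priors(default_priors(kinds[i]))))
      ds <- simulate_dataset(params, n_ind = n_ind[i], n_loci = n_loci[i],
                             species_id = sp, seed = species_seeds[i])
      if (config$missing_rate > 0) {
        miss <- matrix(stats::runif(n_ind[i] * n_loci[i]) < config$missing_rate,
                       n_ind[i], n_loci[i])
        # never blank out a whole locus
        full <- colSums(!miss) == 0
        miss[1, full] <- FALSE
        ds$allele1[miss] <- NA_integer_
        ds$allele2[miss] <- NA_integer_
      }
      file <- NA_character_
      if (!is.null(dir)) {
        if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
        file <- file.path(dir, paste0(sp, ".gen"))
        write_genepop(ds, file)
      }
      datasets[[i]] <- ds
      pr <- params[c("Ne", "Ne_hist", "Ne_bot", "t_bot_start", "t_bot_end",
                     "t_hist", "mu", "gsm_par")]
      pr[vapply(pr, is.null, logical(1))] <- NA_real_
      rows[[i]] <- data.frame(species_id = sp, model = kinds[i],
                              as.data.frame(pr), n_ind = n_ind[i],
                              n_loci = n_loci[i], seed = species_seeds[i],
                              file = file)
    }
    names(datasets) <- vapply(rows, function(r) r$species_id, character(1))
    manifest <- do.call(rbind, rows)
    structure(list(datasets = datasets, manifest = manifest,
                   master_seed = seed),
              class = "synthetic_panel")
  })
}

#' @export
print.synthetic_panel <- function(x, ...) {
  cat("Synthetic panel:", length(x$datasets), "species (",
      sum(x$manifest$model == "bottleneck"), "bottlenecked );",
      "master seed", x$master_seed, "\n")
  cat("  individuals:", paste(range(x$manifest$n_ind), collapse = "-"),
      " loci:", paste(range(x$manifest$n_loci), collapse = "-"), "\n")
  invisible(x)
}

#' Write / read a truth manifest as JSON
#' @param panel a [generate_panel()] result.
#' @param path JSON path.
#' @return `path` invisibly; `read_manifest` returns the manifest data.frame.
#' @export
write_manifest <- function(panel, path) {
  jsonlite::write_json(panel$manifest, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
}

#' Deterministic edge-case fixtures
#'
#' Small hand-specified datasets exercising documented edge cases:
#' `"monomorphic"` (one allele everywhere), `"missing_heavy"` (~30% missing
#' calls), `"two_allele_hwe"` (a locus in exact Hardy-Weinberg proportions),
#' `"off_lattice"` (bp alleles deviating from motif periodicity, triggering
#' the approximate repeat-unit mapping) and `"tiny"` (16 individuals, below
#' the 40-individual resampling size).
#'
#' @param kind fixture name.
#' @return A [genotype_dataset()].
#' @export
generate_fixture <- function(kind = c("monomorphic", "missing_heavy",
                                      "two_allele_hwe", "off_lattice",
                                      "tiny")) {
  kind <- match.arg(kind)
  loci2 <- function(n) data.frame(id = paste0("L", seq_len(n)), motif_bp = 2L)
  switch(kind,
    monomorphic = genotype_dataset(
      "fix_monomorphic",
      matrix(100L, 8, 2), matrix(100L, 8, 2), loci2(2),
      encoding = "repeat_units"),
    missing_heavy = {
      set.seed(42)
      a1 <- matrix(sample(10:14, 60, TRUE), 20, 3)
      a2 <- matrix(sample(10:14, 60, TRUE), 20, 3)
      miss <- matrix(stats::runif(60) < 0.3, 20, 3)
      miss[1, ] <- FALSE
      a1[miss] <- NA_integer_; a2[miss] <- NA_integer_
      genotype_dataset("fix_missing", a1, a2, loci2(3),
                       encoding = "repeat_units")
    },
    two_allele_hwe = {
      # 25 aa / 50 ab / 25 bb: chi-square exactly 0
      a1 <- matrix(c(rep(10L, 25), rep(10L, 50), rep(12L, 25)), 100, 1)
      a2 <- matrix(c(rep(10L, 25), rep(12L, 50), rep(12L, 25)), 100, 1)
      genotype_dataset("fix_hwe", a1, a2, loci2(1), encoding = "repeat_units")
    },
    off_lattice = genotype_dataset(
      "fix_off_lattice",
      matrix(c(150L, 150L, 152L, 155L), 4, 1),
      matrix(c(150L, 152L, 154L, 155L), 4, 1),
      loci2(1), encoding = "bp"),
    tiny = {
      set.seed(7)
      a1 <- matrix(sample(8:16, 16 * 5, TRUE), 16, 5)
      a2 <- matrix(sample(8:16, 16 * 5, TRUE), 16, 5)
      genotype_dataset("fix_tiny", a1, a2, loci2(5),
                       encoding = "repeat_units")
    })
}
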