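test_that("prior draws respect the stated supports and constraints", {
  d <- sample_priors(default_priors("bottleneck"), 10000, seed = 41)
  expect_true(all(d$Ne_bot >= 1 & d$Ne_bot <= 500))
  expect_lt(abs(mean(d$Ne_bot) - 250.5), 4 * 144 / sqrt(10000))
  # lognormal size prior: median = exp(10.5)
  expect_lt(abs(log(median(d$Ne)) - 10.5), 4 * 1 / sqrt(10000) * sqrt(pi / 2))
  expect_true(all(d$t_bot_end < d$t_bot_start))  # enforced by rejection
  expect_true(all(d$mu >= 1e-5 & d$mu <= 1e-4))
  expect_true(all(d$gsm_par >= 0 & d$gsm_par <= 0.3))
  # rejection preserves the marginal supports
  expect_lt(min(d$t_bot_end), 3); expect_gt(max(d$t_bot_end), 27)
  expect_lt(min(d$t_bot_start), 13); expect_gt(max(d$t_bot_start), 67)
})

test_that("genealogies have n-1 ordered coalescences", {
  p <- demographic_params("bottleneck", Ne = 5000, Ne_hist = 20000,
                          Ne_bot = 50, t_bot_start = 60, t_bot_end = 10,
                          mu = 5e-5)
  for (n in c(2, 7, 40)) {
    g <- simulate_genealogy(n, p, seed = n)
    expect_length(g$parent, 2 * n - 1)
    expect_equal(sum(is.na(g$parent)), 1)      # one root
    internal <- g$time[(n + 1):(2 * n - 1)]
    expect_true(all(diff(internal) > 0))       # strictly increasing rootward
    expect_true(all(internal > 0))
    expect_gt(total_branch_length(g), 0)
    # every parent is older than its child
    ok <- !is.na(g$parent)
    expect_true(all(g$time[g$parent[ok]] > g$time[ok]))
  }
})

test_that("coalescent waiting times match their expectations", {
  p <- demographic_params("non_bottleneck", Ne = 800, Ne_hist = 800,
                          t_hist = 10, mu = 0)
  set.seed(42)
  tm <- replicate(4000, tmrca(simulate_genealogy(2, p)))
  # E[TMRCA] = 2N for two gene copies, diploid units; sd = 2N
  expect_lt(abs(mean(tm) - 1600), 4 * 1600 / sqrt(4000))
  tb <- replicate(2000, total_branch_length(simulate_genealogy(10, p)))
  expect_lt(abs(mean(tb) - 4 * 800 * sum(1 / (1:9))),
            5 * sd(tb) / sqrt(2000))
})

test_that("a long severe bottleneck almost always absorbs the MRCA", {
  p <- demographic_params("bottleneck", Ne = 30000, Ne_hist = 30000,
                          Ne_bot = 5, t_bot_start = 70, t_bot_end = 1,
                          mu = 0)
  set.seed(43)
  older <- mean(replicate(400, tmrca(simulate_genealogy(20, p)) > 70))
  expect_lt(older, 0.05)  # lineages coalesce inside the bottleneck epoch
})

test_that("stepwise mutation follows the model conventions", {
  p <- demographic_params("non_bottleneck", Ne = 1000, Ne_hist = 1000,
                          t_hist = 10, mu = 0)
  g <- simulate_genealogy(30, p, seed = 44)
  # mu = 0: every copy equals the root state
  expect_true(all(mutate_gsm(g, mu = 0, model = 0, seed = 1) == 100L))
  # gsm_par = 0: strict SMM, tip distance from root bounded by mutation count
  tips <- mutate_gsm(g, mu = 1e-3, model = 0, seed = 2)
  expect_true(all(tips >= 1))
  # multistep fraction of GSM steps ~ gsm_par: estimate from a 2-tip star
  # genealogy with a huge mutation supply via heq machinery is indirect;
  # instead check the geometric magnitudes through tpm_model(0, variance)
  m <- gsm_model(0.2)
  expect_equal(m$q_mult, 0.8)
  set.seed(3)
  steps <- rgeom(1e5, m$q_mult) + 1   # the magnitude law used internally
  expect_lt(abs(mean(steps >= 2) - 0.2), 3 * sqrt(0.2 * 0.8 / 1e5))
})

test_that("simulated datasets reproduce the stepwise equilibrium
           heterozygosity across a theta grid", {
  mu <- 5e-5
  for (theta in c(0.1, 1, 10)) {
    Ne <- theta / (4 * mu)
    p <- demographic_params("non_bottleneck", Ne = Ne, Ne_hist = Ne,
                            t_hist = 10, mu = mu)
    ds <- simulate_dataset(p, n_ind = 40, n_loci = 500, model = smm_model(),
                           seed = round(1000 * theta))
    he <- vapply(ds$loci$id, function(l) locus_stats(ds, l)$He, numeric(1))
    mc_se <- sd(he) / sqrt(500)
    expect_lt(abs(mean(he) - equilibrium_het_smm(Ne, mu)), 3 * mc_se)
  }
})

test_that("equilibrium_het_smm is the stated closed form", {
  expect_equal(equilibrium_het_smm(2500, 1e-4), 1 - 1 / sqrt(3))
  expect_equal(equilibrium_het_smm(1000, 0), 0)
  grid <- equilibrium_het_smm(10^seq(2, 6, by = 0.5), 1e-4)
  expect_true(all(diff(grid) > 0))  # strictly increasing
  expect_error(equilibrium_het_smm(0, 1e-4), "Ne")
})

test_that("simulate_dataset is seed-deterministic with exchangeable pairing
           and a shift-invariant allele scale", {
  p <- demographic_params("bottleneck", Ne = 10000, Ne_hist = 30000,
                          Ne_bot = 100, t_bot_start = 50, t_bot_end = 5,
                          mu = 5e-5, gsm_par = 0.1)
  d1 <- simulate_dataset(p, n_ind = 40, n_loci = 10, seed = 7)
  d2 <- simulate_dataset(p, n_ind = 40, n_loci = 10, seed = 7)
  expect_identical(d1, d2)
  expect_equal(dim(d1$allele1), c(40L, 10L))
  # changing the root reference shifts every allele identically
  d3 <- simulate_dataset(p, n_ind = 40, n_loci = 10, root_state = 150L,
                         seed = 7)
  expect_equal(d3$allele1, d1$allele1 + 50L)
  expect_equal(unname(mean_sumstats(d3) - mean_sumstats(d1)),
               rep(0, 5))
})

test_that("size units control the coalescent rate", {
  pd <- demographic_params("non_bottleneck", Ne = 1000, Ne_hist = 1000,
                           t_hist = 5, mu = 0)
  pg <- demographic_params("non_bottleneck", Ne = 1000, Ne_hist = 1000,
                           t_hist = 5, mu = 0, size_units = "gene_copies")
  set.seed(45)
  td <- mean(replicate(2000, tmrca(simulate_genealogy(2, pd))))
  tg <- mean(replicate(2000, tmrca(simulate_genealogy(2, pg))))
  expect_lt(abs(td - 2000), 4 * 2000 / sqrt(2000))
  expect_lt(abs(tg - 1000), 4 * 1000 / sqrt(2000))
})
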