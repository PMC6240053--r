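# a hand-built reference table whose statistics have known structure
fake_table <- function(n = 400, seed = 55, informative = TRUE) {
  set.seed(seed)
  d <- sample_priors(default_priors("non_bottleneck"), n)
  z <- log(d$Ne)
  noise <- rnorm(n, 0, if (informative) 0.05 else 1)
  # informative: one statistic tracks log(Ne), the rest are constant (and
  # so are dropped from the distance); uninformative: all pure noise
  stats <- data.frame(
    k = if (informative) 0.5 * z + noise else rnorm(n),
    r = if (informative) 0 else rnorm(n),
    He = if (informative) 0 else rnorm(n),
    M = if (informative) 0 else rnorm(n),
    lfa = if (informative) 0 else rnorm(n))
  structure(cbind(d, stats), n_ind = 40, n_loci = 10,
            class = c("reference_table", "data.frame"))
}

test_that("reference tables are balanced, reproducible, and pass the priors
           through", {
  tab <- small_table()
  expect_equal(nrow(tab), 5000)
  expect_equal(as.vector(table(tab$model)), c(2500L, 2500L))
  expect_true(all(is.finite(as.matrix(tab[, c("k", "r", "He", "M", "lfa")]))))
  again <- build_reference_table(100, seed = 101)
  expect_identical(again[1:200, c("Ne", "mu", "k", "He")],
                   build_reference_table(100, seed = 101)[1:200,
                                                          c("Ne", "mu", "k", "He")])
  # the Ne_bot column is a pure prior pass-through: U[1, 500]
  ks <- suppressWarnings(
    stats::ks.test(tab$Ne_bot[tab$model == "bottleneck"], "punif", 1, 500))
  expect_gt(ks$p.value, 0.01)
})

test_that("rejection accepts exactly ceiling(tolerance x rows), closest
           first", {
  tab <- small_table()
  obs <- unlist(tab[17, c("k", "r", "He", "M", "lfa")])
  for (tol in c(5e-4, 0.01, 0.2, 1)) {
    rej <- abc_reject(obs, tab, tol)
    expect_equal(rej$n_accept, ceiling(tol * nrow(tab)))
    expect_length(rej$accepted, rej$n_accept)
  }
  # the full-scale arithmetic: 5e-4 of 1e7 rows -> 5000, checked symbolically
  expect_equal(ceiling(5e-4 * 1e7), 5000)
  # a row identical to the observation has distance zero and is accepted
  rej <- abc_reject(obs, tab, 5e-4)
  expect_equal(rej$distance[1], 0)
  expect_true(17 %in% rej$accepted)
  # acceptance is monotone in tolerance
  r1 <- abc_reject(obs, tab, 0.01); r2 <- abc_reject(obs, tab, 0.05)
  expect_true(all(r1$accepted %in% r2$accepted))
})

test_that("model probabilities sum to one and the rejection method equals
           accepted-label proportions", {
  tab <- small_table()
  obs <- unlist(tab[3, c("k", "r", "He", "M", "lfa")])
  mp <- model_posterior(obs, tab, tolerance = 0.02)
  expect_equal(sum(mp$prob), 1)
  expect_true(mp$p_bot >= 0 && mp$p_bot <= 1)
  rej <- abc_reject(obs, tab, 0.02)
  expect_equal(unname(mp$rejection_prob["bottleneck"]),
               mean(tab$model[rej$accepted] == "bottleneck"))
  mp_rej <- model_posterior(obs, tab, tolerance = 0.02, method = "rejection")
  expect_equal(mp_rej$prob, mp$rejection_prob)
})

test_that("two models simulated from the identical process give p_bot near
           one half", {
  set.seed(56)
  d <- sample_priors(default_priors("non_bottleneck"), 4000)
  ep <- msatabc:::epochs_matrix(d)
  st <- msatabc:::cpp_batch_sumstats(40L, 10L, ep$start, ep$N, d$mu,
                                     rep(0, 4000), 1 - d$gsm_par, 100L)
  tab <- structure(cbind(d, as.data.frame(st)), n_ind = 40, n_loci = 10,
                   class = c("reference_table", "data.frame"))
  tab$model <- rep(c("bottleneck", "non_bottleneck"), 2000)  # same process
  picks <- seq(11, 4000, by = 250)
  rej <- vapply(picks, function(i) {
    model_posterior(unlist(tab[i, c("k", "r", "He", "M", "lfa")]),
                    tab, tolerance = 0.05, method = "rejection")$p_bot
  }, numeric(1))
  expect_true(all(abs(rej - 0.5) < 0.15))  # label proportions are symmetric
  mnl <- vapply(picks, function(i) {
    model_posterior(unlist(tab[i, c("k", "r", "He", "M", "lfa")]),
                    tab, tolerance = 0.05)$p_bot
  }, numeric(1))
  expect_lt(abs(mean(mnl) - 0.5), 0.1)  # regression is noisier per draw
})

test_that("local-linear adjustment recovers the analytic conditional
           expectation on a linear toy problem", {
  tab <- fake_table(1000, seed = 57)
  obs <- c(k = 0.5 * 10.8, r = 0, He = 0, M = 0, lfa = 0)
  post <- suppressWarnings(
    param_posterior(obs, tab, model = "non_bottleneck", tolerance = 0.5))
  # independent oracle: unweighted linear regression of log Ne on the
  # informative statistic, evaluated at the observation
  fit <- lm(log(Ne) ~ k, data = tab)
  pred <- unname(predict(fit, newdata = data.frame(k = obs[["k"]])))
  adj_mean <- mean(log(post$adjusted$Ne))
  expect_lt(abs(adj_mean - pred), 0.1)
  # the adjusted spread collapses toward the residual scale
  expect_lt(sd(log(post$adjusted$Ne)), sd(log(post$raw$Ne)))
})

test_that("constant statistics leave raw draws unchanged and adjusted draws
           respect prior supports", {
  tab <- fake_table(400, seed = 58)
  tab$k <- 1  # now every statistic is uninformative or constant
  tab$r <- 2; tab$He <- 3; tab$M <- 4; tab$lfa <- 5
  obs <- c(k = 1, r = 2, He = 3, M = 4, lfa = 5)
  post <- suppressWarnings(
    param_posterior(obs, tab, model = "non_bottleneck", tolerance = 1))
  expect_equal(post$adjusted, post$raw)

  tab2 <- small_table()
  obs2 <- unlist(tab2[8, c("k", "r", "He", "M", "lfa")])
  post2 <- param_posterior(obs2, tab2, model = "bottleneck",
                           tolerance = 0.08)
  expect_true(all(post2$adjusted$Ne_bot >= 1 & post2$adjusted$Ne_bot <= 500))
  expect_true(all(post2$adjusted$mu >= 1e-5 & post2$adjusted$mu <= 1e-4))
  expect_true(all(post2$adjusted$gsm_par >= 0 & post2$adjusted$gsm_par <= 0.3))
  expect_error(param_posterior(obs2, tab2, model = "bottleneck",
                               tolerance = 1e-3, min_accepted = 1e4),
               "accepted")
})

test_that("point estimates: mode finds the taller peak, intervals bracket
           the median, degenerate samples collapse", {
  set.seed(59)
  x <- c(rnorm(700, 0, 0.3), rnorm(300, 4, 0.3))  # taller mode at 0
  fake_post <- structure(list(model = "non_bottleneck",
                              raw = data.frame(Ne = exp(x)),
                              adjusted = data.frame(Ne = exp(x)),
                              weights = rep(1 / 1000, 1000)),
                         class = "abc_posterior")
  pe <- point_estimates(fake_post)
  expect_lt(abs(log(pe$mode[pe$parameter == "Ne"])), 0.2)
  expect_true(pe$lower <= pe$median && pe$median <= pe$upper)
  const <- structure(list(model = "non_bottleneck",
                          raw = data.frame(Ne = rep(7, 200)),
                          adjusted = data.frame(Ne = rep(7, 200)),
                          weights = rep(1 / 200, 200)),
                     class = "abc_posterior")
  pc <- point_estimates(const)
  expect_equal(pc$mode, 7); expect_equal(pc$lower, 7); expect_equal(pc$upper, 7)
})

test_that("cross-validated prediction error separates informative from
           uninformative statistics", {
  # statistics tightly determine log(Ne): error far below 1
  tab <- fake_table(600, seed = 60, informative = TRUE)
  cv <- suppressWarnings(
    cv_param_error(tab, model = "non_bottleneck", n_reps = 40,
                   tolerance = 0.05, seed = 61))
  expect_lt(cv$errors[["Ne"]], 0.35)
  expect_true(all(cv$errors >= 0))
  # pure-noise statistics: the rejection median is the prior median, and the
  # normalised error is ~1 for the (symmetric) uniform time parameter
  tab2 <- fake_table(600, seed = 62, informative = FALSE)
  cv2 <- suppressWarnings(
    cv_param_error(tab2, model = "non_bottleneck", n_reps = 60,
                   tolerance = 0.05, seed = 63))
  expect_lt(abs(cv2$errors[["t_hist"]] - 1), 0.45)
})

test_that("goodness of fit is calibrated for self-drawn observations and
           rejects absurd ones", {
  tab <- small_table()
  sub <- tab[tab$model == "non_bottleneck", , drop = FALSE]
  set.seed(64)
  picks <- sample(nrow(sub), 60)
  pvals <- vapply(picks, function(i) {
    suppressWarnings(
      goodness_of_fit(unlist(sub[i, c("k", "r", "He", "M", "lfa")]),
                      sub[-i, , drop = FALSE], model = "non_bottleneck",
                      n_null = 100, tolerance = 0.05, seed = i))$p_value
  }, numeric(1))
  expect_lt(mean(pvals < 0.05), 0.15)  # ~5% nominal
  expect_gt(mean(pvals), 0.3)          # roughly uniform, not stacked at 0
  absurd <- c(k = 2, r = 300, He = 0.99, M = 0.01, lfa = 0.9)
  g <- suppressWarnings(
    goodness_of_fit(absurd, tab, model = "non_bottleneck",
                    n_null = 100, tolerance = 0.05, seed = 65))
  expect_lt(g$p_value, 0.02)
})

test_that("posterior predictive simulations have the requested size and
           cover self-consistent observations", {
  tab <- small_table()
  obs <- unlist(tab[12, c("k", "r", "He", "M", "lfa")])
  m <- tab$model[12]
  post <- param_posterior(obs, tab, model = m, tolerance = 0.05)
  pp <- posterior_predictive(post, n_draws = 300, seed = 66)
  expect_equal(nrow(pp), 300)
  expect_true(all(c("k", "r", "He", "M", "lfa") %in% names(pp)))
  inside <- vapply(c("k", "r", "He", "M", "lfa"), function(cn) {
    q <- quantile(pp[[cn]], c(0.025, 0.975))
    obs[[cn]] >= q[1] && obs[[cn]] <= q[2]
  }, logical(1))
  expect_gte(sum(inside), 4)  # a self-drawn observation fits its model
})
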