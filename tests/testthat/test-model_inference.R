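test_that("aic_table computes Akaike weights in closed form", {
  fake_fit <- function(name, aic, k = 1) {
    structure(list(spec = list(name = name), rates = 0.1, logL = -aic / 2,
                   k = k, n = 100, AIC = aic, AICc = aic),
              class = "mk_fit")
  }
  one <- aic_table(list(M = fake_fit("M", 100)))
  expect_equal(one$AICw, 1.0)

  two_eq <- aic_table(list(A = fake_fit("A", 100), B = fake_fit("B", 100)))
  expect_equal(two_eq$AICw, c(0.5, 0.5))

  two <- aic_table(list(A = fake_fit("A", 100), B = fake_fit("B", 102)))
  expect_equal(two$AICw, c(exp(0), exp(-1)) / (1 + exp(-1)),
               tolerance = 1e-9)
  expect_equal(round(two$AICw, 4), c(0.7311, 0.2689))
  expect_equal(sum(two$AICw), 1, tolerance = 1e-12)
})

test_that("AICc carries the exact small-sample correction", {
  set.seed(1)
  tree <- simulate_tree(30, seed = 1)
  s3 <- state_space("three")
  d <- simulate_trait(tree, build_q(model_catalog("ER", s3), 0.02),
                      seed = 2)
  f <- fit_ml(tree, d$tip_states, model_catalog("SYM", s3),
              n_restarts = 1, seed = 1)
  expect_equal(f$AICc - f$AIC, 2 * f$k * (f$k + 1) / (f$n - f$k - 1),
               tolerance = 1e-12)
})

test_that("invariant data drive rates to zero under a fixed root state", {
  tree <- simulate_tree(20, seed = 4)
  s3 <- state_space("three")
  tt <- trait_table(stats::setNames(rep("S", 20), tree$tip.label), s3)
  f <- fit_ml(tree, tt, model_catalog("ER", s3),
              root_prior = c(1, 0, 0), n_restarts = 2, seed = 1)
  expect_lt(f$rates, 1e-4)
  expect_gt(f$logL, -1e-3)
})

test_that("ML recovers the generating ER rate on simulated data", {
  hits <- 0
  for (rep in 1:5) {
    tree <- simulate_tree(300, seed = 20 + rep)
    s3 <- state_space("three")
    q <- build_q(model_catalog("ER", s3), 0.02)
    d <- simulate_trait(tree, q, seed = 40 + rep)
    f <- fit_ml(tree, d$tip_states, model_catalog("ER", s3),
                n_restarts = 1, seed = rep)
    if (abs(f$rates - 0.02) / 0.02 < 0.3) hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("nested models keep the likelihood ordering ARD >= SYM >= ER", {
  for (rep in 1:3) {
    tree <- simulate_tree(80, seed = 60 + rep)
    s4 <- state_space("four")
    q <- build_q(model_catalog("SYM", s4),
                 c(0.02, 0.01, 0.015, 0.025, 0.02, 0.01))
    d <- simulate_trait(tree, q, seed = 80 + rep)
    fits <- fit_models(tree, d$tip_states, c("ER", "SYM", "ARD"), s4,
                       n_restarts = 1, seed = rep)
    expect_gte(fits$ARD$logL, fits$SYM$logL - 1e-6)
    expect_gte(fits$SYM$logL, fits$ER$logL - 1e-6)
  }
})

test_that("log Bayes factors reproduce the published comparison rows", {
  bf1 <- log_bayes_factor(-79.07, -80.47)
  expect_equal(bf1$value, 2.80, tolerance = 1e-9)
  expect_match(bf1$interpretation, "positive")

  bf2 <- log_bayes_factor(-79.07, -83.45)
  expect_equal(bf2$value, 8.76, tolerance = 1e-9)
  expect_match(bf2$interpretation, "^strong")

  bf3 <- log_bayes_factor(-79.07, -103.49)
  expect_equal(bf3$value, 48.84, tolerance = 1e-9)
  expect_match(bf3$interpretation, "very strong")

  expect_equal(log_bayes_factor(-10, -10)$value, 0)
  expect_match(log_bayes_factor(-10, -10)$interpretation, "weak")

  # antisymmetry
  expect_equal(log_bayes_factor(-79.07, -80.47)$value,
               -log_bayes_factor(-80.47, -79.07)$value)
  expect_error(log_bayes_factor(-Inf, -10), "finite")
})

test_that("MCMC sampling is reproducible and matches the ML point", {
  tree <- simulate_tree(200, seed = 7)
  s3 <- state_space("three")
  q <- build_q(model_catalog("ER", s3), 0.02)
  d <- simulate_trait(tree, q, seed = 9)
  spec <- model_catalog("ER", s3)
  st <- mcmc_settings(n_iter = 6000, burn_in = 2000, thin = 5, seed = 3,
                      prior_mean = 1)
  p1 <- suppressWarnings(mcmc_sample(tree, d$tip_states, spec, st))
  p2 <- suppressWarnings(mcmc_sample(tree, d$tip_states, spec, st))
  expect_identical(p1$draws, p2$draws)

  f <- fit_ml(tree, d$tip_states, spec, n_restarts = 1, seed = 1)
  expect_equal(mean(p1$draws[, 1]), f$rates, tolerance = 0.25)
})

test_that("prior-only MCMC reproduces the hyperprior rate mean", {
  tree <- simulate_tree(10, seed = 2)
  s3 <- state_space("three")
  tt <- simulate_trait(tree, build_q(model_catalog("ER", s3), 0.02),
                       seed = 3)$tip_states
  st <- mcmc_settings(n_iter = 40000, burn_in = 4000, thin = 10, seed = 6)
  p <- suppressWarnings(mcmc_sample(tree, tt, model_catalog("ER", s3), st,
                                    prior_only = TRUE))
  # rates ~ Exp(mean m), m ~ U(0, 10): marginal E[rate] = E[m] = 5
  expect_equal(mean(p$draws[, 1]), 5, tolerance = 1.5)
  expect_equal(mean(p$prior_mean), 5, tolerance = 1.2)
})

test_that("mcmc_settings validates its invariants", {
  expect_error(mcmc_settings(n_iter = 100, burn_in = 100), "burn_in")
  expect_error(mcmc_settings(thin = 0), "thin")
})

test_that("stepping stone is exact for a zero-parameter model and guarded", {
  tree <- read_newick("((A:1,B:1):1,C:2);")
  s2 <- state_space(c("0", "1"))
  tt <- trait_table(c(A = "0", B = "0", C = "0"), s2)
  spec <- model_spec(matrix(c(NA, 0L, 0L, NA), 2, 2), s2, "none")
  ss <- stepping_stone_ml(tree, tt, spec, mcmc_settings(seed = 1),
                          n_stones = 8, iter_per_stone = 100)
  expect_equal(ss$log_marginal,
               prune_log_likelihood(tree, tt, build_q(spec, numeric(0))),
               tolerance = 1e-12)
  expect_error(stepping_stone_ml(tree, tt, model_catalog("ER", s2),
                                 mcmc_settings(), n_stones = 1),
               "at least 2")
  # stones increase from the prior to the posterior
  expect_true(all(diff(ss$stones) > 0))
  expect_equal(range(ss$stones), c(0, 1))
})

test_that("bayes_table ranks models and labels evidence", {
  mk <- function(lm, name) structure(list(log_marginal = lm, model = name),
                                     class = "stepping_stone_result")
  tab <- bayes_table(list(IC = mk(-79.07, "IC"), SYM = mk(-80.47, "SYM"),
                          SHULTZ = mk(-103.49, "SHULTZ")))
  expect_equal(tab$model, c("IC", "SYM", "SHULTZ"))
  expect_equal(tab$logBF_vs_best[2:3], c(2.80, 48.84), tolerance = 1e-9)
  expect_match(tab$interpretation[3], "very strong")
})

test_that("canonical model strings ignore class relabeling", {
  expect_equal(canonical_model_string(c(0L, 3L, 3L, 7L)), "Z A A B")
  set.seed(12)
  for (i in 1:25) {
    n <- sample(4:12, 1)
    asg <- sample(0:4, n, replace = TRUE)
    ids <- unique(asg[asg > 0])
    relab <- sample(100:200, length(ids))
    asg2 <- asg
    for (j in seq_along(ids)) asg2[asg == ids[j]] <- relab[j]
    expect_equal(canonical_model_string(asg2), canonical_model_string(asg))
  }
})

test_that("reversible jump recovers a single shared rate under ER data", {
  tree <- simulate_tree(250, seed = 31)
  s2 <- state_space(c("0", "1"))
  d <- simulate_trait(tree, build_q(model_catalog("ER", s2), 0.02),
                      seed = 32)
  st <- mcmc_settings(n_iter = 6000, burn_in = 2000, thin = 5, seed = 33)
  rj <- rj_mcmc(tree, d$tip_states, s2, st)
  expect_equal(rj$models$model_string[1], "A A")
  expect_gt(rj$top_support, 0.5)

  # determinism under a fixed seed
  rj2 <- rj_mcmc(tree, d$tip_states, s2, st)
  expect_identical(rj$draws, rj2$draws)
})

test_that("invariant data favor zero-heavy partitions in the RJ search", {
  tree <- simulate_tree(40, seed = 35)
  s4 <- state_space("four")
  tt <- trait_table(stats::setNames(rep("S", 40), tree$tip.label), s4)
  st <- mcmc_settings(n_iter = 4000, burn_in = 1000, thin = 5, seed = 36)
  rj <- suppressWarnings(rj_mcmc(tree, tt, s4, st))
  zmat <- do.call(rbind, strsplit(rj$draws$model_string, " "))
  expect_gt(mean(zmat == "Z"), 0.5)
})
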