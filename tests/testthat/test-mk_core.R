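test_that("catalog models have the published parameter counts", {
  s4 <- state_space("four")
  counts4 <- vapply(c("ER", "SYM", "ARD", "IC", "SHULTZ", "RJ_DERIVED"),
                    function(n) n_free_rates(model_catalog(n, s4)),
                    numeric(1))
  expect_equal(unname(counts4), c(1, 6, 12, 6, 4, 6))

  s3 <- state_space("three")
  counts3 <- vapply(c("ER", "SYM", "ARD", "IC", "SHULTZ"),
                    function(n) n_free_rates(model_catalog(n, s3)),
                    numeric(1))
  expect_equal(unname(counts3), c(1, 3, 6, 4, 2))

  expect_error(model_catalog("NOPE", s4), "catalog")
})

test_that("catalog structures forbid exactly the stated transitions", {
  s4 <- state_space("four")
  rj <- model_catalog("RJ_DERIVED", s4)$index
  zero_cells <- list(c("S", "UM"), c("UM", "S"), c("S", "MM"),
                     c("MM", "S"), c("P", "UM"), c("UM", "P"))
  for (z in zero_cells) expect_equal(unname(rj[z[1], z[2]]), 0)
  expect_equal(sum(rj > 0, na.rm = TRUE), 6)

  ic <- model_catalog("IC", s4)$index
  expect_true(ic["S", "P"] > 0 && ic["P", "UM"] > 0 && ic["UM", "MM"] > 0)
  expect_equal(unname(ic["S", "UM"]), 0)
  expect_equal(unname(ic["P", "MM"]), 0)

  # once social, never solitary again under the Shultz structure
  sh <- model_catalog("SHULTZ", s4)$index
  expect_true(sh["S", "MM"] > 0)
  expect_true(all(sh[c("P", "UM", "MM"), "S"] == 0))
  expect_true(sh["MM", "P"] > 0 && sh["MM", "UM"] > 0 && sh["UM", "MM"] > 0)
  expect_equal(n_free_rates(model_catalog("SHULTZ_5", s4)), 5)

  sh3 <- model_catalog("SHULTZ", state_space("three"))$index
  expect_true(sh3["S", "G"] > 0 && sh3["G", "P"] > 0)
  expect_equal(sum(sh3 > 0, na.rm = TRUE), 2)

  # three-state RJ-derived coincides with IC
  s3 <- state_space("three")
  expect_equal(model_catalog("RJ_DERIVED", s3)$index,
               model_catalog("IC", s3)$index)
})

test_that("model specs serialize to and from the matrix grammar", {
  s4 <- state_space("four")
  for (nm in c("ER", "SYM", "ARD", "IC", "SHULTZ", "RJ_DERIVED")) {
    spec <- model_catalog(nm, s4)
    back <- read_model_spec(format_model_spec(spec), s4, name = nm)
    expect_equal(back$index, spec$index)
  }
  expect_error(read_model_spec(c("A A", ". A"), s4), "expected 4 rows")
})

test_that("build_q fills classes and zeroes the diagonal to row sums", {
  s3 <- state_space("three")
  q <- build_q(model_catalog("ER", s3), 0.1)
  expect_equal(unname(diag(q$q)), rep(-0.2, 3))
  expect_equal(unname(q$q["S", "P"]), 0.1)

  q0 <- build_q(model_catalog("SYM", s3), rep(0, 3))
  expect_equal(unname(q0$q), matrix(0, 3, 3))

  s4 <- state_space("four")
  qr <- build_q(model_catalog("RJ_DERIVED", s4), seq(0.1, 0.6, by = 0.1))
  off <- qr$q[row(qr$q) != col(qr$q)]
  expect_equal(sum(off > 0), 6)

  expect_error(build_q(model_catalog("ER", s3), -1), "non-negative")
  expect_error(build_q(model_catalog("ER", s3), c(1, 2)), "expected 1")
})

test_that("transition_matrix matches closed forms and CTMC laws", {
  s2 <- state_space(c("0", "1"))
  q <- build_q(model_catalog("ER", s2), 1)
  expect_equal(transition_matrix(q, 0), diag(2), ignore_attr = TRUE)
  P1 <- transition_matrix(q, 1)
  expect_equal(P1["0", "0"], 0.5 + 0.5 * exp(-2), tolerance = 1e-12)
  expect_error(transition_matrix(q, -1), "non-negative")

  # Chapman-Kolmogorov on random asymmetric rate matrices
  for (seed in 1:5) {
    set.seed(seed)
    s3 <- state_space("three")
    qq <- build_q(model_catalog("ARD", s3), runif(6, 0.1, 2))
    s <- runif(1, 0.1, 2)
    t <- runif(1, 0.1, 2)
    expect_equal(transition_matrix(qq, s) %*% transition_matrix(qq, t),
                 transition_matrix(qq, s + t), tolerance = 1e-9)
    expect_equal(unname(rowSums(transition_matrix(qq, t))), rep(1, 3),
                 tolerance = 1e-10)
  }

  # ergodic limit: rows approach the stationary distribution
  set.seed(9)
  qq <- build_q(model_catalog("ARD", state_space("three")), runif(6, 0.5, 2))
  Pinf <- transition_matrix(qq, 1e4)
  pi <- stationary_dist(qq)
  for (i in 1:3) expect_equal(unname(Pinf[i, ]), unname(pi),
                              tolerance = 1e-6)
})

test_that("lambda_transform rescales internal branches preserving depths", {
  tr <- read_newick("((A:1,B:1):1,C:2);")
  expect_equal(lambda_transform(tr, 1), tr)

  half <- lambda_transform(tr, 0.5)
  d <- ape::cophenetic.phylo(half)
  internal <- half$edge.length[half$edge[, 2] > 3]
  expect_equal(internal, 0.5)
  tip_len <- half$edge.length[half$edge[, 2] <= 3]
  names(tip_len) <- half$tip.label[half$edge[half$edge[, 2] <= 3, 2]]
  expect_equal(tip_len[["A"]], 1.5)
  expect_equal(tip_len[["C"]], 2)

  star <- lambda_transform(tr, 0)
  expect_equal(max(star$edge.length[star$edge[, 2] > 3]), 0)
  expect_equal(ape::node.depth.edgelength(star)[1:3],
               ape::node.depth.edgelength(tr)[1:3])

  expect_error(lambda_transform(tr, 1.2), "0, 1")
})

test_that("pruning likelihood reproduces closed-form worked examples", {
  s2 <- state_space(c("0", "1"))
  q <- build_q(model_catalog("ER", s2), 1)

  # known tip plus fully ambiguous tip on zero branches: L = 1/K
  tr0 <- read_newick("(A:0,B:0);")
  tt <- trait_table(c(A = "0", B = "0|1"), s2)
  expect_equal(prune_log_likelihood(tr0, tt, q), log(1 / 2),
               tolerance = 1e-12)

  # everything ambiguous normalizes to 1
  tta <- trait_table(c(A = "0|1", B = "0|1"), s2)
  expect_equal(prune_log_likelihood(tr0, tta, q), 0, tolerance = 1e-12)

  # two matching tips at distance 1 from the root, symmetric rate 1
  tr1 <- read_newick("(A:1,B:1);")
  tt1 <- trait_table(c(A = "0", B = "0"), s2)
  p00 <- 0.5 + 0.5 * exp(-2)
  p01 <- 0.5 - 0.5 * exp(-2)
  expect_equal(prune_log_likelihood(tr1, tt1, q),
               log(0.5 * (p00^2 + p01^2)), tolerance = 1e-12)

  # structurally impossible data yield -Inf with a warning, not an error
  qz <- build_q(model_catalog("SYM", s2), 0)
  tt2 <- trait_table(c(A = "0", B = "1"), s2)
  expect_warning(v <- prune_log_likelihood(tr1, tt2, qz), "impossible")
  expect_identical(v, -Inf)
})

test_that("pruning likelihood matches brute-force enumeration", {
  for (seed in 1:40) {
    fx <- random_fixture(seed)
    got <- suppressWarnings(prune_log_likelihood(fx$tree, fx$traits, fx$q))
    want <- brute_force_loglik(fx$tree, fx$traits, fx$q$q)
    expect_equal(got, want, tolerance = 1e-10,
                 label = paste("fixture", seed, fx$spec$name))
  }
})

test_that("root prior options behave as defined", {
  fx <- random_fixture(101)
  K <- length(fx$traits$states$labels)
  # fixed-vector prior equals the weighted sum of fixed-root likelihoods
  Droot <- vapply(seq_len(K), function(s) {
    prior <- rep(0, K)
    prior[s] <- 1
    exp(prune_log_likelihood(fx$tree, fx$traits, fx$q, root_prior = prior))
  }, numeric(1))
  lu <- prune_log_likelihood(fx$tree, fx$traits, fx$q, "uniform")
  expect_equal(lu, log(mean(Droot)), tolerance = 1e-10)
  lf <- prune_log_likelihood(fx$tree, fx$traits, fx$q, "fitzjohn")
  expect_equal(lf, log(sum(Droot^2) / sum(Droot)), tolerance = 1e-10)
})

test_that("ER likelihood is invariant under joint state relabeling", {
  set.seed(77)
  tr <- ape::rtree(6)
  s3 <- state_space("three")
  q <- build_q(model_catalog("ER", s3), 0.3)
  vals <- c(t1 = "S", t2 = "P", t3 = "G", t4 = "S", t5 = "P", t6 = "G")
  base <- prune_log_likelihood(tr, trait_table(vals, s3), q)
  perm <- c(S = "G", P = "S", G = "P")
  permuted <- trait_table(stats::setNames(perm[vals], names(vals)), s3)
  expect_equal(prune_log_likelihood(tr, permuted, q), base,
               tolerance = 1e-12)
})

test_that("lambda = 0 likelihood equals independent tips at root depth", {
  set.seed(5)
  tree <- simulate_tree(12, seed = 5, depth = 3)
  s3 <- state_space("three")
  q <- build_q(model_catalog("SYM", s3), c(0.3, 0.2, 0.4))
  vals <- stats::setNames(sample(s3$labels, 12, replace = TRUE),
                          tree$tip.label)
  tt <- trait_table(vals, s3)
  star <- lambda_transform(tree, 0)
  got <- prune_log_likelihood(star, tt, q)
  depth <- max(ape::node.depth.edgelength(tree))
  P <- transition_matrix(q, depth)
  idx <- match(vals, s3$labels)
  want <- log(mean(vapply(1:3, function(s) prod(P[s, idx]), numeric(1))))
  expect_equal(got, want, tolerance = 1e-9)
})
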