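test_that("marginal reconstruction matches the two-tip closed form", {
  s2 <- state_space(c("0", "1"))
  tr <- read_newick("(A:1,B:1);")
  tt <- trait_table(c(A = "0", B = "0"), s2)
  q <- build_q(model_catalog("ER", s2), 1)
  a <- marginal_asr(tr, tt, q)
  p00 <- 0.5 + 0.5 * exp(-2)
  p01 <- 0.5 - 0.5 * exp(-2)
  expect_equal(unname(a$probs["3", "0"]), p00^2 / (p00^2 + p01^2),
               tolerance = 1e-10)
  expect_equal(unname(rowSums(a$probs)), rep(1, nrow(a$probs)),
               tolerance = 1e-9)

  # short branches pin the root; long branches wash out to the prior
  near <- marginal_asr(read_newick("(A:0.001,B:0.001);"), tt, q)
  expect_gt(near$probs["3", "0"], 0.99)
  far <- marginal_asr(read_newick("(A:500,B:500);"), tt, q)
  expect_equal(unname(far$probs["3", ]), c(0.5, 0.5), tolerance = 1e-3)
})

test_that("marginal reconstruction agrees with brute-force enumeration", {
  for (seed in c(1:12, 50:57)) {
    fx <- random_fixture(seed)
    got <- tryCatch(marginal_asr(fx$tree, fx$traits, fx$q),
                    error = function(e) NULL)
    if (is.null(got)) next  # structurally impossible fixture
    want <- brute_force_marginals(fx$tree, fx$traits, fx$q$q)
    expect_equal(unname(got$probs), unname(want), tolerance = 1e-10,
                 label = paste("fixture", seed, fx$spec$name))
  }
})

test_that("marginal reconstruction equals re-rooting for symmetric models", {
  set.seed(21)
  tr <- ape::rtree(6)
  s3 <- state_space("three")
  q <- build_q(model_catalog("SYM", s3), c(0.4, 0.3, 0.5))
  vals <- stats::setNames(sample(s3$labels, 6, replace = TRUE),
                          tr$tip.label)
  tt <- trait_table(vals, s3)
  asr <- marginal_asr(tr, tt, q)
  n_tip <- 6
  for (node in (n_tip + 2):(n_tip + tr$Nnode)) {
    rr <- phytools::reroot(tr, node)
    dp <- primsoc:::down_partials(rr, tt, q$q)
    m <- dp$root / sum(dp$root)
    expect_equal(unname(asr$probs[as.character(node), ]), m,
                 tolerance = 1e-8, label = paste("node", node))
  }
})

test_that("mrca_probs addresses internal nodes by tip sets", {
  tr <- read_newick("((A:1,B:1):1,C:2);")
  s2 <- state_space(c("0", "1"))
  tt <- trait_table(c(A = "0", B = "0", C = "1"), s2)
  q <- build_q(model_catalog("ER", s2), 0.3)
  a <- marginal_asr(tr, tt, q)
  expect_equal(mrca_probs(a, c("A", "B")), a$probs["5", ])
  expect_equal(mrca_probs(a, c("A", "C")), a$probs["4", ])
})

test_that("stochastic maps are deterministic, exhaustive and consistent", {
  s2 <- state_space(c("0", "1"))
  tr <- read_newick("((A:1,B:2):1,C:1.5);")
  tt <- trait_table(c(A = "0", B = "1", C = "0"), s2)
  q <- build_q(model_catalog("ER", s2), 0.6)
  m1 <- stochastic_map(tr, tt, q, n_maps = 20, seed = 5)
  m2 <- stochastic_map(tr, tt, q, n_maps = 20, seed = 5)
  expect_identical(m1, m2)

  pre <- reorder(tr, "cladewise")
  for (h in m1[1:5]) {
    for (e in seq_along(h$edge_paths)) {
      expect_equal(sum(h$edge_paths[[e]]$durations), pre$edge.length[e],
                   tolerance = 1e-9)
    }
    expect_true(all(h$counts >= 0))
    expect_equal(unname(diag(h$counts)), c(0, 0))
    expect_equal(h$counts == round(h$counts),
                 matrix(TRUE, 2, 2), ignore_attr = TRUE)
    # recount transitions from the raw paths: bookkeeping identity
    recount <- matrix(0, 2, 2)
    for (e in seq_along(h$edge_paths)) {
      st <- h$edge_paths[[e]]$states
      if (length(st) > 1) {
        for (i in seq_len(length(st) - 1)) {
          recount[st[i], st[i + 1]] <- recount[st[i], st[i + 1]] + 1
        }
      }
    }
    expect_equal(unname(h$counts), recount)
  }
})

test_that("a near-zero rate matrix yields constant histories", {
  s2 <- state_space(c("0", "1"))
  tr <- read_newick("((A:1,B:1):1,C:2);")
  tt <- trait_table(c(A = "0", B = "0", C = "0"), s2)
  q <- build_q(model_catalog("ER", s2), 1e-9)
  maps <- stochastic_map(tr, tt, q, n_maps = 10, seed = 2)
  for (h in maps) expect_equal(sum(h$counts), 0)
})

test_that("root states across maps match the marginal reconstruction", {
  s3 <- state_space("three")
  tr <- read_newick("(((A:6,B:6):4,C:10):5,(D:8,E:8):7);")
  tt <- trait_table(c(A = "S", B = "P", C = "S", D = "G", E = "P"), s3)
  q <- build_q(model_catalog("SYM", s3), c(0.08, 0.05, 0.06))
  asr <- marginal_asr(tr, tt, q)
  maps <- stochastic_map(tr, tt, q, n_maps = 3000, seed = 9)
  root <- length(tr$tip.label) + 1
  roots <- vapply(maps, function(h) h$node_state[root], integer(1))
  obs <- tabulate(roots, 3)
  p <- suppressWarnings(
    stats::chisq.test(obs, p = asr$probs[as.character(root), ])$p.value)
  expect_gt(p, 1e-3)
})

test_that("uniformization path sampling matches rejection sampling", {
  set.seed(14)
  Q <- build_q(model_catalog("SYM", state_space(c("0", "1"))), 0.8)$q
  # conditional distribution of jump counts on one branch, both samplers
  rej <- rejection_branch_counts(1, 2, 1.5, Q, n_ok = 800)
  s2 <- state_space(c("0", "1"))
  tr <- read_newick("(A:1.5,B:0.0001);")
  tt <- trait_table(c(A = "1", B = "0"), s2)
  maps <- stochastic_map(tr, tt, build_q(model_catalog("SYM", s2), 0.8),
                         n_maps = 800, seed = 15)
  pre <- reorder(tr, "cladewise")
  eA <- which(pre$edge[, 2] == which(pre$tip.label == "A"))
  root_zero <- vapply(maps, function(h) h$node_state[3] == 1L, logical(1))
  uni <- vapply(maps[root_zero], function(h) {
    length(h$edge_paths[[eA]]$states) - 1L
  }, integer(1))
  # same parity constraint and matching means within Monte Carlo error
  expect_true(all(uni %% 2 == 1))
  expect_true(all(rej %% 2 == 1))
  se <- sqrt(stats::var(uni) / length(uni) + stats::var(rej) / length(rej))
  expect_lt(abs(mean(uni) - mean(rej)), 4 * se)
})

test_that("transition summaries aggregate counts and dwell times", {
  s2 <- state_space(c("0", "1"))
  tr <- read_newick("((A:1,B:2):1,C:1.5);")
  tt <- trait_table(c(A = "0", B = "1", C = "0"), s2)
  q <- build_q(model_catalog("ER", s2), 0.6)
  maps <- stochastic_map(tr, tt, q, n_maps = 30, seed = 8)
  s <- summarize_transitions(maps)
  expect_equal(s$n_maps, 30)
  expect_equal(sum(s$dwell_proportions), 1, tolerance = 1e-9)
  one <- summarize_transitions(maps[1])
  expect_equal(one$mean_counts, maps[[1]]$counts + 0, ignore_attr = TRUE)
  expect_equal(unname(one$sd_counts), matrix(0, 2, 2))

  s3maps <- stochastic_map(tr, trait_table(c(A = "S", B = "P", C = "S"),
                                           state_space("three")),
                           build_q(model_catalog("ER",
                                                 state_space("three")),
                                   0.3),
                           n_maps = 2, seed = 1)
  expect_error(summarize_transitions(c(maps[1], s3maps[1])),
               "different state spaces")
})

test_that("SIMMAP text round-trips through phytools with equal counts", {
  s3 <- state_space("three")
  tr <- read_newick("((A:2,B:2):1,(C:1,D:1):2);")
  tt <- trait_table(c(A = "S", B = "P", C = "G", D = "G"), s3)
  q <- build_q(model_catalog("SYM", s3), c(0.3, 0.2, 0.25))
  maps <- stochastic_map(tr, tt, q, n_maps = 5, seed = 21)
  for (h in maps) {
    f <- tempfile(fileext = ".tre")
    write_simmap(h, f)
    back <- phytools::read.simmap(f, format = "phylip")
    cnt <- phytools::countSimmap(back)$Tr
    cnt <- cnt[rownames(h$counts), colnames(h$counts)]
    expect_equal(unname(cnt), unname(h$counts))
  }
})

test_that("maps distribute across a posterior tree sample", {
  s2 <- state_space(c("0", "1"))
  trees <- c(read_newick("((A:1,B:1):1,C:2);"),
             read_newick("((A:2,B:2):1,C:3);"))
  class(trees) <- "multiPhylo"
  tt <- trait_table(c(A = "0", B = "1", C = "0"), s2)
  q <- build_q(model_catalog("ER", s2), 0.4)
  maps <- stochastic_map(trees, tt, q, n_maps = 10, seed = 3)
  expect_equal(length(maps), 10)
  depths <- vapply(maps, function(h) sum(h$dwell), numeric(1))
  expect_equal(length(unique(round(depths, 6))), 2)
})
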