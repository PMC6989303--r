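# Independent oracles used across the suite. They deliberately avoid the
# package's own C++ kernels: matrix exponentials come from Matrix::expm and
# likelihoods/marginals from explicit enumeration over internal-node state
# assignments, so agreement is a genuine cross-check.

expm_ref <- function(M) as.matrix(Matrix::expm(Matrix::Matrix(M)))

# Sum over all joint internal-node state assignments; tips contribute
# their partial (indicator or probability) summed against the edge kernel.
brute_force_loglik <- function(tree, traits, Q, root_prior = NULL) {
  K <- nrow(Q)
  n_tip <- length(tree$tip.label)
  part <- traits$partial[tree$tip.label, , drop = FALSE]
  P <- lapply(seq_len(nrow(tree$edge)),
              function(e) expm_ref(Q * tree$edge.length[e]))
  if (is.null(root_prior)) root_prior <- rep(1 / K, K)
  internal <- (n_tip + 1):(n_tip + tree$Nnode)
  root <- n_tip + 1
  grid <- as.matrix(expand.grid(rep(list(seq_len(K)), length(internal))))
  total <- 0
  for (g in seq_len(nrow(grid))) {
    assign <- grid[g, ]
    names(assign) <- internal
    p <- root_prior[assign[as.character(root)]]
    for (e in seq_len(nrow(tree$edge))) {
      a <- assign[as.character(tree$edge[e, 1])]
      ch <- tree$edge[e, 2]
      p <- p * if (ch <= n_tip) {
        sum(P[[e]][a, ] * part[tree$tip.label[ch], ])
      } else {
        P[[e]][a, assign[as.character(ch)]]
      }
      if (p == 0) break
    }
    total <- total + p
  }
  log(total)
}

# Marginal node probabilities by the same enumeration.
brute_force_marginals <- function(tree, traits, Q, root_prior = NULL) {
  K <- nrow(Q)
  n_tip <- length(tree$tip.label)
  part <- traits$partial[tree$tip.label, , drop = FALSE]
  P <- lapply(seq_len(nrow(tree$edge)),
              function(e) expm_ref(Q * tree$edge.length[e]))
  if (is.null(root_prior)) root_prior <- rep(1 / K, K)
  internal <- (n_tip + 1):(n_tip + tree$Nnode)
  root <- n_tip + 1
  grid <- as.matrix(expand.grid(rep(list(seq_len(K)), length(internal))))
  probs <- matrix(0, length(internal), K, dimnames = list(internal, NULL))
  for (g in seq_len(nrow(grid))) {
    assign <- grid[g, ]
    names(assign) <- internal
    p <- root_prior[assign[as.character(root)]]
    for (e in seq_len(nrow(tree$edge))) {
      a <- assign[as.character(tree$edge[e, 1])]
      ch <- tree$edge[e, 2]
      p <- p * if (ch <= n_tip) {
        sum(P[[e]][a, ] * part[tree$tip.label[ch], ])
      } else {
        P[[e]][a, assign[as.character(ch)]]
      }
      if (p == 0) break
    }
    for (v in internal) {
      probs[as.character(v), assign[as.character(v)]] <-
        probs[as.character(v), assign[as.character(v)]] + p
    }
  }
  probs / rowSums(probs)
}

# Random small fixture: tree of 2..6 tips, a catalog model, positive rates
# on a scale where transitions happen, and a mix of known/polymorphic tips.
random_fixture <- function(seed) {
  set.seed(seed)
  n <- sample(2:6, 1)
  tree <- ape::rtree(n)
  tree$edge.length <- tree$edge.length + 0.05
  scheme <- sample(c("three", "four"), 1)
  states <- state_space(scheme)
  nm <- sample(c("ER", "SYM", "ARD", "IC", "SHULTZ", "RJ_DERIVED"), 1)
  spec <- model_catalog(nm, states)
  rates <- stats::runif(n_free_rates(spec), 0.05, 1.2)
  K <- length(states$labels)
  vals <- vapply(seq_len(n), function(i) {
    m <- sample(seq_len(K), 1, prob = c(0.7, 0.2, 0.1, 0.1)[seq_len(K)])
    paste(sample(states$labels, m), collapse = "|")
  }, character(1))
  names(vals) <- tree$tip.label
  list(tree = tree, traits = trait_table(vals, states),
       spec = spec, rates = rates, q = build_q(spec, rates))
}

# Marginal likelihood by quadrature for toys with an exponential rate
# prior of fixed mean (1-D and 2-D).
quad_logml_1d <- function(loglik, prior_mean) {
  f <- Vectorize(function(r) exp(loglik(r)) * stats::dexp(r, 1 / prior_mean))
  log(stats::integrate(f, 0, Inf, rel.tol = 1e-10)$value)
}

quad_logml_2d <- function(loglik2, prior_mean) {
  inner <- Vectorize(function(r1) {
    f2 <- Vectorize(function(r2) {
      exp(loglik2(r1, r2)) * stats::dexp(r2, 1 / prior_mean)
    })
    stats::integrate(f2, 0, Inf, rel.tol = 1e-8)$value *
      stats::dexp(r1, 1 / prior_mean)
  })
  log(stats::integrate(inner, 0, Inf, rel.tol = 1e-8)$value)
}

# Analytic expected transition counts E[N_ij | data]: enumeration over
# internal assignments combined with per-branch conditional expectations
# computed by Simpson quadrature of P(u)[a,i] q_ij P(T-u)[j,b] / P(T)[a,b].
# Requires single-state (unambiguous) tips.
expected_counts_oracle <- function(tree, tip_states, Q, n_grid = 200) {
  K <- nrow(Q)
  n_tip <- length(tree$tip.label)
  tipidx <- apply(tip_states$partial[tree$tip.label, , drop = FALSE], 1,
                  function(r) which(r > 0)[1])
  internal <- (n_tip + 1):(n_tip + tree$Nnode)
  root <- n_tip + 1
  prior <- rep(1 / K, K)
  n_edge <- nrow(tree$edge)
  PT <- lapply(seq_len(n_edge),
               function(e) expm_ref(Q * tree$edge.length[e]))
  # per-edge conditional expected counts given endpoints: array [a,b,i,j]
  econd <- vector("list", n_edge)
  for (e in seq_len(n_edge)) {
    T <- tree$edge.length[e]
    us <- seq(0, T, length.out = n_grid + 1)
    Pu <- lapply(us, function(u) expm_ref(Q * u))
    w <- c(1, rep(c(4, 2), length.out = n_grid - 1), 1) * (T / n_grid) / 3
    arr <- array(0, dim = c(K, K, K, K))
    for (i in seq_len(K)) for (j in seq_len(K)) {
      if (i == j || Q[i, j] == 0) next
      s <- matrix(0, K, K)
      for (kk in seq_along(us)) {
        # P(T-u) is the reversed grid entry
        s <- s + w[kk] * outer(Pu[[kk]][, i],
                               Pu[[length(us) - kk + 1]][j, ])
      }
      arr[, , i, j] <- Q[i, j] * s / PT[[e]]
    }
    econd[[e]] <- arr
  }
  grid <- as.matrix(expand.grid(rep(list(seq_len(K)), length(internal))))
  total <- matrix(0, K, K)
  L <- 0
  for (g in seq_len(nrow(grid))) {
    assign <- grid[g, ]
    names(assign) <- internal
    p <- prior[assign[as.character(root)]]
    ab <- matrix(0L, n_edge, 2)
    for (e in seq_len(n_edge)) {
      a <- assign[as.character(tree$edge[e, 1])]
      ch <- tree$edge[e, 2]
      b <- if (ch <= n_tip) tipidx[tree$tip.label[ch]]
        else assign[as.character(ch)]
      ab[e, ] <- c(a, b)
      p <- p * PT[[e]][a, b]
      if (p == 0) break
    }
    if (p == 0) next
    L <- L + p
    cnt <- matrix(0, K, K)
    for (e in seq_len(n_edge)) {
      cnt <- cnt + econd[[e]][ab[e, 1], ab[e, 2], , ]
    }
    total <- total + p * cnt
  }
  total / L
}

# Naive rejection sampler for a single branch path conditional on its
# endpoints (cross-check for the uniformization sampler).
rejection_branch_counts <- function(a, b, T, Q, n_ok = 500, max_try = 1e6) {
  K <- nrow(Q)
  counts <- integer(0)
  tries <- 0
  while (length(counts) < n_ok && tries < max_try) {
    tries <- tries + 1
    s <- a
    t <- 0
    n <- 0
    repeat {
      rate <- -Q[s, s]
      if (rate <= 0) break
      dt <- stats::rexp(1, rate)
      if (t + dt >= T) break
      t <- t + dt
      w <- Q[s, ]
      w[s] <- 0
      s <- sample.int(K, 1, prob = w / sum(w))
      n <- n + 1
    }
    if (s == b) counts <- c(counts, n)
  }
  counts
}
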