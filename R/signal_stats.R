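#' Phylogenetic signal results
#'
#' Container for the three signal statistics used for the social-organization
#' trait: Blomberg's K (with a tip-shuffle randomization of the variance of
#' phylogenetically independent contrasts), Pagel's lambda estimated by
#' maximum likelihood on the discrete character, and the Fritz-Purvis D
#' statistic for binary traits (with tip-shuffle and threshold-Brownian
#' nulls).
#'
#' @name signal_result
NULL

signal_result <- function(statistic, estimate, z_random = NA_real_,
                          p_random = NA_real_, p_brownian = NA_real_,
                          logL = NA_real_, logL0 = NA_real_,
                          aicc = NA_real_, n_null = NA_integer_,
                          details = list()) {
  if (!is.na(p_random) && (p_random < 0 || p_random > 1)) {
    stop("p_random outside [0, 1]")
  }
  structure(list(statistic = statistic, estimate = estimate,
                 z_random = z_random, p_random = p_random,
                 p_brownian = p_brownian, logL = logL, logL0 = logL0,
                 aicc = aicc, n_null = n_null, details = details),
            class = "signal_result")
}

#' @export
print.signal_result <- function(x, ...) {
  cat("Phylogenetic signal: ", x$statistic, " = ",
      signif(x$estimate, 4), sep = "")
  if (!is.na(x$z_random)) cat(", z = ", signif(x$z_random, 4), sep = "")
  if (!is.na(x$p_random)) cat(", p(random) = ", signif(x$p_random, 3),
                              sep = "")
  if (!is.na(x$p_brownian)) cat(", p(Brownian) = ",
                                signif(x$p_brownian, 3), sep = "")
  if (!is.na(x$logL)) cat(", logL = ", round(x$logL, 3), sep = "")
  cat("\n")
  invisible(x)
}

#' Numeric coding of a categorical social-organization trait
#'
#' Blomberg's K needs a numeric trait. The default coding is the ordinal
#' complexity rank S=1, P=2, UM=3, MM=4 (three-state: S=1, P=2, G=3);
#' polymorphic taxa receive the probability-weighted mean of their state
#' codes. The coding used is recorded in the result.
#'
#' @param traits a \code{trait_table}.
#' @param coding optional named numeric vector mapping state labels to
#'   codes.
#' @return named numeric vector (one value per taxon) with the coding kept
#'   as an attribute.
#' @export
ordinal_coding <- function(traits, coding = NULL) {
  lab <- traits$states$labels
  if (is.null(coding)) {
    coding <- seq_along(lab)
    names(coding) <- lab
  }
  if (!all(lab %in% names(coding))) stop("coding must cover all states")
  w <- traits$partial / rowSums(traits$partial)
  x <- drop(w %*% coding[lab])
  names(x) <- rownames(traits$partial)
  attr(x, "coding") <- coding
  x
}

#' Blomberg's K with tip-shuffle randomization
#'
#' K compares the observed ratio of the mean squared error of the
#' phylogenetically corrected mean to the mean squared error based on the
#' variance-covariance structure of the tree against its Brownian
#' expectation; K = 1 under Brownian motion, K > 1 when variation clusters
#' within clades. Significance comes from shuffling tip values: the z-score
#' of the observed variance of phylogenetically independent contrasts under
#' the null (negative z means more signal than chance) and its rank p.
#'
#' @param tree a \code{phylo}.
#' @param trait numeric per-tip values (named, or ordered as
#'   \code{tree$tip.label}), or a \code{trait_table} to be coded via
#'   \code{\link{ordinal_coding}}.
#' @param n_null number of randomizations (at least 10).
#' @param seed integer seed.
#' @param coding optional coding passed to \code{\link{ordinal_coding}}.
#' @return a \code{signal_result}.
#' @export
blomberg_k <- function(tree, trait, n_null = 999, seed = 1, coding = NULL) {
  if (n_null < 10) stop("n_null must be at least 10")
  used_coding <- NULL
  if (inherits(trait, "trait_table")) {
    trait <- ordinal_coding(trait, coding)
    used_coding <- attr(trait, "coding")
  }
  if (!is.null(names(trait))) {
    miss <- setdiff(tree$tip.label, names(trait))
    if (length(miss)) stop("trait missing for: ",
                           paste(utils::head(miss, 5), collapse = ", "))
    trait <- trait[tree$tip.label]
  } else if (length(trait) != length(tree$tip.label)) {
    stop("trait length does not match the number of tips")
  }
  if (stats::var(trait) == 0) stop("zero variance: trait is constant")
  tr <- if (ape::is.binary(tree)) tree else ape::multi2di(tree)
  set.seed(seed)
  ps <- picante::phylosignal(trait, tr, reps = n_null)
  signal_result("K", estimate = ps$K, z_random = ps$PIC.variance.Z,
                p_random = ps$PIC.variance.P, n_null = as.integer(n_null),
                details = list(coding = used_coding, seed = seed))
}

#' Maximum-likelihood Pagel's lambda for a discrete trait
#'
#' Jointly maximizes the Mk likelihood over lambda in [0, 1] (via the
#' depth-preserving branch-length transform) and the base model's rates.
#' Reports the ML lambda, its log-likelihood, the log-likelihood at lambda =
#' 0 with rates re-optimized (star phylogeny), a 1-df likelihood-ratio p
#' value, and AICc with k = (free rates + 1) parameters and n = number of
#' tips.
#'
#' @param tree a \code{phylo}.
#' @param traits a \code{trait_table}.
#' @param base a \code{model_spec} used as the rate backbone (ER or SYM
#'   recommended).
#' @param root_prior root prior passed to the likelihood.
#' @param n_restarts optimizer restarts per inner fit.
#' @param seed integer seed for the restarts.
#' @return a \code{signal_result} with \code{estimate} = lambda-hat.
#' @export
pagel_lambda_ml <- function(tree, traits, base, root_prior = "uniform",
                            n_restarts = 2, seed = 1) {
  depth <- ape::node.depth.edgelength(tree)
  tipd <- depth[seq_along(tree$tip.label)]
  if (diff(range(tipd)) > 1e-6 * max(tipd)) {
    warning("tree is not ultrametric; lambda transform preserves depths")
  }
  fit_at <- function(lam) {
    fit_ml(lambda_transform(tree, lam), traits, base,
           root_prior = root_prior, n_restarts = n_restarts, seed = seed)
  }
  prof <- function(lam) fit_at(lam)$logL
  opt <- stats::optimize(prof, c(0, 1), maximum = TRUE, tol = 1e-3)
  cand <- c(opt$maximum, 0, 1)
  vals <- c(opt$objective, prof(0), prof(1))
  lam_hat <- cand[which.max(vals)]
  fit1 <- fit_at(lam_hat)
  logL <- fit1$logL
  logL0 <- vals[2]
  lrt <- max(0, 2 * (logL - logL0))
  p <- stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  k <- n_free_rates(base) + 1
  n <- length(tree$tip.label)
  aicc <- -2 * logL + 2 * k + 2 * k * (k + 1) / (n - k - 1)
  signal_result("lambda", estimate = lam_hat, p_random = p, logL = logL,
                logL0 = logL0, aicc = aicc,
                details = list(lrt = lrt, base = base$name,
                               rates = fit1$rates, k = k, n = n))
}

# children list indexed by node id
node_children <- function(tree) {
  n_all <- length(tree$tip.label) + tree$Nnode
  ch <- vector("list", n_all)
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]
    ch[[p]] <- c(ch[[p]], tree$edge[e, 2])
  }
  ch
}

# Sum of changes in estimated nodal values (Fritz-Purvis convention):
# nodal value = unweighted mean of daughter values; the change at a node is
# the sum of absolute daughter deviations (= |v1 - v2| for a bifurcation).
# Vectorized over replicate columns of x (tips x reps).
sum_d <- function(tree, x, children = node_children(tree),
                  postorder_nodes = NULL) {
  n_tip <- length(tree$tip.label)
  x <- as.matrix(x)
  vals <- matrix(0, n_tip + tree$Nnode, ncol(x))
  vals[seq_len(n_tip), ] <- x
  if (is.null(postorder_nodes)) {
    po <- stats::reorder(tree, "postorder")
    postorder_nodes <- unique(po$edge[, 1])
  }
  total <- numeric(ncol(x))
  for (v in postorder_nodes) {
    kids <- children[[v]]
    kv <- vals[kids, , drop = FALSE]
    m <- colMeans(kv)
    vals[v, ] <- m
    total <- total + colSums(abs(sweep(kv, 2, m)))
  }
  total
}

# Brownian tip values: preorder accumulation of normal increments with
# variance equal to branch length; columns are replicates.
simulate_bm_tips <- function(tree, n_rep) {
  n_tip <- length(tree$tip.label)
  n_all <- n_tip + tree$Nnode
  pre <- stats::reorder(tree, "cladewise")
  vals <- matrix(0, n_all, n_rep)
  for (e in seq_len(nrow(pre$edge))) {
    p <- pre$edge[e, 1]
    v <- pre$edge[e, 2]
    vals[v, ] <- vals[p, ] +
      stats::rnorm(n_rep, 0, sqrt(pre$edge.length[e]))
  }
  vals[seq_len(n_tip), , drop = FALSE]
}

#' Fritz-Purvis D statistic for a binary trait
#'
#' D scales the observed sum of sister-clade differences in estimated nodal
#' values between the expectation under threshold-Brownian evolution (D = 0,
#' strong signal) and under random shuffling of tip states (D = 1, no
#' signal); negative D indicates more conservation than Brownian. The
#' Brownian null simulates Brownian values on the tree and thresholds them
#' at the observed prevalence; both null distributions are recomputed with
#' the same nodal estimator as the observed statistic.
#'
#' @param tree a \code{phylo}.
#' @param trait per-tip 0/1 values (named or in tip order).
#' @param n_null permutations/simulations per null (at least 100; 1000 is
#'   typical).
#' @param seed integer seed.
#' @return a \code{signal_result}; \code{p_random} and \code{p_brownian}
#'   are lower-tail rank probabilities of the observed sum in each null.
#' @export
d_statistic <- function(tree, trait, n_null = 1000, seed = 1) {
  if (n_null < 100) stop("n_null must be at least 100")
  if (!is.null(names(trait))) trait <- trait[tree$tip.label]
  trait <- as.numeric(trait)
  if (!all(trait %in% c(0, 1))) stop("trait must be binary 0/1")
  n1 <- sum(trait)
  if (n1 == 0 || n1 == length(trait)) {
    stop("trait must include both 0s and 1s")
  }
  children <- node_children(tree)
  po <- stats::reorder(tree, "postorder")
  ponodes <- unique(po$edge[, 1])
  set.seed(seed)
  d_obs <- sum_d(tree, trait, children, ponodes)
  perm <- replicate(n_null, sample(trait))
  d_rand <- sum_d(tree, perm, children, ponodes)
  bm <- simulate_bm_tips(tree, n_null)
  # threshold at matched prevalence: top n1 values become state 1
  bin <- apply(bm, 2, function(col) {
    as.numeric(rank(col, ties.method = "first") >
                 (length(col) - n1))
  })
  d_brown <- sum_d(tree, bin, children, ponodes)
  D <- (d_obs - mean(d_brown)) / (mean(d_rand) - mean(d_brown))
  p_rand <- (1 + sum(d_rand <= d_obs)) / (1 + n_null)
  p_brown <- (1 + sum(d_brown <= d_obs)) / (1 + n_null)
  signal_result("D", estimate = D,
                p_random = p_rand, p_brownian = p_brown,
                n_null = as.integer(n_null),
                details = list(sum_d_obs = d_obs,
                               mean_sum_d_random = mean(d_rand),
                               mean_sum_d_brownian = mean(d_brown),
                               prevalence = n1 / length(trait),
                               seed = seed))
}

#' Export signal results as a TSV table
#'
#' @param results named list of \code{signal_result} objects.
#' @param file output path.
#' @param scheme optional scheme label recorded per row.
#' @export
write_signal_table <- function(results, file, scheme = NA_character_) {
  rows <- lapply(names(results), function(nm) {
    r <- results[[nm]]
    coding <- r$details$coding
    data.frame(statistic = r$statistic, trait = nm, scheme = scheme,
               estimate = r$estimate, z = r$z_random,
               p_random = r$p_random, p_brownian = r$p_brownian,
               logL = r$logL, logL0 = r$logL0, aicc = r$aicc,
               n_null = r$n_null,
               seed = if (is.null(r$details$seed)) NA else r$details$seed,
               coding = if (is.null(coding)) NA_character_
                        else paste(names(coding), coding, sep = "=",
                                   collapse = ";"))
  })
  df <- do.call(rbind, rows)
  utils::write.table(df, file, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(df)
}
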