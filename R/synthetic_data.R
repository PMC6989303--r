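# Ground-truth generator: birth-death trees, exact Gillespie simulation of
# the trait along every branch (the realized history is the reference for
# stochastic-mapping tests), and injection of tip-state polymorphism.

#' Simulate a dated birth-death tree
#'
#' Constant-rate birth-death tree conditioned on the number of extant
#' tips, rescaled to a fixed root depth (default 70 time units, a
#' primate-like crown age in millions of years).
#'
#' @param n_tips number of tips (>= 2).
#' @param birth speciation rate (> death).
#' @param death extinction rate (>= 0).
#' @param seed integer seed.
#' @param depth root depth to scale to; NULL keeps the simulated depth.
#' @param max_tries retry budget for total-extinction outcomes.
#' @return an ultrametric \code{phylo}.
#' @export
simulate_tree <- function(n_tips, birth = 1, death = 0, seed = 1,
                          depth = 70, max_tries = 50) {
  if (n_tips < 2) stop("n_tips must be at least 2")
  if (!(birth > death) || death < 0) stop("need birth > death >= 0")
  set.seed(seed)
  tree <- NULL
  for (i in seq_len(max_tries)) {
    tree <- tryCatch(
      phytools::pbtree(b = birth, d = death, n = n_tips, type = "continuous",
                       extant.only = TRUE, quiet = TRUE),
      error = function(e) NULL)
    if (!is.null(tree) && length(tree$tip.label) == n_tips) break
    tree <- NULL
  }
  if (is.null(tree)) {
    stop("birth-death simulation failed (total extinction) after ",
         max_tries, " tries")
  }
  if (!is.null(depth)) {
    d0 <- max(ape::node.depth.edgelength(tree))
    tree$edge.length <- tree$edge.length * depth / d0
  }
  tree$tip.label <- sprintf("t%d", seq_len(n_tips))
  tree
}

# exact Gillespie path down one branch from a known starting state
gillespie_branch <- function(a, T, Q) {
  states <- a
  times <- numeric(0)
  t <- 0
  s <- a
  repeat {
    out_rate <- -Q[s, s]
    if (out_rate <= 0) break
    dt <- stats::rexp(1, out_rate)
    if (t + dt >= T) break
    t <- t + dt
    w <- Q[s, ]
    w[s] <- 0
    s <- rcat(w)
    states <- c(states, s)
    times <- c(times, t)
  }
  list(states = states, durations = diff(c(0, times, T)))
}

#' Simulate a discrete trait with its full history
#'
#' Draws a root state and evolves the character by exact Gillespie
#' simulation down every branch, recording the complete realized history
#' (the ground truth for transition-count and mapping tests); tip states
#' are the terminal segment states.
#'
#' @param tree a \code{phylo}.
#' @param q a \code{q_matrix}.
#' @param root_state a state label, a probability vector, or
#'   \code{"stationary"} (default: uniform draw).
#' @param seed integer seed.
#' @return a \code{synthetic_dataset}: tree, q, the true history (a
#'   \code{simmap_history}), a set-coded \code{trait_table} of tip states,
#'   and the root state.
#' @export
simulate_trait <- function(tree, q, root_state = NULL, seed = 1) {
  Q <- as_q(q)
  K <- nrow(Q)
  states <- if (inherits(q, "q_matrix")) q$states
    else state_space(as.character(seq_len(K)))
  labels <- states$labels
  set.seed(seed)
  root <- if (is.null(root_state)) {
    sample.int(K, 1)
  } else if (identical(root_state, "stationary")) {
    rcat(stationary_dist(Q))
  } else if (is.numeric(root_state)) {
    rcat(root_state)
  } else {
    state_index(states, root_state)
  }
  pre <- stats::reorder(tree, "cladewise")
  n_tip <- length(pre$tip.label)
  node_state <- integer(n_tip + pre$Nnode)
  node_state[n_tip + 1L] <- root
  n_edge <- nrow(pre$edge)
  paths <- vector("list", n_edge)
  counts <- matrix(0, K, K, dimnames = list(labels, labels))
  dwell <- stats::setNames(numeric(K), labels)
  for (e in seq_len(n_edge)) {
    a <- node_state[pre$edge[e, 1]]
    pth <- gillespie_branch(a, pre$edge.length[e], Q)
    paths[[e]] <- pth
    node_state[pre$edge[e, 2]] <- pth$states[length(pth$states)]
    ns <- length(pth$states)
    if (ns > 1) {
      for (i in seq_len(ns - 1)) {
        counts[pth$states[i], pth$states[i + 1]] <-
          counts[pth$states[i], pth$states[i + 1]] + 1
      }
    }
    for (i in seq_len(ns)) {
      dwell[pth$states[i]] <- dwell[pth$states[i]] + pth$durations[i]
    }
  }
  history <- structure(list(tree = pre, edge_paths = paths,
                            counts = counts, dwell = dwell,
                            node_state = node_state, states = labels),
                       class = "simmap_history")
  tips <- stats::setNames(labels[node_state[seq_len(n_tip)]],
                          pre$tip.label)
  structure(list(tree = tree, q = q,
                 true_history = history,
                 tip_states = trait_table(tips, states),
                 root_state = labels[root], seed = seed),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("Synthetic dataset: ", length(x$tree$tip.label), " tips, ",
      sum(x$true_history$counts), " true transition(s), root state ",
      x$root_state, "\n", sep = "")
  invisible(x)
}

#' Inject tip-state polymorphism into a synthetic dataset
#'
#' A random fraction of taxa receive a second admissible state adjacent to
#' their true state under the generating model (a state reachable in one
#' permitted transition), emulating intraspecific variability in social
#' organization records.
#'
#' @param d a \code{synthetic_dataset}.
#' @param poly_fraction fraction of taxa to make polymorphic, in [0, 1].
#' @param seed integer seed.
#' @return a set-coded \code{trait_table}.
#' @export
inject_uncertainty <- function(d, poly_fraction, seed = 1) {
  if (poly_fraction < 0 || poly_fraction > 1) {
    stop("poly_fraction must lie in [0, 1]")
  }
  tt <- d$tip_states
  if (poly_fraction == 0) return(tt)
  Q <- as_q(d$q)
  part <- tt$partial
  taxa <- rownames(part)
  set.seed(seed)
  n_poly <- round(poly_fraction * length(taxa))
  chosen <- sample(taxa, n_poly)
  for (tx in chosen) {
    i <- which(part[tx, ] > 0)[1]
    cand <- which(Q[i, ] > 0)
    if (!length(cand)) cand <- which(Q[, i] > 0)  # absorbing state: use inbound
    if (length(cand)) {
      j <- if (length(cand) == 1) cand else sample(cand, 1)
      part[tx, j] <- 1
    }
  }
  structure(list(states = tt$states, partial = part, type = "set"),
            class = "trait_table")
}

#' Write a synthetic dataset as a (Newick, trait CSV, truth JSON) triple
#'
#' @param d a \code{synthetic_dataset}.
#' @param stem output path stem; writes \code{<stem>.nwk},
#'   \code{<stem>_traits.csv} and \code{<stem>_truth.json}.
#' @export
write_synthetic_dataset <- function(d, stem) {
  write_newick(d$tree, paste0(stem, ".nwk"))
  write_trait_table(d$tip_states, paste0(stem, "_traits.csv"))
  truth <- list(root_state = d$root_state,
                seed = d$seed,
                q = as_q(d$q),
                true_counts = d$true_history$counts,
                true_dwell = d$true_history$dwell)
  jsonlite::write_json(truth, paste0(stem, "_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(stem)
}
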