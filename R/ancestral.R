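# Two-pass marginal ancestral state reconstruction and stochastic
# character mapping (backward pruning, forward sampling, branch paths by
# uniformization).

# down-pass conditional partials for every node (rows rescaled); R-side
# companion of the C++ pruning used where all node partials are needed
down_partials <- function(tree, traits, Q) {
  part <- tip_partials(tree, traits)
  tr <- stats::reorder(tree, "postorder")
  res <- cpp_mk_partials(tr$edge, tr$edge.length, length(tr$tip.label),
                         part, Q, TRUE)
  list(partials = res$partials, impossible = isTRUE(res$impossible),
       root = res$root, logscale = res$logscale)
}

#' Marginal ancestral state probabilities
#'
#' Two-pass (rootward then tipward) conditional-probability algorithm: the
#' marginal posterior of each internal node's state given all tip data,
#' equivalent to re-rooting the tree at every node. Rows sum to 1.
#'
#' @param tree a \code{phylo}.
#' @param traits a \code{trait_table}.
#' @param q a \code{q_matrix} (fitted or supplied).
#' @param root_prior root prior (see \code{\link{prune_log_likelihood}}).
#' @return an \code{ancestral_states} object: matrix of node probabilities
#'   (rownames = internal node ids) with the tree attached.
#' @export
marginal_asr <- function(tree, traits, q, root_prior = "uniform") {
  Q <- as_q(q)
  K <- nrow(Q)
  n_tip <- length(tree$tip.label)
  dp <- down_partials(tree, traits, Q)
  if (dp$impossible) stop("data impossible under structural zeros")
  D <- dp$partials
  prior <- resolve_root_prior(root_prior, Q, dp$root)
  pre <- stats::reorder(tree, "cladewise")
  children <- node_children(tree)
  # per-edge kernels and per-child "lifted" contributions P(t_c) %*% D_c
  n_all <- n_tip + tree$Nnode
  Pk <- vector("list", n_all)   # kernel of the edge above each node
  lift <- vector("list", n_all)
  for (e in seq_len(nrow(pre$edge))) {
    v <- pre$edge[e, 2]
    Pk[[v]] <- cpp_expm(Q, pre$edge.length[e])
    lift[[v]] <- drop(Pk[[v]] %*% D[v, ])
  }
  up <- matrix(NA_real_, n_all, K)
  root <- n_tip + 1L
  up[root, ] <- prior
  for (e in seq_len(nrow(pre$edge))) {  # cladewise = parents first
    p <- pre$edge[e, 1]
    v <- pre$edge[e, 2]
    g <- up[p, ]
    for (s in setdiff(children[[p]], v)) g <- g * lift[[s]]
    uv <- drop(g %*% Pk[[v]])
    tot <- sum(uv)
    up[v, ] <- if (tot > 0) uv / tot else uv
  }
  nodes <- root:(n_tip + tree$Nnode)
  probs <- matrix(NA_real_, length(nodes), K,
                  dimnames = list(nodes, colnames(Q)))
  for (i in seq_along(nodes)) {
    v <- nodes[i]
    m <- up[v, ] * D[v, ]
    tot <- sum(m)
    if (tot < 1e-300) {
      warning("node ", v, " has near-zero total probability; renormalized")
      m <- m + 1e-300
      tot <- sum(m)
    }
    probs[i, ] <- m / tot
  }
  if (is.null(colnames(probs))) {
    colnames(probs) <- traits$states$labels
  }
  structure(list(probs = probs, tree = tree, states = traits$states),
            class = "ancestral_states")
}

#' @export
print.ancestral_states <- function(x, ...) {
  cat("Marginal ancestral states for ", nrow(x$probs),
      " internal nodes\n", sep = "")
  root <- as.character(length(x$tree$tip.label) + 1)
  cat("root:", paste(colnames(x$probs),
                     round(x$probs[root, ], 4), sep = "=",
                     collapse = " "), "\n")
  invisible(x)
}

#' Ancestral probabilities at the MRCA of a set of tips
#'
#' Internal node numbering is tree-dependent, so reporting nodes (the
#' primate root, clade roots) are addressed as most recent common ancestors
#' of named tips.
#'
#' @param asr an \code{ancestral_states} object.
#' @param tips character vector of at least two tip labels.
#' @export
mrca_probs <- function(asr, tips) {
  node <- ape::getMRCA(asr$tree, tips)
  asr$probs[as.character(node), ]
}

# sample one index from (possibly unnormalized) weights
rcat <- function(w) {
  s <- sum(w)
  if (s <= 0) return(NA_integer_)
  sample.int(length(w), 1, prob = w / s)
}

# conditional path on one branch by uniformization: number of virtual
# jumps given endpoints, bridge-sampled jump chain, uniform order-statistic
# times; virtual (self) jumps are dropped.
sample_branch_path <- function(a, b, T, Q, Rpow, Lam, Pab) {
  K <- nrow(Q)
  if (Lam == 0 || T == 0) {
    return(list(states = a, durations = T))
  }
  lt <- Lam * T
  nmax <- max(4, stats::qpois(1 - 1e-12, lt) + 4)
  while (length(Rpow) < nmax + 1) {
    Rpow[[length(Rpow) + 1]] <- Rpow[[length(Rpow)]] %*% Rpow[[2]]
  }
  w <- vapply(0:nmax, function(n) {
    stats::dpois(n, lt) * Rpow[[n + 1]][a, b]
  }, numeric(1))
  n <- rcat(w) - 1L
  states <- a
  if (n > 0) {
    R <- Rpow[[2]]
    for (step in seq_len(n)) {
      prev <- states[length(states)]
      wts <- R[prev, ] * Rpow[[n - step + 1]][, b]
      states <- c(states, rcat(wts))
    }
    times <- sort(stats::runif(n)) * T
  } else {
    times <- numeric(0)
  }
  # collapse virtual jumps
  bounds <- c(0, times, T)
  keep_states <- states[1]
  keep_bounds <- 0
  for (i in seq_along(states)[-1]) {
    if (states[i] != keep_states[length(keep_states)]) {
      keep_states <- c(keep_states, states[i])
      keep_bounds <- c(keep_bounds, bounds[i])
    }
  }
  durations <- diff(c(keep_bounds, T))
  list(states = keep_states, durations = durations, Rpow = Rpow)
}

#' Stochastic character mapping
#'
#' Samples complete character histories conditional on the tip data and Q:
#' node states are drawn from their joint conditional distribution
#' (backward pruning, forward sampling), tip states are drawn from their
#' probability weights per map, and each branch path is sampled conditional
#' on its endpoints by uniformization. Supplying a \code{multiPhylo}
#' distributes the maps evenly across the trees.
#'
#' @param tree a \code{phylo} or \code{multiPhylo}.
#' @param traits a \code{trait_table}; set-coded tables are converted to
#'   equal probability weights.
#' @param q a \code{q_matrix}.
#' @param root_prior root prior.
#' @param n_maps number of histories to sample.
#' @param seed integer seed.
#' @return a list of \code{simmap_history} objects, each with per-branch
#'   (state, duration) segments, a K x K realized transition-count matrix
#'   and per-state dwell times.
#' @export
stochastic_map <- function(tree, traits, q, root_prior = "uniform",
                           n_maps = 100, seed = 1) {
  if (inherits(tree, "multiPhylo")) {
    n_each <- diff(round(seq(0, n_maps, length.out = length(tree) + 1)))
    out <- list()
    for (i in seq_along(tree)) {
      if (n_each[i] > 0) {
        out <- c(out, stochastic_map(tree[[i]], traits, q, root_prior,
                                     n_each[i], seed + i))
      }
    }
    return(out)
  }
  stopifnot(n_maps >= 1)
  Q <- as_q(q)
  K <- nrow(Q)
  traits <- as_prob_table(traits)
  n_tip <- length(tree$tip.label)
  dp <- down_partials(tree, traits, Q)
  if (dp$impossible) stop("data impossible under structural zeros")
  D <- dp$partials
  prior <- resolve_root_prior(root_prior, Q, dp$root)
  pre <- stats::reorder(tree, "cladewise")
  n_edge <- nrow(pre$edge)
  Pk <- vector("list", n_edge)
  for (e in seq_len(n_edge)) {
    Pk[[e]] <- cpp_expm(Q, pre$edge.length[e])
  }
  Lam <- max(-diag(Q))
  Rpow <- list(diag(K))
  if (Lam > 0) Rpow[[2]] <- diag(K) + Q / Lam
  root <- n_tip + 1L
  set.seed(seed)
  labels <- colnames(Q)
  if (is.null(labels)) labels <- traits$states$labels
  out <- vector("list", n_maps)
  for (mp in seq_len(n_maps)) {
    node_state <- integer(n_tip + tree$Nnode)
    for (try in 1:50) {
      node_state[root] <- rcat(prior * D[root, ])
      ok <- TRUE
      for (e in seq_len(n_edge)) {
        p <- pre$edge[e, 1]
        v <- pre$edge[e, 2]
        w <- Pk[[e]][node_state[p], ] * D[v, ]
        s <- rcat(w)
        if (is.na(s)) { ok <- FALSE; break }
        node_state[v] <- s
      }
      if (ok) break
      if (try == 50) stop("could not sample node states consistent with ",
                          "the structural zeros")
    }
    paths <- vector("list", n_edge)
    counts <- matrix(0, K, K, dimnames = list(labels, labels))
    dwell <- stats::setNames(numeric(K), labels)
    for (e in seq_len(n_edge)) {
      a <- node_state[pre$edge[e, 1]]
      b <- node_state[pre$edge[e, 2]]
      pth <- sample_branch_path(a, b, pre$edge.length[e], Q, Rpow, Lam,
                                Pk[[e]][a, b])
      if (!is.null(pth$Rpow)) Rpow <- pth$Rpow
      paths[[e]] <- list(states = pth$states, durations = pth$durations)
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
    out[[mp]] <- structure(list(tree = pre, edge_paths = paths,
                                counts = counts, dwell = dwell,
                                node_state = node_state,
                                states = labels),
                           class = "simmap_history")
  }
  out
}

#' @export
print.simmap_history <- function(x, ...) {
  cat("Stochastic map: ", sum(x$counts), " transition(s), total time ",
      round(sum(x$dwell), 3), "\n", sep = "")
  invisible(x)
}

#' Summarize transition counts and dwell times over stochastic maps
#'
#' @param histories list of \code{simmap_history} objects on a common
#'   state space.
#' @return list with \code{mean_counts}, \code{sd_counts},
#'   \code{dwell_proportions} (mean per-history dwell fractions) and
#'   \code{n_maps}.
#' @export
summarize_transitions <- function(histories) {
  stopifnot(length(histories) >= 1)
  labs <- histories[[1]]$states
  for (h in histories) {
    if (!identical(h$states, labs)) {
      stop("histories are on different state spaces")
    }
  }
  arr <- vapply(histories, function(h) h$counts,
                matrix(0, length(labs), length(labs)))
  mean_counts <- apply(arr, c(1, 2), mean)
  sd_counts <- if (length(histories) > 1) apply(arr, c(1, 2), stats::sd)
    else mean_counts * 0
  dimnames(mean_counts) <- dimnames(sd_counts) <- list(labs, labs)
  dw <- vapply(histories, function(h) h$dwell / sum(h$dwell),
               numeric(length(labs)))
  dwell <- if (is.matrix(dw)) rowMeans(dw) else dw
  names(dwell) <- labs
  list(mean_counts = mean_counts, sd_counts = sd_counts,
       dwell_proportions = dwell, n_maps = length(histories))
}

#' Write transition summaries as TSV
#'
#' @param summary output of \code{\link{summarize_transitions}}.
#' @param file output path.
#' @export
write_transition_table <- function(summary, file) {
  labs <- rownames(summary$mean_counts)
  rows <- expand.grid(from_state = labs, to_state = labs,
                      stringsAsFactors = FALSE)
  rows <- rows[rows$from_state != rows$to_state, ]
  rows$mean <- summary$mean_counts[cbind(rows$from_state, rows$to_state)]
  rows$sd <- summary$sd_counts[cbind(rows$from_state, rows$to_state)]
  utils::write.table(rows, file, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(rows)
}

#' Write a stochastic map in SIMMAP-annotated Newick
#'
#' Branches carry \code{{state,duration:...}} annotations with segments
#' listed tipward-first (the phytools dialect).
#'
#' @param history a \code{simmap_history}.
#' @param file optional output path; the string is returned invisibly.
#' @export
write_simmap <- function(history, file = NULL) {
  tree <- history$tree
  n_tip <- length(tree$tip.label)
  children <- node_children(tree)
  edge_of <- integer(n_tip + tree$Nnode)
  edge_of[tree$edge[, 2]] <- seq_len(nrow(tree$edge))
  ann <- function(v) {
    p <- history$edge_paths[[edge_of[v]]]
    ord <- rev(seq_along(p$states))  # segments written tipward-first
    paste0("{", paste(history$states[p$states[ord]],
                      format(p$durations[ord], trim = TRUE), sep = ",",
                      collapse = ":"), "}")
  }
  build <- function(v) {
    if (v <= n_tip) {
      paste0(tree$tip.label[v], ":", ann(v))
    } else {
      inner <- paste(vapply(children[[v]], build, character(1)),
                     collapse = ",")
      if (v == n_tip + 1L) {
        paste0("(", inner, ");")
      } else {
        paste0("(", inner, "):", ann(v))
      }
    }
  }
  txt <- build(n_tip + 1L)
  if (!is.null(file)) writeLines(txt, file)
  invisible(txt)
}
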