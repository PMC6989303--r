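#' Constrained Mk model specifications
#'
#' A \code{model_spec} constrains the off-diagonal cells of a K x K
#' instantaneous rate matrix by assigning each ordered pair (i, j) either to
#' a rate class (cells in one class share a rate) or to the structural-zero
#' class (the transition is forbidden). The number of free parameters equals
#' the number of distinct non-zero classes.
#'
#' @param index integer K x K matrix: \code{NA} on the diagonal, 0 for
#'   forbidden cells, positive integers for rate classes.
#' @param states a \code{state_space}.
#' @param name optional catalog name.
#' @export
model_spec <- function(index, states, name = NULL) {
  stopifnot(is_state_space(states))
  K <- n_states(states)
  if (!is.matrix(index) || nrow(index) != K || ncol(index) != K) {
    stop("index must be a ", K, "x", K, " matrix")
  }
  if (!all(is.na(diag(index)))) diag(index) <- NA
  off <- index[!is.na(index)]
  if (any(off < 0) || any(off != floor(off))) {
    stop("index cells must be NA, 0, or positive class integers")
  }
  # canonicalize class ids to 1..k in order of first appearance (row-major)
  ord <- t(index)  # row-major traversal of (i, j) cells
  seen <- unique(ord[!is.na(ord) & ord > 0])
  relab <- index
  for (k in seq_along(seen)) relab[index == seen[k]] <- k
  dimnames(relab) <- list(states$labels, states$labels)
  structure(list(states = states, index = relab,
                 name = if (is.null(name)) "custom" else name),
            class = "model_spec")
}

#' Number of free rate parameters of a model specification
#' @param spec a \code{model_spec}.
#' @export
n_free_rates <- function(spec) {
  off <- spec$index[!is.na(spec$index)]
  length(unique(off[off > 0]))
}

#' @export
print.model_spec <- function(x, ...) {
  cat("Mk model '", x$name, "' on ", n_states(x$states), " states (",
      n_free_rates(x), " free rates)\n", sep = "")
  print(format_model_spec(x))
  invisible(x)
}

# helper: build an index matrix from a list of class -> list of c(from, to)
spec_from_cells <- function(cells, states, name) {
  K <- n_states(states)
  idx <- matrix(0L, K, K)
  diag(idx) <- NA
  for (k in seq_along(cells)) {
    for (cell in cells[[k]]) {
      i <- state_index(states, cell[1])
      j <- state_index(states, cell[2])
      idx[i, j] <- k
    }
  }
  model_spec(idx, states, name)
}

#' Catalog of candidate models of social evolution
#'
#' Returns one of the standard transition structures compared in the
#' analysis of primate social organization:
#' \describe{
#'   \item{ER}{equal rates: one shared rate on every cell.}
#'   \item{SYM}{symmetric: forward and reverse rates tied, each pair its own
#'     class.}
#'   \item{ARD}{all rates different.}
#'   \item{IC}{increasing complexity: transitions only along the ladder
#'     S-P-UM-MM (three-state: S-P-G), each direction free.}
#'   \item{SHULTZ}{solitary-to-group first: S to MM, MM to P, MM to UM and
#'     UM back to MM; transitions from solitary to social are never
#'     reversed. The three-state "modified" version allows S to G and G to
#'     P only.}
#'   \item{SHULTZ_5}{sensitivity variant of the four-state SHULTZ structure
#'     with the additional P to MM arrow.}
#'   \item{RJ_DERIVED}{the reversible-jump-supported structure: S-P, P-MM
#'     and MM-UM, all reversible; pair living is the stepping stone between
#'     solitary and multimale groups. In the three-state scheme this
#'     coincides with IC.}
#' }
#'
#' @param name catalog name (see above).
#' @param states a \code{state_space} (three- or four-state scheme).
#' @return a \code{model_spec}.
#' @export
model_catalog <- function(name, states) {
  stopifnot(is_state_space(states))
  valid <- c("ER", "SYM", "ARD", "IC", "SHULTZ", "SHULTZ_5", "RJ_DERIVED")
  name <- toupper(name)
  if (!name %in% valid) {
    stop("unknown model '", name, "'; catalog: ",
         paste(valid, collapse = ", "))
  }
  K <- n_states(states)
  lab <- states$labels
  if (name %in% c("ER", "SYM", "ARD")) {
    idx <- matrix(0L, K, K)
    diag(idx) <- NA
    cells <- which(!is.na(idx), arr.ind = TRUE)
    if (name == "ER") {
      idx[cells] <- 1L
    } else if (name == "ARD") {
      idx[cells] <- seq_len(nrow(cells))
    } else {
      k <- 0L
      for (i in seq_len(K - 1)) for (j in (i + 1):K) {
        k <- k + 1L
        idx[i, j] <- k
        idx[j, i] <- k
      }
    }
    return(model_spec(idx, states, name))
  }
  if (states$scheme == "four") {
    cells <- switch(name,
      IC = list(list(c("S", "P")), list(c("P", "S")),
                list(c("P", "UM")), list(c("UM", "P")),
                list(c("UM", "MM")), list(c("MM", "UM"))),
      RJ_DERIVED = list(list(c("S", "P")), list(c("P", "S")),
                        list(c("P", "MM")), list(c("MM", "P")),
                        list(c("MM", "UM")), list(c("UM", "MM"))),
      SHULTZ = list(list(c("S", "MM")), list(c("MM", "P")),
                    list(c("MM", "UM")), list(c("UM", "MM"))),
      SHULTZ_5 = list(list(c("S", "MM")), list(c("MM", "P")),
                      list(c("P", "MM")), list(c("MM", "UM")),
                      list(c("UM", "MM"))),
      stop("model '", name, "' is not defined for the four-state scheme"))
  } else if (states$scheme == "three") {
    cells <- switch(name,
      IC = ,
      RJ_DERIVED = list(list(c("S", "P")), list(c("P", "S")),
                        list(c("P", "G")), list(c("G", "P"))),
      SHULTZ = list(list(c("S", "G")), list(c("G", "P"))),
      stop("model '", name, "' is not defined for the three-state scheme"))
  } else {
    stop("model '", name, "' needs the three- or four-state scheme")
  }
  spec_from_cells(cells, states, name)
}

#' Serialize a model specification to the plain-text matrix grammar
#'
#' One row per state: class labels for permitted cells, \code{"0"} for
#' structural zeros and \code{"."} on the diagonal. Classes are lettered
#' A, B, ... in canonical (row-major first appearance) order.
#'
#' @param spec a \code{model_spec}.
#' @return character vector of rows.
#' @export
format_model_spec <- function(spec) {
  idx <- spec$index
  K <- nrow(idx)
  chr <- matrix(".", K, K)
  chr[which(idx == 0, arr.ind = TRUE)] <- "0"
  pos <- which(!is.na(idx) & idx > 0, arr.ind = TRUE)
  chr[pos] <- LETTERS[idx[pos]]
  apply(chr, 1, paste, collapse = " ")
}

#' Parse the plain-text matrix grammar back to a model specification
#'
#' @param text character vector of rows (or one string with newlines) as
#'   produced by \code{\link{format_model_spec}}.
#' @param states the \code{state_space} the rows are indexed on.
#' @param name optional model name.
#' @export
read_model_spec <- function(text, states, name = NULL) {
  if (length(text) == 1L && grepl("\n", text)) {
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  }
  text <- text[nzchar(trimws(text))]
  K <- n_states(states)
  if (length(text) != K) stop("expected ", K, " rows, got ", length(text))
  idx <- matrix(NA_integer_, K, K)
  for (i in seq_len(K)) {
    toks <- strsplit(trimws(text[i]), "\\s+")[[1]]
    if (length(toks) != K) stop("row ", i, " has ", length(toks), " cells")
    for (j in seq_len(K)) {
      tk <- toks[j]
      if (tk == ".") {
        if (i != j) stop("'.' off the diagonal at (", i, ",", j, ")")
      } else if (tk == "0") {
        idx[i, j] <- 0L
      } else {
        cls <- match(tk, LETTERS)
        if (is.na(cls)) stop("bad class token '", tk, "' at (", i, ",", j, ")")
        idx[i, j] <- cls
      }
    }
  }
  model_spec(idx, states, name)
}

#' Build an instantaneous rate matrix from a specification and rates
#'
#' Cell (i, j) receives the rate of its class (0 for forbidden cells); the
#' diagonal is set to minus the row sum so each row sums to zero.
#'
#' @param spec a \code{model_spec}.
#' @param rates numeric vector, one non-negative rate per class, in events
#'   per unit branch length (here: per million years).
#' @return an object of class \code{q_matrix}.
#' @export
build_q <- function(spec, rates) {
  stopifnot(inherits(spec, "model_spec"))
  k <- n_free_rates(spec)
  if (length(rates) != k) {
    stop("expected ", k, " rates, got ", length(rates))
  }
  if (any(rates < 0) || anyNA(rates)) stop("rates must be non-negative")
  K <- n_states(spec$states)
  q <- matrix(0, K, K, dimnames = dimnames(spec$index))
  pos <- which(!is.na(spec$index) & spec$index > 0, arr.ind = TRUE)
  q[pos] <- rates[spec$index[pos]]
  diag(q) <- -rowSums(q)
  structure(list(q = q, states = spec$states), class = "q_matrix")
}

#' @export
print.q_matrix <- function(x, ...) {
  cat("Instantaneous rate matrix (", n_states(x$states), " states):\n",
      sep = "")
  print(round(x$q, 6))
  invisible(x)
}

as_q <- function(q) {
  if (inherits(q, "q_matrix")) q$q else as.matrix(q)
}

#' CTMC transition probability matrix P(t) = exp(Qt)
#'
#' Computed by scaling-and-squaring with Pade approximation, which remains
#' well-behaved for the non-reversible catalog structures whose
#' eigendecomposition can be defective.
#'
#' @param q a \code{q_matrix} (or plain rate matrix).
#' @param t non-negative duration.
#' @export
transition_matrix <- function(q, t) {
  if (t < 0) stop("duration must be non-negative")
  Q <- as_q(q)
  P <- cpp_expm(Q, t)
  dimnames(P) <- dimnames(Q)
  P
}

#' Stationary distribution of a rate matrix
#'
#' Left null vector of Q (pi Q = 0) normalized to sum 1; for reducible
#' structures with transient states the limiting distribution puts zero mass
#' on the transient states.
#'
#' @param q a \code{q_matrix} or plain rate matrix.
#' @export
stationary_dist <- function(q) {
  Q <- as_q(q)
  K <- nrow(Q)
  if (all(Q == 0)) return(rep(1 / K, K))
  # long-run row of P(t): robust to reducibility and defective eigenvectors
  scale <- max(abs(diag(Q)))
  P <- cpp_expm(Q, 1e6 / scale)
  pi <- colMeans(P)
  pi[pi < 0] <- 0
  pi / sum(pi)
}

#' Pagel's lambda branch-length transformation
#'
#' Multiplies internal branch lengths by \code{lam} and extends each
#' terminal branch so that every root-to-tip distance is preserved. At
#' \code{lam = 0} the tree becomes a star phylogeny with depths intact; at
#' \code{lam = 1} the tree is unchanged.
#'
#' @param tree a \code{phylo} (ultrametric or near-ultrametric; for
#'   non-ultrametric trees the depth-preservation rule still applies, with a
#'   warning).
#' @param lam real in [0, 1].
#' @export
lambda_transform <- function(tree, lam) {
  if (lam < 0 || lam > 1) stop("lambda must lie in [0, 1]")
  if (lam == 1) return(tree)
  depth <- ape::node.depth.edgelength(tree)
  tipd <- depth[seq_along(tree$tip.label)]
  if (diff(range(tipd)) > 1e-6 * max(tipd)) {
    warning("tree is not ultrametric; applying depth-preserving transform")
  }
  is_tip <- tree$edge[, 2] <= length(tree$tip.label)
  el <- tree$edge.length * lam
  # terminal edges: keep each tip at its original depth
  parent_depth <- depth[tree$edge[is_tip, 1]]
  el[is_tip] <- tree$edge.length[is_tip] + (1 - lam) * parent_depth
  tree$edge.length <- el
  tree
}

resolve_root_prior <- function(root_prior, q, root_partial = NULL) {
  K <- nrow(as_q(q))
  if (is.numeric(root_prior)) {
    if (length(root_prior) != K || any(root_prior < 0)) {
      stop("fixed root prior must be a non-negative vector of length ", K)
    }
    return(root_prior / sum(root_prior))
  }
  switch(match.arg(root_prior, c("uniform", "stationary", "fitzjohn")),
         uniform = rep(1 / K, K),
         stationary = stationary_dist(q),
         fitzjohn = {
           if (is.null(root_partial)) stop("fitzjohn prior needs partials")
           s <- sum(root_partial)
           if (s <= 0) rep(1 / K, K) else root_partial / s
         })
}

#' Log-likelihood of a trait table under an Mk model
#'
#' Felsenstein pruning: post-order conditional likelihoods with per-node
#' rescaling, tip partials taken as indicator vectors over admissible states
#' (set coding) or as the supplied probability weights, root partials
#' combined with the chosen prior. Structurally impossible data yield
#' \code{-Inf} with a warning rather than an error.
#'
#' @param tree a \code{phylo}.
#' @param traits a \code{trait_table} covering all tips.
#' @param q a \code{q_matrix} on the same state space.
#' @param root_prior \code{"uniform"} (default), \code{"stationary"},
#'   \code{"fitzjohn"}, or a fixed probability vector.
#' @return natural-log likelihood (scalar).
#' @export
prune_log_likelihood <- function(tree, traits, q, root_prior = "uniform") {
  Q <- as_q(q)
  part <- tip_partials(tree, traits)
  tr <- stats::reorder(tree, "postorder")
  res <- cpp_mk_partials(tr$edge, tr$edge.length, length(tr$tip.label),
                         part, Q, FALSE)
  if (isTRUE(res$impossible)) {
    warning("data impossible under structural zeros; log-likelihood is -Inf")
    return(-Inf)
  }
  prior <- resolve_root_prior(root_prior, Q, res$root)
  s <- sum(res$root * prior)
  if (s <= 0) {
    warning("data impossible under structural zeros; log-likelihood is -Inf")
    return(-Inf)
  }
  log(s) + res$logscale
}
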