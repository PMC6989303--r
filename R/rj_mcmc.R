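# Reversible-jump MCMC over rate-class partitions of the off-diagonal
# cells of Q. The chain state is (assignment of each cell to the
# structural-zero bin or to a rate class, one rate per class, hyperprior
# mean); moves reassign single cells (with prior-draw births, so prior
# densities cancel against the proposal), update class rates on the log
# scale, and resample the exponential-prior mean.

# ordered off-diagonal cells in row-major order; the canonical cell order
# used by model strings and zero patterns
rate_cells <- function(K) {
  cells <- expand.grid(j = seq_len(K), i = seq_len(K))[, c("i", "j")]
  cells <- cells[cells$i != cells$j, ]
  as.matrix(cells[order(cells$i, cells$j), ])
}

#' Canonical model string of a rate-class assignment
#'
#' Cells are read in row-major order over the ordered state pairs;
#' structural zeros print as \code{"Z"} and classes are lettered A, B, ...
#' in order of first appearance, so any relabeling of classes yields the
#' same string.
#'
#' @param assignment integer vector over the K(K-1) cells: 0 for the zero
#'   bin, positive ids for classes.
#' @return character scalar such as \code{"A A Z B"}.
#' @export
canonical_model_string <- function(assignment) {
  out <- character(length(assignment))
  seen <- integer(0)
  for (i in seq_along(assignment)) {
    a <- assignment[i]
    if (a == 0) {
      out[i] <- "Z"
    } else {
      pos <- match(a, seen)
      if (is.na(pos)) {
        seen <- c(seen, a)
        pos <- length(seen)
      }
      out[i] <- LETTERS[pos]
    }
  }
  paste(out, collapse = " ")
}

# log count of configurations with z zero cells and k rate classes among
# n cells: choose(n, z) * S2(n - z, k) (Stirling second kind). The RJ prior
# is uniform over (z, k) strata and uniform within each stratum, so model
# dimension is not swamped by the combinatorial explosion of many-class
# partitions.
log_config_count <- function(n_cells) {
  S2 <- matrix(0, n_cells + 1, n_cells + 1)  # [n+1, k+1]
  S2[1, 1] <- 1
  for (n in seq_len(n_cells)) {
    for (k in seq_len(n)) {
      S2[n + 1, k + 1] <- k * S2[n, k + 1] + S2[n, k]
    }
  }
  out <- matrix(-Inf, n_cells + 1, n_cells + 1)  # [z+1, k+1]
  for (z in 0:n_cells) {
    for (k in 0:(n_cells - z)) {
      cnt <- choose(n_cells, z) * S2[n_cells - z + 1, k + 1]
      if (cnt > 0) out[z + 1, k + 1] <- log(cnt)
    }
  }
  out
}

# menu of reassignment targets for one cell: the zero bin, every other
# existing class, and a fresh class (unless the cell is already alone in
# its own class, where a fresh class would be a no-op)
cell_menu <- function(assignment, cell) {
  cur <- assignment[cell]
  classes <- unique(assignment[assignment > 0])
  menu <- list()
  if (cur != 0) menu <- c(menu, list(0L))
  for (cl in setdiff(classes, cur)) menu <- c(menu, list(cl))
  if (cur == 0 || sum(assignment == cur) > 1) menu <- c(menu, list(-1L))
  menu
}

#' Reversible-jump MCMC over transition-rate model structures
#'
#' Searches the space of constrained Mk models (partitions of the rate
#' cells into shared-rate classes plus a structural-zero bin) jointly with
#' the class rates. The structure prior is uniform over (number of
#' forbidden cells, number of rate classes) strata and uniform within each
#' stratum, so sparse few-parameter structures are not swamped by the
#' combinatorial mass of many-class partitions; rates carry the
#' exponential(hyperprior) prior. Visited structures are ranked by
#' posterior frequency of their canonical model string; the zero pattern
#' (which transitions are forbidden) is tabulated separately.
#'
#' @param tree a \code{phylo}.
#' @param traits a \code{trait_table}.
#' @param states a \code{state_space}.
#' @param settings an \code{\link{mcmc_settings}}.
#' @param root_prior root prior for the likelihood.
#' @return an \code{rj_result}: draws (model string, k, logL per kept
#'   iteration), ranked \code{models} and \code{zero_patterns} tables, and
#'   \code{top_support} (posterior frequency of the modal structure).
#' @export
rj_mcmc <- function(tree, traits, states, settings = mcmc_settings(),
                    root_prior = "uniform") {
  K <- n_states(states)
  cells <- rate_cells(K)
  n_cells <- nrow(cells)
  ll <- make_loglik(tree, traits, states, root_prior)
  loglik_of <- function(assignment, rates) {
    q <- matrix(0, K, K)
    nz <- assignment > 0
    q[cells[nz, , drop = FALSE]] <- rates[as.character(assignment[nz])]
    diag(q) <- -rowSums(q)
    ll(q)
  }
  lcfg <- log_config_count(n_cells)
  set.seed(settings$seed)
  hyper <- is.null(settings$prior_mean)
  m <- if (hyper) stats::runif(1, 0.1, 10) else settings$prior_mean
  depth <- max(ape::node.depth.edgelength(tree))
  assignment <- rep(1L, n_cells)
  rates <- c("1" = 0.5 / depth)
  next_id <- 2L
  cur_ll <- loglik_of(assignment, rates)
  cur_lp <- log_prior_rates(rates, m)
  rw_scale <- 0.5
  n_keep <- floor((settings$n_iter - settings$burn_in) / settings$thin)
  rec_model <- rec_zero <- character(n_keep)
  rec_k <- integer(n_keep)
  rec_ll <- numeric(n_keep)
  kept <- 0
  init_string <- canonical_model_string(assignment)
  left_initial <- FALSE
  acc <- tries <- 0
  for (it in seq_len(settings$n_iter)) {
    if (stats::runif(1) < 0.5) {
      # partition move: reassign one cell
      cell <- sample.int(n_cells, 1)
      cur <- assignment[cell]
      menu <- cell_menu(assignment, cell)
      tgt <- menu[[sample.int(length(menu), 1)]]
      new_assignment <- assignment
      new_rates <- rates
      if (tgt == -1L) {
        id <- next_id
        new_rates[as.character(id)] <- stats::rexp(1, rate = 1 / m)
        new_assignment[cell] <- id
      } else {
        new_assignment[cell] <- tgt
      }
      if (cur > 0 && sum(assignment == cur) == 1) {
        new_rates <- new_rates[names(new_rates) != as.character(cur)]
      }
      new_ll <- loglik_of(new_assignment, new_rates)
      menu_rev <- cell_menu(new_assignment, cell)
      z_cur <- sum(assignment == 0)
      k_cur <- length(unique(assignment[assignment > 0]))
      z_new <- sum(new_assignment == 0)
      k_new <- length(unique(new_assignment[new_assignment > 0]))
      a <- new_ll - cur_ll +
        lcfg[z_cur + 1, k_cur + 1] - lcfg[z_new + 1, k_new + 1] +
        log(length(menu)) - log(length(menu_rev))
      if (is.finite(a) && log(stats::runif(1)) < a) {
        assignment <- new_assignment
        rates <- new_rates
        if (tgt == -1L) next_id <- next_id + 1L
        cur_ll <- new_ll
        cur_lp <- log_prior_rates(rates, m)
      }
    } else if (length(rates)) {
      # rate move on one class
      j <- sample.int(length(rates), 1)
      prop <- rates
      prop[j] <- prop[j] * exp(stats::rnorm(1, 0, rw_scale))
      new_ll <- loglik_of(assignment, prop)
      new_lp <- log_prior_rates(prop, m)
      a <- (new_ll + new_lp) - (cur_ll + cur_lp) + log(prop[j] / rates[j])
      tries <- tries + 1
      if (is.finite(a) && log(stats::runif(1)) < a) {
        rates <- prop; cur_ll <- new_ll; cur_lp <- new_lp
        acc <- acc + 1
      }
      if (it <= settings$burn_in && tries >= 100) {
        rw_scale <- min(5, max(0.02, rw_scale * exp(acc / tries - 0.3)))
        acc <- tries <- 0
      }
    }
    if (hyper && it %% 10 == 0 && length(rates)) {
      mp <- m + stats::rnorm(1, 0, 1)
      if (mp > 0 && mp < 10) {
        lpp <- log_prior_rates(rates, mp)
        if (log(stats::runif(1)) < lpp - cur_lp) {
          m <- mp; cur_lp <- lpp
        }
      }
    }
    if (!left_initial && it > settings$burn_in &&
        canonical_model_string(assignment) != init_string) {
      left_initial <- TRUE
    }
    if (it > settings$burn_in &&
        (it - settings$burn_in) %% settings$thin == 0) {
      kept <- kept + 1
      rec_model[kept] <- canonical_model_string(assignment)
      rec_zero[kept] <- paste(as.integer(assignment == 0), collapse = "")
      rec_k[kept] <- length(unique(assignment[assignment > 0]))
      rec_ll[kept] <- cur_ll
    }
  }
  if (!left_initial && all(rec_model == init_string)) {
    warning("RJ chain never left its initial partition after adaptation")
  }
  tab <- sort(table(rec_model), decreasing = TRUE)
  models <- data.frame(model_string = names(tab),
                       freq = as.numeric(tab) / kept,
                       rank = seq_along(tab), row.names = NULL)
  ztab <- sort(table(rec_zero), decreasing = TRUE)
  zeros <- data.frame(zero_pattern = names(ztab),
                      freq = as.numeric(ztab) / kept,
                      rank = seq_along(ztab), row.names = NULL)
  structure(list(draws = data.frame(model_string = rec_model,
                                    k = rec_k, logL = rec_ll),
                 models = models, zero_patterns = zeros,
                 top_support = models$freq[1], cells = cells,
                 states = states, settings = settings),
            class = "rj_result")
}

#' @export
print.rj_result <- function(x, ...) {
  cat("Reversible-jump model search over ", nrow(x$cells),
      " rate cells (", nrow(x$draws), " kept draws)\n", sep = "")
  cat("top structure (support ", round(x$top_support, 3), "): ",
      x$models$model_string[1], "\n", sep = "")
  invisible(x)
}

#' Zero pattern of a model specification
#'
#' The 0/1 string (in canonical cell order) marking which transitions a
#' structure forbids; used to compare reversible-jump output with catalog
#' models.
#'
#' @param spec a \code{model_spec}.
#' @export
zero_pattern <- function(spec) {
  K <- n_states(spec$states)
  cells <- rate_cells(K)
  paste(as.integer(spec$index[cells] == 0), collapse = "")
}
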