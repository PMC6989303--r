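# Taxon-subsampling robustness experiment: nested random subsets of the
# taxa, per-subset model selection by ML/AICw, support aggregated per
# sampling scheme.

#' Build subsampling schemes from fractions of the taxon set
#'
#' Subset sizes use round-half-up (so 75% of 362 taxa is 272, not 271),
#' matching the published scheme sizes 344, 326, 308, 290, 272, 253, 235,
#' 217, 199, 181 for fractions 0.95 down to 0.50 of 362 species.
#'
#' @param total total taxon count.
#' @param fractions fractions in (0, 1].
#' @param replicates independent subsamples per scheme.
#' @param seed master seed; each scheme derives its own stream so adding a
#'   scheme never perturbs earlier draws.
#' @return list of \code{subsample_scheme} objects.
#' @export
make_schemes <- function(total, fractions = seq(0.95, 0.50, by = -0.05),
                         replicates = 10, seed = 1) {
  if (any(fractions <= 0 | fractions > 1)) {
    stop("fractions must lie in (0, 1]")
  }
  if (replicates < 1) stop("replicates must be >= 1")
  lapply(fractions, function(f) {
    structure(list(total = total, fraction = f,
                   n_taxa = floor(f * total + 0.5),
                   replicates = as.integer(replicates),
                   seed = as.integer(seed + round(f * 1e4))),
              class = "subsample_scheme")
  })
}

#' @export
print.subsample_scheme <- function(x, ...) {
  cat("Subsampling scheme: ", x$n_taxa, "/", x$total, " taxa (",
      round(100 * x$fraction), "%), ", x$replicates, " replicate(s)\n",
      sep = "")
  invisible(x)
}

has_trait_variation <- function(traits) {
  pat <- apply(traits$partial > 0, 1, paste, collapse = "")
  length(unique(pat)) > 1
}

#' Run the taxon-subsampling robustness experiment
#'
#' For every scheme and replicate: draw taxa uniformly without replacement,
#' prune the tree and trait table, fit the candidate models by maximum
#' likelihood and compute Akaike weights. Replicates whose subsample lacks
#' trait variation are redrawn (logged) up to a bounded number of tries.
#'
#' @param tree a \code{phylo}.
#' @param traits a \code{trait_table} covering the tree's tips.
#' @param schemes list from \code{\link{make_schemes}}.
#' @param models character vector of catalog model names.
#' @param states a \code{state_space}.
#' @param root_prior,n_restarts passed to the ML fits.
#' @param criterion \code{"AIC"} or \code{"AICc"} for the weights.
#' @param max_redraw redraw budget per replicate.
#' @return list with \code{details} (one row per scheme x replicate x
#'   model) and \code{summary} (mean AICw and winning frequency per scheme
#'   x model).
#' @export
run_robustness <- function(tree, traits, schemes, models, states,
                           root_prior = "uniform", n_restarts = 1,
                           criterion = "AIC", max_redraw = 20) {
  taxa_all <- tree$tip.label
  details <- list()
  for (sc in schemes) {
    if (sc$n_taxa > length(taxa_all)) {
      stop("scheme asks for ", sc$n_taxa, " taxa but only ",
           length(taxa_all), " are available")
    }
    for (rep_i in seq_len(sc$replicates)) {
      set.seed(sc$seed + rep_i)
      sub <- NULL
      for (try_i in seq_len(max_redraw)) {
        cand <- sample(taxa_all, sc$n_taxa)
        if (has_trait_variation(subset_traits(traits, cand))) {
          sub <- cand
          if (try_i > 1) {
            message("scheme ", round(100 * sc$fraction),
                    "% replicate ", rep_i, ": redrew subsample ",
                    try_i - 1, " time(s) for trait variation")
          }
          break
        }
      }
      if (is.null(sub)) {
        stop("no subsample with trait variation after ", max_redraw,
             " redraws")
      }
      sub_tree <- prune_to_taxa(tree, sub)
      sub_traits <- subset_traits(traits, sub_tree$tip.label)
      fits <- fit_models(sub_tree, sub_traits, models, states,
                         root_prior = root_prior,
                         n_restarts = n_restarts,
                         seed = sc$seed + rep_i)
      tab <- aic_table(fits, criterion = criterion)
      details[[length(details) + 1]] <- data.frame(
        fraction = sc$fraction, n_taxa = sc$n_taxa, replicate = rep_i,
        model = tab$model, AIC = tab[[criterion]], AICw = tab$AICw,
        rank = tab$rank, row.names = NULL)
    }
  }
  details <- do.call(rbind, details)
  summary <- do.call(rbind, lapply(split(
    details, list(details$fraction, details$model), drop = TRUE),
    function(d) data.frame(fraction = d$fraction[1],
                           n_taxa = d$n_taxa[1], model = d$model[1],
                           mean_AICw = mean(d$AICw),
                           win_freq = mean(d$rank == 1),
                           row.names = NULL)))
  summary <- summary[order(-summary$fraction, -summary$mean_AICw), ]
  rownames(summary) <- NULL
  list(details = details, summary = summary)
}
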