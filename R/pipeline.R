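# Configuration-driven orchestration: signal -> ML comparison ->
# stepping-stone comparison -> reversible jump -> ASR / stochastic mapping
# under the winning model -> subsampling robustness, with all randomness
# split from one master seed and every table written as TSV.

#' Build an analysis configuration
#'
#' @param tree path to a Newick/Nexus file, or a \code{phylo}/
#'   \code{multiPhylo}.
#' @param traits path to a trait CSV (\code{taxon,state} grammar) or a
#'   \code{trait_table}.
#' @param scheme \code{"three"} or \code{"four"}.
#' @param stages subset of \code{c("signal", "ml", "bayes", "rj", "asr",
#'   "simmap", "robustness")}.
#' @param models catalog models to compare.
#' @param seed master seed; each stage derives its own stream.
#' @param out_dir output directory for the report bundle.
#' @param settings named list of per-stage settings overriding the
#'   desk-scale defaults: \code{signal} (n_null), \code{ml} (n_restarts),
#'   \code{bayes} (n_iter, burn_in, thin, n_stones, iter_per_stone,
#'   n_chains), \code{rj} (n_iter, burn_in, thin), \code{simmap} (n_maps),
#'   \code{robustness} (fractions, replicates), \code{root_prior}.
#' @export
analysis_config <- function(tree, traits, scheme = "four",
                            stages = c("signal", "ml", "bayes", "rj",
                                       "asr", "simmap", "robustness"),
                            models = c("ER", "SYM", "ARD", "IC",
                                       "SHULTZ", "RJ_DERIVED"),
                            seed = 1, out_dir = tempfile("primsoc_run_"),
                            settings = list()) {
  stages <- unlist(stages)
  models <- unlist(models)
  known <- c("signal", "ml", "bayes", "rj", "asr", "simmap", "robustness")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  for (f in c(tree, traits)) {
    if (is.character(f) && !file.exists(f)) stop("file not found: ", f)
  }
  structure(list(tree = tree, traits = traits, scheme = scheme,
                 stages = stages, models = models, seed = as.integer(seed),
                 out_dir = out_dir, settings = settings),
            class = "analysis_config")
}

#' Read an analysis configuration from YAML or JSON
#'
#' @param path config file; keys mirror \code{\link{analysis_config}}
#'   arguments.
#' @export
read_analysis_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
    else yaml::read_yaml(path)
  args <- cfg[intersect(names(cfg),
                        names(formals(analysis_config)))]
  do.call(analysis_config, args)
}

cfg_setting <- function(cfg, stage, key, default) {
  v <- cfg$settings[[stage]][[key]]
  if (is.null(v)) default else v
}

#' Run the full comparative analysis
#'
#' Executes the requested stages in dependency order and writes the report
#' bundle: a signal table, an ML comparison, a Bayesian (stepping-stone)
#' comparison with log Bayes factors, the reversible-jump structure
#' ranking, a per-node ancestral-state table, a transition-count summary
#' from stochastic mapping under the winning model, the robustness table,
#' and a run log with seeds. Taxa are restricted to the intersection of
#' the tree and the trait table.
#'
#' @param cfg an \code{\link{analysis_config}}.
#' @return invisibly, a named list of stage results and output paths.
#' @export
run_full_analysis <- function(cfg) {
  stopifnot(inherits(cfg, "analysis_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  states <- state_space(cfg$scheme)
  tree <- if (is.character(cfg$tree)) read_newick(cfg$tree) else cfg$tree
  trees <- if (inherits(tree, "multiPhylo")) tree else NULL
  if (!is.null(trees)) tree <- trees[[1]]
  traits <- if (is.character(cfg$traits)) {
    read_trait_table(cfg$traits, states)
  } else cfg$traits
  common <- intersect(tree$tip.label, rownames(traits$partial))
  if (length(common) < 3) stop("fewer than 3 taxa shared by tree and traits")
  tree <- prune_to_taxa(tree, common)
  traits <- subset_traits(traits, tree$tip.label)
  root_prior <- cfg_setting(cfg, "root_prior", 1, "uniform")
  if (is.list(root_prior)) root_prior <- "uniform"
  seed <- cfg$seed
  res <- list()
  log_lines <- c(sprintf("primsoc run: %d taxa, %s-state scheme, seed %d",
                         length(tree$tip.label), cfg$scheme, seed),
                 sprintf("stages: %s", paste(cfg$stages, collapse = ", ")))
  out <- function(name) file.path(cfg$out_dir, name)
  stage_on <- function(s) s %in% cfg$stages

  if (stage_on("signal")) {
    n_null <- cfg_setting(cfg, "signal", "n_null", 999)
    sig <- list(K = blomberg_k(tree, traits, n_null = n_null,
                               seed = seed + 11))
    sig$lambda <- pagel_lambda_ml(tree, traits,
                                  model_catalog("ER", states),
                                  root_prior = root_prior,
                                  seed = seed + 12)
    for (st in states$labels) {
      bin <- as.numeric(traits$partial[tree$tip.label, st] > 0)
      if (length(unique(bin)) == 2) {
        sig[[paste0("D_", st)]] <-
          d_statistic(tree, bin, n_null = max(100, n_null),
                      seed = seed + 13)
      }
    }
    write_signal_table(sig, out("signal.tsv"), scheme = cfg$scheme)
    res$signal <- sig
    log_lines <- c(log_lines, "stage signal: done")
  }

  fits <- NULL
  if (stage_on("ml") || stage_on("asr") || stage_on("simmap")) {
    fits <- fit_models(tree, traits, cfg$models, states,
                       root_prior = root_prior,
                       n_restarts = cfg_setting(cfg, "ml", "n_restarts", 2),
                       seed = seed + 21)
    ml_tab <- aic_table(fits)
    utils::write.table(ml_tab, out("ml_comparison.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    res$ml <- ml_tab
    log_lines <- c(log_lines, "stage ml: done")
  }

  if (stage_on("bayes")) {
    ms <- mcmc_settings(
      n_iter = cfg_setting(cfg, "bayes", "n_iter", 2e4),
      burn_in = cfg_setting(cfg, "bayes", "burn_in", 5e3),
      thin = cfg_setting(cfg, "bayes", "thin", 10),
      seed = seed + 31,
      n_chains = cfg_setting(cfg, "bayes", "n_chains", 1))
    ss <- lapply(cfg$models, function(nm) {
      stepping_stone_ml(tree, traits, model_catalog(nm, states),
                        settings = ms,
                        n_stones = cfg_setting(cfg, "bayes", "n_stones", 16),
                        iter_per_stone =
                          cfg_setting(cfg, "bayes", "iter_per_stone", 500),
                        root_prior = root_prior)
    })
    names(ss) <- cfg$models
    btab <- bayes_table(ss)
    utils::write.table(btab, out("bayes_comparison.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    res$bayes <- btab
    log_lines <- c(log_lines, "stage bayes: done")
  }

  if (stage_on("rj")) {
    rs <- mcmc_settings(
      n_iter = cfg_setting(cfg, "rj", "n_iter", 2e4),
      burn_in = cfg_setting(cfg, "rj", "burn_in", 5e3),
      thin = cfg_setting(cfg, "rj", "thin", 10),
      seed = seed + 41)
    rj <- rj_mcmc(tree, traits, states, settings = rs,
                  root_prior = root_prior)
    utils::write.table(rj$models, out("rj_models.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    res$rj <- rj
    log_lines <- c(log_lines,
                   sprintf("stage rj: top support %.3f", rj$top_support))
  }

  if (stage_on("asr") || stage_on("simmap")) {
    # winning model: top of the Bayesian comparison when available,
    # otherwise top of the ML table
    win <- if (!is.null(res$bayes)) res$bayes$model[1] else res$ml$model[1]
    res$winning_model <- win
    wfit <- fits[[win]]
    q <- build_q(wfit$spec, wfit$rates)
    if (stage_on("asr")) {
      asr <- marginal_asr(tree, traits, q, root_prior = root_prior)
      df <- data.frame(node = rownames(asr$probs), asr$probs,
                       check.names = FALSE)
      utils::write.table(df, out("ancestral_states.tsv"), sep = "\t",
                         row.names = FALSE, quote = FALSE)
      res$asr <- asr
      log_lines <- c(log_lines,
                     sprintf("stage asr: done under %s", win))
    }
    if (stage_on("simmap")) {
      maps <- stochastic_map(if (!is.null(trees)) trees else tree,
                             traits, q, root_prior = root_prior,
                             n_maps = cfg_setting(cfg, "simmap",
                                                  "n_maps", 100),
                             seed = seed + 51)
      sm <- summarize_transitions(maps)
      write_transition_table(sm, out("transitions.tsv"))
      res$simmap <- sm
      log_lines <- c(log_lines,
                     sprintf("stage simmap: %d maps under %s",
                             sm$n_maps, win))
    }
  }

  if (stage_on("robustness")) {
    schemes <- make_schemes(
      length(tree$tip.label),
      fractions = cfg_setting(cfg, "robustness", "fractions",
                              seq(0.95, 0.50, by = -0.05)),
      replicates = cfg_setting(cfg, "robustness", "replicates", 10),
      seed = seed + 61)
    rb <- run_robustness(tree, traits, schemes, cfg$models, states,
                         root_prior = root_prior)
    utils::write.table(rb$summary, out("robustness.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    res$robustness <- rb
    log_lines <- c(log_lines, "stage robustness: done")
  }

  # provenance: config serialized verbatim plus the run log
  yaml::write_yaml(list(scheme = cfg$scheme, stages = cfg$stages,
                        models = cfg$models, seed = cfg$seed,
                        settings = cfg$settings),
                   out("config.yaml"))
  writeLines(log_lines, out("run_log.txt"))
  res$out_dir <- cfg$out_dir
  invisible(res)
}
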