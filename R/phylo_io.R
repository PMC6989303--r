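#' Read a phylogeny from Newick or Nexus text
#'
#' Thin validating wrapper around \pkg{ape}'s parsers. Accepts a file path or
#' a literal tree string; Nexus input is detected by its \code{#NEXUS}
#' header. Trees must be rooted for downstream likelihood work; edges without
#' lengths are assigned unit length with a warning (all analyses in this
#' package assume dated trees).
#'
#' @param x file path, or a character scalar holding Newick (or a Nexus
#'   TREES block).
#' @return an object of class \code{phylo} (single tree) or \code{multiPhylo}
#'   (multi-tree input, e.g. posterior samples).
#' @export
read_newick <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  is_file <- !grepl("(", x, fixed = TRUE) && file.exists(x)
  txt <- if (is_file) paste(readLines(x, warn = FALSE), collapse = "\n") else x
  tr <- if (grepl("^\\s*#NEXUS", txt, ignore.case = TRUE)) {
    if (is_file) ape::read.nexus(x) else {
      tf <- tempfile(fileext = ".nex")
      on.exit(unlink(tf))
      writeLines(txt, tf)
      ape::read.nexus(tf)
    }
  } else {
    out <- tryCatch(ape::read.tree(text = txt),
                    error = function(e) stop("Newick parse error: ",
                                             conditionMessage(e)))
    if (is.null(out)) stop("Newick parse error: malformed tree text")
    out
  }
  if (inherits(tr, "multiPhylo")) {
    for (i in seq_along(tr)) tr[[i]] <- validate_phylo(tr[[i]])
    tr
  } else {
    validate_phylo(tr)
  }
}

validate_phylo <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylogeny")
  if (anyDuplicated(tree$tip.label)) {
    dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
    stop("duplicate tip label(s): ", paste(dup, collapse = ", "))
  }
  if (is.null(tree$edge.length)) {
    warning("tree has no branch lengths; assigning unit lengths")
    tree$edge.length <- rep(1, nrow(tree$edge))
  }
  if (anyNA(tree$edge.length) || any(tree$edge.length < 0)) {
    bad <- which(is.na(tree$edge.length) | tree$edge.length < 0)
    stop("negative or missing branch length on edge(s): ",
         paste(bad, collapse = ", "))
  }
  tree
}

#' Write a phylogeny as Newick text
#'
#' @param tree a \code{phylo} or \code{multiPhylo} object.
#' @param file optional path; when empty the Newick string is returned.
#' @export
write_newick <- function(tree, file = "") {
  ape::write.tree(tree, file = file)
}

#' Prune a phylogeny to a set of taxa
#'
#' Drops all tips not in \code{keep}; degree-2 nodes created by the pruning
#' are suppressed with their incident edge lengths summed, so the patristic
#' distance between any two retained tips is unchanged.
#'
#' @param tree a \code{phylo} object.
#' @param keep character vector of tip labels to retain (at least 2).
#' @return the pruned \code{phylo}.
#' @export
prune_to_taxa <- function(tree, keep) {
  keep <- unique(as.character(keep))
  unknown <- setdiff(keep, tree$tip.label)
  if (length(unknown)) {
    stop("taxa not in tree: ", paste(unknown, collapse = ", "))
  }
  if (length(keep) < 2L) stop("pruning requires at least 2 retained taxa")
  if (length(keep) == length(tree$tip.label)) return(tree)
  ape::keep.tip(tree, keep)
}

#' Trait tables: species-to-state assignments with polymorphism
#'
#' A trait table maps each taxon to either a non-empty set of admissible
#' states (stored as 0/1 indicator rows) or to a probability vector over the
#' state space (rows summing to 1). Sets are the default coding for
#' likelihood and Bayesian fits; probability weights are the convention for
#' stochastic mapping, where a species recorded in two states is coded
#' P1 = P2 = 0.5.
#'
#' @param x a named character vector of states (polymorphism written
#'   \code{"S|P"}), or a numeric matrix with taxa as rownames and one column
#'   per state.
#' @param states a \code{state_space}.
#' @return an object of class \code{trait_table} with elements
#'   \code{states}, \code{partial} (taxa x states matrix) and \code{type}
#'   (\code{"set"} or \code{"prob"}).
#' @export
trait_table <- function(x, states) {
  stopifnot(is_state_space(states))
  K <- n_states(states)
  if (is.matrix(x)) {
    if (is.null(rownames(x))) stop("probability matrix needs taxon rownames")
    if (ncol(x) != K) stop("matrix must have one column per state")
    if (any(x < 0)) stop("negative probability weight")
    s <- rowSums(x)
    if (any(abs(s - 1) > 1e-9)) {
      stop("probability rows must sum to 1 (taxon ",
           rownames(x)[which(abs(s - 1) > 1e-9)[1]], ")")
    }
    part <- x
    colnames(part) <- states$labels
    type <- "prob"
  } else {
    if (is.null(names(x))) stop("state vector needs taxon names")
    part <- matrix(0, length(x), K,
                   dimnames = list(names(x), states$labels))
    for (i in seq_along(x)) {
      ss <- strsplit(as.character(x[i]), "|", fixed = TRUE)[[1]]
      ss <- ss[nzchar(ss)]
      if (!length(ss)) stop("empty state field for taxon ", names(x)[i])
      part[i, state_index(states, ss)] <- 1
    }
    type <- "set"
  }
  if (anyDuplicated(rownames(part))) {
    stop("repeated taxon: ",
         rownames(part)[duplicated(rownames(part))][1])
  }
  structure(list(states = states, partial = part, type = type),
            class = "trait_table")
}

#' @export
print.trait_table <- function(x, ...) {
  cat("Trait table: ", nrow(x$partial), " taxa, ",
      n_states(x$states), " states (", x$states$scheme, " scheme, ",
      x$type, " coding)\n", sep = "")
  invisible(x)
}

#' Read a trait table from delimited text
#'
#' Expects a header \code{taxon,state} (comma or tab separated); polymorphic
#' entries join states with \code{"|"} (e.g. \code{"S|P"}).
#'
#' @param x file path or literal text.
#' @param states a \code{state_space}; defaults to the scheme inferred from
#'   the states present is not attempted -- the caller must say.
#' @export
read_trait_table <- function(x, states) {
  stopifnot(is_state_space(states))
  is_file <- !grepl("[,\t\n]", x) && file.exists(x)
  lines <- if (is_file) readLines(x, warn = FALSE)
    else strsplit(x, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(trimws(lines))]
  sep <- if (grepl("\t", lines[1])) "\t" else ","
  df <- utils::read.table(text = lines, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, strip.white = TRUE)
  if (ncol(df) < 2L) stop("trait table needs columns taxon,state")
  taxa <- gsub("\\s+", "_", trimws(df[[1]]))
  if (anyDuplicated(taxa)) {
    row <- which(duplicated(taxa))[1]
    stop("taxon repeated at row ", row, ": ", taxa[row])
  }
  st <- trimws(as.character(df[[2]]))
  for (i in seq_along(st)) {
    if (is.na(st[i]) || !nzchar(st[i])) {
      stop("empty state field at row ", i, " (", taxa[i], ")")
    }
    ss <- strsplit(st[i], "|", fixed = TRUE)[[1]]
    ss <- ss[nzchar(ss)]
    if (!length(ss)) stop("empty state field at row ", i, " (", taxa[i], ")")
    bad <- setdiff(ss, states$labels)
    if (length(bad)) {
      stop("unknown state label at row ", i, " (", taxa[i], "): ",
           paste(bad, collapse = ", "))
    }
  }
  names(st) <- taxa
  trait_table(st, states)
}

#' Collapse a four-state trait table to the three-state scheme
#'
#' Maps both group-living states (UM and MM) onto G; probability weight on
#' UM and MM is summed onto G and admissible sets are mapped elementwise.
#' Total probability mass per taxon is preserved.
#'
#' @param x a \code{trait_table} on the four-state space.
#' @export
collapse_scheme <- function(x) {
  stopifnot(inherits(x, "trait_table"))
  if (x$states$scheme != "four") {
    stop("collapse_scheme expects a four-state trait table")
  }
  s3 <- state_space("three")
  p <- x$partial
  q <- cbind(S = p[, "S"], P = p[, "P"], G = p[, "UM"] + p[, "MM"])
  if (x$type == "set") q <- (q > 0) + 0
  rownames(q) <- rownames(p)
  out <- structure(list(states = s3, partial = q, type = x$type),
                   class = "trait_table")
  out
}

#' Convert set-coded tips to probability weights
#'
#' A taxon admissible in m states receives weight 1/m on each (the
#' equal-probability convention used for polymorphic tips in stochastic
#' mapping).
#'
#' @param x a \code{trait_table}.
#' @export
as_prob_table <- function(x) {
  stopifnot(inherits(x, "trait_table"))
  if (x$type == "prob") return(x)
  p <- x$partial / rowSums(x$partial)
  structure(list(states = x$states, partial = p, type = "prob"),
            class = "trait_table")
}

# Tip partial matrix aligned to a tree's tip order; errors if any tip lacks
# an entry. Likelihood code consumes the rows as conditional partials, so a
# set-coded table yields indicator partials and a prob-coded table yields
# the weights themselves.
tip_partials <- function(tree, traits) {
  stopifnot(inherits(traits, "trait_table"))
  miss <- setdiff(tree$tip.label, rownames(traits$partial))
  if (length(miss)) {
    stop("taxa in tree but not in trait table: ",
         paste(utils::head(miss, 5), collapse = ", "),
         if (length(miss) > 5) " ...")
  }
  traits$partial[tree$tip.label, , drop = FALSE]
}

#' Subset a trait table to a set of taxa
#'
#' @param x a \code{trait_table}.
#' @param taxa character vector of taxa to keep.
#' @export
subset_traits <- function(x, taxa) {
  miss <- setdiff(taxa, rownames(x$partial))
  if (length(miss)) stop("taxa missing from trait table: ",
                         paste(miss, collapse = ", "))
  structure(list(states = x$states,
                 partial = x$partial[taxa, , drop = FALSE],
                 type = x$type),
            class = "trait_table")
}

#' Write a trait table as delimited text
#'
#' Set-coded tables are written in the \code{taxon,state} grammar with
#' \code{"|"} joining polymorphic states; probability tables are written
#' with one column per state.
#'
#' @param x a \code{trait_table}.
#' @param file output path.
#' @export
write_trait_table <- function(x, file) {
  if (x$type == "set") {
    st <- apply(x$partial, 1, function(r) {
      paste(colnames(x$partial)[r > 0], collapse = "|")
    })
    utils::write.csv(data.frame(taxon = rownames(x$partial), state = st,
                                row.names = NULL),
                     file, row.names = FALSE, quote = FALSE)
  } else {
    utils::write.csv(data.frame(taxon = rownames(x$partial), x$partial,
                                row.names = NULL, check.names = FALSE),
                     file, row.names = FALSE, quote = FALSE)
  }
  invisible(file)
}
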