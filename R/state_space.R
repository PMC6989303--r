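#' Discrete social-organization state spaces
#'
#' A state space fixes the set and the ordering of the character states used
#' throughout the package. Two schemes are predefined for primate social
#' organization: the three-state scheme solitary (S), pair-living (P),
#' group-living (G), and the four-state scheme that splits groups into
#' unimale (UM) and multimale (MM). Arbitrary label vectors are accepted for
#' toy models. The label order is fixed (S < P < UM < MM; S < P < G) and is
#' used for all matrix indexing.
#'
#' @param x either a scheme name (\code{"three"} or \code{"four"}) or a
#'   character vector of unique state labels.
#' @return an object of class \code{state_space} with elements \code{labels}
#'   and \code{scheme}.
#' @examples
#' state_space("four")
#' state_space(c("0", "1"))
#' @export
state_space <- function(x = c("three", "four")) {
  if (is.character(x) && length(x) == 1L && x %in% c("three", "four")) {
    labels <- if (x == "three") c("S", "P", "G") else c("S", "P", "UM", "MM")
    scheme <- x
  } else {
    labels <- as.character(x)
    if (anyDuplicated(labels)) stop("state labels must be unique")
    if (length(labels) < 2L) stop("a state space needs at least two states")
    scheme <- if (identical(labels, c("S", "P", "G"))) "three"
      else if (identical(labels, c("S", "P", "UM", "MM"))) "four"
      else "custom"
  }
  structure(list(labels = labels, scheme = scheme), class = "state_space")
}

#' @export
print.state_space <- function(x, ...) {
  cat("State space (", x$scheme, "): ",
      paste(x$labels, collapse = " < "), "\n", sep = "")
  invisible(x)
}

n_states <- function(states) length(states$labels)

is_state_space <- function(x) inherits(x, "state_space")

state_index <- function(states, labels) {
  i <- match(labels, states$labels)
  if (anyNA(i)) {
    stop("unknown state label(s): ",
         paste(labels[is.na(i)], collapse = ", "))
  }
  i
}
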