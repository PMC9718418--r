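#' @useDynLib crnlearn, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats quantile runif sd setNames approx rbinom
#' @importFrom utils write.csv head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

.check_species_name <- function(name) {
  ok <- is.character(name) & nzchar(name) & grepl("^[A-Za-z0-9_]+$", name)
  if (!all(ok)) {
    stop("invalid species name(s): ",
         paste(sQuote(name[!ok]), collapse = ", "),
         " (letters, digits and underscore only)", call. = FALSE)
  }
  invisible(name)
}

# Normalise a species multiset given as a character vector (with repetition
# for stoichiometry > 1) or a named integer vector, into a named integer
# vector of multiplicities.
.as_multiset <- function(x) {
  if (is.null(x) || length(x) == 0L) {
    return(setNames(integer(0), character(0)))
  }
  if (is.character(x)) {
    tab <- table(x)
    out <- setNames(as.integer(tab), names(tab))
  } else if (is.numeric(x) && !is.null(names(x))) {
    if (any(x < 0) || any(x != round(x))) {
      stop("multiplicities must be non-negative integers", call. = FALSE)
    }
    out <- setNames(as.integer(x), names(x))
    out <- out[out > 0L]
  } else {
    stop("species multiset must be a character vector or named integer vector",
         call. = FALSE)
  }
  .check_species_name(names(out))
  # stable order: first mention
  out
}

#' Define a mass-action reaction rule
#'
#' A reaction converts a multiset of reactant species into a multiset of
#' product species with a stochastic (count-space) rate constant.  Catalysts
#' appear on both sides; an empty product set is a degradation and an empty
#' reactant set is a zeroth-order source.  Rate constants have units of
#' time^-1 x count^(1-order); no volume scaling is applied anywhere.
#'
#' @param reactants Character vector of reactant species, repeated for
#'   stoichiometry > 1 (e.g. `c("B", "B")`), or a named integer vector of
#'   multiplicities.  Empty for a source reaction.
#' @param products Products, same formats as `reactants`.  Empty for a
#'   degradation.
#' @param rate Non-negative stochastic rate constant.
#' @return An object of class `crn_reaction`.
#' @examples
#' reaction(c("X", "Y", "Stimulus"), c("B", "B", "Stimulus"), 1)
#' reaction("Good", character(0), 1)  # degradation
#' @export
reaction <- function(reactants, products, rate) {
  if (!is.numeric(rate) || length(rate) != 1L || is.na(rate) || rate < 0) {
    stop("rate must be a single non-negative number", call. = FALSE)
  }
  structure(
    list(reactants = .as_multiset(reactants),
         products = .as_multiset(products),
         rate = as.numeric(rate)),
    class = "crn_reaction")
}

#' @export
print.crn_reaction <- function(x, ...) {
  cat(.format_reaction(x), "\n")
  invisible(x)
}

.format_side <- function(ms) {
  if (length(ms) == 0L) return("0")
  paste(rep(names(ms), ms), collapse = " + ")
}

.format_reaction <- function(r) {
  sprintf("%s -> %s @ %s", .format_side(r$reactants),
          .format_side(r$products), format(r$rate, digits = 15))
}

#' Assemble a reaction network
#'
#' Species order is canonical: insertion order of first mention across the
#' reactions (reactants before products, reactions in the given order), so
#' that formatted output is byte-stable.  Extra species (e.g. ones only ever
#' injected by perturbations) can be appended via `species`.
#'
#' @param reactions List of [reaction()] objects.
#' @param species Optional character vector of additional species to include
#'   after those mentioned in the reactions.
#' @return An object of class `crn_network` with fields `species` and
#'   `reactions`.
#' @export
reaction_network <- function(reactions = list(), species = character(0)) {
  if (inherits(reactions, "crn_reaction")) reactions <- list(reactions)
  ok <- vapply(reactions, inherits, logical(1), "crn_reaction")
  if (!all(ok)) stop("all elements must be crn_reaction objects", call. = FALSE)
  mentioned <- unlist(lapply(reactions, function(r) {
    c(names(r$reactants), names(r$products))
  }), use.names = FALSE)
  if (length(species)) .check_species_name(species)
  sp <- unique(c(mentioned, species))
  structure(list(species = sp, reactions = reactions), class = "crn_network")
}

#' @export
print.crn_network <- function(x, ...) {
  cat(sprintf("<crn_network: %d species, %d reactions>\n",
              length(x$species), length(x$reactions)))
  cat(format_network(x))
  invisible(x)
}

#' Combine reaction networks
#'
#' @param ... `crn_network` objects (or lists of reactions).
#' @return A single `crn_network`; reaction order is concatenation order.
#' @export
c.crn_network <- function(...) {
  parts <- list(...)
  rxns <- unlist(lapply(parts, function(p) {
    if (inherits(p, "crn_network")) p$reactions else p
  }), recursive = FALSE)
  sp <- unlist(lapply(parts, function(p) {
    if (inherits(p, "crn_network")) p$species else character(0)
  }), use.names = FALSE)
  reaction_network(rxns, species = sp)
}

#' Stochastic propensity of a reaction
#'
#' Uses the combination-counting convention: `rate * prod_s C(x_s, m_s)`
#' over the distinct reactant species `s` with multiplicity `m_s`.  Every
#' reactant with multiplicity 1 (the only case in the decision-making
#' networks here) contributes a plain factor of its count.
#'
#' @param rule A [reaction()].
#' @param counts Named integer vector of current molecule counts; must
#'   contain every reactant species.
#' @return Non-negative numeric propensity.
#' @examples
#' propensity(reaction("X", "Y", 1), c(X = 100))  # 100
#' @export
propensity <- function(rule, counts) {
  stopifnot(inherits(rule, "crn_reaction"))
  need <- names(rule$reactants)
  missing <- setdiff(need, names(counts))
  if (length(missing)) {
    stop("unknown species in state: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  a <- rule$rate
  for (s in need) {
    a <- a * choose(counts[[s]], rule$reactants[[s]])
  }
  as.numeric(a)
}

#' Fire a reaction once
#'
#' Decrements reactant multiplicities and increments product multiplicities.
#' Errors if the rule cannot fire (propensity zero) or if bookkeeping would
#' drive a count negative.
#'
#' @inheritParams propensity
#' @return Updated named count vector.
#' @export
fire <- function(rule, counts) {
  if (propensity(rule, counts) <= 0) {
    stop("reaction cannot fire in this state (zero propensity)",
         call. = FALSE)
  }
  for (s in names(rule$reactants)) {
    counts[[s]] <- counts[[s]] - rule$reactants[[s]]
  }
  for (s in names(rule$products)) {
    if (!s %in% names(counts)) counts[[s]] <- 0L
    counts[[s]] <- counts[[s]] + rule$products[[s]]
  }
  if (any(counts < 0)) {
    stop("firing drove a count negative: ",
         paste(names(counts)[counts < 0], collapse = ", "), call. = FALSE)
  }
  counts
}

.parse_side <- function(txt, line_no) {
  txt <- trimws(txt)
  if (txt == "0" || txt == "∅" || txt == "") {
    return(character(0))
  }
  parts <- trimws(strsplit(txt, "+", fixed = TRUE)[[1]])
  if (any(!nzchar(parts)) || !all(grepl("^[A-Za-z0-9_]+$", parts))) {
    stop(sprintf("line %d: malformed species list '%s'", line_no, txt),
         call. = FALSE)
  }
  parts
}

#' Parse a plain-text reaction network
#'
#' One reaction per line: `R1 + R2 -> P1 + P2 @ <rate>`.  `0` (or the empty
#' string) denotes an empty side; stoichiometry above one is written by
#' repetition (`B + B`); `#` starts a comment; blank lines are ignored.
#'
#' @param text A single string (possibly multi-line) or character vector of
#'   lines.
#' @return A `crn_network`; reaction order follows the text, and the
#'   species order is first-mention order so [format_network()] round-trips.
#' @examples
#' parse_network("X + Y + Stimulus -> B + B + Stimulus @ 1.0")
#' @export
parse_network <- function(text) {
  lines <- unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
  rxns <- list()
  for (i in seq_along(lines)) {
    line <- sub("#.*$", "", lines[[i]])
    line <- trimws(line)
    if (!nzchar(line)) next
    if (!grepl("->", line, fixed = TRUE)) {
      stop(sprintf("line %d: missing '->'", i), call. = FALSE)
    }
    halves <- strsplit(line, "->", fixed = TRUE)[[1]]
    if (length(halves) != 2L) {
      stop(sprintf("line %d: expected exactly one '->'", i), call. = FALSE)
    }
    rhs <- strsplit(halves[[2]], "@", fixed = TRUE)[[1]]
    if (length(rhs) != 2L) {
      stop(sprintf("line %d: expected '@ <rate>' after products", i),
           call. = FALSE)
    }
    rate <- suppressWarnings(as.numeric(trimws(rhs[[2]])))
    if (is.na(rate)) {
      stop(sprintf("line %d: non-numeric rate '%s'", i, trimws(rhs[[2]])),
           call. = FALSE)
    }
    if (rate < 0) {
      stop(sprintf("line %d: negative rate", i), call. = FALSE)
    }
    rxns[[length(rxns) + 1L]] <- reaction(
      .parse_side(halves[[1]], i), .parse_side(rhs[[1]], i), rate)
  }
  reaction_network(rxns)
}

#' Format a reaction network as text
#'
#' Inverse of [parse_network()]: one canonical `reactants -> products @ rate`
#' line per reaction, in network order.
#'
#' @param network A `crn_network`.
#' @return A single string (lines joined by newlines; empty string for an
#'   empty network).
#' @export
format_network <- function(network) {
  stopifnot(inherits(network, "crn_network"))
  if (length(network$reactions) == 0L) return("")
  paste0(paste(vapply(network$reactions, .format_reaction, character(1)),
               collapse = "\n"), "\n")
}

#' Diagnose a reaction network
#'
#' Reports structural oddities that are usually mistakes: species that are
#' never consumed or never produced (and never act as catalysts), duplicate
#' rules, and zero-rate ("dead") rules.  An empty character vector means
#' clean.
#'
#' @param network A `crn_network`.
#' @return Character vector of diagnostic messages.
#' @export
validate_network <- function(network) {
  stopifnot(inherits(network, "crn_network"))
  diags <- character(0)
  touched <- character(0)
  for (r in network$reactions) {
    touched <- union(touched, union(names(r$reactants), names(r$products)))
  }
  untouched <- setdiff(network$species, touched)
  for (s in untouched) {
    diags <- c(diags, sprintf("species '%s' appears in no reaction", s))
  }
  keys <- vapply(network$reactions, .format_reaction, character(1))
  dup <- unique(keys[duplicated(keys)])
  for (d in dup) {
    diags <- c(diags, sprintf("duplicate reaction: %s", d))
  }
  for (i in seq_along(network$reactions)) {
    if (network$reactions[[i]]$rate == 0) {
      diags <- c(diags, sprintf("dead reaction (rate 0): %s", keys[[i]]))
    }
  }
  diags
}

# Net stoichiometric change of one reaction as a named integer vector over
# the network species (products minus reactants).
.net_change <- function(rule, species) {
  v <- setNames(integer(length(species)), species)
  for (s in names(rule$reactants)) v[[s]] <- v[[s]] - rule$reactants[[s]]
  for (s in names(rule$products)) v[[s]] <- v[[s]] + rule$products[[s]]
  v
}

#' Net stoichiometry matrix
#'
#' @param network A `crn_network`.
#' @return Integer matrix, species x reactions, of net molecule changes.
#' @export
stoichiometry <- function(network) {
  stopifnot(inherits(network, "crn_network"))
  m <- vapply(network$reactions, .net_change, integer(length(network$species)),
              species = network$species)
  if (length(network$reactions) == 0L) {
    m <- matrix(0L, nrow = length(network$species), ncol = 0L)
  }
  rownames(m) <- network$species
  m
}

# Flatten a network to the CSR-style arrays the C++ kernel consumes.
# Returned indices are 0-based.
.compile_network <- function(network) {
  sp <- network$species
  n_rxn <- length(network$reactions)
  react_ptr <- integer(n_rxn + 1L)
  react_idx <- integer(0)
  react_mult <- integer(0)
  net_ptr <- integer(n_rxn + 1L)
  net_idx <- integer(0)
  net_delta <- integer(0)
  rates <- numeric(n_rxn)
  for (j in seq_len(n_rxn)) {
    r <- network$reactions[[j]]
    rates[[j]] <- r$rate
    idx <- match(names(r$reactants), sp) - 1L
    react_idx <- c(react_idx, idx)
    react_mult <- c(react_mult, unname(r$reactants))
    react_ptr[[j + 1L]] <- length(react_idx)
    nc <- .net_change(r, sp)
    nz <- which(nc != 0L)
    net_idx <- c(net_idx, nz - 1L)
    net_delta <- c(net_delta, unname(nc[nz]))
    net_ptr[[j + 1L]] <- length(net_idx)
  }
  list(species = sp, react_ptr = react_ptr, react_idx = react_idx,
       react_mult = react_mult, net_ptr = net_ptr, net_idx = net_idx,
       net_delta = net_delta, rates = rates)
}

# Expand user-supplied initial counts over the network species, zero-filling.
.full_counts <- function(network, counts) {
  unknown <- setdiff(names(counts), network$species)
  if (length(unknown)) {
    stop("initial counts name species absent from the network: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  x <- setNames(integer(length(network$species)), network$species)
  if (length(counts)) x[names(counts)] <- as.integer(counts)
  if (any(x < 0)) stop("counts must be non-negative", call. = FALSE)
  x
}
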