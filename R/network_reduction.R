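# Structural node classifications driving the backward basin search.
#
# Peeling: a node with no outgoing (essential) edge influences nothing, so a
# basin is closed under flipping its value ("symmetric" node, marginal mean
# 0.5 over any basin). Removing it can expose further outdegree-0 nodes, so
# peeling iterates to a fixpoint, leaving a core with no outdegree-0 node.
# Self-edges count toward outdegree: a self-regulating node influences its
# own future and is never symmetric.

#' Iteratively peel outdegree-0 (symmetric) nodes
#'
#' @param net a `boolean_network`.
#' @return list with `symmetric_rounds` (list of character vectors, one per
#'   peel round), `symmetric_nodes` (all peeled nodes in peel order), and
#'   `core` (the remaining subnetwork as a `boolean_network`, or `NULL` when
#'   every node peels away).
#' @export
peel_symmetric_nodes <- function(net) {
  alive <- seq_along(net$nodes)
  rounds <- list()
  repeat {
    # outdegree over edges among surviving nodes only
    outdeg <- integer(length(net$nodes))
    for (i in alive) outdeg[net$rules[[i]]$inputs] <-
        outdeg[net$rules[[i]]$inputs] + 1L
    peel <- alive[outdeg[alive] == 0L]
    if (length(peel) == 0L) break
    rounds[[length(rounds) + 1L]] <- net$nodes[peel]
    alive <- setdiff(alive, peel)
  }
  core <- if (length(alive) > 0L) subnetwork(net, alive) else NULL
  structure(list(symmetric_rounds = rounds,
                 symmetric_nodes = unlist(rounds, use.names = FALSE) %||%
                   character(0),
                 core = core),
            class = "bn_peeling")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Deterministic / nondeterministic partition of a core network
#'
#' A core node x is "deterministic" when some node y has x as its only
#' essential input: y's rule is then identity or negation in x (a 1-input
#' rule that survives essential-input pruning is never constant), so y's
#' value at time t+1 invertibly forces x's value at time t. Nodes that are
#' not deterministic are "nondeterministic"; among those, the ones with at
#' least one deterministic input supply the second family of terminal-state
#' conditions.
#'
#' @param core a `boolean_network` with no outdegree-0 node (see
#'   [peel_symmetric_nodes()]).
#' @return object of class `bn_classification` with `v_det`, `v_nondet`,
#'   `v_nondet_inputdet` (character vectors) and `det_targets` (named list:
#'   for each deterministic node, its indegree-1 target nodes).
#' @export
classify_deterministic <- function(core) {
  nodes <- core$nodes
  det_targets <- list()
  for (i in seq_along(nodes)) {
    r <- core$rules[[i]]
    if (length(r$inputs) == 1L) {
      x <- nodes[r$inputs]
      det_targets[[x]] <- c(det_targets[[x]], nodes[i])
    }
  }
  v_det <- names(det_targets)
  if (is.null(v_det)) v_det <- character(0)
  v_nondet <- setdiff(nodes, v_det)
  has_det_input <- vapply(v_nondet, function(nm) {
    i <- match(nm, nodes)
    any(nodes[core$rules[[i]]$inputs] %in% v_det)
  }, logical(1))
  structure(list(core_nodes = nodes,
                 v_det = v_det,
                 v_nondet = v_nondet,
                 v_nondet_inputdet = v_nondet[has_det_input],
                 det_targets = det_targets),
            class = "bn_classification")
}

#' Full node classification of a network
#'
#' Combines symmetric-node peeling of the full network with the
#' deterministic/nondeterministic partition of its core.
#'
#' @param net a `boolean_network`.
#' @return list with the `bn_peeling` under `peeling` and, when a core
#'   exists, the core `bn_classification` under `classification`.
#' @export
node_classification <- function(net) {
  peeling <- peel_symmetric_nodes(net)
  classification <- if (!is.null(peeling$core)) {
    classify_deterministic(peeling$core)
  } else NULL
  list(peeling = peeling, classification = classification)
}

#' Project an attractor of the full network onto the core
#'
#' Drops the symmetric-node coordinates and verifies that the projected
#' cycle is an attractor of the core by stepping it.
#'
#' @param attractor a `bn_attractor` of the full network.
#' @param peeling result of [peel_symmetric_nodes()] for the same network.
#' @return a `bn_attractor` on the core nodes (zero-column states when the
#'   core is empty).
#' @export
project_attractor <- function(attractor, peeling) {
  core <- peeling$core
  full_nodes <- colnames(attractor$states)
  if (is.null(core)) {
    if (attractor$length != 1L) {
      stop("inconsistent reduction: cyclic attractor on an empty core",
           call. = FALSE)
    }
    st <- matrix(integer(0), nrow = 1L, ncol = 0L)
    return(structure(list(states = st, length = 1L), class = "bn_attractor"))
  }
  keep <- match(core$nodes, full_nodes)
  if (anyNA(keep)) stop("attractor/network node mismatch", call. = FALSE)
  proj <- unique(attractor$states[, keep, drop = FALSE])
  red <- new_attractor(proj, core$nodes)
  # assert the projection is a genuine core attractor
  for (i in seq_len(red$length)) {
    nxt <- synchronous_step(core, red$states[i, ])
    expect <- red$states[if (i == red$length) 1L else i + 1L, ]
    if (!all(nxt == expect)) {
      stop("inconsistent reduction: projected cycle is not a core attractor",
           call. = FALSE)
    }
  }
  red
}

#' Per-node classification report
#'
#' @param net a `boolean_network`.
#' @return data.frame with columns `node` and `class`, where `class` is one
#'   of `symmetric(round k)`, `deterministic`, `nondeterministic`, or
#'   `nondeterministic-with-det-input`.
#' @export
classification_report <- function(net) {
  nc <- node_classification(net)
  cls <- setNames(rep(NA_character_, length(net$nodes)), net$nodes)
  for (k in seq_along(nc$peeling$symmetric_rounds)) {
    cls[nc$peeling$symmetric_rounds[[k]]] <- sprintf("symmetric(round %d)", k)
  }
  if (!is.null(nc$classification)) {
    cl <- nc$classification
    cls[cl$v_det] <- "deterministic"
    cls[cl$v_nondet] <- "nondeterministic"
    cls[cl$v_nondet_inputdet] <- "nondeterministic-with-det-input"
  }
  data.frame(node = net$nodes, class = unname(cls[net$nodes]),
             stringsAsFactors = FALSE)
}
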