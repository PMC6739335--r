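# Hierarchical backward identification of the exact basin of attraction.
#
# Working on the peeled core, predecessors of a target state are found by
# (i) inverting the "deterministic equations": if y's only essential input
# is x, then x(t) = f^{-1}(y(t+1)) -- a 1-input rule surviving pruning is
# identity or negation, hence invertible; and (ii) solving the remaining
# Boolean constraints f_v(prev) = target[v] over the nondeterministic
# coordinates by unit propagation with branching, emitting wildcard cubes
# for don't-care variables. Every node's equation is enforced, so the
# result is the exact preimage. Because the synchronous map is a function,
# preimages of disjoint sets are disjoint: the backward layers never
# reconverge and no global deduplication is needed -- only the attractor's
# own states are excluded (cycle closure), which keeps local basins of
# distinct attractor states disjoint.

#' Deterministic-equation inverse map
#'
#' For each deterministic core node x, records all indegree-1 nodes whose
#' sole essential input is x together with their (invertible) 1-input
#' tables. The first target supplies the primary inverse; the rest serve as
#' consistency checks (contradictory forced values mean the target state
#' has no predecessor).
#'
#' @param core core `boolean_network`.
#' @param classification result of [classify_deterministic()].
#' @return named list: per deterministic node, `targets` (character) and
#'   `tables` (list of length-2 0/1 vectors, `table[v+1] = f(v)`).
#' @export
build_deterministic_inverses <- function(core, classification) {
  inv <- list()
  for (x in classification$v_det) {
    targets <- classification$det_targets[[x]]
    tables <- lapply(targets, function(y) {
      core$rules[[match(y, core$nodes)]]$table
    })
    inv[[x]] <- list(targets = targets, tables = tables)
  }
  inv
}

# invert a 1-input table: which input value maps to observed output v
invert_table1 <- function(table, v) {
  match(v, table) - 1L   # table is invertible (non-constant), so unique
}

#' Sufficient terminal-state conditions
#'
#' Checks the two families of sufficient conditions for a core state to be
#' a terminal basin state (a state with no predecessor): (1) two indegree-1
#' targets of the same deterministic node force contradictory values on it;
#' (2) for a nondeterministic node with deterministic inputs, substituting
#' the forced deterministic values and ranging every nondeterministic input
#' over 0/1 cannot produce the node's observed value. The conditions are
#' sufficient, not necessary: `is_terminal = FALSE` means "unknown".
#'
#' @param core core `boolean_network`.
#' @param classification result of [classify_deterministic()].
#' @param s core state.
#' @param inverses optional precomputed [build_deterministic_inverses()].
#' @return list with `is_terminal` (logical) and `fired` (character vector
#'   of condition identifiers).
#' @export
terminal_check <- function(core, classification, s, inverses = NULL) {
  if (is.null(inverses)) {
    inverses <- build_deterministic_inverses(core, classification)
  }
  s <- as.integer(s)
  nodes <- core$nodes
  fired <- character(0)
  forced <- setNames(rep(NA_integer_, length(nodes)), nodes)
  for (x in names(inverses)) {
    e <- inverses[[x]]
    vals <- vapply(seq_along(e$targets), function(j) {
      invert_table1(e$tables[[j]], s[match(e$targets[j], nodes)])
    }, integer(1))
    if (length(unique(vals)) > 1L) {
      fired <- c(fired, paste0("contradictory-inverse:", x))
    } else {
      forced[x] <- vals[1L]
    }
  }
  if (length(fired) == 0L) {
    for (tau in classification$v_nondet_inputdet) {
      r <- core$rules[[match(tau, nodes)]]
      in_names <- nodes[r$inputs]
      det_pos <- which(!is.na(forced[in_names]))
      free_pos <- setdiff(seq_along(in_names), det_pos)
      base <- 0L
      for (p in det_pos) base <- base + forced[in_names[p]] * 2^(p - 1L)
      m <- length(free_pos)
      attainable <- vapply(0:(2^m - 1), function(b) {
        idx <- base
        for (j in seq_len(m)) {
          idx <- idx + bitwAnd(bitwShiftR(b, j - 1L), 1L) *
            2^(free_pos[j] - 1L)
        }
        r$table[idx + 1L]
      }, integer(1))
      if (!(s[match(tau, nodes)] %in% attainable)) {
        fired <- c(fired, paste0("nondet-unreachable:", tau))
      }
    }
  }
  list(is_terminal = length(fired) > 0L, fired = fired)
}

# ---- exact preimage solver --------------------------------------------------

# Exact preimage of a target cube (0/1/NA vector over core nodes) under the
# core's synchronous map, as a list of disjoint cube rows over the core
# nodes (values at time t). Constraints: f_v(prev) = target[v] for every
# non-wildcard coordinate v; deterministic coordinates are pre-forced by
# the inverse map.
preimage_cubes <- function(core, classification, inverses, target) {
  nodes <- core$nodes
  n <- length(nodes)
  asg <- rep(NA_integer_, n)

  # force deterministic prev values from indegree-1 targets with a value
  for (x in names(inverses)) {
    e <- inverses[[x]]
    xi <- match(x, nodes)
    for (j in seq_along(e$targets)) {
      tv <- target[match(e$targets[j], nodes)]
      if (is.na(tv)) next
      v <- invert_table1(e$tables[[j]], tv)
      if (!is.na(asg[xi]) && asg[xi] != v) return(NULL)  # Eq.2 contradiction
      asg[xi] <- v
    }
  }

  constraints <- list()
  for (v in which(!is.na(target))) {
    r <- core$rules[[v]]
    constraints[[length(constraints) + 1L]] <-
      list(inputs = r$inputs, table = r$table, value = target[v])
  }

  out <- list()
  solve <- function(asg, active) {
    # unit propagation to fixpoint
    repeat {
      changed <- FALSE
      drop <- logical(length(active))
      for (ci in seq_along(active)) {
        cst <- active[[ci]]
        k <- length(cst$inputs)
        rows <- 0:(2^k - 1)
        ok <- cst$table[rows + 1L] == cst$value
        for (j in seq_len(k)) {
          av <- asg[cst$inputs[j]]
          if (!is.na(av)) {
            ok <- ok & (bitwAnd(bitwShiftR(rows, j - 1L), 1L) == av)
          }
        }
        n_comp <- sum(ok)
        if (n_comp == 0L) return(invisible(NULL))
        unknown <- which(is.na(asg[cst$inputs]))
        n_free_rows <- 2^length(unknown)
        if (n_comp == n_free_rows) { drop[ci] <- TRUE; next }
        comp <- rows[ok]
        for (j in unknown) {
          bits <- bitwAnd(bitwShiftR(comp, j - 1L), 1L)
          if (all(bits == bits[1L])) {
            asg[cst$inputs[j]] <- bits[1L]
            changed <- TRUE
          }
        }
      }
      active <- active[!drop]
      if (!changed) break
    }
    if (length(active) == 0L) {
      out[[length(out) + 1L]] <<- asg
      return(invisible(NULL))
    }
    # branch on the unassigned variable occurring in most constraints
    occ <- integer(n)
    for (cst in active) {
      u <- cst$inputs[is.na(asg[cst$inputs])]
      occ[u] <- occ[u] + 1L
    }
    b <- which.max(occ)
    for (val in c(0L, 1L)) {
      a2 <- asg
      a2[b] <- val
      solve(a2, active)
    }
    invisible(NULL)
  }
  solve(asg, constraints)
  if (length(out) == 0L) return(NULL)
  do.call(rbind, out)
}

#' Exact predecessors of a core state
#'
#' @param core core `boolean_network`.
#' @param classification result of [classify_deterministic()].
#' @param s core state.
#' @param inverses optional precomputed inverse map.
#' @return `state_cubes` over the core nodes: exactly the states mapping to
#'   `s` in one synchronous step (possibly empty).
#' @export
predecessor_states <- function(core, classification, s, inverses = NULL) {
  if (is.null(inverses)) {
    inverses <- build_deterministic_inverses(core, classification)
  }
  mat <- preimage_cubes(core, classification, inverses, as.integer(s))
  new_cubes(mat, core$nodes)
}

#' Local basin of one attractor state of the core
#'
#' Breadth-first backward layering: layer 1 is the attractor state itself;
#' each next layer is the exact preimage of the current layer with the
#' attractor's own states removed (so local basins of distinct attractor
#' states stay disjoint). Full states satisfying a sufficient terminal
#' condition are not expanded; for other states the exact (empty) preimage
#' terminates the branch anyway.
#'
#' @param core core `boolean_network`.
#' @param classification result of [classify_deterministic()].
#' @param s_q an attractor state of the core.
#' @param attractor_states matrix of all reduced-attractor states.
#' @param inverses optional precomputed inverse map.
#' @param use_terminal_check use the sufficient conditions as a pruning
#'   accelerator (result is identical either way).
#' @param max_cubes abort exact mode when the stored cube count exceeds
#'   this (larger runs need cluster-scale memory).
#' @return list with `cubes` (`state_cubes`, the local basin including
#'   `s_q`), `layers` (layer index per cube) and `terminal_states` (matrix
#'   of full states found to have no predecessor).
#' @export
local_basin <- function(core, classification, s_q, attractor_states,
                        inverses = NULL, use_terminal_check = TRUE,
                        max_cubes = 1e6) {
  if (is.null(inverses)) {
    inverses <- build_deterministic_inverses(core, classification)
  }
  n <- length(core$nodes)
  acc <- list(matrix(as.integer(s_q), nrow = 1L))
  layer_of <- 1L
  terminal <- list()
  frontier <- acc[[1L]]
  layer <- 1L
  total <- 1L
  while (nrow(frontier) > 0L) {
    nxt <- list()
    for (i in seq_len(nrow(frontier))) {
      tc <- frontier[i, ]
      full <- !anyNA(tc)
      if (full && use_terminal_check) {
        chk <- terminal_check(core, classification, tc, inverses)
        if (chk$is_terminal) {
          terminal[[length(terminal) + 1L]] <- tc
          next
        }
      }
      pre <- preimage_cubes(core, classification, inverses, tc)
      if (is.null(pre)) {
        if (full) terminal[[length(terminal) + 1L]] <- tc
        next
      }
      pre <- cubes_subtract_states(new_cubes(pre, core$nodes),
                                   attractor_states)$mat
      if (nrow(pre) == 0L) next
      nxt[[length(nxt) + 1L]] <- pre
    }
    frontier <- if (length(nxt) > 0L) do.call(rbind, nxt) else
      matrix(integer(0), 0L, n)
    if (nrow(frontier) > 0L) {
      layer <- layer + 1L
      acc[[length(acc) + 1L]] <- frontier
      layer_of <- c(layer_of, rep(layer, nrow(frontier)))
      total <- total + nrow(frontier)
      if (total > max_cubes) {
        stop("exact basin mode aborted: stored cube count exceeded ",
             max_cubes, " (increase max_cubes or use the Monte-Carlo ",
             "landscape)", call. = FALSE)
      }
    }
  }
  mat <- do.call(rbind, acc)
  list(cubes = new_cubes(mat, core$nodes),
       layers = layer_of,
       terminal_states = if (length(terminal) > 0L)
         do.call(rbind, terminal) else matrix(integer(0), 0L, n))
}

# ---- full-network basin -----------------------------------------------------

#' Exact basin of attraction of an attractor
#'
#' Runs the whole pipeline: peel symmetric nodes, project the attractor
#' onto the core, classify the core, compute the local basin of each
#' reduced-attractor state backward, take their (disjoint) union, and lift
#' the result over all symmetric-node value combinations. The basin of the
#' full network is `{sym values arbitrary} x {core coordinates in the
#' reduced basin}` and its exact size is `reduced count * 2^n_sym`.
#'
#' @param net a `boolean_network`.
#' @param attractor a `bn_attractor` of `net` (checked by stepping).
#' @param use_terminal_check,max_cubes see [local_basin()].
#' @return object of class `basin_result`.
#' @export
basin_of_attractor <- function(net, attractor, use_terminal_check = TRUE,
                               max_cubes = 1e6) {
  # the attractor must be reproduced by forward stepping
  for (i in seq_len(attractor$length)) {
    nxt <- synchronous_step(net, attractor$states[i, ])
    expect <- attractor$states[if (i == attractor$length) 1L else i + 1L, ]
    if (!all(nxt == expect)) {
      stop("not an attractor of this network (forward step mismatch)",
           call. = FALSE)
    }
  }
  peeling <- peel_symmetric_nodes(net)
  red <- project_attractor(attractor, peeling)
  n_sym <- length(peeling$symmetric_nodes)
  if (is.null(peeling$core)) {
    cubes <- new_cubes(matrix(integer(0), 1L, 0L), character(0))
    res <- list(network = net, attractor = attractor,
                reduced_attractor = red, peeling = peeling,
                classification = NULL, cubes = cubes,
                local_basins = list(cubes), layers = 1L,
                terminal_states = matrix(integer(0), 0L, 0L),
                n_sym = n_sym, reduced_count = 1,
                full_count = 2^n_sym)
    return(structure(res, class = "basin_result"))
  }
  core <- peeling$core
  classification <- classify_deterministic(core)
  inverses <- build_deterministic_inverses(core, classification)
  lbs <- lapply(seq_len(red$length), function(q) {
    local_basin(core, classification, red$states[q, ], red$states,
                inverses, use_terminal_check, max_cubes)
  })
  mat <- do.call(rbind, lapply(lbs, function(lb) lb$cubes$mat))
  cubes <- new_cubes(mat, core$nodes)
  reduced_count <- cube_count(cubes)
  res <- list(network = net, attractor = attractor,
              reduced_attractor = red, peeling = peeling,
              classification = classification, cubes = cubes,
              local_basins = lapply(lbs, `[[`, "cubes"),
              layers = unlist(lapply(lbs, `[[`, "layers")),
              terminal_states = do.call(rbind, lapply(lbs, `[[`,
                                                      "terminal_states")),
              n_sym = n_sym, reduced_count = reduced_count,
              full_count = reduced_count * 2^n_sym)
  structure(res, class = "basin_result")
}

#' @export
print.basin_result <- function(x, ...) {
  cat("Exact basin of attraction\n")
  cat("  network:", length(x$network$nodes), "nodes;",
      x$n_sym, "symmetric,", length(x$cubes$nodes), "core\n")
  cat("  attractor length:", x$attractor$length, "\n")
  cat("  reduced basin:", sprintf("%.0f", x$reduced_count), "states in",
      nrow(x$cubes$mat), "cubes\n")
  cat("  full basin size:", sprintf("%.0f", x$full_count),
      sprintf("(fraction %.6g of 2^%d)",
              x$full_count / 2^length(x$network$nodes),
              length(x$network$nodes)), "\n")
  invisible(x)
}

#' Membership test against a computed basin
#'
#' @param basin a `basin_result`.
#' @param s full-network state.
#' @return TRUE iff `s` converges to the basin's attractor (symmetric
#'   coordinates are free; the core coordinates are matched against the
#'   reduced basin's cubes).
#' @export
basin_contains <- function(basin, s) {
  s <- as.integer(s)
  nodes <- basin$network$nodes
  if (length(s) != length(nodes)) {
    stop("state width does not match network", call. = FALSE)
  }
  if (length(basin$cubes$nodes) == 0L) return(TRUE)
  core_idx <- match(basin$cubes$nodes, nodes)
  cube_member(basin$cubes, s[core_idx])
}

#' Union of basins of several desired attractors
#'
#' Basins of distinct attractors are disjoint, so the exact union count is
#' the sum of the individual counts and membership is the disjunction.
#'
#' @param results list of `basin_result` objects on the same network.
#' @return object of class `basin_union` with `full_count` and the parts.
#' @export
basin_union <- function(results) {
  if (length(results) == 0L) stop("empty basin list", call. = FALSE)
  ref <- results[[1L]]$network$nodes
  keys <- vapply(results, function(b) attractor_key(b$attractor),
                 character(1))
  for (b in results) {
    if (!identical(b$network$nodes, ref)) {
      stop("basins come from different networks", call. = FALSE)
    }
  }
  keep <- !duplicated(keys)   # union of a basin with itself is itself
  results <- results[keep]
  structure(list(parts = results,
                 full_count = sum(vapply(results, `[[`, numeric(1),
                                         "full_count"))),
            class = "basin_union")
}

#' @export
print.basin_union <- function(x, ...) {
  cat("Union of", length(x$parts), "attractor basins:",
      sprintf("%.0f", x$full_count), "states\n")
  invisible(x)
}

#' @rdname basin_contains
#' @export
basin_union_contains <- function(basin, s) {
  any(vapply(basin$parts, basin_contains, logical(1), s = s))
}

#' Explicit states of a computed basin
#'
#' Lifts the reduced-basin cubes over all symmetric-node combinations and
#' expands them to an explicit full-state matrix. Intended for small
#' basins (activity profiles, spot checks); large basins should stay in
#' cube form.
#'
#' @param basin a `basin_result`.
#' @param max_states refuse to expand beyond this many states.
#' @return integer matrix, one basin state per row, columns named by node.
#' @export
basin_states <- function(basin, max_states = 2^20) {
  nodes <- basin$network$nodes
  full <- matrix(NA_integer_, nrow = nrow(basin$cubes$mat),
                 ncol = length(nodes))
  if (length(basin$cubes$nodes) > 0L) {
    full[, match(basin$cubes$nodes, nodes)] <- basin$cubes$mat
  }
  cubes_expand(new_cubes(full, nodes), max_states = max_states)
}
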