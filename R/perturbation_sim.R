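# Temporary vs persistent intervention simulation. A temporary (one-time)
# perturbation overwrites node values once and lets the network evolve
# freely; a persistent perturbation clamps the targets every step, which
# spreads indirectly: nodes whose rules become constant given the already
# fixed values are fixed in turn, stage by stage, until (possibly) the
# whole state is pinned.

#' One-time temporary perturbation
#'
#' Overwrites the given node values once, then follows the free synchronous
#' dynamics to an attractor.
#'
#' @param net a `boolean_network`.
#' @param state starting state.
#' @param assignments named 0/1 vector of node values to set (may be
#'   empty).
#' @return list with `perturbed_state`, `trajectory` (matrix, first row =
#'   perturbed state, last rows on the attractor), `attractor` and
#'   `transient`.
#' @export
temporary_perturbation <- function(net, state, assignments = integer(0)) {
  s <- as_state(state, net$nodes)
  if (length(assignments) > 0L) {
    idx <- match(names(assignments), net$nodes)
    if (anyNA(idx)) stop("unknown node in assignments", call. = FALSE)
    s[idx] <- as.integer(assignments)
  }
  fa <- find_attractor(net, s)
  # trajectory from the perturbed state through one full pass of the cycle
  n_rows <- fa$transient + fa$attractor$length
  traj <- matrix(NA_integer_, nrow = n_rows, ncol = length(net$nodes),
                 dimnames = list(NULL, net$nodes))
  cur <- s
  for (t in seq_len(n_rows)) {
    traj[t, ] <- cur
    if (t < n_rows) cur <- synchronous_step(net, cur)
  }
  list(perturbed_state = s, trajectory = traj,
       attractor = fa$attractor, transient = fa$transient)
}

#' Indirect fixation cascade under persistent clamping
#'
#' Stage 1 is the clamped pattern itself; stage k+1 adds every node whose
#' rule is constant over all completions of the stage-k pattern (decided by
#' exact truth-table restriction). The fixed set grows monotonically and
#' closes in at most n stages. When the closure pins every node, the final
#' state is a fixed point of the clamped network.
#'
#' @param net a `boolean_network`.
#' @param clamps named 0/1 vector of persistently fixed nodes.
#' @return object of class `fixation_cascade`: `stages` (list of named 0/1
#'   vectors of newly fixed nodes), `total_states` (stage count when the
#'   cascade completes, else NA), `transitions` (`total_states - 1`),
#'   `complete`, `final_state` (when complete) and `residual_nodes`.
#' @export
persistent_fixation_cascade <- function(net, clamps) {
  nodes <- net$nodes
  idx <- match(names(clamps), nodes)
  if (anyNA(idx)) stop("unknown node in clamps", call. = FALSE)
  fixed <- setNames(rep(NA_integer_, length(nodes)), nodes)
  fixed[idx] <- as.integer(clamps)
  stages <- list(setNames(as.integer(clamps), names(clamps)))
  repeat {
    fixed_idx <- which(!is.na(fixed))
    newly <- integer(0)
    for (i in seq_along(nodes)) {
      r <- restrict_rule(net$rules[[i]], fixed_idx, fixed[fixed_idx])
      if (length(r$inputs) == 0L) {
        v <- r$table[1L]
        if (i %in% idx) next                  # clamp overrides the rule
        if (!is.na(fixed[i])) next            # already fixed (stays fixed)
        newly[nodes[i]] <- v
      }
    }
    if (length(newly) == 0L) break
    fixed[names(newly)] <- newly
    stages[[length(stages) + 1L]] <- newly
  }
  complete <- !anyNA(fixed)
  structure(list(stages = stages,
                 total_states = if (complete) length(stages) else
                   NA_integer_,
                 transitions = if (complete) length(stages) - 1L else
                   NA_integer_,
                 complete = complete,
                 final_state = if (complete) fixed else NULL,
                 residual_nodes = nodes[is.na(fixed)]),
            class = "fixation_cascade")
}

#' @export
print.fixation_cascade <- function(x, ...) {
  cat("Persistent-clamping fixation cascade\n")
  for (k in seq_along(x$stages)) {
    st <- x$stages[[k]]
    cat(sprintf("  stage %d: %d node(s) fixed (%s)\n", k, length(st),
                paste(sprintf("%s=%d", names(st), st), collapse = ", ")))
  }
  if (x$complete) {
    cat("  complete after", x$total_states, "states (",
        x$transitions, "transitions )\n")
  } else {
    cat("  incomplete; free nodes:",
        paste(x$residual_nodes, collapse = ", "), "\n")
  }
  invisible(x)
}

# one synchronous step of the clamped dynamics
clamped_step <- function(net, s, clamp_idx, clamp_val) {
  nxt <- synchronous_step(net, s)
  nxt[clamp_idx] <- clamp_val
  nxt
}

#' Success rate of an interrupted persistent perturbation
#'
#' Clamps are held for `interrupt_step` transitions (with the clamped
#' values imposed from the start), then released; the free dynamics is
#' followed to its attractor and success means reaching a desired
#' attractor. With `interrupt_step = 0` no clamping is applied at all, so
#' the rate is the sample's unperturbed desired-basin fraction.
#'
#' @param net a `boolean_network`.
#' @param clamps named 0/1 vector.
#' @param interrupt_step number of clamped transitions before release.
#' @param initial_states matrix of initial states (one per row), or NULL
#'   to sample.
#' @param n_samples,seed sampling controls when `initial_states` is NULL.
#' @param desired either a list of `bn_attractor`s or a
#'   [phenotype_condition()] defining success.
#' @return list with `rate`, `se` (binomial standard error) and `n`.
#' @export
interruption_success_rate <- function(net, clamps, interrupt_step,
                                      initial_states = NULL,
                                      n_samples = 1000L, seed = NULL,
                                      desired) {
  stopifnot(interrupt_step >= 0L)
  if (is.null(initial_states)) {
    if (!is.null(seed)) {
      initial_states <- with_seed(seed, random_states(n_samples,
                                                      length(net$nodes)))
    } else {
      initial_states <- random_states(n_samples, length(net$nodes))
    }
  }
  clamp_idx <- match(names(clamps), net$nodes)
  clamp_val <- as.integer(clamps)
  ok <- logical(nrow(initial_states))
  for (i in seq_len(nrow(initial_states))) {
    s <- as.integer(initial_states[i, ])
    if (interrupt_step > 0L) {
      s[clamp_idx] <- clamp_val
      for (t in seq_len(interrupt_step)) {
        s <- clamped_step(net, s, clamp_idx, clamp_val)
      }
    }
    attr_f <- find_attractor(net, s)$attractor
    ok[i] <- attractor_is_desired(attr_f, desired)
  }
  p <- mean(ok)
  n <- length(ok)
  list(rate = p, se = sqrt(p * (1 - p) / n), n = n)
}

# success test shared by simulation entry points: `desired` is a list of
# attractors or a phenotype condition
attractor_is_desired <- function(attr, desired) {
  if (inherits(desired, "phenotype_condition")) {
    return(attractor_satisfies(attr, desired))
  }
  if (inherits(desired, "bn_attractor")) desired <- list(desired)
  attractor_key(attr) %in% vapply(desired, attractor_key, character(1))
}

random_states <- function(n, width) {
  matrix(sample(c(0L, 1L), n * width, replace = TRUE), nrow = n)
}

# evaluate a callback under a temporary RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  expr
}
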