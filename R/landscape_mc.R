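# Monte-Carlo attractor-landscape estimation and the node-level summaries
# used to relate control targets to activity differences between undesired
# and desired states.

#' Phenotype condition labelling attractors
#'
#' An attractor satisfies the condition when every constrained node holds
#' its required value in every attractor state (constant over the
#' attractor). The condition's negation (all constrained nodes constantly
#' at the opposite value) labels the undesired attractors; attractors
#' matching neither are "other".
#'
#' @param constraints named 0/1 vector, e.g. `c(Proliferation = 0)`.
#' @return object of class `phenotype_condition`.
#' @export
phenotype_condition <- function(constraints) {
  vals <- as.integer(constraints)
  if (is.null(names(constraints)) || !all(vals %in% c(0L, 1L))) {
    stop("constraints must be a named 0/1 vector", call. = FALSE)
  }
  structure(list(constraints = setNames(vals, names(constraints))),
            class = "phenotype_condition")
}

#' @rdname phenotype_condition
#' @param attractor a `bn_attractor`.
#' @param condition a `phenotype_condition`.
#' @export
attractor_satisfies <- function(attractor, condition) {
  nms <- names(condition$constraints)
  idx <- match(nms, colnames(attractor$states))
  if (anyNA(idx)) stop("phenotype node not in network", call. = FALSE)
  all(vapply(seq_along(idx), function(j) {
    all(attractor$states[, idx[j]] == condition$constraints[j])
  }, logical(1)))
}

attractor_phenotype_label <- function(attractor, condition) {
  if (is.null(condition)) return("unlabelled")
  if (attractor_satisfies(attractor, condition)) return("desired")
  anti <- phenotype_condition(1L - condition$constraints)
  if (attractor_satisfies(attractor, anti)) return("undesired")
  "other"
}

#' Monte-Carlo attractor landscape
#'
#' Samples uniform random initial states, follows each to its attractor,
#' pools attractors by their canonical form and reports estimated basin
#' fractions with binomial standard errors. With a phenotype condition the
#' attractors are labelled desired / undesired / other.
#'
#' @param net a `boolean_network`.
#' @param n_samples number of random initial states.
#' @param seed RNG seed (runs are bit-reproducible for a given seed).
#' @param phenotype optional [phenotype_condition()].
#' @return object of class `landscape_summary`: `attractors`, `labels`,
#'   `counts`, `basin_ratio`, `se`, `n_samples`, `seed`, and
#'   `sample_labels` (attractor index per sample, for reuse).
#' @export
mc_attractor_landscape <- function(net, n_samples = 10000L, seed = 1L,
                                   phenotype = NULL) {
  states <- with_seed(seed, random_states(n_samples, length(net$nodes)))
  pool <- new.env(hash = TRUE, parent = emptyenv())
  attractors <- list()
  labels <- integer(n_samples)
  for (i in seq_len(n_samples)) {
    a <- find_attractor(net, states[i, ])$attractor
    key <- attractor_key(a)
    id <- pool[[key]]
    if (is.null(id)) {
      attractors[[length(attractors) + 1L]] <- a
      id <- length(attractors)
      pool[[key]] <- id
    }
    labels[i] <- id
  }
  counts <- tabulate(labels, nbins = length(attractors))
  p <- counts / n_samples
  structure(list(attractors = attractors,
                 labels = vapply(attractors, attractor_phenotype_label,
                                 character(1), condition = phenotype),
                 counts = counts,
                 basin_ratio = p,
                 se = sqrt(p * (1 - p) / n_samples),
                 n_samples = n_samples,
                 seed = seed,
                 sample_labels = labels,
                 sample_states = states),
            class = "landscape_summary")
}

#' @export
print.landscape_summary <- function(x, ...) {
  cat("Monte-Carlo attractor landscape (", x$n_samples, "samples )\n")
  for (i in seq_along(x$attractors)) {
    cat(sprintf("  attractor %d: length %d, ratio %.4f +/- %.4f [%s]\n",
                i, x$attractors[[i]]$length, x$basin_ratio[i], x$se[i],
                x$labels[i]))
  }
  invisible(x)
}

#' Sample random states converging to a given phenotype
#'
#' Rejection sampling: uniform random states are kept when their attractor
#' carries the requested label under the phenotype condition.
#'
#' @param net a `boolean_network`.
#' @param phenotype a [phenotype_condition()].
#' @param polarity `"desired"` or `"undesired"`.
#' @param n number of states to return.
#' @param seed RNG seed.
#' @param max_attempts cap on total draws; if reached, an error reports the
#'   achieved count (acceptance probability too small).
#' @return matrix of states (one per row).
#' @export
sample_states_by_phenotype <- function(net, phenotype,
                                       polarity = c("desired", "undesired"),
                                       n, seed = 1L,
                                       max_attempts = 1000L * n) {
  polarity <- match.arg(polarity)
  out <- matrix(NA_integer_, nrow = n, ncol = length(net$nodes),
                dimnames = list(NULL, net$nodes))
  got <- 0L
  with_seed(seed, {
    attempts <- 0L
    while (got < n && attempts < max_attempts) {
      batch <- random_states(min(256L, max_attempts - attempts),
                             length(net$nodes))
      attempts <- attempts + nrow(batch)
      for (i in seq_len(nrow(batch))) {
        a <- find_attractor(net, batch[i, ])$attractor
        if (attractor_phenotype_label(a, phenotype) == polarity) {
          got <- got + 1L
          out[got, ] <- batch[i, ]
          if (got == n) break
        }
      }
    }
  })
  if (got < n) {
    stop("attempt cap reached with ", got, " of ", n, " states of polarity '",
         polarity, "'", call. = FALSE)
  }
  out
}

#' Control-target inclusion probabilities
#'
#' Pools the enumerated minimum control target sets over many undesired
#' states and reports, per node, the fraction of all target sets that
#' contain it (control target probability) and the fraction of its
#' inclusions that assign value 0 (zero-activity probability).
#'
#' @param control_results list of `control_result` objects on one network.
#' @return data.frame with columns `node`, `inclusion_prob`, `zero_prob`,
#'   `n_sets`.
#' @export
control_target_probability <- function(control_results) {
  if (length(control_results) == 0L) stop("empty result list", call. = FALSE)
  nodes <- names(control_results[[1L]]$alpha)
  incl <- setNames(numeric(length(nodes)), nodes)
  zero <- setNames(numeric(length(nodes)), nodes)
  n_sets <- 0L
  for (cr in control_results) {
    for (ts in cr$target_sets) {
      n_sets <- n_sets + 1L
      if (length(ts) == 0L) next
      incl[names(ts)] <- incl[names(ts)] + 1
      z <- names(ts)[ts == 0L]
      zero[z] <- zero[z] + 1
    }
  }
  data.frame(node = nodes,
             inclusion_prob = unname(incl / n_sets),
             zero_prob = unname(ifelse(incl > 0, zero / incl, NA_real_)),
             n_sets = n_sets,
             stringsAsFactors = FALSE)
}

#' Mean activity level per node over a state collection
#'
#' @param states matrix of states (one per row, columns named by node).
#' @return data.frame with columns `node` and `activity`.
#' @export
activity_level_profile <- function(states) {
  if (nrow(states) == 0L) stop("empty state collection", call. = FALSE)
  data.frame(node = colnames(states), activity = unname(colMeans(states)),
             stringsAsFactors = FALSE)
}

#' Correlation between activity difference and control-target probability
#'
#' Tests whether nodes whose mean activity differs more between undesired
#' and desired states are more likely to appear in control target sets
#' (Pearson correlation of `|V_undesired - V_desired|` with the inclusion
#' probability), and tabulates the signed difference against the
#' zero-activity probability.
#'
#' @param profile_undesired,profile_desired data.frames from
#'   [activity_level_profile()] over undesired/desired state collections.
#' @param inclusion data.frame from [control_target_probability()].
#' @return list with `r`, `p` and `table` (per-node signed difference,
#'   absolute difference, inclusion and zero-activity probabilities).
#' @export
difference_correlation <- function(profile_undesired, profile_desired,
                                   inclusion) {
  nodes <- inclusion$node
  vu <- profile_undesired$activity[match(nodes, profile_undesired$node)]
  vd <- profile_desired$activity[match(nodes, profile_desired$node)]
  diff_abs <- abs(vu - vd)
  pr <- inclusion$inclusion_prob
  keep <- !is.na(diff_abs) & !is.na(pr)
  if (sum(keep) < 3L) stop("need at least 3 nodes", call. = FALSE)
  if (stats::sd(diff_abs[keep]) == 0 || stats::sd(pr[keep]) == 0) {
    stop("undefined correlation: zero variance", call. = FALSE)
  }
  ct <- stats::cor.test(diff_abs[keep], pr[keep], method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value,
       table = data.frame(node = nodes,
                          diff_signed = vu - vd,
                          diff_abs = diff_abs,
                          inclusion_prob = pr,
                          zero_prob = inclusion$zero_prob,
                          stringsAsFactors = FALSE))
}
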