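# Boundary-reaching control: given an undesired state alpha and the exact
# basin of a desired attractor, find the minimum number of one-time node
# flips (mHD) that place alpha inside the basin, and enumerate every
# minimum control target set. The decomposition of basin nodes into
# symmetric / fixed / unfixed makes the distance separable:
# mHD = rho_fixed (mandatory corrections of fixed nodes) + rho_unfixed
# (best match over the unfixed coordinates of any basin member).

#' Decompose basin nodes into symmetric / fixed / unfixed
#'
#' Fixed nodes take one value in every basin member (read off the cube
#' columns). Symmetric nodes are the structurally peeled nodes plus any
#' core node whose single flip maps the reduced basin onto itself
#' (verified over the cube set; a node failing verification stays
#' unfixed). The remaining core nodes are unfixed.
#'
#' @param basin a `basin_result`.
#' @return object of class `basin_decomposition` with `symmetric`
#'   (character), `fixed` (named 0/1 vector) and `unfixed` (character).
#' @export
decompose_basin_nodes <- function(basin) {
  if (basin$full_count == 0) stop("empty basin", call. = FALSE)
  cubes <- basin$cubes
  mat <- cubes$mat
  core_nodes <- cubes$nodes
  fixed <- integer(0)
  sym_core <- character(0)
  unfixed <- character(0)
  for (j in seq_along(core_nodes)) {
    col <- mat[, j]
    vals <- unique(col[!is.na(col)])
    if (!anyNA(col) && length(vals) == 1L) {
      fixed[core_nodes[j]] <- vals
    } else if (cubes_flip_closed(cubes, j)) {
      sym_core <- c(sym_core, core_nodes[j])
    } else {
      unfixed <- c(unfixed, core_nodes[j])
    }
  }
  structure(list(symmetric = c(basin$peeling$symmetric_nodes, sym_core),
                 symmetric_core = sym_core,
                 fixed = fixed,
                 unfixed = unfixed),
            class = "basin_decomposition")
}

#' @export
print.basin_decomposition <- function(x, ...) {
  cat("Basin node decomposition\n")
  cat("  symmetric:", paste(x$symmetric, collapse = ", "), "\n")
  cat("  fixed:    ",
      paste(sprintf("%s=%d", names(x$fixed), x$fixed), collapse = ", "),
      "\n")
  cat("  unfixed:  ", paste(x$unfixed, collapse = ", "), "\n")
  invisible(x)
}

# per-cube mismatch positions of alpha on the non-fixed core coordinates;
# returns list(min = rho_unfixed, sets = list of unique index vectors into
# the core nodes achieving the minimum)
cube_mismatch_sets <- function(basin, decomposition, alpha_core) {
  mat <- basin$cubes$mat
  core_nodes <- basin$cubes$nodes
  fixed_j <- match(names(decomposition$fixed), core_nodes)
  cand_j <- setdiff(seq_along(core_nodes), fixed_j)
  if (nrow(mat) == 0L) return(list(min = Inf, sets = list()))
  mism <- lapply(seq_len(nrow(mat)), function(i) {
    r <- mat[i, cand_j]
    a <- alpha_core[cand_j]
    cand_j[!is.na(r) & r != a]
  })
  counts <- lengths(mism)
  rho <- min(counts)
  sets <- unique(mism[counts == rho])
  list(min = rho, sets = sets)
}

#' Minimum Hamming distance from a state to a basin
#'
#' `rho_fixed` counts fixed basin nodes where `alpha` disagrees with the
#' fixed value; `rho_unfixed` is the minimum Hamming distance between
#' `alpha`'s remaining core coordinates and those of any basin member
#' (computed over the cubes); symmetric nodes contribute nothing.
#'
#' @param alpha full-network state (not required to be outside the basin;
#'   members get distance 0).
#' @param basin a `basin_result`.
#' @param decomposition optional precomputed [decompose_basin_nodes()].
#' @return list with `mhd`, `rho_fixed`, `rho_unfixed`.
#' @export
minimum_hamming_distance <- function(alpha, basin, decomposition = NULL) {
  if (is.null(decomposition)) decomposition <- decompose_basin_nodes(basin)
  alpha <- as_state(alpha, basin$network$nodes)
  if (basin_contains(basin, alpha)) {
    return(list(mhd = 0L, rho_fixed = 0L, rho_unfixed = 0L))
  }
  core_idx <- match(basin$cubes$nodes, basin$network$nodes)
  alpha_core <- alpha[core_idx]
  names(alpha_core) <- basin$cubes$nodes
  rho_fixed <- sum(alpha_core[names(decomposition$fixed)] !=
                     decomposition$fixed)
  mm <- cube_mismatch_sets(basin, decomposition, alpha_core)
  list(mhd = as.integer(rho_fixed + mm$min),
       rho_fixed = as.integer(rho_fixed),
       rho_unfixed = as.integer(mm$min))
}

#' Enumerate all minimum control target sets
#'
#' Every minimum control target set consists of the mandatory fixed-node
#' corrections plus one tuple of unfixed-node flips realising
#' `rho_unfixed`; the tuples are exactly the mismatch sets of the cubes
#' attaining the minimum. Applying any target set to `alpha` yields a
#' basin member (the corresponding boundary state).
#'
#' @param alpha undesired full-network state.
#' @param basin a `basin_result`.
#' @param decomposition optional precomputed [decompose_basin_nodes()].
#' @param max_report cap on the number of reported target sets/boundary
#'   states (the exact total is always reported).
#' @return object of class `control_result`: `alpha`, `mhd`, `rho_fixed`,
#'   `rho_unfixed`, `target_sets` (list of named 0/1 vectors),
#'   `boundary_states` (matrix), `index_set_size`, `capped`.
#' @export
control_target_sets <- function(alpha, basin, decomposition = NULL,
                                max_report = 1e4) {
  if (is.null(decomposition)) decomposition <- decompose_basin_nodes(basin)
  alpha <- as_state(alpha, basin$network$nodes)
  nodes <- basin$network$nodes
  if (basin_contains(basin, alpha)) {
    res <- list(alpha = alpha, mhd = 0L, rho_fixed = 0L, rho_unfixed = 0L,
                target_sets = list(setNames(integer(0), character(0))),
                boundary_states = matrix(alpha, nrow = 1L,
                                         dimnames = list(NULL, nodes)),
                index_set_size = 1L, capped = FALSE)
    return(structure(res, class = "control_result"))
  }
  core_nodes <- basin$cubes$nodes
  core_idx <- match(core_nodes, nodes)
  alpha_core <- alpha[core_idx]
  names(alpha_core) <- core_nodes
  fixed_mismatch <- names(decomposition$fixed)[
    alpha_core[names(decomposition$fixed)] != decomposition$fixed]
  mm <- cube_mismatch_sets(basin, decomposition, alpha_core)
  total <- length(mm$sets)
  capped <- total > max_report
  use <- mm$sets[seq_len(min(total, max_report))]
  target_sets <- lapply(use, function(set_j) {
    nms <- c(fixed_mismatch, core_nodes[set_j])
    vals <- 1L - alpha[match(nms, nodes)]
    setNames(as.integer(vals), nms)
  })
  boundary <- t(vapply(target_sets, function(ts) {
    s <- alpha
    s[match(names(ts), nodes)] <- ts
    s
  }, integer(length(nodes))))
  colnames(boundary) <- nodes
  for (i in seq_len(nrow(boundary))) {
    if (!basin_contains(basin, boundary[i, ])) {
      stop("internal error: boundary state outside the basin", call. = FALSE)
    }
  }
  res <- list(alpha = alpha,
              mhd = as.integer(length(fixed_mismatch) + mm$min),
              rho_fixed = length(fixed_mismatch),
              rho_unfixed = as.integer(mm$min),
              target_sets = target_sets,
              boundary_states = boundary,
              index_set_size = total,
              capped = capped)
  structure(res, class = "control_result")
}

#' @export
print.control_result <- function(x, ...) {
  cat("Boundary-reaching control result\n")
  cat("  alpha:", state_string(x$alpha), "\n")
  cat("  mHD:", x$mhd, sprintf("(fixed %d + unfixed %d)", x$rho_fixed,
                               x$rho_unfixed), "\n")
  cat("  control target sets:", x$index_set_size,
      if (isTRUE(x$capped)) "(reported list capped)" else "", "\n")
  show <- utils::head(x$target_sets, 5L)
  for (ts in show) {
    cat("   {", paste(sprintf("%s=%d", names(ts), ts), collapse = ", "),
        "}\n")
  }
  if (length(x$target_sets) > 5L) cat("    ...\n")
  invisible(x)
}

#' Forward control search for large desired basins
#'
#' When the desired basin covers most of the state space, control targets
#' can be found without the exact basin: flip sets over the candidate
#' nodes are enumerated breadth-first by size; each flipped state is
#' simulated forward and accepted when it converges to one of the desired
#' attractors. The search stops at the first size with a hit and returns
#' all hits at that size.
#'
#' @param net a `boolean_network`.
#' @param alpha undesired state.
#' @param candidate_nodes character vector of perturbable nodes (default:
#'   all nodes).
#' @param desired_attractors list of `bn_attractor` objects (e.g. from a
#'   Monte-Carlo landscape).
#' @param max_hd largest flip-set size to try.
#' @return a `control_result`-like object with `found`; when no flip set
#'   within `max_hd` works, `found` is FALSE.
#' @export
large_basin_control_search <- function(net, alpha, candidate_nodes = NULL,
                                       desired_attractors, max_hd = 4L) {
  alpha <- as_state(alpha, net$nodes)
  if (is.null(candidate_nodes)) candidate_nodes <- net$nodes
  cand_idx <- match(candidate_nodes, net$nodes)
  if (anyNA(cand_idx)) stop("unknown candidate node(s)", call. = FALSE)
  desired_keys <- vapply(desired_attractors, attractor_key, character(1))
  is_desired <- function(s) {
    attractor_key(find_attractor(net, s)$attractor) %in% desired_keys
  }
  for (size in 0:max_hd) {
    hits <- list()
    combos <- if (size == 0L) list(integer(0)) else
      utils::combn(cand_idx, size, simplify = FALSE)
    for (fl in combos) {
      s <- alpha
      s[fl] <- 1L - s[fl]
      if (is_desired(s)) hits[[length(hits) + 1L]] <- fl
    }
    if (length(hits) > 0L) {
      target_sets <- lapply(hits, function(fl) {
        setNames(1L - alpha[fl], net$nodes[fl])
      })
      boundary <- t(vapply(hits, function(fl) {
        s <- alpha; s[fl] <- 1L - s[fl]; s
      }, integer(length(net$nodes))))
      colnames(boundary) <- net$nodes
      res <- list(alpha = alpha, mhd = size,
                  rho_fixed = NA_integer_, rho_unfixed = NA_integer_,
                  target_sets = target_sets, boundary_states = boundary,
                  index_set_size = length(hits), capped = FALSE,
                  found = TRUE, mode = "forward")
      return(structure(res, class = "control_result"))
    }
  }
  structure(list(alpha = alpha, mhd = NA_integer_, target_sets = list(),
                 boundary_states = NULL, index_set_size = 0L,
                 capped = FALSE, found = FALSE, mode = "forward",
                 max_hd = max_hd),
            class = "control_result")
}
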