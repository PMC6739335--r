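# Compressed state sets: disjoint wildcard patterns ("cubes") over the core
# nodes. A cube is a row with entries 0, 1 or NA (NA = "*", either value).
# All constructors in the basin search emit pairwise-disjoint cubes, so the
# exact cardinality is the plain sum of 2^(number of wildcards) per cube.
# Counts are doubles (exact up to 2^53); export formats them as decimal
# strings to avoid precision loss downstream.

new_cubes <- function(mat, nodes) {
  if (is.null(mat)) mat <- matrix(NA_integer_, nrow = 0L,
                                  ncol = length(nodes))
  if (!is.matrix(mat)) mat <- matrix(mat, nrow = 1L)
  # keep the row count explicit: a zero-column cube (empty pattern over an
  # empty core) still denotes one state per row
  mat <- matrix(as.integer(mat), nrow = nrow(mat), ncol = length(nodes),
                dimnames = list(NULL, nodes))
  structure(list(mat = mat, nodes = nodes), class = "state_cubes")
}

#' Construct a compressed state set from pattern strings
#'
#' @param patterns character vector of patterns over `0`, `1` and `*`.
#' @param nodes character vector naming the coordinates.
#' @return object of class `state_cubes`.
#' @export
state_cubes <- function(patterns, nodes) {
  rows <- lapply(patterns, function(p) {
    ch <- strsplit(p, "", fixed = TRUE)[[1]]
    if (length(ch) != length(nodes)) {
      stop("pattern width does not match node count", call. = FALSE)
    }
    v <- match(ch, c("0", "1")) - 1L   # "*" -> NA
    v
  })
  new_cubes(do.call(rbind, rows), nodes)
}

cube_patterns <- function(cubes) {
  apply(cubes$mat, 1L, function(r) {
    paste(ifelse(is.na(r), "*", as.character(r)), collapse = "")
  })
}

#' @export
print.state_cubes <- function(x, ...) {
  cat("Compressed state set:", nrow(x$mat), "cubes,",
      format(cube_count(x), big.mark = ","), "states over",
      length(x$nodes), "nodes\n")
  pats <- cube_patterns(x)
  show <- utils::head(pats, 10L)
  for (p in show) cat(" ", p, "\n")
  if (length(pats) > 10L) cat("  ...\n")
  invisible(x)
}

#' Exact number of states in a compressed state set
#'
#' @param cubes a `state_cubes` object (cubes are pairwise disjoint).
#' @return double; exact for up to 2^53 states.
#' @export
cube_count <- function(cubes) {
  if (nrow(cubes$mat) == 0L) return(0)
  sum(2^rowSums(is.na(cubes$mat)))
}

#' Membership test against a compressed state set
#'
#' @param cubes a `state_cubes` object.
#' @param s state on the same coordinates.
#' @return TRUE iff some cube matches `s` on every non-wildcard position.
#' @export
cube_member <- function(cubes, s) {
  s <- as.integer(s)
  if (length(s) != ncol(cubes$mat)) {
    stop("state width does not match cube width", call. = FALSE)
  }
  if (nrow(cubes$mat) == 0L) return(FALSE)
  for (i in seq_len(nrow(cubes$mat))) {
    r <- cubes$mat[i, ]
    nz <- !is.na(r)
    if (all(r[nz] == s[nz])) return(TRUE)
  }
  FALSE
}

# subtract a single full state from a cube row; returns matrix of cube rows
cube_minus_state <- function(row, s) {
  fits <- all(row[!is.na(row)] == s[!is.na(row)])
  if (!fits) return(matrix(row, nrow = 1L))
  free <- which(is.na(row))
  if (length(free) == 0L) return(NULL)   # cube was exactly s
  out <- vector("list", length(free))
  cur <- row
  for (j in seq_along(free)) {
    piece <- cur
    piece[free[j]] <- 1L - s[free[j]]
    out[[j]] <- piece
    cur[free[j]] <- s[free[j]]
  }
  do.call(rbind, out)
}

# remove explicit states (matrix rows) from a cube set; stays disjoint/exact
cubes_subtract_states <- function(cubes, states) {
  mat <- cubes$mat
  if (is.vector(states)) states <- matrix(states, nrow = 1L)
  for (k in seq_len(nrow(states))) {
    s <- as.integer(states[k, ])
    pieces <- lapply(seq_len(nrow(mat)), function(i) {
      cube_minus_state(mat[i, ], s)
    })
    mat <- do.call(rbind, pieces)
    if (is.null(mat)) mat <- matrix(NA_integer_, 0L, ncol(cubes$mat))
  }
  new_cubes(mat, cubes$nodes)
}

# is the cube `row` entirely covered by the union of `mat`'s cubes?
cube_covered <- function(row, mat) {
  if (nrow(mat) == 0L) return(FALSE)
  for (i in seq_len(nrow(mat))) {
    r <- mat[i, ]
    conflict <- !is.na(r) & !is.na(row) & r != row
    if (any(conflict)) next
    extra <- which(!is.na(r) & is.na(row))   # coords where r is stricter
    if (length(extra) == 0L) return(TRUE)    # r covers row completely
    # split row on the first stricter coordinate and recurse
    j <- extra[1L]
    r0 <- row; r0[j] <- 0L
    r1 <- row; r1[j] <- 1L
    return(cube_covered(r0, mat) && cube_covered(r1, mat))
  }
  FALSE
}

# is the state set closed under flipping coordinate j?
cubes_flip_closed <- function(cubes, j) {
  mat <- cubes$mat
  if (nrow(mat) == 0L) return(TRUE)
  for (i in seq_len(nrow(mat))) {
    if (is.na(mat[i, j])) next
    flipped <- mat[i, ]
    flipped[j] <- 1L - flipped[j]
    if (!cube_covered(flipped, mat)) return(FALSE)
  }
  TRUE
}

# expand a cube set to an explicit state matrix (small sets only)
cubes_expand <- function(cubes, max_states = 2^20) {
  n <- cube_count(cubes)
  if (n > max_states) {
    stop("refusing to expand ", n, " states (> ", max_states, ")",
         call. = FALSE)
  }
  if (nrow(cubes$mat) == 0L) {
    return(matrix(integer(0), 0L, ncol(cubes$mat),
                  dimnames = list(NULL, cubes$nodes)))
  }
  rows <- lapply(seq_len(nrow(cubes$mat)), function(i) {
    r <- cubes$mat[i, ]
    free <- which(is.na(r))
    if (length(free) == 0L) return(matrix(r, nrow = 1L))
    grid <- as.matrix(expand.grid(rep(list(0:1), length(free))))
    out <- matrix(rep(r, each = nrow(grid)), nrow = nrow(grid))
    out[, free] <- grid
    out
  })
  out <- do.call(rbind, rows)
  colnames(out) <- cubes$nodes
  out
}

# uniformly sample m member states from a (disjoint) cube set
cubes_sample <- function(cubes, m) {
  sizes <- 2^rowSums(is.na(cubes$mat))
  pick <- sample.int(nrow(cubes$mat), m, replace = TRUE,
                     prob = sizes / sum(sizes))
  t(vapply(pick, function(i) {
    r <- cubes$mat[i, ]
    free <- is.na(r)
    r[free] <- sample(c(0L, 1L), sum(free), replace = TRUE)
    r
  }, integer(ncol(cubes$mat))))
}

# column-wise summary over the state set: for each coordinate, the exact
# mean value over all member states (wildcards contribute half weight)
cubes_column_means <- function(cubes) {
  mat <- cubes$mat
  sizes <- 2^rowSums(is.na(mat))
  tot <- sum(sizes)
  means <- vapply(seq_len(ncol(mat)), function(j) {
    v <- mat[, j]
    contrib <- ifelse(is.na(v), sizes / 2, v * sizes)
    sum(contrib) / tot
  }, numeric(1))
  names(means) <- cubes$nodes
  means
}

#' Export a compressed basin as pattern text plus JSON metadata
#'
#' Writes one `0/1/*` pattern per line and a JSON sidecar with the node
#' order and the exact count (as a decimal string).
#'
#' @param cubes a `state_cubes` object.
#' @param file path for the pattern text; metadata goes to `<file>.json`.
#' @return invisibly, the metadata list.
#' @export
write_cubes <- function(cubes, file) {
  writeLines(cube_patterns(cubes), file)
  meta <- list(nodes = cubes$nodes,
               n_cubes = nrow(cubes$mat),
               count = sprintf("%.0f", cube_count(cubes)))
  jsonlite::write_json(meta, paste0(file, ".json"), auto_unbox = TRUE)
  invisible(meta)
}
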