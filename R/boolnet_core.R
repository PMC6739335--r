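# ---- states -----------------------------------------------------------------

#' Parse a state string into a bit vector
#'
#' States are length-n vectors of 0/1 aligned with the network's node order.
#' The string form lists bits in node order, e.g. `"0010100"`.
#'
#' @param x character scalar of 0/1 digits, or a 0/1 vector (returned as-is
#'   after validation).
#' @param nodes optional character vector of node names used to name the bits.
#' @return integer vector of 0/1, named by `nodes` when given.
#' @export
as_state <- function(x, nodes = NULL) {
  if (is.character(x) && length(x) == 1L) {
    bits <- as.integer(strsplit(x, "", fixed = TRUE)[[1]])
  } else {
    bits <- as.integer(x)
  }
  if (anyNA(bits) || !all(bits %in% c(0L, 1L))) {
    stop("state must consist of 0/1 values", call. = FALSE)
  }
  if (!is.null(nodes)) {
    if (length(bits) != length(nodes)) {
      stop("state width ", length(bits), " does not match ", length(nodes),
           " nodes", call. = FALSE)
    }
    names(bits) <- nodes
  }
  bits
}

#' @rdname as_state
#' @param s a state (0/1 vector).
#' @export
state_string <- function(s) paste(as.integer(s), collapse = "")

# Key usable for hashing / canonical ordering. Node 1 is the least significant
# bit, so the minimal-integer-encoding order equals lexicographic order of the
# reversed bit string (works for any width, unlike a numeric encoding).
state_key <- function(s) paste(rev(as.integer(s)), collapse = "")

#' Hamming distance between two states
#'
#' @param a,b states of equal width.
#' @return number of positions where `a` and `b` differ.
#' @export
hamming_distance <- function(a, b) {
  if (length(a) != length(b)) {
    stop("states have different widths (", length(a), " vs ", length(b), ")",
         call. = FALSE)
  }
  sum(as.integer(a) != as.integer(b))
}

# ---- network construction ---------------------------------------------------

# A rule is list(inputs = integer indices into nodes, table = integer 0/1
# vector of length 2^k, indexed with inputs[1] as the least significant bit).
rule_eval <- function(rule, s) {
  k <- length(rule$inputs)
  if (k == 0L) return(rule$table[1L])
  idx <- sum(s[rule$inputs] * 2^(seq_len(k) - 1L)) + 1L
  rule$table[idx]
}

# which inputs the table actually depends on
essential_inputs <- function(table, k) {
  if (k == 0L) return(logical(0))
  idx <- 0:(2^k - 1)
  vapply(seq_len(k), function(j) {
    flip <- bitwXor(idx, 2^(j - 1L))
    any(table[idx + 1L] != table[flip + 1L])
  }, logical(1))
}

# drop inessential inputs from a rule, keeping the restricted table
prune_rule <- function(rule) {
  k <- length(rule$inputs)
  keep <- essential_inputs(rule$table, k)
  if (all(keep)) return(rule)
  kept <- which(keep)
  if (length(kept) == 0L) {
    return(list(inputs = integer(0), table = rule$table[1L]))
  }
  m <- length(kept)
  combs <- 0:(2^m - 1)
  full_idx <- integer(length(combs))
  for (j in seq_len(m)) {
    bit <- bitwAnd(bitwShiftR(combs, j - 1L), 1L)
    full_idx <- full_idx + bit * 2^(kept[j] - 1L)
  }
  list(inputs = rule$inputs[kept], table = rule$table[full_idx + 1L])
}

#' Construct a Boolean network from truth-table rules
#'
#' Inputs that the truth table does not actually depend on are pruned, so the
#' derived edge set reflects functional (essential) dependence. This matters
#' for the structural classifications: a syntactic-only edge would wrongly
#' keep a node's outdegree positive during symmetric-node peeling.
#'
#' @param nodes character vector of unique node names.
#' @param rules named list; each element `list(inputs=, table=)` with `inputs`
#'   node names or indices and `table` an integer 0/1 vector of length
#'   `2^length(inputs)` (first input = least significant bit).
#' @return object of class `boolean_network`.
#' @export
boolean_network <- function(nodes, rules) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicate node names", call. = FALSE)
  if (!setequal(names(rules), nodes)) {
    stop("rules must be named by the declared nodes", call. = FALSE)
  }
  rules <- rules[nodes]
  rules <- lapply(rules, function(r) {
    inputs <- r$inputs
    if (is.character(inputs)) {
      idx <- match(inputs, nodes)
      if (anyNA(idx)) {
        stop("undeclared node referenced: ",
             paste(inputs[is.na(idx)], collapse = ", "), call. = FALSE)
      }
      inputs <- idx
    }
    inputs <- as.integer(inputs)
    table <- as.integer(r$table)
    if (length(table) != 2^length(inputs) || !all(table %in% c(0L, 1L))) {
      stop("rule table must be a 0/1 vector of length 2^k", call. = FALSE)
    }
    prune_rule(list(inputs = inputs, table = table))
  })
  net <- structure(list(nodes = nodes, rules = rules),
                   class = "boolean_network")
  net
}

#' Derived edge list of a Boolean network
#'
#' @param net a `boolean_network`.
#' @return data.frame with columns `from`, `to`; one row per essential
#'   regulatory edge.
#' @export
network_edges <- function(net) {
  from <- unlist(lapply(net$rules, function(r) r$inputs), use.names = FALSE)
  to <- rep(seq_along(net$nodes),
            vapply(net$rules, function(r) length(r$inputs), integer(1)))
  data.frame(from = net$nodes[from], to = net$nodes[to],
             stringsAsFactors = FALSE)
}

#' @export
print.boolean_network <- function(x, ...) {
  cat("Boolean network:", length(x$nodes), "nodes,",
      nrow(network_edges(x)), "edges\n")
  cat(serialize_network(x))
  invisible(x)
}

# ---- parsing ----------------------------------------------------------------

# tokens allowed in the rule dialect
.tok_re <- "[A-Za-z][A-Za-z0-9_.]*|[01]|&+|\\|+|!|\\(|\\)|AND|OR|NOT"

parse_expression <- function(expr_text, line_no) {
  txt <- gsub("\\bAND\\b", "&", expr_text)
  txt <- gsub("\\bOR\\b", "|", txt)
  txt <- gsub("\\bNOT\\b", "!", txt)
  toks <- regmatches(txt, gregexpr(
    "[A-Za-z][A-Za-z0-9_.]*|[01]|&|\\||!|\\(|\\)|\\s+", txt))[[1]]
  if (paste(toks, collapse = "") != txt) {
    stop("parse error at line ", line_no, ": unrecognised token in '",
         expr_text, "'", call. = FALSE)
  }
  toks <- toks[!grepl("^\\s+$", toks)]
  if (length(toks) == 0L) {
    stop("parse error at line ", line_no, ": empty rule", call. = FALSE)
  }
  vars <- unique(toks[grepl("^[A-Za-z]", toks)])
  parsed <- tryCatch(str2lang(paste(toks, collapse = " ")),
                     error = function(e) {
                       stop("parse error at line ", line_no, ": ",
                            conditionMessage(e), call. = FALSE)
                     })
  list(expr = parsed, vars = vars)
}

expr_to_table <- function(expr, vars) {
  k <- length(vars)
  if (k == 0L) {
    v <- eval(expr, envir = baseenv())
    return(list(inputs = character(0), table = as.integer(as.logical(v))))
  }
  idx <- 0:(2^k - 1)
  env <- new.env(parent = baseenv())
  for (j in seq_len(k)) {
    assign(vars[j], bitwAnd(bitwShiftR(idx, j - 1L), 1L), envir = env)
  }
  val <- eval(expr, envir = env)
  val <- as.integer(as.logical(val) | FALSE)
  if (length(val) == 1L) val <- rep(val, 2^k)
  list(inputs = vars, table = val)
}

#' Parse a Boolean network from rule text
#'
#' Reads the plain-text logic dialect used by `.bnet` files: one rule per
#' line, `target, expression`, with operators `&`/`AND`, `|`/`OR`, `!`/`NOT`,
#' parentheses and the constants 0/1. An optional `targets, factors` header
#' and `#` comment lines are ignored.
#'
#' @param text character scalar (whole text) or vector of lines.
#' @param file alternatively, path to a rule file.
#' @return a [boolean_network()].
#' @export
parse_network <- function(text = NULL, file = NULL) {
  if (!is.null(file)) {
    if (!file.exists(file)) stop("no such file: ", file, call. = FALSE)
    lines <- readLines(file, warn = FALSE)
  } else {
    lines <- unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
  }
  targets <- character(0)
  parsed <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "" || startsWith(ln, "#")) next
    if (grepl("^targets\\s*,\\s*factors$", ln, ignore.case = TRUE)) next
    comma <- regexpr(",", ln, fixed = TRUE)
    if (comma < 0) {
      stop("parse error at line ", i, ": expected 'target, expression'",
           call. = FALSE)
    }
    target <- trimws(substr(ln, 1L, comma - 1L))
    rhs <- trimws(substr(ln, comma + 1L, nchar(ln)))
    if (!grepl("^[A-Za-z][A-Za-z0-9_.]*$", target)) {
      stop("parse error at line ", i, ": bad target name '", target, "'",
           call. = FALSE)
    }
    if (target %in% targets) {
      stop("parse error at line ", i, ": duplicate target '", target, "'",
           call. = FALSE)
    }
    if (rhs == "") stop("parse error at line ", i, ": empty rule",
                        call. = FALSE)
    pe <- parse_expression(rhs, i)
    targets <- c(targets, target)
    parsed[[target]] <- pe
  }
  if (length(targets) == 0L) stop("no rules found", call. = FALSE)
  all_vars <- unique(unlist(lapply(parsed, `[[`, "vars"), use.names = FALSE))
  undeclared <- setdiff(all_vars, targets)
  if (length(undeclared) > 0L) {
    stop("undeclared node reference: ", paste(undeclared, collapse = ", "),
         call. = FALSE)
  }
  rules <- lapply(parsed, function(pe) expr_to_table(pe$expr, pe$vars))
  boolean_network(targets, rules)
}

# minterm DNF text of one rule (canonical serialization)
rule_text <- function(rule, nodes) {
  k <- length(rule$inputs)
  if (k == 0L) return(as.character(rule$table[1L]))
  on_rows <- which(rule$table == 1L) - 1L
  if (length(on_rows) == 0L) return("0")
  if (length(on_rows) == 2^k) return("1")
  terms <- vapply(on_rows, function(row) {
    lits <- vapply(seq_len(k), function(j) {
      nm <- nodes[rule$inputs[j]]
      if (bitwAnd(bitwShiftR(row, j - 1L), 1L) == 1L) nm else paste0("!", nm)
    }, character(1))
    paste0("(", paste(lits, collapse = " & "), ")")
  }, character(1))
  paste(terms, collapse = " | ")
}

#' Serialize a Boolean network to canonical rule text
#'
#' Rules are written in disjunctive normal form over their essential inputs,
#' so `parse_network(serialize_network(net))` reproduces `net` truth-table
#' for truth-table.
#'
#' @param net a `boolean_network`.
#' @param file optional path; when given the text is also written there.
#' @return the rule text, invisibly when `file` is given.
#' @export
serialize_network <- function(net, file = NULL) {
  lines <- vapply(seq_along(net$nodes), function(i) {
    paste0(net$nodes[i], ", ", rule_text(net$rules[[i]], net$nodes))
  }, character(1))
  txt <- paste0(paste(lines, collapse = "\n"), "\n")
  if (!is.null(file)) {
    writeLines(sub("\n$", "", txt), file)
    return(invisible(txt))
  }
  txt
}

# ---- dynamics ---------------------------------------------------------------

#' Synchronous update of a network state
#'
#' Every node's next value is its update rule evaluated on the current state;
#' the map is deterministic (one successor per state).
#'
#' @param net a `boolean_network`.
#' @param s state (0/1 vector of the network's width).
#' @return the successor state, named by node.
#' @export
synchronous_step <- function(net, s) {
  if (length(s) != length(net$nodes)) {
    stop("state width ", length(s), " does not match network size ",
         length(net$nodes), call. = FALSE)
  }
  s <- as.integer(s)
  out <- vapply(net$rules, rule_eval, integer(1), s = s)
  names(out) <- net$nodes
  out
}

# rotate a cycle (matrix, rows = states) so it starts at the minimal encoding
canonical_rotation <- function(states) {
  keys <- apply(states, 1L, state_key)
  shift <- which.min(rank(keys, ties.method = "first"))
  idx <- c(shift:nrow(states), if (shift > 1L) 1:(shift - 1L))
  states[idx, , drop = FALSE]
}

new_attractor <- function(states, nodes) {
  states <- matrix(as.integer(states), ncol = length(nodes),
                   dimnames = list(NULL, nodes))
  structure(list(states = canonical_rotation(states), length = nrow(states)),
            class = "bn_attractor")
}

#' @export
print.bn_attractor <- function(x, ...) {
  cat("Attractor of length", x$length, "\n")
  for (i in seq_len(x$length)) cat(" ", state_string(x$states[i, ]), "\n")
  invisible(x)
}

attractor_key <- function(attr) {
  paste(apply(attr$states, 1L, state_string), collapse = ";")
}

#' Follow a trajectory to its attractor
#'
#' Iterates the synchronous map from `s` until a state repeats (exact
#' visited-set hashing), and returns the cycle in canonical rotation together
#' with the number of steps taken before entering it.
#'
#' @param net a `boolean_network`.
#' @param s initial state.
#' @param max_steps safety cap on the number of transitions (default `2^n`,
#'   capped at 1e6); exceeding it signals a dynamics bug.
#' @return list with `attractor` (a `bn_attractor`) and `transient` (steps
#'   before the cycle is entered).
#' @export
find_attractor <- function(net, s, max_steps = NULL) {
  n <- length(net$nodes)
  if (is.null(max_steps)) max_steps <- min(2^n, 1e6)
  s <- as_state(s, net$nodes)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  path <- vector("list", 64L)
  cur <- s
  t <- 0L
  repeat {
    key <- state_key(cur)
    hit <- seen[[key]]
    if (!is.null(hit)) {
      cycle <- do.call(rbind, path[(hit + 1L):t])
      return(list(attractor = new_attractor(cycle, net$nodes),
                  transient = hit))
    }
    if (t >= max_steps) {
      stop("no revisit within max_steps; dynamics bug?", call. = FALSE)
    }
    t <- t + 1L
    if (t > length(path)) path <- c(path, vector("list", length(path)))
    path[[t]] <- cur
    seen[[key]] <- t - 1L
    cur <- synchronous_step(net, cur)
  }
}

# ---- exhaustive enumeration -------------------------------------------------

# full synchronous transition table: succ[i+1] = code of successor of state
# code i (codes 0..2^n-1, node 1 = least significant bit). Vectorised per
# node; memory is O(2^n) integers.
transition_table <- function(net) {
  n <- length(net$nodes)
  if (n > 25L) stop("transition table limited to n <= 25", call. = FALSE)
  codes <- 0:(2^n - 1)
  succ <- integer(length(codes))
  for (i in seq_len(n)) {
    r <- net$rules[[i]]
    k <- length(r$inputs)
    if (k == 0L) {
      bit <- rep(r$table[1L], length(codes))
    } else {
      idx <- integer(length(codes))
      for (j in seq_len(k)) {
        idx <- idx + bitwAnd(bitwShiftR(codes, r$inputs[j] - 1L), 1L) *
          2^(j - 1L)
      }
      bit <- r$table[idx + 1L]
    }
    succ <- succ + bit * 2^(i - 1L)
  }
  succ
}

code_to_state <- function(code, n) {
  vapply(seq_len(n), function(j) bitwAnd(bitwShiftR(code, j - 1L), 1L),
         integer(1))
}

state_to_code <- function(s) sum(as.integer(s) * 2^(seq_along(s) - 1L))

#' Exhaustive attractor enumeration with exact basin sizes
#'
#' Builds the full 2^n synchronous transition table and assigns every state
#' to its attractor by pointer doubling, so basin sizes are exact and sum to
#' 2^n. Intended for networks small enough to enumerate (the hierarchical
#' backward search in [basin_of_attractor()] is the scalable path).
#'
#' @param net a `boolean_network`.
#' @param limit refuse networks larger than this many nodes (default 22).
#' @return list with `attractors` (list of `bn_attractor`), `basin_sizes`
#'   (integer vector), and `labels` (attractor index for every state code,
#'   in code order 0..2^n-1).
#' @export
enumerate_attractors_exhaustive <- function(net, limit = 22L) {
  if (is.null(net) || length(net$nodes) == 0L) {
    stop("empty network", call. = FALSE)
  }
  n <- length(net$nodes)
  if (n > limit) {
    stop("network has ", n, " nodes (> limit ", limit,
         "); use the Monte-Carlo landscape instead", call. = FALSE)
  }
  succ <- transition_table(net)
  # after n_doubling squarings g(s) lies on s's cycle (transients < 2^n)
  g <- succ
  for (d in seq_len(n)) g <- g[g + 1L]
  cyc_reps <- unique(g)
  attractors <- list()
  cyc_codes <- integer(0)
  cyc_label <- integer(0)
  for (r in cyc_reps) {
    if (r %in% cyc_codes) next
    cyc <- r
    cur <- succ[r + 1L]
    while (cur != r) { cyc <- c(cyc, cur); cur <- succ[cur + 1L] }
    states <- t(vapply(cyc, code_to_state, integer(n), n = n))
    attractors[[length(attractors) + 1L]] <- new_attractor(states, net$nodes)
    cyc_codes <- c(cyc_codes, cyc)
    cyc_label <- c(cyc_label, rep(length(attractors), length(cyc)))
  }
  labels <- cyc_label[match(g, cyc_codes)]
  sizes <- tabulate(labels, nbins = length(attractors))
  list(attractors = attractors, basin_sizes = sizes, labels = labels)
}

# ---- clamping ---------------------------------------------------------------

# restrict a rule's table by fixing a subset of its inputs (named int vector
# of node index -> value); returns pruned rule on remaining inputs
restrict_rule <- function(rule, fixed_idx, fixed_val) {
  k <- length(rule$inputs)
  pos <- match(rule$inputs, fixed_idx)
  bound <- which(!is.na(pos))
  if (length(bound) == 0L) return(rule)
  free <- setdiff(seq_len(k), bound)
  m <- length(free)
  combs <- 0:(2^m - 1)
  idx <- integer(length(combs))
  for (j in seq_along(free)) {
    idx <- idx + bitwAnd(bitwShiftR(combs, j - 1L), 1L) * 2^(free[j] - 1L)
  }
  for (b in bound) idx <- idx + fixed_val[pos[b]] * 2^(b - 1L)
  prune_rule(list(inputs = rule$inputs[free], table = rule$table[idx + 1L]))
}

#' Clamp nodes and propagate the induced constants
#'
#' Clamped nodes' rules are replaced by constants (modelling mutations or
#' fixed inputs); a node whose rule becomes constant once already-fixed
#' inputs are substituted is fixed in turn, to closure. The reduced network
#' on the still-free nodes has the same restricted dynamics as the clamped
#' original.
#'
#' @param net a `boolean_network`.
#' @param clamps named 0/1 vector of node values to clamp.
#' @return list with `network` (reduced `boolean_network` on free nodes) and
#'   `fixed` (named 0/1 vector: clamped nodes plus all induced constants).
#' @export
clamp_and_propagate <- function(net, clamps) {
  vals <- as.integer(clamps)
  nms <- names(clamps)
  if (is.null(nms)) stop("clamps must be a named vector", call. = FALSE)
  if (anyDuplicated(nms)) {
    dup <- nms[duplicated(nms)]
    bad <- vapply(unique(dup), function(d) {
      length(unique(vals[nms == d])) > 1L
    }, logical(1))
    if (any(bad)) {
      stop("contradictory clamp for node(s): ",
           paste(unique(dup)[bad], collapse = ", "), call. = FALSE)
    }
    keep <- !duplicated(nms)
    vals <- vals[keep]; nms <- nms[keep]
  }
  miss <- setdiff(nms, net$nodes)
  if (length(miss) > 0L) {
    stop("clamped node(s) not in network: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  fixed_idx <- match(nms, net$nodes)
  fixed_val <- vals
  rules <- net$rules
  for (i in seq_along(fixed_idx)) {
    rules[[fixed_idx[i]]] <- list(inputs = integer(0),
                                  table = fixed_val[i])
  }
  repeat {
    changed <- FALSE
    for (i in seq_along(net$nodes)) {
      if (i %in% fixed_idx) next
      r <- restrict_rule(rules[[i]], fixed_idx, fixed_val)
      rules[[i]] <- r
      if (length(r$inputs) == 0L) {
        fixed_idx <- c(fixed_idx, i)
        fixed_val <- c(fixed_val, r$table[1L])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  free <- setdiff(seq_along(net$nodes), fixed_idx)
  fixed <- fixed_val
  names(fixed) <- net$nodes[fixed_idx]
  fixed <- fixed[order(match(names(fixed), net$nodes))]
  if (length(free) == 0L) {
    reduced <- NULL
  } else {
    remap <- match(seq_along(net$nodes), free)
    sub_rules <- lapply(rules[free], function(r) {
      list(inputs = remap[r$inputs], table = r$table)
    })
    names(sub_rules) <- net$nodes[free]
    reduced <- boolean_network(net$nodes[free], sub_rules)
  }
  list(network = reduced, fixed = fixed)
}

# restrict a network to a node subset whose rules only use surviving inputs
subnetwork <- function(net, keep_idx) {
  keep_idx <- sort(keep_idx)
  remap <- match(seq_along(net$nodes), keep_idx)
  rules <- lapply(net$rules[keep_idx], function(r) {
    if (anyNA(remap[r$inputs])) {
      stop("internal error: subnetwork rule references removed node",
           call. = FALSE)
    }
    list(inputs = remap[r$inputs], table = r$table)
  })
  names(rules) <- net$nodes[keep_idx]
  boolean_network(net$nodes[keep_idx], rules)
}
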