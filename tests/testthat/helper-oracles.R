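# Shared fixtures and independent brute-force oracles. The oracles use
# plain per-state stepping and explicit set arithmetic, independent of the
# backward search and of the vectorised exhaustive enumerator they check.

toy_model <- function() {
  load_model("toy7",
             models_dir = system.file("extdata", "models",
                                      package = "brcnet"))$network
}

state_code <- function(s) sum(as.integer(s) * 2^(seq_along(s) - 1L))

code_state <- function(code, n) {
  vapply(seq_len(n), function(j) bitwAnd(bitwShiftR(code, j - 1L), 1L),
         integer(1))
}

# evaluate one node's rule by direct table lookup (independent of
# synchronous_step's internals)
oracle_node_value <- function(net, i, s) {
  r <- net$rules[[i]]
  if (length(r$inputs) == 0L) return(r$table[1L])
  idx <- 1L
  w <- 1L
  for (j in r$inputs) {
    idx <- idx + s[j] * w
    w <- w * 2L
  }
  r$table[idx]
}

oracle_step <- function(net, s) {
  vapply(seq_along(net$nodes), oracle_node_value, integer(1),
         net = net, s = as.integer(s))
}

# basin label of every state (code order 0..2^n-1): the minimal state code
# on the attractor cycle it converges to; memoised forward walking
oracle_basins <- function(net) {
  n <- length(net$nodes)
  total <- 2^n
  succ <- vapply(0:(total - 1), function(code) {
    state_code(oracle_step(net, code_state(code, n)))
  }, numeric(1))
  lab <- rep(NA_real_, total)
  for (start in 0:(total - 1)) {
    if (!is.na(lab[start + 1])) next
    path <- start
    cur <- start
    repeat {
      nxt <- succ[cur + 1]
      if (!is.na(lab[nxt + 1])) { root <- lab[nxt + 1]; break }
      if (nxt %in% path) {
        # found a new cycle; its label is its minimal code
        cyc_start <- match(nxt, path)
        root <- min(path[cyc_start:length(path)])
        break
      }
      path <- c(path, nxt)
      cur <- nxt
    }
    lab[path + 1] <- root
  }
  lab
}

# full-state codes of a computed basin (cubes lifted over symmetric nodes)
oracle_basin_codes <- function(b) {
  ex <- basin_states(b, max_states = 2^22)
  vapply(seq_len(nrow(ex)), function(i) state_code(ex[i, ]), numeric(1))
}

# a small battery of seeded random networks
random_net_battery <- function(n_nets, sizes, seed0, k_max = 3L,
                               p_det = 0.3) {
  lapply(seq_len(n_nets), function(i) {
    random_boolean_network(sizes[((i - 1L) %% length(sizes)) + 1L],
                           k_max = k_max, p_deterministic = p_det,
                           n_peelable = (i %% 4L),
                           seed = seed0 + i)
  })
}
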