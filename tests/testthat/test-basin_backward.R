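test_that("deterministic equations invert identity and negation targets", {
  # y1 = x (copy), y2 = !x (negation), x = y1 | y2 keeps outdegrees positive
  net <- parse_network(text = "x, y1 | y2\ny1, x\ny2, !x")
  cl <- classify_deterministic(net)
  inv <- build_deterministic_inverses(net, cl)
  expect_named(inv, "x")
  expect_setequal(inv$x$targets, c("y1", "y2"))
  copy_tab <- inv$x$tables[[match("y1", inv$x$targets)]]
  neg_tab <- inv$x$tables[[match("y2", inv$x$targets)]]
  expect_identical(copy_tab, c(0L, 1L))   # x(t) = y1(t+1)
  expect_identical(neg_tab, c(1L, 0L))    # x(t) = 1 - y2(t+1)
})

test_that("terminal conditions fire on forced contradictions", {
  # two copy-targets of x: states with y1 != y2 have no predecessor
  net <- parse_network(text = "x, y1 | y2\ny1, x\ny2, x")
  cl <- classify_deterministic(net)
  chk <- terminal_check(net, cl, c(0L, 0L, 1L))
  expect_true(chk$is_terminal)
  expect_match(chk$fired, "contradictory-inverse:x")
  expect_false(terminal_check(net, cl, c(1L, 1L, 1L))$is_terminal)

  # toy network: the printed terminal state fires a condition
  toy <- toy_model()
  p <- peel_symmetric_nodes(toy)
  cl_toy <- classify_deterministic(p$core)
  expect_true(terminal_check(p$core, cl_toy, c(0L, 0L, 1L, 0L, 0L))$is_terminal)
})

test_that("flagged terminal states have empty brute-force preimages", {
  for (i in 1:10) {
    net <- random_boolean_network(8, k_max = 3, p_deterministic = 0.35,
                                  n_peelable = 0, seed = 1100 + i)
    core <- peel_symmetric_nodes(net)$core
    if (is.null(core)) next
    n <- length(core$nodes)
    cl <- classify_deterministic(core)
    succ <- vapply(0:(2^n - 1), function(code) {
      state_code(oracle_step(core, code_state(code, n)))
    }, numeric(1))
    for (code in 0:(2^n - 1)) {
      s <- code_state(code, n)
      if (terminal_check(core, cl, s)$is_terminal) {
        expect_false(code %in% succ)
      }
    }
  }
})

test_that("predecessor computation equals the brute-force preimage", {
  # a fixed point is its own predecessor
  toy <- toy_model()
  p <- peel_symmetric_nodes(toy)
  cl <- classify_deterministic(p$core)
  beta_core <- c(1L, 0L, 1L, 1L, 1L)
  pre <- predecessor_states(p$core, cl, beta_core)
  expect_true(cube_member(pre, beta_core))

  for (i in 1:12) {
    net <- random_boolean_network(8, k_max = 3, p_deterministic = 0.25,
                                  n_peelable = 0, seed = 1200 + i)
    core <- peel_symmetric_nodes(net)$core
    if (is.null(core)) next
    n <- length(core$nodes)
    cl <- classify_deterministic(core)
    succ <- vapply(0:(2^n - 1), function(code) {
      state_code(oracle_step(core, code_state(code, n)))
    }, numeric(1))
    for (code in unique(pmin(c(0, 3, 2^n - 1, (i * 29) %% 2^n), 2^n - 1))) {
      s <- code_state(code, n)
      pre <- predecessor_states(core, cl, s)
      truth <- which(succ == code) - 1
      members <- if (nrow(pre$mat) == 0L) numeric(0) else {
        ex <- brcnet:::cubes_expand(pre)
        sort(as.numeric(ex %*% 2^(0:(n - 1))))
      }
      expect_equal(members, sort(truth))
      expect_equal(cube_count(pre), length(truth))
      # consistency with the terminal conditions
      if (terminal_check(core, cl, s)$is_terminal) {
        expect_equal(nrow(pre$mat), 0L)
      }
    }
  }
})

test_that("local basins are rooted breadth-first and stay disjoint", {
  # a fixed point whose only predecessor is itself: local basin is itself
  net <- parse_network(text = "A, !B\nB, !A")
  cl <- classify_deterministic(net)
  lb <- local_basin(net, cl, c(0L, 1L), matrix(c(0L, 1L), nrow = 1L))
  expect_equal(cube_count(lb$cubes), 1)
  expect_true(cube_member(lb$cubes, c(0L, 1L)))

  # toy network: the trajectory from the terminal state lies in the basin
  toy <- toy_model()
  p <- peel_symmetric_nodes(toy)
  cl_toy <- classify_deterministic(p$core)
  beta_core <- c(1L, 0L, 1L, 1L, 1L)
  lb_toy <- local_basin(p$core, cl_toy, beta_core,
                        matrix(beta_core, nrow = 1L))
  s <- c(0L, 0L, 1L, 0L, 0L)
  repeat {
    expect_true(cube_member(lb_toy$cubes, s))
    if (all(s == beta_core)) break
    s <- unname(synchronous_step(p$core, s))
  }

  # cyclic attractors: local basins partition the basin, overlapping only
  # in no state (each attractor state belongs to its own local basin)
  for (i in 1:8) {
    net <- random_boolean_network(8, k_max = 3, p_deterministic = 0.2,
                                  n_peelable = 0, seed = 1300 + i)
    core <- peel_symmetric_nodes(net)$core
    if (is.null(core)) next
    n <- length(core$nodes)
    en <- enumerate_attractors_exhaustive(core)
    ai <- which.max(vapply(en$attractors, `[[`, integer(1), "length"))
    attr <- en$attractors[[ai]]
    if (attr$length < 2) next
    cl <- classify_deterministic(core)
    lbs <- lapply(seq_len(attr$length), function(q) {
      local_basin(core, cl, attr$states[q, ], attr$states)
    })
    all_codes <- unlist(lapply(lbs, function(lb) {
      ex <- brcnet:::cubes_expand(lb$cubes)
      as.numeric(ex %*% 2^(0:(n - 1)))
    }))
    expect_equal(anyDuplicated(all_codes), 0L)
    expect_equal(length(all_codes), sum(en$labels == ai))
  }
})

test_that("the exact basin equals forward brute force and counts exactly", {
  # whole-space basin: single-attractor feed-forward network
  casc <- parse_network(text = "A, 1\nB, A\nC, B\nD, C & B")
  fa <- find_attractor(casc, c(0L, 0L, 0L, 0L))
  b <- basin_of_attractor(casc, fa$attractor)
  expect_equal(b$full_count, 2^4)

  # toy network: both printed states lie in the basin of beta
  toy <- toy_model()
  beta <- find_attractor(toy, as_state("1011110", toy$nodes))$attractor
  bt <- basin_of_attractor(toy, beta)
  expect_true(basin_contains(bt, as_state("0010000", toy$nodes)))
  expect_true(basin_contains(bt, as_state("0010100", toy$nodes)))
  expect_equal(bt$full_count, bt$reduced_count * 2^bt$n_sym)

  expect_error(basin_of_attractor(toy, local({
    a <- beta; a$states[1, 1] <- 1L - a$states[1, 1]; a
  })), "not an attractor")

  for (i in 1:15) {
    n <- 8 + (i %% 4)
    net <- random_boolean_network(n, k_max = 3, p_deterministic = 0.25,
                                  n_peelable = i %% 4, seed = 1400 + i)
    lab <- oracle_basins(net)
    en <- enumerate_attractors_exhaustive(net)
    for (ai in seq_along(en$attractors)) {
      b <- basin_of_attractor(net, en$attractors[[ai]])
      truth <- which(en$labels == ai) - 1L
      expect_equal(b$full_count, length(truth))
      expect_equal(b$full_count %% 2^b$n_sym, 0)
      got <- sort(oracle_basin_codes(b))
      expect_equal(got, sort(as.numeric(truth)))
    }
  }
})

test_that("sampled basin members converge to the attractor", {
  for (i in 1:5) {
    net <- random_boolean_network(10, k_max = 2, p_deterministic = 0.3,
                                  n_peelable = 2, seed = 1500 + i)
    en <- enumerate_attractors_exhaustive(net)
    ai <- which.max(en$basin_sizes)
    b <- basin_of_attractor(net, en$attractors[[ai]])
    sts <- basin_states(b)
    key <- paste(apply(en$attractors[[ai]]$states, 1, state_string),
                 collapse = ";")
    pick <- sts[seq(1, nrow(sts), length.out = min(50, nrow(sts))), ,
                drop = FALSE]
    for (r in seq_len(nrow(pick))) {
      fa <- find_attractor(net, pick[r, ])
      expect_equal(paste(apply(fa$attractor$states, 1, state_string),
                         collapse = ";"), key)
    }
  }
})

test_that("basin union counts are additive over disjoint basins", {
  for (i in 1:5) {
    net <- random_boolean_network(10, k_max = 3, p_deterministic = 0.25,
                                  n_peelable = 1, seed = 1600 + i)
    en <- enumerate_attractors_exhaustive(net)
    basins <- lapply(en$attractors, function(a) basin_of_attractor(net, a))
    u <- basin_union(basins)
    expect_equal(u$full_count, 2^10)   # all basins partition the space
    # union with itself does not double-count
    u2 <- basin_union(c(basins[1], basins[1]))
    expect_equal(u2$full_count, basins[[1]]$full_count)
    # membership is the disjunction
    s <- code_state(123, 10)
    expect_true(basin_union_contains(u, s))
  }
})

test_that("cube sets report patterns, counts and export round-trips", {
  cs <- state_cubes(c("01*", "1*0"), c("a", "b", "c"))
  expect_equal(cube_count(cs), 4)
  expect_true(cube_member(cs, c(0L, 1L, 1L)))
  expect_false(cube_member(cs, c(0L, 0L, 0L)))
  f <- tempfile()
  meta <- write_cubes(cs, f)
  expect_identical(readLines(f), c("01*", "1*0"))
  expect_identical(meta$count, "4")
  expect_true(file.exists(paste0(f, ".json")))
})
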