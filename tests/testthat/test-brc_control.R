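toy <- toy_model()
toy_beta <- find_attractor(toy, as_state("1011110", toy$nodes))$attractor
toy_basin <- basin_of_attractor(toy, toy_beta)
toy_alpha <- as_state("0000100", toy$nodes)

test_that("basin nodes decompose into symmetric, fixed and unfixed", {
  dec <- decompose_basin_nodes(toy_basin)
  expect_setequal(dec$symmetric, c("F", "G"))
  expect_identical(dec$fixed, c(C = 1L))
  expect_setequal(dec$unfixed, c("A", "B", "D", "E"))
  # fixed value holds in every basin member
  sts <- basin_states(toy_basin)
  expect_true(all(sts[, "C"] == 1L))
  # symmetric nodes have mean exactly 0.5 over the basin
  expect_equal(unname(colMeans(sts)[c("F", "G")]), c(0.5, 0.5))

  # whole-space basin: every node symmetric, none fixed
  casc <- parse_network(text = "A, 1\nB, A\nC, B")
  bw <- basin_of_attractor(casc, find_attractor(casc, c(0L, 0L, 0L))$attractor)
  dw <- decompose_basin_nodes(bw)
  expect_setequal(dw$symmetric, c("A", "B", "C"))
  expect_length(dw$fixed, 0L)
  expect_length(dw$unfixed, 0L)
})

test_that("minimum Hamming distance splits into fixed and unfixed parts", {
  mh <- minimum_hamming_distance(toy_alpha, toy_basin)
  expect_equal(mh$mhd, 1L)
  expect_equal(mh$rho_fixed, 1L)
  expect_equal(mh$rho_unfixed, 0L)

  inside <- as_state("0010100", toy$nodes)
  expect_equal(minimum_hamming_distance(inside, toy_basin)$mhd, 0L)

  # brute-force minimum over the enumerated basin
  for (i in 1:10) {
    n <- 8 + (i %% 4)
    net <- random_boolean_network(n, k_max = 3, p_deterministic = 0.3,
                                  n_peelable = i %% 3, seed = 1700 + i)
    en <- enumerate_attractors_exhaustive(net)
    ai <- which.max(en$basin_sizes)
    b <- basin_of_attractor(net, en$attractors[[ai]])
    members <- which(en$labels == ai) - 1L
    outside <- setdiff(0:(2^n - 1), members)
    if (length(outside) == 0L) next
    member_states <- t(vapply(members, code_state, integer(n), n = n))
    for (code in outside[c(1, length(outside) %/% 2, length(outside))]) {
      alpha <- as_state(code_state(code, n), net$nodes)
      truth <- min(apply(member_states, 1, function(m) sum(m != alpha)))
      expect_equal(minimum_hamming_distance(alpha, b)$mhd, truth)
    }
  }
})

test_that("control target sets are exactly the minimum flip sets", {
  cr <- control_target_sets(toy_alpha, toy_basin)
  expect_equal(cr$index_set_size, 1L)
  expect_identical(cr$target_sets[[1]], c(C = 1L))
  expect_identical(state_string(cr$boundary_states[1, ]), "0010100")
  expect_equal(hamming_distance(cr$boundary_states[1, ], toy_alpha), 1L)

  inside <- as_state("0010100", toy$nodes)
  cri <- control_target_sets(inside, toy_basin)
  expect_equal(cri$mhd, 0L)
  expect_length(cri$target_sets[[1]], 0L)
  expect_identical(unname(cri$boundary_states[1, ]), unname(inside))

  for (i in 1:8) {
    n <- 8 + (i %% 3)
    net <- random_boolean_network(n, k_max = 3, p_deterministic = 0.3,
                                  n_peelable = i %% 3, seed = 1800 + i)
    en <- enumerate_attractors_exhaustive(net)
    ai <- which.max(en$basin_sizes)
    b <- basin_of_attractor(net, en$attractors[[ai]])
    members <- which(en$labels == ai) - 1L
    outside <- setdiff(0:(2^n - 1), members)
    if (length(outside) == 0L) next
    for (code in outside[c(1, length(outside))]) {
      alpha <- as_state(code_state(code, n), net$nodes)
      cr <- control_target_sets(alpha, b)
      # exhaustive flip-set oracle: all subsets of size mhd that land in
      # the basin, and none smaller
      hits <- list()
      for (size in 0:cr$mhd) {
        for (fl in utils::combn(n, size, simplify = FALSE)) {
          s <- alpha
          s[fl] <- 1L - s[fl]
          if (state_code(s) %in% members) {
            expect_gte(size, cr$mhd)   # minimality
            hits[[length(hits) + 1L]] <- sort(net$nodes[fl])
          }
        }
      }
      got <- lapply(cr$target_sets, function(ts) sort(names(ts)))
      expect_equal(length(hits), cr$index_set_size)
      expect_setequal(vapply(got, paste, character(1), collapse = ","),
                      vapply(hits, paste, character(1), collapse = ","))
      # every emitted set lands in the basin
      for (r in seq_len(nrow(cr$boundary_states))) {
        expect_true(basin_contains(b, cr$boundary_states[r, ]))
        expect_equal(hamming_distance(cr$boundary_states[r, ], alpha),
                     cr$mhd)
      }
    }
  }
})

test_that("forward search reproduces the exact method on small networks", {
  # already-desired state: size-0 hit
  fw0 <- large_basin_control_search(toy, as_state("1011110", toy$nodes),
                                    NULL, list(toy_beta), max_hd = 2)
  expect_true(fw0$found)
  expect_equal(fw0$mhd, 0L)

  fw <- large_basin_control_search(toy, toy_alpha, NULL, list(toy_beta),
                                   max_hd = 3)
  expect_true(fw$found)
  expect_equal(fw$mhd, 1L)
  expect_identical(fw$target_sets[[1]], c(C = 1L))

  # bound exceeded reports not-found
  nf <- large_basin_control_search(toy, toy_alpha, "A", list(toy_beta),
                                   max_hd = 1)
  expect_false(nf$found)

  for (i in 1:6) {
    net <- random_boolean_network(9, k_max = 3, p_deterministic = 0.3,
                                  n_peelable = i %% 3, seed = 1900 + i)
    en <- enumerate_attractors_exhaustive(net)
    ai <- which.max(en$basin_sizes)
    b <- basin_of_attractor(net, en$attractors[[ai]])
    members <- which(en$labels == ai) - 1L
    outside <- setdiff(0:(2^9 - 1), members)
    if (length(outside) == 0L) next
    alpha <- as_state(code_state(outside[1], 9), net$nodes)
    exact <- control_target_sets(alpha, b)
    fw <- large_basin_control_search(net, alpha, NULL,
                                     list(en$attractors[[ai]]),
                                     max_hd = exact$mhd + 1)
    expect_equal(fw$mhd, exact$mhd)
    key <- function(ts) paste(sort(sprintf("%s=%d", names(ts), ts)),
                              collapse = ",")
    expect_setequal(vapply(fw$target_sets, key, character(1)),
                    vapply(exact$target_sets, key, character(1)))
  }
})

test_that("enlarging the desired basin never increases the distance", {
  for (i in 1:6) {
    net <- random_boolean_network(9, k_max = 3, p_deterministic = 0.25,
                                  n_peelable = i %% 3, seed = 2000 + i)
    en <- enumerate_attractors_exhaustive(net)
    if (length(en$attractors) < 2L) next
    ord <- order(-en$basin_sizes)
    b1 <- basin_of_attractor(net, en$attractors[[ord[1]]])
    b2 <- basin_of_attractor(net, en$attractors[[ord[2]]])
    outside <- setdiff(0:(2^9 - 1),
                       c(which(en$labels == ord[1]) - 1L,
                         which(en$labels == ord[2]) - 1L))
    if (length(outside) == 0L) next
    alpha <- as_state(code_state(outside[1], 9), net$nodes)
    mhd1 <- minimum_hamming_distance(alpha, b1)$mhd
    mhd_union <- min(mhd1, minimum_hamming_distance(alpha, b2)$mhd)
    expect_lte(mhd_union, mhd1)
  }
})

test_that("temporary application of any target set reaches the attractor", {
  key <- paste(apply(toy_beta$states, 1, state_string), collapse = ";")
  cr <- control_target_sets(toy_alpha, toy_basin)
  for (ts in cr$target_sets) {
    tp <- temporary_perturbation(toy, toy_alpha, ts)
    expect_equal(paste(apply(tp$attractor$states, 1, state_string),
                       collapse = ";"), key)
  }
})
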