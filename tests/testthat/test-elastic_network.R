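test_that("three collinear beads give exactly the two short constraints", {
  s <- cloud_structure(matrix(c(0, 0.38, 0.76, 0, 0, 0, 0, 0, 0), ncol = 3))
  p <- en_params(lower_cutoff = 0.3, upper_cutoff = 0.7, min_seq_sep = 1)
  net <- build_network(s, p)
  expect_equal(net$constraints$i, c(1L, 2L))
  expect_equal(net$constraints$j, c(2L, 3L))
  expect_equal(net$constraints$d0, c(0.38, 0.38), tolerance = 1e-12)
  expect_equal(net$constraints$k, c(500, 500))
})

test_that("an upper cutoff below the bead spacing yields an empty network", {
  s <- cloud_structure(matrix(c(0, 1, 2, 0, 0, 0, 0, 0, 0), ncol = 3))
  net <- build_network(s, en_params(lower_cutoff = 0.1, upper_cutoff = 0.5,
                                    min_seq_sep = 1))
  expect_equal(nrow(net$constraints), 0)
})

test_that("build_network matches the brute-force all-pairs oracle", {
  params <- en_params()
  for (seed in 1:20) {
    n <- sample(c(30, 50, 120, 200), 1)
    s <- random_cloud(n, seed)
    net <- build_network(s, params)
    oracle <- brute_force_network(s, params)
    expect_equal(net$constraints[, c("i", "j")], oracle[, c("i", "j")],
                 ignore_attr = TRUE)
    expect_equal(net$constraints$d0, oracle$d0, tolerance = 1e-12)
  }
})

test_that("sequence separation applies within chains but not across them", {
  xyz <- matrix(c(0, 0.6, 0, 0.6, 0, 0, 0.6, 0.6, rep(0, 4)), ncol = 3)
  b <- data.frame(chain = c("A", "A", "B", "B"), resid = c(1L, 2L, 1L, 2L),
                  resname = "ALA", x = xyz[, 1], y = xyz[, 2], z = xyz[, 3])
  s <- bead_structure(b, "x", "synthetic")
  net <- build_network(s, en_params(min_seq_sep = 3))
  same <- s$beads$chain[net$constraints$i] == s$beads$chain[net$constraints$j]
  expect_false(any(same))
  expect_gt(nrow(net$constraints), 0)
})

test_that("identical states keep every constraint", {
  fx <- make_two_state_bundle(bundle_spec(hinge_deg = 0))
  net <- build_network(fx$state_a)
  res <- comdyn_filter(net, fx$state_a, fx$state_b, fx$map)
  expect_equal(res$n_kept, res$n_input)
  expect_equal(res$kept_fraction, 1.0)
})

test_that("a rigid-body transform of one state keeps 100% of constraints", {
  fx <- make_two_state_bundle()
  R <- random_rotation(4)
  xb <- coords(fx$state_a) %*% R
  xb <- sweep(xb, 2, c(1, -2, 3), "+")
  b_rot <- bead_structure(transform(fx$state_a$beads,
                                    x = xb[, 1], y = xb[, 2], z = xb[, 3]),
                          "Arot", "synthetic")
  net <- build_network(fx$state_a)
  res <- comdyn_filter(net, fx$state_a, b_rot, fx$map)
  expect_equal(res$kept_fraction, 1.0)
})

test_that("a constructed 6-bead two-state case keeps exactly the unchanged pairs", {
  # 5 constraints in state A; pairs (1,4) and (2,5) move by 0.2 nm in B,
  # the rest by 0 — hand enumeration says 3 are kept
  xa <- matrix(c(0, 0, 0,
                 0.6, 0, 0,
                 1.2, 0, 0,
                 0, 0.7, 0,
                 0.6, 0.7, 0,
                 5, 5, 5), ncol = 3, byrow = TRUE)
  xb <- xa
  xb[4, 2] <- xb[4, 2] + 0.2  # stretches (1,4) and shifts (4,5) along x? no:
  xb[5, 2] <- xb[5, 2] + 0.2  # move beads 4,5 together: (4,5) unchanged,
                              # (1,4), (2,5), (2,4), (1,5) change
  b <- data.frame(chain = LETTERS[1:6], resid = 1L, resname = "ALA",
                  x = xa[, 1], y = xa[, 2], z = xa[, 3])
  sa <- bead_structure(b, "A", "synthetic")
  sb <- bead_structure(transform(b, x = xb[, 1], y = xb[, 2], z = xb[, 3]),
                       "B", "synthetic")
  params <- en_params(lower_cutoff = 0.5, upper_cutoff = 0.95)
  net <- build_network(sa, params)
  # hand enumeration of state-A distances in [0.5, 0.95]:
  # (1,2)=(2,3)=(4,5)=0.6, (1,4)=(2,5)=0.7, (1,5)=(2,4)=(3,5)=0.922
  expect_equal(nrow(net$constraints), 8)
  m <- map_residues(sa, sb, mode = "identity")
  res <- comdyn_filter(net, sa, sb, m, params)
  kept_pairs <- paste(res$filtered$constraints$i, res$filtered$constraints$j)
  expect_setequal(kept_pairs, c("1 2", "2 3", "4 5"))
  # dropped pairs carry the constructed distance changes:
  # (1,4) and (2,5) stretch from 0.7 to 0.9; the three 0.922 diagonals
  # stretch to sqrt(0.36 + 0.81)
  expect_equal(sort(res$dropped$delta_d)[4:5], rep(0.9 - 0.7, 2),
               tolerance = 1e-9)
  expect_equal(sort(res$dropped$delta_d)[1:3],
               rep(sqrt(0.36 + 0.81) - sqrt(0.36 + 0.49), 3),
               tolerance = 1e-9)
})

test_that("the filtered network is a subset and grows with the threshold", {
  fx <- make_two_state_bundle()
  net <- build_network(fx$state_a)
  key <- function(cn) paste(cn$i, cn$j)
  kept_prev <- -1
  for (thr in c(0.02, 0.05, 0.1, 0.2, 0.5)) {
    p <- en_params(comdyn_threshold = thr)
    res <- comdyn_filter(net, fx$state_a, fx$state_b, fx$map, p)
    expect_true(all(key(res$filtered$constraints) %in% key(net$constraints)))
    expect_gte(res$n_kept, kept_prev)
    kept_prev <- res$n_kept
  }
})

test_that("unmapped endpoints are dropped by default and kept on request", {
  fx <- make_two_state_bundle()
  # remove chain F from the map
  m <- fx$map
  keep <- m$pairs$chain_a != "F"
  m$pairs <- m$pairs[keep, ]
  net <- build_network(fx$state_a)
  touches_f <- fx$state_a$beads$chain[net$constraints$i] == "F" |
    fx$state_a$beads$chain[net$constraints$j] == "F"
  res_drop <- comdyn_filter(net, fx$state_a, fx$state_b, m)
  res_keep <- comdyn_filter(net, fx$state_a, fx$state_b, m,
                            unmapped = "keep")
  expect_equal(res_keep$n_kept - res_drop$n_kept, sum(touches_f))
  expect_error(comdyn_filter(net, fx$state_a, fx$state_b,
                             structure(list(pairs = data.frame()),
                                       class = "residue_map")),
               "empty")
})

test_that("topology files round-trip and follow the itp line format", {
  s <- cloud_structure(matrix(c(0, 0.38, 0, 0, 0, 0), ncol = 3))
  net <- build_network(s, en_params(lower_cutoff = 0.3, upper_cutoff = 0.5,
                                    min_seq_sep = 1))
  p <- tempfile(fileext = ".itp")
  write_topology(net, p)
  lines <- readLines(p)
  data_lines <- grep("^[0-9]", lines, value = TRUE)
  expect_equal(data_lines, "1 2 1 0.38000 500")

  # random 100-constraint network round-trip
  s2 <- random_cloud(80, seed = 9)
  net2 <- build_network(s2)
  expect_gt(nrow(net2$constraints), 100)
  p2 <- tempfile(fileext = ".itp")
  write_topology(net2, p2, funct = 6)
  back <- read_topology(p2)
  expect_equal(back$constraints$i, net2$constraints$i)
  expect_equal(back$constraints$j, net2$constraints$j)
  expect_equal(back$constraints$d0, net2$constraints$d0, tolerance = 1e-5)
  expect_equal(back$constraints$k, net2$constraints$k)
})

test_that("topology reader handles empty sections and flags bad lines", {
  p <- tempfile()
  writeLines(c("; header", "[ bonds ]"), p)
  expect_equal(nrow(read_topology(p)$constraints), 0)

  writeLines(c("[ bonds ]", "1 2 1 0.38000 500", "garbage line here x"), p)
  expect_error(read_topology(p), "line 3")

  writeLines(c("[ bonds ]", "1 2 9 0.38000 500"), p)
  expect_error(read_topology(p), "funct")
})

test_that("en_params rejects inverted shells and zero thresholds", {
  expect_error(en_params(lower_cutoff = 1, upper_cutoff = 0.5))
  expect_error(en_params(comdyn_threshold = 0))
  expect_error(en_params(force_constant = -1))
})
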