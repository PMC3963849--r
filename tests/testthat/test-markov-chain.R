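test_that("grid construction keeps hypercubes with feasible centers", {
  g1 <- build_grid(1, 0.25)
  expect_equal(g1$N, 4)
  expect_equal(as.numeric(g1$centers), c(0.125, 0.375, 0.625, 0.875))
  g2 <- build_grid(2, 0.5)
  expect_equal(g2$N, 3)  # (0.75, 0.75) rejected: total 1.5 > 1
  expect_false(any(rowSums(g2$centers) > 1))
  expect_error(build_grid(1, 0.3), "does not divide")
})

test_that("exact 1-d transition rows are normalized interval overlaps", {
  # pure contraction x -> 0.5 x maps the first cell into itself
  m_half <- tree_model(0.5, 0.5, a = 0, fire = fire_model(0.2, 0.8))
  tr <- build_conditional_transitions(build_grid(1, 0.5), m_half)
  expect_equal(tr$T_nf[1, ], c(1, 0))
  expect_equal(tr$T_nf[2, ], c(1, 0))  # [0.25, 0.5] also in cell 1
  # affine map x -> 0.81 x + 0.1: image of [0, 0.5) is [0.1, 0.505)
  m_ref <- tree_model(0.9, 0.4, a = 0.1, fire = fire_model(0.2, 0.8))
  tr2 <- build_conditional_transitions(build_grid(1, 0.5), m_ref)
  expect_equal(tr2$T_nf[1, ], c(0.4, 0.005) / 0.405, tolerance = 1e-12)
  # the identity map yields the identity matrix
  m_id <- tree_model(1, 1, a = 0, fire = fire_model(0.2, 0.8))
  tr3 <- build_conditional_transitions(build_grid(1, 0.25), m_id)
  expect_equal(tr3$T_nf, diag(4))
  expect_equal(tr3$T_f, diag(4))
})

test_that("sampled multi-dimensional transitions are row-stochastic and land on accepted cells", {
  set.seed(11)
  m <- random_model(2)
  g <- build_grid(2, 0.25)
  tr <- build_conditional_transitions(g, m, samples_per_axis = 4)
  for (Tm in tr) {
    expect_equal(rowSums(Tm), rep(1, g$N), tolerance = 1e-12)
    expect_true(all(Tm >= 0))
  }
  # a pure contraction concentrates every row on the low-cover cells
  m0 <- tree_model(diag(0.1, 2), diag(0.1, 2), a = 0,
                   fire = fire_model(0.2, 0.8))
  tr0 <- build_conditional_transitions(build_grid(2, 0.5), m0)
  expect_equal(tr0$T_nf[, 1], rep(1, 3))
})

test_that("mixture follows the theorem of total probability", {
  T_nf <- matrix(c(1, 0, 0.5, 0.5), 2, byrow = TRUE)
  T_f <- matrix(c(0, 1, 0.25, 0.75), 2, byrow = TRUE)
  expect_equal(mix_transitions(T_nf, T_f, c(0, 0)), T_nf)
  expect_equal(mix_transitions(T_nf, T_f, c(1, 1)), T_f)
  expect_equal(mix_transitions(T_nf, T_f, c(0.5, 0.5))[1, ], c(0.5, 0.5))
  expect_error(mix_transitions(T_nf, T_f, c(0.5)), "shape")
})

test_that("stationary solver matches hand-solved and eigen oracles", {
  T2 <- matrix(c(0.9, 0.1, 0.2, 0.8), 2, byrow = TRUE)
  w <- stationary_distribution(T2)
  expect_equal(as.numeric(w), c(2 / 3, 1 / 3), tolerance = 1e-12)
  Ts <- matrix(0.5, 2, 2)
  expect_equal(as.numeric(stationary_distribution(Ts)), c(0.5, 0.5))
  # identity chain: any distribution is stationary; uniform returned, flagged
  expect_warning(wi <- stationary_distribution(diag(2)), "not unique")
  expect_equal(as.numeric(wi), c(0.5, 0.5))
  expect_false(attr(wi, "unique"))
  # random small chains against an independent eigen decomposition
  set.seed(7)
  for (N in c(2, 3, 4, 5)) {
    Tr <- random_row_stochastic(N)
    w1 <- as.numeric(stationary_distribution(Tr))
    expect_equal(w1, stationary_by_eigen(Tr), tolerance = 1e-12)
    expect_lt(sum(abs(drop(w1 %*% Tr) - w1)), 1e-10)
  }
})

test_that("ergodicity check classifies chain structure", {
  e1 <- ergodicity_check(matrix(c(0.9, 0.1, 0.2, 0.8), 2, byrow = TRUE))
  expect_true(e1$irreducible)
  expect_true(e1$aperiodic)
  e2 <- ergodicity_check(diag(2))
  expect_equal(e2$closed_classes, 2)
  e3 <- ergodicity_check(matrix(c(0, 1, 1, 0), 2))
  expect_true(e3$irreducible)
  expect_false(e3$aperiodic)
  expect_equal(e3$period, 2L)
  # transient state feeding one closed class
  T4 <- matrix(c(0.5, 0.5, 0, 1), 2, byrow = TRUE)
  e4 <- ergodicity_check(T4)
  expect_false(e4$irreducible)
  expect_equal(e4$closed_classes, 1)
  expect_equal(as.numeric(stationary_distribution(T4)), c(0, 1))
})

test_that("full chain pipeline satisfies its type invariants", {
  m <- reference_model()
  ch <- build_chain(m, delta = 0.05)
  expect_equal(rowSums(ch$T_nf), rep(1, ch$grid$N), tolerance = 1e-10)
  expect_equal(rowSums(ch$T_f), rep(1, ch$grid$N), tolerance = 1e-10)
  expect_equal(ch$T, (1 - ch$p_state) * ch$T_nf + ch$p_state * ch$T_f,
               tolerance = 1e-14)
  w <- as.numeric(ch$w)
  expect_true(all(w >= 0))
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_lt(sum(abs(drop(w %*% ch$T) - w)), 1e-10)
  # the chain is seed-free: rebuilding gives identical output
  ch2 <- build_chain(m, delta = 0.05)
  expect_identical(ch$T, ch2$T)
  expect_equal(as.numeric(ch$w), as.numeric(ch2$w), tolerance = 1e-14)
})

test_that("cover distribution aggregates stationary mass with conservation", {
  fake <- structure(list(grid = build_grid(1, 0.25),
                         w = rep(0.25, 4)), class = "tree_chain")
  h <- cover_distribution(fake, bin_width = 0.5)
  expect_equal(h$mass, c(0.5, 0.5))
  one <- structure(list(grid = build_grid(1, 0.25),
                        w = c(1, 0, 0, 0)), class = "tree_chain")
  h1 <- suppressWarnings(cover_distribution(one, bin_width = 0.1))
  expect_equal(h1$mass[2], 1)  # cover 0.125 falls in [0.1, 0.2)
  expect_equal(sum(h1$mass), 1, tolerance = 1e-12)
  expect_warning(cover_distribution(fake, bin_width = 1 / 3), "rebinning")
})
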