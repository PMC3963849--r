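test_that("fire probability follows the piecewise-linear feedback curve", {
  f <- fire_model(0.2, 0.8, p_max = 1, p_min = 0)
  expect_equal(fire_probability(0.2, f), 1)
  expect_equal(fire_probability(0.5, f), 0.5)
  expect_equal(fire_probability(0.9, f), 0)
  expect_equal(fire_probability(0, f), 1)
  # degenerate thresholds act as a step function
  fs <- fire_model(0.5, 0.5, p_max = 0.8, p_min = 0.1)
  expect_equal(fire_probability(0.5, fs), 0.8)
  expect_equal(fire_probability(0.5 + 1e-9, fs), 0.1)
})

test_that("fire probability is non-increasing in cover for random curves", {
  set.seed(101)
  C <- seq(0, 1, by = 0.01)
  for (i in 1:50) {
    f <- random_fire_curve()
    p <- fire_probability(C, f)
    expect_true(all(diff(p) <= 1e-12))
    expect_true(all(p >= f$p_min - 1e-12 & p <= f$p_max + 1e-12))
  }
})

test_that("effective cover sums the masked classes", {
  f <- fire_model(0.1, 0.6, cover_classes = c(2, 3))
  expect_equal(effective_cover(c(0.1, 0.2, 0.3), f), 0.5)
  expect_equal(effective_cover(c(0, 0, 0), f), 0)
  expect_equal(effective_cover(0.4, fire_model(0.2, 0.8)), 0.4)
  expect_error(effective_cover(c(0.1, 0.2), f), "cover_classes")
})

test_that("model construction validates stage matrices and recruitment", {
  expect_error(tree_model(1.2, 0.4, a = 0.1, fire = fire_model(0.2, 0.8)),
               "column 1")
  expect_error(tree_model(matrix(c(0.5, 0.6, 0.5, 0.5), 2), diag(0.5, 2),
                          a = 0.1, fire = fire_model(0.2, 0.8)),
               "column 1")
  expect_error(tree_model(0.9, 0.4, a = 1.3, fire = fire_model(0.2, 0.8)),
               "recruitment")
  expect_error(tree_model(0.9, 0.4, a = 0.1,
                          fire = fire_model(0.2, 0.8, cover_classes = 2)),
               "cover_classes")
  expect_error(fire_model(0.9, 0.2), "theta1")
})

test_that("one-year update applies survival then space-limited recruitment", {
  m <- tree_model(0.9, 0.0, a = 0.1, fire = fire_model(0.2, 0.8))
  expect_equal(cover_step(0.5, FALSE, m), 0.505)  # 0.45 + 0.1 * 0.55
  m2 <- tree_model(0.9, 0.0, a = 0, fire = fire_model(0.2, 0.8))
  expect_equal(cover_step(0.5, TRUE, m2), 0)      # total kill, no recruitment
  m3 <- random_model(3)
  m3$a <- 0.2
  expect_equal(cover_step(c(0, 0, 0), FALSE, m3), c(0.2, 0, 0))
  # constant recruitment adds a regardless of free space
  mc <- tree_model(0.9, 0.4, a = 0.1, fire = fire_model(0.2, 0.8),
                   recruitment = "constant")
  expect_equal(cover_step(0.5, FALSE, mc), 0.55)
})

test_that("simulation is deterministic and respects degenerate fire", {
  m <- reference_model(seed = 7)
  s1 <- simulate_tree_cover(m, horizon = 500)
  s2 <- simulate_tree_cover(m, horizon = 500)
  expect_identical(s1$states, s2$states)
  expect_identical(s1$fire, s2$fire)
  expect_length(s1$fire, 500)
  expect_equal(nrow(s1$states), 501)
  m0 <- tree_model(0.9, 0.4, a = 0.1,
                   fire = fire_model(0.2, 0.8, p_max = 0, p_min = 0))
  s0 <- simulate_tree_cover(m0, horizon = 200, seed = 3)
  expect_true(all(s0$fire == 0))
})

test_that("forced single-dynamic runs converge to the closed-form steady state", {
  m <- tree_model(0.9, 0.4, a = 0.1, fire = fire_model(0.2, 0.8))
  s <- simulate_tree_cover(m, x0 = 0, horizon = 2000, forced_fire = FALSE,
                           seed = 1)
  expect_lt(abs(s$states[2001, 1] - 0.1 / 0.19), 1e-8)
  # multi-class forced fire run against the matrix closed form
  set.seed(42)
  m3 <- random_model(3)
  s3 <- simulate_tree_cover(m3, horizon = 2000, forced_fire = TRUE, seed = 1)
  expect_lt(sum(abs(s3$states[2001, ] - steady_state(m3, "fire"))), 1e-10)
  # the approach is monotone contraction in L1
  err <- abs(s$states[, 1] - 0.1 / 0.19)
  expect_true(all(diff(err[err > 1e-14]) < 0))
})

test_that("closed-form steady states match hand arithmetic and fix the map", {
  m <- tree_model(0.9, 0.4, a = 0.1, fire = fire_model(0.2, 0.8))
  expect_equal(steady_state(m, "no_fire"), 0.1 / 0.19, tolerance = 1e-12)
  expect_equal(steady_state(m, "fire"), 0.15625, tolerance = 1e-12)
  m0 <- tree_model(0.9, 0.0, a = 0.1, fire = fire_model(0.2, 0.8))
  expect_equal(steady_state(m0, "fire"), 0.1, tolerance = 1e-12)
  set.seed(5)
  for (n in c(1, 2, 3)) {
    mr <- random_model(n)
    for (w in c("no_fire", "fire")) {
      xs <- steady_state(mr, w)
      expect_lt(sum(abs(cover_step(xs, w == "fire", mr) - xs)), 1e-12)
    }
  }
  # spectral radius 1 has no steady state
  m1 <- tree_model(1, 0.4, a = 0, fire = fire_model(0.2, 0.8))
  expect_error(steady_state(m1, "no_fire"), "spectral radius")
})

test_that("stability check reports contraction norms of the update maps", {
  m <- tree_model(0.9, 0.4, a = 0.1, fire = fire_model(0.2, 0.8))
  st <- stability_check(m)
  expect_true(st$stable_nf)
  expect_equal(st$norms["no_fire", "norm1"], 0.81)
  m1 <- tree_model(1, 1, a = 0, fire = fire_model(0.2, 0.8))
  st1 <- stability_check(m1)
  expect_false(st1$stable_nf)
  expect_false(st1$stable_f)
  # column sums of the effective map scale by (1 - a)
  A <- matrix(c(0.6, 0.4, 0.7, 0.3), 2)
  m2 <- tree_model(A, A, a = 0.2, fire = fire_model(0.2, 0.8))
  st2 <- stability_check(m2)
  expect_equal(st2$norms["no_fire", "norm1"], 0.8, tolerance = 1e-12)
  expect_true(st2$stable_nf)
})

test_that("threshold inversion solves the two-point feedback conditions", {
  # steady covers 0.8 and 0.2: alpha_nf = 0.9375, alpha_f = 0, a = 0.2
  m <- tree_model(0.9375, 0, a = 0.2, fire = fire_model(0.2, 0.8))
  ss <- steady_states(m)
  expect_equal(ss$C_nf, 0.8, tolerance = 1e-12)
  expect_equal(ss$C_f, 0.2, tolerance = 1e-12)
  th <- invert_fire_thresholds(0.1, 0.9, m)
  expect_equal(unname(th), c(0.125, 0.875), tolerance = 1e-12)
  # round trip: forward evaluation reproduces the targets
  f <- fire_model(th[["theta1"]], th[["theta2"]])
  expect_equal(fire_probability(ss$C_nf, f), 0.1, tolerance = 1e-12)
  expect_equal(fire_probability(ss$C_f, f), 0.9, tolerance = 1e-12)
  expect_error(invert_fire_thresholds(0.5, 0.5, m), "p_at_f > p_at_nf")
  expect_error(invert_fire_thresholds(0.9, 0.95, m), "infeasible|escape")
})

test_that("trajectories stay on the unit simplex for random valid models", {
  set.seed(2024)
  for (i in 1:20) {
    n <- sample(1:3, 1)
    m <- random_model(n, max_colsum = 1)
    s <- simulate_tree_cover(m, x0 = random_state(n), horizon = 500, seed = i)
    expect_true(all(s$states >= -1e-12))
    expect_true(all(rowSums(s$states) <= 1 + 1e-12))
  }
})
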