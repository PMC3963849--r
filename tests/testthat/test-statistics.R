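test_that("permanence ratios count post-burn-in years", {
  p <- permanence_ratios(c(1, 0, 0, 1, 0))
  expect_equal(p$ratio_f, 0.4)
  expect_equal(p$ratio_nf, 0.6)
  expect_equal(permanence_ratios(rep(0, 10))$ratio_f, 0)
  p2 <- permanence_ratios(c(1, 1, 0, 0), burn_in = 2)
  expect_equal(p2$ratio_f, 0)
  expect_equal(p2$V_nf, 2)
  expect_error(permanence_ratios(c(1, 0), burn_in = 2), "burn_in")
})

test_that("empirical fire chain counts transitions and flags unvisited states", {
  P0 <- estimate_fire_chain(c(0, 0, 0, 0))
  expect_equal(P0["no_fire", ], c(no_fire = 1, fire = 0))
  expect_true(all(is.na(P0["fire", ])))
  expect_equal(attr(P0, "undefined_rows"), "fire")
  Pa <- estimate_fire_chain(c(0, 1, 0, 1, 0))
  expect_equal(Pa["no_fire", "fire"], 1)
  expect_equal(Pa["fire", "no_fire"], 1)
  Pb <- estimate_fire_chain(c(0, 0, 1, 1, 0, 0))
  expect_equal(Pb["no_fire", ], c(no_fire = 2 / 3, fire = 1 / 3))
  expect_equal(Pb["fire", ], c(no_fire = 1 / 2, fire = 1 / 2))
})

test_that("histograms use half-open bins with centers at l + width/2", {
  h <- cover_histogram(c(0.1, 0.9, 0.95), 0.1)
  expect_equal(h$centers[2], 0.15)
  expect_equal(h$freq[2], 1)       # 0.1 belongs to [0.1, 0.2)
  expect_equal(h$freq[10], 2)      # last bin closed
  expect_equal(sum(h$mass), 1)
  he <- cover_histogram(numeric(0), 0.1)
  expect_true(he$empty)
  expect_equal(sum(he$freq), 0)
  expect_equal(cover_histogram(1, 0.25)$freq[4], 1)  # cover exactly 1
})

test_that("per-dynamic histograms partition the total exactly", {
  m <- bimodal_reference_model(seed = 9)
  sim <- simulate_tree_cover(m, horizon = 2000)
  hs <- histogram_by_dynamic(sim, bin_width = 0.1, burn_in = 100)
  expect_equal(hs$fire$freq + hs$no_fire$freq, hs$total$freq)
  expect_equal(sum(hs$total$freq), 1900)
  forced <- simulate_tree_cover(m, horizon = 500, forced_fire = FALSE, seed = 1)
  hf <- histogram_by_dynamic(forced, burn_in = 100)
  expect_true(hf$fire$empty)
  # constant trajectory: all mass in one bin
  mc <- tree_model(1, 1, a = 0, fire = fire_model(0.2, 0.8))
  sc <- simulate_tree_cover(mc, x0 = 0.55, horizon = 300,
                            forced_fire = FALSE, seed = 1)
  hc <- histogram_by_dynamic(sc, burn_in = 100)
  expect_equal(hc$total$mass[6], 1)  # bin [0.5, 0.6), center 0.55
})

test_that("bimodality index reproduces the two-point oracle", {
  # 70% of years under fire at cover 0.1, 30% no-fire at 0.9, 0.1 bins:
  # binned means are mu = 0.7*0.15 + 0.3*0.95 = 0.39 and mu* = 0.15
  r <- pooled_bimodality(c(rep(0.1, 70), rep(0.9, 30)),
                         c(rep(1, 70), rep(0, 30)))
  expect_equal(r$mu, 0.39, tolerance = 1e-12)
  expect_equal(r$mu_star, 0.15, tolerance = 1e-12)
  expect_equal(r$B, 0.24, tolerance = 1e-12)
  expect_equal(r$verdict, "bimodal")
  expect_equal(r$dominant_dynamic, "fire")
  expect_equal(r$mu_raw, 0.34, tolerance = 1e-12)
})

test_that("verdict is a pure threshold function flipping exactly at B = threshold", {
  covers <- c(rep(0.1, 70), rep(0.9, 30))
  status <- c(rep(1, 70), rep(0, 30))
  at <- pooled_bimodality(covers, status, threshold = 0.24)
  expect_equal(at$verdict, "bimodal")      # B >= threshold is bimodal
  above <- pooled_bimodality(covers, status, threshold = 0.24 + 1e-12)
  expect_equal(above$verdict, "unimodal")
})

test_that("single-dynamic constant-cover distributions are unimodal with B = 0", {
  r <- pooled_bimodality(rep(0.35, 50), rep(0, 50))
  expect_equal(r$B, 0)
  expect_equal(r$verdict, "unimodal")
  # exact dominance tie: broken toward no-fire and flagged
  rt <- pooled_bimodality(c(0.1, 0.9), c(1, 0))
  expect_true(rt$tie)
  expect_equal(rt$dominant_dynamic, "no_fire")
})

test_that("adding mass at the mean to both dynamics preserves dominance", {
  set.seed(3)
  covers <- runif(90)
  status <- rbinom(90, 1, 0.6)
  base <- pooled_bimodality(covers, status)
  extra_f <- round(sum(status) / 3)
  extra_nf <- round(sum(1 - status) / 3)
  r2 <- pooled_bimodality(c(covers, rep(base$mu, extra_f + extra_nf)),
                          c(status, rep(1, extra_f), rep(0, extra_nf)))
  expect_equal(r2$dominant_dynamic, base$dominant_dynamic)
})

test_that("chain-mode and trajectory-mode bimodality agree for the scalar model", {
  m <- bimodal_reference_model(seed = 21)
  sim <- simulate_tree_cover(m, horizon = 2e5)
  b_traj <- bimodality_index(sim, bin_width = 0.1, burn_in = 100)
  b_chain <- bimodality_index(build_chain(m, delta = 0.01), bin_width = 0.1)
  expect_lt(abs(b_traj$B - b_chain$B), 0.02)
  expect_equal(b_traj$verdict, "bimodal")
  expect_equal(b_chain$verdict, "bimodal")
})
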