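make_state <- function(v, spores = NULL) {
  population_state(setNames(v, paste0("s", seq_along(v))), spores)
}

test_that("particle conservation: full sporulation, no dilution, no capacity", {
  p <- simulation_params(2, growth_yield = 10, sporulation_fraction = 1,
                         dilution_fraction = 1, carrying_capacity = Inf)
  set.seed(1)
  st <- simulate_cycle(make_state(c(1000, 500)), p)
  # every cell sporulates, every spore survives the heat and the "bottleneck"
  expect_equal(sum(st$vegetative), sum(attr(st, "post_growth")))
  expect_equal(unname(st$vegetative), c(10000, 5000))
})

test_that("non-sporulating strains are eliminated by the heat-kill", {
  p <- simulation_params(2, growth_yield = 5,
                         sporulation_fraction = c(1, 0),
                         dilution_fraction = 1, carrying_capacity = Inf)
  set.seed(1)
  st <- simulate_cycle(make_state(c(1000, 1000)), p)
  expect_equal(unname(st$vegetative[2]), 0)
  expect_gt(st$vegetative[1], 0)
})

test_that("20x growth with 1/20 dilution conserves expected population size", {
  p <- simulation_params(1, growth_yield = 20, sporulation_fraction = 1,
                         dilution_fraction = 1 / 20, carrying_capacity = Inf)
  set.seed(7)
  n0 <- 1e6
  st <- simulate_cycle(make_state(n0), p)
  # transfer ~ Binomial(2e7, 1/20): mean n0, sd ~ 975
  se <- sqrt(20 * n0 * (1 / 20) * (19 / 20))
  expect_lt(abs(sum(st$vegetative) - n0), 5 * se)
})

test_that("one-cycle selection matches the closed form f' = f r / (f r + 1 - f)", {
  p <- simulation_params(2, growth_yield = 20,
                         sporulation_fraction = c(0.8, 0.4),
                         dilution_fraction = 1 / 20, carrying_capacity = Inf)
  set.seed(3)
  st <- simulate_cycle(make_state(c(5e5, 5e5)), p)
  f <- st$vegetative[1] / sum(st$vegetative)
  # expected 0.8 / (0.8 + 0.4) = 2/3; allow 3 binomial SEs on the transfer
  n_out <- sum(st$vegetative)
  se <- sqrt((2 / 3) * (1 / 3) / n_out)
  expect_lt(abs(f - 2 / 3), 3 * se)
})

test_that("neutrality: identical strains stay at 1/n on average", {
  n_strains <- 10
  n_rep <- 200
  panel <- build_strain_panel(paste0("rap", LETTERS[1:4]))  # 11 genotypes
  p <- simulation_params(n_strains, n_cycles = 3, initial_cells = 2e4,
                         carrying_capacity = Inf, seed = 99)
  finals <- matrix(NA_real_, n_rep, n_strains)
  for (r in seq_len(n_rep)) {
    tr <- simulate_experiment(panel[1:n_strains, ], p, mix = 1, replicate = r)
    finals[r, ] <- tr$frequencies[nrow(tr$frequencies), ]
  }
  means <- colMeans(finals)
  mc_se <- apply(finals, 2, sd) / sqrt(n_rep)
  expect_true(all(abs(means - 1 / n_strains) < 4 * mc_se))
})

test_that("trajectories are bit-identical under the same root seed", {
  fx <- full_fixture()
  p <- simulation_params(79, n_cycles = 4, seed = 1234)
  t1 <- simulate_experiment(fx$panel, p, mix = 2, replicate = 3)
  t2 <- simulate_experiment(fx$panel, p, mix = 2, replicate = 3)
  expect_identical(t1$frequencies, t2$frequencies)
  t3 <- simulate_experiment(fx$panel, p, mix = 2, replicate = 4)
  expect_false(identical(t1$frequencies, t3$frequencies))
})

test_that("a growth-yield advantage produces monotone frequency gain", {
  n <- 4
  panel <- build_strain_panel(c("rapA", "rapB"))  # WT, A, B, AB
  yld <- c(30, rep(20, n - 1))  # 1.5x advantage for the first strain
  p <- simulation_params(n, growth_yield = yld, sporulation_fraction = 0.8,
                         n_cycles = 9, initial_cells = 1e8,
                         carrying_capacity = Inf, seed = 5)
  tr <- simulate_experiment(panel[1:n, ], p)
  f <- tr$frequencies[, 1]
  expect_true(all(diff(f) > 0))
  # deterministic-limit recursion as an oracle for the final frequency
  fdet <- 1 / n
  for (k in 1:9) fdet <- fdet * 1.5 / (fdet * 1.5 + (1 - fdet))
  expect_lt(abs(f[10] - fdet), 0.01)
})

test_that("n_cycles = 0 returns only the inoculum", {
  panel <- build_strain_panel()
  p <- simulation_params(79, n_cycles = 0)
  tr <- simulate_experiment(panel, p)
  expect_equal(nrow(tr$frequencies), 1)
  expect_equal(unname(tr$frequencies[1, ]), rep(1 / 79, 79))
})

test_that("extinction is flagged, not raised", {
  p <- simulation_params(2, growth_yield = 2, sporulation_fraction = 0,
                         carrying_capacity = Inf)
  set.seed(1)
  st <- simulate_cycle(make_state(c(100, 100)), p)
  expect_true(st$extinct)
  expect_equal(sum(st$vegetative), 0)
})

test_that("carrying capacity rescales composition-preservingly", {
  p <- simulation_params(2, growth_yield = c(40, 20),
                         sporulation_fraction = 1, dilution_fraction = 1,
                         carrying_capacity = 3e4)
  set.seed(2)
  st <- simulate_cycle(make_state(c(1000, 1000)), p)
  pg <- attr(st, "post_growth")
  expect_equal(sum(pg), 3e4)
  expect_equal(unname(pg[1] / pg[2]), 2, tolerance = 1e-3)
})

test_that("the fitness-modifier hook scales growth at the stated cycle", {
  panel <- build_strain_panel(c("rapA", "rapB"))
  mod <- function(cycle) if (cycle >= 5) c(2, rep(1, 3)) else rep(1, 4)
  p <- simulation_params(4, n_cycles = 9, initial_cells = 1e7,
                         carrying_capacity = Inf, seed = 8,
                         fitness_modifier = mod)
  tr <- simulate_experiment(panel, p)
  f <- tr$frequencies[, 1]
  expect_lt(abs(f[5] - 0.25), 0.01)   # neutral until cycle 5
  expect_gt(f[10], 0.8)               # then sweeps
})

test_that("simulate_competition recovers the sporulation ratio in expectation", {
  set.seed(42)
  recs <- do.call(rbind, lapply(1:10, function(i)
    simulate_competition(1e5, 1e5, spo_a = 0.8, spo_b = 0.4)))
  sf <- mapply(sporulation_fitness, recs$spores_a_48h, recs$cfu_a_start,
               recs$spores_b_48h, recs$cfu_b_start)
  expect_lt(abs(mean(sf) - 2) / 2, 0.1)
})
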