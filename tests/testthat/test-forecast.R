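# Toy cells use point-mass positives (gamma shape 1e12, so draws round to
# the mean exactly), which makes every forward distribution enumerable.

test_that("forward simulation matches exhaustive enumeration on a toy", {
  cells <- toy_cells(22:23, p = 0.5, mu = 1000)
  set.seed(1)
  tot <- forward_simulate_remainder(0, 22, "weekday", ref_profile(), cells,
                                    n_paths = 10000)
  # two independent hours, each 0 or 1000 w.p. 1/2:
  # P(2000) = 1/4, P(1000) = 1/2, P(0) = 1/4
  expect_setequal(unique(tot), c(0, 1000, 2000))
  se <- sqrt(0.25 * 0.75 / 10000)
  expect_lt(abs(mean(tot >= 2000) - 0.25), 3 * se)
  expect_lt(abs(mean(tot == 0) - 0.25), 3 * se)
  # trajectory conservation: totals never fall below the start
  tot2 <- forward_simulate_remainder(3000, 22, "weekday", ref_profile(),
                                     cells, n_paths = 500)
  expect_true(all(tot2 >= 3000))
})

test_that("boundary and degenerate futures behave exactly", {
  cells <- toy_cells(12:23, p = 0.5, mu = 1000)
  # h = 24: no hours left
  expect_identical(
    forward_simulate_remainder(4321, 24, "weekday", ref_profile(), cells,
                               n_paths = 50),
    rep(4321, 50))
  # all remaining hurdles closed: total stays at c on every path
  dead <- toy_cells(20:23, p = 1e-12, mu = 1000)
  set.seed(2)
  expect_identical(
    unique(forward_simulate_remainder(700, 20, "weekday", ref_profile(),
                                      dead, n_paths = 300)),
    700)
  # missing cell named in the error
  expect_error(
    forward_simulate_remainder(0, 21, "weekday", ref_profile(),
                               toy_cells(22:23)),
    "h21_weekday_S1")
})

test_that("goal probability matches enumeration and its trivial cases", {
  cells <- toy_cells(22:23, p = 0.5, mu = 1000)
  set.seed(3)
  gp <- goal_probability(0, 22, "weekday", ref_profile(), cells,
                         goal = 2000, n_paths = 10000)
  expect_lt(abs(gp$probability - 0.25), 3 * gp$se)
  expect_true(gp$interval[1] >= 0 && gp$interval[2] <= 1)
  # already achieved / zero goal
  expect_equal(goal_probability(5000, 22, "weekday", ref_profile(), cells,
                                goal = 5000, n_paths = 200)$probability, 1)
  expect_equal(goal_probability(0, 22, "weekday", ref_profile(), cells,
                                goal = 0, n_paths = 200)$probability, 1)
  expect_warning(goal_probability(0, 22, "weekday", ref_profile(), cells,
                                  goal = 1000, n_paths = 50), "noisy")
})

test_that("goal probability is monotone in accumulated steps and in the goal", {
  cells <- toy_cells(20:23, p = 0.6, mu = 800)
  set.seed(4)
  grid <- seq(0, 12000, by = 1500)
  pr <- vapply(grid, function(c0) {
    goal_probability(c0, 20, "weekday", ref_profile(), cells,
                     goal = 10000, n_paths = 4000)$probability
  }, numeric(1))
  expect_true(all(diff(pr) >= -0.03)) # non-decreasing up to MC noise
  pg <- vapply(c(5000, 7500, 10000), function(g) {
    goal_probability(6000, 20, "weekday", ref_profile(), cells,
                     goal = g, n_paths = 4000)$probability
  }, numeric(1))
  expect_true(all(diff(pg) <= 0.03)) # non-increasing in the goal
})

test_that("predicted mean chains the one-step closed form", {
  # one remaining hour: mean = c + p * mu exactly (point-mass positives)
  p <- 0.37
  mu <- 600
  cells <- toy_cells(23, p = p, mu = mu)
  set.seed(5)
  pm <- predict_mean_and_ci(2000, 23, "weekday", ref_profile(), cells,
                            n_draws = 40, n_paths_per_draw = 400)
  mc_se <- sd(pm$draw_means) / sqrt(length(pm$draw_means))
  expect_lt(abs(pm$mean - (2000 + p * mu)), 4 * mc_se + 1)
  # degenerate always-zero future: mean = c with a zero-width interval
  dead <- toy_cells(23, p = 1e-12, mu = 500)
  pm0 <- predict_mean_and_ci(900, 23, "weekday", ref_profile(), dead,
                             n_draws = 20, n_paths_per_draw = 50)
  expect_equal(pm0$mean, 900)
  expect_equal(pm0$lower, 900)
  expect_equal(pm0$upper, 900)
  # mean forecast non-decreasing along the accumulated grid
  cells2 <- toy_cells(21:23, p = 0.5, mu = 700)
  set.seed(6)
  ms <- vapply(seq(0, 12000, 2000), function(c0) {
    predict_mean_and_ci(c0, 21, "weekday", ref_profile(), cells2,
                        n_draws = 20, n_paths_per_draw = 200)$mean
  }, numeric(1))
  expect_true(all(diff(ms) > 0))
})

test_that("threshold recommendation matches a brute-force grid oracle", {
  cells <- toy_cells(22:23, p = 1 - 1e-12, mu = 500) # deterministic +1000
  set.seed(7)
  r <- recommend_thresholds(22, 10000, "weekday", ref_profile(), cells,
                            n_draws = 10, n_paths_per_draw = 20,
                            n_paths = 500)
  # every path adds exactly 1000, so the smallest qualifying c is 9000
  expect_equal(r$threshold, 9000)
  expect_equal(r$probability, 1)
  # brute-force scan oracle over the full grid
  grid <- seq(0, 12500, 500)
  means <- vapply(grid, function(c0) {
    predict_mean_and_ci(c0, 22, "weekday", ref_profile(), cells,
                        n_draws = 5, n_paths_per_draw = 10)$mean
  }, numeric(1))
  expect_equal(r$threshold, grid[which(means >= 10000)[1]])
  # goal 0: the first grid point qualifies
  r0 <- recommend_thresholds(22, 0, "weekday", ref_profile(), cells,
                             n_draws = 5, n_paths_per_draw = 10,
                             n_paths = 200)
  expect_equal(r0$threshold, 0)
  # always-zero future, goal 10,000: first grid point at or above the goal
  dead <- toy_cells(22:23, p = 1e-12, mu = 500)
  rd <- recommend_thresholds(22, 10000, "weekday", ref_profile(), dead,
                             n_draws = 5, n_paths_per_draw = 10,
                             n_paths = 200)
  expect_equal(rd$threshold, 10000)
  expect_equal(rd$probability, 1)
  # unattainable: grid capped below the goal with no future steps
  ru <- recommend_thresholds(22, 10000, "weekday", ref_profile(), dead,
                             grid = seq(0, 5000, 500), n_draws = 5,
                             n_paths_per_draw = 10, n_paths = 200)
  expect_true(is.na(ru$threshold))
})

test_that("probability criterion and consistency at the threshold", {
  cells <- toy_cells(22:23, p = 0.5, mu = 1000)
  set.seed(8)
  rp <- recommend_thresholds(22, 10000, "weekday", ref_profile(), cells,
                             criterion = "probability", prob_target = 0.7,
                             n_paths = 4000)
  # enumeration: from c the reachable totals are c, c+1000, c+2000 with
  # probs 1/4, 1/2, 1/4 -> P(>= 10000) is 1 for c >= 10,000, 0.75 for
  # c in [9000, 9999], 0.25 for c in [8000, 8999]
  expect_equal(rp$threshold, 9000)
  set.seed(9)
  p_at <- goal_probability(rp$threshold, 22, "weekday", ref_profile(),
                           cells, 10000, n_paths = 4000)$probability
  p_below <- goal_probability(rp$threshold - 500, 22, "weekday",
                              ref_profile(), cells, 10000,
                              n_paths = 4000)$probability
  expect_gte(p_at, p_below)
})

test_that("recommendation tables assemble across hours and goals", {
  cells <- toy_cells(21:23, p = 1 - 1e-12, mu = 500)
  set.seed(10)
  tab <- recommendation_table("weekday", ref_profile(), cells,
                              hours = 21:22, goals = c(5000, 10000),
                              n_draws = 5, n_paths_per_draw = 10,
                              n_paths = 200)
  expect_equal(nrow(tab), 4)
  # more remaining hours need a smaller threshold for the same goal
  t10 <- tab[tab$goal == 10000, ]
  expect_lte(t10$threshold[t10$hour == 21], t10$threshold[t10$hour == 22])
})

test_that("posterior fits plug into forecasting as cell draws", {
  cfg <- tiny_gen_config()
  tp <- truth_parameters(cfg)[["h23_weekday_S1"]]
  sim <- simulate_cell_data(tp, 800, "S1", seed = 12)
  fit <- run_mcmc(sim$X, sim$y, n_chains = 2, n_burn = 150, n_keep = 150,
                  seed = 13)
  cf <- as_cell_fit(fit)
  expect_equal(cf$n_draws, 300)
  expect_true(cf$has_cum)
  cells <- list()
  for (s in c("S1", "S2", "S3", "S4")) {
    cells[[cell_key(23, "weekday", s)]] <- fit
  }
  set.seed(14)
  tot <- forward_simulate_remainder(100, 23, "weekday", ref_profile(),
                                    cells, n_paths = 2000)
  p_true <- plogis(drop(c(1, rep(0, 8), 0.01) %*% tp$beta))
  expect_lt(abs(mean(tot > 100) - p_true), 0.1)
})
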