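test_that("generator config validates marginals and bounds", {
  expect_error(generator_config(demographic_marginals = list(
    sex = c(female = 0.7, male = 0.2),
    age_group = default_marginals()$age_group,
    bmi_group = default_marginals()$bmi_group)), "sex")
  expect_error(generator_config(dispersion = 0))
  expect_error(generator_config(date_start = "2018-02-01",
                                date_end = "2018-01-01"))
})

test_that("profile generation is deterministic and honours the empty case", {
  cfg0 <- generator_config(n_participants = 0)
  expect_equal(nrow(generate_profiles(cfg0)), 0)
  cfg <- generator_config(n_participants = 100, seed = 7)
  p1 <- generate_profiles(cfg)
  p2 <- generate_profiles(cfg)
  expect_identical(p1, p2)
  expect_true(all(p1$age >= 17))
  expect_true(all(p1$weight >= 30 & p1$weight <= 300))
  expect_true(all(p1$height >= 101 & p1$height <= 220))
  expect_false(any(p1$pledge))
  # stated BMI group consistent with derived bmi
  expect_identical(p1$bmi_group,
                   derive_groups(p1[, 1:6])$bmi_group)
})

test_that("generated marginals track the configured cohort fractions", {
  cfg <- generator_config(n_participants = 20000, seed = 13)
  p <- generate_profiles(cfg)
  m <- default_marginals()
  # male fraction within 2 percentage points of 40.4%
  expect_lt(abs(mean(p$sex == "male") - 0.404), 0.02)
  # every category frequency within 3 SE of its configured marginal
  for (cat in c("sex", "age_group", "bmi_group")) {
    col <- c(sex = "sex", age_group = "age_group",
             bmi_group = "bmi_group")[[cat]]
    for (lv in names(m[[cat]])) {
      pr <- m[[cat]][[lv]]
      se <- sqrt(pr * (1 - pr) / 20000)
      expect_lt(abs(mean(p[[col]] == lv) - pr), 3 * se + 0.003)
    }
  }
})

test_that("hourly generation is deterministic, non-negative and hurdle-consistent", {
  cfg <- tiny_gen_config()
  p <- generate_profiles(cfg)
  d1 <- generate_hourly_steps(p, cfg)
  d2 <- generate_hourly_steps(p, cfg)
  expect_identical(d1, d2)
  H <- as.matrix(d1[, paste0("h", 0:23), with = FALSE])
  expect_true(all(H >= 0))
  expect_true(all(H == floor(H)))
  expect_equal(d1$daily_total, unname(rowSums(H)))
  expect_equal(nrow(d1), nrow(p) * 7)
  # degenerate hurdle: activity probability 0 everywhere -> all zeros
  prof0 <- copy(cfg$diurnal_profile)
  prof0$p_active <- 1e-12
  cfg0 <- generator_config(n_participants = 10, date_end = "2018-01-10",
                           diurnal_profile = prof0, seed = 2)
  d0 <- generate_hourly_steps(generate_profiles(cfg0), cfg0)
  expect_true(all(as.matrix(d0[, paste0("h", 0:23), with = FALSE]) == 0))
})

test_that("goal boost bunches daily totals just above 10,000", {
  base <- list(n_participants = 400, date_start = "2018-01-08",
               date_end = "2018-01-14", seed = 21)
  cfg_b <- do.call(generator_config, base)
  d_b <- generate_hourly_steps(generate_profiles(cfg_b), cfg_b)
  lo <- sum(d_b$daily_total >= 9500 & d_b$daily_total < 10000)
  hi <- sum(d_b$daily_total >= 10000 & d_b$daily_total < 10500)
  expect_gt(hi, lo) # the spike direction observed above the top goal
  cfg_0 <- do.call(generator_config, c(base, list(
    goal_boost = list(window_steps = 0, boost_probability = 0,
                      mean_boost = 1))))
  d_0 <- generate_hourly_steps(generate_profiles(cfg_0), cfg_0)
  lo0 <- sum(d_0$daily_total >= 9500 & d_0$daily_total < 10000)
  hi0 <- sum(d_0$daily_total >= 10000 & d_0$daily_total < 10500)
  # no-boost null: neighbouring bands comparable, no discontinuity
  expect_gt(hi0 / lo0, 2 / 3)
  expect_lt(hi0 / lo0, 3 / 2)
})

test_that("block emission conserves hourly sums and round-trips", {
  cfg <- tiny_gen_config()
  d <- generate_hourly_steps(generate_profiles(cfg), cfg)
  b <- emit_block_records(d, cfg)
  expect_true(all(b$block_index %in% 0:47))
  expect_true(all(b$steps > 0))
  # conservation per participant-day
  tot <- as.data.table(b)[, .(s = sum(steps)), by = .(participant_id, date)]
  mrg <- merge(tot, d[, c("participant_id", "date", "daily_total"),
                      with = FALSE], by = c("participant_id", "date"))
  expect_equal(mrg$s, mrg$daily_total)
  # clean + aggregate recovers the generated hourly matrix exactly
  agg <- impute_and_aggregate(clean_blocks(b))
  keep <- d[d$daily_total > 0, ]
  setkey(agg, participant_id, date)
  dd <- as.data.table(keep)[order(participant_id, date)]
  expect_equal(as.matrix(agg[, paste0("h", 0:23), with = FALSE]),
               as.matrix(dd[, paste0("h", 0:23), with = FALSE]))
})

test_that("injected corruption is labelled and cleaned away exactly", {
  cfg <- tiny_gen_config()
  d <- generate_hourly_steps(generate_profiles(cfg), cfg)
  b1 <- emit_block_records(d, cfg, corrupt_n = 1L)
  side <- attr(b1, "corruption")
  expect_equal(nrow(side), 1)
  expect_equal(side$kind, "bad_block_index")
  expect_equal(side$block_index, 48L)
  cl <- clean_blocks(b1)
  expect_equal(sum(attr(cl, "removed")), 1)
  expect_equal(unname(attr(cl, "removed")["bad_block_index"]), 1)
  b6 <- emit_block_records(d, cfg, corrupt_n = 6L)
  cl6 <- clean_blocks(b6)
  expect_equal(sum(attr(cl6, "removed")), 6)
  # cleaning the corrupted stream equals the uncorrupted stream
  b0 <- emit_block_records(d, cfg)
  expect_equal(as.data.frame(cl6), as.data.frame(clean_blocks(b0)),
               ignore_attr = TRUE)
})

test_that("truth records exist per cell and reproduce simulated moments", {
  cfg <- tiny_gen_config()
  tr <- truth_parameters(cfg)
  # 12 morning + 12 x 4 stratified cells per day type
  expect_length(tr, 2 * (12 + 48))
  expect_true(all(c("h00_weekday_M", "h23_weekend_S4") %in% names(tr)))
  tp <- tr[["h13_weekday_S1"]]
  expect_s3_class(tp, "twopart_params")
  sim <- simulate_cell_data(tp, 40000, "S1", seed = 3)
  p_exp <- mean(plogis(drop(sim$X %*% tp$beta)))
  expect_lt(abs(mean(sim$y > 0) - p_exp), 3 * sqrt(p_exp * (1 - p_exp) / 40000))
})

test_that("generator artefacts round-trip through CSV and JSON", {
  cfg <- tiny_gen_config()
  p <- generate_profiles(cfg)
  d <- generate_hourly_steps(p, cfg)
  b <- emit_block_records(d, cfg)
  td <- tempdir()
  write_blocks_csv(b, file.path(td, "b.csv"))
  write_profiles_csv(p, file.path(td, "p.csv"))
  b2 <- read_blocks_csv(file.path(td, "b.csv"))
  expect_equal(as.data.frame(b2),
               as.data.frame(b[, c("participant_id", "date", "block_index",
                                   "steps"), with = FALSE]),
               ignore_attr = TRUE)
  p2 <- read_profiles_csv(file.path(td, "p.csv"))
  expect_equal(p2$weight, p$weight)
  write_config_json(cfg, file.path(td, "cfg.json"))
  cfg2 <- read_config_json(file.path(td, "cfg.json"))
  expect_equal(cfg2$demographic_marginals, cfg$demographic_marginals)
  expect_equal(cfg2$seed, cfg$seed)
  expect_identical(generate_profiles(cfg2), p)
})
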