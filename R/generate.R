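## Synthetic tracker-data generator. The motivating programme data are not
## openly available, so this module generates participant profiles and
## intra-day step counts with the statistical structure the analysis
## assumes: diurnal weekday/weekend activity with commute and lunch peaks,
## a high proportion of zero hours, right-skewed positive counts,
## demographic effects, and an optional evening "goal boost" that bunches
## daily totals just above the incentive thresholds. Generation draws
## literally from per-cell two-part GLM parameters (the truth records), so
## with the boost disabled each model cell's data-generating process is
## exactly the family the inference module fits.

#' Default demographic marginals
#'
#' The exact participant fractions of the motivating programme cohort
#' (N = 3075): 40.4% male; age groups 14.8/25.0/25.2/20.8/14.1%; BMI
#' groups 4.2/28.3/39.1/28.4%.
#'
#' @return Named list of probability vectors for `sex`, `age_group`,
#'   `bmi_group`.
#' @export
default_marginals <- function() {
  list(
    sex = c(female = 1834, male = 1241) / 3075,
    age_group = setNames(c(456, 769, 775, 640, 435) / 3075, .AGE_LEVELS),
    bmi_group = setNames(c(128, 870, 1203, 874) / 3075, .BMI_LEVELS)
  )
}

#' Default diurnal activity profile
#'
#' Weekday tri-modal (commute ~7-9 a.m., lunch ~12-2 p.m., evening
#' ~6-8 p.m.), weekend bi-modal (late morning, early evening); the senior
#' band (age 60+) starts earlier with a larger morning peak and smaller
#' lunch/evening peaks. `p_active` is the hourly probability of any steps
#' for the reference demographic group; `mean_pos` the mean of positive
#' counts. Night inactivity levels put the overall zero proportion near
#' 45% on weekdays and 51% on weekends.
#'
#' @return `data.table` keyed by day type, age band and hour.
#' @export
default_diurnal_profile <- function() {
  wd_a_p <- c(.10, .06, .04, .03, .03, .08, .45, .85, .88, .72, .70, .72,
              .88, .86, .72, .70, .72, .80, .90, .88, .72, .60, .45, .25)
  wd_a_m <- c(60, 40, 30, 30, 30, 50, 300, 1250, 1200, 600, 500, 600,
              1300, 1250, 600, 500, 600, 900, 1600, 1600, 800, 600, 400, 200)
  wd_s_p <- c(.12, .07, .05, .04, .05, .15, .55, .80, .90, .88, .75, .72,
              .80, .78, .70, .68, .70, .78, .80, .75, .60, .45, .30, .15)
  wd_s_m <- c(60, 40, 30, 30, 40, 80, 500, 1200, 1500, 1300, 700, 600,
              1000, 950, 600, 550, 650, 900, 1200, 1100, 600, 400, 250, 150)
  we_a_p <- c(.12, .08, .05, .04, .04, .06, .25, .50, .65, .78, .80, .75,
              .78, .75, .70, .68, .75, .82, .80, .70, .60, .50, .40, .22)
  we_a_m <- c(80, 50, 40, 30, 30, 50, 200, 500, 1000, 1500, 1400, 800,
              900, 800, 600, 550, 900, 1500, 1300, 900, 600, 450, 300, 180)
  we_s_p <- c(.12, .08, .05, .04, .05, .10, .40, .70, .85, .85, .80, .72,
              .75, .72, .68, .65, .72, .78, .72, .62, .50, .38, .25, .12)
  we_s_m <- c(70, 50, 40, 30, 40, 70, 350, 900, 1400, 1400, 1000, 700,
              850, 750, 600, 550, 800, 1200, 1000, 750, 500, 350, 220, 130)
  data.table(
    day_type = rep(.DAY_TYPES, each = 48L),
    age_band = rep(rep(c("adult", "senior"), each = 24L), times = 2L),
    hour = rep(0:23, times = 4L),
    p_active = c(wd_a_p, wd_s_p, we_a_p, we_s_p),
    mean_pos = c(wd_a_m, wd_s_m, we_a_m, we_s_m)
  )
}

#' Default covariate effects
#'
#' Multiplicative effects on the activity odds and the positive mean,
#' relative to the reference group (female, age 17-29, BMI 18.5-22.9).
#' Directions follow the observed gradients: daily steps rise with age,
#' are higher for men and for the overweight group, lower for the obese
#' group; the negative `cum10k` effects encode easing off once goals are
#' achieved.
#'
#' @return List with `activity_odds` and `mean_mult` named vectors.
#' @export
default_covariate_effects <- function() {
  list(
    activity_odds = c(`age30-39` = 0.97, `age40-49` = 1.06,
                      `age50-59` = 1.12, `age60+` = 1.00,
                      `bmi<18.5` = 0.96, `bmi23-27.4` = 1.05,
                      `bmi>=27.5` = 0.90, sexmale = 1.05, cum10k = 0.55),
    mean_mult = c(`age30-39` = 1.03, `age40-49` = 1.10,
                  `age50-59` = 1.13, `age60+` = 1.00,
                  `bmi<18.5` = 0.94, `bmi23-27.4` = 1.05,
                  `bmi>=27.5` = 0.88, sexmale = 1.12, cum10k = 0.65)
  )
}

#' Synthetic-data generator configuration
#'
#' @param n_participants Number of participants (>= 0).
#' @param date_start,date_end Calendar window (inclusive).
#' @param demographic_marginals List of probability vectors for `sex`,
#'   `age_group`, `bmi_group`; each must sum to one.
#' @param diurnal_profile Table (day_type, age_band, hour) -> activity
#'   probability and mean positive steps for the reference group.
#' @param dispersion Gamma shape (> 0) of positive hourly counts.
#' @param covariate_effects Multipliers on activity odds and positive mean
#'   per covariate (including `cum10k`, per unit of accumulated steps /
#'   10,000, applied from noon onward).
#' @param goal_boost List `(window_steps, boost_probability, mean_boost)`:
#'   in the evening (6 p.m. onward), when the running total is within
#'   `window_steps` below the nearest unmet goal, the activity probability
#'   is raised by `boost_probability` of the remaining headroom and the
#'   positive mean is inflated to at least the deficit - the extra effort
#'   that bunches daily totals just above the incentive thresholds. Set
#'   `window_steps = 0` to disable.
#' @param seed Integer seed; all generator output is deterministic given it.
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(n_participants = 50L,
                             date_start = "2018-01-08",
                             date_end = "2018-01-21",
                             demographic_marginals = default_marginals(),
                             diurnal_profile = default_diurnal_profile(),
                             dispersion = 1.5,
                             covariate_effects = default_covariate_effects(),
                             goal_boost = list(window_steps = 1000,
                                               boost_probability = 0.5,
                                               mean_boost = 1.5),
                             seed = 1L) {
  stopifnot(n_participants >= 0, dispersion > 0,
            as.Date(date_start) <= as.Date(date_end),
            goal_boost$window_steps >= 0,
            goal_boost$boost_probability >= 0,
            goal_boost$boost_probability <= 1)
  for (nm in c("sex", "age_group", "bmi_group")) {
    m <- demographic_marginals[[nm]]
    if (is.null(m) || any(m < 0) || abs(sum(m) - 1) > 1e-8) {
      stop("demographic marginals for '", nm, "' must be non-negative and sum to 1")
    }
  }
  dp <- as.data.table(diurnal_profile)
  stopifnot(all(dp$p_active >= 0 & dp$p_active <= 1),
            all(dp$mean_pos > 0))
  structure(list(n_participants = as.integer(n_participants),
                 date_start = date_start, date_end = date_end,
                 demographic_marginals = demographic_marginals,
                 diurnal_profile = dp, dispersion = dispersion,
                 covariate_effects = covariate_effects,
                 goal_boost = goal_boost, seed = as.integer(seed)),
            class = "generator_config")
}

#' Ground-truth two-part parameters implied by a generator configuration
#'
#' One record per model cell (hour x day type x stratum), in the exact
#' parameterisation the inference module fits. The hour-specific senior
#' baseline shift is folded into that cell's age-60+ dummy coefficient;
#' afternoon/evening strata share identical truth (the generating process
#' depends on accumulated steps only through the `cum10k` covariate).
#'
#' @param config A [generator_config()].
#' @return Named list of [twopart_params()] keyed by [cell_key()].
#' @export
truth_parameters <- function(config) {
  eff <- config$covariate_effects
  ao <- eff$activity_odds
  mm <- eff$mean_mult
  dp <- config$diurnal_profile
  dnames <- c("(Intercept)", "age30-39", "age40-49", "age50-59", "age60+",
              "bmi<18.5", "bmi23-27.4", "bmi>=27.5", "sexmale")
  out <- list()
  for (dt in .DAY_TYPES) {
    for (h in 0:23) {
      a <- dp[day_type == dt & hour == h & age_band == "adult"]
      s <- dp[day_type == dt & hour == h & age_band == "senior"]
      sb_b <- qlogis(s$p_active) - qlogis(a$p_active)
      sb_g <- log(s$mean_pos) - log(a$mean_pos)
      beta <- c(qlogis(a$p_active), log(ao["age30-39"]), log(ao["age40-49"]),
                log(ao["age50-59"]), log(ao["age60+"]) + sb_b,
                log(ao["bmi<18.5"]), log(ao["bmi23-27.4"]),
                log(ao["bmi>=27.5"]), log(ao["sexmale"]))
      gam <- c(log(a$mean_pos), log(mm["age30-39"]), log(mm["age40-49"]),
               log(mm["age50-59"]), log(mm["age60+"]) + sb_g,
               log(mm["bmi<18.5"]), log(mm["bmi23-27.4"]),
               log(mm["bmi>=27.5"]), log(mm["sexmale"]))
      names(beta) <- names(gam) <- dnames
      if (h < 12L) {
        out[[cell_key(h, dt, "M")]] <-
          twopart_params(beta, gam, config$dispersion)
      } else {
        beta <- c(beta, cum10k = unname(log(ao["cum10k"])))
        gam <- c(gam, cum10k = unname(log(mm["cum10k"])))
        for (st in .STRATA) {
          out[[cell_key(h, dt, st)]] <-
            twopart_params(beta, gam, config$dispersion)
        }
      }
    }
  }
  out
}

#' Generate participant profiles
#'
#' Sex, age group, and BMI group are drawn from the configured marginals;
#' age is uniform within its group, height is drawn around sex-specific
#' means, and weight is back-computed from a BMI drawn within the group so
#' that the derived BMI category is consistent with the draw.
#'
#' @param config A [generator_config()].
#' @return `data.table` with `participant_id`, `sex`, `age`, `height`,
#'   `weight`, `pledge` (all `FALSE`) plus derived `age_group`, `bmi`,
#'   `bmi_group`. Deterministic given `config$seed`.
#' @export
generate_profiles <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_participants
  cols <- c("participant_id", "sex", "age", "height", "weight", "pledge")
  if (n == 0L) {
    empty <- data.table(participant_id = character(), sex = character(),
                        age = numeric(), height = numeric(),
                        weight = numeric(), pledge = logical())
    return(empty)
  }
  m <- config$demographic_marginals
  set.seed(config$seed)
  sex <- sample(names(m$sex), n, replace = TRUE, prob = m$sex)
  ag <- sample(names(m$age_group), n, replace = TRUE, prob = m$age_group)
  bg <- sample(names(m$bmi_group), n, replace = TRUE, prob = m$bmi_group)
  age_lo <- c(`17-29` = 17, `30-39` = 30, `40-49` = 40, `50-59` = 50,
              `60+` = 60)
  age_hi <- c(`17-29` = 29, `30-39` = 39, `40-49` = 49, `50-59` = 59,
              `60+` = 79)
  age <- floor(runif(n, age_lo[ag], age_hi[ag] + 1))
  height <- round(rnorm(n, ifelse(sex == "male", 171, 159), 6), 1)
  height <- pmin(pmax(height, 145), 200)
  bmi_lo <- c(`<18.5` = 16, `18.5-22.9` = 18.5, `23-27.4` = 23,
              `>=27.5` = 27.5)
  bmi_hi <- c(`<18.5` = 18.4, `18.5-22.9` = 22.9, `23-27.4` = 27.4,
              `>=27.5` = 35)
  bmi <- runif(n, bmi_lo[bg], bmi_hi[bg])
  weight <- round(bmi * (height / 100)^2, 1)
  out <- data.table(participant_id = sprintf("P%05d", seq_len(n)),
                    sex = sex, age = age, height = height, weight = weight,
                    pledge = FALSE)
  derive_groups(out)
}

#' Generate hourly step counts for participant-days
#'
#' Every participant contributes one day per calendar date in the window.
#' Hour by hour, the count is zero with the hurdle probability of the
#' matching truth cell and otherwise a rounded gamma draw (floor one)
#' around the cell's conditional mean; from noon onward both parts depend
#' on the accumulated total through the scaled `cum10k` covariate, and in
#' the evening the configured goal boost may apply.
#'
#' @param profiles Profiles as returned by [generate_profiles()].
#' @param config A [generator_config()].
#' @return `data.table` with `participant_id`, `date`, `day_type`,
#'   `h0`-`h23` and `daily_total`. Deterministic given `config$seed`.
#' @export
generate_hourly_steps <- function(profiles, config) {
  stopifnot(inherits(config, "generator_config"))
  p <- as.data.table(profiles)
  if (nrow(p) == 0L) {
    empty <- data.table(participant_id = character(), date = character(),
                        day_type = character())
    for (h in c(paste0("h", 0:23), "daily_total")) empty[, (h) := numeric()]
    return(empty[])
  }
  if (!all(c("age_group", "bmi_group") %in% names(p))) p <- derive_groups(p)
  X0 <- build_design(p, include_cum = FALSE)
  dates <- seq(as.Date(config$date_start), as.Date(config$date_end), by = 1)
  dts <- ifelse(format(dates, "%u") %in% c("6", "7"), "weekend", "weekday")
  truth <- truth_parameters(config)

  n_p <- nrow(p)
  n_d <- length(dates)
  pid <- rep(p$participant_id, times = n_d)
  prow <- rep(seq_len(n_p), times = n_d)
  date_v <- rep(as.character(dates), each = n_p)
  dt_v <- rep(dts, each = n_p)
  n_pd <- n_p * n_d

  # per (day_type, hour): linear predictors at cum = 0 for every participant
  eta_b0 <- eta_g0 <- array(NA_real_, dim = c(n_p, 24L, 2L),
                            dimnames = list(NULL, NULL, .DAY_TYPES))
  b_cum <- g_cum <- matrix(0, 24L, 2L, dimnames = list(NULL, .DAY_TYPES))
  for (dt in .DAY_TYPES) {
    for (h in 0:23) {
      key <- cell_key(h, dt, if (h < 12L) "M" else "S1")
      tp <- truth[[key]]
      eta_b0[, h + 1L, dt] <- drop(X0 %*% tp$beta[1:9])
      eta_g0[, h + 1L, dt] <- drop(X0 %*% tp$gamma[1:9])
      if (h >= 12L) {
        b_cum[h + 1L, dt] <- tp$beta[["cum10k"]]
        g_cum[h + 1L, dt] <- tp$gamma[["cum10k"]]
      }
    }
  }

  gb <- config$goal_boost
  boost_on <- gb$window_steps > 0 && gb$boost_probability > 0
  alpha <- config$dispersion
  set.seed(config$seed + 1000L)
  Y <- matrix(0, n_pd, 24L)
  cum <- numeric(n_pd)
  iwd <- dt_v == "weekday"
  for (h in 0:23) {
    eta_b <- ifelse(iwd, eta_b0[cbind(prow, h + 1L, 1L)],
                    eta_b0[cbind(prow, h + 1L, 2L)])
    eta_g <- ifelse(iwd, eta_g0[cbind(prow, h + 1L, 1L)],
                    eta_g0[cbind(prow, h + 1L, 2L)])
    if (h >= 12L) {
      sc <- cum / 10000
      eta_b <- eta_b + ifelse(iwd, b_cum[h + 1L, 1L], b_cum[h + 1L, 2L]) * sc
      eta_g <- eta_g + ifelse(iwd, g_cum[h + 1L, 1L], g_cum[h + 1L, 2L]) * sc
    }
    pr <- plogis(eta_b)
    mu <- exp(eta_g)
    if (boost_on && h >= 18L) {
      nxt <- .GOALS[findInterval(cum, .GOALS) + 1L]
      deficit <- nxt - cum
      hit <- !is.na(nxt) & deficit <= gb$window_steps
      if (any(hit)) {
        pr[hit] <- pr[hit] + gb$boost_probability * (1 - pr[hit])
        mu[hit] <- pmax(mu[hit] * gb$mean_boost, deficit[hit] + 250)
      }
    }
    active <- runif(n_pd) < pr
    y <- numeric(n_pd)
    if (any(active)) {
      y[active] <- pmax(1, round(rgamma(sum(active), shape = alpha,
                                        rate = alpha / mu[active])))
    }
    Y[, h + 1L] <- y
    cum <- cum + y
  }
  out <- data.table(participant_id = pid, date = date_v, day_type = dt_v)
  for (h in 0:23) out[, (paste0("h", h)) := Y[, h + 1L]]
  out[, daily_total := cum]
  out[]
}

#' Emit raw 30-minute block records (optionally corrupted)
#'
#' Splits each positive hour binomially into its two 30-minute blocks
#' (conserving the hourly sum) and emits only non-empty blocks, mirroring
#' sparse tracker sync output. `corrupt_n` invalid records (alternating
#' out-of-range block indices >= 48 and negative step counts) can be
#' injected to exercise the cleaning rules; injected rows are returned in
#' the `"corruption"` attribute for test assertions.
#'
#' @param days Participant-day table from [generate_hourly_steps()].
#' @param config A [generator_config()] (seeds the split).
#' @param corrupt_n Number of invalid records to inject.
#' @return `data.table` with `participant_id`, `date`, `block_index`,
#'   `steps`; attribute `corruption` labels injected rows.
#' @export
emit_block_records <- function(days, config, corrupt_n = 0L) {
  d <- as.data.table(days)
  set.seed(config$seed + 2000L)
  hcols <- paste0("h", 0:23)
  Y <- as.matrix(d[, hcols, with = FALSE])
  n <- nrow(Y)
  recs <- vector("list", 24L)
  for (h in 0:23) {
    y <- Y[, h + 1L]
    pos <- which(y > 0)
    if (!length(pos)) next
    b1 <- rbinom(length(pos), y[pos], 0.5)
    b2 <- y[pos] - b1
    recs[[h + 1L]] <- data.table(
      participant_id = rep(d$participant_id[pos], 2L),
      date = rep(as.character(d$date[pos]), 2L),
      block_index = rep(c(2L * h, 2L * h + 1L), each = length(pos)),
      steps = c(b1, b2)
    )
  }
  out <- rbindlist(recs)
  if (nrow(out)) out <- out[steps > 0]
  corruption <- data.table(participant_id = character(),
                           date = character(), block_index = integer(),
                           steps = numeric(), kind = character())
  if (corrupt_n > 0L && nrow(d) > 0L) {
    pick <- sample.int(nrow(d), corrupt_n, replace = TRUE)
    kind <- rep(c("bad_block_index", "negative_steps"),
                length.out = corrupt_n)
    corruption <- data.table(
      participant_id = d$participant_id[pick],
      date = as.character(d$date[pick]),
      block_index = ifelse(kind == "bad_block_index",
                           47L + seq_len(corrupt_n),
                           sample(0:47, corrupt_n, replace = TRUE)),
      steps = ifelse(kind == "bad_block_index", 100, -5),
      kind = kind
    )
    out <- rbind(out, corruption[, -"kind"])
  }
  setorder(out, participant_id, date, block_index)
  setattr(out, "corruption", corruption)
  out[]
}

#' Write and read generator artefacts
#'
#' Blocks and profiles round-trip as plain CSV; configurations as JSON.
#'
#' @param x Object to write.
#' @param path File path.
#' @name generator_io
NULL

#' @rdname generator_io
#' @export
write_blocks_csv <- function(x, path) {
  fwrite(as.data.table(x)[, .(participant_id, date, block_index, steps)],
         path)
  invisible(path)
}

#' @rdname generator_io
#' @export
write_profiles_csv <- function(x, path) {
  fwrite(as.data.table(x)[, .(participant_id, sex, age, height, weight,
                              pledge)], path)
  invisible(path)
}

#' @rdname generator_io
#' @export
read_blocks_csv <- function(path) fread(path, colClasses = list(
  character = c("participant_id", "date")))

#' @rdname generator_io
#' @export
read_profiles_csv <- function(path) {
  fread(path, colClasses = list(character = "participant_id"))
}

#' @rdname generator_io
#' @export
write_config_json <- function(x, path) {
  y <- unclass(x)
  # named vectors serialise as JSON objects so category names survive
  y$demographic_marginals <- lapply(y$demographic_marginals, as.list)
  y$covariate_effects <- lapply(y$covariate_effects, as.list)
  jsonlite::write_json(y, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname generator_io
#' @export
read_config_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$demographic_marginals <- lapply(raw$demographic_marginals, unlist)
  raw$covariate_effects <- lapply(raw$covariate_effects, unlist)
  raw$diurnal_profile <- as.data.table(raw$diurnal_profile)
  do.call(generator_config, raw)
}
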