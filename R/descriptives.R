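## Descriptive layer: incentive-point accounting, daily and hourly
## summaries, goal-band breakdowns, and the cluster-robust joint test for
## group differences in mean daily steps.

#' Reward schedule
#'
#' Daily goals of 5000, 7500 and 10,000 steps earn 10, 25 and 40
#' HealthPoints respectively; the first reward tier requires `tier_points`
#' (750 by default, consistent with the 30-day / 19-day completion
#' arithmetic at 25 vs 40 points per day).
#'
#' @param thresholds Strictly increasing goal thresholds.
#' @param points Non-decreasing points per threshold.
#' @param tier_points Points needed for the first reward tier.
#' @return List of class `reward_schedule`.
#' @export
reward_schedule <- function(thresholds = c(5000, 7500, 10000),
                            points = c(10, 25, 40), tier_points = 750) {
  stopifnot(length(thresholds) == length(points),
            all(diff(thresholds) > 0), all(diff(points) >= 0),
            tier_points >= 0)
  structure(list(thresholds = thresholds, points = points,
                 tier_points = tier_points), class = "reward_schedule")
}

#' HealthPoints earned for a daily total
#'
#' A non-decreasing step function: 0 below 5000 steps, then 10, 25 and 40
#' points at the 5000/7500/10,000 thresholds (inclusive).
#'
#' @param daily_total Non-negative daily step totals (vectorised).
#' @param schedule A [reward_schedule()].
#' @return Points earned per day.
#' @export
healthpoints_for_day <- function(daily_total, schedule = reward_schedule()) {
  if (any(is.na(daily_total)) || any(daily_total < 0)) {
    stop("`daily_total` must be non-negative")
  }
  c(0, schedule$points)[findInterval(daily_total,
                                     c(0, schedule$thresholds))]
}

#' Days needed to complete a reward tier
#'
#' `ceiling(tier_points / points_per_day)`: e.g. a 750-point tier takes 30
#' days at 25 points per day but 19 days at 40.
#'
#' @param tier_points Points required (>= 0).
#' @param points_per_day Points earned per day (> 0).
#' @return Integer number of days.
#' @export
days_to_complete_tier <- function(tier_points, points_per_day) {
  stopifnot(all(tier_points >= 0))
  if (any(points_per_day <= 0)) stop("`points_per_day` must be positive")
  ceiling(tier_points / points_per_day)
}

#' Percentage of participant-days per goal band
#'
#' @param daily_totals Daily step totals.
#' @param breaks Band edges; default bands are 0-4999, 5000-7499,
#'   7500-9999, >= 10,000.
#' @return `data.frame` with band label, count and percentage.
#' @export
goal_band_percentages <- function(daily_totals,
                                  breaks = c(0, 5000, 7500, 10000, Inf)) {
  idx <- findInterval(daily_totals, breaks)
  labs <- paste0("[", head(breaks, -1), ",", tail(breaks, -1), ")")
  cnt <- tabulate(idx, nbins = length(breaks) - 1L)
  data.frame(band = labs, n = cnt,
             percent = 100 * cnt / length(daily_totals))
}

#' Daily step summaries by demographic group
#'
#' Mean and SD of daily totals per level of a grouping factor, plus the
#' overall summary and the goal-band breakdown.
#'
#' @param days Participant-day table with `daily_total`.
#' @param profiles Profiles with derived groups.
#' @param grouping One of `"age_group"`, `"bmi_group"`, `"sex"`,
#'   `"overall"`.
#' @return List with `by_group` (level, n participant-days, mean, sd),
#'   `overall` and `bands`.
#' @export
daily_summary <- function(days, profiles, grouping = "overall") {
  ok <- c("age_group", "bmi_group", "sex", "overall")
  if (!grouping %in% ok) {
    stop("unknown grouping '", grouping, "'; use one of ",
         paste(ok, collapse = ", "))
  }
  d <- as.data.table(days)
  p <- as.data.table(profiles)
  if (!all(c("age_group", "bmi_group") %in% names(p))) p <- derive_groups(p)
  d <- merge(d, p, by = "participant_id")
  if (nrow(d) < nrow(as.data.table(days))) {
    stop("some participant-days do not join to a profile")
  }
  by_group <- if (grouping == "overall") {
    d[, .(level = "overall", n = .N, mean = mean(daily_total),
          sd = sd(daily_total))]
  } else {
    setnames(
      d[, .(n = .N, mean = mean(daily_total), sd = sd(daily_total)),
        keyby = grouping],
      grouping, "level")
  }
  list(by_group = as.data.frame(by_group),
       overall = data.frame(n = nrow(d), mean = mean(d$daily_total),
                            sd = sd(d$daily_total)),
       bands = goal_band_percentages(d$daily_total))
}

#' Hourly mean steps and proportion of zero counts
#'
#' @param days Participant-day table (`h0`-`h23` plus the stratifier
#'   column).
#' @param stratifier Column of `days` to stratify by (e.g. `"day_type"`),
#'   or `NULL` for a single stratum.
#' @return `data.frame` with `hour` (0-23), the stratifier level,
#'   `mean_steps` and `prop_zero`, covering all 24 hours.
#' @export
hourly_summary <- function(days, stratifier = "day_type") {
  d <- copy(as.data.table(days))
  hcols <- paste0("h", 0:23)
  if (is.null(stratifier)) {
    d[, strat_all := "all"]
    stratifier <- "strat_all"
  }
  long <- melt(d, id.vars = stratifier, measure.vars = hcols,
               variable.name = "hour", value.name = "y")
  long[, hour := as.integer(sub("^h", "", hour))]
  out <- long[, .(mean_steps = mean(y), prop_zero = mean(y == 0)),
              keyby = c(stratifier, "hour")]
  as.data.frame(out)
}

#' Cluster-robust joint test for group differences in daily steps
#'
#' Regresses daily totals on `k - 1` group dummies, computes the CR1
#' cluster-sandwich covariance (clusters = participants) and a joint Wald
#' F test that all dummy coefficients are zero, referred to
#' `F(k - 1, G - 1)` with `G` clusters.
#'
#' @param y Daily step totals.
#' @param group Grouping factor (k levels).
#' @param cluster Cluster ids (participant per observation).
#' @return List with `F`, `df1`, `df2`, `p_value`, the coefficient table
#'   (estimate, cluster-robust SE) and the robust covariance `vcov`.
#' @export
cluster_robust_group_test <- function(y, group, cluster) {
  group <- droplevels(factor(group))
  stopifnot(length(y) == length(group), length(y) == length(cluster))
  if (nlevels(group) < 2L) stop("`group` needs at least 2 levels")
  G <- length(unique(cluster))
  if (G < 2L) stop("need at least 2 clusters")
  X <- model.matrix(~group)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[setdiff(seq_len(ncol(X)), qrX$pivot[seq_len(qrX$rank)])]
    stop("design matrix rank deficient; offending column(s): ",
         paste(bad, collapse = ", "))
  }
  n <- nrow(X)
  k <- ncol(X)
  fit <- lm.fit(X, y)
  b <- fit$coefficients
  e <- fit$residuals
  bread <- chol2inv(chol(crossprod(X)))
  Xe <- X * e
  meat <- crossprod(rowsum(Xe, cluster))
  cr1 <- G / (G - 1) * (n - 1) / (n - k)
  V <- cr1 * bread %*% meat %*% bread
  dimnames(V) <- list(colnames(X), colnames(X))
  sel <- 2:k # all dummies; intercept excluded from the null
  q <- length(sel)
  Fstat <- drop(t(b[sel]) %*% solve(V[sel, sel, drop = FALSE], b[sel])) / q
  pval <- pf(Fstat, q, G - 1, lower.tail = FALSE)
  list(F = Fstat, df1 = q, df2 = G - 1, p_value = pval,
       coefficients = data.frame(term = colnames(X), estimate = b,
                                 se = sqrt(diag(V)), row.names = NULL),
       vcov = V)
}
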