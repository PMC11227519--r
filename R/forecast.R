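## Forward propagation of fitted hourly cells to the end of the day.
## Each simulated path re-selects its stratum every hour from the running
## cumulative total, so a path that crosses 5000 steps mid-evening switches
## model cells, honouring the conditioning on steps accumulated up to the
## previous hour. Estimation uncertainty is propagated by resampling
## posterior parameter draws per path.

#' Convert a fit or fixed parameters to a forecasting cell
#'
#' @param x A [run_mcmc()] result or a [twopart_params()] object (fixed
#'   parameters give a single "draw", useful for toy models and oracles).
#' @return Object of class `cell_fit` holding draw matrices for beta and
#'   gamma and a vector of shape draws.
#' @export
as_cell_fit <- function(x) {
  if (inherits(x, "cell_fit")) return(x)
  if (inherits(x, "posterior_draws")) {
    m <- merged_draws(x)
    bcols <- grep("^beta\\.", colnames(m))
    gcols <- grep("^gamma\\.", colnames(m))
    beta <- m[, bcols, drop = FALSE]
    gamma <- m[, gcols, drop = FALSE]
    colnames(beta) <- sub("^beta\\.", "", colnames(beta))
    colnames(gamma) <- sub("^gamma\\.", "", colnames(gamma))
    alpha <- exp(m[, "log_alpha"])
  } else if (inherits(x, "twopart_params")) {
    beta <- matrix(x$beta, nrow = 1,
                   dimnames = list(NULL, names(x$beta)))
    gamma <- matrix(x$gamma, nrow = 1,
                    dimnames = list(NULL, names(x$gamma)))
    alpha <- x$alpha
  } else {
    stop("cannot convert object of class ", class(x)[1], " to cell_fit")
  }
  has_cum <- "cum10k" %in% colnames(beta)
  structure(list(beta = beta, gamma = gamma, alpha = alpha,
                 has_cum = has_cum, n_draws = nrow(beta)),
            class = "cell_fit")
}

# Per-draw linear predictors at a fixed covariate row x0 (without the
# cumulative term, which varies along a path and is added per hour).
.cell_terms <- function(cell, x0) {
  cell <- as_cell_fit(cell)
  p0 <- length(x0)
  if (cell$has_cum) {
    stopifnot(ncol(cell$beta) == p0 + 1L)
    list(eta_b0 = drop(cell$beta[, seq_len(p0), drop = FALSE] %*% x0),
         b_cum = cell$beta[, p0 + 1L],
         eta_g0 = drop(cell$gamma[, seq_len(p0), drop = FALSE] %*% x0),
         g_cum = cell$gamma[, p0 + 1L],
         alpha = cell$alpha, n_draws = cell$n_draws)
  } else {
    stopifnot(ncol(cell$beta) == p0)
    list(eta_b0 = drop(cell$beta %*% x0), b_cum = rep(0, cell$n_draws),
         eta_g0 = drop(cell$gamma %*% x0), g_cum = rep(0, cell$n_draws),
         alpha = cell$alpha, n_draws = cell$n_draws)
  }
}

# Covariate row (no cumulative column) for one profile.
.profile_design_row <- function(profile) {
  drop(build_design(as.data.frame(profile)[1, ], include_cum = FALSE))
}

#' Forward-simulate end-of-day totals
#'
#' Starting from `cum` accumulated steps at the beginning of hour `hour`,
#' simulates the remaining hours through hour 23. Each hour the path's
#' stratum is re-evaluated from its running total and the matching fitted
#' cell samples that hour's count; posterior parameter draws are resampled
#' per path unless `draw_index` pins them. The conditional hourly mean is
#' capped at 30,000 steps (physiological plausibility bound).
#'
#' @param cum Accumulated steps at the start of `hour` (>= 0).
#' @param hour Starting hour, 12-24; 24 means no hours remain.
#' @param day_type `"weekday"` or `"weekend"`.
#' @param profile One-row profile (needs `age_group`, `bmi_group`, `sex`).
#' @param cells Named list of fitted cells keyed by [cell_key()]; values are
#'   [run_mcmc()] fits, [twopart_params()] or `cell_fit` objects.
#' @param n_paths Number of forward paths.
#' @param draw_index Optional: a single draw index applied to every cell and
#'   path (used when conditioning on one posterior draw), or a named list of
#'   per-cell indices.
#' @return Numeric vector of `n_paths` end-of-day totals. Uses the current
#'   RNG state; set a seed for reproducibility.
#' @export
forward_simulate_remainder <- function(cum, hour, day_type, profile, cells,
                                       n_paths = 1000L, draw_index = NULL) {
  stopifnot(length(cum) == 1L, cum >= 0, hour >= 12L, hour <= 24L,
            n_paths >= 1L)
  day_type <- match.arg(day_type, .DAY_TYPES)
  totals <- rep(as.numeric(cum), n_paths)
  if (hour == 24L) return(totals)

  x0 <- .profile_design_row(profile)
  hrs <- hour:23
  keys <- as.vector(outer(.STRATA, hrs,
                          function(s, h) cell_key(h, day_type, s)))
  missing_keys <- setdiff(keys, names(cells))
  if (length(missing_keys)) {
    stop("missing fitted cell(s): ", paste(missing_keys, collapse = ", "))
  }
  terms <- lapply(cells[keys], .cell_terms, x0 = x0)
  di <- lapply(keys, function(k) {
    nd <- terms[[k]]$n_draws
    if (is.null(draw_index)) {
      if (nd == 1L) rep(1L, n_paths) else sample.int(nd, n_paths,
                                                     replace = TRUE)
    } else if (is.list(draw_index)) {
      rep_len(as.integer(draw_index[[k]]), n_paths)
    } else {
      rep_len(as.integer(draw_index), n_paths)
    }
  })
  names(di) <- keys

  for (h in hrs) {
    strat <- stratum_of(totals, h)
    for (s in unique(strat)) {
      key <- cell_key(h, day_type, s)
      idx <- which(strat == s)
      tm <- terms[[key]]
      d <- di[[key]][idx]
      sc <- totals[idx] / 10000
      p <- plogis(tm$eta_b0[d] + tm$b_cum[d] * sc)
      active <- runif(length(idx)) < p
      if (any(active)) {
        ia <- idx[active]
        da <- d[active]
        # plausibility cap on the conditional mean (30,000 steps in one
        # hour is beyond sustained human cadence); also guards against
        # overflow from posterior-tail draws of thinly-informed cells
        mu <- exp(pmin(tm$eta_g0[da] + tm$g_cum[da] * totals[ia] / 10000,
                       log(30000)))
        a <- tm$alpha[da]
        totals[ia] <- totals[ia] +
          pmax(1, round(rgamma(length(ia), shape = a, rate = a / mu)))
      }
    }
  }
  totals
}

#' Probability of reaching a daily goal
#'
#' Fraction of forward-simulated end-of-day totals at or above `goal`, with
#' a binomial Monte-Carlo standard-error band.
#'
#' @inheritParams forward_simulate_remainder
#' @param goal Daily step goal (e.g. 5000, 7500 or 10,000).
#' @return List with `probability`, `se`, `interval` (+-1.96 SE, clipped to
#'   `[0,1]`) and `n_paths`.
#' @export
goal_probability <- function(cum, hour, day_type, profile, cells,
                             goal, n_paths = 10000L, draw_index = NULL) {
  stopifnot(goal >= 0)
  if (n_paths < 100L) {
    warning("n_paths < 100: goal probability will be very noisy")
  }
  totals <- forward_simulate_remainder(cum, hour, day_type, profile, cells,
                                       n_paths, draw_index)
  p <- mean(totals >= goal)
  se <- sqrt(p * (1 - p) / n_paths)
  list(probability = p, se = se,
       interval = c(max(0, p - 1.96 * se), min(1, p + 1.96 * se)),
       n_paths = n_paths)
}

#' Predicted mean end-of-day total with a credible interval on the mean
#'
#' For each of `n_draws` posterior parameter draws, the model-implied mean
#' end-of-day total is estimated by Monte-Carlo chaining with
#' `n_paths_per_draw` paths; the point estimate is the average over draws
#' and the 95% interval the 2.5/97.5 percentiles of the per-draw means -
#' an interval on the mean, not on individual totals.
#'
#' @inheritParams forward_simulate_remainder
#' @param n_draws Number of posterior draws to condition on.
#' @param n_paths_per_draw Paths used to estimate the mean under each draw.
#' @return List with `mean`, `lower`, `upper` and the per-draw means.
#' @export
predict_mean_and_ci <- function(cum, hour, day_type, profile, cells,
                                n_draws = 200L, n_paths_per_draw = 20L) {
  if (hour == 24L) {
    return(list(mean = cum, lower = cum, upper = cum,
                draw_means = rep(cum, n_draws)))
  }
  day_type <- match.arg(day_type, .DAY_TYPES)
  keys <- as.vector(outer(.STRATA, hour:23,
                          function(s, h) cell_key(h, day_type, s)))
  nd_cell <- vapply(keys, function(k) {
    if (is.null(cells[[k]])) return(NA_integer_)
    as_cell_fit(cells[[k]])$n_draws
  }, integer(1))
  if (anyNA(nd_cell)) {
    stop("missing fitted cell(s): ",
         paste(keys[is.na(nd_cell)], collapse = ", "))
  }
  means <- vapply(seq_len(n_draws), function(j) {
    dix <- lapply(nd_cell, function(nd) if (nd == 1L) 1L
                  else sample.int(nd, 1L))
    names(dix) <- keys
    mean(forward_simulate_remainder(cum, hour, day_type, profile, cells,
                                    n_paths_per_draw, draw_index = dix))
  }, numeric(1))
  qs <- quantile(means, c(0.025, 0.975), names = FALSE, type = 7)
  list(mean = mean(means), lower = qs[1], upper = qs[2], draw_means = means)
}

#' Smallest accumulated-step threshold meeting a daily goal criterion
#'
#' Scans the 500-step grid of accumulated totals at hour `hour` and returns
#' the smallest grid value whose forecast meets the criterion: under
#' `"mean"` (the default, reconstructing the goal-diagonal crossing of the
#' conditional-mean forecast), the predicted mean end-of-day total must be
#' at or above `goal`; under `"probability"`, the goal-attainment
#' probability must reach `prob_target`. The attainment probability at the
#' returned threshold is reported alongside, which is why a tabled
#' mean-based threshold can carry an attainment probability well below one.
#'
#' @inheritParams predict_mean_and_ci
#' @param goal Daily goal in steps.
#' @param grid Candidate accumulated totals (default 0-12,500 by 500).
#' @param criterion `"mean"` or `"probability"`.
#' @param prob_target Required probability under `criterion = "probability"`.
#' @param n_paths Paths for the reported attainment probability.
#' @return One-row `data.frame`: `hour`, `goal`, `threshold` (NA if no grid
#'   point qualifies, i.e. unattainable), `probability`, `criterion`.
#' @export
recommend_thresholds <- function(hour, goal, day_type, profile, cells,
                                 grid = seq(0, 12500, by = 500),
                                 criterion = c("mean", "probability"),
                                 prob_target = 0.9, n_draws = 100L,
                                 n_paths_per_draw = 20L, n_paths = 2000L) {
  criterion <- match.arg(criterion)
  grid <- sort(grid)
  meets <- function(cval) {
    if (criterion == "mean") {
      predict_mean_and_ci(cval, hour, day_type, profile, cells,
                          n_draws, n_paths_per_draw)$mean >= goal
    } else {
      goal_probability(cval, hour, day_type, profile, cells, goal,
                       n_paths)$probability >= prob_target
    }
  }
  # binary search for the first qualifying grid point (the forecast measure
  # is monotone non-decreasing in the accumulated total)
  lo <- 1L
  hi <- length(grid)
  if (!meets(grid[hi])) {
    return(data.frame(hour = hour, goal = goal, threshold = NA_real_,
                      probability = NA_real_, criterion = criterion))
  }
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (meets(grid[mid])) hi <- mid else lo <- mid + 1L
  }
  cstar <- grid[lo]
  pr <- goal_probability(cstar, hour, day_type, profile, cells, goal,
                         n_paths)$probability
  data.frame(hour = hour, goal = goal, threshold = cstar, probability = pr,
             criterion = criterion)
}

#' Recommendation grid over evening hours and goals
#'
#' @inheritParams recommend_thresholds
#' @param hours Hours to tabulate (default 18-23, i.e. 6-11 p.m.).
#' @param goals Daily goals (default 5000, 7500, 10,000).
#' @param subgroup Label attached to the rows.
#' @return `data.frame` with one row per (hour, goal).
#' @export
recommendation_table <- function(day_type, profile, cells,
                                 hours = 18:23, goals = .GOALS,
                                 subgroup = "overall", ...) {
  out <- do.call(rbind, lapply(goals, function(g) {
    do.call(rbind, lapply(hours, function(h) {
      recommend_thresholds(h, g, day_type, profile, cells, ...)
    }))
  }))
  out$day_type <- day_type
  out$subgroup <- subgroup
  out
}
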