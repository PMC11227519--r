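## Hour-specific two-part (hurdle) model: a logistic part for the odds of
## any positive step count in the hour, and a gamma regression with log link
## for the size of the count when positive. Afternoon/evening hours are
## additionally stratified by the steps accumulated up to the previous hour.

#' Cumulative-step stratum for a model cell
#'
#' Hours before noon use a single unstratified "morning" specification
#' (`"M"`). From noon onward the model cell is selected by the steps
#' accumulated up to the previous hour: `S1` = 0-4999, `S2` = 5000-7499,
#' `S3` = 7500-9999, `S4` = 10,000 and above.
#'
#' @param cum_steps Non-negative accumulated steps at the start of the hour
#'   (vectorised).
#' @param hour Hour of day, 0-23 (vectorised, recycled against `cum_steps`).
#' @return Character vector of stratum ids (`"M"`, `"S1"`-`"S4"`).
#' @examples
#' stratum_of(4999, 15) # "S1"
#' stratum_of(5000, 15) # "S2"
#' stratum_of(3000, 9)  # "M"
#' @export
stratum_of <- function(cum_steps, hour) {
  if (any(!is.finite(hour)) || any(hour < 0L | hour > 23L)) {
    stop("`hour` must be in 0-23")
  }
  if (any(!is.finite(cum_steps)) || any(cum_steps < 0)) {
    stop("`cum_steps` must be non-negative")
  }
  n <- max(length(cum_steps), length(hour))
  cum_steps <- rep_len(cum_steps, n)
  hour <- rep_len(hour, n)
  s <- .STRATA[findInterval(cum_steps, c(0, 5000, 7500, 10000))]
  s[hour < 12L] <- "M"
  s
}

#' Scaled cumulative step covariate
#'
#' Accumulated steps divided by 10,000, so the covariate equals one exactly
#' when all daily goals have just been completed.
#'
#' @param cum_steps Non-negative accumulated steps.
#' @return `cum_steps / 10000`.
#' @export
scaled_cumulative <- function(cum_steps) {
  stopifnot(all(cum_steps >= 0))
  cum_steps / 10000
}

#' Key identifying one model cell
#'
#' @param hour Hour 0-23.
#' @param day_type `"weekday"` or `"weekend"`.
#' @param stratum `"M"` or `"S1"`-`"S4"`; must be `"M"` iff `hour < 12`.
#' @return Character key, e.g. `"h18_weekday_S2"`.
#' @export
cell_key <- function(hour, day_type, stratum) {
  day_type <- match.arg(day_type, .DAY_TYPES, several.ok = TRUE)
  ok <- (hour < 12L) == (stratum == "M")
  if (!all(ok)) stop("stratum must be 'M' exactly when hour < 12")
  sprintf("h%02d_%s_%s", hour, day_type, stratum)
}

#' Design matrix for a model cell
#'
#' Columns: intercept, four age-group dummies (reference 17-29), three
#' BMI-group dummies (reference 18.5-22.9), a male dummy, and - for
#' afternoon/evening cells only - the accumulated steps up to the previous
#' hour divided by 10,000.
#'
#' @param df Data with columns `age_group`, `bmi_group`, `sex` and, when
#'   `include_cum = TRUE`, `cum_prev` (raw accumulated steps).
#' @param include_cum Include the scaled cumulative-step column?
#' @return Numeric design matrix.
#' @export
build_design <- function(df, include_cum = FALSE) {
  df <- as.data.frame(df)
  ag <- factor(df$age_group, levels = .AGE_LEVELS)
  bg <- factor(df$bmi_group, levels = .BMI_LEVELS)
  sx <- factor(df$sex, levels = .SEX_LEVELS)
  if (anyNA(ag) || anyNA(bg) || anyNA(sx)) {
    stop("age_group/bmi_group/sex contain values outside the known levels")
  }
  n <- nrow(df)
  X <- cbind(
    `(Intercept)` = rep(1, n),
    `age30-39` = as.numeric(ag == "30-39"),
    `age40-49` = as.numeric(ag == "40-49"),
    `age50-59` = as.numeric(ag == "50-59"),
    `age60+` = as.numeric(ag == "60+"),
    `bmi<18.5` = as.numeric(bg == "<18.5"),
    `bmi23-27.4` = as.numeric(bg == "23-27.4"),
    `bmi>=27.5` = as.numeric(bg == ">=27.5"),
    sexmale = as.numeric(sx == "male")
  )
  if (include_cum) {
    if (is.null(df$cum_prev)) stop("`cum_prev` required when include_cum = TRUE")
    X <- cbind(X, cum10k = scaled_cumulative(df$cum_prev))
  }
  X
}

#' Two-part model parameters for one cell
#'
#' @param beta Logistic coefficients (probability of any positive count).
#' @param gamma Gamma-regression coefficients (log link on the positive mean).
#' @param alpha Gamma shape, > 0.
#' @return Object of class `twopart_params`.
#' @export
twopart_params <- function(beta, gamma, alpha) {
  stopifnot(length(beta) == length(gamma), length(alpha) == 1L, alpha > 0,
            all(is.finite(beta)), all(is.finite(gamma)), is.finite(alpha))
  structure(list(beta = beta, gamma = gamma, alpha = alpha),
            class = "twopart_params")
}

#' Two-part log-likelihood
#'
#' A zero count contributes `log(1 - p)`; a positive count contributes
#' `log(p)` plus the gamma log-density with shape `alpha` and mean
#' `exp(gamma . x)`, where `p = plogis(beta . x)`. Positive counts are
#' treated as continuous; the rounding applied when data are generated is a
#' documented approximation ignored by the likelihood.
#'
#' @param params A [twopart_params()] object.
#' @param X Design matrix (rows aligned with `y`).
#' @param y Non-negative counts.
#' @return Scalar log-likelihood.
#' @export
twopart_loglik <- function(params, X, y) {
  stopifnot(inherits(params, "twopart_params"), nrow(X) == length(y),
            all(y >= 0))
  if (!all(is.finite(params$beta)) || !all(is.finite(params$gamma)) ||
      !is.finite(params$alpha)) {
    stop("non-finite parameter")
  }
  eta_b <- drop(X %*% params$beta)
  pos <- y > 0
  # log(p) = -log1p(exp(-eta)), log(1-p) = -log1p(exp(eta)): stable tails
  ll <- sum(-log1p(exp(eta_b[!pos]))) + sum(-log1p(exp(-eta_b[pos])))
  if (any(pos)) {
    mu <- exp(drop(X[pos, , drop = FALSE] %*% params$gamma))
    ll <- ll + sum(dgamma(y[pos], shape = params$alpha,
                          rate = params$alpha / mu, log = TRUE))
  }
  ll
}

#' Sample hourly counts from a two-part model cell
#'
#' The generative counterpart of [twopart_loglik()]: zero with probability
#' `1 - p`, otherwise a gamma draw with mean `exp(gamma . x)` and shape
#' `alpha`, rounded with a floor of one so positivity and the hurdle
#' indicator agree.
#'
#' @param params A [twopart_params()] object.
#' @param X Design matrix; one draw per row. A single design row may be
#'   passed as a vector.
#' @return Integer-valued vector of counts, one per row of `X`.
#' @export
sample_one_hour <- function(params, X) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  stopifnot(inherits(params, "twopart_params"),
            ncol(X) == length(params$beta))
  p <- plogis(drop(X %*% params$beta))
  mu <- exp(drop(X %*% params$gamma))
  n <- nrow(X)
  active <- runif(n) < p
  out <- numeric(n)
  if (any(active)) {
    draw <- rgamma(sum(active), shape = params$alpha,
                   rate = params$alpha / mu[active])
    out[active] <- pmax(1, round(draw))
  }
  out
}
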