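## Cleaning and aggregation of raw 30-minute tracker blocks into
## analysis-ready participant-days, plus demographic filtering and
## categorisation. Every removal is attributed to a named rule so that
## exclusion counts reconcile input and output sizes.

#' Clean raw 30-minute block records
#'
#' Drops implausible time blocks (index 48 and above, negative or
#' non-integer indices) and negative step counts; keeps blocks 0-47 with
#' steps >= 0. Removal counts by rule are attached as the `"removed"`
#' attribute.
#'
#' @param blocks `data.frame`/`data.table` with columns `participant_id`,
#'   `date`, `block_index`, `steps`.
#' @return Cleaned `data.table` with attribute `removed` (named counts:
#'   `bad_block_index`, `negative_steps`, `missing`).
#' @export
clean_blocks <- function(blocks) {
  b <- as.data.table(blocks)
  stopifnot(all(c("participant_id", "date", "block_index", "steps")
                %in% names(b)))
  n0 <- nrow(b)
  miss <- !complete.cases(b[, .(participant_id, date, block_index, steps)])
  b <- b[!miss]
  bad_idx <- !is.finite(b$block_index) | b$block_index != floor(b$block_index) |
    b$block_index < 0 | b$block_index > 47
  b <- b[!bad_idx]
  neg <- b$steps < 0
  b <- b[!neg]
  removed <- c(missing = sum(miss), bad_block_index = sum(bad_idx),
               negative_steps = sum(neg))
  if (sum(removed) != n0 - nrow(b)) stop("exclusion accounting mismatch")
  setattr(b, "removed", removed)
  b[]
}

#' Aggregate blocks into hourly participant-days
#'
#' For each participant and date with at least one strictly positive block,
#' missing blocks are imputed with zero, duplicated
#' (participant, date, block) entries are summed with a warning, and hour
#' `h` is the sum of blocks `2h` and `2h + 1`. Days whose blocks are all
#' zero or absent are dropped.
#'
#' @param blocks Cleaned block records (see [clean_blocks()]).
#' @return `data.table` with `participant_id`, `date`, hourly columns
#'   `h0`-`h23` and `daily_total`.
#' @export
impute_and_aggregate <- function(blocks) {
  b <- as.data.table(blocks)
  if (anyDuplicated(b, by = c("participant_id", "date", "block_index"))) {
    warning("duplicate (participant, date, block) records summed")
    b <- b[, .(steps = sum(steps)),
           by = .(participant_id, date, block_index)]
  }
  # keep only days with a non-zero block; remaining blocks imputed as 0
  b <- b[, if (any(steps > 0)) .SD, by = .(participant_id, date)]
  if (nrow(b) == 0L) {
    empty <- data.table(participant_id = character(), date = character())
    for (h in c(paste0("h", 0:23), "daily_total")) empty[, (h) := numeric()]
    return(empty[])
  }
  b[, hour := block_index %/% 2L]
  hourly <- b[, .(y = sum(steps)), by = .(participant_id, date, hour)]
  wide <- dcast(hourly, participant_id + date ~ hour, value.var = "y",
                fill = 0)
  have <- setdiff(names(wide), c("participant_id", "date"))
  for (h in setdiff(as.character(0:23), have)) wide[, (h) := 0]
  setnames(wide, as.character(0:23), paste0("h", 0:23))
  setcolorder(wide, c("participant_id", "date", paste0("h", 0:23)))
  wide[, daily_total := rowSums(.SD), .SDcols = paste0("h", 0:23)]
  wide[]
}

#' Filter participant profiles on plausibility rules
#'
#' Retains profiles with non-missing age/height/weight, age at least 17,
#' weight in [30, 300] kg, height in [101, 220] cm and no personal-pledge
#' participation. Exclusion reasons (first matching rule per profile) are
#' tallied in the `"excluded"` attribute.
#'
#' @param profiles `data.frame` with `participant_id`, `sex`, `age`,
#'   `height`, `weight`, `pledge`.
#' @return Filtered `data.table` with attribute `excluded`.
#' @export
filter_profiles <- function(profiles) {
  p <- as.data.table(profiles)
  reason <- rep(NA_character_, nrow(p))
  mark <- function(cond, lab) {
    cond[is.na(cond)] <- FALSE
    reason[is.na(reason) & cond] <<- lab
  }
  mark(is.na(p$age) | is.na(p$height) | is.na(p$weight), "missing")
  mark(p$age < 17, "age")
  mark(p$weight < 30 | p$weight > 300, "weight")
  mark(p$height < 101 | p$height > 220, "height")
  mark(p$pledge, "pledge")
  keep <- is.na(reason)
  out <- p[keep]
  tab <- table(factor(reason[!keep],
                      levels = c("missing", "age", "weight", "height",
                                 "pledge")))
  setattr(out, "excluded", setNames(as.integer(tab), names(tab)))
  out[]
}

#' Derive age group, BMI and BMI group
#'
#' Age groups: 17-29, 30-39, 40-49, 50-59, 60+. BMI = weight / (height in
#' m)^2, grouped by the Asian cut-offs <18.5 (underweight), 18.5-22.9
#' (normal), 23-27.4 (overweight), >=27.5 (obese). Both groupings use
#' half-open, lower-inclusive intervals.
#'
#' @param profiles Filtered profiles (see [filter_profiles()]).
#' @return `data.table` with added `age_group`, `bmi`, `bmi_group`.
#' @export
derive_groups <- function(profiles) {
  p <- as.data.table(profiles)
  p[, age_group := .AGE_LEVELS[findInterval(age, c(17, 30, 40, 50, 60))]]
  p[, bmi := weight / (height / 100)^2]
  p[, bmi_group := .BMI_LEVELS[findInterval(bmi, c(0, 18.5, 23, 27.5))]]
  p[]
}

#' Restrict to the study window and label the day type
#'
#' Keeps dates from Monday 2018-01-08 through 2018-03-31 (inclusive) and
#' labels Saturdays and Sundays as weekend days. Unparseable dates are
#' dropped and counted in the `"removed_dates"` attribute.
#'
#' @param days Participant-day table with a `date` column.
#' @param start,end Window bounds (inclusive).
#' @return Filtered `data.table` with an added `day_type` column.
#' @export
restrict_window_and_daytype <- function(days, start = "2018-01-08",
                                        end = "2018-03-31") {
  d <- as.data.table(days)
  dt <- suppressWarnings(as.Date(d$date))
  bad <- is.na(dt)
  d <- d[!bad]
  dt <- dt[!bad]
  keep <- dt >= as.Date(start) & dt <= as.Date(end)
  d <- d[keep]
  dt <- dt[keep]
  d[, day_type := ifelse(format(dt, "%u") %in% c("6", "7"),
                         "weekend", "weekday")]
  setattr(d, "removed_dates", sum(bad))
  d[]
}

#' Long model-ready table of hourly observations
#'
#' Joins participant-days with profiles and expands to one row per
#' (participant-day, hour) with the count, the steps accumulated up to the
#' previous hour, and the model-cell stratum.
#'
#' @param days Participant-day table (`h0`-`h23`, `day_type`).
#' @param profiles Profiles with derived groups.
#' @return `data.table` with `participant_id`, `date`, `day_type`, `hour`,
#'   `y`, `cum_prev`, `stratum` and the demographic columns.
#' @export
build_model_data <- function(days, profiles) {
  d <- as.data.table(days)
  p <- as.data.table(profiles)
  need <- c("age_group", "bmi_group", "sex")
  if (!all(need %in% names(p))) p <- derive_groups(p)
  d <- merge(d, p[, c("participant_id", need), with = FALSE],
             by = "participant_id")
  hcols <- paste0("h", 0:23)
  Y <- as.matrix(d[, hcols, with = FALSE])
  cum <- cbind(0, t(apply(Y, 1, cumsum))[, 1:23, drop = FALSE])
  n <- nrow(d)
  long <- data.table(
    participant_id = rep(d$participant_id, each = 24L),
    date = rep(d$date, each = 24L),
    day_type = rep(d$day_type, each = 24L),
    age_group = rep(d$age_group, each = 24L),
    bmi_group = rep(d$bmi_group, each = 24L),
    sex = rep(d$sex, each = 24L),
    hour = rep(0:23, times = n),
    y = as.vector(t(Y)),
    cum_prev = as.vector(t(cum))
  )
  long[, stratum := stratum_of(cum_prev, hour)]
  long[]
}
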