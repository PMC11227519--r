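## End-to-end orchestration: generate -> preprocess -> describe -> fit ->
## forecast -> recommend, plus the parameter-recovery experiment that
## closes the loop between the generator's truth records and the
## inference module.

#' Pipeline run configuration
#'
#' @param out_dir Output directory for stage artefacts (CSV/JSON), or
#'   `NULL` to keep everything in memory.
#' @param generator A [generator_config()].
#' @param priors A [prior_spec()].
#' @param mcmc List `n_chains`, `n_burn`, `n_keep` per model cell. The
#'   reference analysis used 4 chains x 5000/5000; the desk-scale default
#'   is 4 x 500/500.
#' @param hours Hours whose cells are fitted (default 18-23, the evening
#'   hours that feed the recommendation grid).
#' @param day_types Day types to fit.
#' @param min_cell_n Minimum rows for a cell to be fitted.
#' @param forecast List of forecasting knobs: `grid`, `n_paths`, `n_draws`,
#'   `n_paths_per_draw`, `criterion` (`"mean"` or `"probability"`),
#'   `prob_target`, `hours`.
#' @param goals Daily goals.
#' @param reference_profile One-row data.frame of covariates used for the
#'   "overall" recommendation rows (default: the modal subgroup).
#' @param seed Master seed; every stochastic stage derives its seed from it.
#' @return List of class `run_config`.
#' @export
run_config <- function(out_dir = NULL,
                       generator = generator_config(),
                       priors = prior_spec(),
                       mcmc = list(n_chains = 4L, n_burn = 500L,
                                   n_keep = 500L),
                       hours = 18:23,
                       day_types = .DAY_TYPES,
                       min_cell_n = 10L,
                       forecast = list(grid = seq(0, 12500, 500),
                                       n_paths = 2000L, n_draws = 100L,
                                       n_paths_per_draw = 20L,
                                       criterion = "mean",
                                       prob_target = 0.9, hours = 18:23),
                       goals = .GOALS,
                       reference_profile = data.frame(
                         age_group = "40-49", bmi_group = "23-27.4",
                         sex = "female"),
                       seed = 1L) {
  structure(list(out_dir = out_dir, generator = generator, priors = priors,
                 mcmc = mcmc, hours = hours, day_types = day_types,
                 min_cell_n = min_cell_n, forecast = forecast,
                 goals = goals, reference_profile = reference_profile,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Fit all model cells present in a model-data table
#'
#' @param model_data Long table from [build_model_data()].
#' @param hours,day_types Cells to fit.
#' @param priors A [prior_spec()].
#' @param n_chains,n_burn,n_keep MCMC sizes per cell.
#' @param min_cell_n Cells with fewer rows are skipped (recorded, not
#'   fitted).
#' @param seed Base seed; cell `i` uses `seed + i`.
#' @return List: `cells` (named [run_mcmc()] fits), `rhat` (long table of
#'   per-parameter Rhat), `skipped` (cell keys with row counts), `n_rows`.
#' @export
fit_cells <- function(model_data, hours = 18:23, day_types = .DAY_TYPES,
                      priors = prior_spec(), n_chains = 4L, n_burn = 500L,
                      n_keep = 500L, min_cell_n = 10L, seed = 1L) {
  md <- as.data.table(model_data)
  grid <- CJ(hour = hours, day_type = day_types)
  cells <- list()
  skipped <- list()
  rhat_rows <- list()
  i <- 0L
  for (r in seq_len(nrow(grid))) {
    h <- grid$hour[r]
    dt <- grid$day_type[r]
    strata <- if (h < 12L) "M" else .STRATA
    for (st in strata) {
      i <- i + 1L
      key <- cell_key(h, dt, st)
      rows <- md[hour == h & day_type == dt & stratum == st]
      if (nrow(rows) < min_cell_n) {
        skipped[[key]] <- nrow(rows)
        next
      }
      X <- build_design(rows, include_cum = h >= 12L)
      fit <- run_mcmc(X, rows$y, priors, n_chains, n_burn, n_keep,
                      seed = seed + i)
      cells[[key]] <- fit
      rhat_rows[[key]] <- data.table(cell = key,
                                     parameter = fit$parameters,
                                     rhat = unname(fit$rhat),
                                     n_rows = nrow(rows))
    }
  }
  list(cells = cells,
       rhat = if (length(rhat_rows)) rbindlist(rhat_rows) else
         data.table(cell = character(), parameter = character(),
                    rhat = numeric(), n_rows = integer()),
       skipped = skipped)
}

#' Run the full pipeline
#'
#' Generates synthetic blocks and profiles, applies the cleaning and
#' filtering rules, computes the descriptive layer, fits the configured
#' model cells, derives the recommendation grid, and returns a manifest.
#' Outputs are also written under `config$out_dir` when set.
#'
#' @param config A [run_config()].
#' @return List with `profiles`, `days`, `descriptives`, `fits`,
#'   `forecast_cells` (fitted cells with thin-stratum substitutions applied,
#'   ready for the forecasting API), `recommendations` and `manifest`
#'   (seeds, row counts per stage, Rhat summary with cells at or above 1.01
#'   flagged).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  gen <- config$generator
  message("stage generate")
  profiles_raw <- generate_profiles(gen)
  days_raw <- generate_hourly_steps(profiles_raw, gen)
  blocks <- emit_block_records(days_raw, gen)

  message("stage preprocess")
  cleaned <- clean_blocks(blocks)
  days <- impute_and_aggregate(cleaned)
  days <- restrict_window_and_daytype(days)
  profiles <- derive_groups(filter_profiles(profiles_raw))
  days <- days[days$participant_id %in% profiles$participant_id, ]

  message("stage describe")
  descr <- list(
    overall = daily_summary(days, profiles, "overall"),
    by_age = daily_summary(days, profiles, "age_group"),
    by_bmi = daily_summary(days, profiles, "bmi_group"),
    by_sex = daily_summary(days, profiles, "sex"),
    hourly = hourly_summary(days, "day_type")
  )
  dj <- merge(as.data.table(days), as.data.table(profiles),
              by = "participant_id")
  descr$group_tests <- lapply(
    setNames(nm = c("age_group", "bmi_group", "sex")),
    function(g) {
      if (length(unique(dj[[g]])) < 2L) return(NULL)
      tst <- cluster_robust_group_test(dj$daily_total, dj[[g]],
                                       dj$participant_id)
      tst[c("F", "df1", "df2", "p_value")]
    })

  message("stage fit")
  md <- build_model_data(days, profiles)
  fits <- fit_cells(md, hours = config$hours, day_types = config$day_types,
                    priors = config$priors,
                    n_chains = config$mcmc$n_chains,
                    n_burn = config$mcmc$n_burn,
                    n_keep = config$mcmc$n_keep,
                    min_cell_n = config$min_cell_n,
                    seed = config$seed + 5000L)

  message("stage recommend")
  fc <- config$forecast
  set.seed(config$seed + 3000L)
  # a stratum cell that was too thin to fit borrows the nearest fitted
  # stratum of the same hour/day type (documented pooling fallback)
  fc_cells <- fits$cells
  substituted <- character(0)
  for (dt in config$day_types) {
    for (h in intersect(config$hours, 12:23)) {
      for (si in seq_along(.STRATA)) {
        key <- cell_key(h, dt, .STRATA[si])
        if (!is.null(fc_cells[[key]])) next
        nbr <- .STRATA[order(abs(seq_along(.STRATA) - si))]
        for (s2 in nbr) {
          alt <- cell_key(h, dt, s2)
          if (!is.null(fits$cells[[alt]])) {
            fc_cells[[key]] <- fits$cells[[alt]]
            substituted <- c(substituted, paste0(key, "<-", alt))
            break
          }
        }
      }
    }
  }
  recs <- list()
  rec_skipped <- character(0)
  for (dt in config$day_types) {
    for (h in fc$hours) {
      need <- as.vector(outer(.STRATA, h:23,
                              function(s, hh) cell_key(hh, dt, s)))
      if (!all(need %in% names(fc_cells))) {
        rec_skipped <- c(rec_skipped, sprintf("%s_h%02d", dt, h))
        next
      }
      for (g in config$goals) {
        recs[[length(recs) + 1L]] <- cbind(
          recommend_thresholds(h, g, dt, config$reference_profile,
                               fc_cells, grid = fc$grid,
                               criterion = fc$criterion,
                               prob_target = fc$prob_target,
                               n_draws = fc$n_draws,
                               n_paths_per_draw = fc$n_paths_per_draw,
                               n_paths = fc$n_paths),
          data.frame(day_type = dt, subgroup = "overall"))
      }
    }
  }
  recommendations <- if (length(recs)) do.call(rbind, recs) else NULL

  flagged <- fits$rhat[fits$rhat$rhat >= 1.01, ]
  manifest <- list(
    package = "steppace",
    version = as.character(packageVersion("steppace")),
    seed = config$seed,
    stages = list(
      generate = list(n_participants = nrow(profiles_raw),
                      n_participant_days = nrow(days_raw),
                      n_blocks = nrow(blocks)),
      preprocess = list(n_blocks_clean = nrow(cleaned),
                        n_days = nrow(days),
                        n_profiles = nrow(profiles),
                        blocks_removed = as.list(attr(cleaned, "removed"))),
      fit = list(n_cells = length(fits$cells),
                 n_skipped = length(fits$skipped),
                 skipped = fits$skipped,
                 max_rhat = if (nrow(fits$rhat)) max(fits$rhat$rhat) else NA,
                 n_rhat_flagged = nrow(flagged)),
      recommend = list(n_rows = if (is.null(recommendations)) 0L else
        nrow(recommendations), skipped = rec_skipped,
        substituted_cells = substituted)
    ),
    rhat_flagged = as.data.frame(flagged)
  )

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    od <- config$out_dir
    write_blocks_csv(blocks, file.path(od, "blocks.csv"))
    write_profiles_csv(profiles_raw, file.path(od, "profiles.csv"))
    fwrite(days, file.path(od, "participant_days.csv"))
    fwrite(fits$rhat, file.path(od, "rhat.csv"))
    if (!is.null(recommendations)) {
      fwrite(recommendations, file.path(od, "recommendations.csv"))
    }
    jsonlite::write_json(manifest, file.path(od, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
  }
  list(profiles = profiles, days = days, descriptives = descr, fits = fits,
       forecast_cells = fc_cells, recommendations = recommendations,
       manifest = manifest)
}

#' Simulate model-cell data directly from truth parameters
#'
#' Draws demographic covariates from the configured marginals, an
#' accumulated total appropriate for the cell's stratum, and hourly counts
#' from the cell's exact two-part parameters - the sampling model the
#' inference module assumes (up to integer rounding of positive draws).
#'
#' @param truth A [twopart_params()] truth record.
#' @param n_rows Number of observations.
#' @param stratum `"M"` or `"S1"`-`"S4"` (selects the accumulated-step
#'   range; `"M"` omits the cumulative covariate).
#' @param marginals Demographic marginals (see [default_marginals()]).
#' @param seed Integer seed.
#' @return List with `X` (design matrix), `y` (counts) and the sampled
#'   covariate table `df`.
#' @export
simulate_cell_data <- function(truth, n_rows, stratum = "S1",
                               marginals = default_marginals(),
                               seed = 1L) {
  set.seed(seed)
  df <- data.frame(
    age_group = sample(names(marginals$age_group), n_rows, TRUE,
                       marginals$age_group),
    bmi_group = sample(names(marginals$bmi_group), n_rows, TRUE,
                       marginals$bmi_group),
    sex = sample(names(marginals$sex), n_rows, TRUE, marginals$sex)
  )
  include_cum <- stratum != "M"
  if (include_cum) {
    rng <- switch(stratum, S1 = c(0, 4999), S2 = c(5000, 7499),
                  S3 = c(7500, 9999), S4 = c(10000, 15000))
    df$cum_prev <- runif(n_rows, rng[1], rng[2])
  }
  X <- build_design(df, include_cum = include_cum)
  y <- sample_one_hour(truth, X)
  list(X = X, y = y, df = df)
}

#' Parameter-recovery experiment
#'
#' For each requested model cell, simulates `n_rows` observations from the
#' generator's truth record, fits the cell by MCMC, and compares posterior
#' means against truth: z-scores (posterior-SD units) and 95%-interval
#' coverage per parameter.
#'
#' @param gen_config A [generator_config()] defining the truth.
#' @param cell_keys Cells to test (default: one morning and one evening
#'   weekday cell).
#' @param n_rows Simulated observations per cell.
#' @param n_chains,n_burn,n_keep MCMC sizes.
#' @param seed Base seed.
#' @param z_tol Pass threshold on |z|.
#' @return List with `table` (cell, parameter, truth, posterior mean/SD,
#'   z, covered), `max_abs_z`, `coverage` and `pass`.
#' @export
parameter_recovery_experiment <- function(gen_config = generator_config(),
                                          cell_keys = c("h08_weekday_M",
                                                        "h19_weekday_S2"),
                                          n_rows = 5000L, n_chains = 4L,
                                          n_burn = 500L, n_keep = 500L,
                                          seed = 1L, z_tol = 3) {
  truth_all <- truth_parameters(gen_config)
  out <- list()
  for (i in seq_along(cell_keys)) {
    key <- cell_keys[i]
    tp <- truth_all[[key]]
    if (is.null(tp)) stop("unknown cell key: ", key)
    st <- sub(".*_", "", key)
    sim <- simulate_cell_data(tp, n_rows, stratum = st,
                              marginals = gen_config$demographic_marginals,
                              seed = seed + i)
    fit <- run_mcmc(sim$X, sim$y, n_chains = n_chains, n_burn = n_burn,
                    n_keep = n_keep, seed = seed + 100L + i)
    sm <- summarize_posterior(fit)
    m <- merged_draws(fit)
    truth_vec <- c(tp$beta, tp$gamma, log(tp$alpha))
    post_sd <- apply(m, 2, sd)
    out[[key]] <- data.frame(
      cell = key, parameter = sm$parameter, truth = unname(truth_vec),
      post_mean = sm$mean, post_sd = unname(post_sd),
      z = (sm$mean - unname(truth_vec)) / unname(post_sd),
      covered = sm$lower <= truth_vec & truth_vec <= sm$upper,
      rhat = sm$rhat, row.names = NULL)
  }
  tab <- do.call(rbind, out)
  list(table = tab, max_abs_z = max(abs(tab$z)),
       coverage = mean(tab$covered), pass = all(abs(tab$z) <= z_tol))
}

#' Reduced replicate coverage experiment
#'
#' Repeatedly simulates a cell at small `n_rows`, fits it with a reduced
#' MCMC, and records whether each parameter's nominal 95% interval covers
#' its generating value. Calibration implies pooled coverage near 0.95.
#'
#' @inheritParams parameter_recovery_experiment
#' @param n_reps Number of replicates.
#' @param cell_key Cell to replicate.
#' @return List with `coverage` (pooled), `per_parameter` and `n_reps`.
#' @export
recovery_coverage_experiment <- function(gen_config = generator_config(),
                                         cell_key = "h08_weekday_M",
                                         n_reps = 100L, n_rows = 400L,
                                         n_chains = 2L, n_burn = 300L,
                                         n_keep = 300L, seed = 1L) {
  tp <- truth_parameters(gen_config)[[cell_key]]
  st <- sub(".*_", "", cell_key)
  truth_vec <- c(tp$beta, tp$gamma, log(tp$alpha))
  cov <- matrix(NA, n_reps, length(truth_vec))
  for (r in seq_len(n_reps)) {
    sim <- simulate_cell_data(tp, n_rows, stratum = st,
                              marginals = gen_config$demographic_marginals,
                              seed = seed + 7L * r)
    fit <- run_mcmc(sim$X, sim$y, n_chains = n_chains, n_burn = n_burn,
                    n_keep = n_keep, seed = seed + 7L * r + 3L)
    sm <- summarize_posterior(fit)
    cov[r, ] <- sm$lower <= truth_vec & truth_vec <= sm$upper
  }
  colnames(cov) <- names(truth_vec)
  list(coverage = mean(cov), per_parameter = colMeans(cov), n_reps = n_reps)
}
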