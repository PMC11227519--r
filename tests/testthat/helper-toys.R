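# Shared toy builders. Toy cells use an enormous gamma shape so positive
# draws are exact point masses after rounding, which makes forward
# simulation enumerable by hand.

design_names <- function(cum = TRUE) {
  nm <- c("(Intercept)", "age30-39", "age40-49", "age50-59", "age60+",
          "bmi<18.5", "bmi23-27.4", "bmi>=27.5", "sexmale")
  if (cum) c(nm, "cum10k") else nm
}

toy_params <- function(p, mu, alpha = 1e12, cum = TRUE, b_cum = 0,
                       g_cum = 0) {
  nm <- design_names(cum)
  b <- setNames(c(qlogis(p), rep(0, 8), if (cum) b_cum), nm)
  g <- setNames(c(log(mu), rep(0, 8), if (cum) g_cum), nm)
  twopart_params(b, g, alpha)
}

# fitted-cell list covering hours `hours` x all strata with identical
# fixed parameters
toy_cells <- function(hours, day_type = "weekday", p = 0.5, mu = 1000,
                      ...) {
  cells <- list()
  for (h in hours) {
    for (s in c("S1", "S2", "S3", "S4")) {
      cells[[cell_key(h, day_type, s)]] <- toy_params(p, mu, ...)
    }
  }
  cells
}

ref_profile <- function() {
  data.frame(age_group = "17-29", bmi_group = "18.5-22.9", sex = "female")
}

tiny_gen_config <- function(...) {
  generator_config(n_participants = 20, date_start = "2018-01-08",
                   date_end = "2018-01-14", seed = 42, ...)
}

# independent gamma log-density oracle (no dgamma): shape a, mean m
oracle_gamma_logpdf <- function(y, a, m) {
  r <- a / m
  a * log(r) + (a - 1) * log(y) - r * y - lgamma(a)
}
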