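# hand-built record sets for closed-form checks
make_records <- function(observed_age, event = "death", sex = "female",
                         treatment = "control", isoline = "iso01") {
  n <- length(observed_age)
  data.frame(fly_id = sprintf("f%03d", seq_len(n)),
             isoline = rep_len(isoline, n), sex = rep_len(sex, n),
             treatment = rep_len(treatment, n),
             observed_age = observed_age, event = rep_len(event, n),
             stringsAsFactors = FALSE)
}

# small but non-degenerate simulated cohort reused across tests
small_cohort <- function(seed = 11, n_isolines = 6, n_per_group = 40,
                         ...) {
  simulate_cohort(cohort_design(n_isolines = n_isolines,
                                n_per_group = n_per_group, max_age = 250),
                  gompertz_frailty_params(...), seed = seed)
}

# brute-force product-limit estimator: direct product over event times,
# independent of the survival-package path used by km_fit()
km_oracle <- function(time, death, at) {
  tev <- sort(unique(time[death]))
  S <- 1
  out <- numeric(length(at))
  for (i in seq_along(at)) {
    S <- 1
    for (t in tev[tev <= at[i]]) {
      n_risk <- sum(time >= t)
      d <- sum(time == t & death)
      S <- S * (1 - d / n_risk)
    }
    out[i] <- S
  }
  out
}
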