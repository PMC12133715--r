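# Independent brute-force oracles, deliberately naive: explicit loops,
# survival recomputed from scratch at every step.  They share no code with
# the estimators they check.

# Cause-k cumulative incidence at time tq by direct product-limit
# enumeration over the raw (time, cause) pairs.
oracle_cif <- function(time, cause, k, tq) {
  ev_times <- sort(unique(time[cause != "censored"]))
  total <- 0
  for (tj in ev_times[ev_times <= tq]) {
    n_at_risk <- sum(time >= tj)
    d_k <- sum(time == tj & cause == k)
    S <- 1
    for (ts in ev_times[ev_times < tj]) {
      S <- S * (1 - sum(time == ts & cause != "censored") / sum(time >= ts))
    }
    total <- total + S * d_k / n_at_risk
  }
  total
}

# Earliest indicator claim for one patient by exhaustive search over all
# (claim, class) pairs.
oracle_first_indicator <- function(claim_dates, claim_codes, code_set, start_date) {
  best_date <- as.Date(NA)
  best_class <- NA_integer_
  for (i in seq_along(claim_dates)) {
    if (claim_dates[i] < start_date) next
    for (k in seq_along(code_set)) {
      hit <- FALSE
      for (code in claim_codes[[i]]) {
        for (p in code_set[[k]]) {
          if (startsWith(code, p)) hit <- TRUE
        }
      }
      if (hit && (is.na(best_date) || claim_dates[i] < best_date ||
                  (claim_dates[i] == best_date && k < best_class))) {
        best_date <- claim_dates[i]
        best_class <- k
        break
      }
    }
  }
  list(date = best_date, class = best_class)
}

# Random competing-risks dataset with ties and censoring.
random_timelines <- function(seed, n_max = 8, causes = c("rec", "death")) {
  set.seed(seed)
  n <- sample(1:n_max, 1)
  tibble::tibble(
    time_days = sample(1:6, n, replace = TRUE),
    cause = sample(c(causes, "censored"), n, replace = TRUE)
  )
}

# Small simulation shared by the detection-recovery checks: zero claim
# delay, no missed claims, no emigration.
exact_claims_config <- function(n = 2000, seed = 11) {
  simulation_config(
    n_patients = n, seed = seed,
    emigration_hazard = 0,
    claim_model = claim_model(claim_delay_days = 0L, p_missed_recurrence = 0)
  )
}
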