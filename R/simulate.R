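#' Default cause-specific hazard table for the simulator
#'
#' Constant cause-specific hazards per year by surrogate subtype and stage,
#' for recurrence, second primary cancer and death before any other event.
#' The values are calibrated so that the qualitative ordering of 10-year
#' recurrence cumulative incidence follows the clinical gradient (stage
#' III > II > I; triple-negative > HER2+ > HR+/HER2-), with an overall
#' 10-year recurrence incidence around 20 %.  They are defaults for
#' synthetic-data generation, not estimates from any real cohort.
#'
#' @return A tibble with columns `subtype`, `stage`, `lambda_rec`,
#'   `lambda_sp`, `lambda_death` (rates per person-year).
#' @export
default_hazard_table <- function() {
  base <- tribble(
    ~subtype,      ~stage, ~lambda_rec,
    "HR+/HER2-",   "I",    0.013,
    "HR+/HER2-",   "II",   0.025,
    "HR+/HER2-",   "III",  0.050,
    "HER2+",       "I",    0.016,
    "HER2+",       "II",   0.030,
    "HER2+",       "III",  0.058,
    "TN",          "I",    0.028,
    "TN",          "II",   0.050,
    "TN",          "III",  0.085,
    "not_available", "I",   0.013,
    "not_available", "II",  0.025,
    "not_available", "III", 0.050
  )
  death_by_stage <- c(I = 0.008, II = 0.012, III = 0.025)
  base |>
    mutate(
      lambda_sp = 0.008,
      lambda_death = unname(death_by_stage[.data$stage])
    )
}

#' Default claim-generation model
#'
#' Controls how administrative claims are emitted from the latent event
#' history: the class mix of the first recurrence-indicating claim
#' (chemotherapy, radiotherapy, breast surgery/malignant-breast admission,
#' secondary malignant neoplasm), the delay between the true recurrence and
#' its first claim, the length of the initial primary-treatment window in
#' which treatment codes are emitted for every patient, and the probability
#' that a true recurrence never surfaces in claims.
#'
#' @param p_indicator_class Weights over indicator classes 1-4 for the
#'   first recurrence claim.
#' @param claim_delay_days Nonnegative integer delay(s), sampled uniformly
#'   when a vector is given.
#' @param primary_treatment_claim_months Length in months of the initial
#'   window in which primary-treatment codes are emitted for HER2-negative
#'   patients; HER2-positive patients use twice-length treatment (24
#'   months) reflecting a year of targeted therapy.
#' @param p_missed_recurrence Probability in \[0, 1) that a true recurrence
#'   generates no claim.
#' @return A named list.
#' @export
claim_model <- function(p_indicator_class = c(0.20, 0.16, 0.51, 0.13),
                        claim_delay_days = 30L,
                        primary_treatment_claim_months = 12L,
                        p_missed_recurrence = 0) {
  list(
    p_indicator_class = p_indicator_class,
    claim_delay_days = claim_delay_days,
    primary_treatment_claim_months = primary_treatment_claim_months,
    p_missed_recurrence = p_missed_recurrence
  )
}

#' Build and validate a simulation configuration
#'
#' Defines the population and event process from which linked synthetic
#' registry and claims tables are drawn: competing latent event times
#' (recurrence, second primary cancer, death, emigration) with constant
#' cause-specific hazards per (subtype, stage), administrative censoring at
#' a fixed calendar cutoff, and a claims layer generated from the latent
#' history.  Default marginal distributions of age, stage and subtype
#' follow the composition typical of a population-based non-metastatic
#' breast-cancer cohort diagnosed 2004-2010 and followed to the end of
#' 2021.
#'
#' @param n_patients Number of women to simulate.
#' @param seed Integer seed; identical configurations produce
#'   byte-identical output tables.
#' @param diagnosis_window Two dates: earliest and latest diagnosis date.
#' @param age_distribution Named weights over age bands
#'   20-39/40-49/50-59/60-69/70-74.
#' @param stage_distribution Named weights over stages I/II/III.
#' @param subtype_distribution Named weights over HR+/HER2-, HER2+, TN and
#'   missing (incomplete marker profile).
#' @param hazard_table Tibble as [default_hazard_table()].
#' @param post_recurrence_death_hazard Death hazard per year after a
#'   recurrence or second primary.
#' @param emigration_hazard Emigration (loss to follow-up) hazard per year.
#' @param admin_cutoff End of follow-up (administrative censoring date).
#' @param claim_model Claims layer, see [claim_model()].
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_patients,
                              seed = 1L,
                              diagnosis_window = as.Date(c("2004-01-01", "2010-12-31")),
                              age_distribution = c(
                                "20-39" = 0.055, "40-49" = 0.198, "50-59" = 0.255,
                                "60-69" = 0.360, "70-74" = 0.132
                              ),
                              stage_distribution = c(I = 0.510, II = 0.358, III = 0.132),
                              subtype_distribution = c(
                                "HR+/HER2-" = 0.661, "HER2+" = 0.145,
                                "TN" = 0.078, "missing" = 0.116
                              ),
                              hazard_table = default_hazard_table(),
                              post_recurrence_death_hazard = 0.15,
                              emigration_hazard = 0.002,
                              admin_cutoff = as.Date("2021-12-31"),
                              claim_model = recurrisk::claim_model()) {
  if (!is.numeric(n_patients) || length(n_patients) != 1 ||
      is.na(n_patients) || n_patients < 0 || n_patients != floor(n_patients)) {
    stop_field("n_patients", "must be a single nonnegative integer")
  }
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    stop_field("seed", "must be a single integer")
  }
  check_date(diagnosis_window, "diagnosis_window")
  if (length(diagnosis_window) != 2 || diagnosis_window[1] > diagnosis_window[2]) {
    stop_field("diagnosis_window", "must be two ordered dates")
  }
  check_weights(age_distribution, "age_distribution", AGE_BANDS_FIVE)
  check_weights(stage_distribution, "stage_distribution", c("I", "II", "III"))
  check_weights(
    subtype_distribution, "subtype_distribution",
    c("HR+/HER2-", "HER2+", "TN", "missing")
  )
  ht <- as_tibble(hazard_table)
  need <- c("subtype", "stage", "lambda_rec", "lambda_sp", "lambda_death")
  if (!all(need %in% names(ht))) {
    stop_field("hazard_table", paste("must have columns", paste(need, collapse = ", ")))
  }
  if (any(ht$lambda_rec < 0 | ht$lambda_sp < 0 | ht$lambda_death < 0)) {
    stop_field("hazard_table", "hazards must be nonnegative")
  }
  if (post_recurrence_death_hazard < 0) {
    stop_field("post_recurrence_death_hazard", "must be nonnegative")
  }
  if (emigration_hazard < 0) stop_field("emigration_hazard", "must be nonnegative")
  check_date(admin_cutoff, "admin_cutoff")
  if (admin_cutoff <= diagnosis_window[2]) {
    stop_field("admin_cutoff", "must fall after the end of diagnosis_window")
  }
  cm <- claim_model
  check_weights(cm$p_indicator_class / sum(cm$p_indicator_class), "claim_model$p_indicator_class")
  if (length(cm$p_indicator_class) != 4) {
    stop_field("claim_model$p_indicator_class", "must have four weights (classes 1-4)")
  }
  if (any(cm$claim_delay_days < 0) || any(cm$claim_delay_days != floor(cm$claim_delay_days))) {
    stop_field("claim_model$claim_delay_days", "must be nonnegative integer(s)")
  }
  if (cm$p_missed_recurrence < 0 || cm$p_missed_recurrence >= 1) {
    stop_field("claim_model$p_missed_recurrence", "must lie in [0, 1)")
  }
  structure(
    list(
      n_patients = as.integer(n_patients), seed = as.integer(seed),
      diagnosis_window = diagnosis_window,
      age_distribution = age_distribution,
      stage_distribution = stage_distribution,
      subtype_distribution = subtype_distribution,
      hazard_table = ht,
      post_recurrence_death_hazard = post_recurrence_death_hazard,
      emigration_hazard = emigration_hazard,
      admin_cutoff = admin_cutoff,
      claim_model = cm
    ),
    class = "simulation_config"
  )
}

# Exponential draw that returns Inf when the rate is zero.
rexp_or_inf <- function(n, rate) {
  if (rate <= 0) rep(Inf, n) else rexp(n, rate)
}

age_band_bounds <- list(
  "20-39" = c(20L, 39L), "40-49" = c(40L, 49L), "50-59" = c(50L, 59L),
  "60-69" = c(60L, 69L), "70-74" = c(70L, 74L)
)

empty_sim_tables <- function() {
  list(
    registry = registry_skeleton(0),
    hdd = tibble(
      patient_id = character(), admission_date = as.Date(character()),
      discharge_date = as.Date(character()),
      diagnosis_codes = character(), procedure_codes = character()
    ),
    ops = tibble(
      patient_id = character(), service_date = as.Date(character()),
      service_code = character()
    ),
    truth = tibble(
      patient_id = character(), true_event = character(),
      true_time_days = integer(), true_death_time_days = integer()
    )
  )
}

#' Simulate linked registry, claims and truth tables
#'
#' Draws one latent event history per woman under independent exponential
#' cause-specific clocks (recurrence, second primary cancer, death,
#' emigration); the earliest clock, or the administrative cutoff, wins.
#' After a recurrence or second primary, survival continues under the
#' post-event death hazard.  A claims layer is then generated: every woman
#' receives primary-treatment codes (breast surgery admission, chemo- and
#' radiotherapy services) inside her initial treatment window, and each
#' non-missed true recurrence emits one indicator claim of a sampled class
#' after a configurable delay.  Claims never postdate death or the
#' administrative cutoff.  Second primaries do not emit claims: they enter
#' the analysis through their registry date, as competing events.
#'
#' @param config A [simulation_config()].
#' @return A list of four tibbles: `registry` (one row per woman), `hdd`
#'   (hospital discharge claims), `ops` (outpatient service claims) and
#'   `truth` (the latent first event per woman, for recovery testing).
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "simulation_config")) {
    config <- do.call(simulation_config, config)
  }
  n <- config$n_patients
  if (n == 0) return(empty_sim_tables())
  set.seed(config$seed)

  id <- sprintf("P%06d", seq_len(n))
  window_days <- as.integer(config$diagnosis_window[2] - config$diagnosis_window[1])
  diagnosis_date <- config$diagnosis_window[1] +
    sample.int(window_days + 1L, n, replace = TRUE) - 1L

  band <- sample(names(config$age_distribution), n,
    replace = TRUE, prob = config$age_distribution
  )
  lo <- map_int(age_band_bounds[band], 1)
  hi <- map_int(age_band_bounds[band], 2)
  age <- lo + floor(runif(n) * (hi - lo + 1L))
  # extra offset < 350 days keeps floor(days/365.25) equal to `age`
  birth_date <- diagnosis_date - as.integer(round(age * DAYS_PER_YEAR)) -
    floor(runif(n) * 350)

  stage <- sample(names(config$stage_distribution), n,
    replace = TRUE, prob = config$stage_distribution
  )
  subtype <- sample(names(config$subtype_distribution), n,
    replace = TRUE, prob = config$subtype_distribution
  )

  er <- pr <- her2 <- character(n)
  is_hr <- subtype == "HR+/HER2-"
  is_her2 <- subtype == "HER2+"
  is_tn <- subtype == "TN"
  is_na_sub <- subtype == "missing"
  er[is_hr] <- "positive"
  pr[is_hr] <- sample(c("positive", "negative"), sum(is_hr), TRUE, c(0.8, 0.2))
  her2[is_hr] <- "negative"
  her2[is_her2] <- "positive"
  er[is_her2] <- sample(MARKER_LEVELS[1:2], sum(is_her2), TRUE, c(0.5, 0.5))
  pr[is_her2] <- sample(MARKER_LEVELS[1:2], sum(is_her2), TRUE, c(0.4, 0.6))
  er[is_tn] <- "negative"; pr[is_tn] <- "negative"; her2[is_tn] <- "negative"
  er[is_na_sub] <- "positive"; pr[is_na_sub] <- "negative"; her2[is_na_sub] <- "missing"

  haz_key <- ifelse(is_na_sub, "not_available", subtype)
  ht <- config$hazard_table
  idx <- match(paste(haz_key, stage), paste(ht$subtype, ht$stage))
  if (anyNA(idx)) {
    stop_field("hazard_table", "missing a (subtype, stage) combination present in the cohort")
  }

  # per-patient rates: inverse-cdf draws so that rate 0 maps to Inf
  u1 <- runif(n); u2 <- runif(n); u3 <- runif(n); u4 <- runif(n)
  inv_exp <- function(u, rate) ifelse(rate > 0, -log(u) / rate, Inf)
  t_rec <- inv_exp(u1, ht$lambda_rec[idx])
  t_sp <- inv_exp(u2, ht$lambda_sp[idx])
  t_death <- inv_exp(u3, ht$lambda_death[idx])
  t_emig <- inv_exp(u4, rep(config$emigration_hazard, n))
  t_admin <- as.numeric(config$admin_cutoff - diagnosis_date) / DAYS_PER_YEAR

  lat <- cbind(t_rec, t_sp, t_death, t_emig, t_admin)
  which_min <- max.col(-lat, ties.method = "first")
  true_event <- EVENT_LEVELS[which_min]
  t_first <- lat[cbind(seq_len(n), which_min)]
  admin_days <- as.integer(config$admin_cutoff - diagnosis_date)
  true_time_days <- pmax(
    pmin(as.integer(round(t_first * DAYS_PER_YEAR)), admin_days), 1L
  )
  # guard the day-resolution boundary: an event rounded onto the cutoff stays an event
  true_time_days[true_event == "admin_censor"] <- admin_days[true_event == "admin_censor"]

  # survival after an intermediate event (recurrence or second primary)
  post <- true_event %in% c("recurrence", "second_primary")
  u5 <- runif(n)
  t_post_death <- ifelse(
    post,
    t_first + inv_exp(u5, rep(config$post_recurrence_death_hazard, n)),
    Inf
  )
  death_days <- rep(NA_integer_, n)
  death_days[true_event == "death"] <- true_time_days[true_event == "death"]
  post_obs <- post & round(t_post_death * DAYS_PER_YEAR) <= admin_days
  death_days[post_obs] <- pmax(
    as.integer(round(t_post_death[post_obs] * DAYS_PER_YEAR)),
    true_time_days[post_obs]
  )
  true_death_time_days <- death_days

  sp_sites <- c("C18", "C34", "C56", "C61", "C73", "C50")
  second_primary_site <- ifelse(
    true_event == "second_primary",
    sample(sp_sites, n, replace = TRUE), NA_character_
  )
  second_primary_date <- as.Date(ifelse(
    true_event == "second_primary",
    diagnosis_date + true_time_days, NA
  ), origin = "1970-01-01")

  registry <- tibble(
    patient_id = id,
    birth_date = birth_date,
    diagnosis_date = diagnosis_date,
    topography = "C50.9",
    stage_tnm = stage,
    er_status = er, pr_status = pr, her2_status = her2,
    histology = sample(
      c("ductal", "lobular", "other"), n, TRUE, c(0.80, 0.12, 0.08)
    ),
    prior_cancer_date = as.Date(NA),
    prior_cancer_site = NA_character_,
    synchronous_cancer_flag = FALSE,
    dco_or_autopsy_flag = FALSE,
    vital_status = ifelse(is.na(death_days), "alive", "dead"),
    death_date = as.Date(
      ifelse(is.na(death_days), NA, diagnosis_date + death_days),
      origin = "1970-01-01"
    ),
    emigration_date = as.Date(ifelse(
      true_event == "emigration", diagnosis_date + true_time_days, NA
    ), origin = "1970-01-01"),
    second_primary_site = second_primary_site,
    second_primary_date = second_primary_date
  )

  truth <- tibble(
    patient_id = id,
    true_event = true_event,
    true_time_days = true_time_days,
    true_death_time_days = true_death_time_days
  )

  cm <- config$claim_model
  claims <- build_claims(
    id, diagnosis_date, her2, true_event, true_time_days,
    death_days, admin_days, cm
  )

  list(registry = registry, hdd = claims$hdd, ops = claims$ops, truth = truth)
}

# Primary-treatment claims for everyone plus one indicator claim per
# non-missed recurrence.  All dates are clamped to death / cutoff.
build_claims <- function(id, diagnosis_date, her2, true_event, true_time_days,
                         death_days, admin_days, cm) {
  n <- length(id)
  last_day <- pmin(ifelse(is.na(death_days), admin_days, death_days), admin_days)
  tx_months <- ifelse(her2 == "positive", 2L, 1L) * cm$primary_treatment_claim_months
  tx_days <- months_to_days(tx_months)

  # surgery admission early after diagnosis (class-3 codes inside the window)
  surg_day <- pmin(7L + floor(runif(n) * 38), last_day)
  hdd_primary <- tibble(
    patient_id = id,
    admission_date = diagnosis_date + surg_day,
    discharge_date = diagnosis_date + surg_day + 3L,
    diagnosis_codes = "1749",
    procedure_codes = "8543"
  )
  # chemo + radiotherapy services spread over the treatment window
  chemo_day <- pmin(60L + floor(runif(n) * pmax(tx_days - 120L, 1L)), last_day)
  radio_day <- pmin(90L + floor(runif(n) * pmax(tx_days - 150L, 1L)), last_day)
  ops_primary <- bind_rows(
    tibble(patient_id = id, service_date = diagnosis_date + chemo_day,
           service_code = "9925"),
    tibble(patient_id = id, service_date = diagnosis_date + radio_day,
           service_code = "9229")
  )

  rec <- true_event == "recurrence" & runif(n) >= cm$p_missed_recurrence
  k <- sum(rec)
  hdd_rec <- hdd_primary[0, ]
  ops_rec <- ops_primary[0, ]
  if (k > 0) {
    delay <- if (length(cm$claim_delay_days) == 1) {
      rep(as.integer(cm$claim_delay_days), k)
    } else {
      sample(as.integer(cm$claim_delay_days), k, replace = TRUE)
    }
    cls <- sample(1:4, k, replace = TRUE, prob = cm$p_indicator_class)
    day <- pmin(true_time_days[rec] + delay, last_day[rec])
    keep <- day <= admin_days[rec]   # claims can never pass the cutoff
    rid <- id[rec][keep]; day <- day[keep]; cls <- cls[keep]
    rdate <- diagnosis_date[rec][keep] + day
    in_hdd <- cls >= 3
    hdd_rec <- tibble(
      patient_id = rid[in_hdd],
      admission_date = rdate[in_hdd],
      discharge_date = rdate[in_hdd] + 2L,
      diagnosis_codes = ifelse(cls[in_hdd] == 3, "1749", "1970"),
      procedure_codes = ifelse(cls[in_hdd] == 3, "8541", "")
    )
    ops_rec <- tibble(
      patient_id = rid[!in_hdd],
      service_date = rdate[!in_hdd],
      service_code = ifelse(cls[!in_hdd] == 1, "9925", "9229")
    )
  }

  hdd <- bind_rows(hdd_primary, hdd_rec) |>
    arrange(.data$patient_id, .data$admission_date)
  ops <- bind_rows(ops_primary, ops_rec) |>
    arrange(.data$patient_id, .data$service_date)
  list(hdd = hdd, ops = ops)
}

#' Closed-form cumulative incidence under constant hazards
#'
#' With independent constant cause-specific hazards, the cumulative
#' incidence of cause k by time t is
#' (lambda_k / lambda_total) * (1 - exp(-lambda_total * t)).
#' Serves as the analytic oracle against which the nonparametric estimator
#' is checked on simulated data.
#'
#' @param lambda_cause Cause-specific hazard per year (> 0).
#' @param lambda_total Sum of all cause-specific hazards per year.
#' @param t Time in years (>= 0), vectorised.
#' @return Probability (vector over `t`).
#' @export
#' @examples
#' analytic_cif(0.02, 0.04, 10)
analytic_cif <- function(lambda_cause, lambda_total, t) {
  if (lambda_cause <= 0) stop_field("lambda_cause", "must be positive")
  if (lambda_cause > lambda_total) {
    stop_field("lambda_cause", "must not exceed lambda_total")
  }
  if (any(t < 0)) stop_field("t", "must be nonnegative")
  (lambda_cause / lambda_total) * (1 - exp(-lambda_total * t))
}

#' Blank eligible registry rows
#'
#' Produces `n` registry rows that pass every eligibility criterion
#' (no prior or synchronous cancer, clinically valid stage, age within
#' 20-74, alive at follow-up end).  Intended as a starting point for
#' constructing small registries that exercise specific exclusion rules by
#' mutating columns.
#'
#' @param n Number of rows.
#' @param diagnosis_date Diagnosis date given to every row.
#' @return A registry tibble.
#' @export
registry_skeleton <- function(n, diagnosis_date = as.Date("2005-06-15")) {
  tibble(
    patient_id = if (n > 0) sprintf("S%06d", seq_len(n)) else character(),
    birth_date = rep(diagnosis_date - as.integer(round(55 * DAYS_PER_YEAR)), n),
    diagnosis_date = rep(diagnosis_date, n),
    topography = rep("C50.9", n),
    stage_tnm = rep("I", n),
    er_status = rep("positive", n),
    pr_status = rep("positive", n),
    her2_status = rep("negative", n),
    histology = rep("ductal", n),
    prior_cancer_date = rep(as.Date(NA), n),
    prior_cancer_site = rep(NA_character_, n),
    synchronous_cancer_flag = rep(FALSE, n),
    dco_or_autopsy_flag = rep(FALSE, n),
    vital_status = rep("alive", n),
    death_date = rep(as.Date(NA), n),
    emigration_date = rep(as.Date(NA), n),
    second_primary_site = rep(NA_character_, n),
    second_primary_date = rep(as.Date(NA), n)
  )
}
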