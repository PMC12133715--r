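#' Build event timelines for cumulative-incidence estimation
#'
#' Joins resolved outcomes with cohort strata and recodes the censoring
#' events (emigration, administrative cutoff) to `"censored"`.  With
#' `left_truncation = TRUE`, each woman's entry time is her surveillance
#' start (12/24 months by HER2 status), and women whose outcome precedes
#' their entry are dropped from estimation; by default risk time counts
#' from diagnosis for all women (entry 0).
#'
#' @param outcomes [resolve_outcomes()] output.
#' @param cohort Cohort with strata columns (see [derive_strata()]).
#' @param left_truncation Use delayed entry at the surveillance start.
#' @param sensitivity_12m Uniform 12-month window (affects entry only).
#' @return Timelines tibble for [aalen_johansen()] with stratum columns.
#' @export
build_timelines <- function(outcomes, cohort, left_truncation = FALSE,
                            sensitivity_12m = FALSE) {
  x <- outcomes |>
    inner_join(
      select(cohort, "patient_id", any_of(c(
        "her2_status", "period", "age_group", "subtype", "stage"
      ))),
      by = "patient_id"
    ) |>
    mutate(
      cause = ifelse(
        .data$event %in% c("emigration", "admin_censor"),
        "censored", .data$event
      ),
      entry_days = 0
    )
  if (left_truncation) {
    x <- x |>
      mutate(entry_days = months_to_days(
        surveillance_start(.data$her2_status, sensitivity_12m)
      )) |>
      filter(.data$time_days > .data$entry_days |
               (.data$cause == "censored" & .data$time_days >= .data$entry_days))
  }
  x
}

#' Pipeline run configuration
#'
#' Either a [simulation_config()] (synthetic mode) or paths to the three
#' input tables (registry, HDD, OPS) — exactly one of the two.
#'
#' @param simulation Optional [simulation_config()].
#' @param registry_path,hdd_path,ops_path Optional CSV paths.
#' @param code_set Indicator code set (list or YAML path).
#' @param admin_cutoff Administrative censoring date.
#' @param sensitivity_12m Uniform 12-month surveillance window.
#' @param left_truncation Delayed entry at the surveillance start.
#' @param output_dir Directory for the CSV outputs (created if needed);
#'   `NULL` skips writing.
#' @param seed Integer seed forwarded to the simulation stage.
#' @return A list of class `run_config`.
#' @export
run_config <- function(simulation = NULL,
                       registry_path = NULL, hdd_path = NULL, ops_path = NULL,
                       code_set = default_code_set(),
                       admin_cutoff = as.Date("2021-12-31"),
                       sensitivity_12m = FALSE,
                       left_truncation = FALSE,
                       output_dir = NULL,
                       seed = 1L) {
  synthetic <- !is.null(simulation)
  files <- !is.null(registry_path)
  if (synthetic == files) {
    abort("Provide exactly one of `simulation` or the three input paths")
  }
  if (files && (is.null(hdd_path) || is.null(ops_path))) {
    abort("File mode needs `registry_path`, `hdd_path` and `ops_path`")
  }
  if (is.character(code_set)) code_set <- read_code_set(code_set)
  structure(
    list(
      simulation = simulation,
      registry_path = registry_path, hdd_path = hdd_path, ops_path = ops_path,
      code_set = validate_code_set(code_set),
      admin_cutoff = as.Date(admin_cutoff),
      sensitivity_12m = isTRUE(sensitivity_12m),
      left_truncation = isTRUE(left_truncation),
      output_dir = output_dir,
      seed = as.integer(seed)
    ),
    class = "run_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Recognised keys mirror the arguments of [run_config()]; a `simulation`
#' block is forwarded to [simulation_config()] (dates as ISO-8601
#' strings).
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim <- NULL
  if (!is.null(y$simulation)) {
    s <- y$simulation
    if (!is.null(s$diagnosis_window)) s$diagnosis_window <- as.Date(unlist(s$diagnosis_window))
    if (!is.null(s$admin_cutoff)) s$admin_cutoff <- as.Date(s$admin_cutoff)
    for (w in c("age_distribution", "stage_distribution", "subtype_distribution")) {
      if (!is.null(s[[w]])) s[[w]] <- unlist(s[[w]])
    }
    if (!is.null(s$hazard_table)) s$hazard_table <- as_tibble(bind_rows(s$hazard_table))
    if (!is.null(s$claim_model)) s$claim_model <- do.call(claim_model, s$claim_model)
    sim <- do.call(simulation_config, s)
  }
  run_config(
    simulation = sim,
    registry_path = y$registry_path, hdd_path = y$hdd_path, ops_path = y$ops_path,
    code_set = y$code_set %||% default_code_set(),
    admin_cutoff = as.Date(y$admin_cutoff %||% "2021-12-31"),
    sensitivity_12m = isTRUE(y$sensitivity_12m),
    left_truncation = isTRUE(y$left_truncation),
    output_dir = y$output_dir,
    seed = y$seed %||% 1L
  )
}

read_registry_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(
                    patient_id = "c", topography = "c", stage_tnm = "c",
                    er_status = "c", pr_status = "c", her2_status = "c",
                    histology = "c", prior_cancer_site = "c",
                    vital_status = "c", second_primary_site = "c",
                    .default = readr::col_guess()
                  ))
}

read_hdd_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(
                    patient_id = "c", diagnosis_codes = "c",
                    procedure_codes = "c", .default = readr::col_guess()
                  ))
}

read_ops_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(
                    patient_id = "c", service_code = "c",
                    .default = readr::col_guess()
                  ))
}

#' Run the full recurrence-estimation pipeline
#'
#' Composes all stages: (synthetic or file) input tables, eligibility
#' cascade, stratum derivation, claims-based recurrence ascertainment,
#' first-event resolution, overall and stratified Aalen-Johansen
#' cumulative incidence with 5- and 10-year summaries, crude rates per
#' 1000 person-years, and the six-state 10-year status table.  With an
#' `output_dir`, writes `exclusions.csv`, `cohort.csv`, `outcomes.csv`,
#' `cif_overall.csv`, `cif_<stratum>.csv`, `rates.csv`, `status10y.csv`
#' and `summary.txt` (RFC-4180 CSV, ISO-8601 dates).  Identical
#' configuration and seed give byte-identical outputs.
#'
#' @param config A [run_config()].
#' @return A `recurrisk_report`: list with the cohort, exclusion log,
#'   outcomes, fitted estimates, summary tables and a configuration hash.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(config$simulation)) {
    sim <- config$simulation
    tabs <- simulate_cohort(sim)
    registry <- tabs$registry
    hdd <- tabs$hdd
    ops <- tabs$ops
    truth <- tabs$truth
    admin_cutoff <- sim$admin_cutoff
  } else {
    for (p in c(config$registry_path, config$hdd_path, config$ops_path)) {
      if (!file.exists(p)) abort(sprintf("Input file not found: %s", p))
    }
    registry <- read_registry_csv(config$registry_path)
    hdd <- read_hdd_csv(config$hdd_path)
    ops <- read_ops_csv(config$ops_path)
    truth <- NULL
    admin_cutoff <- config$admin_cutoff
  }

  elig <- apply_eligibility(registry, reference_end = admin_cutoff)
  cohort <- derive_strata(elig$cohort)

  claims <- collect_claims(hdd, ops)
  recurrences <- ascertain_recurrence(
    cohort, claims, config$code_set, config$sensitivity_12m
  )
  outcomes <- resolve_outcomes(cohort, recurrences, admin_cutoff)

  timelines <- build_timelines(
    outcomes, cohort,
    left_truncation = config$left_truncation,
    sensitivity_12m = config$sensitivity_12m
  )
  overall <- if (nrow(timelines) > 0) aalen_johansen(timelines) else NULL
  strata <- c("period", "age_group", "subtype", "stage")
  by_stratum <- if (nrow(timelines) > 0) {
    setNames(lapply(strata, \(s) suppressMessages(
      stratified_cif(timelines, s)
    )), strata)
  } else {
    setNames(vector("list", length(strata)), strata)
  }

  cif_summary <- summarise_cif(overall, by_stratum)

  py <- person_years(outcomes$time_days)
  n_rec <- sum(outcomes$event == "recurrence")
  rates <- tibble(
    stratum = "all", level = "all",
    n = nrow(outcomes), n_recurrences = n_rec,
    person_years = py,
    rate_per_1000py = if (py > 0) crude_rate(n_rec, py) else NA_real_
  )
  for (s in strata) {
    tl <- timelines
    lev <- tl[[s]]
    keep <- !is.na(lev) & lev != "not_available"
    if (!any(keep)) next
    r <- tl[keep, ] |>
      group_by(level = .data[[s]]) |>
      summarise(
        n = n(),
        n_recurrences = sum(.data$event == "recurrence"),
        person_years = person_years(.data$time_days),
        .groups = "drop"
      ) |>
      mutate(
        stratum = s,
        rate_per_1000py = crude_rate(.data$n_recurrences, .data$person_years)
      )
    rates <- bind_rows(rates, select(r, names(rates)))
  }

  status_input <- outcomes |>
    left_join(
      cohort |>
        transmute(
          .data$patient_id,
          death_time_days = as.integer(.data$death_date - .data$diagnosis_date)
        ),
      by = "patient_id"
    )
  statuses <- status_at_10y(status_input)
  status_table <- tabulate_status(cohort, statuses)

  report <- structure(
    list(
      n_input = attr(elig$log, "initial"),
      cohort = cohort,
      exclusion_log = elig$log,
      outcomes = outcomes,
      truth = truth,
      overall = overall,
      by_stratum = by_stratum,
      cif_summary = cif_summary,
      rates = rates,
      statuses = statuses,
      status_table = status_table,
      # hash of the analysis-relevant configuration (where outputs land
      # must not change what they contain)
      config_hash = rlang::hash(config[setdiff(names(config), "output_dir")]),
      config = config
    ),
    class = "recurrisk_report"
  )

  if (!is.null(config$output_dir)) write_report(report, config$output_dir)
  report
}

cif_summary_row <- function(fit, stratum, level) {
  if (is.null(fit) || !"recurrence" %in% fit$causes) {
    return(tibble(
      stratum = stratum, level = level, n = if (is.null(fit)) 0L else fit$n,
      cif5 = 0, cif5_low = 0, cif5_high = 0,
      cif10 = 0, cif10_low = 0, cif10_high = 0
    ))
  }
  a5 <- cif_at(fit, "recurrence", 5)
  a10 <- cif_at(fit, "recurrence", 10)
  tibble(
    stratum = stratum, level = level, n = fit$n,
    cif5 = a5$estimate, cif5_low = a5$conf_low, cif5_high = a5$conf_high,
    cif10 = a10$estimate, cif10_low = a10$conf_low, cif10_high = a10$conf_high
  )
}

summarise_cif <- function(overall, by_stratum) {
  rows <- list(cif_summary_row(overall, "all", "all"))
  for (s in names(by_stratum)) {
    for (lev in names(by_stratum[[s]])) {
      rows <- c(rows, list(cif_summary_row(by_stratum[[s]][[lev]], s, lev)))
    }
  }
  list_rbind(rows) |>
    mutate(across(
      c("cif5", "cif5_low", "cif5_high", "cif10", "cif10_low", "cif10_high"),
      \(v) round_half_up(100 * v, 1)
    ))
}

write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, name) {
    readr::write_csv(x, file.path(dir, name), progress = FALSE)
  }
  log <- report$exclusion_log
  w(tibble(
    criterion = log$criterion, label = log$label, n_removed = log$n_removed
  ), "exclusions.csv")
  w(report$cohort, "cohort.csv")
  w(report$outcomes, "outcomes.csv")
  if (!is.null(report$overall)) w(tidy(report$overall), "cif_overall.csv")
  for (s in names(report$by_stratum)) {
    fits <- report$by_stratum[[s]]
    if (length(fits) == 0) next
    tab <- imap(fits, \(f, lev) mutate(tidy(f), level = lev, .before = 1)) |>
      list_rbind()
    w(tab, sprintf("cif_%s.csv", s))
  }
  w(report$rates, "rates.csv")
  w(report$status_table, "status10y.csv")
  writeLines(format_report(report), file.path(dir, "summary.txt"))
  invisible(dir)
}

fmt_ci <- function(p, lo, hi) sprintf("%.1f%% (%.1f%%-%.1f%%)", p, lo, hi)

format_report <- function(x) {
  out <- c(
    sprintf("Cohort: %d eligible of %d registry records", nrow(x$cohort), x$n_input),
    sprintf("Config hash: %s", x$config_hash),
    "",
    "Cumulative incidence of recurrence (competing risks):"
  )
  cs <- x$cif_summary
  for (i in seq_len(nrow(cs))) {
    out <- c(out, sprintf(
      "  %-10s %-10s n=%5d   5y %s   10y %s",
      cs$stratum[i], cs$level[i], cs$n[i],
      fmt_ci(cs$cif5[i], cs$cif5_low[i], cs$cif5_high[i]),
      fmt_ci(cs$cif10[i], cs$cif10_low[i], cs$cif10_high[i])
    ))
  }
  out <- c(out, "", "Crude recurrence rates per 1000 person-years:")
  for (i in seq_len(nrow(x$rates))) {
    out <- c(out, sprintf(
      "  %-10s %-10s %d events / %.1f py = %.1f",
      x$rates$stratum[i], x$rates$level[i], x$rates$n_recurrences[i],
      x$rates$person_years[i], x$rates$rate_per_1000py[i]
    ))
  }
  out <- c(out, "", "Follow-up status at 10 years (all cohort):")
  st <- filter(x$status_table, .data$stratum == "all")
  for (i in seq_len(nrow(st))) {
    out <- c(out, sprintf(
      "  %-26s %6d (%.1f%%)", st$state[i], st$n[i], st$pct[i]
    ))
  }
  out
}

#' @export
print.recurrisk_report <- function(x, ...) {
  cat(paste(format_report(x), collapse = "\n"), "\n")
  invisible(x)
}
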