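#' Aalen-Johansen cumulative incidence under competing risks
#'
#' Nonparametric estimator of the cause-specific cumulative incidence
#' functions.  At each distinct event time \eqn{t_j} with \eqn{n_j} at
#' risk and \eqn{d_{kj}} events of cause \eqn{k}, the event-free survival
#' is the product-limit \eqn{S(t_j) = \prod_{i \le j} (1 - d_i / n_i)}
#' over all causes pooled, and
#' \eqn{\hat F_k(t) = \sum_{t_j \le t} S(t_{j-1})\, d_{kj} / n_j}.
#' Variances use the Aalen-type (delta-method) estimator and 95\%
#' confidence intervals the log(-log) transformation, clamped to \[0, 1\].
#' Delayed entry (left truncation) is supported through `entry_days`:
#' a subject is at risk at \eqn{t} when \eqn{entry < t \le time}.
#'
#' @param data Tibble with one row per subject: `time_days` (nonnegative),
#'   `cause` (character; `"censored"` marks censoring, any other labels are
#'   competing causes), optional `entry_days` (default 0).
#' @param conf_level Confidence level for the intervals.
#' @return An object of class `cif_estimate`: a list with `steps` (one row
#'   per event time and cause: `time`, `cause`, `n_risk`, `n_event`,
#'   `estimate`, `std_error`, `conf_low`, `conf_high`), `surv` (event-free
#'   survival steps), `causes`, `n`, `n_events`, `max_time`.
#' @export
#' @examples
#' d <- tibble::tibble(
#'   time_days = c(365, 730, 1095, 1460),
#'   cause = c("recurrence", "death", "censored", "recurrence")
#' )
#' fit <- aalen_johansen(d)
#' cif_at(fit, "recurrence", 3)
aalen_johansen <- function(data, conf_level = 0.95) {
  data <- as_tibble(data)
  if (nrow(data) == 0) abort("Need at least one timeline")
  if (!all(c("time_days", "cause") %in% names(data))) {
    abort("`data` must have columns time_days and cause")
  }
  time <- as.numeric(data$time_days)
  cause <- as.character(data$cause)
  entry <- if ("entry_days" %in% names(data)) as.numeric(data$entry_days) else rep(0, length(time))
  if (any(is.na(time)) || any(time < 0)) abort("Times must be nonnegative")
  if (any(entry > time)) abort("`entry_days` must not exceed `time_days`")
  is_event <- cause != "censored"
  if (any(is_event & time == 0)) {
    abort("Events at time 0 are not estimable (no time at risk)")
  }
  if (all(time == 0)) abort("All timelines censored at time 0")

  causes <- sort(unique(cause[is_event]))
  tj <- sort(unique(time[is_event]))
  J <- length(tj)
  N <- length(time)
  max_time <- max(time)

  if (J == 0) {
    # no events at all: survival 1 throughout, no CIF steps
    out <- list(
      steps = tibble(
        time = numeric(), cause = character(), n_risk = numeric(),
        n_event = integer(), estimate = numeric(), std_error = numeric(),
        conf_low = numeric(), conf_high = numeric()
      ),
      surv = tibble(time = 0, n_risk = N, n_event = 0L, estimate = 1),
      causes = character(), n = N,
      n_events = integer(), max_time = max_time, conf_level = conf_level
    )
    class(out) <- "cif_estimate"
    return(out)
  }

  # risk set: entry < t_j <= time
  st <- sort(time)
  se <- sort(entry)
  n_in <- N - findInterval(tj - 1e-9, st)            # time >= t_j
  n_out <- length(se) - findInterval(tj - 1e-9, se)  # entry >= t_j
  n_risk <- n_in - n_out
  if (any(n_risk <= 0)) {
    abort("Empty risk set at an event time (check entry times)")
  }

  d_k <- vapply(causes, function(k) {
    tabulate(match(time[is_event & cause == k], tj), nbins = J)
  }, numeric(J))
  d_k <- matrix(unname(d_k), nrow = J, dimnames = list(NULL, causes))
  d_tot <- rowSums(d_k)

  S <- cumprod(1 - d_tot / n_risk)
  S_prev <- c(1, S[-J])

  z <- qnorm(1 - (1 - conf_level) / 2)
  a_j <- ifelse(n_risk - d_tot > 0, d_tot / (n_risk * (n_risk - d_tot)), 0)

  steps <- map(causes, function(k) {
    dk <- unname(d_k[, k])
    f <- S_prev * dk / n_risk
    Fk <- cumsum(f)
    b_j <- S_prev * dk / n_risk^2
    c_j <- S_prev^2 * ((n_risk - dk) / n_risk) * dk / n_risk^2
    A <- cumsum(a_j); AF <- cumsum(Fk * a_j); AF2 <- cumsum(Fk^2 * a_j)
    B <- cumsum(b_j); BF <- cumsum(Fk * b_j); C <- cumsum(c_j)
    V <- Fk^2 * A - 2 * Fk * AF + AF2 + C - 2 * Fk * B + 2 * BF
    V <- pmax(V, 0)
    se_f <- sqrt(V)
    inner <- Fk > 0 & Fk < 1 & se_f > 0
    lo <- hi <- numeric(J)
    lo[Fk == 0] <- 0; hi[Fk == 0] <- 0
    lo[Fk >= 1] <- 1; hi[Fk >= 1] <- 1
    if (any(inner)) {
      g <- log(-log(Fk[inner]))
      sg <- se_f[inner] / abs(Fk[inner] * log(Fk[inner]))
      lo[inner] <- exp(-exp(g + z * sg))
      hi[inner] <- exp(-exp(g - z * sg))
    }
    tibble(
      time = tj, cause = k, n_risk = n_risk, n_event = as.integer(dk),
      estimate = Fk, std_error = se_f,
      conf_low = pmin(pmax(lo, 0), 1), conf_high = pmin(pmax(hi, 0), 1)
    )
  }) |> list_rbind()

  out <- list(
    steps = steps,
    surv = tibble(
      time = tj, n_risk = n_risk, n_event = as.integer(d_tot), estimate = S
    ),
    causes = causes,
    n = N,
    n_events = vapply(causes, function(k) sum(d_k[, k]), numeric(1)),
    max_time = max_time,
    conf_level = conf_level
  )
  class(out) <- "cif_estimate"
  out
}

step_lookup <- function(times, values, t, before = 0) {
  idx <- findInterval(t, times)  # right-continuous: step at t counts
  ifelse(idx == 0, before, values[pmax(idx, 1)])
}

#' Cumulative incidence at a time point
#'
#' Right-continuous step lookup of the estimated cumulative incidence of
#' one cause at `t` years, with its confidence bounds.  A lookup beyond
#' the last observed follow-up returns the last value, flagged in the
#' `extrapolated` column.
#'
#' @param estimate A `cif_estimate`.
#' @param cause Cause label.
#' @param t Time(s) in years since diagnosis.
#' @return Tibble `(cause, t_years, estimate, conf_low, conf_high,
#'   extrapolated)`.
#' @export
cif_at <- function(estimate, cause, t) {
  stopifnot(inherits(estimate, "cif_estimate"))
  if (any(t < 0)) abort("`t` must be nonnegative")
  s <- filter(estimate$steps, .data$cause == !!cause)
  td <- years_to_days(t)
  extrap <- td > estimate$max_time
  tibble(
    cause = cause,
    t_years = t,
    estimate = step_lookup(s$time, s$estimate, td),
    conf_low = step_lookup(s$time, s$conf_low, td),
    conf_high = step_lookup(s$time, s$conf_high, td),
    extrapolated = extrap
  )
}

# Event-free survival S(t), right-continuous, t in years.
surv_at <- function(estimate, t) {
  td <- years_to_days(t)
  step_lookup(estimate$surv$time, estimate$surv$estimate, td, before = 1)
}

#' Crude event rate per 1000 person-years
#'
#' @param n_events Number of events.
#' @param person_years Total person-years at risk (> 0).
#' @return Rate per 1000 person-years.
#' @export
#' @examples
#' crude_rate(10, 5000)
crude_rate <- function(n_events, person_years) {
  if (any(person_years <= 0)) abort("`person_years` must be positive")
  1000 * n_events / person_years
}

#' Person-years at risk from follow-up days
#'
#' @param time_days Per-subject follow-up in days (diagnosis to outcome).
#' @return Total person-years (days / 365.25).
#' @export
person_years <- function(time_days) {
  sum(as.numeric(time_days)) / DAYS_PER_YEAR
}

#' Conditional cumulative incidence between two horizons
#'
#' Probability of a cause-k event in (t1, t2] given event-free survival to
#' t1: `(F_k(t2) - F_k(t1)) / S(t1)`.  Undefined (NA with a warning) when
#' no one remains event-free at t1.
#'
#' @param estimate A `cif_estimate`.
#' @param cause Cause label.
#' @param t1,t2 Years since diagnosis, `t1 < t2`.
#' @return Single probability.
#' @export
conditional_cif <- function(estimate, cause, t1, t2) {
  if (t1 >= t2) abort("`t1` must be strictly less than `t2`")
  f1 <- cif_at(estimate, cause, t1)$estimate
  f2 <- cif_at(estimate, cause, t2)$estimate
  s1 <- surv_at(estimate, t1)
  if (s1 <= 0) {
    warn("No event-free survivors at t1: conditional probability undefined")
    return(NA_real_)
  }
  (f2 - f1) / s1
}

#' Stratified cumulative incidence
#'
#' Fits an independent Aalen-Johansen estimate inside each level of a
#' stratum column.  Rows with a missing stratum are excluded from that
#' stratification only; degenerate strata (no estimable data) are omitted
#' with a warning.
#'
#' @param data Timelines tibble as for [aalen_johansen()], plus the
#'   stratum column.
#' @param by Name of the stratum column (e.g. `"period"`, `"age_group"`,
#'   `"subtype"`, `"stage"`).
#' @param conf_level Confidence level.
#' @return Named list of `cif_estimate`, one per stratum level.
#' @export
stratified_cif <- function(data, by, conf_level = 0.95) {
  if (!by %in% names(data)) abort(sprintf("No column `%s` in `data`", by))
  lab <- data[[by]]
  drop_na <- is.na(lab) | lab == "not_available"
  if (any(drop_na)) {
    inform(sprintf(
      "%d subject(s) with missing `%s` excluded from this stratification",
      sum(drop_na), by
    ))
  }
  data <- data[!drop_na, , drop = FALSE]
  out <- list()
  for (lev in sort(unique(data[[by]]))) {
    sub <- data[data[[by]] == lev, , drop = FALSE]
    fit <- tryCatch(
      aalen_johansen(sub, conf_level = conf_level),
      error = function(e) {
        warn(sprintf("Stratum `%s` omitted: %s", lev, conditionMessage(e)))
        NULL
      }
    )
    if (!is.null(fit)) out[[lev]] <- fit
  }
  out
}

#' @export
print.cif_estimate <- function(x, ...) {
  cat(sprintf(
    "Aalen-Johansen cumulative incidence: %d subjects, causes: %s\n",
    x$n, paste(x$causes, collapse = ", ")
  ))
  for (k in x$causes) {
    at5 <- cif_at(x, k, 5)$estimate
    at10 <- cif_at(x, k, 10)$estimate
    cat(sprintf(
      "  %-16s %4d events  CIF 5y %5.1f%%  10y %5.1f%%\n",
      k, x$n_events[[k]], 100 * at5, 100 * at10
    ))
  }
  invisible(x)
}

#' @describeIn aalen_johansen Step-level tidy table of the fit.
#' @param x A `cif_estimate`.
#' @param ... Unused.
#' @export
tidy.cif_estimate <- function(x, ...) {
  x$steps
}

#' @describeIn aalen_johansen One-row model summary.
#' @export
glance.cif_estimate <- function(x, ...) {
  tibble(
    n = x$n,
    n_causes = length(x$causes),
    n_events = sum(x$n_events),
    max_time_days = x$max_time,
    conf_level = x$conf_level
  )
}

#' @describeIn aalen_johansen Step-function plot of all cause-specific
#'   cumulative incidence curves with confidence bands.
#' @param object A `cif_estimate`.
#' @export
autoplot.cif_estimate <- function(object, ...) {
  max_t <- object$max_time
  line_d <- object$steps |>
    group_by(.data$cause) |>
    group_modify(\(g, ...) {
      bind_rows(
        tibble(time = 0, estimate = 0),
        select(g, "time", "estimate"),
        tibble(time = max_t, estimate = max(g$estimate))
      )
    }) |>
    ungroup() |>
    mutate(t_years = .data$time / DAYS_PER_YEAR)
  # piecewise-constant confidence band as rectangles between step times
  band_d <- object$steps |>
    group_by(.data$cause) |>
    group_modify(\(g, ...) {
      tibble(
        xmin = g$time, xmax = c(g$time[-1], max_t),
        ymin = g$conf_low, ymax = g$conf_high
      )
    }) |>
    ungroup() |>
    mutate(
      xmin = .data$xmin / DAYS_PER_YEAR,
      xmax = .data$xmax / DAYS_PER_YEAR
    )
  ggplot2::ggplot() +
    ggplot2::geom_rect(
      data = band_d,
      ggplot2::aes(
        xmin = .data$xmin, xmax = .data$xmax,
        ymin = .data$ymin, ymax = .data$ymax, fill = .data$cause
      ),
      alpha = 0.15
    ) +
    ggplot2::geom_step(
      data = line_d,
      ggplot2::aes(.data$t_years, .data$estimate, colour = .data$cause),
      linewidth = 0.7
    ) +
    ggplot2::labs(
      x = "Years since diagnosis", y = "Cumulative incidence",
      colour = NULL, fill = NULL
    ) +
    ggplot2::theme_minimal()
}
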