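hand_example <- function() {
  tibble::tibble(
    time_days = c(365, 730, 1095, 1460),
    cause = c("recurrence", "death", "censored", "recurrence")
  )
}

test_that("the four-patient hand example reproduces the product-limit arithmetic", {
  fit <- aalen_johansen(hand_example())
  rec <- dplyr::filter(fit$steps, cause == "recurrence")
  expect_equal(rec$estimate, c(0.25, 0.25, 0.75))
  dth <- dplyr::filter(fit$steps, cause == "death")
  expect_equal(dth$estimate[dth$time == 730], 0.25)
  expect_equal(fit$surv$estimate, c(0.75, 0.50, 0))
  expect_equal(cif_at(fit, "recurrence", 3)$estimate, 0.25)
  # right-continuity: lookup exactly on a step returns the post-jump value
  expect_equal(cif_at(fit, "recurrence", 365 / 365.25)$estimate, 0.25)
  expect_equal(cif_at(fit, "recurrence", 364 / 365.25)$estimate, 0)
  # conditional probability between 3 and 5 years
  expect_equal(conditional_cif(fit, "recurrence", 3, 5), (0.75 - 0.25) / 0.50)
  expect_error(conditional_cif(fit, "recurrence", 5, 3), "t1")
})

test_that("with a single uncensored cause the CIF is the empirical CDF", {
  set.seed(1)
  t <- sample(1:50, 30, TRUE)
  fit <- aalen_johansen(tibble::tibble(time_days = t, cause = "recurrence"))
  s <- dplyr::filter(fit$steps, cause == "recurrence")
  expect_equal(s$estimate, ecdf(t)(s$time), tolerance = 1e-12)
})

test_that("a cause absent from the data has identically zero incidence", {
  fit <- aalen_johansen(hand_example())
  at <- cif_at(fit, "second_primary", c(1, 5, 20))
  expect_equal(at$estimate, c(0, 0, 0))
  expect_equal(at$conf_low, c(0, 0, 0))
})

test_that("lookups beyond the last follow-up return the last value, flagged", {
  fit <- aalen_johansen(hand_example())
  at <- cif_at(fit, "recurrence", 30)
  expect_equal(at$estimate, 0.75)
  expect_true(at$extrapolated)
  expect_false(cif_at(fit, "recurrence", 3)$extrapolated)
})

test_that("estimator equals the brute-force oracle on random tiny datasets", {
  for (seed in 1:60) {
    d <- random_timelines(seed)
    if (all(d$time_days == 0) || !any(d$cause != "censored")) next
    fit <- aalen_johansen(d)
    for (k in fit$causes) {
      s <- dplyr::filter(fit$steps, cause == k)
      for (j in seq_len(nrow(s))) {
        expect_equal(
          s$estimate[j],
          oracle_cif(d$time_days, d$cause, k, s$time[j]),
          tolerance = 1e-10
        )
      }
    }
  }
})

test_that("point estimates and variances agree with the survival and cmprsk packages", {
  skip_if_not_installed("survival")
  skip_if_not_installed("cmprsk")
  set.seed(7)
  n <- 120
  t <- sample(1:300, n, TRUE)
  cs <- sample(c("recurrence", "death", "censored"), n, TRUE, c(.4, .3, .3))
  fit <- aalen_johansen(tibble::tibble(time_days = t, cause = cs))
  s <- dplyr::filter(fit$steps, cause == "recurrence")
  sf <- survival::survfit(
    survival::Surv(t, factor(cs, levels = c("censored", "recurrence", "death"))) ~ 1
  )
  idx <- match(s$time, sf$time)
  k <- which(sf$states == "recurrence")
  expect_equal(s$estimate, sf$pstate[idx, k], tolerance = 1e-10)
  expect_equal(s$std_error, sf$std.err[idx, k], tolerance = 1e-10)
  fs <- ifelse(cs == "censored", 0L, ifelse(cs == "recurrence", 1L, 2L))
  cm <- cmprsk::cuminc(t, fs, cencode = 0)
  tp <- cmprsk::timepoints(cm, s$time)
  expect_equal(s$estimate, unname(tp$est["1 1", ]), tolerance = 1e-10)
})

test_that("cause CIFs and event-free survival always sum to one", {
  for (seed in 1:25) {
    d <- random_timelines(seed + 500, n_max = 40,
                          causes = c("recurrence", "death", "second_primary"))
    if (all(d$time_days == 0) || !any(d$cause != "censored")) next
    fit <- aalen_johansen(d)
    wide <- fit$steps |>
      dplyr::select(time, cause, estimate) |>
      tidyr::pivot_wider(names_from = cause, values_from = estimate)
    tot <- rowSums(wide[, -1, drop = FALSE]) + fit$surv$estimate
    expect_true(all(abs(tot - 1) < 1e-10))
    # monotone within [0,1], CI brackets the estimate
    for (k in fit$causes) {
      s <- dplyr::filter(fit$steps, cause == k)
      expect_true(all(diff(s$estimate) >= -1e-12))
      expect_true(all(s$estimate >= 0 & s$estimate <= 1))
      expect_true(all(s$conf_low <= s$estimate + 1e-12 &
                        s$estimate <= s$conf_high + 1e-12))
    }
  }
})

test_that("removing competing causes reduces the CIF to one minus Kaplan-Meier", {
  skip_if_not_installed("survival")
  set.seed(3)
  n <- 80
  t <- sample(1:200, n, TRUE)
  cs <- sample(c("recurrence", "censored"), n, TRUE, c(.6, .4))
  fit <- aalen_johansen(tibble::tibble(time_days = t, cause = cs))
  s <- dplyr::filter(fit$steps, cause == "recurrence")
  km <- survival::survfit(survival::Surv(t, cs == "recurrence") ~ 1)
  expect_equal(s$estimate, 1 - km$surv[match(s$time, km$time)], tolerance = 1e-12)
})

test_that("delayed entry shrinks the early risk sets as hand-computed", {
  d <- tibble::tibble(
    time_days = c(5, 8, 10),
    cause = c("recurrence", "death", "censored"),
    entry_days = c(0, 3, 2)
  )
  fit <- aalen_johansen(d)
  rec <- dplyr::filter(fit$steps, cause == "recurrence")
  dth <- dplyr::filter(fit$steps, cause == "death")
  expect_equal(rec$estimate[rec$time == 5], 1 / 3)
  expect_equal(dth$estimate[dth$time == 8], (2 / 3) * (1 / 2))
  expect_error(
    aalen_johansen(tibble::tibble(
      time_days = 2, cause = "recurrence", entry_days = 3
    )),
    "entry_days"
  )
})

test_that("degenerate inputs are rejected", {
  expect_error(aalen_johansen(tibble::tibble(time_days = numeric(), cause = character())))
  expect_error(
    aalen_johansen(tibble::tibble(time_days = 0, cause = "censored")),
    "time 0"
  )
  expect_error(
    aalen_johansen(tibble::tibble(time_days = 0, cause = "recurrence")),
    "time 0"
  )
})

test_that("crude rates are events per 1000 person-years", {
  expect_equal(crude_rate(10, 5000), 2.0)
  expect_equal(crude_rate(0, 100), 0)
  expect_equal(crude_rate(1522, 63562), 1000 * 1522 / 63562)
  expect_error(crude_rate(5, 0), "person_years")
  expect_equal(person_years(c(365.25, 730.5)), 3)
})

test_that("conditional CIF handles the trivial and undefined cases", {
  fit <- aalen_johansen(hand_example())
  expect_equal(
    conditional_cif(fit, "recurrence", 0, 5),
    cif_at(fit, "recurrence", 5)$estimate
  )
  # no events in the window
  expect_equal(conditional_cif(fit, "death", 3, 3.5), 0)
  # everyone has had an event by day 1460 -> S = 0 past it
  expect_warning(
    out <- conditional_cif(fit, "recurrence", 4.5, 6),
    "undefined"
  )
  expect_true(is.na(out))
})

test_that("stratified estimation is per-group composition with missing levels dropped", {
  d <- dplyr::bind_rows(
    dplyr::mutate(hand_example(), stage = "I"),
    dplyr::mutate(hand_example(), stage = "III"),
    tibble::tibble(time_days = 100, cause = "recurrence", stage = NA)
  )
  expect_message(fits <- stratified_cif(d, "stage"), "missing")
  expect_named(fits, c("I", "III"))
  expect_equal(
    cif_at(fits$I, "recurrence", 5)$estimate,
    cif_at(aalen_johansen(hand_example()), "recurrence", 5)$estimate
  )
  expect_error(stratified_cif(d, "nope"), "nope")
})

test_that("tidy, glance and autoplot expose the fit", {
  fit <- aalen_johansen(hand_example())
  td <- generics::tidy(fit)
  expect_true(all(c("time", "cause", "estimate", "conf_low") %in% names(td)))
  gl <- generics::glance(fit)
  expect_equal(gl$n, 4)
  expect_equal(gl$n_events, 3)
  p <- ggplot2::autoplot(fit)
  expect_s3_class(p, "ggplot")
})
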