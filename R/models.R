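weight_covariates <- c("gender", "age_band", "married", "location",
                       "baseline_cd4", "baseline_weight_kg", "who34",
                       "tb_at_initiation", "side_effect_to_date",
                       "n_regimens", "ever_pi")
cd4_covariates <- c("gender", "age_band", "married", "location",
                    "baseline_cd4", "who34", "tb_at_initiation",
                    "side_effect_to_date", "n_regimens", "ever_pi",
                    "days_to_test")

# cumulative covariates evaluated at each visit ("to date")
cumulative_covariates <- function(cohort) {
  disp <- cohort$dispensings
  if (!"contains_pi" %in% names(disp)) disp$contains_pi <- FALSE
  vis <- cohort$visits
  if (!"side_effect_or_oi_flag" %in% names(vis)) {
    vis$side_effect_or_oi_flag <- FALSE
  }
  if (!"regimen_id" %in% names(vis)) vis$regimen_id <- "reg"
  pi_by_day <- data.table::as.data.table(
    disp[, c("patient_id", "dispense_date", "contains_pi")]
  )[, list(pi_here = any(contains_pi)), by = c("patient_id", "dispense_date")]
  dt <- data.table::as.data.table(
    vis[, c("patient_id", "actual_date", "side_effect_or_oi_flag",
            "regimen_id")]
  )
  dt <- merge(dt, pi_by_day,
              by.x = c("patient_id", "actual_date"),
              by.y = c("patient_id", "dispense_date"), all.x = TRUE)
  data.table::setorderv(dt, c("patient_id", "actual_date"))
  dt[, `:=`(
    side_effect_to_date = cumsum(as.integer(!is.na(side_effect_or_oi_flag) &
                                              side_effect_or_oi_flag)) > 0L,
    n_regimens = cumsum(!duplicated(regimen_id)),
    ever_pi = cumsum(as.integer(!is.na(pi_here) & pi_here)) > 0L
  ), by = "patient_id"]
  tibble::as_tibble(dt[, c("patient_id", "actual_date", "side_effect_to_date",
                           "n_regimens", "ever_pi"), with = FALSE])
}

patient_covariates <- function(cohort) {
  dplyr::mutate(
    cohort$patients,
    who34 = .data$who_stage >= 3L,
    gender = factor(.data$gender, levels = c("female", "male")),
    age_band = factor(.data$age_band, levels = c("<=30", "31-40", ">40")),
    location = factor(.data$location, levels = c("capital", "other_urban",
                                                 "rural"))
  )
}

#' Build the longitudinal weight-change panel
#'
#' One row per (patient, follow-up visit) within the first 270 days after
#' initiation, restricted to visits with a recorded weight. The outcome is
#' weight change from baseline; all indicator values are cumulative "to
#' date" at that visit; covariates include the month index (30-day bins of
#' time since initiation) and the cumulative side-effect, regimen-count and
#' ever-PI flags. Patients without a baseline weight are excluded and
#' counted.
#'
#' @param cohort A [cohort_data()].
#' @param include Optional patient ids (e.g. the screened-in set).
#' @param max_day Panel horizon in days since initiation (default 270).
#' @return Tibble panel; excluded row/patient counts in
#'   `attr(, "exclusions")`.
#' @export
build_weight_panel <- function(cohort, include = NULL, max_day = 270L) {
  snaps <- cohort_snapshots(cohort, at = "visits", max_day = max_day,
                            include = include)
  p <- patient_covariates(cohort)
  no_bw <- p$patient_id[is.na(p$baseline_weight_kg)]
  cum <- cumulative_covariates(cohort)
  init <- setNames(p$initiation_date, p$patient_id)
  cum$asof_day <- days_since(cum$actual_date, init[cum$patient_id])

  panel <- snaps |>
    dplyr::filter(!.data$patient_id %in% no_bw) |>
    dplyr::left_join(cum[, c("patient_id", "asof_day", "side_effect_to_date",
                             "n_regimens", "ever_pi")],
                     by = c("patient_id", "asof_day")) |>
    dplyr::left_join(
      p[, c("patient_id", "gender", "age_band", "married", "location",
            "baseline_cd4", "baseline_weight_kg", "who34",
            "tb_at_initiation")],
      by = "patient_id"
    ) |>
    dplyr::mutate(
      weight_change = .data$weight_kg - .data$baseline_weight_kg,
      month = factor(pmin(ceiling(.data$asof_day / 30), 9L), levels = 1:9)
    )
  n_missing_weight <- sum(is.na(panel$weight_change))
  panel <- dplyr::filter(panel, !is.na(.data$weight_change))
  attr(panel, "exclusions") <- list(
    patients_no_baseline_weight = length(no_bw),
    visits_missing_weight = n_missing_weight
  )
  panel
}

#' Build the CD4-change table
#'
#' One row per patient with a follow-up CD4 test in days 91-270 after
#' initiation; the test closest to day 180 is used (equidistant ties to the
#' earlier test). The outcome is the change from the baseline count, and all
#' indicator values are evaluated as of the test date.
#'
#' @inheritParams build_weight_panel
#' @param window Follow-up test window in days since initiation.
#' @return Tibble with one row per eligible patient.
#' @export
build_cd4_table <- function(cohort, include = NULL, window = c(91L, 270L)) {
  p <- patient_covariates(cohort)
  if (!is.null(include)) p <- p[p$patient_id %in% include, ]
  tests <- cohort$cd4_tests |>
    dplyr::inner_join(p[, c("patient_id", "initiation_date", "baseline_cd4")],
                      by = "patient_id") |>
    dplyr::mutate(day = days_since(.data$test_date, .data$initiation_date)) |>
    dplyr::filter(.data$day >= window[1], .data$day <= window[2]) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::slice(which.min(abs(.data$day - 180L) + 1e-6 * (.data$day > 180L))) |>
    dplyr::ungroup() |>
    dplyr::transmute(.data$patient_id, days_to_test = .data$day,
                     cd4_change = .data$count - .data$baseline_cd4)

  pr <- prep_events(cohort)
  rows <- lapply(seq_len(nrow(tests)), function(j) {
    i <- match(tests$patient_id[j], pr$patients$patient_id)
    v <- pr$visits[[i]]
    d <- pr$disp[[i]]
    indicator_series(v$day, v$sched, v$selfreport_code, d$day, d$supply,
                     tests$days_to_test[j])
  })
  snaps <- if (length(rows)) {
    dplyr::bind_rows(rows)
  } else {
    # 0-row snapshot table with the full column set
    indicator_series(0L, NA_integer_, NA_integer_, 0L, 30L, integer(0))
  }
  snaps$patient_id <- tests$patient_id

  cum <- cumulative_covariates(cohort)
  init <- setNames(p$initiation_date, p$patient_id)
  cum$day <- days_since(cum$actual_date, init[cum$patient_id])
  # cumulative covariates at the last visit on or before the test date
  cum_at <- dplyr::inner_join(cum, tests[, c("patient_id", "days_to_test")],
                              by = "patient_id") |>
    dplyr::filter(.data$day <= .data$days_to_test) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::slice_max(.data$day, n = 1L, with_ties = FALSE) |>
    dplyr::ungroup()

  tests |>
    dplyr::left_join(snaps, by = "patient_id") |>
    dplyr::left_join(cum_at[, c("patient_id", "side_effect_to_date",
                                "n_regimens", "ever_pi")],
                     by = "patient_id") |>
    dplyr::left_join(
      p[, c("patient_id", "selfreport_scale", "gender", "age_band", "married",
            "location", "baseline_cd4", "who34", "tb_at_initiation")],
      by = "patient_id"
    ) |>
    mask_two_level()
}

# indicator term specifications for the validation models
indicator_terms <- function(indicator) {
  switch(indicator,
    coverage_band = list(var = "coverage_band", selfreport = FALSE),
    gap_gt30 = list(var = "gap_gt30", selfreport = FALSE),
    selfreport_avg_cat = list(var = "selfreport_avg_cat", selfreport = TRUE),
    any_imperfect = list(var = "any_imperfect_selfreport", selfreport = TRUE),
    ontime_lt80 = list(var = "ontime_lt80", selfreport = FALSE),
    within3_lt80 = list(var = "within3_lt80", selfreport = FALSE),
    exhaustion_lt80 = list(var = "exhaustion_lt80", selfreport = FALSE),
    abort(paste("unknown indicator:", indicator))
  )
}

#' @rdname fit_weight_model
#' @export
model_indicators <- function() {
  c("coverage_band", "gap_gt30", "selfreport_avg_cat", "any_imperfect",
    "ontime_lt80", "within3_lt80", "exhaustion_lt80")
}

# derive the modeled indicator variable; drops rows where it is undefined
add_indicator <- function(data, indicator) {
  spec <- indicator_terms(indicator)
  out <- switch(indicator,
    coverage_band = dplyr::mutate(data, coverage_band = stats::relevel(
      categorize_coverage(.data$pct_days_covered, "model"), ref = "100%")),
    gap_gt30 = data,
    selfreport_avg_cat = dplyr::mutate(data, selfreport_avg_cat = factor(
      dplyr::case_when(
        is.na(.data$avg_selfreport) ~ NA_character_,
        .data$avg_selfreport == 1 ~ "all perfect",
        .data$avg_selfreport < 2 ~ "better than good, less than perfect",
        TRUE ~ "good or worse"
      ),
      levels = c("all perfect", "better than good, less than perfect",
                 "good or worse")
    )),
    any_imperfect = data,
    ontime_lt80 = dplyr::mutate(
      data, ontime_lt80 = .data$pct_visits_on_or_before < 80),
    within3_lt80 = dplyr::mutate(
      data, within3_lt80 = .data$pct_visits_within_3d < 80),
    exhaustion_lt80 = dplyr::mutate(
      data, exhaustion_lt80 = .data$pct_visits_before_exhaustion < 80)
  )
  if (spec$selfreport) out <- dplyr::filter(out,
                                            .data$selfreport_scale != "two_level")
  dplyr::filter(out, !is.na(.data[[spec$var]]))
}

check_indicator_varies <- function(data, var) {
  v <- data[[var]]
  if (length(unique(v[!is.na(v)])) < 2L) {
    abort(sprintf("indicator `%s` takes a single level in these data", var))
  }
}

#' Fit an adherence-indicator validation model
#'
#' `fit_weight_model()` fits the longitudinal weight-change model: a Gaussian
#' GEE of weight change on one adherence indicator at a time, with patient as
#' cluster, exchangeable working correlation, robust (sandwich) variance, the
#' month index of time since initiation, and the full covariate set (gender,
#' age band, marital status, clinic location, baseline CD4, baseline weight,
#' WHO stage 3-4, TB at initiation, side-effects/OIs to date, number of
#' regimens to date, ever on a protease inhibitor). `fit_cd4_model()` fits
#' the cross-sectional CD4-change model by ordinary least squares with the
#' same covariates (baseline weight replaced by days to the follow-up test).
#' Patients on the 2-level self-report scale are excluded from self-report
#' indicator models.
#'
#' @param panel Panel from [build_weight_panel()].
#' @param indicator One of `model_indicators()`: `"coverage_band"` (model
#'   coverage bands, reference `"100%"`), `"gap_gt30"`,
#'   `"selfreport_avg_cat"` (all perfect / better than good / good or
#'   worse), `"any_imperfect"`, `"ontime_lt80"`, `"within3_lt80"`,
#'   `"exhaustion_lt80"`.
#' @param corstr Working correlation for the GEE.
#' @param time Time coding: `"month"` (30-day bins, default) or
#'   `"linear"` (continuous days).
#' @return An `adherence_model`: indicator-term estimates with 95% Wald
#'   intervals, the underlying fit, and exclusion bookkeeping. Methods:
#'   [tidy()], [glance()], [autoplot()].
#' @export
fit_weight_model <- function(panel, indicator = "coverage_band",
                             corstr = "exchangeable", time = c("month",
                                                               "linear")) {
  time <- match.arg(time)
  spec <- indicator_terms(indicator)
  dat <- add_indicator(panel, indicator)
  dat <- dat[complete.cases(dat[, c(spec$var, weight_covariates,
                                    "weight_change", "month")]), ]
  check_indicator_varies(dat, spec$var)
  time_term <- if (time == "month") "month" else "asof_day"
  fml <- reformulate(c(spec$var, time_term, weight_covariates),
                     response = "weight_change")
  fit <- gee_gauss(fml, data = dat, id = patient_id, corstr = corstr)
  new_adherence_model(fit, kind = "gee_weight", indicator = indicator,
                      var = spec$var,
                      n_patients = dplyr::n_distinct(dat$patient_id),
                      n_obs = nrow(dat),
                      n_patients_input = dplyr::n_distinct(panel$patient_id))
}

#' @rdname fit_weight_model
#' @param cd4_table Table from [build_cd4_table()].
#' @export
fit_cd4_model <- function(cd4_table, indicator = "coverage_band") {
  spec <- indicator_terms(indicator)
  dat <- add_indicator(cd4_table, indicator)
  dat <- dat[complete.cases(dat[, c(spec$var, cd4_covariates,
                                    "cd4_change")]), ]
  check_indicator_varies(dat, spec$var)
  fml <- reformulate(c(spec$var, cd4_covariates), response = "cd4_change")
  fit <- lm(fml, data = dat)
  new_adherence_model(fit, kind = "ols_cd4", indicator = indicator,
                      var = spec$var, n_patients = nrow(dat), n_obs = nrow(dat),
                      n_patients_input = nrow(cd4_table))
}

new_adherence_model <- function(fit, kind, indicator, var, n_patients, n_obs,
                                n_patients_input) {
  est <- if (inherits(fit, "gee_gauss")) tidy(fit) else tidy_lm(fit)
  ind_terms <- dplyr::filter(est, startsWith(.data$term, var))
  structure(
    list(kind = kind, indicator = indicator, indicator_var = var,
         indicator_terms = ind_terms, all_terms = est, fit = fit,
         n_patients = n_patients, n_obs = n_obs,
         n_patients_excluded = n_patients_input - n_patients,
         converged = if (inherits(fit, "gee_gauss")) fit$converged else TRUE),
    class = "adherence_model"
  )
}

# broom-style tidy for lm with Wald 95% intervals (keeps output shape
# identical to the GEE tidier)
tidy_lm <- function(fit, conf.level = 0.95) {
  sm <- summary(fit)$coefficients
  ci <- confint(fit, level = conf.level)
  tibble::tibble(
    term = rownames(sm),
    estimate = sm[, 1L], std.error = sm[, 2L],
    statistic = sm[, 3L], p.value = sm[, 4L],
    conf.low = ci[, 1L], conf.high = ci[, 2L]
  )
}

#' @export
print.adherence_model <- function(x, ...) {
  cat("<adherence_model>", x$kind, "| indicator:", x$indicator, "\n")
  cat("  n =", x$n_patients, "patients,", x$n_obs, "observations (",
      x$n_patients_excluded, "patients excluded )\n")
  print(as.data.frame(x$indicator_terms[, c("term", "estimate", "p.value",
                                            "conf.low", "conf.high")]),
        row.names = FALSE, digits = 3)
  invisible(x)
}

#' @rdname fit_weight_model
#' @param x,object An `adherence_model`.
#' @param ... Unused.
#' @method tidy adherence_model
#' @export
tidy.adherence_model <- function(x, ...) x$all_terms

#' @rdname fit_weight_model
#' @method glance adherence_model
#' @export
glance.adherence_model <- function(x, ...) {
  tibble::tibble(kind = x$kind, indicator = x$indicator,
                 n_patients = x$n_patients, n_obs = x$n_obs,
                 n_patients_excluded = x$n_patients_excluded,
                 converged = x$converged)
}

#' @method autoplot adherence_model
#' @export
autoplot.adherence_model <- function(object, ...) {
  df <- object$indicator_terms
  ggplot2::ggplot(df, ggplot2::aes(.data$estimate, .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::labs(
      x = if (object$kind == "gee_weight") "weight change (kg)" else
        "CD4 change (cells/mm3)",
      y = NULL,
      title = paste("Indicator:", object$indicator)
    ) +
    ggplot2::theme_minimal()
}

#' Adjusted predictions from a fitted validation model
#'
#' Two modes: `"typical"` predicts the outcome change for a fixed covariate
#' profile (a typical patient); `"population"` averages per-row predictions
#' over the observed covariate distribution of the model data
#' (population-averaged standardization). In both modes the indicator is set
#' to each of its levels in turn, so the result traces the adjusted
#' outcome-by-adherence curve.
#'
#' @param model An `adherence_model`.
#' @param profile Named list of covariate values for `"typical"` mode; must
#'   cover every model covariate (an informative error names any missing
#'   one). Ignored in `"population"` mode.
#' @param horizon_day Day since initiation at which to predict (sets the
#'   month bin for weight models; ignored for CD4 models, which carry
#'   `days_to_test` in the profile/population).
#' @param mode `"typical"` or `"population"`.
#' @param conf.level Confidence level.
#' @return Tibble: one row per indicator level with `estimate`, `conf.low`,
#'   `conf.high`.
#' @export
adjusted_prediction <- function(model, profile = NULL, horizon_day = 270L,
                                mode = c("typical", "population"),
                                conf.level = 0.95) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "adherence_model"))
  fit <- model$fit
  tt <- delete.response(terms(fit))
  mf <- model.frame(fit)
  var <- model$indicator_var
  levels_of <- function(v) {
    x <- mf[[v]]
    if (is.factor(x)) levels(x) else sort(unique(x))
  }
  ind_levels <- levels_of(var)
  needed <- setdiff(all.vars(tt), var)

  beta <- coef(fit)
  V <- if (inherits(fit, "gee_gauss")) fit$vcov_robust else vcov(fit)
  zq <- qnorm(1 - (1 - conf.level) / 2)

  rows <- lapply(ind_levels, function(lv) {
    if (mode == "typical") {
      miss <- setdiff(needed, c(names(profile), "month"))
      if (length(miss)) {
        abort(paste("profile is missing covariate(s):",
                    paste(miss, collapse = ", ")))
      }
      nd <- as.data.frame(profile, stringsAsFactors = FALSE)
      if ("month" %in% needed && is.null(profile$month)) {
        nd$month <- pmin(ceiling(horizon_day / 30), 9)
      }
      nd[[var]] <- lv
      for (v in names(mf)) {
        if (v %in% names(nd) && is.factor(mf[[v]])) {
          nd[[v]] <- factor(nd[[v]], levels = levels(mf[[v]]))
        }
      }
      X <- model.matrix(tt, model.frame(tt, nd))
      xbar <- colMeans(X)
    } else {
      nd <- mf
      if ("month" %in% names(nd)) {
        nd$month <- factor(pmin(ceiling(horizon_day / 30), 9),
                           levels = levels(mf$month))
      }
      nd[[var]] <- if (is.factor(mf[[var]])) {
        factor(lv, levels = levels(mf[[var]]))
      } else {
        lv
      }
      X <- model.matrix(tt, nd)
      xbar <- colMeans(X)
    }
    est <- sum(xbar * beta)
    se <- sqrt(drop(t(xbar) %*% V %*% xbar))
    tibble::tibble(level = as.character(lv), estimate = est,
                   conf.low = est - zq * se, conf.high = est + zq * se)
  })
  dplyr::bind_rows(rows)
}
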