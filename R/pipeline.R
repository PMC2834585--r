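#' Cohort characteristics table
#'
#' Frequency distribution of the demographic and clinical intake variables,
#' for the full cohort and (optionally) for the subgroup with a follow-up CD4
#' test, mirroring a baseline-characteristics table. Percentages to 1
#' decimal; baseline weight reported as gender-specific mean (SD).
#'
#' @param cohort A [cohort_data()].
#' @param include Optional patient ids defining the analysis cohort.
#' @param subgroup_ids Optional ids of the CD4-test subgroup.
#' @return Long tibble: `variable`, `level`, `overall`, `subgroup`.
#' @export
summarize_characteristics <- function(cohort, include = NULL,
                                      subgroup_ids = NULL) {
  p <- cohort$patients
  if (!is.null(include)) p <- p[p$patient_id %in% include, ]
  ps <- if (is.null(subgroup_ids)) p[0, ] else
    p[p$patient_id %in% subgroup_ids, ]

  cat_vars <- c("gender", "age_band", "education", "married", "living",
                "occupation", "facility_management", "location", "who_stage",
                "support_partner", "tb_at_initiation")
  pct_tab <- function(df, v) {
    x <- df[[v]]
    if (is.logical(x)) x <- ifelse(x, "yes", "no")
    tab <- table(factor(x))
    tibble::tibble(variable = v, level = names(tab),
                   value = round(100 * as.numeric(tab) / max(nrow(df), 1L), 1))
  }
  block <- function(df) {
    rows <- dplyr::bind_rows(lapply(cat_vars, function(v) pct_tab(df, v)))
    pm <- df[df$gender == "male", "baseline_weight_kg", drop = TRUE]
    pf <- df[df$gender == "female", "baseline_weight_kg", drop = TRUE]
    pmt <- df[df$gender == "female", "pmtct_history", drop = TRUE]
    dplyr::bind_rows(
      tibble::tibble(variable = "n", level = "patients", value = nrow(df)),
      rows,
      tibble::tibble(
        variable = "pmtct_history_female",
        level = "yes",
        value = round(100 * mean(pmt, na.rm = TRUE), 1)
      ),
      tibble::tibble(
        variable = rep(c("baseline_weight_male", "baseline_weight_female"),
                       each = 2L),
        level = rep(c("mean", "sd"), 2L),
        value = round(c(mean(pm, na.rm = TRUE), sd(pm, na.rm = TRUE),
                        mean(pf, na.rm = TRUE), sd(pf, na.rm = TRUE)), 1)
      )
    )
  }
  overall <- dplyr::rename(block(p), overall = "value")
  if (nrow(ps)) {
    sub <- dplyr::rename(block(ps), subgroup = "value")
    dplyr::full_join(overall, sub, by = c("variable", "level"))
  } else {
    dplyr::mutate(overall, subgroup = NA_real_)
  }
}

#' Indicator distributions at the index visit
#'
#' Banded frequency distributions and means/SDs of the adherence, attendance
#' and outcome measures at the index visit, for the full cohort and the
#' CD4-test subgroup. Coverage uses the report bands (`<80%`, `80% to <85%`,
#' ..., `100%`), the attendance percentages use `<80%`, `80% to <90%`,
#' `90% to 100%`. Band frequencies are percentages rounded to 1 decimal and
#' sum to 100 per measure (up to rounding).
#'
#' @param snapshots Index-visit snapshots from [cohort_snapshots()].
#' @param cd4_table Optional table from [build_cd4_table()]; defines the
#'   subgroup column and contributes the CD4-change summary.
#' @return Long tibble: `section`, `measure`, `statistic`, `overall`,
#'   `subgroup`.
#' @export
summarize_indicators <- function(snapshots, cd4_table = NULL) {
  sub_ids <- if (is.null(cd4_table)) character() else cd4_table$patient_id
  atten_bands <- function(x) {
    cut(x, breaks = c(-Inf, 80, 90, Inf),
        labels = c("<80%", "80% to <90%", "90% to 100%"), right = FALSE)
  }
  one <- function(df, cd4t) {
    band_rows <- function(section, measure, f) {
      tab <- table(f)
      tibble::tibble(section = section, measure = measure,
                     statistic = names(tab),
                     value = round(100 * as.numeric(tab) / sum(tab), 1))
    }
    stat_rows <- function(section, measure, x) {
      tibble::tibble(section = section, measure = measure,
                     statistic = c("mean", "sd"),
                     value = round(c(mean(x, na.rm = TRUE),
                                     sd(x, na.rm = TRUE)), 1))
    }
    sr <- df[df$selfreport_scale == "three_level", ]
    dplyr::bind_rows(
      tibble::tibble(section = "window", measure = "days_since_initiation",
                     statistic = c("mean", "min", "max"),
                     value = c(round(mean(df$asof_day), 0), min(df$asof_day),
                               max(df$asof_day))),
      band_rows("dispensing", "pct_days_covered",
                categorize_coverage(df$pct_days_covered, "table2")),
      tibble::tibble(section = "dispensing", measure = "gap_gt30",
                     statistic = "pct_true",
                     value = round(100 * mean(df$gap_gt30), 1)),
      stat_rows("selfreport", "n_selfreports", sr$n_selfreports),
      stat_rows("selfreport", "avg_selfreport", sr$avg_selfreport),
      tibble::tibble(section = "selfreport", measure = "all_perfect",
                     statistic = "pct_true",
                     value = round(100 * mean(!sr$any_imperfect_selfreport,
                                              na.rm = TRUE), 1)),
      tibble::tibble(section = "selfreport", measure = "any_poor",
                     statistic = "pct_true",
                     value = round(100 * mean(sr$any_poor_selfreport,
                                              na.rm = TRUE), 1)),
      stat_rows("attendance", "n_visits", df$n_visits),
      band_rows("attendance", "pct_visits_on_or_before",
                atten_bands(df$pct_visits_on_or_before)),
      band_rows("attendance", "pct_visits_within_3d",
                atten_bands(df$pct_visits_within_3d)),
      band_rows("attendance", "pct_visits_before_exhaustion",
                atten_bands(df$pct_visits_before_exhaustion)),
      if ("weight_change" %in% names(df)) {
        stat_rows("outcome", "weight_gain_kg", df$weight_change)
      },
      if (!is.null(cd4t) && nrow(cd4t)) {
        stat_rows("outcome", "cd4_change", cd4t$cd4_change)
      }
    )
  }
  overall <- dplyr::rename(one(snapshots, NULL), overall = "value")
  if (length(sub_ids)) {
    subgroup <- one(snapshots[snapshots$patient_id %in% sub_ids, ], cd4_table)
    subgroup <- dplyr::rename(subgroup, subgroup = "value")
    dplyr::full_join(overall, subgroup,
                     by = c("section", "measure", "statistic"))
  } else {
    dplyr::mutate(overall, subgroup = NA_real_)
  }
}

#' Run the full adherence-measurement pipeline
#'
#' Orchestrates generate/read, eligibility screening, index-visit snapshots,
#' the indicator correlation matrix, and both validation model families, and
#' writes the report bundle: `table1.csv` (cohort characteristics),
#' `table2.csv` (indicator distributions at the index visit), `table3.csv`
#' (correlation matrix), `table4.csv` / `table5.csv` (weight and CD4 model
#' estimates; coefficients to 3 decimals), `rejects.csv` (malformed input
#' rows, if any) and `manifest.json` (seed, config hash, row counts per
#' stage, warnings). The run is deterministic: fixed seed and config give a
#' byte-identical bundle. Stage row counts are logged to stderr and itemized
#' in the manifest, so patients are never silently created or lost.
#'
#' @param config A [cohort_config()] for synthetic input, or `NULL` when
#'   `cohort_dir` is given.
#' @param cohort_dir Directory of event-log files to read instead of
#'   generating.
#' @param seed Seed for synthetic generation.
#' @param out_dir Output directory for the report bundle.
#' @param indicators Indicators to model (default all of
#'   [model_indicators()]).
#' @param quiet Suppress stage logging.
#' @return Invisibly, a list with the tables, fitted models, manifest and
#'   output paths.
#' @export
run_pipeline <- function(config = NULL, cohort_dir = NULL, seed = 1L,
                         out_dir, indicators = model_indicators(),
                         quiet = FALSE) {
  log_ <- function(...) if (!quiet) message("[adherr] ", sprintf(...))
  if (is.null(config) && is.null(cohort_dir)) {
    abort("give either a synthetic `config` or a `cohort_dir` to read")
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  manifest <- list(seed = as.integer(seed), stages = list(), warnings = list())

  ## stage: input
  if (!is.null(config)) {
    gen <- generate_cohort(config, seed = seed)
    cohort <- gen$cohort
    manifest$config_hash <- rlang::hash(config)
    manifest$input <- "synthetic"
  } else {
    cohort <- read_cohort(cohort_dir)
    manifest$input <- "files"
    manifest$config_hash <- NA
  }
  rej <- cohort_rejects(cohort)
  manifest$stages$input <- list(
    patients = nrow(cohort$patients), visits = nrow(cohort$visits),
    dispensing_rows = nrow(cohort$dispensings),
    cd4_tests = nrow(cohort$cd4_tests), rejected_rows = nrow(rej)
  )
  log_("input: %d patients, %d visits (%d rejected rows)",
       nrow(cohort$patients), nrow(cohort$visits), nrow(rej))
  if (nrow(cohort$patients) == 0L) {
    abort("pipeline aborted at screening stage: empty cohort")
  }

  ## stage: eligibility screen
  elig <- screen_eligibility(cohort)
  manifest$stages$screen <- list(
    screened = elig$n_screened, included = length(elig$included),
    excluded = nrow(elig$excluded),
    by_criterion = as.list(setNames(elig$fractions$n_failed,
                                    elig$fractions$criterion))
  )
  log_("screen: %d of %d patients eligible", length(elig$included),
       elig$n_screened)
  if (!length(elig$included)) {
    abort("pipeline aborted at screening stage: no eligible patients")
  }

  ## stage: snapshots at the index visit
  snaps <- cohort_snapshots(cohort, at = "index", include = elig$included)
  weight_at_index <- dplyr::left_join(
    snaps,
    cohort$patients[, c("patient_id", "baseline_weight_kg")],
    by = "patient_id"
  )
  snaps$weight_change <- weight_at_index$weight_kg -
    weight_at_index$baseline_weight_kg
  manifest$stages$snapshots <- list(index_snapshots = nrow(snaps))
  log_("snapshots: %d index-visit snapshots", nrow(snaps))

  ## stage: tables 1-3
  cd4_tab <- build_cd4_table(cohort, include = elig$included)
  table1 <- summarize_characteristics(cohort, include = elig$included,
                                      subgroup_ids = cd4_tab$patient_id)
  table2 <- summarize_indicators(snaps, cd4_table = cd4_tab)
  cmat <- correlation_matrix(snaps)
  table3 <- dplyr::mutate(cmat,
                          estimate = round(.data$estimate, 3),
                          p_value = signif(.data$p_value, 3))
  manifest$stages$cd4_table <- list(patients_with_window_test = nrow(cd4_tab))

  ## stage: validation models
  panel <- build_weight_panel(cohort, include = elig$included)
  manifest$stages$weight_panel <- c(
    list(rows = nrow(panel),
         patients = dplyr::n_distinct(panel$patient_id)),
    attr(panel, "exclusions")
  )
  log_("panel: %d weight observations from %d patients", nrow(panel),
       dplyr::n_distinct(panel$patient_id))

  fit_safely <- function(fun, dat, ind) {
    tryCatch(fun(dat, indicator = ind), error = function(e) {
      manifest$warnings[[length(manifest$warnings) + 1L]] <<-
        sprintf("%s/%s: %s", deparse(substitute(fun)), ind,
                conditionMessage(e))
      NULL
    })
  }
  weight_models <- lapply(indicators, function(ind)
    fit_safely(fit_weight_model, panel, ind))
  cd4_models <- lapply(indicators, function(ind)
    fit_safely(fit_cd4_model, cd4_tab, ind))
  names(weight_models) <- names(cd4_models) <- indicators

  model_table <- function(models) {
    dplyr::bind_rows(lapply(Filter(Negate(is.null), models), function(m) {
      dplyr::mutate(m$indicator_terms,
                    indicator = m$indicator, n_patients = m$n_patients,
                    n_obs = m$n_obs, .before = 1L) |>
        dplyr::mutate(dplyr::across(c("estimate", "std.error", "conf.low",
                                      "conf.high"), ~ round(.x, 3)),
                      p.value = signif(.data$p.value, 3),
                      statistic = round(.data$statistic, 3))
    }))
  }
  table4 <- model_table(weight_models)
  table5 <- model_table(cd4_models)
  log_("models: %d weight, %d CD4 fits",
       sum(!vapply(weight_models, is.null, logical(1))),
       sum(!vapply(cd4_models, is.null, logical(1))))

  ## write bundle
  paths <- c(table1 = "table1.csv", table2 = "table2.csv",
             table3 = "table3.csv", table4 = "table4.csv",
             table5 = "table5.csv", rejects = "rejects.csv",
             manifest = "manifest.json")
  paths <- setNames(file.path(out_dir, paths), names(paths))
  readr::write_csv(table1, paths[["table1"]], na = "", progress = FALSE)
  readr::write_csv(table2, paths[["table2"]], na = "", progress = FALSE)
  readr::write_csv(table3, paths[["table3"]], na = "", progress = FALSE)
  readr::write_csv(table4, paths[["table4"]], na = "", progress = FALSE)
  readr::write_csv(table5, paths[["table5"]], na = "", progress = FALSE)
  readr::write_csv(rej, paths[["rejects"]], na = "", progress = FALSE)
  manifest$package_version <- as.character(utils::packageVersion("adherr"))
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  invisible(list(
    cohort = cohort, eligibility = elig, snapshots = snaps,
    cd4_table = cd4_tab, weight_panel = panel,
    tables = list(table1 = table1, table2 = table2, table3 = table3,
                  table4 = table4, table5 = table5),
    weight_models = weight_models, cd4_models = cd4_models,
    manifest = manifest, paths = paths
  ))
}
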