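# compact builders for hand-made cohorts used across the unit tests

ORIGIN <- as.Date("2007-03-01")

fixture_patient <- function(patient_id = "P1", age_years = 30,
                            gender = "female", init = ORIGIN,
                            prior_art = FALSE, scale = "three_level",
                            baseline_weight = 55, baseline_cd4 = 150,
                            cd4_day = -30, followup_days = 540) {
  tibble::tibble(
    patient_id = patient_id, gender = gender, age_years = age_years,
    age_band = dplyr::case_when(age_years <= 30 ~ "<=30",
                                age_years <= 40 ~ "31-40", TRUE ~ ">40"),
    married = TRUE, education = "primary", occupation = "employed",
    living = "with_adult", support_partner = TRUE, facility_id = 5L,
    facility_management = "government", location = "capital", who_stage = 2L,
    tb_at_initiation = FALSE, pmtct_history = FALSE,
    prior_art_exposure = prior_art, initiation_date = init,
    baseline_weight_kg = baseline_weight, baseline_cd4 = baseline_cd4,
    baseline_cd4_date = init + cd4_day,
    data_collection_date = init + followup_days,
    selfreport_scale = scale
  )
}

# visits given as day offsets; sched/code/weight vectors recycled or NA
fixture_visits <- function(patient_id, days, sched = days, code = 1L,
                           weight = 55, init = ORIGIN) {
  n <- length(days)
  tibble::tibble(
    patient_id = patient_id,
    actual_date = init + days,
    scheduled_date = if (all(is.na(sched))) as.Date(NA) else init + sched,
    weight_kg = rep_len(weight, n),
    selfreport_code = rep_len(code, n),
    regimen_id = "reg1",
    side_effect_or_oi_flag = FALSE
  )
}

fixture_dispensings <- function(patient_id, days, supply = 30L, init = ORIGIN) {
  tibble::tibble(
    patient_id = patient_id,
    dispense_date = init + days,
    drug_code = "d1",
    days_of_supply = rep_len(supply, length(days)),
    regimen_id = "reg1",
    contains_pi = FALSE
  )
}

fixture_cd4 <- function(patient_id, days, counts, init = ORIGIN) {
  tibble::tibble(patient_id = patient_id, test_date = init + days,
                 count = counts)
}

# one fully adherent patient with monthly visits through `months` months
fixture_cohort <- function(months = 7, patient = fixture_patient()) {
  days <- seq(0, months * 30, by = 30)
  cohort_data(
    patient,
    fixture_visits(patient$patient_id, days),
    fixture_dispensings(patient$patient_id, days),
    fixture_cd4(patient$patient_id, c(-30, 180), c(150, 290))
  )
}

empty_cohort <- function() {
  p <- fixture_patient()[0, ]
  cohort_data(p, fixture_visits("x", numeric(0))[0, ],
              fixture_dispensings("x", numeric(0))[0, ],
              fixture_cd4("x", numeric(0), integer(0))[0, ])
}

# timeline from raw day/supply vectors
tl_from <- function(disp_day, supply, t) {
  d <- fixture_dispensings("P1", disp_day)
  d$days_of_supply <- as.integer(supply)
  build_coverage_timeline(d, ORIGIN, ORIGIN + t)
}
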