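#' Metastatic dissemination tally per cohort and site
#'
#' Counts, per arm and metastatic site, the patients with at least one
#' recorded metastasis at that site (a patient with several sites contributes
#' to each once), the fraction of the arm's metastatic patients involved, and
#' a per-site one-sided Fisher enrichment in the High arm over all arm
#' patients, Benjamini-Hochberg corrected across sites.
#'
#' @param clinical Clinical table with metastasis records.
#' @param assignment Cohort assignment (clinical `patient` IDs are matched to
#'   assignment `sample` IDs).
#' @param sites Optional site vocabulary; defaults to all observed sites.
#' @return List with `table` (cohort x site counts and fractions) and `tests`
#'   (per-site enrichment).
#' @export
tally_dissemination <- function(clinical, assignment, sites = NULL) {
  clinical <- validate_clinical(clinical)
  arms <- filter(assignment, .data$cohort %in% c("High", "Low"))
  ev <- metastasis_events(clinical) |>
    inner_join(select(arms, patient = "sample", "cohort"), by = "patient")
  if (is.null(sites)) sites <- sort(unique(ev$site))
  arm_patients <- clinical |>
    inner_join(select(arms, patient = "sample", "cohort"), by = "patient")
  n_arm <- arm_patients |> count(.data$cohort, name = "n_patients")
  n_met <- arm_patients |>
    mutate(met = purrr::map_int(.data$mets, nrow) > 0) |>
    group_by(.data$cohort) |>
    summarise(n_metastatic = sum(.data$met), .groups = "drop")
  tab <- ev |>
    filter(.data$site %in% sites) |>
    distinct(.data$patient, .data$site, .data$cohort) |>
    count(.data$cohort, .data$site) |>
    tidyr::complete(cohort = c("High", "Low"), site = sites,
                    fill = list(n = 0L)) |>
    left_join(n_met, by = "cohort") |>
    left_join(n_arm, by = "cohort") |>
    mutate(
      cohort = as.character(.data$cohort),
      fraction_of_metastatic = ifelse(.data$n_metastatic > 0,
                                      .data$n / .data$n_metastatic, 0)
    )
  traits <- purrr::map_dfr(sites, function(s) {
    pats <- unique(ev$patient[ev$site == s])
    tibble(sample = arm_patients$patient, trait = s,
           present = arm_patients$patient %in% pats)
  })
  tests <- cohort_enrichment(traits, arms) |>
    rename(site = "trait")
  list(table = tab, tests = tests)
}

#' Compare time to first metastasis between cohorts
#'
#' Two-sample two-sided Wilcoxon rank-sum test on the time from diagnosis to
#' the first metastatic event, restricted to metastatic patients. Requires at
#' least 3 metastatic patients per arm.
#'
#' @param clinical Clinical table.
#' @param assignment Cohort assignment.
#' @return One-row tibble: `test`, `statistic`, `p_value`, per-arm n and
#'   median times (days).
#' @export
compare_time_to_met <- function(clinical, assignment) {
  clinical <- validate_clinical(clinical)
  arms <- filter(assignment, .data$cohort %in% c("High", "Low"))
  ev <- metastasis_events(clinical)
  if (nrow(ev) == 0) abort("compare_time_to_met: need >= 3 metastatic patients per arm")
  first_met <- ev |>
    group_by(.data$patient) |>
    summarise(time = min(.data$time), .groups = "drop") |>
    inner_join(select(arms, patient = "sample", "cohort"), by = "patient")
  hv <- first_met$time[first_met$cohort == "High"]
  lv <- first_met$time[first_met$cohort == "Low"]
  if (length(hv) < 3 || length(lv) < 3) {
    abort("compare_time_to_met: need >= 3 metastatic patients per arm")
  }
  wt <- suppressWarnings(wilcox.test(hv, lv, alternative = "two.sided"))
  tibble(
    test = "Wilcoxon rank-sum", sidedness = "two-sided",
    statistic = unname(wt$statistic), p_value = wt$p.value,
    n_high = length(hv), n_low = length(lv),
    median_high = median(hv), median_low = median(lv)
  )
}

#' Brain metastasis risk as a combined probability
#'
#' Risk percent = P(metastasis) x P(brain | metastasis) x 100, which
#' simplifies algebraically to `100 * n_brain / n_total`. Both factor
#' probabilities are reported alongside the risk.
#'
#' @param n_total Patients in the cohort.
#' @param n_metastatic Patients who developed any metastasis.
#' @param n_brain Patients with brain metastases.
#' @return One-row tibble: counts, `p_met`, `p_brain_given_met`, `risk_pct`.
#' @export
brain_met_risk <- function(n_total, n_metastatic, n_brain) {
  if (n_total <= 0) abort("brain_met_risk: n_total must be > 0")
  if (n_metastatic > n_total || n_brain > n_metastatic || n_brain < 0) {
    abort("brain_met_risk: need n_brain <= n_metastatic <= n_total")
  }
  if (n_metastatic == 0) {
    return(tibble(n_total = n_total, n_metastatic = 0L, n_brain = 0L,
                  p_met = 0, p_brain_given_met = NA_real_, risk_pct = 0))
  }
  p_met <- n_metastatic / n_total
  p_brain <- n_brain / n_metastatic
  tibble(
    n_total = n_total, n_metastatic = n_metastatic, n_brain = n_brain,
    p_met = p_met, p_brain_given_met = p_brain,
    risk_pct = 100 * p_met * p_brain
  )
}

#' Brain metastasis risk per cohort from clinical records
#'
#' @param clinical Clinical table.
#' @param assignment Cohort assignment.
#' @param brain_site Site label identifying brain metastases.
#' @return Tibble with one [brain_met_risk()] row per arm, plus `cohort`.
#' @export
brain_met_risk_by_cohort <- function(clinical, assignment, brain_site = "brain") {
  clinical <- validate_clinical(clinical)
  arms <- filter(assignment, .data$cohort %in% c("High", "Low"))
  x <- clinical |>
    inner_join(select(arms, patient = "sample", "cohort"), by = "patient") |>
    mutate(
      met = purrr::map_int(.data$mets, nrow) > 0,
      brain = purrr::map_lgl(.data$mets, ~ brain_site %in% .x$site)
    )
  purrr::map_dfr(c("High", "Low"), function(a) {
    sub <- filter(x, .data$cohort == a)
    bind_cols(tibble(cohort = a),
              brain_met_risk(nrow(sub), sum(sub$met), sum(sub$brain)))
  })
}

#' Per-patient metastasis timeline export
#'
#' Swimmer-plot-ready long table: one row per patient per metastatic event,
#' with follow-up time for context.
#'
#' @param clinical Clinical table.
#' @param assignment Cohort assignment.
#' @return Tibble: `patient`, `cohort`, `site`, `time`, `os_time`, `os_event`.
#' @export
met_timelines <- function(clinical, assignment) {
  clinical <- validate_clinical(clinical)
  metastasis_events(clinical) |>
    inner_join(select(assignment, patient = "sample", "cohort"), by = "patient") |>
    left_join(select(clinical, "patient", "os_time", "os_event"), by = "patient") |>
    arrange(.data$cohort, .data$patient, .data$time)
}
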