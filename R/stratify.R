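#' Quartile stratification by a marker gene's expression
#'
#' Ranks samples by the log2 expression of one gene (MYBL2 by default) and
#' labels the top quarter `High`, the bottom quarter `Low`, and the remainder
#' `Mid`. Each extreme arm holds exactly `floor(n/4)` samples. Ties are broken
#' deterministically: samples are ordered by (expression, sample ID), so at a
#' tied quartile boundary the lexicographically later sample ID lands in the
#' higher arm.
#'
#' @param expr Expression table (`gene` column + one numeric column per sample).
#' @param gene Marker gene symbol.
#' @return Tibble with columns `sample`, `cohort` (factor High/Mid/Low) and
#'   `expression` (the marker's value), one row per sample.
#' @export
stratify_quartiles <- function(expr, gene = "MYBL2") {
  expr <- validate_expression(expr)
  row <- which(expr$gene == gene)
  if (length(row) == 0) abort(paste0("gene '", gene, "' not found in expression table"))
  samples <- setdiff(names(expr), "gene")
  n <- length(samples)
  if (n < 8) abort("need at least 8 samples for quartile stratification")
  values <- as.numeric(unlist(expr[row, samples]))
  if (length(unique(values)) == 1) {
    abort("degenerate ranking: all samples have identical expression")
  }
  q <- floor(n / 4)
  ord <- order(values, samples) # ascending, sample-ID tie-break
  cohort <- rep("Mid", n)
  cohort[ord[seq_len(q)]] <- "Low"
  cohort[ord[seq(n - q + 1, n)]] <- "High"
  tibble(
    sample = samples,
    cohort = factor(cohort, levels = c("High", "Mid", "Low")),
    expression = values
  )
}

#' Kaplan-Meier product-limit estimate
#'
#' Fits the product-limit estimator to right-censored times. Subjects without
#' an event are censored at their recorded time (time of last contact).
#'
#' @param data Data frame of one row per subject.
#' @param time,event Column names (strings) holding time in days (>= 0) and the
#'   event flag (1 = event, 0 = censored).
#' @return Object of class `rin_km`; use [tidy()][generics::tidy] for the
#'   step-curve table, [glance()][generics::glance] for the fit summary, and
#'   [autoplot()][ggplot2::autoplot] for a step plot.
#' @export
km_estimate <- function(data, time = "time", event = "event") {
  stopifnot(is.data.frame(data))
  t <- data[[time]]
  e <- data[[event]]
  if (is.null(t) || is.null(e)) abort("time/event columns not found")
  keep <- !is.na(t) & !is.na(e)
  dropped <- sum(!keep)
  if (dropped > 0) inform(paste0("km_estimate: dropped ", dropped, " subjects with missing time/event"))
  t <- t[keep]; e <- e[keep]
  if (length(t) == 0) abort("no subjects with complete time/event data")
  if (any(t < 0)) abort("negative survival time")
  if (any(!e %in% c(0, 1))) abort("event flags must be 0 or 1")
  fit <- survival::survfit(survival::Surv(t, e) ~ 1, conf.type = "none")
  curve <- tibble(
    time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
    n_censor = fit$n.censor, survival = fit$surv
  )
  structure(
    list(curve = curve, n = length(t), events = sum(e),
         median = unname(summary(fit)$table["median"]), dropped = dropped),
    class = "rin_km"
  )
}

#' @export
print.rin_km <- function(x, ...) {
  cat("Kaplan-Meier estimate: ", x$n, " subjects, ", x$events, " events; median ",
      ifelse(is.na(x$median), "not reached", paste0(x$median, " days")), "\n", sep = "")
  print(x$curve, n = 6)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @exportS3Method generics::tidy
tidy.rin_km <- function(x, ...) x$curve

#' @exportS3Method generics::glance
glance.rin_km <- function(x, ...) {
  tibble(n = x$n, events = x$events, median_survival = x$median,
         dropped = x$dropped)
}

#' Two-sided log-rank test between two survival arms
#'
#' @param data Data frame of one row per subject.
#' @param time,event As in [km_estimate()].
#' @param group Column name holding the two-arm label.
#' @return One-row tibble: `test`, `statistic` (chi-square, 1 df), `p_value`,
#'   and per-arm subject/event counts.
#' @export
logrank_test <- function(data, time = "time", event = "event", group = "group") {
  stopifnot(is.data.frame(data))
  t <- data[[time]]; e <- data[[event]]; g <- as.character(data[[group]])
  keep <- !is.na(t) & !is.na(e) & !is.na(g)
  if (sum(!keep) > 0) {
    inform(paste0("logrank_test: dropped ", sum(!keep), " subjects with missing data"))
  }
  t <- t[keep]; e <- e[keep]; g <- g[keep]
  arms <- sort(unique(g))
  if (length(arms) != 2) abort("logrank_test: exactly two groups required")
  if (any(t < 0)) abort("negative survival time")
  if (sum(e) < 1) abort("logrank_test: no events in either arm")
  sd <- survival::survdiff(survival::Surv(t, e) ~ g)
  p <- stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
  tibble(
    test = "log-rank", sidedness = "two-sided",
    statistic = unname(sd$chisq), p_value = p,
    n_a = unname(sd$n[1]), n_b = unname(sd$n[2]),
    events_a = unname(sd$obs[1]), events_b = unname(sd$obs[2])
  )
}

#' Restrict a clinical table to one treatment class
#'
#' Stratification is intended to be re-run within the returned subset, so
#' treatment-specific cohorts are formed from treatment-specific quartiles.
#'
#' @param clinical Clinical table.
#' @param treatment Treatment label to keep.
#' @return The restricted clinical table.
#' @export
treatment_subset <- function(clinical, treatment) {
  clinical <- validate_clinical(clinical)
  out <- filter(clinical, .data$treatment == !!treatment)
  if (nrow(out) == 0) {
    abort(paste0("no patients with treatment '", treatment, "'"))
  }
  out
}

#' One-sided Fisher enrichment of binary traits in the High arm
#'
#' For each trait, builds the 2x2 table of cohort (High/Low) against trait
#' presence and tests for enrichment in the High arm with a one-sided Fisher
#' exact test; Benjamini-Hochberg correction is applied across the supplied
#' trait family. Mid-arm samples are ignored. A trait with an empty margin
#' (absent everywhere, or present everywhere) is reported with `p = 1` and
#' flagged `degenerate`.
#'
#' @param traits Tibble with columns `sample`, `trait`, `present` (logical);
#'   one row per sample x trait. Every High/Low sample must appear for each
#'   trait.
#' @param assignment Cohort assignment from [stratify_quartiles()].
#' @return Tibble per trait: 2x2 counts, `odds_ratio`, `p_value`, `q_value`,
#'   `degenerate`.
#' @export
cohort_enrichment <- function(traits, assignment) {
  stopifnot(is.data.frame(traits), is.data.frame(assignment))
  need <- c("sample", "trait", "present")
  missing <- setdiff(need, names(traits))
  if (length(missing) > 0) {
    abort(paste0("traits: missing column(s): ", paste(missing, collapse = ", ")))
  }
  arms <- filter(assignment, .data$cohort %in% c("High", "Low"))
  x <- inner_join(traits, select(arms, "sample", "cohort"), by = "sample")
  miss <- anti_join_count(traits, arms)
  out <- x |>
    group_by(.data$trait) |>
    summarise(
      high_pos = sum(.data$cohort == "High" & .data$present),
      high_neg = sum(.data$cohort == "High" & !.data$present),
      low_pos = sum(.data$cohort == "Low" & .data$present),
      low_neg = sum(.data$cohort == "Low" & !.data$present),
      .groups = "drop"
    )
  res <- purrr::pmap(out, function(trait, high_pos, high_neg, low_pos, low_neg) {
    m <- matrix(c(high_pos, high_neg, low_pos, low_neg), nrow = 2)
    degenerate <- (high_pos + low_pos == 0) || (high_neg + low_neg == 0)
    if (degenerate) {
      tibble(odds_ratio = NA_real_, p_value = 1, degenerate = TRUE)
    } else {
      ft <- fisher.test(m, alternative = "greater")
      tibble(odds_ratio = unname(ft$estimate), p_value = ft$p.value,
             degenerate = FALSE)
    }
  })
  out <- bind_cols(out, bind_rows(res))
  out$q_value <- p.adjust(out$p_value, method = "BH")
  out
}

# number of trait samples not present among High/Low arms (internal)
anti_join_count <- function(traits, arms) {
  length(setdiff(unique(traits$sample), arms$sample))
}
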