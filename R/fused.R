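#' Fusion junction classification rules
#'
#' An ordered rule table mapping junction features to the error-prone repair
#' pathway of origin. Each rule is a conjunction of interval predicates on
#' microhomology length, untemplated insertion length, and (optionally)
#' inter-chromosomal status; `NA` bounds are unconstrained. The first matching
#' rule wins and a catch-all final rule guarantees a label.
#'
#' The default table encodes the standard literature convention for junction
#' classification: an untemplated insertion of >= 1 bp or microhomology of
#' <= 1 bp indicates non-homologous end joining (NHEJ); 2-20 bp of
#' microhomology indicates microhomology-mediated end joining (MMEJ); > 20 bp
#' indicates single-strand annealing (SSA). The table is externalized as a
#' TSV so alternative rule sets can be dropped in.
#'
#' @param path TSV with columns `priority`, `label`, `mh_min`, `mh_max`,
#'   `ins_min`, `ins_max`, `interchrom`.
#' @return Tibble of rules ordered by `priority`.
#' @export
read_fusion_rules <- function(path) {
  x <- readr::read_tsv(path, col_types = "icddddl", progress = FALSE)
  need <- c("priority", "label", "mh_min", "mh_max", "ins_min", "ins_max",
            "interchrom")
  missing <- setdiff(need, names(x))
  if (length(missing) > 0) {
    abort(paste0("fusion rules: missing column(s): ", paste(missing, collapse = ", ")))
  }
  x <- arrange(as_tibble(x), .data$priority)
  last <- x[nrow(x), ]
  if (!all(is.na(c(last$mh_min, last$mh_max, last$ins_min, last$ins_max,
                   last$interchrom)))) {
    abort("fusion rules: last rule must be an unconditional catch-all")
  }
  x
}

#' @rdname read_fusion_rules
#' @export
default_fusion_rules <- function() {
  read_fusion_rules(rin_extdata("fused_rules_default.tsv"))
}

rule_matches <- function(rule, mh, ins, inter) {
  ok <- rep(TRUE, length(mh))
  if (!is.na(rule$mh_min)) ok <- ok & mh >= rule$mh_min
  if (!is.na(rule$mh_max)) ok <- ok & mh <= rule$mh_max
  if (!is.na(rule$ins_min)) ok <- ok & ins >= rule$ins_min
  if (!is.na(rule$ins_max)) ok <- ok & ins <= rule$ins_max
  if (!is.na(rule$interchrom)) ok <- ok & (inter == rule$interchrom)
  ok
}

#' Classify fusion junctions by repair pathway of origin
#'
#' Applies the ordered rule table to each fusion record; classification is a
#' pure function of the record and the rules. With `check_overlap = TRUE`
#' (default) the rule table is screened for ambiguous pairs — overlapping
#' predicates with different labels, where ordering decides — and a warning
#' names the first such pair.
#'
#' @param fusions Fusion table (see [read_fusions()]).
#' @param rules Rule table (default [default_fusion_rules()]).
#' @param check_overlap Warn on ambiguous (order-dependent) rule tables.
#' @return The fusion table with a `pathway` label column appended.
#' @export
classify_fusions <- function(fusions, rules = default_fusion_rules(),
                             check_overlap = TRUE) {
  fusions <- validate_fusions(fusions)
  if (check_overlap) warn_on_rule_overlap(rules)
  inter <- if (all(c("chrom_a", "chrom_b") %in% names(fusions))) {
    fusions$chrom_a != fusions$chrom_b
  } else {
    rep(NA, nrow(fusions))
  }
  label <- rep(NA_character_, nrow(fusions))
  for (i in seq_len(nrow(rules))) {
    hit <- is.na(label) & rule_matches(rules[i, ], fusions$microhomology,
                                       fusions$insertion, inter)
    label[hit] <- rules$label[i]
  }
  mutate(fusions, pathway = label)
}

# two rules overlap if their interval predicates intersect; differing labels
# make the table order-dependent
warn_on_rule_overlap <- function(rules) {
  iv <- function(lo, hi) c(ifelse(is.na(lo), -Inf, lo), ifelse(is.na(hi), Inf, hi))
  n <- nrow(rules)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (rules$label[i] == rules$label[j]) next
      if (j == n) next # catch-all overlaps everything by design
      mi <- iv(rules$mh_min[i], rules$mh_max[i]); mj <- iv(rules$mh_min[j], rules$mh_max[j])
      ii <- iv(rules$ins_min[i], rules$ins_max[i]); ij <- iv(rules$ins_min[j], rules$ins_max[j])
      mh_olap <- mi[1] <= mj[2] && mj[1] <= mi[2]
      ins_olap <- ii[1] <= ij[2] && ij[1] <= ii[2]
      inter_olap <- is.na(rules$interchrom[i]) || is.na(rules$interchrom[j]) ||
        rules$interchrom[i] == rules$interchrom[j]
      # the joint region may require mh > 0 and insertion > 0 at once, which
      # valid junctions never satisfy
      reachable <- !(max(mi[1], mj[1]) > 0 && max(ii[1], ij[1]) > 0)
      if (mh_olap && ins_olap && inter_olap && reachable) {
        warn(paste0("fusion rules ", rules$priority[i], " and ", rules$priority[j],
                    " overlap with different labels; order decides"))
        return(invisible(FALSE))
      }
    }
  }
  invisible(TRUE)
}

#' Summarize fusion repair-pathway origin per cohort
#'
#' Classifies all fusions, tallies counts and proportions per pathway label
#' within each arm (proportions sum to 1 per arm), and tests each label for
#' excess in the High arm with a one-sided Fisher exact test over fusion
#' counts, Benjamini-Hochberg corrected across labels.
#'
#' @param fusions Fusion table.
#' @param assignment Cohort assignment.
#' @param rules Rule table.
#' @return List with `summary` (per cohort x label counts/proportions) and
#'   `tests` (per-label enrichment).
#' @export
summarize_origin <- function(fusions, assignment, rules = default_fusion_rules()) {
  labeled <- classify_fusions(fusions, rules) |>
    inner_join(select(assignment, "sample", "cohort"), by = "sample") |>
    filter(.data$cohort %in% c("High", "Low"))
  if (nrow(labeled) == 0 || length(unique(labeled$cohort)) < 2) {
    abort("summarize_origin: need at least one fusion in each arm")
  }
  labels <- unique(rules$label)
  summary <- labeled |>
    count(.data$cohort, .data$pathway) |>
    tidyr::complete(cohort = c("High", "Low"), pathway = labels,
                    fill = list(n = 0L)) |>
    group_by(.data$cohort) |>
    mutate(proportion = .data$n / sum(.data$n)) |>
    ungroup() |>
    mutate(cohort = as.character(.data$cohort))
  n_high <- sum(summary$n[summary$cohort == "High"])
  n_low <- sum(summary$n[summary$cohort == "Low"])
  tests <- purrr::map_dfr(labels, function(lb) {
    hp <- summary$n[summary$cohort == "High" & summary$pathway == lb]
    lp <- summary$n[summary$cohort == "Low" & summary$pathway == lb]
    m <- matrix(c(hp, n_high - hp, lp, n_low - lp), nrow = 2)
    if (hp + lp == 0) {
      return(tibble(pathway = lb, high = hp, low = lp, p_value = 1,
                    degenerate = TRUE))
    }
    ft <- fisher.test(m, alternative = "greater")
    tibble(pathway = lb, high = hp, low = lp, p_value = ft$p.value,
           degenerate = FALSE)
  })
  tests$q_value <- p.adjust(tests$p_value, method = "BH")
  list(summary = summary, tests = tests)
}
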