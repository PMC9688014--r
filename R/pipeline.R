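#' Pipeline configuration
#'
#' Bundles every tunable the end-to-end analysis uses: fixture tables
#' (pathway registry, RS gene list, RSS catalogs, cluster map, fusion rules),
#' the stratification gene, and thresholds. Defaults mirror the package's
#' shipped fixtures and the analysis conventions (BH q = 0.05, long-gene
#' boundary 3000 bp, quartile fraction 1/4).
#'
#' @param gene Stratification marker gene.
#' @param q_threshold BH significance threshold used by concordance flagging.
#' @param long_threshold Long/short gene boundary (bp) for MPS.
#' @param pathways Pathway registry tibble.
#' @param rs_genes RS gene list tibble.
#' @param rss_catalog RSS catalog tibble.
#' @param clusters Functional cluster map tibble.
#' @param fusion_rules Fusion rule table.
#' @param variant_whitelist Variant classes counting as mutations.
#' @param brain_site Site label identifying brain metastases.
#' @return List of class `rin_config`.
#' @export
rin_config <- function(gene = "MYBL2",
                       q_threshold = 0.05,
                       long_threshold = 3000,
                       pathways = default_pathways(),
                       rs_genes = default_rs_genes(),
                       rss_catalog = default_rss_catalog(),
                       clusters = default_clusters(),
                       fusion_rules = default_fusion_rules(),
                       variant_whitelist = default_variant_whitelist(),
                       brain_site = "brain") {
  if (q_threshold <= 0 || q_threshold >= 1) abort("q_threshold must be in (0, 1)")
  if (long_threshold <= 0) abort("long_threshold must be > 0")
  structure(
    list(gene = gene, q_threshold = q_threshold, long_threshold = long_threshold,
         pathways = pathways, rs_genes = rs_genes, rss_catalog = rss_catalog,
         clusters = clusters, fusion_rules = fusion_rules,
         variant_whitelist = variant_whitelist, brain_site = brain_site),
    class = "rin_config"
  )
}

#' Run the full replicative-instability characterization pipeline
#'
#' Orchestrates every stage on one cohort: quartile stratification,
#' Kaplan-Meier/log-rank survival comparison for OS/DSS/PFS, differential
#' expression and WE pathway scores, heterozygous-loss enrichment and
#' loss-expression association for repair effectors, RS score comparison,
#' MPS distribution comparison per gene length class, RSS alteration
#' frequencies with per-class burden tests, concordant dysregulation by
#' functional cluster, fusion origin summary, and metastasis summaries
#' (dissemination, time to metastasis, brain-met risk). Deterministic: no
#' randomness is consumed.
#'
#' Samples missing from a stage's tables are dropped for that stage; the
#' manifest records the package version and every threshold in effect.
#'
#' @param cohort Named list of tables as produced by [simulate_cohort()] or
#'   [read_cohort()] (`truth` optional and unused).
#' @param config A [rin_config()] object.
#' @return Named list of stage outputs plus `manifest`.
#' @export
run_pipeline <- function(cohort, config = rin_config()) {
  stopifnot(inherits(config, "rin_config"))
  need <- c("expression", "mutations", "copy_number", "annotation",
            "clinical", "fusions")
  missing <- setdiff(need, names(cohort))
  if (length(missing) > 0) {
    abort(paste0("cohort is missing table(s): ", paste(missing, collapse = ", ")))
  }

  # optional stages refuse on cohorts too small to support them; the refusal
  # is recorded in the manifest rather than aborting the whole run
  skipped <- character()
  maybe <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      skipped <<- c(skipped, paste0(name, ": ", conditionMessage(e)))
      NULL
    })
  }

  assignment <- stratify_quartiles(cohort$expression, config$gene)

  clin <- cohort$clinical |>
    inner_join(select(assignment, patient = "sample", "cohort"), by = "patient")
  survival_results <- purrr::map_dfr(c("os", "dss", "pfs"), function(ep) {
    sub <- filter(clin, .data$cohort %in% c("High", "Low"))
    dat <- tibble(time = sub[[paste0(ep, "_time")]],
                  event = sub[[paste0(ep, "_event")]],
                  group = as.character(sub$cohort))
    mutate(logrank_test(dat), endpoint = toupper(ep), .before = 1)
  })
  km_curves <- purrr::map(c(High = "High", Low = "Low"), function(a) {
    sub <- filter(clin, .data$cohort == a)
    km_estimate(tibble(time = sub$os_time, event = sub$os_event))
  })

  de <- differential_expression(cohort$expression, assignment)
  we <- we_scores(de, config$pathways)

  effectors <- intersect(unique(config$pathways$gene), cohort$copy_number$gene)
  hetloss <- hetloss_enrichment(cohort$copy_number, assignment, effectors)
  # association needs both call groups populated; restrict to testable genes
  samples <- intersect(setdiff(names(cohort$copy_number), "gene"),
                       setdiff(names(cohort$expression), "gene"))
  testable <- purrr::keep(intersect(effectors, cohort$expression$gene), function(g) {
    calls <- as.integer(unlist(cohort$copy_number[cohort$copy_number$gene == g, samples]))
    sum(calls == -1L) >= 3 && sum(calls == 0L) >= 3
  })
  loss_assoc <- if (length(testable) > 0) {
    loss_expression_association(cohort$copy_number, cohort$expression, testable)
  } else {
    NULL
  }

  rs <- rs_score(cohort$expression, config$rs_genes)
  rs_test <- compare_rs(rs, assignment)

  mps_records <- mps(cohort$mutations, cohort$annotation,
                     long_threshold = config$long_threshold)
  mps_tests <- purrr::map_dfr(c("long", "short"), function(cl) {
    out <- maybe(paste0("mps_", cl), compare_mps(mps_records, assignment, cl))
    if (is.null(out)) tibble() else out
  })

  freqs <- alteration_frequencies(cohort$copy_number, cohort$mutations,
                                  assignment, config$rss_catalog,
                                  config$variant_whitelist)
  burden <- purrr::map_dfr(c("amplification", "gain", "hetloss", "homdel",
                             "mutation"),
                           function(cl) compare_burden(freqs, cl))

  catalog_genes <- intersect(config$rss_catalog$gene, cohort$copy_number$gene)
  gain_enr <- cn_direction_enrichment(cohort$copy_number, assignment,
                                      catalog_genes, "up")
  loss_enr <- cn_direction_enrichment(cohort$copy_number, assignment,
                                      catalog_genes, "down")
  concordance <- concordant_dysregulation(de, gain_enr, loss_enr,
                                          config$clusters, config$q_threshold)

  origin <- maybe("fusion_origin",
                  summarize_origin(cohort$fusions, assignment, config$fusion_rules))

  dissemination <- tally_dissemination(cohort$clinical, assignment)
  time_to_met <- maybe("time_to_met",
                       compare_time_to_met(cohort$clinical, assignment))
  brain_risk <- brain_met_risk_by_cohort(cohort$clinical, assignment,
                                         config$brain_site)

  manifest <- list(
    package_version = as.character(packageVersion("rinstab")),
    gene = config$gene, q_threshold = config$q_threshold,
    long_threshold = config$long_threshold,
    n_samples = nrow(assignment),
    n_high = sum(assignment$cohort == "High"),
    n_low = sum(assignment$cohort == "Low"),
    mps_skipped_unannotated = attr(mps_records, "n_unannotated"),
    mps_skipped_outside = attr(mps_records, "n_outside"),
    rss_coverage = attr(freqs, "coverage"),
    variant_whitelist = config$variant_whitelist,
    skipped_stages = skipped,
    config_hash = rlang::hash(config)
  )

  list(
    assignment = assignment, survival = survival_results, km = km_curves,
    differential_expression = de, we_scores = we, hetloss = hetloss,
    loss_expression = loss_assoc, rs_scores = rs, rs_test = rs_test,
    mps_records = mps_records, mps_tests = mps_tests,
    alteration_frequencies = freqs, burden = burden,
    concordance = concordance, fusion_origin = origin,
    dissemination = dissemination, time_to_met = time_to_met,
    brain_met_risk = brain_risk, manifest = manifest
  )
}
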