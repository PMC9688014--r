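# small in-code fixtures shared across test files

# expression tibble from a named list of per-sample values;
# genes given as a character vector
make_expr <- function(genes, ...) {
  vals <- list(...)
  tibble::tibble(gene = genes, !!!vals)
}

# copy-number tibble, same shape, integer calls
make_cn <- function(genes, ...) {
  vals <- lapply(list(...), as.integer)
  tibble::tibble(gene = genes, !!!vals)
}

# minimal clinical table; mets is a list of tibble(site, time)
make_clinical <- function(patient, os_time, os_event, treatment = "none",
                          mets = NULL) {
  n <- length(patient)
  if (is.null(mets)) {
    mets <- replicate(n, tibble::tibble(site = character(), time = numeric()),
                      simplify = FALSE)
  }
  tibble::tibble(
    patient = patient,
    os_time = os_time, os_event = os_event,
    dss_time = os_time, dss_event = os_event,
    pfs_time = os_time, pfs_event = os_event,
    treatment = rep_len(treatment, n),
    mets = mets
  )
}

# assignment tibble from sample vectors
make_assignment <- function(high, low, mid = character()) {
  tibble::tibble(
    sample = c(high, low, mid),
    cohort = factor(rep(c("High", "Low", "Mid"),
                        c(length(high), length(low), length(mid))),
                    levels = c("High", "Mid", "Low"))
  )
}

# a small planted cohort reused by several files (computed once per run)
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- rinstab::simulate_cohort(rinstab::sim_config(n_per_arm = 30, seed = 42))
    }
    cache
  }
})
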