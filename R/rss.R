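#' Build the replication-stress sensitive (RSS) site catalog
#'
#' Merges an early-replicating fragile site (ERFS) gene list with mitotic DNA
#' synthesis (MiDAS) sites. MiDAS sites attributable to more than two genes
#' are dropped entirely; genes present in both lists are resolved to MiDAS
#' (removed from ERFS); remaining ERFS genes keep their class. The merge is
#' idempotent and order-independent.
#'
#' @param erfs_genes Character vector (or tibble with `gene` column) of ERFS
#'   genes.
#' @param midas_sites Tibble with columns `site`, `gene`: one row per gene
#'   attribution of a MiDAS site.
#' @return Tibble: `gene`, `class` (`"ERFS"` or `"MiDAS"`), one row per gene.
#' @export
build_rss_catalog <- function(erfs_genes, midas_sites) {
  if (is.data.frame(erfs_genes)) erfs_genes <- erfs_genes$gene
  stopifnot(is.character(erfs_genes), is.data.frame(midas_sites))
  if (!all(c("site", "gene") %in% names(midas_sites))) {
    abort("midas_sites needs 'site' and 'gene' columns")
  }
  keep_sites <- midas_sites |>
    distinct(.data$site, .data$gene) |>
    count(.data$site) |>
    filter(n <= 2) |>
    pull("site")
  midas_genes <- midas_sites |>
    filter(.data$site %in% keep_sites) |>
    pull("gene") |>
    unique()
  erfs_only <- setdiff(unique(erfs_genes), midas_genes)
  out <- bind_rows(
    tibble(gene = sort(erfs_only), class = "ERFS"),
    tibble(gene = sort(midas_genes), class = "MiDAS")
  )
  if (nrow(out) == 0) abort("RSS catalog is empty after filtering")
  out
}

#' @rdname build_rss_catalog
#' @export
default_rss_catalog <- function() {
  erfs <- readr::read_tsv(rin_extdata("erfs_synthetic.tsv"),
                          col_types = "c", progress = FALSE)
  midas <- readr::read_tsv(rin_extdata("midas_sites_synthetic.tsv"),
                           col_types = "cc", progress = FALSE)
  build_rss_catalog(erfs, midas)
}

#' Functional cluster map for RSS catalog genes
#'
#' Thirteen functional clusters binning RSS-site genes by biological process.
#' The shipped map is a synthetic stand-in covering the shipped catalogs.
#'
#' @param path TSV with columns `gene`, `cluster_id`, `cluster_label`.
#' @return Tibble with those columns; 13 distinct clusters expected.
#' @export
read_clusters <- function(path) {
  x <- readr::read_tsv(path, col_types = "cic", progress = FALSE)
  need <- c("gene", "cluster_id", "cluster_label")
  missing <- setdiff(need, names(x))
  if (length(missing) > 0) {
    abort(paste0("cluster map: missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(x$gene)) abort("cluster map: gene mapped to several clusters")
  as_tibble(x)
}

#' @rdname read_clusters
#' @export
default_clusters <- function() {
  read_clusters(rin_extdata("functional_clusters_synthetic.tsv"))
}

#' Per-gene alteration frequencies at RSS sites
#'
#' For each catalog gene and cohort arm, the fraction of arm samples carrying
#' each alteration class: amplification (+2), gain (+1), heterozygous loss
#' (-1), homozygous deletion (-2), and mutation (at least one MAF record whose
#' variant classification is in the whitelist). Fractions are per class, so a
#' sample carrying both a copy-number change and a mutation counts in both —
#' the five fractions may sum above 1 for a gene.
#'
#' Catalog genes absent from the copy-number table are dropped with a warning;
#' coverage is reported in the `coverage` attribute.
#'
#' @param cn Copy-number table.
#' @param mutations Mutation table.
#' @param assignment Cohort assignment.
#' @param catalog RSS catalog from [build_rss_catalog()].
#' @param variant_whitelist Variant classes counting as mutations.
#' @return Long tibble: `gene`, `class` (site class), `cohort`, `alteration`,
#'   `n_altered`, `n_samples`, `frequency`.
#' @export
alteration_frequencies <- function(cn, mutations, assignment, catalog,
                                   variant_whitelist = default_variant_whitelist()) {
  cn <- validate_copy_number(cn)
  mutations <- validate_mutations(mutations)
  present <- intersect(catalog$gene, cn$gene)
  missing <- setdiff(catalog$gene, cn$gene)
  if (length(missing) > 0) {
    warn(paste0("alteration_frequencies: ", length(missing),
                " catalog genes absent from copy-number data (coverage ",
                round(100 * length(present) / nrow(catalog)), "%)"))
  }
  if (length(present) == 0) abort("no catalog genes present in copy-number data")
  arms <- filter(assignment, .data$cohort %in% c("High", "Low"))
  alt_classes <- c(amplification = 2L, gain = 1L, hetloss = -1L, homdel = -2L)
  cn_long <- cn |>
    filter(.data$gene %in% present) |>
    tidyr::pivot_longer(-"gene", names_to = "sample", values_to = "call") |>
    inner_join(select(arms, "sample", "cohort"), by = "sample")
  mut_flag <- mutations |>
    filter(.data$gene %in% present,
           .data$variant_class %in% variant_whitelist) |>
    distinct(.data$gene, .data$sample) |>
    mutate(mutated = TRUE)
  out <- purrr::map_dfr(names(alt_classes), function(cl) {
    cn_long |>
      group_by(.data$gene, .data$cohort) |>
      summarise(
        n_altered = sum(.data$call == alt_classes[[cl]]),
        n_samples = n(), .groups = "drop"
      ) |>
      mutate(alteration = cl)
  })
  mut_out <- cn_long |>
    left_join(mut_flag, by = c("gene", "sample")) |>
    group_by(.data$gene, .data$cohort) |>
    summarise(
      n_altered = sum(!is.na(.data$mutated)),
      n_samples = n(), .groups = "drop"
    ) |>
    mutate(alteration = "mutation")
  out <- bind_rows(out, mut_out) |>
    left_join(catalog, by = "gene") |>
    mutate(
      cohort = as.character(.data$cohort),
      frequency = .data$n_altered / .data$n_samples
    ) |>
    select("gene", "class", "cohort", "alteration", "n_altered",
           "n_samples", "frequency") |>
    arrange(.data$gene, .data$cohort, .data$alteration)
  attr(out, "coverage") <- length(present) / nrow(catalog)
  out
}

#' Compare per-gene alteration burden between cohorts
#'
#' Paired Wilcoxon signed-rank test across genes of the High-arm minus
#' Low-arm alteration frequency for one alteration class (pairing is by gene,
#' which is legitimate here: each gene contributes one frequency per arm).
#' Identical frequency vectors give `p = 1`.
#'
#' @param freqs Output of [alteration_frequencies()].
#' @param alteration One of `"amplification"`, `"gain"`, `"hetloss"`,
#'   `"homdel"`, `"mutation"`.
#' @return One-row tibble: `test`, `alteration`, `statistic` (V), `p_value`,
#'   `n_genes`, mean per-arm frequencies.
#' @export
compare_burden <- function(freqs, alteration = c("gain", "hetloss",
                                                 "amplification", "homdel",
                                                 "mutation")) {
  alteration <- match.arg(alteration)
  x <- freqs |>
    filter(.data$alteration == !!alteration) |>
    select("gene", "cohort", "frequency") |>
    tidyr::pivot_wider(names_from = "cohort", values_from = "frequency")
  if (!all(c("High", "Low") %in% names(x))) {
    abort("compare_burden: need frequencies for both High and Low arms")
  }
  d <- x$High - x$Low
  if (all(d == 0)) {
    return(tibble(test = "Wilcoxon signed-rank (paired by gene)",
                  alteration = alteration, statistic = 0, p_value = 1,
                  n_genes = nrow(x), mean_high = mean(x$High),
                  mean_low = mean(x$Low)))
  }
  wt <- suppressWarnings(wilcox.test(x$High, x$Low, paired = TRUE,
                                     alternative = "two.sided"))
  tibble(
    test = "Wilcoxon signed-rank (paired by gene)", alteration = alteration,
    statistic = unname(wt$statistic), p_value = wt$p.value,
    n_genes = nrow(x), mean_high = mean(x$High), mean_low = mean(x$Low)
  )
}

#' Copy-number direction enrichment per gene
#'
#' One-sided Fisher enrichment (in the High arm) of directional copy-number
#' change per gene — `"up"` tests gain-or-amplification calls (> 0), `"down"`
#' heterozygous-loss-or-deletion calls (< 0) — Benjamini-Hochberg corrected
#' across the gene set. Feeds [concordant_dysregulation()].
#'
#' @param cn Copy-number table.
#' @param assignment Cohort assignment.
#' @param genes Genes to test.
#' @param direction `"up"` or `"down"`.
#' @return Tibble per gene: counts, `odds_ratio`, `p_value`, `q_value`.
#' @export
cn_direction_enrichment <- function(cn, assignment, genes,
                                    direction = c("up", "down")) {
  direction <- match.arg(direction)
  cn <- validate_copy_number(cn)
  missing <- setdiff(genes, cn$gene)
  if (length(missing) > 0) {
    abort(paste0("genes absent from copy-number table: ",
                 paste(missing, collapse = ", ")))
  }
  pred <- if (direction == "up") function(call) call > 0L else function(call) call < 0L
  traits <- cn_trait_table(cn, genes, pred)
  out <- cohort_enrichment(traits, assignment)
  rename(out, gene = "trait")
}

#' Concordantly dysregulated genes at RSS sites
#'
#' Flags genes whose copy-number enrichment and expression change agree:
#' concordant-up if gain/amplification enrichment `q < q_threshold`, positive
#' log2 fold change, and expression `q < q_threshold`; concordant-down
#' analogously for loss enrichment and negative fold change. Output is
#' grouped by functional cluster.
#'
#' @param de Differential-expression table.
#' @param gain_enrichment,loss_enrichment Per-gene enrichment tables from
#'   [cn_direction_enrichment()] (directions `"up"` and `"down"`).
#' @param clusters Functional cluster map (see [read_clusters()]).
#' @param q_threshold Significance threshold on both q values.
#' @return Tibble per gene: `cluster_id`, `cluster_label`, `log2fc`,
#'   `expr_q`, `gain_q`, `loss_q`, `concordant` (`"up"`, `"down"`, or
#'   `"none"`), sorted by cluster.
#' @export
concordant_dysregulation <- function(de, gain_enrichment, loss_enrichment,
                                     clusters, q_threshold = 0.05) {
  x <- de |>
    select("gene", "log2fc", expr_q = "q_value") |>
    inner_join(select(gain_enrichment, "gene", gain_q = "q_value"), by = "gene") |>
    inner_join(select(loss_enrichment, "gene", loss_q = "q_value"), by = "gene") |>
    left_join(clusters, by = "gene")
  x |>
    mutate(concordant = dplyr::case_when(
      .data$gain_q < q_threshold & .data$log2fc > 0 & .data$expr_q < q_threshold ~ "up",
      .data$loss_q < q_threshold & .data$log2fc < 0 & .data$expr_q < q_threshold ~ "down",
      TRUE ~ "none"
    )) |>
    arrange(.data$cluster_id, .data$gene)
}
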