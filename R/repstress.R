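#' Replication-stress response gene list
#'
#' The RS score averages expression over a curated list of replication-stress
#' response genes (fork sensing, protection, processing and restart). The
#' shipped list is a synthetic stand-in of 205 unique symbols: a genuine core
#' of well-known replication-stress genes padded with `RSR###` placeholder
#' symbols so the list size matches the curated original; the synthetic
#' cohort generator includes every listed symbol. Supply your own curated
#' list via `read_rs_genes()`.
#'
#' @param path TSV with a single `gene` column.
#' @return Tibble with column `gene`; symbols unique.
#' @export
read_rs_genes <- function(path) {
  x <- readr::read_tsv(path, col_types = "c", progress = FALSE)
  if (!"gene" %in% names(x)) abort("RS gene list: missing 'gene' column")
  if (anyDuplicated(x$gene)) abort("RS gene list: duplicate symbols (redundant entries must be removed)")
  as_tibble(x)
}

#' @rdname read_rs_genes
#' @export
default_rs_genes <- function() {
  read_rs_genes(rin_extdata("rs_genes_synthetic.tsv"))
}

#' Replication-stress (RS) score per sample
#'
#' The RS score of a sample is the sum of its log2 mRNA expression values over
#' the RS response gene list divided by the number of genes in the list —
#' i.e. the arithmetic mean over the list. The denominator is the full list
#' length, so any listed gene missing from the expression table is a hard
#' error naming the genes.
#'
#' @param expr Expression table.
#' @param rs_genes Tibble with a `gene` column (default: shipped 205-gene
#'   synthetic list).
#' @return Tibble: `sample`, `rs_score`.
#' @export
rs_score <- function(expr, rs_genes = default_rs_genes()) {
  expr <- validate_expression(expr)
  genes <- rs_genes$gene
  missing <- setdiff(genes, expr$gene)
  if (length(missing) > 0) {
    abort(paste0("RS genes absent from expression data: ",
                 paste(missing, collapse = ", ")))
  }
  samples <- setdiff(names(expr), "gene")
  sub <- as.matrix(expr[match(genes, expr$gene), samples])
  tibble(sample = samples, rs_score = unname(colMeans(sub)))
}

#' Compare RS scores between cohorts
#'
#' Two-sample two-sided Wilcoxon rank-sum test of RS scores, High vs Low.
#' (The arms are unpaired and of unequal size, so a signed-rank pairing does
#' not exist; the rank-sum test is the unpaired analogue.)
#'
#' @param scores RS score table from [rs_score()].
#' @param assignment Cohort assignment.
#' @return One-row tibble: `test`, `statistic` (rank-sum W), `p_value`,
#'   per-arm n and medians.
#' @export
compare_rs <- function(scores, assignment) {
  x <- inner_join(scores, select(assignment, "sample", "cohort"), by = "sample")
  hv <- x$rs_score[x$cohort == "High"]
  lv <- x$rs_score[x$cohort == "Low"]
  if (length(hv) == 0 || length(lv) == 0) abort("compare_rs: both arms must be non-empty")
  wt <- suppressWarnings(wilcox.test(hv, lv, alternative = "two.sided"))
  tibble(
    test = "Wilcoxon rank-sum", sidedness = "two-sided",
    statistic = unname(wt$statistic), p_value = wt$p.value,
    n_high = length(hv), n_low = length(lv),
    median_high = median(hv), median_low = median(lv)
  )
}

#' Mutational position score (MPS)
#'
#' For each somatic mutation, MPS is the distance from the gene start divided
#' by the gene length: `(position - start) / length`, a relative intragenic
#' location in [0, 1] (0 = gene start, 1 = gene end). Genes are classed `long`
#' or `short` at a length threshold (default 3000 bp; a gene of exactly the
#' threshold length is classed long). Positions are genomic plus-strand
#' coordinates regardless of gene strand; `strand_orient = TRUE` flips MPS to
#' `1 - MPS` for minus-strand genes so the score runs in transcription
#' direction.
#'
#' Mutations in genes absent from the annotation, or falling outside the
#' annotated gene span, are skipped; the dropped counts are reported in
#' attributes `n_unannotated` and `n_outside` and via a message.
#'
#' @param mutations Mutation table (see [read_maf()]).
#' @param annotation Gene annotation (see [read_annotation()]).
#' @param long_threshold Long/short gene length boundary in bp.
#' @param strand_orient Orient MPS along the transcribed strand.
#' @return Tibble: `sample`, `gene`, `mps`, `length_class`.
#' @export
mps <- function(mutations, annotation, long_threshold = 3000,
                strand_orient = FALSE) {
  mutations <- validate_mutations(mutations)
  annotation <- validate_annotation(annotation)
  x <- left_join(mutations, annotation, by = "gene", suffix = c("", ".ann"))
  unann <- is.na(x$start)
  x <- x[!unann, ]
  outside <- x$position < x$start | x$position > x$end
  n_out <- sum(outside)
  x <- x[!outside, ]
  if (sum(unann) + n_out > 0) {
    inform(paste0("mps: skipped ", sum(unann), " mutations in unannotated genes and ",
                  n_out, " outside the annotated gene span"))
  }
  score <- (x$position - x$start) / x$length
  if (strand_orient) score <- ifelse(x$strand == "-", 1 - score, score)
  out <- tibble(
    sample = x$sample, gene = x$gene, mps = score,
    length_class = if_else(x$length >= long_threshold, "long", "short")
  )
  attr(out, "n_unannotated") <- sum(unann)
  attr(out, "n_outside") <- n_out
  out
}

#' Compare MPS distributions between cohorts
#'
#' Two-sample Kolmogorov-Smirnov test of the MPS distributions of two arms
#' within one gene length class. Requires at least 10 records per arm.
#'
#' @param records MPS table from [mps()].
#' @param assignment Cohort assignment.
#' @param length_class `"long"` or `"short"`.
#' @return One-row tibble: `test`, `statistic` (KS D), `p_value`, per-arm n.
#' @export
compare_mps <- function(records, assignment, length_class = c("long", "short")) {
  length_class <- match.arg(length_class)
  x <- records |>
    filter(.data$length_class == !!length_class) |>
    inner_join(select(assignment, "sample", "cohort"), by = "sample")
  hv <- x$mps[x$cohort == "High"]
  lv <- x$mps[x$cohort == "Low"]
  if (length(hv) < 10 || length(lv) < 10) {
    abort(paste0("compare_mps: need >= 10 records per arm in class '",
                 length_class, "' (got ", length(hv), " / ", length(lv), ")"))
  }
  kt <- suppressWarnings(ks.test(hv, lv, alternative = "two.sided"))
  tibble(
    test = "Kolmogorov-Smirnov", sidedness = "two-sided",
    length_class = length_class,
    statistic = unname(kt$statistic), p_value = kt$p.value,
    n_high = length(hv), n_low = length(lv)
  )
}
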