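#' DNA-repair pathway registry
#'
#' A pathway registry maps each named repair pathway to its effector genes,
#' each graded by an essentiality scaling factor (ESF): 3 = essential
#' effector, 2 = important effector / potentially compensable, 1 = accessory
#' effector. The shipped registry (`default_pathways()`) is a synthetic
#' stand-in built from well-known effectors of ten pathways (MMR, BER, NER,
#' TLS, NHEJ, HR, MMEJ, FA, DR, checkpoint); edit the TSV or supply your own
#' curated registry via `read_pathways()`.
#'
#' @param path TSV with columns `pathway`, `gene`, `esf`.
#' @return Tibble with columns `pathway`, `gene`, `esf` (integer in 1..3).
#' @export
read_pathways <- function(path) {
  x <- readr::read_tsv(path, col_types = "cci", progress = FALSE)
  need <- c("pathway", "gene", "esf")
  missing <- setdiff(need, names(x))
  if (length(missing) > 0) {
    abort(paste0("pathway registry: missing column(s): ", paste(missing, collapse = ", ")))
  }
  if (any(!x$esf %in% 1:3)) abort("pathway registry: ESF must be 1, 2 or 3")
  if (nrow(x) == 0) abort("pathway registry: empty")
  dup <- x |> count(.data$pathway, .data$gene) |> filter(n > 1)
  if (nrow(dup) > 0) {
    abort(paste0("pathway registry: gene listed twice in one pathway: ",
                 dup$gene[1], " (", dup$pathway[1], ")"))
  }
  as_tibble(x)
}

#' @rdname read_pathways
#' @export
default_pathways <- function() {
  read_pathways(rin_extdata("repair_pathways_synthetic.tsv"))
}

#' Differential expression between High and Low cohorts
#'
#' For each gene: `log2fc` is the mean log2 expression in the High arm minus
#' the mean in the Low arm (the input matrix is already log2-scale), `p_value`
#' a two-sided Wilcoxon rank-sum test between arms, and `q_value` the
#' Benjamini-Hochberg adjustment across all genes. A gene constant across both
#' arms gets `log2fc = 0`, `p = 1`.
#'
#' @param expr Expression table.
#' @param assignment Cohort assignment from [stratify_quartiles()].
#' @return Tibble: `gene`, `log2fc`, `p_value`, `q_value`.
#' @export
differential_expression <- function(expr, assignment) {
  expr <- validate_expression(expr)
  high <- assignment$sample[assignment$cohort == "High"]
  low <- assignment$sample[assignment$cohort == "Low"]
  high <- intersect(high, names(expr))
  low <- intersect(low, names(expr))
  if (length(high) < 3 || length(low) < 3) {
    abort("differential_expression: need at least 3 samples per arm")
  }
  hm <- as.matrix(expr[, high])
  lm_ <- as.matrix(expr[, low])
  log2fc <- rowMeans(hm) - rowMeans(lm_)
  p <- vapply(seq_len(nrow(expr)), function(i) {
    hv <- hm[i, ]; lv <- lm_[i, ]
    if (length(unique(c(hv, lv))) == 1) return(1)
    suppressWarnings(wilcox.test(hv, lv, alternative = "two.sided")$p.value)
  }, numeric(1))
  log2fc[abs(log2fc) < .Machine$double.eps & p == 1] <- 0
  tibble(gene = expr$gene, log2fc = unname(log2fc), p_value = p,
         q_value = p.adjust(p, method = "BH"))
}

#' Weighted-expression (WE) score of a repair pathway
#'
#' WE is a scaled average: each pathway gene's log2 fold change is multiplied
#' by its ESF, the products are summed, and the sum is divided by the number
#' of genes in the pathway registry entry. Positive WE means the pathway is
#' upregulated in the High cohort. The denominator is the registry gene count,
#' so a pathway gene missing from the differential-expression table is a hard
#' error (silent dropping would bias the score).
#'
#' @param de Differential-expression table from [differential_expression()].
#' @param pathway Tibble with columns `gene`, `esf` (one registry pathway).
#' @return A single numeric WE score.
#' @export
we_score <- function(de, pathway) {
  stopifnot(is.data.frame(de), is.data.frame(pathway))
  if (!all(c("gene", "esf") %in% names(pathway))) {
    abort("pathway must have 'gene' and 'esf' columns")
  }
  if (nrow(pathway) == 0) abort("empty pathway")
  missing <- setdiff(pathway$gene, de$gene)
  if (length(missing) > 0) {
    abort(paste0("pathway genes absent from expression data: ",
                 paste(missing, collapse = ", ")))
  }
  lfc <- de$log2fc[match(pathway$gene, de$gene)]
  sum(lfc * pathway$esf) / nrow(pathway)
}

#' WE scores for every pathway in a registry
#'
#' @param de Differential-expression table.
#' @param registry Pathway registry (see [read_pathways()]).
#' @return Tibble: `pathway`, `n_genes`, `we`.
#' @export
we_scores <- function(de, registry) {
  registry |>
    split(registry$pathway) |>
    purrr::imap_dfr(function(pw, nm) {
      tibble(pathway = nm, n_genes = nrow(pw), we = we_score(de, pw))
    }) |>
    arrange(.data$pathway)
}

#' Cross-cohort correlation of WE score vectors
#'
#' Pairwise Pearson correlation of pathway WE vectors across cohorts or
#' datasets, with a two-sided significance test per pair; pairs that do not
#' reach `alpha` are flagged non-significant.
#'
#' @param we_table Tibble with a `pathway` column and one numeric WE column per
#'   cohort.
#' @param alpha Significance threshold for flagging.
#' @return Tibble: `cohort_a`, `cohort_b`, `r`, `p_value`, `significant`.
#' @export
we_correlation <- function(we_table, alpha = 0.05) {
  stopifnot(is.data.frame(we_table))
  if (!"pathway" %in% names(we_table)) abort("we_table needs a 'pathway' column")
  cohorts <- setdiff(names(we_table), "pathway")
  if (length(cohorts) < 2) abort("need at least two cohort columns")
  if (nrow(we_table) < 3) abort("need at least 3 shared pathways")
  pairs <- utils::combn(cohorts, 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(pr) {
    a <- we_table[[pr[1]]]; b <- we_table[[pr[2]]]
    ct <- suppressWarnings(cor.test(a, b, method = "pearson"))
    tibble(cohort_a = pr[1], cohort_b = pr[2],
           r = unname(ct$estimate), p_value = ct$p.value,
           significant = ct$p.value < alpha)
  })
}

#' Heterozygous-loss enrichment in the High cohort
#'
#' Per gene, tests whether heterozygous-loss calls (-1) are enriched among
#' High-arm samples with a one-sided Fisher exact test, Benjamini-Hochberg
#' corrected across the supplied gene set.
#'
#' @param cn Copy-number table.
#' @param assignment Cohort assignment.
#' @param genes Genes to test (default: repair effectors present in `cn`).
#' @return Tibble per gene: 2x2 counts, `odds_ratio`, `p_value`, `q_value`.
#' @export
hetloss_enrichment <- function(cn, assignment, genes) {
  cn <- validate_copy_number(cn)
  missing <- setdiff(genes, cn$gene)
  if (length(missing) > 0) {
    abort(paste0("genes absent from copy-number table: ",
                 paste(missing, collapse = ", ")))
  }
  traits <- cn_trait_table(cn, genes, function(call) call == -1L)
  out <- cohort_enrichment(traits, assignment)
  rename(out, gene = "trait")
}

# long trait table: one row per sample x gene, present = predicate(call)
cn_trait_table <- function(cn, genes, predicate) {
  samples <- setdiff(names(cn), "gene")
  sub <- cn[match(genes, cn$gene), ]
  purrr::map_dfr(genes, function(g) {
    calls <- as.integer(unlist(sub[sub$gene == g, samples]))
    tibble(sample = samples, trait = g, present = predicate(calls))
  })
}

#' Association of heterozygous loss with decreased expression
#'
#' Per gene, one-sided Wilcoxon rank-sum test that expression in samples with
#' a heterozygous-loss call (-1) is lower than in copy-neutral (0) samples;
#' Benjamini-Hochberg corrected across tested genes. Requires at least 3
#' samples in each group — genes failing that precondition are a refusal,
#' listed in the error.
#'
#' @param cn Copy-number table.
#' @param expr Expression table.
#' @param genes Genes to test.
#' @return Tibble: `gene`, `n_loss`, `n_neutral`, `median_loss`,
#'   `median_neutral`, `p_value`, `q_value`.
#' @export
loss_expression_association <- function(cn, expr, genes) {
  cn <- validate_copy_number(cn)
  expr <- validate_expression(expr)
  samples <- intersect(setdiff(names(cn), "gene"), setdiff(names(expr), "gene"))
  missing <- setdiff(genes, intersect(cn$gene, expr$gene))
  if (length(missing) > 0) {
    abort(paste0("genes absent from copy-number or expression table: ",
                 paste(missing, collapse = ", ")))
  }
  rows <- purrr::map(genes, function(g) {
    calls <- as.integer(unlist(cn[cn$gene == g, samples]))
    ev <- as.numeric(unlist(expr[expr$gene == g, samples]))
    loss <- ev[calls == -1L]
    neutral <- ev[calls == 0L]
    list(gene = g, loss = loss, neutral = neutral)
  })
  bad <- purrr::keep(rows, ~ length(.x$loss) < 3 || length(.x$neutral) < 3)
  if (length(bad) > 0) {
    abort(paste0("loss_expression_association: fewer than 3 samples per group for: ",
                 paste(purrr::map_chr(bad, "gene"), collapse = ", ")))
  }
  out <- purrr::map_dfr(rows, function(r) {
    wt <- suppressWarnings(wilcox.test(r$loss, r$neutral, alternative = "less"))
    tibble(gene = r$gene, n_loss = length(r$loss), n_neutral = length(r$neutral),
           median_loss = median(r$loss), median_neutral = median(r$neutral),
           p_value = wt$p.value)
  })
  out$q_value <- p.adjust(out$p_value, method = "BH")
  out
}
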