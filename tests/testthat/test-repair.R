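test_that("differential expression recovers exact shifts and null gives p = 1", {
  genes <- c("A", "B")
  high <- paste0("H", 1:3)
  low <- paste0("L", 1:3)
  asg <- make_assignment(high, low)
  # gene A doubled in High (+1 log2, no noise); gene B identical
  vals <- c(stats::setNames(rep(list(c(3, 5)), 3), high),
            stats::setNames(rep(list(c(2, 5)), 3), low))
  ex <- tibble::tibble(gene = genes, !!!vals)
  de <- differential_expression(ex, asg)
  expect_equal(de$log2fc[de$gene == "A"], 1)
  expect_equal(de$log2fc[de$gene == "B"], 0)
  expect_equal(de$p_value[de$gene == "B"], 1)

  expect_error(differential_expression(ex, make_assignment(high[1:2], low)),
               "3 samples")
})

test_that("differential expression estimates a planted shift without bias", {
  est <- vapply(1:20, function(s) {
    set.seed(s)
    n <- 50
    ex <- tibble::tibble(
      gene = "G",
      !!!stats::setNames(as.list(c(rnorm(n, 5.5, 1), rnorm(n, 5, 1))),
                         c(paste0("H", 1:n), paste0("L", 1:n)))
    )
    asg <- make_assignment(paste0("H", 1:n), paste0("L", 1:n))
    differential_expression(ex, asg)$log2fc
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.5), 0.1)
})

test_that("WE score equals the ESF-weighted scaled average", {
  de <- tibble::tibble(gene = c("A", "B", "C", "D"),
                       log2fc = c(1, -1, 0.5, 2),
                       p_value = 0.01, q_value = 0.01)
  # (+1*3 + -1*1) / 2
  expect_equal(we_score(de, tibble::tibble(gene = c("A", "B"), esf = c(3, 1))), 1.0)
  # all-zero fold changes
  de0 <- dplyr::mutate(de, log2fc = 0)
  expect_equal(we_score(de0, tibble::tibble(gene = c("A", "B"), esf = c(3, 1))), 0)
  # 4-gene spreadsheet oracle: (1*3 + -1*2 + 0.5*1 + 2*2) / 4 = 5.5 / 4
  pw4 <- tibble::tibble(gene = c("A", "B", "C", "D"), esf = c(3, 2, 1, 2))
  expect_equal(we_score(de, pw4), 5.5 / 4)
  # missing gene is a hard error naming it
  expect_error(we_score(de, tibble::tibble(gene = c("A", "ZZZ"), esf = c(1, 1))),
               "ZZZ")
})

test_that("WE is linear in fold changes and invariant to gene order", {
  set.seed(4)
  de <- tibble::tibble(gene = letters[1:6], log2fc = rnorm(6),
                       p_value = 0.5, q_value = 0.5)
  pw <- tibble::tibble(gene = letters[1:4], esf = c(3, 2, 1, 2))
  w <- we_score(de, pw)
  de_scaled <- dplyr::mutate(de, log2fc = 3.7 * log2fc)
  expect_equal(we_score(de_scaled, pw), 3.7 * w)
  expect_equal(we_score(de, pw[sample(4), ]), w)
  # uniform ESF k reduces to k * mean(log2fc)
  pw_k <- tibble::tibble(gene = letters[1:4], esf = rep(2L, 4))
  expect_equal(we_score(de, pw_k), 2 * mean(de$log2fc[1:4]))
})

test_that("WE correlation returns exact r for identical and anti-ordered vectors", {
  we <- tibble::tibble(pathway = c("p1", "p2", "p3", "p4"),
                       A = c(1, 2, 3, 4), B = c(1, 2, 3, 4),
                       C = c(4, 3, 2, 1))
  res <- we_correlation(we)
  ab <- res[res$cohort_a == "A" & res$cohort_b == "B", ]
  ac <- res[res$cohort_a == "A" & res$cohort_b == "C", ]
  expect_equal(ab$r, 1)
  expect_equal(ac$r, -1)
  expect_error(we_correlation(we[1:2, ]), "3 shared pathways")
  expect_error(we_correlation(we["pathway"]), "two cohort")
})

test_that("two cohorts sharing planted pathway effects give positive WE correlation", {
  r <- vapply(1:20, function(s) {
    co1 <- simulate_cohort(sim_config(n_per_arm = 20, seed = 3000 + s))
    co2 <- simulate_cohort(sim_config(n_per_arm = 20, seed = 6000 + s))
    reg <- default_pathways()
    w1 <- we_scores(differential_expression(co1$expression,
                                            stratify_quartiles(co1$expression)), reg)
    w2 <- we_scores(differential_expression(co2$expression,
                                            stratify_quartiles(co2$expression)), reg)
    cor(w1$we, w2$we)
  }, numeric(1))
  expect_gte(mean(r > 0), 0.95)
})

test_that("hetloss enrichment equals the exact hypergeometric value", {
  high <- paste0("H", 1:10); low <- paste0("L", 1:10)
  asg <- make_assignment(high, low)
  calls <- c(rep(-1L, 8), 0L, 0L, rep(0L, 10)) # 8/10 High lost, 0/10 Low
  cn <- tibble::tibble(gene = "XPC", !!!stats::setNames(as.list(calls), c(high, low)))
  res <- hetloss_enrichment(cn, asg, "XPC")
  oracle <- sum(dhyper(8, 10, 10, 8)) # all 8 losses in the High arm
  expect_equal(res$p_value, oracle, tolerance = 1e-12)

  cn0 <- dplyr::mutate(cn, dplyr::across(-gene, ~0L))
  res0 <- hetloss_enrichment(cn0, asg, "XPC")
  expect_equal(res0$p_value, 1)
  expect_true(res0$degenerate)
})

test_that("hetloss enrichment p-values are valid under label permutation", {
  set.seed(5)
  n <- 20
  samples <- sprintf("S%02d", 1:(2 * n))
  calls <- as.integer(ifelse(runif(2 * n) < 0.4, -1L, 0L))
  cn <- tibble::tibble(gene = "G", !!!stats::setNames(as.list(calls), samples))
  p <- vapply(1:200, function(i) {
    perm <- sample(samples)
    asg <- make_assignment(perm[1:n], perm[(n + 1):(2 * n)])
    hetloss_enrichment(cn, asg, "G")$p_value
  }, numeric(1))
  # exact one-sided p-values are super-uniform: P(p <= a) <= a
  for (a in c(0.05, 0.1, 0.25)) expect_lte(mean(p <= a), a + 0.05)
})

test_that("loss-expression association detects planted downshift and refuses degenerate input", {
  set.seed(6)
  n <- 100
  samples <- sprintf("S%03d", 1:n)
  calls <- as.integer(rep(c(-1L, 0L), each = n / 2))
  expr_vals <- rnorm(n, 8) + ifelse(calls == -1L, -1, 0)
  cn <- tibble::tibble(gene = "G", !!!stats::setNames(as.list(calls), samples))
  ex <- tibble::tibble(gene = "G", !!!stats::setNames(as.list(expr_vals), samples))
  res <- loss_expression_association(cn, ex, "G")
  expect_lt(res$p_value, 0.001)
  expect_lt(res$median_loss, res$median_neutral)

  cn_all <- tibble::tibble(gene = "G", !!!stats::setNames(as.list(rep(-1L, n)), samples))
  expect_error(loss_expression_association(cn_all, ex, "G"), "fewer than 3")
})
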