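test_that("RSS catalog merge follows the stated rules", {
  # overlap resolves to MiDAS
  cat1 <- build_rss_catalog(c("A", "B"),
                            tibble::tibble(site = c("m1", "m1"), gene = c("B", "C")))
  expect_equal(cat1$class[cat1$gene == "A"], "ERFS")
  expect_equal(cat1$class[cat1$gene == "B"], "MiDAS")
  expect_equal(cat1$class[cat1$gene == "C"], "MiDAS")

  # a MiDAS site with three attributed genes is dropped entirely
  cat2 <- build_rss_catalog(c("A"),
                            tibble::tibble(site = rep("m1", 3),
                                           gene = c("X", "Y", "Z")))
  expect_equal(cat2$gene, "A")

  # disjoint lists keep their classes
  cat3 <- build_rss_catalog(c("A", "B"),
                            tibble::tibble(site = c("m1", "m2"), gene = c("C", "D")))
  expect_setequal(cat3$gene[cat3$class == "ERFS"], c("A", "B"))
  expect_setequal(cat3$gene[cat3$class == "MiDAS"], c("C", "D"))

  # idempotent and order-independent
  midas <- tibble::tibble(site = c("m2", "m1", "m1"), gene = c("D", "B", "C"))
  expect_identical(build_rss_catalog(c("B", "A"), midas),
                   build_rss_catalog(c("A", "B"), midas[c(3, 1, 2), ]))

  expect_error(build_rss_catalog(character(),
                                 tibble::tibble(site = character(),
                                                gene = character())),
               "empty")
})

test_that("alteration frequencies match a brute-force counting oracle", {
  set.seed(11)
  genes <- paste0("G", 1:6)
  high <- paste0("H", 1:8); low <- paste0("L", 1:8)
  calls <- matrix(sample(c(-2L, -1L, 0L, 1L, 2L), 6 * 16, replace = TRUE,
                         prob = c(0.1, 0.2, 0.4, 0.2, 0.1)),
                  nrow = 6, dimnames = list(genes, c(high, low)))
  cn <- tibble::tibble(gene = genes, !!!as.data.frame(calls))
  muts <- tibble::tibble(
    sample = sample(c(high, low), 30, replace = TRUE),
    gene = sample(genes, 30, replace = TRUE),
    chrom = "1", position = 100L, ref = "A", alt = "T",
    variant_class = sample(c("Missense_Mutation", "Silent"), 30, replace = TRUE)
  )
  asg <- make_assignment(high, low)
  catalog <- tibble::tibble(gene = genes, class = rep(c("ERFS", "MiDAS"), 3))
  fr <- alteration_frequencies(cn, muts, asg, catalog)

  states <- c(amplification = 2L, gain = 1L, hetloss = -1L, homdel = -2L)
  for (g in genes) {
    for (arm in list(c("High", high), c("Low", low))) {
      ss <- arm[-1]
      for (cl in names(states)) {
        expect_equal(
          fr$frequency[fr$gene == g & fr$cohort == arm[1] & fr$alteration == cl],
          sum(calls[g, ss] == states[[cl]]) / length(ss)
        )
      }
      carriers <- unique(muts$sample[muts$gene == g &
                                       muts$variant_class == "Missense_Mutation"])
      expect_equal(
        fr$frequency[fr$gene == g & fr$cohort == arm[1] &
                       fr$alteration == "mutation"],
        length(intersect(carriers, ss)) / length(ss)
      )
    }
  }
})

test_that("simple frequency cases: 3/10 gains, all-neutral, classes can sum past 1", {
  genes <- "G1"
  high <- paste0("H", 1:10); low <- paste0("L", 1:10)
  calls <- c(rep(1L, 3), rep(0L, 7), rep(0L, 10))
  cn <- tibble::tibble(gene = genes, !!!stats::setNames(as.list(calls), c(high, low)))
  muts <- tibble::tibble(sample = c("H1", "H4"), gene = "G1", chrom = "1",
                         position = 5L, ref = "A", alt = "C",
                         variant_class = "Missense_Mutation")
  asg <- make_assignment(high, low)
  catalog <- tibble::tibble(gene = "G1", class = "ERFS")
  fr <- alteration_frequencies(cn, muts, asg, catalog)
  expect_equal(fr$frequency[fr$cohort == "High" & fr$alteration == "gain"], 0.3)
  # H1 carries both a gain and a mutation: class fractions overlap by design
  tot_high <- sum(fr$frequency[fr$cohort == "High"])
  expect_equal(tot_high, 0.3 + 0.2)

  cn0 <- tibble::tibble(gene = genes,
                        !!!stats::setNames(as.list(rep(0L, 20)), c(high, low)))
  fr0 <- alteration_frequencies(cn0, muts[0, ], asg, catalog)
  expect_true(all(fr0$frequency == 0))
})

test_that("burden comparison is a paired signed-rank over genes with exact edge cases", {
  fr <- tidyr::expand_grid(gene = paste0("G", 1:10),
                           cohort = c("High", "Low")) |>
    dplyr::mutate(class = "ERFS", alteration = "gain", n_altered = 1L,
                  n_samples = 10L, frequency = 0.1)
  res <- compare_burden(fr, "gain")
  expect_equal(res$p_value, 1)
  expect_equal(res$statistic, 0)

  set.seed(12)
  d <- runif(30, -0.2, 0.2)
  fr2 <- dplyr::bind_rows(
    tibble::tibble(gene = paste0("G", 1:30), cohort = "High", class = "E",
                   alteration = "gain", n_altered = 0L, n_samples = 1L,
                   frequency = 0.5 + d),
    tibble::tibble(gene = paste0("G", 1:30), cohort = "Low", class = "E",
                   alteration = "gain", n_altered = 0L, n_samples = 1L,
                   frequency = 0.5)
  )
  fr2_flip <- dplyr::mutate(fr2, frequency = ifelse(cohort == "High",
                                                    0.5 - d[match(gene, paste0("G", 1:30))],
                                                    0.5))
  expect_equal(compare_burden(fr2, "gain")$p_value,
               compare_burden(fr2_flip, "gain")$p_value)
})

test_that("burden comparison detects a planted +0.1 excess across 200 genes", {
  hits <- vapply(1:20, function(s) {
    set.seed(2000 + s)
    genes <- paste0("G", 1:200)
    fr <- dplyr::bind_rows(
      tibble::tibble(gene = genes, cohort = "High", class = "E",
                     alteration = "gain", n_altered = 0L, n_samples = 100L,
                     frequency = rbinom(200, 100, 0.2) / 100),
      tibble::tibble(gene = genes, cohort = "Low", class = "E",
                     alteration = "gain", n_altered = 0L, n_samples = 100L,
                     frequency = rbinom(200, 100, 0.1) / 100)
    )
    compare_burden(fr, "gain")$p_value < 0.001
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("concordant dysregulation flags exactly the constructed true positives", {
  genes <- paste0("G", 1:10)
  clusters <- tibble::tibble(gene = genes,
                             cluster_id = rep(1:5, each = 2),
                             cluster_label = paste0("C", rep(1:5, each = 2)))
  de <- tibble::tibble(
    gene = genes,
    log2fc = c(0.8, -0.7, 0.9, -0.6, 0.5, -0.5, 0.4, -0.3, 0.2, -0.1),
    p_value = 0.001,
    q_value = c(0.001, 0.001, 0.2, 0.001, 0.001, 0.001, 0.001, 0.2, 0.001, 0.001)
  )
  gain_q <- c(0.01, 0.9, 0.01, 0.9, 0.9, 0.02, 0.9, 0.9, 0.04, 0.9)
  loss_q <- c(0.9, 0.01, 0.9, 0.01, 0.9, 0.9, 0.9, 0.01, 0.9, 0.2)
  gain_enr <- tibble::tibble(gene = genes, q_value = gain_q)
  loss_enr <- tibble::tibble(gene = genes, q_value = loss_q)
  out <- concordant_dysregulation(de, gain_enr, loss_enr, clusters)
  # expectations by rule:
  # G1 up (gain q .01, lfc>0, expr q .001); G2 down; G3 not (expr q .2);
  # G4 down; G5 not (no CN signal); G6 not (gain enr but lfc<0);
  # G7 not; G8 not (expr q .2); G9 up; G10 not (loss q .2)
  expect_setequal(out$gene[out$concordant == "up"], c("G1", "G9"))
  expect_setequal(out$gene[out$concordant == "down"], c("G2", "G4"))
  expect_equal(out$cluster_id, sort(out$cluster_id))
})

test_that("shipped catalogs load and have the documented shape", {
  cat <- default_rss_catalog()
  expect_true(all(cat$class %in% c("ERFS", "MiDAS")))
  expect_false(anyDuplicated(cat$gene) > 0)
  # genes claimed by both lists resolve to MiDAS (WWOX/FHIT in both fixtures)
  expect_equal(cat$class[cat$gene %in% c("WWOX", "FHIT")], c("MiDAS", "MiDAS"))
  cl <- default_clusters()
  expect_equal(dplyr::n_distinct(cl$cluster_id), 13L)
})
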