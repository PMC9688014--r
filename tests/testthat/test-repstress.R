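test_that("RS score is the mean log2 expression over the gene list", {
  rsg <- tibble::tibble(gene = c("A", "B"))
  ex <- make_expr(c("A", "B", "C"), S1 = c(5, 5, 99), S2 = c(4, 6, -1))
  rs <- rs_score(ex, rsg)
  expect_equal(rs$rs_score, c(5, 5))

  # independent element-wise oracle on random values over the full 205-gene list
  set.seed(7)
  rsg_full <- default_rs_genes()
  samples <- paste0("S", 1:6)
  vals <- lapply(samples, function(s) rnorm(205, 8, 2))
  ex_full <- tibble::tibble(gene = rsg_full$gene, !!!stats::setNames(vals, samples))
  rs_full <- rs_score(ex_full, rsg_full)
  oracle <- vapply(vals, function(v) sum(v) / 205, numeric(1))
  expect_equal(rs_full$rs_score, oracle)

  expect_error(rs_score(ex, tibble::tibble(gene = c("A", "ZZZ"))), "ZZZ")
})

test_that("RS score is invariant to gene and sample order", {
  set.seed(8)
  genes <- paste0("G", 1:20)
  vals <- stats::setNames(lapply(1:5, function(i) rnorm(20)), paste0("S", 1:5))
  ex <- tibble::tibble(gene = genes, !!!vals)
  rsg <- tibble::tibble(gene = genes)
  base <- rs_score(ex, rsg)
  shuf <- ex[sample(20), c("gene", sample(paste0("S", 1:5)))]
  rs2 <- rs_score(shuf, rsg)
  expect_equal(dplyr::arrange(rs2, sample), dplyr::arrange(base, sample))
})

test_that("RS comparison is symmetric and detects a planted shift", {
  set.seed(9)
  scores <- tibble::tibble(sample = sprintf("S%03d", 1:60),
                           rs_score = rnorm(60, 8, 0.2))
  asg <- make_assignment(scores$sample[1:30], scores$sample[31:60])
  swapped <- make_assignment(scores$sample[31:60], scores$sample[1:30])
  expect_equal(compare_rs(scores, asg)$p_value,
               compare_rs(scores, swapped)$p_value)

  hits <- vapply(1:20, function(s) {
    co <- simulate_cohort(sim_config(n_per_arm = 100, seed = 7000 + s))
    asg <- make_assignment(co$truth$sample[co$truth$arm == "High"],
                           co$truth$sample[co$truth$arm == "Low"])
    compare_rs(rs_score(co$expression), asg)$p_value < 0.001
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("MPS formula and length classes follow the stated arithmetic", {
  ann <- tibble::tibble(gene = c("G1", "G2"), chrom = c("1", "2"),
                        start = c(1000L, 5000L), end = c(3000L, 9000L),
                        strand = c("+", "-"))
  mk_mut <- function(gene, pos) {
    tibble::tibble(sample = "S1", gene = gene, chrom = "1",
                   position = as.integer(pos), ref = "C", alt = "T",
                   variant_class = "Missense_Mutation")
  }
  # position = start -> 0; position = end -> 1
  expect_equal(mps(mk_mut("G1", 1000), ann)$mps, 0)
  expect_equal(mps(mk_mut("G1", 3000), ann)$mps, 1)
  # start 1000, length 2000, position 1500 -> 0.25, short gene
  r <- mps(mk_mut("G1", 1500), ann)
  expect_equal(r$mps, 0.25)
  expect_equal(r$length_class, "short")
  # length 4000 -> long
  expect_equal(mps(mk_mut("G2", 7000), ann)$length_class, "long")
  # boundary: length exactly 3000 is long
  ann3 <- dplyr::mutate(ann, end = dplyr::if_else(gene == "G1", 4000L, end))
  expect_equal(mps(mk_mut("G1", 2000), ann3)$length_class, "long")
  # strand orientation flips MPS for minus-strand genes when asked
  expect_equal(mps(mk_mut("G2", 6000), ann, strand_orient = TRUE)$mps, 0.75)
  expect_equal(mps(mk_mut("G2", 6000), ann)$mps, 0.25)
})

test_that("MPS is invariant to a constant coordinate shift and skips out-of-span records", {
  ann <- tibble::tibble(gene = "G", chrom = "1", start = 2000L, end = 12000L,
                        strand = "+")
  mut <- tibble::tibble(sample = "S1", gene = "G", chrom = "1",
                        position = 4500L, ref = "A", alt = "G",
                        variant_class = "Missense_Mutation")
  base <- mps(mut, ann)$mps
  shift <- 12345L
  ann2 <- dplyr::mutate(ann, start = start + shift, end = end + shift)
  mut2 <- dplyr::mutate(mut, position = position + shift)
  expect_equal(mps(mut2, ann2)$mps, base)

  bad <- dplyr::mutate(mut, position = 100L) # before gene start
  expect_message(out <- mps(bad, ann), "skipped")
  expect_equal(nrow(out), 0)
  expect_equal(attr(out, "n_outside"), 1L)
})

test_that("KS comparison equals the brute-force ECDF gap and is 0 for identical arms", {
  mk_rec <- function(samples, vals) {
    tibble::tibble(sample = samples, gene = "G", mps = vals, length_class = "long")
  }
  set.seed(10)
  v <- runif(12)
  rec <- dplyr::bind_rows(mk_rec(rep("H1", 12), v), mk_rec(rep("L1", 12), v))
  asg <- make_assignment("H1", "L1")
  expect_equal(compare_mps(rec, asg, "long")$statistic, 0)

  va <- runif(15); vb <- runif(20)
  rec2 <- dplyr::bind_rows(mk_rec(rep("H1", 15), va), mk_rec(rep("L1", 20), vb))
  d <- compare_mps(rec2, asg, "long")$statistic
  # brute-force max ECDF gap over the pooled support
  grid <- sort(c(va, vb))
  oracle <- max(abs(vapply(grid, function(x) mean(va <= x) - mean(vb <= x),
                           numeric(1))))
  expect_equal(d, oracle, tolerance = 1e-12)

  expect_error(compare_mps(rec2[1:15, ], asg, "long"), ">= 10")
})

test_that("KS detects Beta(1,1) vs Beta(3,3) position distributions", {
  hits <- vapply(1:20, function(s) {
    set.seed(1000 + s)
    rec <- dplyr::bind_rows(
      tibble::tibble(sample = "H1", gene = "G", mps = rbeta(500, 3, 3),
                     length_class = "long"),
      tibble::tibble(sample = "L1", gene = "G", mps = rbeta(500, 1, 1),
                     length_class = "long")
    )
    compare_mps(rec, make_assignment("H1", "L1"), "long")$p_value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
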