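#' Configuration for the synthetic cohort generator
#'
#' Builds the configuration object consumed by [simulate_cohort()]. Defaults
#' describe a two-arm cohort with planted replicative-instability structure:
#' a strong MYBL2 expression shift separating the arms, a survival
#' disadvantage (hazard ratio 2.5) in the High arm, enriched heterozygous
#' losses of key repair effectors, elevated replication-stress gene
#' expression, arm-specific intragenic mutation-position distributions,
#' excess gains/losses at replication-stress sensitive (RSS) sites, a
#' microhomology-shifted fusion junction distribution, and a brain-tropic
#' metastasis pattern. [sim_config_null()] zeroes every planted effect, making
#' the two arms exchangeable — the configuration used for calibration checks.
#'
#' @param n_per_arm Samples per arm.
#' @param seed Integer seed; all randomness in [simulate_cohort()] flows from it.
#' @param background_genes Number of filler genes beyond the fixture gene sets.
#' @param expr_sd Gaussian noise SD on the log2 expression scale.
#' @param baseline_mean,baseline_sd Per-gene baseline log2 expression levels.
#' @param mybl2_shift Log2 shift added to MYBL2 in the planted High arm.
#' @param rs_shift Log2 shift added to replication-stress genes in High.
#' @param pathway_shift Named log2 shifts applied to repair pathway genes in
#'   High (names are registry pathway names).
#' @param base_hazard Baseline event hazard (events/day) in the Low arm.
#' @param hr_high Named hazard ratios (High vs Low) for `os`, `dss`, `pfs`.
#' @param censor_max Independent uniform censoring horizon (days).
#' @param treatment_probs Named probabilities for treatment labels.
#' @param repair_effectors Genes receiving arm-specific heterozygous-loss rates.
#' @param effector_hetloss_prob Named (`High`, `Low`) heterozygous-loss
#'   probabilities for `repair_effectors`.
#' @param cn_base_probs Baseline probabilities of calls `-2,-1,0,1,2`.
#' @param rss_gain_excess,rss_hetloss_excess Probability added to gain /
#'   heterozygous-loss calls of RSS catalog genes in the High arm.
#' @param hetloss_expr_shift Log2 downshift of expression per lost copy.
#' @param gain_expr_shift Log2 upshift of expression per gained copy.
#' @param mut_rate Expected somatic mutations per sample (Poisson).
#' @param mps_beta Beta parameters of relative mutation position, a list
#'   `list(High = list(long =, short =), Low = ...)` of length-2 vectors.
#' @param long_threshold Gene length (bp) separating long from short genes.
#' @param fusion_rate Expected fusions per sample (Poisson).
#' @param mmej_prob Named probability that a fusion junction is
#'   microhomology-mediated (2-20 bp homology) per arm.
#' @param ssa_prob Probability of a long-homology (>20 bp) junction.
#' @param p_met Named probability of developing any metastasis per arm.
#' @param brain_given_met Named probability the first metastatic site is brain,
#'   given metastasis.
#' @param met_sites Non-brain metastatic site vocabulary.
#' @param met_hazard Hazard (1/days) of the first metastasis time.
#' @param extra_site_rate Poisson rate of additional metastatic sites.
#' @param ... Ignored; present so configs can be built programmatically.
#' @return A list of class `rin_sim_config`.
#' @export
sim_config <- function(n_per_arm = 100,
                       seed = 1,
                       background_genes = 50,
                       expr_sd = 1.0,
                       baseline_mean = 8,
                       baseline_sd = 1.5,
                       mybl2_shift = 4,
                       rs_shift = 0.5,
                       pathway_shift = c(TLS = -0.5, NER = -0.5, NHEJ = -0.5,
                                         checkpoint = 0.5, FA = 0.3, MMEJ = 0.3),
                       base_hazard = 1 / 2000,
                       hr_high = c(os = 2.5, dss = 2.5, pfs = 2.5),
                       censor_max = 3650,
                       treatment_probs = c(chemotherapy = 0.4, irradiation = 0.2,
                                           none = 0.4),
                       repair_effectors = c("XPC", "POLK", "LIG4", "ATM", "TP53BP1"),
                       effector_hetloss_prob = c(High = 0.35, Low = 0.05),
                       cn_base_probs = c(`-2` = 0.01, `-1` = 0.05, `0` = 0.88,
                                         `1` = 0.05, `2` = 0.01),
                       rss_gain_excess = 0.1,
                       rss_hetloss_excess = 0.1,
                       hetloss_expr_shift = 1.0,
                       gain_expr_shift = 0.5,
                       mut_rate = 30,
                       mps_beta = list(
                         High = list(long = c(0.7, 0.7), short = c(3, 3)),
                         Low = list(long = c(1, 1), short = c(1, 1))
                       ),
                       long_threshold = 3000,
                       fusion_rate = 1,
                       mmej_prob = c(High = 0.6, Low = 0.2),
                       ssa_prob = 0.05,
                       p_met = c(High = 0.6, Low = 0.3),
                       brain_given_met = c(High = 0.4, Low = 0.1),
                       met_sites = c("bone", "liver", "lung", "adrenal",
                                     "intrathoracic_lymph_nodes",
                                     "axillary_lymph_nodes"),
                       met_hazard = 1 / 500,
                       extra_site_rate = 0.5,
                       ...) {
  cfg <- list(
    n_per_arm = n_per_arm, seed = seed, background_genes = background_genes,
    expr_sd = expr_sd, baseline_mean = baseline_mean, baseline_sd = baseline_sd,
    mybl2_shift = mybl2_shift, rs_shift = rs_shift, pathway_shift = pathway_shift,
    base_hazard = base_hazard, hr_high = hr_high, censor_max = censor_max,
    treatment_probs = treatment_probs, repair_effectors = repair_effectors,
    effector_hetloss_prob = effector_hetloss_prob, cn_base_probs = cn_base_probs,
    rss_gain_excess = rss_gain_excess, rss_hetloss_excess = rss_hetloss_excess,
    hetloss_expr_shift = hetloss_expr_shift, gain_expr_shift = gain_expr_shift,
    mut_rate = mut_rate, mps_beta = mps_beta, long_threshold = long_threshold,
    fusion_rate = fusion_rate, mmej_prob = mmej_prob, ssa_prob = ssa_prob,
    p_met = p_met, brain_given_met = brain_given_met, met_sites = met_sites,
    met_hazard = met_hazard, extra_site_rate = extra_site_rate
  )
  validate_sim_config(cfg)
  structure(cfg, class = "rin_sim_config")
}

#' @rdname sim_config
#' @export
sim_config_null <- function(n_per_arm = 100, seed = 1, ...) {
  null_args <- list(
    n_per_arm = n_per_arm, seed = seed,
    mybl2_shift = 0, rs_shift = 0,
    pathway_shift = c(TLS = 0, NER = 0, NHEJ = 0, checkpoint = 0, FA = 0, MMEJ = 0),
    hr_high = c(os = 1, dss = 1, pfs = 1),
    effector_hetloss_prob = c(High = 0.05, Low = 0.05),
    rss_gain_excess = 0, rss_hetloss_excess = 0,
    hetloss_expr_shift = 0, gain_expr_shift = 0,
    mps_beta = list(High = list(long = c(1, 1), short = c(1, 1)),
                    Low = list(long = c(1, 1), short = c(1, 1))),
    mmej_prob = c(High = 0.2, Low = 0.2),
    p_met = c(High = 0.3, Low = 0.3),
    brain_given_met = c(High = 0.1, Low = 0.1)
  )
  user <- list(...)
  null_args[names(user)] <- user
  do.call(sim_config, null_args)
}

validate_sim_config <- function(cfg) {
  probs <- c(cfg$effector_hetloss_prob, cfg$cn_base_probs, cfg$mmej_prob,
             cfg$ssa_prob, cfg$p_met, cfg$brain_given_met, cfg$treatment_probs,
             cfg$rss_gain_excess, cfg$rss_hetloss_excess)
  if (any(probs < 0 | probs > 1)) abort("sim config: probabilities must lie in [0, 1]")
  if (cfg$base_hazard <= 0 || any(cfg$hr_high <= 0) || cfg$met_hazard <= 0) {
    abort("sim config: hazards must be > 0")
  }
  betas <- unlist(cfg$mps_beta)
  if (any(betas <= 0)) abort("sim config: Beta parameters must be > 0")
  if (cfg$n_per_arm < 2) abort("sim config: need at least 2 samples per arm")
  if (abs(sum(cfg$cn_base_probs) - 1) > 1e-8) {
    abort("sim config: cn_base_probs must sum to 1")
  }
  invisible(cfg)
}

# run code with a locally-seeded RNG, restoring any prior state
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

sim_gene_universe <- function(cfg) {
  reg <- default_pathways()
  rs <- default_rs_genes()
  erfs <- readr::read_tsv(rin_extdata("erfs_synthetic.tsv"),
                          col_types = "c", progress = FALSE)$gene
  midas <- readr::read_tsv(rin_extdata("midas_sites_synthetic.tsv"),
                           col_types = "cc", progress = FALSE)$gene
  bg <- sprintf("BG%03d", seq_len(cfg$background_genes))
  list(
    genes = unique(c("MYBL2", reg$gene, rs$gene, erfs, midas, bg)),
    registry = reg, rs_genes = rs$gene,
    rss_genes = unique(c(erfs, midas))
  )
}

#' Simulate a complete multi-omics cohort with planted RIN structure
#'
#' Generates every table the pipeline consumes — expression, somatic
#' mutations, thresholded copy number, gene annotation, clinical endpoints
#' with metastasis records, and fusion junctions — for a two-arm cohort whose
#' arm labels are returned in `truth`. All effects are planted per the
#' configuration; with [sim_config_null()] the arms are exchangeable and every
#' downstream two-arm test has its null distribution.
#'
#' Generative model, in order: gene annotation (chromosome, strand, span;
#' gene lengths mixed across the long/short boundary); per-gene copy-number
#' call probabilities (baseline, plus arm-specific heterozygous-loss rates
#' for repair effectors and gain/loss excess at RSS genes), drawn
#' independently per gene and sample; log2 expression as per-gene baseline +
#' arm shifts + copy-number coupling (configurable down/up shift per
#' lost/gained copy) + Gaussian noise; survival times exponential per arm
#' with independent uniform censoring; mutation positions placed as
#' `start + round(u * length)` with `u ~ Beta(arm, length class)`; fusion
#' junctions drawn from an arm-specific microhomology mixture (never
#' microhomology and insertion both positive); metastasis as Bernoulli
#' any-met, a site draw with arm-specific brain tropism, and exponential
#' first-met times.
#'
#' @param config A [sim_config()] object.
#' @return Named list with `expression`, `mutations`, `copy_number`,
#'   `annotation`, `clinical`, `fusions`, and `truth` (tibble of `sample`,
#'   `arm`). All tables pass their validators.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "rin_sim_config"))
  validate_sim_config(config)
  with_local_seed(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(cfg) {
  uni <- sim_gene_universe(cfg)
  genes <- uni$genes
  n <- cfg$n_per_arm
  samples <- sprintf("S%04d", seq_len(2 * n))
  arm <- rep(c("High", "Low"), each = n)
  truth <- tibble(sample = samples, arm = arm)

  # annotation: ~half short (<3000 bp), half long, log-uniform long lengths
  is_long <- runif(length(genes)) < 0.5
  len <- ifelse(is_long,
                round(exp(runif(length(genes), log(3100), log(2e5)))),
                round(runif(length(genes), 500, 2900)))
  start <- sample.int(1e8, length(genes)) + 1e6
  annotation <- validate_annotation(tibble(
    gene = genes, chrom = as.character(sample(1:22, length(genes), replace = TRUE)),
    start = as.integer(start), end = as.integer(start + len),
    strand = sample(c("+", "-"), length(genes), replace = TRUE)
  ))

  # copy number: per-gene x arm call probabilities
  base <- cfg$cn_base_probs
  prob_for <- function(gene, arm_label) {
    p <- base
    if (gene %in% cfg$repair_effectors) {
      p["-1"] <- cfg$effector_hetloss_prob[[arm_label]]
    }
    if (arm_label == "High" && gene %in% uni$rss_genes) {
      p["1"] <- p["1"] + cfg$rss_gain_excess
      p["-1"] <- p["-1"] + cfg$rss_hetloss_excess
    }
    p["0"] <- 1 - sum(p[c("-2", "-1", "1", "2")])
    if (p["0"] < 0) abort("sim config: per-gene call probabilities exceed 1")
    p
  }
  calls <- matrix(0L, nrow = length(genes), ncol = 2 * n,
                  dimnames = list(genes, samples))
  states <- c(-2L, -1L, 0L, 1L, 2L)
  for (a in c("High", "Low")) {
    idx <- which(arm == a)
    # genes sharing a probability vector are drawn in one call
    pmat <- vapply(genes, function(g) prob_for(g, a)[c("-2", "-1", "0", "1", "2")],
                   numeric(5))
    key <- apply(pmat, 2, paste, collapse = ",")
    for (k in unique(key)) {
      gi <- which(key == k)
      p <- pmat[, gi[1]]
      calls[gi, idx] <- sample(states, length(gi) * length(idx),
                               replace = TRUE, prob = p)
    }
  }
  copy_number <- as_tibble(cbind(tibble(gene = genes), as.data.frame(calls)))
  copy_number <- validate_copy_number(copy_number)

  # expression: baseline + arm shifts + CN coupling + noise
  baseline <- rnorm(length(genes), cfg$baseline_mean, cfg$baseline_sd)
  shift <- setNames(numeric(length(genes)), genes)
  shift["MYBL2"] <- shift["MYBL2"] + cfg$mybl2_shift
  shift[names(shift) %in% uni$rs_genes] <-
    shift[names(shift) %in% uni$rs_genes] + cfg$rs_shift
  for (pw in names(cfg$pathway_shift)) {
    pw_genes <- uni$registry$gene[uni$registry$pathway == pw]
    shift[names(shift) %in% pw_genes] <-
      shift[names(shift) %in% pw_genes] + cfg$pathway_shift[[pw]]
  }
  expr_mat <- matrix(rnorm(length(genes) * 2 * n, sd = cfg$expr_sd),
                     nrow = length(genes), dimnames = list(genes, samples))
  expr_mat <- expr_mat + baseline
  expr_mat[, arm == "High"] <- expr_mat[, arm == "High"] + shift
  expr_mat <- expr_mat - cfg$hetloss_expr_shift * pmax(-calls, 0) +
    cfg$gain_expr_shift * pmax(calls, 0)
  expression <- as_tibble(cbind(tibble(gene = genes), as.data.frame(expr_mat)))
  expression <- validate_expression(expression)

  # survival + treatment + metastasis
  clin <- tibble(patient = samples)
  for (ep in c("os", "dss", "pfs")) {
    rate <- ifelse(arm == "High", cfg$base_hazard * cfg$hr_high[[ep]], cfg$base_hazard)
    t_event <- rexp(2 * n, rate)
    t_cens <- runif(2 * n, 0, cfg$censor_max)
    clin[[paste0(ep, "_time")]] <- round(pmin(t_event, t_cens), 1)
    clin[[paste0(ep, "_event")]] <- as.numeric(t_event <= t_cens)
  }
  clin$treatment <- sample(names(cfg$treatment_probs), 2 * n, replace = TRUE,
                           prob = cfg$treatment_probs)
  p_met_i <- ifelse(arm == "High", cfg$p_met[["High"]], cfg$p_met[["Low"]])
  has_met <- runif(2 * n) < p_met_i
  p_brain_i <- ifelse(arm == "High", cfg$brain_given_met[["High"]],
                      cfg$brain_given_met[["Low"]])
  first_brain <- runif(2 * n) < p_brain_i
  empty_mets <- tibble(site = character(), time = numeric())
  clin$mets <- purrr::map(seq_len(2 * n), function(i) {
    if (!has_met[i]) return(empty_mets)
    first_site <- if (first_brain[i]) "brain" else sample(cfg$met_sites, 1)
    extra <- min(rpois(1, cfg$extra_site_rate), length(cfg$met_sites))
    sites <- c(first_site,
               sample(setdiff(c("brain", cfg$met_sites), first_site), extra))
    t0 <- rexp(1, cfg$met_hazard)
    times <- round(t0 + c(0, cumsum(rexp(extra, cfg$met_hazard))), 1)
    tibble(site = sites, time = times)
  })
  clinical <- validate_clinical(clin)

  # somatic mutations: positions via Beta(arm, length class)
  ann_len <- setNames(annotation$length, annotation$gene)
  ann_start <- setNames(annotation$start, annotation$gene)
  n_mut <- rpois(2 * n, cfg$mut_rate)
  mut_sample <- rep(samples, n_mut)
  mut_arm <- rep(arm, n_mut)
  total <- sum(n_mut)
  mut_gene <- sample(genes, total, replace = TRUE)
  gl <- ann_len[mut_gene]
  class_long <- gl >= cfg$long_threshold
  u <- numeric(total)
  for (a in c("High", "Low")) {
    for (cl in c("long", "short")) {
      sel <- mut_arm == a & (class_long == (cl == "long"))
      if (any(sel)) {
        b <- cfg$mps_beta[[a]][[cl]]
        u[sel] <- rbeta(sum(sel), b[1], b[2])
      }
    }
  }
  pos <- ann_start[mut_gene] + round(u * gl)
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, total, replace = TRUE)
  # alt: cyclic offset of 1..3 from ref, never equal to ref
  alt <- bases[(match(ref, bases) - 1L +
                  sample.int(3, total, replace = TRUE)) %% 4L + 1L]
  vclasses <- c("Missense_Mutation", "Silent", "Nonsense_Mutation", "Splice_Site",
                "Frame_Shift_Del", "Intron", "3'UTR")
  vprob <- c(0.55, 0.2, 0.05, 0.05, 0.05, 0.05, 0.05)
  mutations <- validate_mutations(tibble(
    sample = mut_sample, gene = mut_gene,
    chrom = annotation$chrom[match(mut_gene, annotation$gene)],
    position = as.integer(pos), ref = ref, alt = alt,
    variant_class = sample(vclasses, total, replace = TRUE, prob = vprob)
  ))

  # fusions: arm-specific junction microhomology mixture
  n_fus <- rpois(2 * n, cfg$fusion_rate)
  fus_sample <- rep(samples, n_fus)
  fus_arm <- rep(arm, n_fus)
  nf <- sum(n_fus)
  p_m <- ifelse(fus_arm == "High", cfg$mmej_prob[["High"]], cfg$mmej_prob[["Low"]])
  u_cat <- runif(nf)
  is_mmej <- u_cat < p_m
  is_ssa <- !is_mmej & u_cat < p_m + cfg$ssa_prob
  mh <- integer(nf)
  ins <- integer(nf)
  mh[is_mmej] <- sample(2:20, sum(is_mmej), replace = TRUE)
  mh[is_ssa] <- sample(21:60, sum(is_ssa), replace = TRUE)
  nhej <- !is_mmej & !is_ssa
  blunt <- nhej & runif(nf) < 0.5
  mh[blunt] <- sample(0:1, sum(blunt), replace = TRUE)
  insrt <- nhej & !blunt
  ins[insrt] <- sample(1:10, sum(insrt), replace = TRUE)
  ga <- sample(genes, nf, replace = TRUE)
  gb <- sample(genes, nf, replace = TRUE)
  while (any(gb == ga)) { # resample self-fusions
    clash <- gb == ga
    gb[clash] <- sample(genes, sum(clash), replace = TRUE)
  }
  fusions <- validate_fusions(tibble(
    sample = fus_sample, gene_a = ga, gene_b = gb,
    chrom_a = annotation$chrom[match(ga, annotation$gene)],
    pos_a = as.integer(ann_start[ga] + sample.int(1000, nf, replace = TRUE)),
    chrom_b = annotation$chrom[match(gb, annotation$gene)],
    pos_b = as.integer(ann_start[gb] + sample.int(1000, nf, replace = TRUE)),
    microhomology = mh, insertion = ins
  ))

  list(expression = expression, mutations = mutations,
       copy_number = copy_number, annotation = annotation,
       clinical = clinical, fusions = fusions, truth = truth)
}

#' Write or read a simulated cohort as a directory of TSV files
#'
#' @param cohort A list as returned by [simulate_cohort()].
#' @param dir Directory to write to / read from.
#' @return `write_cohort` returns `dir` invisibly; `read_cohort` the cohort list.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_expression(cohort$expression, file.path(dir, "expression.tsv"))
  write_maf(cohort$mutations, file.path(dir, "mutations.maf.tsv"))
  write_copy_number(cohort$copy_number, file.path(dir, "copy_number.tsv"))
  write_annotation(cohort$annotation, file.path(dir, "annotation.tsv"))
  write_clinical(cohort$clinical, file.path(dir, "clinical.tsv"))
  write_fusions(cohort$fusions, file.path(dir, "fusions.tsv"))
  readr::write_tsv(cohort$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  list(
    expression = read_expression(file.path(dir, "expression.tsv")),
    mutations = read_maf(file.path(dir, "mutations.maf.tsv")),
    copy_number = read_copy_number(file.path(dir, "copy_number.tsv")),
    annotation = read_annotation(file.path(dir, "annotation.tsv")),
    clinical = read_clinical(file.path(dir, "clinical.tsv")),
    fusions = read_fusions(file.path(dir, "fusions.tsv")),
    truth = readr::read_tsv(file.path(dir, "truth.tsv"), col_types = "cc",
                            progress = FALSE)
  )
}
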