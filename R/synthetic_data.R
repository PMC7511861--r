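# Synthetic BXD-like cohort generator with known ground truth.
#
# The generator produces, in order: region definitions, a cohort (sample
# covariates + a parallel longevity cohort), a region x sample methylome
# with planted age-/BW0-/LS-DMRs, and matched expression for a subset of
# samples. Every stage is deterministic given the seed carried in the
# config, so downstream recovery tests are exactly reproducible.

# Default strain-by-diet layout: 12 strains (two F1 hybrids, ten inbred
# lines), five strains carrying a matched high-fat-diet group -> 17 groups,
# 69 biospecimen samples. Group mean/SD life spans, biospecimen n and age
# ranges follow the published BXD cohort layout.
default_group_table <- function() {
  df <- utils::read.table(header = TRUE, stringsAsFactors = FALSE, text = "
strain   diet mean_ls sd_ls n age_min age_max
B6D2F1   CD   933     86    5 216 726
BXD102   CD   861     222   5 183 714
BXD40    CD   585     239   8 284 719
BXD48    CD   695     124   3 188 731
BXD48    HFD  523     152   3 189 595
BXD48a   CD   617     196   3 233 604
BXD48a   HFD  635     113   3 233 543
BXD65    CD   824     199   6 181 711
BXD65    HFD  534     128   2 230 541
BXD65b   CD   726     91    4 187 748
BXD73    CD   702     116   4 206 759
BXD73    HFD  699     112   3 206 694
BXD73b   CD   820     129   3 237 743
BXD73b   HFD  742     193   3 237 729
BXD79    CD   417     155   7 217 570
BXD9     CD   507     135   3 245 548
D2B6F1   CD   771     143   4 210 744
")
  df
}

#' Simulation configuration
#'
#' Collects every knob of the synthetic-cohort generator with defaults that
#' emulate the study cohort: 17 strain-by-diet groups over 12 strains, 69
#' samples, collection ages 181-759 days, group mean life spans ~417-933
#' days, 17 percent of bins carrying sequence variants, and planted DMR
#' effects whose directions are coupled to CpG density and baseline
#' methylation.
#'
#' @param n_regions number of 150-bp bins (default 10000)
#' @param group_table strain-by-diet layout (strain, diet, mean_ls, sd_ls,
#'   n, age_min, age_max); default mirrors the published cohort
#' @param n_longevity_per_group animals per group in the parallel longevity
#'   cohort (default 13)
#' @param frac_variant_regions fraction of bins containing variants (0.17)
#' @param frac_island fraction of bins drawn from the CpG-dense island-like
#'   mixture component (0.2)
#' @param frac_age_dmr,frac_bw_dmr,frac_ls_dmr planted DMR fractions
#' @param beta_age_scale,beta_bw_scale,beta_ls_scale effect-size scales
#'   (methylation log10 units per day, per gram, per day of median life
#'   span respectively)
#' @param bw_neg_prob probability a planted BW0-DMR is hypomethylated with
#'   higher weight (default 0.75)
#' @param tau random-intercept SD per strain-by-diet group per region
#' @param sigma residual SD
#' @param bw0_age_slope grams of baseline weight per day of age at weighing
#' @param bw0_ls_coupling grams of strain-mean baseline weight per day of
#'   strain mean life span (negative: heavier strains shorter-lived)
#' @param hfd_weight_gain_g mean final-weight gain on HFD (grams)
#' @param hfd_ls_penalty additive HFD life-span penalty in days, applied
#'   when `group_table` lacks explicit HFD means (default 0; the default
#'   layout already encodes diet-specific means)
#' @param ls_accel_strength strength of life-span-coupled epigenetic aging
#'   rate: the effective age multiplier is
#'   1 + ls_accel_strength x (mean LS of cohort - group mean LS)/(mean LS)
#' @param hfd_accel additive aging-rate increment for HFD groups (default
#'   0.12)
#' @param n_expression samples with matched expression (default 52)
#' @param cis_strength magnitude of the cis methylation->expression slope
#' @param expr_noise_sd expression residual SD
#' @param frac_male fraction of male samples (default 0: all-female cohort)
#' @param seed integer RNG seed
#' @return list of class `"sim_config"`
#' @export
simulation_config <- function(n_regions = 10000,
                              group_table = default_group_table(),
                              n_longevity_per_group = 13,
                              frac_variant_regions = 0.17,
                              frac_island = 0.2,
                              frac_age_dmr = 0.03,
                              frac_bw_dmr = 0.02,
                              frac_ls_dmr = 0.01,
                              beta_age_scale = 0.0012,
                              beta_bw_scale = 0.03,
                              beta_ls_scale = 0.0012,
                              bw_neg_prob = 0.75,
                              tau = 0.10,
                              sigma = 0.15,
                              bw0_age_slope = 0.03,
                              bw0_ls_coupling = -0.012,
                              hfd_weight_gain_g = 15,
                              hfd_ls_penalty = 0,
                              ls_accel_strength = 0.5,
                              hfd_accel = 0.12,
                              n_expression = 52,
                              cis_strength = 0.8,
                              expr_noise_sd = 0.4,
                              frac_male = 0,
                              seed = 1L) {
  cfg <- as.list(environment())
  fr <- c("frac_variant_regions", "frac_island", "frac_age_dmr",
          "frac_bw_dmr", "frac_ls_dmr", "bw_neg_prob", "frac_male")
  for (f in fr)
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(f, " must lie in [0, 1]")
  if (cfg$tau < 0 || cfg$sigma < 0) stop("SDs must be non-negative")
  if (cfg$n_regions < 100) stop("n_regions must be >= 100")
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a region set
#'
#' CpG counts come from a two-component mixture (island-like dense bins vs
#' low-density background); a configurable fraction of bins carries 1+
#' segregating variants; feature labels are assigned so genic bins (with a
#' gene_id) and intergenic bins partition the set, with CpG-island labels
#' concentrated in the dense component.
#'
#' @param config `simulation_config()`
#' @return region set of `config$n_regions` bins
#' @export
simulate_regions <- function(config) {
  set.seed(config$seed)
  n <- config$n_regions
  chrom <- paste0("chr", sample(1:19, n, replace = TRUE))
  # sequential non-overlapping placement per chromosome
  start <- integer(n)
  for (ch in unique(chrom)) {
    i <- which(chrom == ch)
    gaps <- sample(150:5000, length(i), replace = TRUE)
    start[i] <- cumsum(gaps) + 3e6L
  }
  island <- stats::runif(n) < config$frac_island
  cpg <- ifelse(island, stats::rpois(n, 14) + 4L, stats::rpois(n, 3))
  has_var <- stats::runif(n) < config$frac_variant_regions
  variant_count <- ifelse(has_var, 1L + stats::rpois(n, 1), 0L)

  genic <- stats::runif(n) < 0.62
  labs <- character(n)
  gene_pool <- sprintf("gene%05d", seq_len(max(50, round(n * 0.4))))
  gene_id <- character(n)
  for (i in seq_len(n)) {
    if (genic[i]) {
      l <- sample(GENE_FEATURES, 1 + stats::rbinom(1, 1, 0.2),
                  prob = c(0.15, 0.3, 0.45, 0.1))
      if (island[i] && stats::runif(1) < 0.7) l <- c(l, "cpg_island")
      gene_id[i] <- sample(gene_pool, 1)
    } else {
      l <- "intergenic"
      if (island[i] && stats::runif(1) < 0.2) l <- c(l, "cpg_island")
      if (stats::runif(1) < 0.04) l <- c(l, sample(c("rRNA", "LTR"), 1))
    }
    labs[i] <- paste(unique(l), collapse = ";")
  }
  region_set(data.frame(
    chrom = chrom, start = start, end = start + BIN_LENGTH,
    region_id = sprintf("bin%06d", seq_len(n)),
    cpg_count = cpg, variant_count = variant_count,
    feature_labels = labs, gene_id = gene_id,
    stringsAsFactors = FALSE))
}

#' Simulate the cohort (sample covariates + longevity cohort)
#'
#' Life spans for the parallel longevity cohort are drawn per group around
#' the configured means; baseline body weight (BW0) is strain effect +
#' slope x age-at-weighing + noise, with the strain effect negatively
#' coupled to strain mean life span; final weight adds a diet effect on
#' HFD. Collection ages are uniform over each group's configured range, so
#' the age distribution is balanced across life-span classes.
#'
#' @param config `simulation_config()`
#' @return list(samples = sample table, longevity = longevity table)
#' @export
simulate_cohort <- function(config) {
  set.seed(config$seed + 1L)
  gt <- config$group_table
  gt$mean_ls <- gt$mean_ls - config$hfd_ls_penalty * (gt$diet == "HFD")

  longevity <- do.call(rbind, lapply(seq_len(nrow(gt)), function(i) {
    ls <- stats::rnorm(config$n_longevity_per_group, gt$mean_ls[i], gt$sd_ls[i])
    ls <- pmax(ls, 60)
    data.frame(strain = gt$strain[i], diet = gt$diet[i], lifespan_days = ls,
               stringsAsFactors = FALSE)
  }))

  strains <- unique(gt$strain)
  strain_mean_ls <- vapply(strains, function(s)
    mean(gt$mean_ls[gt$strain == s & gt$diet == "CD"]), numeric(1))
  # strain-level BW0 intercept, inversely coupled to life span
  strain_bw <- 22 + config$bw0_ls_coupling *
    (strain_mean_ls - mean(strain_mean_ls)) +
    stats::rnorm(length(strains), 0, 1.5)
  names(strain_bw) <- strains

  rows <- lapply(seq_len(nrow(gt)), function(i) {
    n <- gt$n[i]
    age <- round(stats::runif(n, gt$age_min[i], gt$age_max[i]))
    bw0_age <- round(pmin(pmax(stats::rnorm(n, 134, 60), 40), age - 30))
    bw0 <- strain_bw[gt$strain[i]] + config$bw0_age_slope * bw0_age +
      stats::rnorm(n, 0, 1.8)
    hfd <- gt$diet[i] == "HFD"
    final_w <- bw0 + 3 + (if (hfd) config$hfd_weight_gain_g else 0) +
      stats::rnorm(n, 0, if (hfd) 6 else 3)
    data.frame(
      strain = gt$strain[i], diet = gt$diet[i],
      sex = ifelse(stats::runif(n) < config$frac_male, "M", "F"),
      age_days = age, bw0_g = round(bw0, 1), bw0_age_days = bw0_age,
      final_weight_g = round(final_w, 1),
      liver_weight_g = round(1.22 + 0.07 * hfd + stats::rnorm(n, 0, 0.2), 2),
      days_on_hfd = if (hfd) age - bw0_age else 0L,
      stringsAsFactors = FALSE)
  })
  samples <- do.call(rbind, rows)
  samples <- cbind(sample_id = sprintf("S%03d", seq_len(nrow(samples))),
                   samples, stringsAsFactors = FALSE)
  samples <- validate_sample_table(samples)
  list(samples = samples, longevity = longevity)
}

# per-group effective aging rate: short-lived strains and HFD groups age
# faster epigenetically
aging_rate <- function(samples, longevity, config) {
  ls <- lifespan_summary(longevity)
  mls <- ls$mean_ls[match(samples$group, ls$group)]
  rate <- 1 + config$ls_accel_strength * (mean(mls) - mls) / mean(mls) +
    config$hfd_accel * (samples$diet == "HFD")
  pmax(rate, 0.05)
}

#' Simulate the methylome with planted DMRs
#'
#' Per region j and sample i:
#' value_ij = mu_j + beta_age_j * age*_i + beta_bw_j * BW0*_i +
#'            beta_ls_j * medianLS*_g(i) + u_gj + eps_ij,
#' where starred covariates are cohort-centered (so mu_j is the region's
#' expected methylation at average age/weight/life span and matches its
#' observed mean), age*_i additionally carries the per-sample aging rate
#' rate_g(i), u ~ N(0, tau^2) per strain-by-diet group per region and
#' eps ~ N(0, sigma^2). `rate_g` plants strain- and diet-dependent
#' epigenetic aging rates (see `simulation_config`). Planted age-DMRs are
#' hypermethylated with probability increasing in CpG density and
#' decreasing in baseline methylation; planted BW0-DMRs are hypomethylated
#' with higher weight with probability `bw_neg_prob`. Non-DMR bins carry
#' exactly zero coefficients.
#'
#' @param regions region set from `simulate_regions`
#' @param samples,longevity cohort from `simulate_cohort`
#' @param config `simulation_config()`
#' @return list(methylome = region x sample matrix, truth = list(regions =
#'   per-region true coefficients and flags, groups = per-group true
#'   intercept-free summaries, rate = per-sample aging rate))
#' @export
simulate_methylome <- function(regions, samples, longevity, config) {
  set.seed(config$seed + 2L)
  n_r <- nrow(regions)
  n_s <- nrow(samples)
  if (n_r != config$n_regions)
    stop("regions/config dimension mismatch")
  ls <- lifespan_summary(longevity)
  med_ls <- ls$median_ls[match(samples$group, ls$group)]
  if (anyNA(med_ls)) stop("longevity table missing groups present in samples")

  # baseline methylation: CpG-dense bins start low (island-like)
  mu <- 1.6 - 0.55 * log1p(regions$cpg_count) + stats::rnorm(n_r, 0, 0.25)

  n_age <- round(config$frac_age_dmr * n_r)
  n_bw <- round(config$frac_bw_dmr * n_r)
  n_ls <- round(config$frac_ls_dmr * n_r)
  idx <- sample.int(n_r, n_age + n_bw + n_ls)
  age_idx <- idx[seq_len(n_age)]
  bw_idx <- idx[n_age + seq_len(n_bw)]
  ls_idx <- idx[n_age + n_bw + seq_len(n_ls)]

  beta_age <- beta_bw <- beta_ls <- numeric(n_r)
  # hypermethylation probability rises with CpG density, falls with baseline
  if (n_age) {
    z <- 0.35 * (regions$cpg_count[age_idx] - mean(regions$cpg_count)) -
      2.5 * (mu[age_idx] - mean(mu))
    p_pos <- stats::plogis(z)
    sgn <- ifelse(stats::runif(n_age) < p_pos, 1, -1)
    beta_age[age_idx] <- sgn * config$beta_age_scale *
      stats::runif(n_age, 0.6, 1.4)
  }
  if (n_bw) {
    sgn <- ifelse(stats::runif(n_bw) < config$bw_neg_prob, -1, 1)
    beta_bw[bw_idx] <- sgn * config$beta_bw_scale * stats::runif(n_bw, 0.6, 1.4)
  }
  if (n_ls) {
    sgn <- ifelse(stats::runif(n_ls) < 0.5, 1, -1)
    beta_ls[ls_idx] <- sgn * config$beta_ls_scale * stats::runif(n_ls, 0.6, 1.4)
  }

  rate <- aging_rate(samples, longevity, config)
  eff_age <- samples$age_days * rate
  # covariates enter centered so mu_j stays the region's methylation at
  # cohort-average age/weight/life span (and hence its observed mean)
  eff_age <- eff_age - mean(eff_age)
  bw0_c <- samples$bw0_g - mean(samples$bw0_g)
  med_ls_c <- med_ls - mean(med_ls)

  groups <- sort(unique(samples$group))
  gi <- match(samples$group, groups)
  u <- matrix(stats::rnorm(n_r * length(groups), 0, config$tau),
              n_r, length(groups))
  eps <- matrix(stats::rnorm(n_r * n_s, 0, config$sigma), n_r, n_s)

  m <- mu +
    outer(beta_age, eff_age) +
    outer(beta_bw, bw0_c) +
    outer(beta_ls, med_ls_c) +
    u[, gi, drop = FALSE] + eps
  dimnames(m) <- list(regions$region_id, samples$sample_id)

  truth_regions <- data.frame(
    region_id = regions$region_id, mu = mu,
    beta_age = beta_age, beta_bw = beta_bw, beta_ls = beta_ls,
    is_age_dmr = beta_age != 0, is_bw_dmr = beta_bw != 0,
    is_ls_dmr = beta_ls != 0, stringsAsFactors = FALSE)
  truth_groups <- data.frame(group = groups,
                             median_ls = ls$median_ls[match(groups, ls$group)],
                             mean_ls = ls$mean_ls[match(groups, ls$group)],
                             stringsAsFactors = FALSE)
  list(methylome = m,
       truth = list(regions = truth_regions, groups = truth_groups,
                    rate = stats::setNames(rate, samples$sample_id),
                    random_intercepts = u))
}

#' Simulate matched expression
#'
#' One transcript per gene. For genes whose bin is a planted DMR the
#' transcript tracks its cognate region's methylation with a class-specific
#' slope sign: positive for hypermethylated age-DMRs, negative for
#' hypomethylated age-DMRs and for BW0-hypomethylated DMRs (so expression
#' rises with BW0), positive for BW0-hypermethylated DMRs, negative for
#' LS-DMRs. Null genes get a weak random-sign coupling. Only the first
#' `n_expression` samples carry expression.
#'
#' @param methylome region x sample matrix
#' @param regions region set
#' @param truth ground truth from `simulate_methylome`
#' @param config `simulation_config()`
#' @return transcript x sample matrix (rownames = gene ids)
#' @export
simulate_expression <- function(methylome, regions, truth, config) {
  set.seed(config$seed + 3L)
  keep_samples <- colnames(methylome)[
    seq_len(min(config$n_expression, ncol(methylome)))]
  genic <- which(nzchar(regions$gene_id))
  # one region per gene: the one with the strongest planted signal, else first
  score <- abs(truth$regions$beta_age) + abs(truth$regions$beta_bw) +
    abs(truth$regions$beta_ls)
  ord <- genic[order(-score[genic])]
  pick <- ord[!duplicated(regions$gene_id[ord])]
  genes <- regions$gene_id[pick]

  tr <- truth$regions[pick, ]
  a <- numeric(length(pick))
  for (i in seq_along(pick)) {
    if (tr$is_age_dmr[i]) a[i] <- sign(tr$beta_age[i]) * config$cis_strength
    else if (tr$is_bw_dmr[i]) a[i] <- sign(tr$beta_bw[i]) * config$cis_strength
    else if (tr$is_ls_dmr[i]) a[i] <- -config$cis_strength
    else a[i] <- sample(c(-1, 1), 1) * 0.15
  }
  meth <- methylome[pick, keep_samples, drop = FALSE]
  noise <- matrix(stats::rnorm(length(pick) * length(keep_samples), 0,
                               config$expr_noise_sd),
                  length(pick), length(keep_samples))
  expr <- 5 + a * (meth - rowMeans(meth)) + noise
  dimnames(expr) <- list(genes, keep_samples)
  expr
}

#' Run the full generator
#' @param config `simulation_config()`
#' @return list(regions, samples, longevity, methylome, expression, truth)
#' @export
simulate_study <- function(config = simulation_config()) {
  regions <- simulate_regions(config)
  cohort <- simulate_cohort(config)
  meth <- simulate_methylome(regions, cohort$samples, cohort$longevity, config)
  expr <- simulate_expression(meth$methylome, regions, meth$truth, config)
  list(regions = regions, samples = cohort$samples,
       longevity = cohort$longevity, methylome = meth$methylome,
       expression = expr, truth = meth$truth)
}

#' Write all generator outputs as TSV files
#' @param study result of `simulate_study`
#' @param dir output directory (created if missing)
#' @return the directory, invisibly
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_region_table(study$regions, file.path(dir, "regions.tsv"))
  write_table_tsv(study$samples, file.path(dir, "samples.tsv"))
  write_table_tsv(study$longevity, file.path(dir, "longevity.tsv"))
  write_matrix_tsv(study$methylome, file.path(dir, "methylome.tsv"))
  write_matrix_tsv(study$expression, file.path(dir, "expression.tsv"),
                   id_col = "transcript_id")
  write_table_tsv(study$truth$regions, file.path(dir, "ground_truth.tsv"))
  invisible(dir)
}
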