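# Shared fixtures, built in code once per test run.

# sequential non-overlapping 150-bp bins with simple alternating annotation
make_region_df <- function(n, chrom = "chr1") {
  start <- seq(0L, by = 300L, length.out = n)
  genic <- seq_len(n) %% 2 == 1
  data.frame(
    chrom = chrom, start = start, end = start + 150L,
    region_id = sprintf("r%03d", seq_len(n)),
    cpg_count = (seq_len(n) * 3L) %% 17L,
    variant_count = ifelse(seq_len(n) %% 5 == 0, 2L, 0L),
    feature_labels = ifelse(genic, "exon;intron", "intergenic"),
    gene_id = ifelse(genic, sprintf("g%03d", seq_len(n)), ""),
    stringsAsFactors = FALSE)
}

# a compact simulated study plus its EWAS, reused across test files
fixture_config <- simulation_config(n_regions = 400, seed = 11)
fixture_study <- simulate_study(fixture_config)
fixture_ewas <- run_ewas(fixture_study$methylome, fixture_study$samples,
                         fixture_study$longevity)
fixture_age_dmrs <- call_dmrs(fixture_ewas, "age", 1e-4)

# minimal two-group sample/longevity tables for model-level unit tests
make_flat_cohort <- function(n_per_group = 6, n_groups = 4, seed = 5) {
  set.seed(seed)
  strains <- paste0("St", seq_len(n_groups))
  samples <- do.call(rbind, lapply(strains, function(s) {
    age <- round(runif(n_per_group, 200, 700))
    data.frame(sample_id = paste0(s, "_", seq_len(n_per_group)),
               strain = s, diet = "CD", sex = "F", age_days = age,
               bw0_g = round(rnorm(n_per_group, 25, 3), 1),
               bw0_age_days = 120L, final_weight_g = 30,
               liver_weight_g = 1.2, days_on_hfd = 0L,
               stringsAsFactors = FALSE)
  }))
  samples <- validate_sample_table(samples)
  longevity <- do.call(rbind, lapply(seq_along(strains), function(i)
    data.frame(strain = strains[i], diet = "CD",
               lifespan_days = rnorm(8, 450 + 90 * i, 40),
               stringsAsFactors = FALSE)))
  list(samples = samples, longevity = longevity)
}
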