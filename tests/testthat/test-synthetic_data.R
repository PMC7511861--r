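test_that("generator is fully deterministic under a fixed seed", {
  cfg <- simulation_config(n_regions = 150, seed = 99)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1, s2)

  # byte-identical on disk
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_study(s1, d1); write_study(s2, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})

test_that("variant fraction tracks its configured target", {
  cfg <- simulation_config(n_regions = 10000, frac_variant_regions = 0.17,
                           seed = 21)
  rs <- simulate_regions(cfg)
  obs <- mean(rs$variant_count > 0)
  ci <- qbinom(c(0.005, 0.995), 10000, 0.17) / 10000
  expect_gte(obs, ci[1]); expect_lte(obs, ci[2])

  cfg0 <- simulation_config(n_regions = 500, frac_variant_regions = 0,
                            seed = 21)
  expect_true(all(simulate_regions(cfg0)$variant_count == 0))
})

test_that("a null diet configuration leaves CD and HFD groups exchangeable", {
  gt <- data.frame(strain = paste0("S", rep(1:4, each = 2)),
                   diet = rep(c("CD", "HFD"), 4),
                   mean_ls = 650, sd_ls = 100, n = 6,
                   age_min = 200, age_max = 700,
                   stringsAsFactors = FALSE)
  n_sig_ls <- 0; n_sig_w <- 0
  for (seed in 1:10) {
    cfg <- simulation_config(n_regions = 100, group_table = gt,
                             hfd_weight_gain_g = 0, hfd_ls_penalty = 0,
                             seed = seed)
    co <- simulate_cohort(cfg)
    hf <- co$samples$diet == "HFD"
    n_sig_w <- n_sig_w +
      (welch_t(co$samples$final_weight_g[hf],
               co$samples$final_weight_g[!hf])$p_value < 0.01)
    lf <- co$longevity$diet == "HFD"
    n_sig_ls <- n_sig_ls +
      (welch_t(co$longevity$lifespan_days[lf],
               co$longevity$lifespan_days[!lf])$p_value < 0.01)
  }
  expect_lte(n_sig_w, 2); expect_lte(n_sig_ls, 2)
})

test_that("default cohort shows heavier HFD mice and BW0-age coupling", {
  co <- simulate_cohort(simulation_config(n_regions = 100, seed = 3))
  sm <- co$samples
  both <- intersect(sm$strain[sm$diet == "HFD"], sm$strain[sm$diet == "CD"])
  in_both <- sm$strain %in% both
  expect_gt(mean(sm$final_weight_g[in_both & sm$diet == "HFD"]),
            mean(sm$final_weight_g[in_both & sm$diet == "CD"]))

  # positive BW0 vs age-at-weighing correlation in nearly every cohort draw
  pos <- vapply(1:200, function(seed) {
    s <- simulate_cohort(simulation_config(n_regions = 100,
                                           seed = seed))$samples
    cor(s$bw0_g, s$bw0_age_days) > 0
  }, logical(1))
  expect_gte(mean(pos), 0.95)
})

test_that("methylome obeys the linear generative model exactly when noiseless", {
  # tau = sigma = 0 and no planted effects -> per-region constants
  cfg <- simulation_config(n_regions = 120, tau = 0, sigma = 0,
                           frac_age_dmr = 0, frac_bw_dmr = 0,
                           frac_ls_dmr = 0, ls_accel_strength = 0,
                           hfd_accel = 0, seed = 13)
  st <- simulate_study(cfg)
  expect_equal(st$methylome,
               matrix(st$truth$regions$mu, nrow(st$methylome),
                      ncol(st$methylome),
                      dimnames = dimnames(st$methylome)),
    tolerance = 1e-12)

  # non-DMR bins carry exactly zero coefficients
  expect_true(all(st$truth$regions$beta_age == 0 &
                    st$truth$regions$beta_bw == 0 &
                    st$truth$regions$beta_ls == 0))

  # with noise off, the value difference between two samples at a planted
  # age region is exactly beta_age x their age difference (rates 1);
  # a beta of 0.001 and 100 days apart gives 0.1
  cfg1 <- simulation_config(n_regions = 100, tau = 0, sigma = 0,
                            frac_age_dmr = 0.1, frac_bw_dmr = 0,
                            frac_ls_dmr = 0, ls_accel_strength = 0,
                            hfd_accel = 0, seed = 14)
  st1 <- simulate_study(cfg1)
  tr1 <- st1$truth$regions
  j <- which(tr1$is_age_dmr)[1]
  ages <- st1$samples$age_days
  got <- st1$methylome[j, 2] - st1$methylome[j, 1]
  expect_equal(got, tr1$beta_age[j] * (ages[2] - ages[1]),
               tolerance = 1e-10)
})

test_that("planted age-DMR direction couples to CpG density and baseline", {
  # a generator-only draw large enough for stable per-direction averages
  cfg <- simulation_config(n_regions = 3000, frac_age_dmr = 0.05,
                           frac_bw_dmr = 0.05, seed = 5)
  st <- simulate_study(cfg)
  tr <- st$truth$regions
  pos <- tr$is_age_dmr & tr$beta_age > 0
  neg <- tr$is_age_dmr & tr$beta_age < 0
  cpg <- st$regions$cpg_count
  expect_gt(mean(cpg[pos]), mean(cpg[neg]))
  expect_lt(mean(tr$mu[pos]), mean(tr$mu[neg]))
  # mu is the methylation level at cohort-average covariates, so the same
  # ordering shows in the observed region means
  rmean <- rowMeans(st$methylome)
  expect_lt(mean(rmean[pos]), mean(rmean[neg]))

  # BW0-DMRs predominantly hypomethylated with higher weight
  expect_gt(mean(tr$beta_bw[tr$is_bw_dmr] < 0), 0.5)
})

test_that("planted cis links produce the expected correlation extremes", {
  st <- fixture_study
  # noise-free, slope -1 clone of the methylome gives r = -1 per pair
  cfg0 <- simulation_config(n_regions = 400, cis_strength = 1,
                            expr_noise_sd = 0, seed = 11)
  expr0 <- simulate_expression(st$methylome, st$regions, st$truth, cfg0)
  ids <- intersect(colnames(expr0), colnames(st$methylome))
  # genes whose id maps to a single bin make the cognate region unambiguous
  tab <- table(st$regions$gene_id[nzchar(st$regions$gene_id)])
  unique_genes <- intersect(names(tab)[tab == 1], rownames(expr0))
  g1 <- unique_genes[1]
  reg1 <- st$regions$region_id[match(g1, st$regions$gene_id)]
  r <- cor(expr0[g1, ids], st$methylome[reg1, ids])
  expect_equal(abs(r), 1, tolerance = 1e-8)

  # zero coupling: correlations centered at 0
  cfgz <- simulation_config(n_regions = 400, cis_strength = 0,
                            expr_noise_sd = 0.4, seed = 11)
  exprz <- simulate_expression(st$methylome, st$regions, st$truth, cfgz)
  tr <- st$truth$regions
  dmr_genes <- st$regions$gene_id[
    match(tr$region_id[tr$is_age_dmr], st$regions$region_id)]
  dmr_genes <- intersect(dmr_genes[nzchar(dmr_genes)], rownames(exprz))
  dmr_genes <- intersect(dmr_genes, unique_genes)
  rs <- vapply(dmr_genes, function(g) {
    reg <- st$regions$region_id[match(g, st$regions$gene_id)]
    cor(exprz[g, ids], st$methylome[reg, ids])
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.2)
})
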