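as_dmr_set <- function(df, trait = "age", threshold_p = 1e-4) {
  attr(df, "trait") <- trait
  attr(df, "threshold_p") <- threshold_p
  class(df) <- c("dmr_set", "data.frame")
  df
}

test_that("tallies count directions, genic context and variants exactly", {
  rs <- region_set(make_region_df(40))
  # regions r001..r040: odd = genic, every 5th has variants
  d <- as_dmr_set(data.frame(
    region_id = sprintf("r%03d", 1:10),
    beta = c(1, -1, 1, 1, -1, 1, -1, -1, 1, 1),
    p = rep(1e-6, 10),
    direction = c("+", "-", "+", "+", "-", "+", "-", "-", "+", "+"),
    stringsAsFactors = FALSE))
  tl <- tally_dmrs(d, rs)
  expect_equal(tl$n_total, 10)
  expect_equal(tl$n_positive, 6)
  expect_equal(tl$n_negative, 4)
  # genic = odd ids: r001,r003,r005,r007,r009 -> dirs +,+,-,-,+
  expect_equal(tl$n_genic_pos, 3)
  expect_equal(tl$n_genic_neg, 2)
  expect_equal(tl$n_intergenic_pos, 3)
  expect_equal(tl$n_intergenic_neg, 2)
  expect_equal(tl$n_variant, 2)  # r005, r010
  expect_equal(tl$pct_positive, 60)
  expect_equal(tl$pct_variant, 20)

  # percentages always recompute from counts
  expect_equal(tl$pct_genic_neg, 100 * tl$n_genic_neg / tl$n_total)

  empty <- as_dmr_set(d[0, ])
  tl0 <- tally_dmrs(empty, rs)
  expect_true(tl0$empty)
  expect_equal(tl0$n_total, 0)
  expect_equal(tl0$pct_positive, 0)

  missing <- as_dmr_set(data.frame(region_id = "zzz", beta = 1, p = 0.5,
                                   direction = "+"))
  expect_error(tally_dmrs(missing, rs), "absent")
})

test_that("tally rows serialize and round-trip through TSV", {
  rs <- region_set(make_region_df(40))
  d <- call_dmrs(fixture_ewas, "age", 1e-3)
  tl <- tally_dmrs(d, fixture_study$regions)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_table_tsv(tl, path)
  back <- utils::read.delim(path)
  expect_equal(back$n_positive + back$n_negative, back$n_total)
  expect_equal(back$pct_variant, tl$pct_variant, tolerance = 1e-9)
})

test_that("feature enrichment flags extremes and stays flat under the null", {
  rs <- fixture_study$regions
  # DMRs = all promoter bins: promoter enrichment is the minimum possible,
  # intergenic maximally depleted
  labs <- region_feature_list(rs)
  promoter <- vapply(labs, function(l) "promoter" %in% l, logical(1))
  d <- as_dmr_set(data.frame(region_id = rs$region_id[promoter],
                             beta = 1, p = 1e-6, direction = "+",
                             stringsAsFactors = FALSE))
  en <- feature_enrichment(d, rs)
  prow <- en[en$category == "promoter", ]
  expect_equal(prow$k_in_dmrs, prow$n_dmrs)
  # all draws are successes: the enrichment tail is the single most extreme
  # table, and an independent closed form exists
  expect_equal(prow$p_enrich,
               exp(lchoose(prow$K_in_background, prow$n_dmrs) -
                   lchoose(prow$N_background, prow$n_dmrs)),
               tolerance = 1e-10)
  irow <- en[en$category == "intergenic", ]
  expect_equal(irow$k_in_dmrs, 0)
  expect_equal(irow$p_deplete,
               exp(lchoose(irow$N_background - irow$K_in_background,
                           irow$n_dmrs) -
                   lchoose(irow$N_background, irow$n_dmrs)),
               tolerance = 1e-10)

  # uniform draws: no category should look strongly enriched in most seeds
  set.seed(23)
  n_extreme <- 0
  for (i in 1:20) {
    idx <- sample(nrow(rs), 30)
    dn <- as_dmr_set(data.frame(region_id = rs$region_id[idx], beta = 1,
                                p = 1e-6, direction = "+",
                                stringsAsFactors = FALSE))
    enn <- feature_enrichment(dn, rs)
    n_extreme <- n_extreme + any(enn$p_enrich < 0.001)
  }
  expect_lte(n_extreme, 3)
})

test_that("one hypergeometric tail always covers the observation", {
  set.seed(29)
  rs <- fixture_study$regions
  for (i in 1:10) {
    idx <- sample(nrow(rs), sample(10:60, 1))
    d <- as_dmr_set(data.frame(region_id = rs$region_id[idx], beta = 1,
                               p = 1e-6, direction = "+",
                               stringsAsFactors = FALSE))
    en <- feature_enrichment(d, rs)
    # the two tails overlap in the observed point mass, so their minimum
    # cannot exceed 1/2 by more than that shared mass
    point_mass <- dhyper(en$k_in_dmrs, en$K_in_background,
                         en$N_background - en$K_in_background, en$n_dmrs)
    expect_true(all(pmin(en$p_enrich, en$p_deplete) <=
                      0.5 + point_mass + 1e-12))
  }
})

test_that("coefficient profiles recover planted density/baseline coupling", {
  # truth-derived DMR set on a generator-scale draw: the profile summaries
  # must expose the planted density/baseline coupling without an EWAS pass
  cfg <- simulation_config(n_regions = 3000, frac_age_dmr = 0.05, seed = 5)
  st <- simulate_study(cfg)
  tr <- st$truth$regions
  planted <- tr[tr$is_age_dmr, ]
  d_true <- as_dmr_set(data.frame(region_id = planted$region_id,
                                  beta = planted$beta_age, p = 1e-6,
                                  direction = ifelse(planted$beta_age >= 0,
                                                     "+", "-"),
                                  stringsAsFactors = FALSE))
  ew_stub <- data.frame(region_id = tr$region_id,
                        region_mean = rowMeans(st$methylome))
  prof <- coefficient_profiles(d_true, ew_stub, st$regions)
  dm <- prof$direction_means
  pos <- dm[dm$direction == "+", ]
  neg <- dm[dm$direction == "-", ]
  expect_gt(pos$mean_cpg_count, neg$mean_cpg_count)
  expect_lt(pos$mean_region_mean, neg$mean_region_mean)

  # hand-built 4-region fixture: correlations equal direct arithmetic
  rs4 <- region_set(data.frame(
    chrom = "chr1", start = c(0, 300, 600, 900),
    end = c(150, 450, 750, 1050),
    region_id = paste0("h", 1:4), cpg_count = c(2, 5, 11, 17),
    variant_count = 0L, feature_labels = "exon",
    gene_id = paste0("g", 1:4), stringsAsFactors = FALSE))
  ew4 <- data.frame(region_id = paste0("h", 1:4),
                    beta_age = c(-0.002, -0.001, 0.001, 0.003),
                    p_age = 1e-6, beta_bw0 = 0, p_bw0 = 1,
                    beta_ls = 0, p_ls = 1,
                    region_mean = c(1.4, 1.1, 0.6, 0.3),
                    group_var = 0, resid_var = 1, converged = TRUE)
  d4 <- as_dmr_set(data.frame(region_id = paste0("h", 1:4),
                              beta = ew4$beta_age, p = 1e-6,
                              direction = c("-", "-", "+", "+"),
                              stringsAsFactors = FALSE))
  prof4 <- coefficient_profiles(d4, ew4, rs4)
  all_cpg <- prof4$correlations[
    prof4$correlations$subset == "all" &
      prof4$correlations$covariate == "cpg_count", ]
  expect_equal(all_cpg$r, cor(ew4$beta_age, rs4$cpg_count),
               tolerance = 1e-12)
  all_rm <- prof4$correlations[
    prof4$correlations$subset == "all" &
      prof4$correlations$covariate == "region_mean", ]
  expect_equal(all_rm$r, cor(ew4$beta_age, ew4$region_mean),
               tolerance = 1e-12)

  # constant CpG density: flagged not applicable
  rs4c <- rs4; rs4c$cpg_count <- 7L
  prof4c <- coefficient_profiles(d4, ew4, region_set(rs4c))
  row <- prof4c$correlations[prof4c$correlations$subset == "all" &
                               prof4c$correlations$covariate == "cpg_count", ]
  expect_false(row$applicable)
  expect_true(is.na(row$r))
})
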