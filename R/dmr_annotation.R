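# DMR characterization: direction/feature tallies, hypergeometric
# feature and variant-overlap enrichment, and coefficient profiles against
# CpG density and mean methylation.

#' Tally a DMR set by direction, genic context and variant content
#'
#' Counts positive/negative-coefficient DMRs, split into genic and
#' intergenic bins, plus the number containing sequence variants.
#' Percentages are 100 x count / total DMRs. An empty set reports zeros
#' with `empty = TRUE`.
#'
#' @param dmrs `call_dmrs` result
#' @param regions region set (must contain every DMR)
#' @return one-row data.frame: counts, percentages, `trait`, `empty`
#' @export
tally_dmrs <- function(dmrs, regions) {
  missing <- setdiff(dmrs$region_id, regions$region_id)
  if (length(missing))
    stop("DMR regions absent from region set: ",
         paste(utils::head(missing, 5), collapse = ", "))
  n <- nrow(dmrs)
  if (n == 0) {
    out <- data.frame(n_total = 0L, n_positive = 0L, n_negative = 0L,
                      n_genic_pos = 0L, n_genic_neg = 0L,
                      n_intergenic_pos = 0L, n_intergenic_neg = 0L,
                      n_variant = 0L, pct_positive = 0, pct_negative = 0,
                      pct_genic_pos = 0, pct_genic_neg = 0,
                      pct_intergenic_pos = 0, pct_intergenic_neg = 0,
                      pct_variant = 0, empty = TRUE)
    out$trait <- attr(dmrs, "trait")
    return(out)
  }
  i <- match(dmrs$region_id, regions$region_id)
  genic <- is_genic(regions)[i]
  pos <- dmrs$direction == "+"
  has_var <- regions$variant_count[i] > 0
  counts <- c(n_total = n,
              n_positive = sum(pos), n_negative = sum(!pos),
              n_genic_pos = sum(genic & pos), n_genic_neg = sum(genic & !pos),
              n_intergenic_pos = sum(!genic & pos),
              n_intergenic_neg = sum(!genic & !pos),
              n_variant = sum(has_var))
  pct <- 100 * counts[-1] / n
  names(pct) <- sub("^n_", "pct_", names(pct))
  out <- cbind(as.data.frame(as.list(counts)), as.data.frame(as.list(pct)))
  out$empty <- FALSE
  out$trait <- attr(dmrs, "trait")
  out
}

#' Hypergeometric feature and variant-overlap enrichment of a DMR set
#'
#' For every feature class present in the background (plus the genic /
#' intergenic split and variant-containing bins), tests whether the DMR
#' set is enriched (upper tail, P(X >= k)) or depleted (lower tail,
#' P(X <= k)) relative to the full region set as background. A bin with
#' several labels contributes to each label's contingency independently.
#'
#' @param dmrs `call_dmrs` result
#' @param regions region set (the background)
#' @return data.frame: category, k_in_dmrs, n_dmrs, K_in_background,
#'   N_background, p_enrich, p_deplete
#' @export
feature_enrichment <- function(dmrs, regions) {
  N <- nrow(regions)
  n <- nrow(dmrs)
  i <- match(dmrs$region_id, regions$region_id)
  if (anyNA(i)) stop("DMR regions absent from region set")
  labs_bg <- region_feature_list(regions)
  cats <- intersect(ALL_FEATURES, unique(unlist(labs_bg)))

  membership <- function(cat) {
    switch(cat,
           genic = is_genic(regions),
           intergenic = !is_genic(regions),
           variant_containing = regions$variant_count > 0,
           vapply(labs_bg, function(l) cat %in% l, logical(1)))
  }
  rows <- lapply(c(cats, "genic", "variant_containing"), function(cat) {
    m <- membership(cat)
    K <- sum(m)
    k <- sum(m[i])
    data.frame(category = cat, k_in_dmrs = k, n_dmrs = n,
               K_in_background = K, N_background = N,
               p_enrich = hypergeometric_tail(N, K, n, k),
               p_deplete = hypergeometric_tail(N, K, n, k, lower = TRUE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[!duplicated(out$category), , drop = FALSE]
}

#' Coefficient profiles of a DMR set
#'
#' Relates DMR trait coefficients to local genomic context: Pearson r of
#' beta against CpG count and against mean methylation (overall and within
#' each direction), plus per-direction group means of both covariates.
#' Correlations on constant inputs are reported as NA with
#' `applicable = FALSE`.
#'
#' @param dmrs `call_dmrs` result
#' @param ewas `run_ewas` result (supplies region_mean)
#' @param regions region set (supplies cpg_count)
#' @return list(correlations = data.frame, direction_means = data.frame)
#' @export
coefficient_profiles <- function(dmrs, ewas, regions) {
  ei <- match(dmrs$region_id, ewas$region_id)
  ri <- match(dmrs$region_id, regions$region_id)
  if (anyNA(ei) || anyNA(ri)) stop("DMR regions missing from ewas/regions")
  beta <- dmrs$beta
  cpg <- regions$cpg_count[ri]
  rmean <- ewas$region_mean[ei]

  cor_row <- function(subset_name, idx, covar_name, covar) {
    ok <- length(idx) >= 3 && stats::sd(beta[idx]) > 0 &&
      stats::sd(covar[idx]) > 0
    if (ok) {
      r <- pearson_with_p(beta[idx], covar[idx])
      data.frame(subset = subset_name, covariate = covar_name,
                 r = r$estimate, p_value = r$p_value, n = length(idx),
                 applicable = TRUE, stringsAsFactors = FALSE)
    } else {
      data.frame(subset = subset_name, covariate = covar_name,
                 r = NA_real_, p_value = NA_real_, n = length(idx),
                 applicable = FALSE, stringsAsFactors = FALSE)
    }
  }
  subsets <- list(all = seq_len(nrow(dmrs)),
                  positive = which(dmrs$direction == "+"),
                  negative = which(dmrs$direction == "-"))
  cors <- do.call(rbind, unlist(lapply(names(subsets), function(s)
    list(cor_row(s, subsets[[s]], "cpg_count", cpg),
         cor_row(s, subsets[[s]], "region_mean", rmean))),
    recursive = FALSE))

  dmeans <- do.call(rbind, lapply(c("+", "-"), function(d) {
    idx <- which(dmrs$direction == d)
    data.frame(direction = d, n = length(idx),
               mean_cpg_count = if (length(idx)) mean(cpg[idx]) else NA_real_,
               mean_region_mean = if (length(idx)) mean(rmean[idx])
                                  else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(correlations = cors, direction_means = dmeans)
}
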