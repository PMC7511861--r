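# Global methylome structure: PCA, PC-trait screening, genic/intergenic
# mean methylation, and advisory outlier flagging.

#' Principal component analysis of the methylome
#'
#' Samples are the observations; each region is centered (no scaling)
#' before the decomposition, so variance fractions are interpretable as
#' shares of total between-sample variance.
#'
#' @param methylome region x sample numeric matrix
#' @param n_components number of components to retain
#' @return list of class `"pca_result"`: scores (sample x component),
#'   variance_fraction (per retained component), n_components
#' @export
run_pca <- function(methylome, n_components) {
  n_max <- min(dim(methylome))
  if (n_components > n_max)
    stop("n_components exceeds min(samples, regions) = ", n_max)
  pc <- stats::prcomp(t(methylome), center = TRUE, scale. = FALSE)
  total <- sum(pc$sdev^2)
  out <- list(scores = pc$x[, seq_len(n_components), drop = FALSE],
              variance_fraction = (pc$sdev^2 / total)[seq_len(n_components)],
              n_components = n_components)
  class(out) <- "pca_result"
  out
}

# trait vectors screened against PCs; strain-level life-span statistics are
# expanded to per-sample values through the strain-by-diet group
screen_traits <- function(samples, longevity) {
  ls <- lifespan_summary(longevity)
  i <- match(samples$group, ls$group)
  list(
    age = samples$age_days,
    bw0 = samples$bw0_g,
    final_weight = samples$final_weight_g,
    liver_weight = samples$liver_weight_g,
    mean_lifespan = ls$mean_ls[i],
    median_lifespan = ls$median_ls[i],
    min_lifespan = ls$min_ls[i],
    max_lifespan = ls$max_ls[i])
}

#' Screen principal components against cohort traits
#'
#' Pearson r/p of each retained PC against age, baseline and final body
#' weight, liver weight, and the strain-level mean/median/min/max life
#' span; Welch t for the CD/HFD contrast.
#'
#' @param pca `run_pca` result
#' @param samples sample table (rows aligned with score rows)
#' @param longevity longevity table
#' @param n_pcs number of leading PCs to screen
#' @param diet_subset optional "CD" or "HFD" to restrict the correlations
#' @param exclude_f1 drop F1 hybrid strains (names ending "F1") first
#' @return data.frame: pc, trait, statistic, df, p_value, estimate
#' @export
pc_trait_screen <- function(pca, samples, longevity, n_pcs = 5,
                            diet_subset = NULL, exclude_f1 = FALSE) {
  n_pcs <- min(n_pcs, pca$n_components)
  keep <- rep(TRUE, nrow(samples))
  if (!is.null(diet_subset)) keep <- keep & samples$diet == diet_subset
  if (exclude_f1) keep <- keep & !grepl("F1$", samples$strain)
  sm <- samples[keep, , drop = FALSE]
  sc <- pca$scores[keep, , drop = FALSE]
  traits <- screen_traits(sm, longevity)
  rows <- list()
  for (p in seq_len(n_pcs)) {
    for (tn in names(traits)) {
      tv <- traits[[tn]]
      ok <- is.finite(tv)
      res <- if (sum(ok) >= 3 && stats::sd(tv[ok]) > 0 &&
                 stats::sd(sc[ok, p]) > 0)
        pearson_with_p(sc[ok, p], tv[ok])
      else
        test_result(NA_real_, NA_real_, NA_real_, NA_real_)
      rows[[length(rows) + 1L]] <- cbind(pc = p, trait = tn, res,
                                         test = "pearson")
    }
    if (length(unique(sm$diet)) == 2) {
      res <- welch_t(sc[sm$diet == "HFD", p], sc[sm$diet == "CD", p])
      rows[[length(rows) + 1L]] <- cbind(pc = p, trait = "diet", res,
                                         test = "welch")
    }
  }
  do.call(rbind, rows)
}

#' Per-sample genic and intergenic mean methylation
#'
#' Genic = bins carrying at least one of promoter/exon/intron/UTR;
#' intergenic = the complement.
#'
#' @param methylome region x sample matrix
#' @param regions region set matching the matrix rows
#' @return data.frame: sample_id, genic_mean, intergenic_mean
#' @export
global_mean_methylation <- function(methylome, regions) {
  stopifnot(identical(rownames(methylome), regions$region_id))
  g <- is_genic(regions)
  if (!any(g) || all(g))
    stop("both genic and intergenic bins are required")
  data.frame(sample_id = colnames(methylome),
             genic_mean = colMeans(methylome[g, , drop = FALSE]),
             intergenic_mean = colMeans(methylome[!g, , drop = FALSE]),
             row.names = NULL)
}

#' Flag PCA outliers relative to their strain cluster
#'
#' A sample is flagged when its Euclidean distance from its strain centroid
#' in (PC1, PC2) exceeds `k_sd` times the cohort's median within-strain
#' distance. The centroid is the component-wise median, so a single grossly
#' displaced sample cannot drag its own cluster center (and its strain
#' mates) past the threshold. Advisory only: exclusion is the analyst's
#' decision.
#'
#' @param pca `run_pca` result with >= 2 components
#' @param samples sample table
#' @param k_sd multiplier on the cohort median within-strain distance
#'   (default 6)
#' @return character vector of flagged sample ids
#' @export
flag_pca_outliers <- function(pca, samples, k_sd = 6) {
  stopifnot(pca$n_components >= 2)
  xy <- pca$scores[, 1:2, drop = FALSE]
  dist_to_centroid <- rep(NA_real_, nrow(samples))
  for (s in unique(samples$strain)) {
    i <- which(samples$strain == s)
    if (length(i) < 2) next
    cen <- apply(xy[i, , drop = FALSE], 2, stats::median)
    dist_to_centroid[i] <- sqrt(rowSums(sweep(xy[i, , drop = FALSE],
                                              2, cen)^2))
  }
  ref <- stats::median(dist_to_centroid, na.rm = TRUE)
  if (!is.finite(ref)) return(character(0))
  flagged <- which(!is.na(dist_to_centroid) & dist_to_centroid > k_sd * ref)
  samples$sample_id[flagged]
}
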