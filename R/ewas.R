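# Per-region mixed-model EWAS and DMR calling.
#
# The model at every region is
#   lmer(y ~ age + bw0 + median_ls + (1 | strain_diet), REML)
# with y the region's log-scale methylation across samples. All regions
# share one design, so the first region is fitted with lme4::lmer and the
# rest reuse its factorization through lme4::refit, which keeps a
# genome-wide scan fast. p-values are Wald normal-approximation tests on
# the fixed effects (lme4 reports none natively); regions where the mixed
# fit fails fall back to OLS and are flagged converged = FALSE.

ewas_frame <- function(samples, longevity) {
  ls <- lifespan_summary(longevity)
  med <- ls$median_ls[match(samples$group, ls$group)]
  if (anyNA(med))
    stop("longevity table lacks groups: ",
         paste(setdiff(samples$group, ls$group), collapse = ", "))
  data.frame(age = samples$age_days, bw0 = samples$bw0_g, median_ls = med,
             group = factor(samples$group))
}

#' Fit the per-region linear mixed model
#'
#' Fixed effects: age (days), baseline body weight (grams), group median
#' life span (days); random intercept per strain-by-diet group; REML fit.
#' A constant response short-circuits to a zero-coefficient row with p = 1.
#'
#' @param y per-sample methylation for one region (named by sample id or
#'   aligned with `samples`)
#' @param samples sample table
#' @param longevity longevity table (supplies group median life span)
#' @return one-row data.frame with beta/se/p per covariate, region mean,
#'   variance components and a convergence flag
#' @export
fit_region_mixed_model <- function(y, samples, longevity) {
  fr <- ewas_frame(samples, longevity)
  if (nlevels(fr$group) < 2) stop("need >= 2 strain-by-diet groups")
  res <- fit_one_region(y, fr, template = NULL)
  row <- as.data.frame(as.list(res$vec[-13]))
  row$converged <- res$vec[13] == 1
  row
}

ewas_columns <- c("beta_age", "se_age", "p_age",
                  "beta_bw0", "se_bw0", "p_bw0",
                  "beta_ls", "se_ls", "p_ls",
                  "region_mean", "group_var", "resid_var", "converged")

# shared worker: `template` is a fitted lmerMod reused via refit().
# Returns a bare numeric vector (ewas_columns order) so the genome-wide
# loop can fill a preallocated matrix without per-region data.frame cost.
fit_one_region <- function(y, fr, template = NULL) {
  if (stats::sd(y) == 0) {
    vec <- c(0, NA, 1, 0, NA, 1, 0, NA, 1, mean(y), 0, 0, 1)
    names(vec) <- ewas_columns
    return(list(vec = vec, template = template))
  }
  ext <- tryCatch(suppressMessages({
    fit <- if (is.null(template))
      lme4::lmer(y ~ age + bw0 + median_ls + (1 | group), data = fr,
                 REML = TRUE,
                 control = lme4::lmerControl(
                   calc.derivs = FALSE,
                   check.conv.singular = "ignore"))
    else
      suppressWarnings(lme4::refit(template, newresp = y))
    if (is.null(template)) template <- fit
    beta <- lme4::fixef(fit)
    se <- sqrt(diag(as.matrix(stats::vcov(fit))))
    vc <- lme4::VarCorr(fit)
    list(beta = beta[c("age", "bw0", "median_ls")],
         se = se[c(2, 3, 4)],
         group_var = vc[["group"]][1, 1],
         resid_var = attr(vc, "sc")^2, converged = 1)
  }), error = function(e) NULL, warning = function(w) NULL)
  if (is.null(ext)) {
    f <- stats::lm(y ~ age + bw0 + median_ls, data = fr)
    cf <- summary(f)$coefficients
    ext <- list(beta = cf[c("age", "bw0", "median_ls"), 1],
                se = cf[c("age", "bw0", "median_ls"), 2],
                group_var = NA_real_, resid_var = stats::sigma(f)^2,
                converged = 0)
  }
  p <- 2 * stats::pnorm(-abs(ext$beta / ext$se))
  vec <- c(ext$beta[1], ext$se[1], p[1],
           ext$beta[2], ext$se[2], p[2],
           ext$beta[3], ext$se[3], p[3],
           mean(y), ext$group_var, ext$resid_var, ext$converged)
  names(vec) <- ewas_columns
  list(vec = vec, template = template)
}

#' Genome-wide EWAS scan
#'
#' Fits the mixed model independently at every region of the matrix; the
#' result is one row per region regardless of convergence (failed mixed
#' fits fall back to OLS, flagged). Deterministic given its inputs and
#' independent of region order.
#'
#' @param methylome region x sample matrix (columns must match the sample
#'   table's sample_id set)
#' @param samples sample table
#' @param longevity longevity table
#' @param verbose log convergence-failure count (default FALSE)
#' @return data.frame of class `"ewas_result"`: region_id plus
#'   coefficient/SE/p columns for age, bw0 and median life span,
#'   region_mean, variance components, converged flag
#' @export
run_ewas <- function(methylome, samples, longevity, verbose = FALSE) {
  if (!setequal(colnames(methylome), samples$sample_id))
    stop("matrix columns and sample table disagree")
  methylome <- methylome[, samples$sample_id, drop = FALSE]
  fr <- ewas_frame(samples, longevity)
  if (nlevels(fr$group) < 2) stop("need >= 2 strain-by-diet groups")
  template <- NULL
  vals <- matrix(NA_real_, nrow(methylome), length(ewas_columns),
                 dimnames = list(NULL, ewas_columns))
  for (i in seq_len(nrow(methylome))) {
    res <- fit_one_region(methylome[i, ], fr, template)
    template <- res$template
    vals[i, ] <- res$vec
  }
  out <- as.data.frame(vals)
  out$converged <- out$converged == 1
  out <- cbind(region_id = rownames(methylome), out)
  rownames(out) <- NULL
  n_fail <- sum(!out$converged)
  if (verbose && n_fail > 0)
    message(n_fail, " region(s) fell back to OLS")
  class(out) <- c("ewas_result", "data.frame")
  out
}

#' Bonferroni-corrected per-test threshold
#'
#' family_alpha / n_tests: at 368,300 regions and a 10 percent family rate
#' this is the 2.7e-7 genome-wide line.
#'
#' @param n_tests number of regions tested (>= 1)
#' @param family_alpha family-wise error rate in (0, 1), default 0.10
#' @return per-test p threshold
#' @export
bonferroni_threshold <- function(n_tests, family_alpha = 0.10) {
  stopifnot(n_tests >= 1, family_alpha > 0, family_alpha < 1)
  family_alpha / n_tests
}

#' Call DMRs for one trait at a p threshold
#'
#' @param ewas `run_ewas` result
#' @param trait one of "age", "BW0", "LS"
#' @param threshold_p retain regions with trait p <= threshold_p (the
#'   suggestive default is 1e-4)
#' @return data.frame of class `"dmr_set"` ordered by p then region_id:
#'   region_id, beta, p, direction ("+"/"-"); attributes `trait` and
#'   `threshold_p`
#' @export
call_dmrs <- function(ewas, trait = c("age", "BW0", "LS"),
                      threshold_p = 1e-4) {
  trait <- match.arg(trait)
  cols <- switch(trait,
                 age = c("beta_age", "p_age"),
                 BW0 = c("beta_bw0", "p_bw0"),
                 LS = c("beta_ls", "p_ls"))
  keep <- which(ewas[[cols[2]]] <= threshold_p)
  out <- data.frame(region_id = ewas$region_id[keep],
                    beta = ewas[[cols[1]]][keep],
                    p = ewas[[cols[2]]][keep],
                    stringsAsFactors = FALSE)
  out$direction <- ifelse(out$beta >= 0, "+", "-")
  out <- out[order(out$p, out$region_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "trait") <- trait
  attr(out, "threshold_p") <- threshold_p
  class(out) <- c("dmr_set", "data.frame")
  out
}
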