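# Age-DMR weighted-average epigenetic clock (DMRmAge), age-acceleration
# residuals, trait associations, and subsample train/test validation.
#
# The clock is deliberately simple: each sample's weighted sum
# S_i = sum_j beta_age_j * m_ij over the age-DMRs is affinely rescaled to
# the training cohort's chronological age range,
#   DMRmAge_i = (S_i - min S) * age.range / range(S) + min.age,
# with min/range taken over the training samples. Any positive rescaling
# of the weights, or constant shift of the sums, is absorbed by the affine
# map, which is why no normalization of the "weighted average" is needed.

#' Fit the age-DMR clock
#'
#' Weights are the per-region age regression coefficients from the EWAS;
#' scaling constants (min and range of the weighted sums, minimum age and
#' age range) come from the training samples only.
#'
#' @param methylome region x sample matrix
#' @param age_dmrs `call_dmrs(..., trait = "age")` result
#' @param samples sample table for the training cohort
#' @return list of class `"clock_model"`: region_ids, weights,
#'   min_weighted_sum, weighted_sum_range, min_age_days, age_range_days,
#'   training_sample_ids
#' @export
fit_clock <- function(methylome, age_dmrs, samples) {
  if (nrow(age_dmrs) == 0) stop("no age-DMRs to build a clock from")
  missing <- setdiff(age_dmrs$region_id, rownames(methylome))
  if (length(missing))
    stop("clock regions absent from matrix: ",
         paste(utils::head(missing, 3), collapse = ", "))
  train_ids <- intersect(colnames(methylome), samples$sample_id)
  if (length(train_ids) < 2) stop("need >= 2 training samples")
  ages <- samples$age_days[match(train_ids, samples$sample_id)]
  if (diff(range(ages)) == 0) stop("training ages must span a range")

  s <- weighted_sums(methylome[, train_ids, drop = FALSE],
                     age_dmrs$region_id, age_dmrs$beta)
  if (diff(range(s)) == 0) stop("zero weighted-sum range in training set")
  model <- list(region_ids = age_dmrs$region_id, weights = age_dmrs$beta,
                min_weighted_sum = min(s),
                weighted_sum_range = diff(range(s)),
                min_age_days = min(ages),
                age_range_days = diff(range(ages)),
                training_sample_ids = train_ids)
  class(model) <- "clock_model"
  model
}

weighted_sums <- function(methylome, region_ids, weights) {
  drop(crossprod(methylome[region_ids, , drop = FALSE], weights))
}

#' Predict epigenetic age (DMRmAge)
#'
#' Applies the stored affine map to new weighted sums. Training samples
#' span exactly [min_age, min_age + age_range]; out-of-range predictions
#' for new samples are allowed.
#'
#' @param model `fit_clock` result
#' @param methylome region x sample matrix containing the model regions
#' @return named numeric vector of DMRmAge (days) per sample
#' @export
predict_age <- function(model, methylome) {
  missing <- setdiff(model$region_ids, rownames(methylome))
  if (length(missing))
    stop("matrix lacks clock regions: ",
         paste(utils::head(missing, 3), collapse = ", "))
  s <- weighted_sums(methylome, model$region_ids, model$weights)
  (s - model$min_weighted_sum) * model$age_range_days /
    model$weighted_sum_range + model$min_age_days
}

#' Age-acceleration residuals
#'
#' OLS of DMRmAge on chronological age, fitted over the reference subset
#' (the training split during validation, the whole cohort otherwise);
#' residuals from that line for every sample. Positive = epigenetically
#' older than expected.
#'
#' @param dmrm_age named DMRmAge vector
#' @param ages chronological ages aligned with `dmrm_age`
#' @param reference_ids names defining the subset the line is fitted on
#'   (default: all)
#' @return data.frame: sample_id, dmrm_age_days, acceleration_days
#' @export
age_acceleration <- function(dmrm_age, ages,
                             reference_ids = names(dmrm_age)) {
  stopifnot(length(dmrm_age) == length(ages), !is.null(names(dmrm_age)))
  ref <- match(reference_ids, names(dmrm_age))
  if (anyNA(ref)) stop("unknown reference sample ids")
  if (length(ref) < 3) stop("reference subset must have >= 3 samples")
  if (stats::sd(ages[ref]) == 0) stop("constant reference ages")
  fit <- stats::lm(dmrm_age[ref] ~ ages[ref])
  b <- stats::coef(fit)
  acc <- dmrm_age - (b[1] + b[2] * ages)
  data.frame(sample_id = names(dmrm_age), dmrm_age_days = unname(dmrm_age),
             acceleration_days = unname(acc), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Trait associations of age acceleration
#'
#' Pearson r/p of acceleration against strain maximum life span, baseline
#' body weight and final weight (overall and CD-only); a diet contrast of
#' acceleration restricted to strains carrying both diets (Welch by
#' default, strain-paired optionally); and a multivariable OLS of
#' acceleration on maximum life span + BW0 + diet with a partial F per
#' term. A constant acceleration vector is flagged not-applicable.
#'
#' @param acc `age_acceleration` result
#' @param samples sample table
#' @param longevity longevity table
#' @param paired_diet use the strain-paired diet comparison
#' @return list(correlations, diet_comparison, regression)
#' @export
clock_associations <- function(acc, samples, longevity,
                               paired_diet = FALSE) {
  i <- match(acc$sample_id, samples$sample_id)
  if (anyNA(i)) stop("acceleration samples missing from sample table")
  sm <- samples[i, , drop = FALSE]
  ls <- lifespan_summary(longevity)
  max_ls <- ls$max_ls[match(sm$group, ls$group)]
  a <- acc$acceleration_days

  cor_or_na <- function(x, y, label) {
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) >= 3 && stats::sd(x[ok]) > 0 && stats::sd(y[ok]) > 0) {
      r <- pearson_with_p(x[ok], y[ok])
      cbind(association = label, r, n = sum(ok), applicable = TRUE)
    } else {
      cbind(association = label,
            test_result(NA_real_, NA_real_, NA_real_, NA_real_),
            n = sum(ok), applicable = FALSE)
    }
  }
  cd <- sm$diet == "CD"
  cors <- rbind(
    cor_or_na(a, max_ls, "max_lifespan"),
    cor_or_na(a, sm$bw0_g, "bw0"),
    cor_or_na(a, sm$final_weight_g, "final_weight"),
    cor_or_na(a[cd], max_ls[cd], "max_lifespan_cd"),
    cor_or_na(a[cd], sm$bw0_g[cd], "bw0_cd"),
    cor_or_na(a[cd], sm$final_weight_g[cd], "final_weight_cd"))

  both <- intersect(sm$strain[sm$diet == "HFD"], sm$strain[sm$diet == "CD"])
  diet_cmp <- NULL
  if (length(both) &&
      sum(sm$strain %in% both & sm$diet == "HFD") >= 2 &&
      sum(sm$strain %in% both & sm$diet == "CD") >= 2) {
    in_both <- sm$strain %in% both
    hf <- in_both & sm$diet == "HFD"
    cc <- in_both & sm$diet == "CD"
    diet_cmp <- if (stats::sd(a[hf | cc]) == 0) {
      cbind(test_result(0, NA_real_, 1, 0), n = sum(hf | cc))
    } else if (paired_diet) {
      cbind(welch_t(a[hf], a[cc],
                    paired_by = list(a = sm$strain[hf], b = sm$strain[cc])),
            n = sum(hf | cc))
    } else {
      cbind(welch_t(a[hf], a[cc]), n = sum(hf | cc))
    }
    diet_cmp$mean_hfd <- mean(a[hf])
    diet_cmp$mean_cd <- mean(a[cc])
  }

  regression <- NULL
  if (stats::sd(a) > 0) {
    design <- data.frame(max_lifespan = max_ls, bw0 = sm$bw0_g,
                         diet = factor(sm$diet))
    if (nlevels(design$diet) < 2) design$diet <- NULL
    regression <- do.call(rbind, lapply(names(design), function(tm)
      cbind(term = tm, ols_partial_f(a, design, tm))))
  }
  list(correlations = cors, diet_comparison = diet_cmp,
       regression = regression)
}

#' Subsample train/test validation of the whole clock pipeline
#'
#' Draws `n_train` samples without replacement from the sex-filtered pool
#' (default: females), reruns the EWAS and age-DMR calling on the training
#' split only, fits the clock and the acceleration reference line on the
#' training split, then scores both splits. Samples failing the sex filter
#' are assigned to the test split, mirroring the males-to-test-set design.
#'
#' @param methylome region x sample matrix
#' @param samples sample table
#' @param longevity longevity table
#' @param n_train training-set size (default 55)
#' @param suggestive_p DMR threshold for the training EWAS (default 1e-4)
#' @param sex_filter training sexes (default "F"; NULL = all)
#' @param seed RNG seed for the split
#' @return list(split, n_age_dmrs, model, train, test); train/test each
#'   hold the per-sample predictions and the r(DMRmAge, age) summary
#' @export
split_validate <- function(methylome, samples, longevity, n_train = 55,
                           suggestive_p = 1e-4, sex_filter = "F",
                           seed = 1L) {
  eligible <- if (is.null(sex_filter)) samples$sample_id
              else samples$sample_id[samples$sex %in% sex_filter]
  if (n_train >= length(eligible))
    stop("n_train must be smaller than the eligible pool (",
         length(eligible), ")")
  set.seed(seed)
  train_ids <- sort(sample(eligible, n_train))
  test_ids <- setdiff(samples$sample_id, train_ids)
  if (length(test_ids) < 3) stop("fewer than 3 test samples")

  train_samples <- samples[samples$sample_id %in% train_ids, , drop = FALSE]
  ew <- run_ewas(methylome[, train_samples$sample_id, drop = FALSE],
                 train_samples, longevity)
  dmrs <- call_dmrs(ew, "age", suggestive_p)
  model <- fit_clock(methylome[, train_samples$sample_id, drop = FALSE],
                     dmrs, train_samples)
  pred <- predict_age(model, methylome)
  ages <- samples$age_days[match(names(pred), samples$sample_id)]
  acc <- age_acceleration(pred, ages, reference_ids = train_ids)

  report <- function(ids) {
    k <- acc$sample_id %in% ids
    r <- pearson_with_p(acc$dmrm_age_days[k],
                        ages[match(acc$sample_id[k], acc$sample_id)])
    assoc <- clock_associations(acc[k, , drop = FALSE],
                                samples, longevity)
    list(samples = acc[k, , drop = FALSE], age_correlation = r,
         associations = assoc)
  }
  list(split = list(train = train_ids, test = test_ids),
       n_age_dmrs = nrow(dmrs), model = model,
       train = report(train_ids), test = report(test_ids))
}
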