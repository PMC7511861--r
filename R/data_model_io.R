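# Domain containers and TSV readers/writers.
#
# All containers are plain data.frames / numeric matrices so they compose
# with base R and survive TSV round trips losslessly:
#   region set       data.frame: chrom, start, end, region_id, cpg_count,
#                    variant_count, feature_labels (";"-joined), gene_id
#   methylome /      numeric matrix, rows = regions (or transcripts),
#   expression       columns = samples, dimnames set
#   sample table     data.frame keyed by sample_id
#   longevity table  data.frame: strain, diet, lifespan_days (one row per
#                    animal in the longevity cohort)

BIN_LENGTH <- 150L

GENE_FEATURES <- c("promoter", "exon", "intron", "UTR")
ALL_FEATURES  <- c(GENE_FEATURES, "cpg_island", "intergenic", "rRNA", "LTR")

#' Construct and validate a region set
#'
#' A region set is a table of fixed-width (150 bp) non-overlapping genomic
#' bins with per-bin CpG counts, counts of segregating sequence variants,
#' genomic-feature labels and an optional cognate gene identifier.
#' Coordinates are 0-based half-open (BED convention).
#'
#' @param df data.frame with columns `chrom`, `start`, `end`, `region_id`,
#'   `cpg_count`, `variant_count`, `feature_labels` (semicolon-joined,
#'   possibly empty), `gene_id` (possibly `NA`/empty).
#' @return the validated data.frame, with class `"region_set"` prepended.
#' @export
region_set <- function(df) {
  req <- c("chrom", "start", "end", "region_id", "cpg_count",
           "variant_count", "feature_labels", "gene_id")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("region table missing columns: ", paste(miss, collapse = ", "))
  df <- df[req]
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df$cpg_count <- as.integer(df$cpg_count)
  df$variant_count <- as.integer(df$variant_count)
  df$region_id <- as.character(df$region_id)
  df$feature_labels <- as.character(df$feature_labels)
  df$feature_labels[is.na(df$feature_labels)] <- ""
  df$gene_id <- as.character(df$gene_id)
  df$gene_id[is.na(df$gene_id)] <- ""

  bad_len <- which(df$end - df$start != BIN_LENGTH)
  if (length(bad_len))
    stop("bins must span exactly ", BIN_LENGTH, " bp; offending region_id: ",
         paste(utils::head(df$region_id[bad_len], 5), collapse = ", "))
  if (anyDuplicated(df$region_id))
    stop("duplicate region_id: ",
         df$region_id[anyDuplicated(df$region_id)])
  if (any(df$cpg_count < 0) || any(df$variant_count < 0))
    stop("cpg_count and variant_count must be non-negative")

  labs <- region_feature_list(df)
  unknown <- setdiff(unique(unlist(labs)), ALL_FEATURES)
  if (length(unknown))
    stop("unknown feature labels: ", paste(unknown, collapse = ", "))
  gene_feat <- vapply(labs, function(l) any(l %in% GENE_FEATURES), logical(1))
  inter <- vapply(labs, function(l) "intergenic" %in% l, logical(1))
  if (any(inter & gene_feat))
    stop("intergenic bins may not carry gene feature labels: ",
         paste(utils::head(df$region_id[inter & gene_feat], 5), collapse = ", "))
  if (any(nzchar(df$gene_id) & !gene_feat))
    stop("gene_id present without any gene feature label: ",
         paste(utils::head(df$region_id[nzchar(df$gene_id) & !gene_feat], 5),
               collapse = ", "))

  # overlap check, per chromosome (order-independent)
  for (ch in unique(df$chrom)) {
    s <- sort(df$start[df$chrom == ch])
    if (length(s) > 1 && any(diff(s) < BIN_LENGTH)) {
      i <- which(diff(s) < BIN_LENGTH)[1]
      stop("overlapping bins on ", ch, " near start ", s[i])
    }
  }
  class(df) <- c("region_set", "data.frame")
  df
}

#' Split semicolon-joined feature labels into a list of character vectors
#' @param regions region set
#' @return list, one character vector of labels per bin
#' @export
region_feature_list <- function(regions) {
  strsplit(ifelse(nzchar(regions$feature_labels), regions$feature_labels, NA),
           ";", fixed = TRUE) |>
    lapply(function(x) if (length(x) == 1 && is.na(x)) character(0) else x)
}

#' Classify bins as genic or intergenic
#'
#' A bin is genic when it carries at least one of promoter/exon/intron/UTR;
#' all other bins count as intergenic.
#' @param regions region set
#' @return logical vector, TRUE = genic
#' @export
is_genic <- function(regions) {
  vapply(region_feature_list(regions),
         function(l) any(l %in% GENE_FEATURES), logical(1))
}

#' Read a region table from TSV
#' @param path tab-separated file with the region-set columns
#' @return validated region set
#' @export
read_region_table <- function(path) {
  df <- read_tsv_checked(path, c("chrom", "start", "end", "region_id",
                                 "cpg_count", "variant_count",
                                 "feature_labels", "gene_id"))
  for (col in c("start", "end", "cpg_count", "variant_count")) {
    v <- suppressWarnings(as.integer(df[[col]]))
    if (anyNA(v))
      stop("parse error in ", path, ": non-integer '", col, "' at line ",
           which(is.na(v))[1] + 1L)
    df[[col]] <- v
  }
  region_set(df)
}

#' Write a region table to TSV
#' @param regions region set
#' @param path output path
#' @export
write_region_table <- function(regions, path) {
  utils::write.table(as.data.frame(regions), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_checked <- function(path, required) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = NULL, colClasses = "character")
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("file ", path, " missing columns: ", paste(miss, collapse = ", "))
  df
}

#' Read a numeric matrix (methylome or expression) from TSV
#'
#' First column holds region/transcript ids; remaining column names are
#' sample ids. Every cell must be a finite number; missing values are
#' rejected rather than imputed.
#'
#' @param path TSV path
#' @return numeric matrix, rows = feature ids, columns = sample ids
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = NULL, colClasses = "character")
  if (ncol(df) < 2) stop("matrix file needs an id column plus samples")
  ids <- df[[1]]
  if (anyDuplicated(ids))
    stop("duplicate feature id: ", ids[anyDuplicated(ids)])
  if (anyDuplicated(names(df)[-1]))
    stop("duplicate sample id: ", names(df)[-1][anyDuplicated(names(df)[-1])])
  m <- matrix(NA_real_, nrow(df), ncol(df) - 1L,
              dimnames = list(ids, names(df)[-1]))
  for (j in seq_len(ncol(m))) {
    v <- suppressWarnings(as.numeric(df[[j + 1L]]))
    bad <- which(is.na(v) | !is.finite(v))
    if (length(bad))
      stop("parse error in ", path, ": non-finite value at row ", bad[1],
           " (id ", ids[bad[1]], "), column ", colnames(m)[j])
    m[, j] <- v
  }
  m
}

#' Write a numeric matrix to TSV
#' @param m numeric matrix with dimnames
#' @param path output path
#' @param id_col name for the feature-id column (default "region_id")
#' @export
write_matrix_tsv <- function(m, path, id_col = "region_id") {
  stopifnot(is.matrix(m), !is.null(rownames(m)), !is.null(colnames(m)))
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample metadata table from TSV
#' @param path TSV with columns sample_id, strain, diet, sex, age_days,
#'   bw0_g, bw0_age_days, final_weight_g, liver_weight_g, days_on_hfd
#' @return validated sample table (data.frame)
#' @export
read_sample_table <- function(path) {
  df <- read_tsv_checked(path, c("sample_id", "strain", "diet", "sex",
                                 "age_days", "bw0_g", "bw0_age_days",
                                 "final_weight_g", "liver_weight_g",
                                 "days_on_hfd"))
  for (col in c("age_days", "bw0_g", "bw0_age_days", "final_weight_g",
                "liver_weight_g", "days_on_hfd"))
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
  validate_sample_table(df)
}

#' Validate a sample table
#' @param df data.frame of per-animal covariates
#' @return the data.frame, invisibly checked
#' @export
validate_sample_table <- function(df) {
  stopifnot(!anyDuplicated(df$sample_id))
  if (!all(df$diet %in% c("CD", "HFD"))) stop("diet must be CD or HFD")
  if (!all(df$sex %in% c("F", "M"))) stop("sex must be F or M")
  if (any(df$age_days <= df$bw0_age_days))
    stop("age_days must exceed bw0_age_days")
  if (any(df$bw0_age_days < 0)) stop("bw0_age_days must be >= 0")
  if (any(df$days_on_hfd[df$diet == "CD"] != 0))
    stop("days_on_hfd must be 0 for CD animals")
  df$group <- strain_diet(df)
  df
}

#' Strain-by-diet grouping factor
#' @param samples sample table
#' @return character vector "strain:diet"
#' @export
strain_diet <- function(samples) paste(samples$strain, samples$diet, sep = ":")

#' Read a longevity table from TSV
#' @param path TSV with columns strain, diet, lifespan_days (one row per
#'   animal followed to natural death)
#' @return validated longevity data.frame
#' @export
read_longevity_table <- function(path) {
  df <- read_tsv_checked(path, c("strain", "diet", "lifespan_days"))
  df$lifespan_days <- suppressWarnings(as.numeric(df$lifespan_days))
  if (anyNA(df$lifespan_days) || any(df$lifespan_days <= 0))
    stop("lifespan_days must be positive numbers")
  if (!all(df$diet %in% c("CD", "HFD"))) stop("diet must be CD or HFD")
  df
}

#' Per-group life-span summaries
#' @param longevity longevity table
#' @return data.frame keyed by group ("strain:diet") with mean, median,
#'   min and max life span in days
#' @export
lifespan_summary <- function(longevity) {
  g <- paste(longevity$strain, longevity$diet, sep = ":")
  out <- do.call(rbind, lapply(split(longevity$lifespan_days, g), function(x)
    data.frame(mean_ls = mean(x), median_ls = stats::median(x),
               min_ls = min(x), max_ls = max(x), n = length(x))))
  out$group <- rownames(out)
  rownames(out) <- NULL
  out[c("group", "mean_ls", "median_ls", "min_ls", "max_ls", "n")]
}

#' Write a generic data.frame to TSV
#' @param df data.frame
#' @param path output path
#' @export
write_table_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' log10 RPKM transform of a count matrix
#'
#' RPKM = count / (region length in kb x library size in millions); the
#' returned value is log10(RPKM + offset). The offset (pseudocount, default
#' 1) keeps zero counts finite; downstream per-region inference is affine
#' invariant so the choice only shifts coefficient scale.
#'
#' @param counts integer matrix, rows = regions, cols = samples
#' @param library_sizes per-sample total mapped reads (> 0)
#' @param region_length_bp bin width in bp (default 150)
#' @param offset pseudocount added to RPKM before log10 (default 1)
#' @return numeric matrix of log10 RPKM values
#' @export
log_rpkm <- function(counts, library_sizes, region_length_bp = BIN_LENGTH,
                     offset = 1) {
  stopifnot(is.matrix(counts), length(library_sizes) == ncol(counts))
  if (any(library_sizes <= 0)) stop("library sizes must be positive")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (offset < 0) stop("offset must be non-negative")
  denom <- (region_length_bp / 1000) * (library_sizes / 1e6)
  rpkm <- sweep(counts, 2, denom, "/")
  out <- log10(rpkm + offset)
  if (any(!is.finite(out)))
    stop("non-finite log RPKM; use a positive offset when counts contain 0")
  out
}
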