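# Linking DMRs to cognate transcripts and cis methylation-expression
# correlation with trait-quadrant classification.

#' Pair DMRs with cognate transcripts via gene id
#'
#' A DMR is paired when its bin carries a gene_id present among the
#' expression matrix rows. When several transcripts share a gene id the
#' most variable one is used. DMRs without a gene id, or whose gene is not
#' expressed, are reported as unpaired.
#'
#' @param dmrs `call_dmrs` result
#' @param regions region set
#' @param expr transcript x sample expression matrix (rownames are gene /
#'   transcript ids)
#' @return list(pairs = data.frame(region_id, transcript_id),
#'   unpaired = character vector of DMR region ids)
#' @export
pair_dmrs_to_transcripts <- function(dmrs, regions, expr) {
  i <- match(dmrs$region_id, regions$region_id)
  if (anyNA(i)) stop("DMR regions absent from region set")
  gene <- regions$gene_id[i]
  # resolve duplicate transcript rows per gene by largest variance
  tx_ids <- rownames(expr)
  if (anyDuplicated(tx_ids)) {
    v <- apply(expr, 1, stats::var)
    keep <- unsplit(lapply(split(seq_along(tx_ids), tx_ids),
                           function(ii) ii == ii[which.max(v[ii])]),
                    tx_ids)
    expr_index <- seq_along(tx_ids)[keep]
    names(expr_index) <- tx_ids[keep]
  } else {
    expr_index <- stats::setNames(seq_along(tx_ids), tx_ids)
  }
  paired <- nzchar(gene) & gene %in% names(expr_index)
  list(pairs = data.frame(region_id = dmrs$region_id[paired],
                          transcript_id = gene[paired],
                          stringsAsFactors = FALSE),
       unpaired = dmrs$region_id[!paired])
}

quadrant_label <- function(dmr_dir, r_me, r_et) {
  paste0("meth", dmr_dir, "/expr", ifelse(r_me >= 0, "+", "-"),
         "/trait", ifelse(r_et >= 0, "+", "-"))
}

#' Cis DMR-transcript correlations with trait quadrants
#'
#' Pearson r between each DMR's methylation and its cognate transcript,
#' over the samples shared by both matrices; the transcript is also
#' correlated with the DMR's own trait (age, BW0 per sample, or group
#' median life span). Pairs whose |r_meth_expr| reaches
#' `critical_r(alpha, n_shared)` are flagged significant and given a
#' quadrant label combining the DMR direction with the two correlation
#' signs.
#'
#' @param pairs `pair_dmrs_to_transcripts` result (or its `$pairs`)
#' @param dmrs the `call_dmrs` result the pairs came from
#' @param methylome region x sample matrix
#' @param expr transcript x sample matrix
#' @param samples sample table
#' @param longevity longevity table
#' @param alpha nominal significance level for the |r| cutoff (0.05)
#' @return data.frame of class `"cis_pair_result"`: region_id,
#'   transcript_id, r_meth_expr, p_meth_expr, r_expr_trait, dmr_direction,
#'   significant, quadrant; attributes `r_threshold`, `n_shared`
#' @export
cis_correlations <- function(pairs, dmrs, methylome, expr, samples,
                             longevity, alpha = 0.05) {
  if (is.list(pairs) && !is.data.frame(pairs)) pairs <- pairs$pairs
  shared <- intersect(colnames(methylome), colnames(expr))
  if (length(shared) < 3) stop("need >= 3 shared samples")
  shared <- sort(shared)
  trait <- attr(dmrs, "trait")
  sm <- samples[match(shared, samples$sample_id), , drop = FALSE]
  trait_vec <- switch(trait,
    age = sm$age_days,
    BW0 = sm$bw0_g,
    LS = {
      ls <- lifespan_summary(longevity)
      ls$median_ls[match(sm$group, ls$group)]
    })
  r_star <- critical_r(alpha, length(shared))

  di <- match(pairs$region_id, dmrs$region_id)
  rows <- lapply(seq_len(nrow(pairs)), function(j) {
    m <- methylome[pairs$region_id[j], shared]
    e <- expr[pairs$transcript_id[j], shared]
    if (stats::sd(m) == 0 || stats::sd(e) == 0) return(NULL)
    me <- pearson_with_p(m, e)
    r_et <- if (stats::sd(trait_vec) > 0) stats::cor(e, trait_vec)
            else NA_real_
    data.frame(region_id = pairs$region_id[j],
               transcript_id = pairs$transcript_id[j],
               r_meth_expr = me$estimate, p_meth_expr = me$p_value,
               r_expr_trait = r_et,
               dmr_direction = dmrs$direction[di[j]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(region_id = character(0), transcript_id = character(0),
                      r_meth_expr = numeric(0), p_meth_expr = numeric(0),
                      r_expr_trait = numeric(0), dmr_direction = character(0))
  out$significant <- abs(out$r_meth_expr) >= r_star
  out$quadrant <- ifelse(out$significant,
                         quadrant_label(out$dmr_direction, out$r_meth_expr,
                                        out$r_expr_trait),
                         NA_character_)
  attr(out, "r_threshold") <- r_star
  attr(out, "n_shared") <- length(shared)
  attr(out, "trait") <- trait
  class(out) <- c("cis_pair_result", "data.frame")
  out
}
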