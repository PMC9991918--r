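#' Histone PTM ratio statistics
#'
#' Per (variant, modification): the ratio of replicate-mean relative
#' abundance (knockdown over control), its log2, and a two-tailed t-test on
#' the replicate abundances. Mirroring the source analysis, p-values are NOT
#' adjusted for multiple testing by default; a Benjamini-Hochberg column can
#' be added explicitly and is clearly marked as non-default. Rows with a
#' zero control mean (`ratio` undefined) or zero-variance identical groups
#' (t undefined) are flagged rather than given misleading values.
#'
#' @param records long PTM table: `variant`, `residue`, `modification`,
#'   `condition`, `replicate`, `abundance` (see [simulate_ptm()]).
#' @param conditions length-2 character, reference then treatment.
#' @param pooled use pooled-variance t instead of Welch.
#' @param adjust add the opt-in `fdr_bh` column (default FALSE, matching
#'   the unadjusted presentation).
#' @return data.frame with `variant`, `residue`, `modification`, `ratio`,
#'   `log2_ratio`, `p`, `flag` (`"ok"`, `"zero-control-mean"` or
#'   `"degenerate"`), plus `fdr_bh` when `adjust = TRUE`.
#' @export
ptm_ratio_table <- function(records, conditions = c("control", "KD"),
                            pooled = FALSE, adjust = FALSE) {
  stopifnot(all(c("variant", "residue", "modification", "condition",
                  "replicate", "abundance") %in% names(records)))
  keys <- unique(records[, c("variant", "residue", "modification")])
  keys <- keys[order(keys$variant, keys$residue, keys$modification), ,
               drop = FALSE]
  rows <- lapply(seq_len(nrow(keys)), function(k) {
    sel <- records$variant == keys$variant[k] &
      records$modification == keys$modification[k]
    ref <- records$abundance[sel & records$condition == conditions[1]]
    trt <- records$abundance[sel & records$condition == conditions[2]]
    if (length(ref) < 2L || length(trt) < 2L)
      stop("need at least 2 replicates per condition for ",
           keys$modification[k])
    flag <- "ok"; ratio <- NA_real_; p <- NA_real_
    if (mean(ref) == 0) {
      flag <- "zero-control-mean"
    } else {
      ratio <- mean(trt) / mean(ref)
      wt <- welch_t(trt, ref, pooled = pooled)
      if (wt$degenerate) flag <- "degenerate" else p <- wt$p
    }
    data.frame(variant = keys$variant[k], residue = keys$residue[k],
               modification = keys$modification[k], ratio = ratio,
               log2_ratio = log2(ratio), p = p, flag = flag,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (adjust) out$fdr_bh <- bh_adjust(out$p)
  out
}
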