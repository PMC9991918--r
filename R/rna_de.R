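#' Differential expression test for one knockdown arm versus control
#'
#' A transparent differential-expression engine: per-gene Welch t on
#' log2(CPM + 0.5), log2 fold change on the CPM + 0.5 scale (ratio of group
#' mean CPM after the pseudocount), Benjamini-Hochberg FDR across genes.
#' CPM is computed on median-of-ratios effective library sizes rather than
#' raw totals, so strong asymmetric deregulation does not drag neutral genes
#' into apparent change (composition bias). Genes with zero counts in every
#' sample are dropped and reported in the `dropped` attribute. The class
#' logic downstream ([assign_classes()]) is the analysis's contribution; the
#' engine is deliberately simple and pluggable.
#'
#' @param counts gene x sample integer matrix.
#' @param samples sample sheet with `sample` and `arm`.
#' @param arm knockdown arm to contrast against `control`.
#' @param control name of the reference arm.
#' @return data.frame with `gene`, `log2fc`, `p`, `fdr`; attribute
#'   `dropped` lists all-zero genes.
#' @export
de_test <- function(counts, samples, arm, control = "control") {
  counts <- as.matrix(counts)
  c_ref <- samples$sample[samples$arm == control]
  c_trt <- samples$sample[samples$arm == arm]
  if (length(c_ref) < 2L || length(c_trt) < 2L)
    stop("need at least 2 replicates per group")
  sub <- counts[, c(c_ref, c_trt), drop = FALSE]
  dropped <- rownames(sub)[rowSums(sub) == 0]
  keep <- rowSums(sub) > 0
  sub <- sub[keep, , drop = FALSE]
  ## median-of-ratios size factors (geometric-mean reference over genes
  ## expressed everywhere), scaled so the CPM unit is preserved on average
  pos <- rowSums(sub == 0) == 0
  sf <- if (sum(pos) >= 10) {
    ref <- exp(rowMeans(log(sub[pos, , drop = FALSE])))
    apply(sub[pos, , drop = FALSE], 2, function(cl) stats::median(cl / ref))
  } else colSums(sub) / mean(colSums(sub))
  sf <- sf / exp(mean(log(sf)))
  eff_lib <- sf * mean(colSums(sub))
  cpm <- sweep(sub, 2, eff_lib / 1e6, "/")
  lc <- log2(cpm + 0.5)
  i1 <- seq_along(c_ref); i2 <- length(c_ref) + seq_along(c_trt)
  n1 <- length(i1); n2 <- length(i2)
  m1 <- rowMeans(lc[, i1, drop = FALSE]); m2 <- rowMeans(lc[, i2, drop = FALSE])
  v1 <- rowSums((lc[, i1, drop = FALSE] - m1)^2) / (n1 - 1)
  v2 <- rowSums((lc[, i2, drop = FALSE] - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  t <- (m2 - m1) / sqrt(se2)
  df <- se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1)))
  p <- 2 * stats::pt(-abs(t), df)
  p[se2 == 0] <- 1  # zero-variance identical groups carry no evidence
  lfc <- log2((rowMeans(cpm[, i2, drop = FALSE]) + 0.5) /
                (rowMeans(cpm[, i1, drop = FALSE]) + 0.5))
  out <- data.frame(gene = rownames(sub), log2fc = unname(lfc),
                    p = unname(p), fdr = bh_adjust(unname(p)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}

#' Three-class gene assignment over two knockdown arms
#'
#' Implements the either-arm rule: a gene is `up` when it reaches
#' FDR < `fdr_cut` in at least one arm, every significant arm has a positive
#' log2 fold change, and no significant arm points the other way; `down` is
#' symmetric. Genes whose two arms are significant in opposite directions
#' are `neutral` with `conflict = TRUE`; everything else is `neutral`.
#'
#' @param result_a,result_b per-arm results from [de_test()] over the same
#'   gene universe.
#' @param fdr_cut FDR threshold (default 0.05).
#' @return data.frame with `gene`, `log2fc_shA`, `log2fc_shB`, `p_shA`,
#'   `p_shB`, `fdr_shA`, `fdr_shB`, `de_class`, `conflict`.
#' @export
assign_classes <- function(result_a, result_b, fdr_cut = 0.05) {
  if (!setequal(result_a$gene, result_b$gene))
    stop("gene universes differ between the two arms")
  b <- result_b[match(result_a$gene, result_b$gene), , drop = FALSE]
  a <- result_a
  sig_a <- a$fdr < fdr_cut
  sig_b <- b$fdr < fdr_cut
  up_votes <- (sig_a & a$log2fc > 0) + (sig_b & b$log2fc > 0)
  down_votes <- (sig_a & a$log2fc < 0) + (sig_b & b$log2fc < 0)
  de_class <- rep("neutral", nrow(a))
  conflict <- up_votes > 0 & down_votes > 0
  de_class[up_votes > 0 & down_votes == 0] <- "up"
  de_class[down_votes > 0 & up_votes == 0] <- "down"
  data.frame(gene = a$gene,
             log2fc_shA = a$log2fc, log2fc_shB = b$log2fc,
             p_shA = a$p, p_shB = b$p, fdr_shA = a$fdr, fdr_shB = b$fdr,
             de_class = de_class, conflict = conflict,
             stringsAsFactors = FALSE)
}

#' Two-arm differential expression pipeline
#'
#' Runs [de_test()] for both knockdown arms against control on the common
#' non-zero gene set and applies [assign_classes()].
#'
#' @param counts gene x sample integer matrix.
#' @param samples sample sheet with `sample` and `arm` (arms `control`,
#'   `shA`, `shB`).
#' @param fdr_cut FDR threshold for the class rule.
#' @return data.frame as [assign_classes()].
#' @export
de_pipeline <- function(counts, samples, fdr_cut = 0.05) {
  res_a <- de_test(counts, samples, "shA")
  res_b <- de_test(counts, samples, "shB")
  common <- intersect(res_a$gene, res_b$gene)
  assign_classes(res_a[res_a$gene %in% common, ],
                 res_b[res_b$gene %in% common, ], fdr_cut)
}
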