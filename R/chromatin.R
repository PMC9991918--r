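#' Region-level TPM quantification
#'
#' Converts raw region read counts to reads per kilobase of region per
#' million mapped reads: `TPM = count / (length_kb * libsize_millions)`.
#'
#' @param region_counts integer matrix, region x sample.
#' @param region_lengths region lengths in bp, recycled along rows.
#' @param library_sizes per-sample mapped read totals, recycled along
#'   columns.
#' @return numeric matrix of TPM values.
#' @examples
#' quantify_tpm(matrix(10), 1000, 1e6)  # 10
#' @export
quantify_tpm <- function(region_counts, region_lengths, library_sizes) {
  region_counts <- as.matrix(region_counts)
  if (any(region_lengths <= 0)) stop("zero-length region")
  if (any(library_sizes <= 0)) stop("library sizes must be positive")
  m <- sweep(region_counts, 1, region_lengths / 1000, "/")
  sweep(m, 2, library_sizes / 1e6, "/")
}

replicate_mean <- function(signal, samples, mark, condition) {
  cols <- samples$sample[samples$mark == mark & samples$condition == condition]
  if (length(cols) == 0L) stop("unknown mark/condition: ", mark, "/", condition)
  rowMeans(signal[, cols, drop = FALSE])
}

#' Mark presence by background-quantile threshold
#'
#' A transparent stand-in for peak calling: a mark is present at a region
#' when its replicate-mean TPM strictly exceeds the background threshold,
#' defined as the `background_quantile` quantile of that mark's region-wide
#' mean TPM distribution. The threshold is reported as an attribute.
#'
#' @param signal region x sample TPM matrix (rownames are region ids).
#' @param samples sample sheet with `sample`, `mark`, `condition`,
#'   `replicate`.
#' @param mark mark to test (must exist in the sample sheet).
#' @param condition condition whose replicates are averaged.
#' @param background_quantile quantile defining background (default 0.75).
#' @return logical vector named by region id, with attributes `threshold`
#'   and `mark`.
#' @export
mark_presence <- function(signal, samples, mark, condition = "control",
                          background_quantile = 0.75) {
  if (!mark %in% samples$mark) stop("unknown mark: ", mark)
  n_rep <- sum(samples$mark == mark & samples$condition == condition)
  if (n_rep < 2L) stop("need at least 2 replicates for ", mark, "/", condition)
  means <- replicate_mean(signal, samples, mark, condition)
  thr <- stats::quantile(means, background_quantile, names = FALSE)
  out <- means > thr
  names(out) <- rownames(signal)
  attr(out, "threshold") <- thr
  attr(out, "mark") <- mark
  out
}

#' Promoter chromatin-state classification
#'
#' Combines H3K4me3 and H3K27me3 presence into the four-state partition:
#' H3K4me3 only is active, H3K27me3 only is repressed, both marks is
#' bivalent (the low-activity "ready-to-fire" configuration), neither is
#' unmarked.
#'
#' @param presence_k4me3,presence_k27me3 named logical vectors over the same
#'   promoter set (e.g. from [mark_presence()]).
#' @return data.frame with `region_id` and `state`.
#' @export
classify_promoters <- function(presence_k4me3, presence_k27me3) {
  if (is.null(names(presence_k4me3)) || is.null(names(presence_k27me3)) ||
      !setequal(names(presence_k4me3), names(presence_k27me3)))
    stop("mismatched promoter sets between the two presence vectors")
  k27 <- presence_k27me3[names(presence_k4me3)]
  k4 <- presence_k4me3
  state <- ifelse(k4 & k27, "bivalent",
                  ifelse(k4, "active", ifelse(k27, "repressed", "unmarked")))
  data.frame(region_id = names(k4), state = unname(state),
             stringsAsFactors = FALSE)
}

#' Differential region signal between knockdown and control
#'
#' Per region and mark: the log2 ratio of replicate-mean TPM (knockdown over
#' control, 0.5 TPM pseudocount on both means) plus a moderated-t p-value
#' computed on log2(TPM + 0.5) with an empirical-Bayes shrunken variance,
#' which keeps two-replicate designs stable and null p-values calibrated.
#' FDR is Benjamini-Hochberg across regions within the mark. The exact
#' differential engine behind published "differential peak" volcano plots is
#' typically unstated; the moderated t here is a transparent stand-in and is
#' flagged as such in the output metadata.
#'
#' @param signal region x sample TPM matrix.
#' @param samples sample sheet (`sample`, `mark`, `condition`, `replicate`).
#' @param mark mark to analyze.
#' @param conditions length-2 character: reference then treatment (default
#'   control vs KD).
#' @return data.frame with `region_id`, `mark`, `log2_ratio`, `p`, `fdr`;
#'   attribute `method` records the engine.
#' @export
differential_regions <- function(signal, samples, mark,
                                 conditions = c("control", "KD")) {
  sel <- samples[samples$mark == mark & samples$condition %in% conditions, ,
                 drop = FALSE]
  n_per <- table(factor(sel$condition, levels = conditions))
  if (any(n_per < 2L))
    stop("need at least 2 replicates per condition for ", mark)
  mat <- log2(signal[, sel$sample, drop = FALSE] + 0.5)
  grp <- factor(sel$condition, levels = conditions)
  design <- stats::model.matrix(~grp)
  fit <- limma::eBayes(limma::lmFit(mat, design))
  p <- fit$p.value[, 2]
  mean_ref <- replicate_mean(signal, sel, mark, conditions[1])
  mean_trt <- replicate_mean(signal, sel, mark, conditions[2])
  out <- data.frame(region_id = rownames(signal), mark = mark,
                    log2_ratio = log2((mean_trt + 0.5) / (mean_ref + 0.5)),
                    p = unname(p), fdr = bh_adjust(unname(p)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "method") <-
    "empirical-Bayes moderated t on log2(TPM+0.5); stand-in for unstated published engine"
  out
}

#' TSS metaprofile: per-bin mean and standard error
#'
#' Averages binned signal across a group of regions, orienting minus-strand
#' regions 5' to 3' (their bin order is reversed) so profiles are aligned on
#' the TSS. The standard error is sd/sqrt(n regions) per bin.
#'
#' @param binned matrix, region x bin, uniform bins across the TSS window.
#' @param strand character vector per region (`+`, `-`, `.`).
#' @param groups factor/character per region; one profile per level.
#' @return data.frame with `group`, `bin`, `mean`, `sem`, `n`.
#' @export
tss_metaprofile <- function(binned, strand, groups) {
  binned <- as.matrix(binned)
  stopifnot(length(strand) == nrow(binned), length(groups) == nrow(binned))
  if (nrow(binned) == 0L) stop("empty group: no regions supplied")
  rev_rows <- strand == "-"
  if (any(rev_rows))
    binned[rev_rows, ] <- binned[rev_rows, rev(seq_len(ncol(binned))),
                                 drop = FALSE]
  out <- list()
  for (g in unique(groups)) {
    rows <- binned[groups == g, , drop = FALSE]
    if (nrow(rows) == 0L) stop("empty group: ", g)
    mu <- colMeans(rows)
    sem <- if (nrow(rows) > 1)
      apply(rows, 2, stats::sd) / sqrt(nrow(rows)) else rep(0, ncol(rows))
    out[[length(out) + 1L]] <- data.frame(
      group = g, bin = seq_len(ncol(rows)), mean = mu, sem = sem,
      n = nrow(rows), stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
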