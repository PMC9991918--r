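# Independent brute-force oracles kept deliberately separate from the
# package's implementations.

# BH by explicit sort / scale / running-minimum over the sorted order.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(q)))
  pmin(1, adj)[order(o)]
}

# Two-sided Mann-Whitney p by complete enumeration of group assignments.
mw_oracle <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  idx <- utils::combn(length(pooled), n1)
  u_all <- apply(idx, 2, function(i) sum(r[i])) - n1 * (n1 + 1) / 2
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * length(y) / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9)
}

# Gene-level hit calling by explicit sort, slice and count.
hit_oracle <- function(stats, manifest, direction = "enriched",
                       percentile = 25, min_multiple = 2) {
  keep <- if (direction == "enriched") stats$mean_log2fc > 0
          else stats$mean_log2fc < 0
  df <- stats[keep, , drop = FALSE]
  df <- df[order(-abs(df$mean_log2fc), df$shrna_id), , drop = FALSE]
  top_ids <- df$shrna_id[seq_len(floor(percentile / 100 * nrow(df)))]
  tg <- manifest[!manifest$is_control, , drop = FALSE]
  genes <- sort(unique(tg$gene))
  hits <- vapply(genes, function(g)
    sum(tg$shrna_id[tg$gene == g] %in% top_ids) >= min_multiple, TRUE)
  data.frame(gene = genes, hit = unname(hits), stringsAsFactors = FALSE)
}

# Random shRNA-stat instance for oracle-equivalence checks.
random_screen_instance <- function(n_shrnas, n_genes, seed) {
  set.seed(seed)
  gene <- sample(sprintf("g%02d", seq_len(n_genes)), n_shrnas, replace = TRUE)
  manifest <- data.frame(
    shrna_id = sprintf("sh%03d", seq_len(n_shrnas)), gene = gene,
    is_control = FALSE, stringsAsFactors = FALSE)
  stats <- data.frame(shrna_id = manifest$shrna_id,
                      mean_log2fc = round(rnorm(n_shrnas), 2),
                      stringsAsFactors = FALSE)
  list(manifest = manifest, stats = stats)
}
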