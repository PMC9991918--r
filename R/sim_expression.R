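#' Simulate expression counts and stage-expression profiles
#'
#' Generates gene-level negative-binomial RNA counts for a control arm and
#' two knockdown shRNA arms (`shA`, `shB`) in replicates, with the planted
#' expression link derived from the epigenome truth: genes with bivalent
#' KDM5C-high promoters gain `de_link_strength` log2 units in both knockdown
#' arms; genes with active KDM5C-high promoters gain the weaker
#' `de_link_strength * active_link_ratio` (high-activity promoters are less
#' sensitive to loss of the demethylase); the planted-down set loses
#' `de_link_strength`. Baseline expression depends on promoter state
#' (bivalent and repressed promoters are lowly expressed).
#'
#' The stage matrix gives per-gene log2 expression across the five myeloid
#' differentiation stages (LSK, pre-GM, GMP, Gr, Mono, immature to mature):
#' planted-up genes decrease monotonically with maturation, planted-down
#' genes increase, neutral genes are flat, each plus Gaussian noise
#' (`stage_noise_sd = 0` gives strictly monotone profiles).
#'
#' @param config a [sim_config()] object.
#' @param epigenome_truth the `truth` element of [simulate_epigenome()].
#' @return list with `counts` (gene x sample integer matrix), `samples`
#'   (sample sheet with `sample`, `arm`, `replicate`), `stage_matrix`
#'   (gene x stage log2 expression), and `truth` (data.frame `gene_id`,
#'   `planted_class`, `planted_log2fc`).
#' @export
simulate_expression <- function(config, epigenome_truth) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(epigenome_truth$genes))
    stop("precondition error: epigenome truth missing (run simulate_epigenome)")
  g <- epigenome_truth$genes
  set.seed(substream_seed(config$seed, "expression"))

  lfc <- numeric(nrow(g))
  if (config$de_link_strength != 0) {
    lfc[g$kdm5c_high & g$state == "bivalent"] <- config$de_link_strength
    lfc[g$kdm5c_high & g$state == "active"] <-
      config$de_link_strength * config$active_link_ratio
    lfc[g$planted_down] <- -config$de_link_strength
  }
  planted_class <- ifelse(lfc > 0, "up", ifelse(lfc < 0, "down", "neutral"))

  state_factor <- c(active = 2, bivalent = 0.3, repressed = 0.1, unmarked = 1)
  base_mu <- config$expr_depth * state_factor[g$state]

  samples <- data.frame(
    sample = c(sprintf("control_%d", seq_len(config$n_expr_reps)),
               sprintf("shA_%d", seq_len(config$n_expr_reps)),
               sprintf("shB_%d", seq_len(config$n_expr_reps))),
    arm = rep(c("control", "shA", "shB"), each = config$n_expr_reps),
    replicate = rep(seq_len(config$n_expr_reps), 3),
    stringsAsFactors = FALSE)
  counts <- matrix(0L, nrow(g), nrow(samples),
                   dimnames = list(g$gene_id, samples$sample))
  for (j in seq_len(nrow(samples))) {
    mu <- if (samples$arm[j] == "control") base_mu else base_mu * 2^lfc
    counts[, j] <- rnbinom_disp(nrow(g), mu, config$expr_dispersion)
  }

  ## stage matrix: up genes decrease immature -> mature, down genes increase
  ns <- config$n_stages
  base_log2 <- stats::rnorm(nrow(g), 6, 1)
  slope <- ifelse(planted_class == "up", -1, ifelse(planted_class == "down", 1, 0))
  stage_frac <- (seq_len(ns) - 1) / (ns - 1)
  stage_matrix <- outer(slope * config$stage_trend_log2, stage_frac) + base_log2
  if (config$stage_noise_sd > 0)
    stage_matrix <- stage_matrix +
      matrix(stats::rnorm(length(stage_matrix), 0, config$stage_noise_sd),
             nrow(stage_matrix))
  dimnames(stage_matrix) <- list(g$gene_id, config$stages)

  list(counts = counts, samples = samples, stage_matrix = stage_matrix,
       truth = data.frame(gene_id = g$gene_id, planted_class = planted_class,
                          planted_log2fc = lfc, stringsAsFactors = FALSE))
}
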