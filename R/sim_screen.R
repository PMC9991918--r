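#' Generate a pooled shRNA library manifest
#'
#' Builds the shRNA-to-gene map for the screen: `n_shrnas` targeting hairpins
#' spread as evenly as possible over `n_genes` genes (the remainder of
#' `n_shrnas %% n_genes` extra hairpins is assigned to genes chosen by the
#' seeded RNG), plus `round(controls_frac * n_shrnas)` non-targeting control
#' hairpins flagged `is_control`.
#'
#' @param config a [sim_config()] object.
#' @return data.frame with columns `shrna_id`, `gene` (`NA` for controls),
#'   `is_control`.
#' @examples
#' lib <- generate_library(sim_config(seed = 1))
#' nrow(lib[!lib$is_control, ])           # 849
#' length(unique(stats::na.omit(lib$gene)))  # 315
#' @export
generate_library <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_shrnas < config$n_genes)
    stop("invalid-config: n_shrnas must be at least n_genes")
  set.seed(substream_seed(config$seed, "library"))
  genes <- sprintf("gene_%03d", seq_len(config$n_genes))
  base <- config$n_shrnas %/% config$n_genes
  rem <- config$n_shrnas %% config$n_genes
  per_gene <- rep(base, config$n_genes)
  if (rem > 0) {
    extra <- sample.int(config$n_genes, rem)
    per_gene[extra] <- per_gene[extra] + 1L
  }
  gene_col <- rep(genes, per_gene)
  idx <- unlist(lapply(per_gene, seq_len))
  manifest <- data.frame(
    shrna_id = sprintf("sh_%s_%d", gene_col, idx),
    gene = gene_col,
    is_control = FALSE,
    stringsAsFactors = FALSE)
  n_ctrl <- round(config$controls_frac * config$n_shrnas)
  if (n_ctrl > 0) {
    manifest <- rbind(manifest, data.frame(
      shrna_id = sprintf("sh_ctrl_%03d", seq_len(n_ctrl)),
      gene = NA_character_, is_control = TRUE, stringsAsFactors = FALSE))
  }
  rownames(manifest) <- NULL
  manifest
}

# NB counts with variance = mu + mu^2 * disp; Poisson at disp = 0.
rnbinom_disp <- function(n, mu, disp) {
  if (disp <= 0) stats::rpois(n, mu) else stats::rnbinom(n, mu = mu, size = 1 / disp)
}

#' Simulate pooled screen count matrices with planted fitness effects
#'
#' Draws negative-binomial counts for the input pool(s) and output replicates
#' of the competitive in vivo screen. Planted enriched genes have the
#' expected output counts of all their hairpins multiplied by
#' `2^effect_log2fc`; depleted genes are divided by the same factor; control
#' hairpins and all other genes are null. The planted assignment is returned
#' as a truth table.
#'
#' @param manifest library manifest from [generate_library()].
#' @param config a [sim_config()] object.
#' @return list with `counts` (integer matrix, shRNA x sample), `samples`
#'   (sample sheet with `sample`, `role`, `replicate`), and `truth`
#'   (data.frame `gene`, `direction`).
#' @export
simulate_screen <- function(manifest, config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$depth_per_shrna <= 0 || config$nb_dispersion < 0)
    stop("invalid-config: depth must be positive and dispersion non-negative")
  if (anyDuplicated(manifest$shrna_id)) stop("manifest shrna_id not unique")
  set.seed(substream_seed(config$seed, "screen"))
  genes <- unique(manifest$gene[!manifest$is_control])
  planted <- sample(genes, config$n_planted_enriched + config$n_planted_depleted)
  enriched <- planted[seq_len(config$n_planted_enriched)]
  depleted <- setdiff(planted, enriched)
  eff <- ifelse(manifest$gene %in% enriched, config$effect_log2fc,
                ifelse(manifest$gene %in% depleted, -config$effect_log2fc, 0))
  eff[manifest$is_control] <- 0
  n <- nrow(manifest)
  samples <- data.frame(
    sample = c(sprintf("input_%d", seq_len(config$n_input_reps)),
               sprintf("output_%d", seq_len(config$n_output_reps))),
    role = rep(c("input", "output"), c(config$n_input_reps, config$n_output_reps)),
    replicate = c(seq_len(config$n_input_reps), seq_len(config$n_output_reps)),
    stringsAsFactors = FALSE)
  counts <- matrix(0L, n, nrow(samples),
                   dimnames = list(manifest$shrna_id, samples$sample))
  for (j in seq_len(nrow(samples))) {
    mu <- if (samples$role[j] == "input") rep(config$depth_per_shrna, n)
          else config$depth_per_shrna * 2^eff
    counts[, j] <- rnbinom_disp(n, mu, config$nb_dispersion)
  }
  truth <- data.frame(
    gene = c(enriched, depleted),
    direction = rep(c("enriched", "depleted"),
                    c(length(enriched), length(depleted))),
    stringsAsFactors = FALSE)
  truth <- truth[order(truth$gene), , drop = FALSE]
  rownames(truth) <- NULL
  list(counts = counts, samples = samples, truth = truth)
}
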