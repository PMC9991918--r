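#' Simulation configuration for the synthetic pipeline inputs
#'
#' Bundles and validates every parameter of the synthetic-data generator.
#' The defaults are the study conditions the pipeline is tested under: an
#' 849-shRNA library targeting 315 chromatin factors, a toy single-chromosome
#' genome of promoters and enhancers with planted active/bivalent/repressed
#' states and KDM5C occupancy, a knockdown-induced H3K4me3 gain and H3K4me1
#' loss at KDM5C-bound regions, expression counts for control plus two
#' knockdown shRNA arms in triplicate with the expression link planted at
#' bivalent KDM5C-bound promoters, monotone stage-expression trends across
#' five myeloid differentiation stages (LSK, pre-GM, GMP, Gr, Mono), a
#' two-sex patient cohort in which low expression of the X-linked gene raises
#' hazard in females only, and a histone-PTM relative-abundance table with a
#' planted H3K4me3 shift.
#'
#' All randomness flows from `seed` through named substreams per artifact, so
#' any single output can be regenerated in isolation and identical
#' configurations yield byte-identical files.
#'
#' @param seed integer root seed.
#' @param n_genes,n_shrnas library size: distinct target genes and targeting
#'   shRNAs (defaults 315 and 849).
#' @param controls_frac fraction of `n_shrnas` added as non-targeting control
#'   hairpins (extra rows, flagged in the manifest).
#' @param depth_per_shrna expected sequencing reads per shRNA per pool.
#' @param nb_dispersion negative-binomial dispersion of pool counts
#'   (variance = mu + mu^2 * dispersion); 0 gives Poisson counts.
#' @param n_input_reps,n_output_reps input and output pool replicates.
#' @param n_planted_enriched,n_planted_depleted genes planted with a fitness
#'   effect in the screen.
#' @param effect_log2fc planted gene-level shRNA effect (log2), applied to
#'   all of a gene's hairpins.
#' @param n_promoters,n_enhancers toy genome region counts.
#' @param frac_bivalent,frac_active,frac_repressed promoter state mixture
#'   (remainder is unmarked); must sum to at most 1.
#' @param kdm5c_high_frac fraction of promoters carrying high KDM5C
#'   occupancy, drawn from the bivalent and active classes.
#' @param kd_k4me3_gain,kd_k4me1_loss planted log2 shifts applied in the
#'   knockdown condition to H3K4me3 (gain) and H3K4me1 (loss) at KDM5C-bound
#'   regions.
#' @param signal_log2_sd log2-scale standard deviation of the multiplicative
#'   log-normal replicate noise on ChIP signal; 0 gives noiseless tracks.
#' @param n_signal_reps ChIP replicates per condition.
#' @param de_link_strength planted expression log2 fold change (both
#'   knockdown arms) at bivalent KDM5C-high promoters.
#' @param active_link_ratio multiplier (< 1) giving the weaker planted
#'   expression gain at active KDM5C-high promoters.
#' @param n_planted_down number of genes planted with the opposite
#'   (downregulation) effect; drawn from KDM5C-unbound promoters.
#' @param expr_depth,expr_dispersion,n_expr_reps expression count model:
#'   mean counts per gene, NB dispersion, replicates per arm.
#' @param stage_trend_log2 total planted log2 change across the five
#'   differentiation stages for up (decreasing) and down (increasing) genes.
#' @param stage_noise_sd per-entry Gaussian noise of the stage matrix.
#' @param n_female,n_male cohort sizes.
#' @param female_low_hr hazard ratio for below-median KDM5C expression in
#'   females; males use `male_low_hr` on the summed KDM5C+KDM5D score.
#' @param male_low_hr see above.
#' @param base_hazard baseline event hazard per month.
#' @param censor_hazard independent exponential censoring hazard per month.
#' @param mutation_base_freq baseline per-gene mutation frequency in the
#'   cohort; quartile-enriched genes get their odds multiplied.
#' @param mutation_or odds multiplier for the planted quartile-enriched
#'   mutations.
#' @param n_ptm_reps mass-spec replicates per condition.
#' @param ptm_shift_log2 planted log2 shift of the H3K4me3 relative
#'   abundance in the knockdown condition.
#' @param ptm_noise_sd log-scale replicate noise of PTM abundances before
#'   renormalization.
#' @return object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(seed = 1)
#' cfg$n_shrnas
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 315L, n_shrnas = 849L, controls_frac = 0.05,
                       depth_per_shrna = 1000, nb_dispersion = 0.05,
                       n_input_reps = 1L, n_output_reps = 3L,
                       n_planted_enriched = 30L, n_planted_depleted = 30L,
                       effect_log2fc = 1.5,
                       n_promoters = 2000L, n_enhancers = 500L,
                       frac_bivalent = 0.10, frac_active = 0.12,
                       frac_repressed = 0.12, kdm5c_high_frac = 0.15,
                       kd_k4me3_gain = 1, kd_k4me1_loss = 1,
                       signal_log2_sd = 0.25, n_signal_reps = 2L,
                       de_link_strength = 1.5, active_link_ratio = 0.5,
                       n_planted_down = 150L,
                       expr_depth = 2000, expr_dispersion = 0.01,
                       n_expr_reps = 3L,
                       stage_trend_log2 = 2, stage_noise_sd = 0.1,
                       n_female = 400L, n_male = 400L,
                       female_low_hr = 3, male_low_hr = 2,
                       base_hazard = 0.03, censor_hazard = 0.015,
                       mutation_base_freq = 0.08, mutation_or = 8,
                       n_ptm_reps = 4L, ptm_shift_log2 = 1,
                       ptm_noise_sd = 0.1) {
  cfg <- as.list(environment())
  cfg$stages <- c("LSK", "pre-GM", "GMP", "Gr", "Mono")
  cfg$n_stages <- 5L
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  fracs <- c(controls_frac = cfg$controls_frac, frac_bivalent = cfg$frac_bivalent,
             frac_active = cfg$frac_active, frac_repressed = cfg$frac_repressed,
             kdm5c_high_frac = cfg$kdm5c_high_frac,
             active_link_ratio = cfg$active_link_ratio)
  bad <- fracs < 0 | fracs > 1
  if (any(bad)) stop("invalid-config: fractions outside [0, 1]: ",
                     paste(names(fracs)[bad], collapse = ", "))
  if (cfg$frac_bivalent + cfg$frac_active + cfg$frac_repressed > 1)
    stop("invalid-config: promoter state mixture sums to more than 1")
  counts <- c(n_genes = cfg$n_genes, n_shrnas = cfg$n_shrnas,
              n_promoters = cfg$n_promoters, n_input_reps = cfg$n_input_reps,
              n_output_reps = cfg$n_output_reps, n_expr_reps = cfg$n_expr_reps,
              n_signal_reps = cfg$n_signal_reps, n_ptm_reps = cfg$n_ptm_reps,
              n_female = cfg$n_female, n_male = cfg$n_male)
  if (any(counts < 1)) stop("invalid-config: counts must be positive: ",
                            paste(names(counts)[counts < 1], collapse = ", "))
  if (cfg$n_shrnas < cfg$n_genes)
    stop("invalid-config: n_shrnas (", cfg$n_shrnas,
         ") must be at least n_genes (", cfg$n_genes, ")")
  if (cfg$depth_per_shrna <= 0 || cfg$nb_dispersion < 0)
    stop("invalid-config: depth must be positive and dispersion non-negative")
  if (cfg$female_low_hr <= 0 || cfg$male_low_hr <= 0)
    stop("invalid-config: hazard ratios must be positive")
  if (cfg$n_enhancers < 0 || cfg$n_planted_down < 0 ||
      cfg$n_planted_enriched < 0 || cfg$n_planted_depleted < 0)
    stop("invalid-config: planted counts must be non-negative")
  if (cfg$n_planted_enriched + cfg$n_planted_depleted > cfg$n_genes)
    stop("invalid-config: more planted screen genes than genes")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic pipeline configuration (seed ", x$seed, ")\n", sep = "")
  cat("  screen:    ", x$n_shrnas, " shRNAs / ", x$n_genes, " genes, ",
      x$n_planted_enriched, "+", x$n_planted_depleted,
      " planted at |log2FC| ", x$effect_log2fc, "\n", sep = "")
  cat("  epigenome: ", x$n_promoters, " promoters / ", x$n_enhancers,
      " enhancers on chrS; bivalent ", x$frac_bivalent, ", active ",
      x$frac_active, ", repressed ", x$frac_repressed, "\n", sep = "")
  cat("  expression:", x$n_expr_reps, "reps x {control, shA, shB}, link",
      x$de_link_strength, "log2 at bivalent KDM5C-high promoters\n")
  cat("  cohort:    ", x$n_female, " females / ", x$n_male,
      " males, low-expression HR ", x$female_low_hr, " (F) / ",
      x$male_low_hr, " (M)\n", sep = "")
  invisible(x)
}

# Deterministic substream seed for a named artifact. Keeps every generator
# reproducible in isolation; result stays below 2^31 - 1.
substream_seed <- function(seed, name) {
  codes <- utf8ToInt(name)
  h <- sum(codes * seq_along(codes)) %% 100003
  as.integer((as.numeric(seed) %% 1000003) * 2011 + h * 10007) %% 2147483647L
}
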