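#' Simulate a two-sex AML patient cohort with expression-linked hazard
#'
#' Females: overall-survival hazard is multiplied by `female_low_hr` for
#' patients with below-median KDM5C expression (the X-linked gene escapes
#' X-inactivation, so expression alone is prognostic in females). Males:
#' hazard is tied to the summed KDM5C + KDM5D score (the Y-linked paralog
#' provides redundancy), multiplied by `male_low_hr` below the median sum.
#' Event times are exponential with independent exponential censoring; a
#' disease-free-survival endpoint is generated from the same hazard
#' structure at 1.3x the baseline rate. Mutation columns are Bernoulli with
#' planted odds multipliers in the female expression quartiles:
#' `PML_RARA` and `IDH1` enriched in the top quartile, `DNMT3A` and `KRAS`
#' in the bottom quartile, `NPM1` unenriched.
#'
#' @param config a [sim_config()] object.
#' @return list with `records` (data.frame: `patient_id`, `sex`, `KDM5C`,
#'   `KDM5D`, `os_time`, `os_event`, `dfs_time`, `dfs_event`, and
#'   `mut_*` 0/1 columns; times in months) and `truth` (planted hazard
#'   ratios and mutation enrichment design).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$female_low_hr <= 0 || config$male_low_hr <= 0)
    stop("invalid-config: hazard ratios must be positive")
  set.seed(substream_seed(config$seed, "cohort"))
  nf <- config$n_female; nm <- config$n_male
  n <- nf + nm
  sex <- rep(c("female", "male"), c(nf, nm))
  kdm5c <- c(stats::rnorm(nf, 8, 1), stats::rnorm(nm, 7, 1))
  kdm5d <- ifelse(sex == "male", stats::rnorm(n, 6, 1), 0)

  score <- ifelse(sex == "female", kdm5c, kdm5c + kdm5d)
  low <- logical(n)
  low[sex == "female"] <- score[sex == "female"] <
    stats::median(score[sex == "female"])
  low[sex == "male"] <- score[sex == "male"] <
    stats::median(score[sex == "male"])
  hr <- ifelse(low, ifelse(sex == "female", config$female_low_hr,
                           config$male_low_hr), 1)

  draw_endpoint <- function(rate_scale) {
    ev_t <- stats::rexp(n, config$base_hazard * rate_scale * hr)
    cn_t <- if (config$censor_hazard > 0)
      stats::rexp(n, config$censor_hazard) else rep(Inf, n)
    list(time = pmin(ev_t, cn_t), event = as.integer(ev_t <= cn_t))
  }
  os <- draw_endpoint(1)
  dfs <- draw_endpoint(1.3)

  records <- data.frame(
    patient_id = sprintf("P%04d", seq_len(n)), sex = sex,
    KDM5C = kdm5c, KDM5D = kdm5d,
    os_time = os$time, os_event = os$event,
    dfs_time = dfs$time, dfs_event = dfs$event,
    stringsAsFactors = FALSE)

  ## mutation columns: planted quartile enrichment among females
  mut_design <- data.frame(
    gene = c("PML_RARA", "IDH1", "DNMT3A", "KRAS", "NPM1"),
    enriched_in = c("high", "high", "low", "low", "none"),
    odds_ratio = c(config$mutation_or, config$mutation_or / 2,
                   config$mutation_or / 2, config$mutation_or / 2, 1),
    stringsAsFactors = FALSE)
  f_expr <- kdm5c[sex == "female"]
  qlo <- stats::quantile(f_expr, 0.25, type = 1)
  qhi <- stats::quantile(f_expr, 0.75, type = 1)
  fquart <- rep("mid", n)
  fquart[sex == "female" & kdm5c <= qlo] <- "low"
  fquart[sex == "female" & kdm5c > qhi] <- "high"
  fquart[sex == "male"] <- "mid"
  base_logodds <- stats::qlogis(config$mutation_base_freq)
  for (k in seq_len(nrow(mut_design))) {
    bump <- ifelse(fquart == mut_design$enriched_in[k],
                   log(mut_design$odds_ratio[k]), 0)
    pr <- stats::plogis(base_logodds + bump)
    records[[paste0("mut_", mut_design$gene[k])]] <-
      stats::rbinom(n, 1, pr)
  }

  list(records = records,
       truth = list(female_low_hr = config$female_low_hr,
                    male_low_hr = config$male_low_hr,
                    mutation_design = mut_design))
}

#' Simulate histone PTM relative-abundance tables
#'
#' Per histone variant (H3.1, H3.3) and residue (K4, K27), relative
#' abundances of the modification states are drawn around fixed base
#' proportions with multiplicative log-normal replicate noise and
#' renormalized, so abundances within each
#' (variant, residue, condition, replicate) group sum to exactly 1. In the
#' knockdown condition only the H3K4me3 base proportion is multiplied by
#' `2^ptm_shift_log2` before renormalization (the within-residue
#' renormalization moves the complementary K4 states slightly in the
#' opposite direction, as the closed composition requires).
#'
#' @param config a [sim_config()] object.
#' @return list with `records` (long data.frame: `variant`, `residue`,
#'   `modification`, `condition`, `replicate`, `abundance`) and `truth`
#'   (the shifted modification and its planted log2 shift).
#' @export
simulate_ptm <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(substream_seed(config$seed, "ptm"))
  base <- list(
    K4 = c(K4me0 = 0.70, K4me1 = 0.15, K4me2 = 0.10, K4me3 = 0.05),
    K27 = c(K27me0 = 0.35, K27me1 = 0.25, K27me2 = 0.20, K27me3 = 0.15,
            K27ac = 0.05))
  variants <- c("H3.1", "H3.3")
  out <- list()
  for (v in variants) for (res in names(base)) {
    props <- base[[res]]
    ## mild variant difference so the two tables are not identical
    if (v == "H3.3" && res == "K27") props <- props * c(1.1, 1, 1, 0.8, 1.2)
    for (cond in c("control", "KD")) {
      p0 <- props
      if (cond == "KD" && res == "K4")
        p0["K4me3"] <- p0["K4me3"] * 2^config$ptm_shift_log2
      for (r in seq_len(config$n_ptm_reps)) {
        noise <- if (config$ptm_noise_sd > 0)
          exp(stats::rnorm(length(p0), 0, config$ptm_noise_sd)) else 1
        ab <- p0 * noise
        if (any(ab < 0)) stop("generation error: negative abundance")
        ab <- ab / sum(ab)
        out[[length(out) + 1L]] <- data.frame(
          variant = v, residue = res, modification = names(p0),
          condition = cond, replicate = r, abundance = unname(ab),
          stringsAsFactors = FALSE)
      }
    }
  }
  list(records = do.call(rbind, out),
       truth = list(shifted_modification = "K4me3",
                    shift_log2 = config$ptm_shift_log2))
}
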