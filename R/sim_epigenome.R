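#' Simulate a toy epigenome with planted promoter states and KDM5C occupancy
#'
#' Lays out a single chromosome `chrS` with one promoter per gene (TSS plus
#' or minus 2 kb, one 20 kb slot per gene) and intergenic enhancers placed at
#' least 2 kb from any TSS inside a host gene's slot. Each promoter gets a
#' planted chromatin state (active, bivalent, repressed, unmarked) and the
#' marks' TPM signal is generated to match it: active promoters carry high
#' H3K4me3 and H3K27ac, bivalent promoters carry low-but-present H3K4me3
#' together with H3K27me3, repressed promoters carry H3K27me3 only. A
#' planted subset of bivalent and active promoters (and a subset of
#' enhancers) carries high KDM5C occupancy; in the knockdown condition those
#' regions gain `kd_k4me3_gain` log2 units of H3K4me3 and lose
#' `kd_k4me1_loss` log2 units of H3K4me1, emulating loss of the demethylase.
#' Replicate noise is multiplicative log-normal (`signal_log2_sd = 0` gives
#' noiseless tracks).
#'
#' Genes planted for downregulation (an indirect effect in the underlying
#' biology) are drawn from KDM5C-unbound promoters, receive reduced KDM5C
#' occupancy, shorter CpG islands, and a higher enhancer-assignment weight.
#'
#' @param config a [sim_config()] object.
#' @return list with `regions` (BED-style data.frame: `region_id`, `chrom`,
#'   `start`, `end`, `strand`, `kind`, `gene_id`, `cpg_island_length`),
#'   `tss` (gene_id, tss, strand), `signal` (region x sample TPM matrix),
#'   `samples` (sample sheet: `sample`, `mark`, `condition`, `replicate`),
#'   and `truth` (promoter states, KDM5C-high region ids, gene-level planted
#'   table, enhancer host map).
#' @export
simulate_epigenome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(substream_seed(config$seed, "epigenome"))
  np <- config$n_promoters; ne <- config$n_enhancers
  slot <- 20000L
  tss <- 10000L + (seq_len(np) - 1L) * slot
  strand <- sample(c("+", "-"), np, replace = TRUE)
  gene_id <- sprintf("G%04d", seq_len(np))

  prom <- data.frame(
    region_id = sprintf("prom_%04d", seq_len(np)), chrom = "chrS",
    start = tss - 2000L, end = tss + 2000L, strand = strand,
    kind = "promoter", gene_id = gene_id, stringsAsFactors = FALSE)
  if (any(prom$start < 0)) stop("generation error: negative promoter start")
  ov <- prom$start[-1] < prom$end[-np]
  if (np > 1 && any(ov)) stop("generation error: overlapping promoter intervals")

  ## planted states
  n_biv <- round(config$frac_bivalent * np)
  n_act <- round(config$frac_active * np)
  n_rep <- round(config$frac_repressed * np)
  state <- sample(rep(c("bivalent", "active", "repressed", "unmarked"),
                      c(n_biv, n_act, n_rep, np - n_biv - n_act - n_rep)))

  ## KDM5C-high promoters: drawn from bivalent and active classes
  eligible <- which(state %in% c("bivalent", "active"))
  n_high <- min(round(config$kdm5c_high_frac * np), length(eligible))
  high_idx <- sample(eligible, n_high)
  kdm5c_high <- rep(FALSE, np); kdm5c_high[high_idx] <- TRUE

  ## planted-down genes: KDM5C-unbound promoters
  down_pool <- which(!kdm5c_high)
  n_down <- min(config$n_planted_down, length(down_pool))
  down_idx <- sample(down_pool, n_down)
  planted_down <- rep(FALSE, np); planted_down[down_idx] <- TRUE

  cpg <- round(stats::rlnorm(np, log(1000), 0.3))
  cpg[planted_down] <- round(cpg[planted_down] * 0.5)
  prom$cpg_island_length <- cpg

  ## enhancers: hosts weighted toward planted-down genes, <= 6 per host so
  ## every enhancer stays nearest to its host TSS (offsets 4-9 kb)
  w <- ifelse(planted_down, 3, 1)
  host <- sample.int(np, ne, replace = TRUE, prob = w)
  tab <- table(host)
  over <- as.integer(names(tab))[tab > 6]
  for (h in over) {
    ex <- which(host == h)[-seq_len(6L)]
    for (k in ex) {
      repeat {
        cand <- sample.int(np, 1)
        if (sum(host == cand) < 6) { host[k] <- cand; break }
      }
    }
  }
  off <- integer(ne)
  for (h in unique(host)) {
    at <- which(host == h)
    off[at] <- 4000L + (seq_along(at) - 1L) * 1000L
  }
  enh <- data.frame(
    region_id = sprintf("enh_%04d", seq_len(max(ne, 0L)))[seq_len(ne)],
    chrom = "chrS", start = tss[host] + off, end = tss[host] + off + 1000L,
    strand = ".", kind = "enhancer", gene_id = NA_character_,
    cpg_island_length = NA_real_, stringsAsFactors = FALSE)
  enh_high <- rep(FALSE, ne)
  if (ne > 0) enh_high[sample.int(ne, round(config$kdm5c_high_frac * ne))] <- TRUE
  enh_active <- rep(FALSE, ne)
  if (ne > 0) enh_active[sample.int(ne, floor(ne / 2))] <- TRUE

  regions <- rbind(prom, enh)
  regions <- regions[order(regions$start, regions$end), , drop = FALSE]
  rownames(regions) <- NULL

  ## sample sheet: 4 histone marks x {control, KD} x reps, + KDM5C occupancy
  marks <- c("H3K4me1", "H3K4me3", "H3K27me3", "H3K27ac")
  samples <- expand.grid(replicate = seq_len(config$n_signal_reps),
                         condition = c("control", "KD"), mark = marks,
                         stringsAsFactors = FALSE)[, 3:1]
  samples <- rbind(samples,
                   data.frame(mark = "KDM5C", condition = "control",
                              replicate = seq_len(config$n_signal_reps)))
  samples$sample <- sprintf("%s_%s_%d", samples$mark, samples$condition,
                            samples$replicate)

  ## base mean TPM per region per mark
  is_prom <- regions$kind == "promoter"
  pidx <- match(regions$gene_id, gene_id)          # promoter rows -> gene index
  eidx <- match(regions$region_id, enh$region_id)  # enhancer rows -> enh index
  st <- ifelse(is_prom, state[pidx], NA)
  r_high <- ifelse(is_prom, kdm5c_high[pidx], enh_high[eidx])
  r_down <- ifelse(is_prom, planted_down[pidx], FALSE)
  e_act <- ifelse(is_prom, FALSE, enh_active[eidx])

  base_mean <- function(mark) {
    m <- numeric(nrow(regions))
    if (mark == "H3K4me3")
      m <- ifelse(is_prom, c(active = 40, bivalent = 8, repressed = 0.5,
                             unmarked = 0.5)[st], 1)
    else if (mark == "H3K27me3")
      m <- ifelse(is_prom, c(active = 0.5, bivalent = 25, repressed = 30,
                             unmarked = 0.5)[st], 1)
    else if (mark == "H3K4me1")
      m <- ifelse(is_prom, 5, 20)
    else if (mark == "H3K27ac")
      m <- ifelse(is_prom, ifelse(st == "active", 20, 0.5),
                  ifelse(e_act, 15, 1))
    else if (mark == "KDM5C")
      m <- ifelse(r_high, 20, ifelse(r_down, 0.3, 1))
    else stop("unknown mark: ", mark)
    unname(m)
  }

  signal <- matrix(0, nrow(regions), nrow(samples),
                   dimnames = list(regions$region_id, samples$sample))
  for (j in seq_len(nrow(samples))) {
    mu <- base_mean(samples$mark[j])
    if (samples$condition[j] == "KD") {
      if (samples$mark[j] == "H3K4me3") mu[r_high] <- mu[r_high] * 2^config$kd_k4me3_gain
      if (samples$mark[j] == "H3K4me1") mu[r_high] <- mu[r_high] * 2^-config$kd_k4me1_loss
    }
    noise <- if (config$signal_log2_sd > 0)
      2^stats::rnorm(nrow(regions), 0, config$signal_log2_sd) else 1
    signal[, j] <- mu * noise
  }

  genes <- data.frame(
    gene_id = gene_id, region_id = prom$region_id, state = state,
    kdm5c_high = kdm5c_high, planted_down = planted_down,
    stringsAsFactors = FALSE)
  truth <- list(
    promoter_states = data.frame(region_id = prom$region_id,
                                 gene_id = gene_id, state = state,
                                 stringsAsFactors = FALSE),
    kdm5c_high = c(prom$region_id[kdm5c_high], enh$region_id[enh_high]),
    genes = genes,
    enhancer_hosts = if (ne > 0)
      data.frame(enhancer_id = enh$region_id, host_gene = gene_id[host],
                 stringsAsFactors = FALSE)
    else data.frame(enhancer_id = character(), host_gene = character()))

  list(regions = regions,
       tss = data.frame(gene_id = gene_id, tss = tss, strand = strand,
                        stringsAsFactors = FALSE),
       signal = signal, samples = samples, truth = truth)
}
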