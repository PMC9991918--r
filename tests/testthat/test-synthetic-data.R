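test_that("library manifest has the study's shape: 849 shRNAs over 315 genes", {
  lib <- default_sim()$library
  targeting <- lib[!lib$is_control, ]
  expect_equal(nrow(targeting), 849)
  expect_equal(length(unique(targeting$gene)), 315)
  expect_true(all(table(targeting$gene) >= 1))
  expect_false(anyDuplicated(lib$shrna_id) > 0)
})

test_that("degenerate and invalid library configurations behave per contract", {
  cfg <- sim_config(seed = 2, n_genes = 1, n_shrnas = 3, controls_frac = 0,
                    n_planted_enriched = 0, n_planted_depleted = 0)
  lib <- generate_library(cfg)
  expect_equal(nrow(lib), 3)
  expect_equal(length(unique(lib$gene)), 1)
  expect_error(sim_config(n_genes = 10, n_shrnas = 5), "invalid-config")
  expect_error(sim_config(frac_bivalent = 0.6, frac_active = 0.6),
               "mixture")
  expect_error(sim_config(female_low_hr = -1), "hazard")
})

test_that("identical configurations write byte-identical files", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_simulation(simulate_all(small_cfg(seed = 5)), d1)
  write_simulation(simulate_all(small_cfg(seed = 5)), d2)
  files <- list.files(d1, recursive = TRUE)
  expect_gt(length(files), 15)
  h1 <- unname(tools::md5sum(file.path(d1, files)))
  h2 <- unname(tools::md5sum(file.path(d2, files)))
  expect_identical(h1, h2)
})

test_that("planted screen effect of 2 log2 units yields ~4x output/input ratios", {
  cfg <- sim_config(seed = 3, effect_log2fc = 2, depth_per_shrna = 1e5,
                    nb_dispersion = 0.001, n_output_reps = 4)
  lib <- generate_library(cfg)
  scr <- simulate_screen(lib, cfg)
  enr <- scr$truth$gene[scr$truth$direction == "enriched"]
  in_mean <- rowMeans(scr$counts[, scr$samples$role == "input", drop = FALSE])
  out_mean <- rowMeans(scr$counts[, scr$samples$role == "output", drop = FALSE])
  ratio <- out_mean / in_mean
  enr_rows <- lib$shrna_id[lib$gene %in% enr & !lib$is_control]
  null_rows <- lib$shrna_id[!lib$gene %in% scr$truth$gene & !lib$is_control]
  expect_equal(mean(ratio[rownames(scr$counts) %in% enr_rows]) /
                 mean(ratio[rownames(scr$counts) %in% null_rows]),
               4, tolerance = 0.05)
})

test_that("null screen effect leaves planted genes indistinguishable from controls", {
  cfg <- sim_config(seed = 4, effect_log2fc = 0, depth_per_shrna = 1e5,
                    nb_dispersion = 0.001)
  lib <- generate_library(cfg)
  scr <- simulate_screen(lib, cfg)
  in_mean <- rowMeans(scr$counts[, scr$samples$role == "input", drop = FALSE])
  out_mean <- rowMeans(scr$counts[, scr$samples$role == "output", drop = FALSE])
  ratio <- out_mean / in_mean
  planted <- rownames(scr$counts) %in%
    lib$shrna_id[lib$gene %in% scr$truth$gene]
  expect_equal(mean(ratio[planted]), mean(ratio[!planted]), tolerance = 0.02)
})

test_that("zero dispersion gives Poisson-like counts (variance ~ mean)", {
  cfg <- sim_config(seed = 6, nb_dispersion = 0, n_output_reps = 50,
                    n_genes = 20, n_shrnas = 40, depth_per_shrna = 500,
                    n_planted_enriched = 0, n_planted_depleted = 0)
  scr <- simulate_screen(generate_library(cfg), cfg)
  out <- scr$counts[, scr$samples$role == "output"]
  vm <- apply(out, 1, var) / rowMeans(out)
  expect_equal(mean(vm), 1, tolerance = 0.15)
})

test_that("BED output is 0-based, half-open, sorted and round-trips", {
  d <- withr::local_tempdir()
  write_simulation(simulate_all(small_cfg(seed = 8)), d)
  bed <- read_bed(file.path(d, "regions.bed"))
  expect_false(is.unsorted(bed$start))
  expect_true(all(bed$start >= 0))
  expect_true(all(bed$end > bed$start))
  regions <- simulate_epigenome(small_cfg(seed = 8))$regions
  expect_setequal(bed$region_id, regions$region_id)
})

test_that("malformed BED errors name the offending line", {
  f <- withr::local_tempfile(lines = c("chrS\t0\t100\tok", "chrS\t50\tx\tbad"))
  expect_error(read_bed(f), "line 2")
})

test_that("noiseless epigenome reproduces planted bivalent flags downstream", {
  cfg <- small_cfg(seed = 9, signal_log2_sd = 0)
  epi <- simulate_epigenome(cfg)
  prom <- epi$truth$promoter_states
  p4 <- mark_presence(epi$signal, epi$samples, "H3K4me3", "control")
  p27 <- mark_presence(epi$signal, epi$samples, "H3K27me3", "control")
  biv <- prom$region_id[prom$state == "bivalent"]
  expect_true(all(p4[biv]))
  expect_true(all(p27[biv]))
})

test_that("null knockdown leaves control and KD signal distributions matched", {
  cfg <- small_cfg(seed = 10, kd_k4me3_gain = 0, kd_k4me1_loss = 0,
                   signal_log2_sd = 0)
  epi <- simulate_epigenome(cfg)
  ctl <- rowMeans(
    epi$signal[, epi$samples$sample[epi$samples$mark == "H3K4me3" &
                                      epi$samples$condition == "control"]])
  kd <- rowMeans(
    epi$signal[, epi$samples$sample[epi$samples$mark == "H3K4me3" &
                                      epi$samples$condition == "KD"]])
  expect_equal(ctl, kd, tolerance = 1e-12)
})

test_that("zero expression link empties the planted DE truth", {
  cfg <- small_cfg(seed = 11, de_link_strength = 0)
  epi <- simulate_epigenome(cfg)
  ex <- simulate_expression(cfg, epi$truth)
  expect_true(all(ex$truth$planted_class == "neutral"))
  expect_error(simulate_expression(cfg, list()), "precondition")
})

test_that("noiseless stage profiles are strictly monotone per planted class", {
  cfg <- small_cfg(seed = 12, stage_noise_sd = 0)
  epi <- simulate_epigenome(cfg)
  ex <- simulate_expression(cfg, epi$truth)
  up <- ex$truth$gene_id[ex$truth$planted_class == "up"]
  dn <- ex$truth$gene_id[ex$truth$planted_class == "down"]
  expect_gt(length(up), 0); expect_gt(length(dn), 0)
  expect_true(all(apply(ex$stage_matrix[up, , drop = FALSE], 1,
                        function(v) all(diff(v) < 0))))
  expect_true(all(apply(ex$stage_matrix[dn, , drop = FALSE], 1,
                        function(v) all(diff(v) > 0))))
})

test_that("uncensored cohort KM curves reach zero", {
  cfg <- small_cfg(seed = 13, censor_hazard = 0)
  rec <- simulate_cohort(cfg)$records
  km <- km_curve(rec$os_time, rec$os_event)
  expect_equal(min(km$survival), 0)
  expect_true(all(rec$os_event == 1))
})

test_that("planted quartile mutation enrichment is detectable at n = 400", {
  rec <- default_sim()$cohort$records
  fem <- rec[rec$sex == "female", ]
  me <- mutation_enrichment(fem, "KDM5C")
  expect_lt(me$p[me$mutation == "PML_RARA"], 0.05)
  expect_gt(me$odds_ratio[me$mutation == "PML_RARA"], 1)
  expect_lt(me$p[me$mutation == "KRAS"], 0.05)
  expect_lt(me$odds_ratio[me$mutation == "KRAS"], 1)
})

test_that("PTM abundances sum to one within every replicate group", {
  ptm <- default_sim()$ptm$records
  sums <- aggregate(abundance ~ variant + residue + condition + replicate,
                    ptm, sum)
  expect_true(all(abs(sums$abundance - 1) < 1e-9))
})

test_that("zero PTM shift leaves all expected ratios near one", {
  cfg <- small_cfg(seed = 14, ptm_shift_log2 = 0, ptm_noise_sd = 0.02)
  tab <- ptm_ratio_table(simulate_ptm(cfg)$records)
  expect_true(all(abs(tab$log2_ratio) < 0.15))
})
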