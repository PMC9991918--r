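# Shared simulated datasets, built once per test run.
.fixture_env <- new.env(parent = emptyenv())

default_sim <- function() {
  if (is.null(.fixture_env$sim))
    .fixture_env$sim <- simulate_all(sim_config(seed = 1))
  .fixture_env$sim
}

# Default pipeline products on the default simulation.
default_products <- function() {
  if (is.null(.fixture_env$prod)) {
    sim <- default_sim()
    epi <- sim$epigenome
    de <- de_pipeline(sim$expression$counts, sim$expression$samples)
    prom <- epi$truth$promoter_states$region_id
    p4 <- mark_presence(epi$signal, epi$samples, "H3K4me3", "control")
    p27 <- mark_presence(epi$signal, epi$samples, "H3K27me3", "control")
    .fixture_env$prod <- list(
      de = de,
      states = classify_promoters(p4[prom], p27[prom]),
      diff_k4me3 = differential_regions(epi$signal, epi$samples, "H3K4me3"))
  }
  .fixture_env$prod
}

small_cfg <- function(seed = 7, ...) {
  sim_config(seed = seed, n_genes = 20, n_shrnas = 60, n_promoters = 120,
             n_enhancers = 30, n_female = 60, n_male = 60,
             n_planted_enriched = 3, n_planted_depleted = 3,
             n_planted_down = 10, ...)
}
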