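#' Run the full synthetic-data generator
#'
#' Convenience wrapper producing every pipeline input from one configuration:
#' library manifest, screen counts, toy epigenome (regions + signal + KDM5C
#' occupancy), expression counts and stage matrix, patient cohort, and PTM
#' abundance table, each with its planted-truth table.
#'
#' @param config a [sim_config()] object.
#' @return named list with elements `config`, `library`, `screen`,
#'   `epigenome`, `expression`, `cohort`, `ptm`.
#' @examples
#' sim <- simulate_all(sim_config(seed = 1, n_genes = 10, n_shrnas = 30,
#'                                n_promoters = 50, n_enhancers = 10,
#'                                n_female = 40, n_male = 40))
#' names(sim)
#' @export
simulate_all <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  manifest <- generate_library(config)
  epigenome <- simulate_epigenome(config)
  list(config = config,
       library = manifest,
       screen = simulate_screen(manifest, config),
       epigenome = epigenome,
       expression = simulate_expression(config, epigenome$truth),
       cohort = simulate_cohort(config),
       ptm = simulate_ptm(config))
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

write_matrix_tsv <- function(m, path, id_col) {
  df <- data.frame(id = rownames(m), as.data.frame(m, check.names = FALSE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  write_tsv(df, path)
}

#' Write a simulated dataset to disk
#'
#' Serializes every artifact of [simulate_all()] as plain text:
#' `library.tsv`, `screen_counts.tsv` (+ sample sheet), `regions.bed`
#' (BED6, 0-based half-open, sorted), `signal.tsv` (region x sample TPM),
#' `tss.tsv`, `expression_counts.tsv`, `stage_matrix.tsv`, `cohort.tsv`,
#' `ptm.tsv`, the truth tables under `truth/`, and a `simconfig.yaml` echo
#' of the configuration. Identical configurations produce byte-identical
#' files.
#'
#' @param sim result of [simulate_all()].
#' @param outdir output directory (created if missing).
#' @return invisibly, the vector of files written.
#' @export
write_simulation <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(outdir, "truth"), showWarnings = FALSE)
  p <- function(...) file.path(outdir, ...)

  write_tsv(sim$library, p("library.tsv"))
  write_matrix_tsv(sim$screen$counts, p("screen_counts.tsv"), "shrna_id")
  write_tsv(sim$screen$samples, p("screen_samples.tsv"))
  write_bed(sim$epigenome$regions, p("regions.bed"))
  write_tsv(sim$epigenome$regions, p("regions.tsv"))
  write_tsv(sim$epigenome$tss, p("tss.tsv"))
  write_matrix_tsv(sim$epigenome$signal, p("signal.tsv"), "region_id")
  write_tsv(sim$epigenome$samples, p("signal_samples.tsv"))
  write_matrix_tsv(sim$expression$counts, p("expression_counts.tsv"), "gene_id")
  write_tsv(sim$expression$samples, p("expression_samples.tsv"))
  write_matrix_tsv(round(sim$expression$stage_matrix, 6), p("stage_matrix.tsv"),
                   "gene_id")
  write_tsv(sim$cohort$records, p("cohort.tsv"))
  write_tsv(sim$ptm$records, p("ptm.tsv"))

  write_tsv(sim$screen$truth, p("truth", "screen_hits.tsv"))
  write_tsv(sim$epigenome$truth$promoter_states, p("truth", "promoter_states.tsv"))
  write_tsv(data.frame(region_id = sim$epigenome$truth$kdm5c_high),
            p("truth", "kdm5c_high.tsv"))
  write_tsv(sim$epigenome$truth$genes, p("truth", "genes.tsv"))
  write_tsv(sim$epigenome$truth$enhancer_hosts, p("truth", "enhancer_hosts.tsv"))
  write_tsv(sim$expression$truth, p("truth", "de_classes.tsv"))
  write_tsv(sim$cohort$truth$mutation_design, p("truth", "mutation_design.tsv"))

  cfg <- unclass(sim$config)
  yaml::write_yaml(cfg, p("simconfig.yaml"))
  invisible(list.files(outdir, recursive = TRUE, full.names = TRUE))
}
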