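test_that("stratified rank tests equal brute-force enumeration at small n", {
  set.seed(40)
  for (k in 1:10) {
    v <- c(rnorm(5), rnorm(7, 1), rnorm(4))
    g <- rep(c("a", "b", "c"), c(5, 7, 4))
    sc <- stratified_comparison(v, g)
    for (r in seq_len(nrow(sc$tests))) {
      x <- v[g == sc$tests$group1[r]]; y <- v[g == sc$tests$group2[r]]
      expect_equal(sc$tests$p[r], mw_oracle(x, y), tolerance = 1e-12)
    }
  }
})

test_that("single-member groups are summarized but excluded from testing", {
  expect_warning(
    sc <- stratified_comparison(c(1, 2, 3, 9), c("a", "a", "a", "b")),
    "too small")
  expect_equal(sc$summary$n, c(3, 1))
  expect_null(sc$tests)
})

test_that("H3K4me3 change is concentrated at upregulated promoters", {
  prod <- default_products()
  epi <- default_sim()$epigenome
  sc <- signal_change_by_class(prod$diff_k4me3, epi$regions, prod$de)
  med <- function(g) sc$summary$median[sc$summary$group == g]
  expect_gt(med("up"), med("neutral"))
  expect_gt(med("up"), med("down"))
  p_ud <- sc$tests$p[sc$tests$group1 == "up" & sc$tests$group2 == "down"]
  expect_lt(p_ud, 0.01)
})

test_that("KDM5C occupancy stratifies by DE class and promoter state", {
  sim <- default_sim(); prod <- default_products()
  epi <- sim$epigenome
  by_class <- occupancy_by_group(epi$signal, epi$samples, epi$regions,
                                 prod$de)
  med <- function(sc, g) sc$summary$median[sc$summary$group == g]
  expect_gt(med(by_class, "up"), med(by_class, "down"))
  expect_gt(med(by_class, "neutral"), med(by_class, "down"))
  by_state <- occupancy_by_group(epi$signal, epi$samples, epi$regions,
                                 prod$states)
  expect_gt(med(by_state, "bivalent"), med(by_state, "repressed"))
  bad <- prod$de; bad$de_class[1] <- "sideways"
  expect_error(occupancy_by_group(epi$signal, epi$samples, epi$regions, bad),
               "unknown grouping label")
})

test_that("constant occupancy yields equal medians across groups", {
  sim <- default_sim(); prod <- default_products()
  epi <- sim$epigenome
  flat <- epi$signal
  flat[, epi$samples$sample[epi$samples$mark == "KDM5C"]] <- 7
  sc <- occupancy_by_group(flat, epi$samples, epi$regions, prod$de)
  expect_true(all(sc$summary$median == 7))
})

test_that("upregulated genes gain more expression from bivalent than active promoters", {
  prod <- default_products()
  epi <- default_sim()$epigenome
  suppressWarnings(
    sc <- expression_fc_by_state(prod$de, prod$states, epi$regions,
                                 restrict = "up"))
  med <- function(g) sc$summary$median[sc$summary$group == g]
  expect_gt(med("bivalent"), med("active"))
  expect_warning(
    empty <- expression_fc_by_state(prod$de[0, ], prod$states, epi$regions),
    "no genes")
})

test_that("state fractions per DE class sum to one and recover the planted design", {
  prod <- default_products()
  sim <- default_sim()
  sf <- state_fractions_by_class(prod$states, prod$de,
                                 sim$epigenome$regions)
  states <- c("active", "bivalent", "repressed", "unmarked")
  expect_true(all(abs(rowSums(sf[, states]) - 1) < 1e-12))
  expect_gt(sf$bivalent[sf$de_class == "up"],
            sf$bivalent[sf$de_class == "neutral"])
  none <- prod$de; none$de_class[none$de_class == "down"] <- "neutral"
  sf0 <- state_fractions_by_class(prod$states, none, sim$epigenome$regions)
  expect_equal(sf0$n[sf0$de_class == "down"], 0)
  expect_true(all(sf0[sf0$de_class == "down", states] == 0))
})

test_that("enhancers map to the nearest TSS with the lower-coordinate tie rule", {
  tss <- data.frame(gene_id = c("gA", "gB"), tss = c(1000L, 5000L))
  enh <- data.frame(region_id = c("e1", "e2", "e3"),
                    start = c(2500L, 4400L, 300000L),
                    end = c(3500L, 4600L, 301000L))
  res <- nearest_gene_enhancers(enh, tss, max_distance = 1e5)
  expect_equal(res$map$gene_id, c("gA", "gB", NA))  # e1 equidistant -> gA
  expect_equal(res$map$distance, c(2000, 500, NA))
  expect_equal(res$counts$n_enhancers, c(1L, 1L))
  expect_error(nearest_gene_enhancers(enh[c(2, 1, 3), ], tss), "sorted")
})

test_that("nearest-TSS assignment equals a brute-force all-pairs scan", {
  set.seed(41)
  tss <- data.frame(gene_id = sprintf("g%03d", 1:120),
                    tss = sort(sample.int(2e6, 120)))
  start <- sort(sample.int(2e6, 1000))
  enh <- data.frame(region_id = sprintf("e%04d", 1:1000),
                    start = start, end = start + 800L)
  res <- nearest_gene_enhancers(enh, tss, max_distance = 5e4)
  mid <- floor((enh$start + enh$end) / 2)
  for (k in sample(1000, 200)) {
    d <- abs(tss$tss - mid[k])
    j <- which(d == min(d))[1]  # tss sorted, first minimum = lower coordinate
    if (d[j] > 5e4) expect_true(is.na(res$map$gene_id[k]))
    else expect_equal(res$map$gene_id[k], tss$gene_id[j])
  }
})

test_that("gene attributes stratify by DE class with planted CpG contrast", {
  sim <- default_sim(); prod <- default_products()
  prom <- sim$epigenome$regions
  prom <- prom[prom$kind == "promoter", ]
  attrs <- data.frame(gene_id = prom$gene_id, value = prom$cpg_island_length)
  sc <- attribute_by_class(attrs, prod$de)
  med <- function(g) sc$summary$median[sc$summary$group == g]
  expect_lt(med("down"), med("neutral"))
  const <- attrs; const$value <- 5
  sc0 <- attribute_by_class(const, prod$de)
  expect_true(all(sc0$tests$p == 1))
  missing <- attrs[-(1:10), ]
  scm <- attribute_by_class(missing, prod$de)
  expect_equal(scm$n_excluded, sum(!prod$de$gene %in% missing$gene_id))
})

test_that("planted-down genes carry more assigned enhancers", {
  sim <- default_sim()
  epi <- sim$epigenome
  enh <- epi$regions[epi$regions$kind == "enhancer", ]
  counts <- nearest_gene_enhancers(enh, epi$tss)$counts
  g <- epi$truth$genes
  mean_down <- mean(counts$n_enhancers[counts$gene_id %in%
                                         g$gene_id[g$planted_down]])
  mean_other <- mean(counts$n_enhancers[counts$gene_id %in%
                                          g$gene_id[!g$planted_down]])
  expect_gt(mean_down, mean_other * 1.5)
})

test_that("stage profiles give monotone trends for planted classes", {
  sim <- default_sim(); prod <- default_products()
  sp <- stage_profiles_by_class(sim$expression$stage_matrix, prod$de)
  expect_equal(sp$trend$spearman[sp$trend$de_class == "up"], -1)
  expect_equal(sp$trend$spearman[sp$trend$de_class == "down"], 1)
  ## degenerate: a single-gene class returns its own profile
  one <- data.frame(gene = rownames(sim$expression$stage_matrix)[1],
                    de_class = "up")
  sp1 <- stage_profiles_by_class(sim$expression$stage_matrix[1, , drop = FALSE],
                                 one)
  expect_equal(unname(sp1$profile["up", ]),
               unname(sim$expression$stage_matrix[1, ]))
})
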