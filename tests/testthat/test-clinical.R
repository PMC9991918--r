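test_that("Fisher exact reproduces the sex-bias mutation table at 3 decimals", {
  res <- fisher_exact(matrix(c(10, 2, 317, 441), 2))
  expect_equal(round(res$p, 3), 0.006)
})

test_that("Fisher exact handles degenerate and enumerable tables", {
  expect_equal(fisher_exact(matrix(c(0, 0, 5, 7), 2))$p, 1)
  # margins (4,4)/(4,4): support 0..4, two-sided mass 34/70 at a = 3
  expect_equal(fisher_exact(matrix(c(3, 1, 1, 3), 2))$p, 34 / 70,
               tolerance = 1e-12)
  expect_error(fisher_exact(matrix(c(-1, 1, 1, 1), 2)), "non-negative")
  inf <- fisher_exact(matrix(c(3, 0, 2, 4), 2))
  expect_true(is.infinite(inf$odds_ratio) && inf$or_infinite)
})

test_that("Fisher exact agrees with stats::fisher.test on random tables", {
  set.seed(50)
  for (k in 1:200) {
    tab <- matrix(rpois(4, sample(c(2, 8, 30), 1)), 2)
    expect_equal(fisher_exact(tab)$p, fisher.test(tab)$p.value,
                 tolerance = 1e-7)
  }
})

test_that("median split is strict: ties at the median go Low", {
  r <- data.frame(KDM5C = c(1, 2, 3, 4))
  expect_equal(median_stratify(r, "KDM5C")$strata,
               c("Low", "Low", "High", "High"))
  r2 <- data.frame(KDM5C = c(1, 2, 2, 5))
  expect_equal(median_stratify(r2, "KDM5C")$strata,
               c("Low", "Low", "Low", "High"))
  ## summed score mirrors the single-gene path
  r3 <- data.frame(KDM5C = c(1, 2, 2, 5), KDM5D = 0)
  expect_equal(median_stratify(r3, c("KDM5C", "KDM5D"))$strata,
               median_stratify(r2, "KDM5C")$strata)
  r4 <- data.frame(KDM5C = c(1, NA, 3, 4))
  out <- median_stratify(r4, "KDM5C")
  expect_equal(nrow(out), 3)
  expect_equal(attr(out, "n_excluded"), 1)
})

test_that("follow-up filter keeps the exactly-at-boundary records", {
  rec <- data.frame(os_time = c(3, 6, 10), os_event = c(1, 1, 0))
  kept <- filter_min_followup(rec, 6, "os")
  expect_equal(kept$os_time, c(6, 10))
  expect_equal(attr(kept, "n_excluded"), 1)
  expect_equal(nrow(filter_min_followup(rec, 0, "os")), 3)
  expect_warning(filter_min_followup(rec, 99, "os"), "all records excluded")
})

test_that("Kaplan-Meier product-limit matches hand calculations", {
  km <- km_curve(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0))
  cens <- km_curve(c(1, 2, 3), c(1, 0, 1))
  expect_equal(cens$survival[cens$time == 1], 2 / 3)
  expect_equal(cens$survival[cens$time == 3], 0)  # (2/3) * (1 - 1/1)
  expect_equal(nrow(km_curve(c(1, 2), c(0, 0))), 0)  # no events: S stays 1
  expect_error(km_curve(c(-1, 2), c(1, 1)), "negative")
})

test_that("KM equals 1 - ECDF without censoring and survfit with censoring", {
  skip_if_not_installed("survival")
  set.seed(51)
  t_all <- rexp(60, 0.1)
  km <- km_curve(t_all, rep(1, 60))
  ec <- ecdf(t_all)
  expect_equal(km$survival, 1 - ec(km$time), tolerance = 1e-12)
  ev <- rbinom(60, 1, 0.6)
  km2 <- km_curve(t_all, ev)
  sf <- survival::survfit(survival::Surv(t_all, ev) ~ 1)
  ref <- summary(sf, times = km2$time)
  expect_equal(km2$survival, ref$surv, tolerance = 1e-9)
})

test_that("log-rank is zero for identical groups and label-symmetric", {
  t0 <- c(1, 2, 3, 4, 5); e0 <- c(1, 1, 0, 1, 1)
  res <- logrank(c(t0, t0), c(e0, e0), rep(c("a", "b"), each = 5))
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)
  set.seed(52)
  tt <- rexp(30, 0.1); ee <- rbinom(30, 1, 0.7)
  gg <- rep(c("x", "y"), 15)
  expect_equal(logrank(tt, ee, gg)$statistic,
               logrank(tt, ee, ifelse(gg == "x", "y", "x"))$statistic,
               tolerance = 1e-12)
  expect_error(logrank(tt, ee, rep("x", 30)), "2 levels")
})

test_that("log-rank matches survdiff on random censored fixtures", {
  skip_if_not_installed("survival")
  set.seed(53)
  for (k in 1:20) {
    n <- 40
    tt <- rexp(n, 0.1 * ifelse(seq_len(n) <= n / 2, 1, 1.8))
    ee <- rbinom(n, 1, 0.8)
    gg <- rep(c("a", "b"), each = n / 2)
    mine <- logrank(tt, ee, gg)
    ref <- survival::survdiff(survival::Surv(tt, ee) ~ gg)
    expect_equal(mine$statistic, ref$chisq, tolerance = 1e-9)
  }
})

test_that("quartile mutation tests are consistent with the core Fisher test", {
  rec <- data.frame(KDM5C = seq_len(100),
                    mut_X = c(rep(0, 75), rep(c(0, 1), c(17, 8))))
  res <- mutation_enrichment(rec, "KDM5C", "mut_X")
  direct <- fisher_exact(matrix(c(8, 0, 17, 25), 2))
  expect_equal(res$p, direct$p, tolerance = 1e-12)
  rec$mut_none <- 0
  expect_equal(mutation_enrichment(rec, "KDM5C", "mut_none")$p, 1)
  expect_warning(mutation_enrichment(rec, "KDM5C", c("mut_X", "mut_gone")),
                 "absent")
  tiny <- data.frame(KDM5C = 1:4, mut_X = c(1, 0, 0, 0))
  expect_warning(mutation_enrichment(tiny, "KDM5C", "mut_X"), "low power")
})

test_that("expression by vital status uses Welch and flags degeneracy", {
  rec <- data.frame(KDM5C = c(1, 2, 3, 1, 2, 3),
                    os_event = c(0, 0, 0, 1, 1, 1))
  res <- expression_by_status(rec, "KDM5C", "os")
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)
  flat <- data.frame(KDM5C = rep(2, 6), os_event = c(0, 0, 0, 1, 1, 1))
  expect_true(expression_by_status(flat, "KDM5C", "os")$degenerate)
})

test_that("planted female hazard ratio 3 is detected in most cohorts of 300", {
  hits <- 0L
  for (s in 1:100) {
    cfg <- sim_config(seed = 1000 + s, n_female = 300, n_male = 10,
                      female_low_hr = 3)
    rec <- simulate_cohort(cfg)$records
    sv <- survival_stratified(rec, "KDM5C", sex = "female", min_months = 0,
                              endpoint = "os")
    if (sv$logrank$p < 0.01) hits <- hits + 1L
  }
  expect_gte(hits, 90L)
})

test_that("the full stratified survival pipeline runs on the default cohort", {
  rec <- default_sim()$cohort$records
  sv <- survival_stratified(rec, "KDM5C", sex = "female", min_months = 6,
                            endpoint = "os")
  expect_lt(sv$logrank$p, 0.01)
  expect_named(sv$curves, c("High", "Low"))
  expect_true(all(diff(sv$curves$High$survival) <= 0))
  svm <- survival_stratified(rec, c("KDM5C", "KDM5D"), sex = "male",
                             min_months = 6, endpoint = "dfs")
  expect_lt(svm$logrank$p, 0.05)
})
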