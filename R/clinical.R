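#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by the point-probability rule: with margins fixed, the
#' p-value is the sum of hypergeometric probabilities of all tables whose
#' point probability does not exceed the observed one (within a 1e-7
#' relative slack, the convention of common statistical software). The odds
#' ratio is the cross-product ad/bc, infinite (and flagged) when bc = 0.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return list with `p`, `odds_ratio`, `or_infinite`.
#' @examples
#' fisher_exact(matrix(c(10, 2, 317, 441), 2))$p  # 0.006 at 3 decimals
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == 2L)) stop("table must be 2x2")
  if (any(table < 0)) stop("cells must be non-negative")
  if (any(table != round(table))) stop("cells must be integers")
  a <- table[1, 1]; b <- table[1, 2]; c <- table[2, 1]; d <- table[2, 2]
  m <- a + c; n2 <- b + d; k <- a + b
  if (m + n2 == 0) return(list(p = 1, odds_ratio = NA_real_, or_infinite = FALSE))
  support <- max(0, k - n2):min(k, m)
  probs <- stats::dhyper(support, m, n2, k)
  p_obs <- stats::dhyper(a, m, n2, k)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  p <- min(1, p)
  or_inf <- (b * c == 0) && (a * d > 0)
  or <- if (b * c == 0) { if (a * d == 0) NA_real_ else Inf }
        else a * d / (b * c)
  list(p = p, odds_ratio = or, or_infinite = or_inf)
}

#' Median split of patients by an expression score
#'
#' Labels each record `High` when its score is strictly above the cohort
#' median ("above median"), `Low` otherwise (ties at the median go to Low).
#' The score is a single gene's expression or an unweighted sum of genes
#' (e.g. KDM5C + KDM5D for male patients). Records missing any score gene
#' are excluded and counted.
#'
#' @param records patient data.frame.
#' @param genes character vector of expression columns to sum.
#' @return records with a `strata` column added; attribute `n_excluded`
#'   counts dropped records.
#' @examples
#' r <- data.frame(KDM5C = c(1, 2, 3, 4))
#' median_stratify(r, "KDM5C")$strata  # Low Low High High
#' @export
median_stratify <- function(records, genes = "KDM5C") {
  if (nrow(records) < 2L) stop("need at least 2 records")
  miss <- setdiff(genes, names(records))
  if (length(miss)) stop("missing expression column(s): ",
                         paste(miss, collapse = ", "))
  score <- rowSums(records[, genes, drop = FALSE])
  keep <- !is.na(score)
  out <- records[keep, , drop = FALSE]
  out$strata <- ifelse(score[keep] > stats::median(score[keep]), "High", "Low")
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Exclude patients with short follow-up
#'
#' Keeps records whose endpoint time is at least `min_months` (the
#' exactly-at-boundary records are kept: "less than six months were
#' excluded").
#'
#' @param records patient data.frame.
#' @param min_months exclusion threshold (default 6).
#' @param endpoint `"os"` or `"dfs"`.
#' @return filtered records; attribute `n_excluded` counts removals.
#' @export
filter_min_followup <- function(records, min_months = 6,
                                endpoint = c("os", "dfs")) {
  endpoint <- match.arg(endpoint)
  tcol <- paste0(endpoint, "_time")
  keep <- records[[tcol]] >= min_months
  out <- records[keep, , drop = FALSE]
  attr(out, "n_excluded") <- sum(!keep)
  if (nrow(out) == 0L) warning("all records excluded by follow-up filter")
  out
}

#' Kaplan-Meier product-limit survival curve
#'
#' S(t) is the product over event times up to t of (1 - d_i / n_i), with
#' censored subjects leaving the risk set after their recorded time
#' (censoring ties at an event time stay at risk for that event).
#'
#' @param times non-negative follow-up times.
#' @param events 1 = event, 0 = censored.
#' @return object of class `km_curve`: data.frame with `time`, `n_risk`,
#'   `n_event`, `survival` at each distinct event time.
#' @examples
#' km_curve(c(1, 2, 3), c(1, 1, 1))$survival  # 2/3 1/3 0
#' @export
km_curve <- function(times, events) {
  if (any(times < 0)) stop("negative time")
  stopifnot(length(times) == length(events), all(events %in% c(0, 1)))
  ev_times <- sort(unique(times[events == 1]))
  n_risk <- vapply(ev_times, function(t) sum(times >= t), 0)
  n_event <- vapply(ev_times, function(t) sum(times == t & events == 1), 0)
  surv <- cumprod(1 - n_event / n_risk)
  structure(data.frame(time = ev_times, n_risk = n_risk, n_event = n_event,
                       survival = surv),
            class = c("km_curve", "data.frame"))
}

#' @export
plot.km_curve <- function(x, xlab = "Time (months)", ylab = "Survival",
                          ...) {
  graphics::plot(stats::stepfun(x$time, c(1, x$survival)), do.points = FALSE,
                 xlab = xlab, ylab = ylab, ylim = c(0, 1), ...)
  invisible(x)
}

#' Two-group log-rank test
#'
#' Standard observed-minus-expected statistic over the pooled event times,
#' referred to chi-square with 1 degree of freedom.
#'
#' @param times follow-up times for all subjects.
#' @param events event indicators (1 = event, 0 = censored).
#' @param group two-level group labels.
#' @return list with `statistic`, `p`, `observed` and `expected` per group.
#' @export
logrank <- function(times, events, group) {
  g <- as.factor(group)
  if (nlevels(g) != 2L) stop("group must have exactly 2 levels")
  if (any(table(g) == 0L)) stop("a group has zero subjects")
  ev_times <- sort(unique(times[events == 1]))
  is1 <- g == levels(g)[1]
  o1 <- 0; e1 <- 0; v <- 0
  for (t in ev_times) {
    at <- times >= t
    n <- sum(at); n1 <- sum(at & is1)
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & is1)
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  stat <- if (v > 0) (o1 - e1)^2 / v else 0
  total <- sum(events == 1)
  list(statistic = stat, p = stats::pchisq(stat, 1, lower.tail = FALSE),
       observed = c(o1, total - o1), expected = c(e1, total - e1))
}

#' Mutation enrichment in expression quartiles
#'
#' Splits records into the top and bottom expression quartiles by rank
#' (k = floor(n/4) patients each; rank ties broken by record order, so the
#' boundary is handled symmetrically and deterministically) and tests each
#' mutation column for association with quartile membership by two-sided
#' Fisher's exact test.
#'
#' @param records patient data.frame with 0/1 `mut_*` columns.
#' @param gene expression column defining the quartiles.
#' @param mutation_cols columns to test (default: all starting `mut_`);
#'   absent columns are skipped with a warning.
#' @param quartile fraction per tail (default 0.25).
#' @return data.frame with `mutation`, `n_top`, `n_bottom` (carriers),
#'   `k` (patients per quartile), `odds_ratio`, `p`.
#' @export
mutation_enrichment <- function(records, gene = "KDM5C",
                                mutation_cols = NULL, quartile = 0.25) {
  if (nrow(records) < 4L) stop("need at least 4 records")
  if (is.null(mutation_cols))
    mutation_cols <- grep("^mut_", names(records), value = TRUE)
  absent <- setdiff(mutation_cols, names(records))
  if (length(absent)) {
    warning("mutation column(s) absent, skipped: ",
            paste(absent, collapse = ", "))
    mutation_cols <- setdiff(mutation_cols, absent)
  }
  n <- nrow(records)
  k <- floor(n * quartile)
  if (k < 1L) stop("quartile too small for cohort size")
  if (k < 5L) warning("very small quartiles (k = ", k, "): low power")
  o <- order(records[[gene]], seq_len(n))
  bottom <- o[seq_len(k)]; top <- o[(n - k + 1L):n]
  rows <- lapply(mutation_cols, function(mc) {
    mt <- sum(records[[mc]][top]); mb <- sum(records[[mc]][bottom])
    fe <- fisher_exact(matrix(c(mt, mb, k - mt, k - mb), 2))
    data.frame(mutation = sub("^mut_", "", mc), n_top = mt, n_bottom = mb,
               k = k, odds_ratio = fe$odds_ratio, p = fe$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Expression by vital status (Welch two-tailed t)
#'
#' Compares an expression column between patients who died and patients
#' alive at last follow-up, with Welch's correction. Zero-variance identical
#' groups are flagged instead of reported as p = 0.
#'
#' @param records patient data.frame.
#' @param gene expression column.
#' @param endpoint `"os"` or `"dfs"` (its event column defines status).
#' @return list with `t`, `df`, `p`, `degenerate`, group means.
#' @export
expression_by_status <- function(records, gene = "KDM5C",
                                 endpoint = c("os", "dfs")) {
  endpoint <- match.arg(endpoint)
  ev <- records[[paste0(endpoint, "_event")]]
  dead <- records[[gene]][ev == 1]; alive <- records[[gene]][ev == 0]
  res <- welch_t(alive, dead)
  res$mean_alive <- mean(alive); res$mean_dead <- mean(dead)
  res
}

#' Expression-stratified survival analysis
#'
#' The clinical pipeline: median split on an expression score (one gene, or
#' an unweighted gene sum), exclusion of short-follow-up records, per-stratum
#' Kaplan-Meier curves and the two-group log-rank test. By default the
#' median split is computed before the follow-up exclusion; both orders are
#' available.
#'
#' @param records patient data.frame.
#' @param genes expression column(s) defining the score.
#' @param sex optional sex restriction (`"female"`/`"male"`).
#' @param min_months follow-up exclusion threshold.
#' @param endpoint `"os"` or `"dfs"`.
#' @param split_first compute the median split before the exclusion
#'   (default TRUE).
#' @return list with `curves` (named list of [km_curve()]), `logrank`,
#'   `n_per_stratum`, `n_excluded`.
#' @export
survival_stratified <- function(records, genes = "KDM5C", sex = NULL,
                                min_months = 6, endpoint = c("os", "dfs"),
                                split_first = TRUE) {
  endpoint <- match.arg(endpoint)
  if (!is.null(sex)) records <- records[records$sex == sex, , drop = FALSE]
  if (split_first) {
    records <- median_stratify(records, genes)
    records <- filter_min_followup(records, min_months, endpoint)
  } else {
    records <- filter_min_followup(records, min_months, endpoint)
    records <- median_stratify(records, genes)
  }
  tcol <- paste0(endpoint, "_time"); ecol <- paste0(endpoint, "_event")
  curves <- lapply(split(records, records$strata), function(d)
    km_curve(d[[tcol]], d[[ecol]]))
  list(curves = curves,
       logrank = logrank(records[[tcol]], records[[ecol]], records$strata),
       n_per_stratum = table(records$strata),
       n_excluded = attr(records, "n_excluded"))
}
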