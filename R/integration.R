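#' Stratified comparison of a numeric value across groups
#'
#' Shared machinery for every coupled ChIP/RNA panel: per-group summary
#' (n, median, quartiles) plus all pairwise two-sided Mann-Whitney rank-sum
#' tests. Groups with fewer than 2 values are summarized but excluded from
#' testing, with a warning.
#'
#' @param values numeric vector.
#' @param groups character/factor of the same length.
#' @param group_levels optional explicit group order; groups absent from the
#'   data are reported with n = 0.
#' @return object of class `stratified_comparison`: list with `summary`
#'   (group, n, median, q1, q3) and `tests` (group1, group2, p).
#' @export
stratified_comparison <- function(values, groups, group_levels = NULL) {
  keep <- !is.na(values) & !is.na(groups)
  n_excluded <- sum(!keep)
  values <- values[keep]; groups <- as.character(groups[keep])
  if (is.null(group_levels)) group_levels <- sort(unique(groups))
  summ <- do.call(rbind, lapply(group_levels, function(g) {
    v <- values[groups == g]
    data.frame(group = g, n = length(v),
               median = if (length(v)) stats::median(v) else NA_real_,
               q1 = if (length(v)) unname(stats::quantile(v, 0.25)) else NA_real_,
               q3 = if (length(v)) unname(stats::quantile(v, 0.75)) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  testable <- group_levels[vapply(group_levels,
                                  function(g) sum(groups == g) >= 2L, TRUE)]
  skipped <- setdiff(group_levels, testable)
  if (length(skipped))
    warning("group(s) too small for testing: ", paste(skipped, collapse = ", "))
  tests <- NULL
  if (length(testable) >= 2L) {
    pairs <- utils::combn(testable, 2)
    tests <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                        p = apply(pairs, 2, function(pr) {
                          rank_sum_test(values[groups == pr[1]],
                                        values[groups == pr[2]])$p
                        }), stringsAsFactors = FALSE)
  }
  structure(list(summary = summ, tests = tests, n_excluded = n_excluded),
            class = "stratified_comparison")
}

#' @export
print.stratified_comparison <- function(x, ...) {
  cat("Stratified comparison\n")
  print(x$summary, row.names = FALSE)
  if (!is.null(x$tests)) {
    cat("Pairwise two-sided rank-sum tests:\n")
    print(x$tests, row.names = FALSE)
  }
  if (x$n_excluded > 0) cat("(", x$n_excluded, "records excluded: NA )\n")
  invisible(x)
}

## One promoter per gene: primary TSS = lowest start coordinate.
promoter_gene_map <- function(regions) {
  prom <- regions[regions$kind == "promoter", , drop = FALSE]
  prom <- prom[order(prom$gene_id, prom$start), , drop = FALSE]
  prom[!duplicated(prom$gene_id), c("gene_id", "region_id"), drop = FALSE]
}

de_class_of <- function(de_classes, genes) {
  de_classes$de_class[match(genes, de_classes$gene)]
}

#' Signal change at promoters stratified by DE class
#'
#' Joins per-region differential signal (knockdown vs control) onto genes
#' through the one-promoter-per-gene map and compares the log2 ratio
#' distributions across up-, down- and neutrally regulated genes.
#'
#' @param region_diff output of [differential_regions()] for one mark.
#' @param regions regions table (for the promoter-to-gene map).
#' @param de_classes output of [assign_classes()]/[de_pipeline()].
#' @return a [stratified_comparison()].
#' @export
signal_change_by_class <- function(region_diff, regions, de_classes) {
  map <- promoter_gene_map(regions)
  lr <- region_diff$log2_ratio[match(map$region_id, region_diff$region_id)]
  cls <- de_class_of(de_classes, map$gene_id)
  stratified_comparison(lr, cls, c("up", "down", "neutral"))
}

#' Occupancy signal stratified by DE class or promoter state
#'
#' Compares a single-condition occupancy track (replicate-mean TPM, e.g.
#' KDM5C) across the levels of a grouping defined per promoter: either the
#' DE class of the promoter's gene or the promoter chromatin state.
#'
#' @param signal region x sample TPM matrix.
#' @param samples signal sample sheet.
#' @param regions regions table.
#' @param grouping named vector or data.frame assigning each gene
#'   (`de_class` grouping) or region (`state` grouping) to a group: either
#'   the output of [de_pipeline()] or of [classify_promoters()].
#' @param mark occupancy mark (default `"KDM5C"`).
#' @param condition condition of the occupancy track.
#' @return a [stratified_comparison()].
#' @export
occupancy_by_group <- function(signal, samples, regions, grouping,
                               mark = "KDM5C", condition = "control") {
  occ <- replicate_mean(signal, samples, mark, condition)
  map <- promoter_gene_map(regions)
  if (!is.null(grouping$de_class)) {
    grp <- de_class_of(grouping, map$gene_id)
    levels <- c("up", "down", "neutral")
  } else if (!is.null(grouping$state)) {
    grp <- grouping$state[match(map$region_id, grouping$region_id)]
    levels <- intersect(c("active", "bivalent", "repressed", "unmarked"),
                        unique(grp))
  } else stop("grouping must provide de_class or state")
  if (any(!grp %in% c(levels, NA)))
    stop("unknown grouping label(s): ",
         paste(setdiff(unique(grp), levels), collapse = ", "))
  stratified_comparison(occ[match(map$region_id, names(occ))], grp, levels)
}

#' Expression fold change stratified by promoter state
#'
#' Among a restricted gene set (by default the upregulated class), compares
#' knockdown expression log2 fold change across promoter chromatin states.
#'
#' @param de_classes output of [de_pipeline()].
#' @param promoter_states output of [classify_promoters()].
#' @param regions regions table.
#' @param restrict DE class to restrict to (default `"up"`); `NULL` keeps
#'   all genes.
#' @param arm which arm's fold change to use: `"shA"`, `"shB"` or `"mean"`.
#' @return a [stratified_comparison()] (empty, with warning, if the
#'   restriction removes everything).
#' @export
expression_fc_by_state <- function(de_classes, promoter_states, regions,
                                   restrict = "up", arm = c("shA", "shB", "mean")) {
  arm <- match.arg(arm)
  map <- promoter_gene_map(regions)
  keep <- if (is.null(restrict)) rep(TRUE, nrow(de_classes))
          else de_classes$de_class == restrict
  de <- de_classes[keep, , drop = FALSE]
  if (nrow(de) == 0L) {
    warning("restriction leaves no genes")
    return(stratified_comparison(numeric(0), character(0)))
  }
  fc <- switch(arm, shA = de$log2fc_shA, shB = de$log2fc_shB,
               mean = (de$log2fc_shA + de$log2fc_shB) / 2)
  rid <- map$region_id[match(de$gene, map$gene_id)]
  st <- promoter_states$state[match(rid, promoter_states$region_id)]
  stratified_comparison(fc, st)
}

#' Promoter-state fractions within each DE class
#'
#' Per DE class, the fraction of gene promoters in each chromatin state.
#' Fractions sum to 1 within a class; the unmarked state can be folded in or
#' reported separately.
#'
#' @param promoter_states output of [classify_promoters()].
#' @param de_classes output of [de_pipeline()].
#' @param regions regions table.
#' @param include_unmarked include the unmarked state in the denominator
#'   (default TRUE).
#' @return data.frame: `de_class`, one column per state, `n` genes; empty
#'   classes yield zero rows flagged by `n = 0`.
#' @export
state_fractions_by_class <- function(promoter_states, de_classes, regions,
                                     include_unmarked = TRUE) {
  map <- promoter_gene_map(regions)
  rid <- map$region_id[match(de_classes$gene, map$gene_id)]
  st <- promoter_states$state[match(rid, promoter_states$region_id)]
  states <- c("active", "bivalent", "repressed")
  if (include_unmarked) states <- c(states, "unmarked")
  keep <- st %in% states
  cls <- de_classes$de_class[keep]; st <- st[keep]
  out <- do.call(rbind, lapply(c("up", "down", "neutral"), function(k) {
    sub <- st[cls == k]
    n <- length(sub)
    fr <- if (n) as.numeric(table(factor(sub, levels = states)) / n)
          else rep(0, length(states))
    df <- data.frame(de_class = k, t(fr), n = n, stringsAsFactors = FALSE)
    names(df)[1 + seq_along(states)] <- states
    df
  }))
  rownames(out) <- NULL
  out
}

#' Assign enhancers to their nearest TSS within a distance cap
#'
#' Each enhancer is mapped to the TSS nearest to its midpoint
#' (`floor((start + end)/2)`); ties go to the lower-coordinate TSS;
#' enhancers farther than `max_distance` from every TSS stay unassigned.
#' Also returns the per-gene count of assigned enhancers ("predicted
#' enhancer interactions").
#'
#' @param enhancers data.frame with `region_id`, `start`, `end` (BED
#'   coordinates; must be coordinate-sorted).
#' @param tss data.frame with `gene_id` and `tss` positions.
#' @param max_distance assignment cap in bp (default 100 kb).
#' @return list with `map` (enhancer_id, gene_id, distance; `NA` gene for
#'   unassigned) and `counts` (gene_id, n_enhancers, zeros included).
#' @export
nearest_gene_enhancers <- function(enhancers, tss, max_distance = 1e5) {
  if (is.unsorted(enhancers$start)) stop("enhancers must be sorted by start")
  o <- order(tss$tss, tss$gene_id)
  ts <- tss$tss[o]; tg <- tss$gene_id[o]
  mid <- floor((enhancers$start + enhancers$end) / 2)
  idx <- findInterval(mid, ts)
  n <- length(ts)
  gene <- rep(NA_character_, length(mid)); dist <- rep(NA_real_, length(mid))
  for (k in seq_along(mid)) {
    lo <- idx[k]; hi <- lo + 1L
    d_lo <- if (lo >= 1L) mid[k] - ts[lo] else Inf
    d_hi <- if (hi <= n) ts[hi] - mid[k] else Inf
    ## tie -> lower coordinate TSS wins
    j <- if (d_lo <= d_hi) lo else hi
    d <- min(d_lo, d_hi)
    if (is.finite(d) && d <= max_distance) { gene[k] <- tg[j]; dist[k] <- d }
  }
  counts <- data.frame(
    gene_id = tss$gene_id,
    n_enhancers = as.integer(table(factor(gene, levels = tss$gene_id))),
    stringsAsFactors = FALSE)
  list(map = data.frame(enhancer_id = enhancers$region_id, gene_id = gene,
                        distance = dist, stringsAsFactors = FALSE),
       counts = counts)
}

#' Numeric gene attribute stratified by DE class
#'
#' Generic panel for per-gene attributes such as promoter CpG-island length
#' or predicted enhancer-interaction counts. Genes missing the attribute are
#' excluded and counted in the result's `n_excluded`.
#'
#' @param attributes data.frame with `gene_id` and `value`.
#' @param de_classes output of [de_pipeline()].
#' @return a [stratified_comparison()].
#' @export
attribute_by_class <- function(attributes, de_classes) {
  v <- attributes$value[match(de_classes$gene, attributes$gene_id)]
  stratified_comparison(v, de_classes$de_class, c("up", "down", "neutral"))
}

#' Differentiation-stage expression profiles by DE class
#'
#' Per DE class, the mean log2 expression at each myeloid differentiation
#' stage (ordered immature to mature) and the Spearman correlation of the
#' class-mean profile with the stage index: -1 indicates expression
#' restricted to immature stages and resolved with maturation.
#'
#' @param stage_matrix gene x stage log2 expression matrix, columns ordered
#'   immature to mature.
#' @param de_classes output of [de_pipeline()].
#' @return object of class `stage_profile`: list with `profile` (de_class x
#'   stage means) and `trend` (de_class, spearman, n_genes).
#' @export
stage_profiles_by_class <- function(stage_matrix, de_classes) {
  cls <- de_class_of(de_classes, rownames(stage_matrix))
  classes <- c("up", "down", "neutral")
  prof <- t(vapply(classes, function(k) {
    rows <- stage_matrix[which(cls == k), , drop = FALSE]
    if (nrow(rows) == 0L) rep(NA_real_, ncol(stage_matrix)) else colMeans(rows)
  }, numeric(ncol(stage_matrix))))
  trend <- data.frame(
    de_class = classes,
    spearman = vapply(classes, function(k) {
      m <- prof[k, ]
      if (anyNA(m) || stats::sd(m) == 0) NA_real_
      else stats::cor(m, seq_along(m), method = "spearman")
    }, 0),
    n_genes = vapply(classes, function(k) sum(cls == k, na.rm = TRUE), 0L),
    stringsAsFactors = FALSE)
  rownames(trend) <- NULL
  structure(list(profile = prof, trend = trend,
                 stages = colnames(stage_matrix)),
            class = "stage_profile")
}

#' @export
print.stage_profile <- function(x, ...) {
  cat("Stage-expression profiles (", paste(x$stages, collapse = " -> "),
      ")\n", sep = "")
  print(round(x$profile, 3))
  cat("Spearman trend vs stage index:\n")
  print(x$trend, row.names = FALSE)
  invisible(x)
}
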